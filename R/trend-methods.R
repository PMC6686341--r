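#' @export
print.lek_trend <- function(x, digits = 4, ...) {
  cat("Before/after Poisson trend model",
      if (!is.na(x$lek_id)) sprintf("(lek %s)", x$lek_id) else "", "\n")
  cat(sprintf("  fire year: %d (%d surveys, %s)\n", x$fire_year, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  prefire trend:  %+.*f per year (SE %.4f)\n", digits,
              x$pre_slope, x$pre_slope_se))
  if (x$post_extirpated)
    cat("  postfire trend: not estimable (all postfire counts zero)\n")
  else
    cat(sprintf("  postfire trend: %+.*f per year (SE %.4f)\n", digits,
                x$post_slope, x$post_slope_se))
  invisible(x)
}

#' @export
coef.lek_trend <- function(object, ...) object$coefficients

#' @export
vcov.lek_trend <- function(object, ...) object$vcov

#' Summary of a fitted lek trend model
#'
#' @param object a [lek_trend()] fit.
#' @param ... unused.
#' @return Object of class `summary.lek_trend` with a Wald coefficient table
#'   (z statistics and two-sided p-values), the derived pre/postfire slopes
#'   with standard errors, and deviance information.
#' @export
summary.lek_trend <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, pre_slope = object$pre_slope,
                 post_slope = object$post_slope,
                 pre_slope_se = object$pre_slope_se,
                 post_slope_se = object$post_slope_se,
                 deviance = object$deviance,
                 null_deviance = object$null_deviance,
                 n_obs = object$n_obs, lek_id = object$lek_id,
                 converged = object$converged,
                 post_extirpated = object$post_extirpated),
            class = "summary.lek_trend")
}

#' @export
print.summary.lek_trend <- function(x, ...) {
  cat("Before/after Poisson trend model\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nPrefire slope:  %+.4f (SE %.4f)\n", x$pre_slope,
              x$pre_slope_se))
  if (x$post_extirpated)
    cat("Postfire slope: not estimable (all postfire counts zero)\n")
  else
    cat(sprintf("Postfire slope: %+.4f (SE %.4f)\n", x$post_slope,
                x$post_slope_se))
  cat(sprintf("Deviance: %.3f on %d obs (null %.3f)\n", x$deviance,
              x$n_obs, x$null_deviance))
  invisible(x)
}

# design row(s) for given years
trend_design <- function(object, year) {
  x1 <- year - object$fire_year
  x2 <- as.numeric(if (object$fire_year_is_post) year >= object$fire_year
                   else year > object$fire_year)
  cbind(1, x1, x2, x1 * x2)
}

#' Predict expected male counts
#'
#' @param object a [lek_trend()] fit.
#' @param newdata optional data.frame with a `year` column; defaults to the
#'   fitted years.
#' @param type `"response"` (expected count, default) or `"link"` (log
#'   scale).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lek_trend <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  year <- if (is.null(newdata)) object$data$year else newdata$year
  eta <- drop(trend_design(object, year) %*% object$coefficients)
  if (type == "response") exp(eta) else eta
}

#' @export
fitted.lek_trend <- function(object, ...) predict(object)

#' Residuals of a lek trend fit
#'
#' @param object a [lek_trend()] fit.
#' @param type `"deviance"` (default), `"pearson"` or `"response"`.
#' @param ... unused.
#' @return Numeric vector of residuals.
#' @export
residuals.lek_trend <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  y <- object$data$males
  mu <- fitted(object)
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d2 <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(d2, 0))
         })
}

#' Simulate count series from a fitted trend model
#'
#' @param object a [lek_trend()] fit.
#' @param nsim number of replicate series.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with one column per replicate, rows matching the
#'   fitted years.
#' @export
simulate.lek_trend <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$data$year
  out
}

#' Plot observed counts with the fitted pre- and postfire trend segments
#'
#' Reproduces the standard one-panel trend display: observed yearly peak male
#' counts, a vertical mark at the fire year, and the two fitted exponential
#' trend segments (prefire and postfire).
#'
#' @param x a [lek_trend()] fit.
#' @param main plot title (defaults to the lek id).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lek_trend <- function(x, main = NULL, ...) {
  d <- x$data
  if (is.null(main))
    main <- if (!is.na(x$lek_id)) paste("Lek", x$lek_id) else "Lek trend"
  graphics::plot(d$year, d$males, pch = 16, xlab = "Year",
                 ylab = "Peak male count", main = main, ...)
  graphics::abline(v = x$fire_year - 0.5, lty = 3, col = "firebrick")
  pre_years <- seq(min(d$year), x$fire_year, by = 0.1)
  post_years <- seq(x$fire_year, max(d$year), by = 0.1)
  b <- x$coefficients
  graphics::lines(pre_years, exp(b[1] + b[2] * (pre_years - x$fire_year)),
                  lwd = 2, col = "steelblue")
  if (!x$post_extirpated) {
    xp <- post_years - x$fire_year
    graphics::lines(post_years, exp(b[1] + b[3] + (b[2] + b[4]) * xp),
                    lwd = 2, col = "firebrick")
  }
  invisible(x)
}

#' Wald confidence intervals for the trend model
#'
#' @param object a [lek_trend()] fit.
#' @param parm coefficients to include (default all four plus the two
#'   slopes).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return Matrix of lower/upper bounds; rows include `pre_slope` and
#'   `post_slope`.
#' @export
confint.lek_trend <- function(object, parm = NULL, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(object$coefficients, pre_slope = object$pre_slope,
           post_slope = object$post_slope)
  se <- c(object$se, pre_slope = object$pre_slope_se,
          post_slope = object$post_slope_se)
  out <- cbind(lower = est - q * se, upper = est + q * se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}
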