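#' Apply the lek inclusion criteria
#'
#' A lek enters the trend analysis only if it (a) falls in one of the four
#' fire categories (not `outside`), (b) was surveyed in at least
#' `min_years` (default 6) distinct years, (c) has at least two counts before
#' and two counts after the fire year, and (d) was not already extirpated
#' before the fire — its two most recent prefire surveys are not both zero.
#' The reported exclusion reason is the first failing criterion in (a)-(d)
#' order.
#'
#' @param counts long data.frame `lek_id, year, males`.
#' @param assignments output of [classify_leks()] (columns `lek_id`,
#'   `category`, `burn_year`).
#' @param min_years minimum number of surveyed years (criterion b).
#' @param fire_year_is_post if `TRUE` (default) the fire year itself counts
#'   as postfire.
#' @param zero_rule criterion (d) variant: `"last_two"` (default; the two
#'   most recent prefire surveys are not both zero) or `"any_two"` (no two
#'   consecutive prefire surveys are both zero).
#' @return data.frame, one row per lek: `lek_id`, `category`, `fire_year`,
#'   `included` (logical), `reason` (`"ok"` or `"a"`..`"d"`), `n_years`,
#'   `n_pre`, `n_post`.
#' @export
filter_leks <- function(counts, assignments, min_years = 6,
                        fire_year_is_post = TRUE,
                        zero_rule = c("last_two", "any_two")) {
  zero_rule <- match.arg(zero_rule)
  missing_leks <- setdiff(unique(counts$lek_id), assignments$lek_id)
  if (length(missing_leks))
    stop("no fire-category assignment for lek(s): ",
         paste(missing_leks, collapse = ", "))
  out <- lapply(unique(counts$lek_id), function(id) {
    cc <- counts[counts$lek_id == id, , drop = FALSE]
    cc <- cc[order(cc$year), , drop = FALSE]
    a <- assignments[assignments$lek_id == id, , drop = FALSE][1, ]
    fy <- a$burn_year
    post <- if (fire_year_is_post) cc$year >= fy else cc$year > fy
    n_pre <- sum(!post); n_post <- sum(post)
    pre_counts <- cc$males[!post]
    reason <-
      if (is.na(a$category) || a$category == "outside") "a"
      else if (length(unique(cc$year)) < min_years) "b"
      else if (is.na(fy) || n_pre < 2 || n_post < 2) "c"
      else if (zero_rule == "last_two" &&
               all(utils::tail(pre_counts, 2) == 0)) "d"
      else if (zero_rule == "any_two" && length(pre_counts) >= 2 &&
               any(pre_counts[-1] == 0 & pre_counts[-length(pre_counts)] == 0))
        "d"
      else "ok"
    data.frame(lek_id = id, category = a$category,
               fire_year = if (reason %in% c("a")) NA_integer_ else fy,
               included = reason == "ok", reason = reason,
               n_years = length(unique(cc$year)),
               n_pre = n_pre, n_post = n_post)
  })
  do.call(rbind, out)
}

#' Fit the before/after interaction Poisson trend model for one lek
#'
#' Maximum-likelihood fit of
#' \deqn{E(\ln Y) = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1 X_2}
#' to a lek's yearly peak male counts, where \eqn{X_1} is the survey year
#' (centred internally on the fire year for conditioning; the slopes are
#' invariant to this shift) and \eqn{X_2} the postfire indicator. The prefire
#' male attendance trend is \eqn{\beta_1} and the postfire trend
#' \eqn{\beta_1 + \beta_3}, both on the log scale per year.
#'
#' Fitting is by iteratively reweighted least squares on the log link:
#' starting from \eqn{\beta = (\log(\bar y + 0.5), 0, 0, 0)}, each step
#' solves the weighted least-squares problem by QR decomposition, with step
#' halving whenever the deviance would increase, until the relative deviance
#' change falls below `tol` or `max_iter` iterations.
#'
#' If every postfire count is zero the postfire level is unbounded below and
#' the postfire slope has no finite maximum-likelihood estimate; the fit is
#' returned with `post_slope = NA`, flagged `post_extirpated = TRUE`, and a
#' warning (such leks are reported, not silently dropped, and are excluded
#' from the habitat-averaging stage).
#'
#' @param counts data.frame with columns `year` and `males` for one lek.
#' @param fire_year calendar year of the fire.
#' @param lek_id optional identifier carried into the result.
#' @param fire_year_is_post if `TRUE` (default) the fire-year count is
#'   postfire.
#' @param tol relative deviance-change convergence tolerance (default 1e-10).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return An object of class `lek_trend` with components `coefficients`
#'   (beta0..beta3), `se`, `vcov`, `pre_slope`, `post_slope`,
#'   `pre_slope_se`, `post_slope_se`, `converged`, `n_obs`, `deviance`,
#'   `null_deviance`, `iterations`, `data`, `fire_year`, `lek_id`,
#'   `post_extirpated`.
#' @seealso [summary.lek_trend()], [predict.lek_trend()],
#'   [plot.lek_trend()], [simulate.lek_trend()]
#' @export
lek_trend <- function(counts, fire_year, lek_id = NA_character_,
                      fire_year_is_post = TRUE, tol = 1e-10, max_iter = 50L) {
  counts <- counts[order(counts$year), , drop = FALSE]
  y <- as.numeric(counts$males)
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  x1 <- counts$year - fire_year
  x2 <- as.numeric(if (fire_year_is_post) counts$year >= fire_year
                   else counts$year > fire_year)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, `x1:x2` = x1 * x2)
  if (qr(X)$rank < 4L)
    stop("design matrix is rank deficient; the lek needs at least two ",
         "distinct prefire and two distinct postfire survey years")
  post_extirpated <- all(y[x2 == 1] == 0)

  fit <- poisson_irls(X, y, tol = tol, max_iter = max_iter)
  beta <- fit$beta
  names(beta) <- c("beta0", "beta1", "beta2", "beta3")
  se <- sqrt(diag(fit$vcov))
  names(se) <- names(beta)
  post_var <- fit$vcov[2, 2] + fit$vcov[4, 4] + 2 * fit$vcov[2, 4]

  obj <- structure(list(
    coefficients = beta, se = se, vcov = fit$vcov,
    pre_slope = unname(beta[2]),
    post_slope = if (post_extirpated) NA_real_ else unname(beta[2] + beta[4]),
    pre_slope_se = unname(se[2]),
    post_slope_se = if (post_extirpated) NA_real_ else sqrt(max(post_var, 0)),
    converged = fit$converged && !post_extirpated,
    iterations = fit$iterations,
    deviance = fit$deviance, null_deviance = fit$null_deviance,
    n_obs = length(y), data = counts, fire_year = fire_year,
    fire_year_is_post = fire_year_is_post,
    lek_id = lek_id, post_extirpated = post_extirpated),
    class = "lek_trend")
  if (post_extirpated)
    warning(sprintf(
      "lek %s: all postfire counts are zero; postfire slope is unbounded and reported as NA",
      lek_id), call. = FALSE)
  obj
}

# Poisson deviance; the y = 0 term contributes only 2*mu
poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

# Core IRLS loop for a log-link Poisson regression (canonical link, so the
# observed and expected information coincide and W = mu)
poisson_irls <- function(X, y, tol = 1e-10, max_iter = 50L) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L))
  eta <- drop(X %*% beta)
  dev <- poisson_deviance(y, exp(eta))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    w <- mu
    qr_fit <- qr(X * sqrt(w))
    beta_new <- qr.coef(qr_fit, z * sqrt(w))
    # step-halving: accept only deviance-decreasing steps; a fully rejected
    # step leaves the iterate unchanged and triggers convergence
    step <- beta_new - beta
    cand <- beta; eta_cand <- eta; dev_cand <- dev
    for (h in 0:25) {
      try_beta <- beta + step / 2^h
      try_eta <- drop(X %*% try_beta)
      if (max(abs(try_eta)) > 700) next
      try_dev <- poisson_deviance(y, exp(try_eta))
      if (is.finite(try_dev) && try_dev <= dev + 1e-12) {
        cand <- try_beta; eta_cand <- try_eta; dev_cand <- try_dev
        break
      }
    }
    beta <- cand; eta <- eta_cand
    rel_change <- abs(dev - dev_cand) / (abs(dev_cand) + 0.1)
    dev <- dev_cand
    if (rel_change < tol) { converged <- TRUE; break }
  }
  mu <- exp(eta)
  XtWX <- crossprod(X * sqrt(mu))
  vc <- tryCatch(solve(XtWX), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  mu0 <- mean(y)
  list(beta = beta, vcov = vc, deviance = dev,
       null_deviance = poisson_deviance(y, rep(mu0, length(y))),
       converged = converged, iterations = iter)
}

#' Fit trend models for every included lek
#'
#' @param counts long data.frame `lek_id, year, males`.
#' @param filters output of [filter_leks()].
#' @param ... passed to [lek_trend()].
#' @return data.frame, one row per included lek, with the coefficients,
#'   standard errors, pre/post slopes and convergence flags; the fitted
#'   `lek_trend` objects are attached as attribute `"fits"`.
#' @export
lek_trends <- function(counts, filters, ...) {
  inc <- filters[filters$included, , drop = FALSE]
  fits <- lapply(seq_len(nrow(inc)), function(i) {
    cc <- counts[counts$lek_id == inc$lek_id[i], c("year", "males")]
    lek_trend(cc, fire_year = inc$fire_year[i], lek_id = inc$lek_id[i], ...)
  })
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    lek_id = f$lek_id,
    beta0 = f$coefficients[1], beta1 = f$coefficients[2],
    beta2 = f$coefficients[3], beta3 = f$coefficients[4],
    se_beta0 = f$se[1], se_beta1 = f$se[2],
    se_beta2 = f$se[3], se_beta3 = f$se[4],
    pre_slope = f$pre_slope, post_slope = f$post_slope,
    pre_slope_se = f$pre_slope_se, post_slope_se = f$post_slope_se,
    converged = f$converged, post_extirpated = f$post_extirpated,
    n_obs = f$n_obs, row.names = NULL)))
  tab$category <- inc$category[match(tab$lek_id, inc$lek_id)]
  attr(tab, "fits") <- fits
  tab
}
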