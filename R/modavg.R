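#' Collinearity screening of candidate predictors
#'
#' Computes the Spearman rank correlation matrix and, from a full ordinary
#' least squares model, the variance inflation factor
#' \eqn{VIF_j = 1/(1 - R^2_j)} of each predictor regressed on all others.
#' Predictors are then reduced to a retained set in which every pair
#' satisfies `|r| < r_max` and every VIF is at most `vif_max`: while the
#' constraint is violated, the predictor with the largest mean absolute
#' correlation to the others (then the largest VIF) is removed. Nothing is
#' dropped silently; the removed predictors and the reason are reported.
#'
#' @param covariates numeric data.frame or matrix of predictors (>= 2
#'   columns, none constant).
#' @param r_max pairwise Spearman correlation limit (default 0.5, exclusive).
#' @param vif_max VIF limit (default 3, inclusive).
#' @return List of class `screening_report`: `spearman` (matrix), `vif`
#'   (named vector; `Inf` for perfectly collinear predictors), `retained`
#'   (character), `dropped` (data.frame with `predictor`, `reason`).
#' @export
screen_collinearity <- function(covariates, r_max = 0.5, vif_max = 3) {
  X <- as.matrix(covariates)
  if (ncol(X) < 2) stop("need at least two predictors to screen")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  rho <- stats::cor(X, method = "spearman")
  vif <- vif_values(X)

  retained <- colnames(X)
  dropped <- list()
  repeat {
    r_sub <- rho[retained, retained, drop = FALSE]
    v_sub <- vif_values(X[, retained, drop = FALSE])
    off <- abs(r_sub); diag(off) <- 0
    bad_r <- max(off) >= r_max
    bad_v <- any(v_sub > vif_max)
    if ((!bad_r && !bad_v) || length(retained) == 1L) break
    if (bad_r) {
      worst_pair <- which(off == max(off), arr.ind = TRUE)[1, ]
      cand <- retained[worst_pair]
      mean_abs <- rowMeans(off[cand, , drop = FALSE])
      drop_this <- cand[which.max(mean_abs)]
      reason <- sprintf("|spearman r| = %.3f with %s", max(off),
                        setdiff(cand, drop_this)[1])
    } else {
      drop_this <- retained[which.max(v_sub)]
      reason <- sprintf("VIF = %.2f > %g", max(v_sub), vif_max)
    }
    dropped[[length(dropped) + 1L]] <-
      data.frame(predictor = drop_this, reason = reason)
    retained <- setdiff(retained, drop_this)
  }
  structure(list(spearman = rho, vif = vif, retained = retained,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(predictor = character(),
                                           reason = character()),
                 r_max = r_max, vif_max = vif_max),
            class = "screening_report")
}

# VIF of each column regressed on the others (QR-based R^2); Inf when the
# column is perfectly explained
vif_values <- function(X) {
  p <- ncol(X)
  if (p < 2) return(stats::setNames(1, colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), yj)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Collinearity screening (|r| < %g, VIF <= %g)\n", x$r_max,
              x$vif_max))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("    %s (%s)\n", x$dropped$predictor[i],
                  x$dropped$reason[i]))
  } else cat("  dropped: none\n")
  invisible(x)
}

#' Standardise predictor columns to mean 0, SD 1
#'
#' @param covariates numeric data.frame or matrix; every column must have
#'   positive standard deviation.
#' @return data.frame of standardised columns with attributes `center` and
#'   `scale` (the original means and SDs).
#' @export
standardize_columns <- function(covariates) {
  X <- as.matrix(covariates)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0))
    stop("cannot standardise constant column(s): ",
         paste(colnames(X)[sd == 0], collapse = ", "))
  out <- as.data.frame(sweep(sweep(X, 2, mu), 2, sd, `/`))
  attr(out, "center") <- mu
  attr(out, "scale") <- sd
  out
}

#' Enumerate the candidate model set
#'
#' Builds every model in which each habitat variable appears at no more than
#' one spatial scale: each variable is either absent or enters at exactly one
#' of its scales, and the intercept-only (all-absent) model is excluded,
#' giving \eqn{(s + 1)^v - 1} models. With the study's three variables and
#' three scales this is the 63-model candidate set. The unconstrained
#' all-subsets alternative (every variable-scale column free to enter,
#' \eqn{2^{vs} - 1} models) is available via `one_scale_per_variable =
#' FALSE`.
#'
#' @param variables character vector of variable stems (default the three
#'   habitat variables).
#' @param scales character vector of scale suffixes (default the three
#'   radii).
#' @param sep separator between stem and suffix in term names (default
#'   `"_"`).
#' @param one_scale_per_variable constrain each variable to one scale
#'   (default TRUE).
#' @return List of character vectors, each the terms of one candidate model.
#' @export
enumerate_candidates <- function(variables = c("veg_height", "cheat_frac",
                                               "elevation"),
                                 scales = c("0.8km", "6.4km", "18km"),
                                 sep = "_",
                                 one_scale_per_variable = TRUE) {
  if (!length(variables) || !length(scales))
    stop("need at least one variable and one scale")
  if (one_scale_per_variable) {
    choices <- c(NA_character_, scales)
    grid <- expand.grid(rep(list(choices), length(variables)),
                        stringsAsFactors = FALSE)
    models <- lapply(seq_len(nrow(grid)), function(i) {
      sel <- as.character(grid[i, ])
      keep <- !is.na(sel)
      if (!any(keep)) return(NULL)
      paste(variables[keep], sel[keep], sep = sep)
    })
    models <- Filter(Negate(is.null), models)
  } else {
    terms <- as.vector(outer(variables, scales, paste, sep = sep))
    models <- lapply(seq_len(2^length(terms) - 1L), function(m) {
      terms[bitwAnd(m, bitwShiftL(1L, seq_along(terms) - 1L)) > 0]
    })
  }
  models
}

#' Fit one candidate model by OLS and score it with AICc
#'
#' Ordinary least squares via QR decomposition, Gaussian log-likelihood with
#' the maximum-likelihood variance \eqn{\hat\sigma^2 = RSS/n}, and
#' \deqn{AICc = -2\log L + 2k + 2k(k+1)/(n - k - 1)}
#' where `k` counts the intercept, the slopes and the residual variance.
#'
#' @param response numeric vector (postfire slopes).
#' @param covariates data.frame holding at least the model's terms.
#' @param terms character vector of predictor columns (may be empty for the
#'   intercept-only model).
#' @return List: `terms`, `k`, `loglik`, `aicc`, `coefficients` (named,
#'   including `(Intercept)`), `se`, `rss`, `n`. `NULL` with a warning when
#'   `n <= k + 1` (the AICc correction is undefined).
#' @export
fit_ols_aicc <- function(response, covariates, terms) {
  y <- as.numeric(response)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(terms)) {
    miss <- setdiff(terms, colnames(covariates))
    if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
    X <- cbind(X, as.matrix(covariates[, terms, drop = FALSE]))
  }
  k <- ncol(X) + 1L  # slopes + intercept + residual variance
  if (n <= k + 1L) {
    warning(sprintf("model {%s} skipped: n = %d too small for k = %d",
                    paste(terms, collapse = ", "), n, k), call. = FALSE)
    return(NULL)
  }
  qr_fit <- qr(X)
  coefs <- qr.coef(qr_fit, y)
  res <- qr.resid(qr_fit, y)
  rss <- sum(res^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  aicc <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  # coefficient covariance with the unbiased residual variance
  p <- ncol(X)
  XtXinv <- chol2inv(qr.R(qr_fit))
  se <- sqrt(diag(XtXinv) * rss / (n - p))
  names(se) <- colnames(X)
  list(terms = terms, k = k, loglik = loglik, aicc = aicc,
       coefficients = coefs, se = se, rss = rss, n = n)
}

#' Akaike weights from AICc values
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AICc_i - \min AICc}; invariant under adding a constant to
#' every AICc.
#'
#' @param aicc numeric vector of finite AICc values.
#' @return Numeric weights summing to 1.
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc) || any(!is.finite(aicc)))
    stop("AICc values must be a nonempty finite vector")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' AICc-weighted model averaging of coefficients
#'
#' Averages each predictor's coefficient over a fitted candidate set using
#' Akaike weights. With `averaging = "full"` (default) a model in which the
#' term is absent contributes a coefficient of 0 with that model's weight
#' (shrinking weakly supported terms toward zero); with `"conditional"` the
#' weights are renormalised over only the models containing the term. The
#' unconditional standard error combines within-model variance and
#' between-model spread; `se_method = "classic"` (default) uses
#' \eqn{SE = \sum_i w_i \sqrt{var_i + (\hat\beta_i - \bar\beta)^2}} and
#' `"revised"` the square-root-of-weighted-mean form
#' \eqn{SE = \sqrt{\sum_i w_i (var_i + (\hat\beta_i - \bar\beta)^2)}}.
#' Confidence limits are normal-quantile symmetric
#' (\eqn{\bar\beta \pm z_{0.975} SE}) and p-values come from the normal
#' approximation.
#'
#' @param fits list of [fit_ols_aicc()] results (NULL entries are removed).
#' @param predictors character vector of terms to average (default: union of
#'   all terms in the set).
#' @param averaging `"full"` (default) or `"conditional"`.
#' @param se_method `"classic"` (default) or `"revised"`.
#' @param level confidence level (default 0.95).
#' @return data.frame, one row per predictor: `predictor`, `estimate`, `se`,
#'   `lower`, `upper`, `p_value`, `n_models` (models containing the term),
#'   `weight_sum` (total weight of those models).
#' @export
model_average <- function(fits, predictors = NULL,
                          averaging = c("full", "conditional"),
                          se_method = c("classic", "revised"),
                          level = 0.95) {
  averaging <- match.arg(averaging)
  se_method <- match.arg(se_method)
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("empty model set")
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  w <- akaike_weights(aicc)
  if (is.null(predictors))
    predictors <- unique(unlist(lapply(fits, `[[`, "terms")))
  q <- stats::qnorm(1 - (1 - level) / 2)

  out <- lapply(predictors, function(term) {
    beta_i <- vapply(fits, function(f)
      if (term %in% f$terms) unname(f$coefficients[term]) else 0, numeric(1))
    var_i <- vapply(fits, function(f)
      if (term %in% f$terms) unname(f$se[term])^2 else 0, numeric(1))
    present <- vapply(fits, function(f) term %in% f$terms, logical(1))
    if (!any(present))
      stop("predictor '", term, "' appears in no model")
    if (averaging == "full") {
      wt <- w
      est <- sum(wt * beta_i)
      spread <- (beta_i - est)^2
    } else {
      wt <- w[present] / sum(w[present])
      beta_i <- beta_i[present]; var_i <- var_i[present]
      est <- sum(wt * beta_i)
      spread <- (beta_i - est)^2
    }
    se <- if (se_method == "classic") sum(wt * sqrt(var_i + spread))
          else sqrt(sum(wt * (var_i + spread)))
    data.frame(predictor = term, estimate = est, se = se,
               lower = est - q * se, upper = est + q * se,
               p_value = 2 * stats::pnorm(-abs(est) / se),
               n_models = sum(present), weight_sum = sum(w[present]))
  })
  do.call(rbind, out)
}

#' Explain postfire trends by AICc multimodel averaging
#'
#' The one-call interface for the habitat-composition inference: standardises
#' the covariates, enumerates the one-scale-per-variable candidate models,
#' fits each by OLS, ranks them by AICc and returns the weight-averaged
#' coefficients. Covariates are assumed already screened for collinearity
#' (run [screen_collinearity()] beforehand if the set is larger than the
#' three habitat variables).
#'
#' @param response numeric vector of postfire slopes (one per lek).
#' @param covariates data.frame of habitat covariates (columns named
#'   `<variable><sep><scale>`); standardised internally unless
#'   `standardize = FALSE`.
#' @param variables,scales,sep passed to [enumerate_candidates()].
#' @param one_scale_per_variable see [enumerate_candidates()].
#' @param averaging,se_method,level see [model_average()].
#' @param standardize standardise covariates to mean 0, SD 1 (default TRUE).
#' @return Object of class `lek_modavg`: list with `average` (the averaged
#'   coefficient table), `models` (ranked model table with terms, k, logLik,
#'   AICc, delta and weight), `fits`, `response`, `covariates`, `averaging`,
#'   `se_method`.
#' @export
aicc_average <- function(response, covariates,
                         variables = c("veg_height", "cheat_frac",
                                       "elevation"),
                         scales = c("0.8km", "6.4km", "18km"),
                         sep = "_",
                         one_scale_per_variable = TRUE,
                         averaging = c("full", "conditional"),
                         se_method = c("classic", "revised"),
                         level = 0.95, standardize = TRUE) {
  averaging <- match.arg(averaging)
  se_method <- match.arg(se_method)
  terms_all <- as.vector(outer(variables, scales, paste, sep = sep))
  miss <- setdiff(terms_all, colnames(covariates))
  if (length(miss))
    stop("covariates lack column(s): ", paste(miss, collapse = ", "))
  Z <- covariates[, terms_all, drop = FALSE]
  if (standardize) Z <- standardize_columns(Z)
  models <- enumerate_candidates(variables, scales, sep,
                                 one_scale_per_variable)
  fits <- lapply(models, function(tt) fit_ols_aicc(response, Z, tt))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no fittable candidate model (n too small)")
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  w <- akaike_weights(aicc)
  ord <- order(aicc)
  model_tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "1",
      character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = aicc, delta = aicc - min(aicc), weight = w)[ord, ]
  rownames(model_tab) <- NULL
  avg <- model_average(fits, predictors = terms_all, averaging = averaging,
                       se_method = se_method, level = level)
  structure(list(average = avg, models = model_tab, fits = fits,
                 response = response, covariates = Z,
                 averaging = averaging, se_method = se_method,
                 level = level),
            class = "lek_modavg")
}

#' @export
print.lek_modavg <- function(x, digits = 4, ...) {
  cat(sprintf(
    "AICc model averaging (%d models, %s averaging, n = %d leks)\n\n",
    nrow(x$models), x$averaging, length(x$response)))
  tab <- x$average
  tab[, c("estimate", "se", "lower", "upper", "p_value")] <-
    round(tab[, c("estimate", "se", "lower", "upper", "p_value")], digits)
  print(tab[, c("predictor", "estimate", "se", "lower", "upper", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.lek_modavg <- function(object, n_top = 5, ...) {
  cat(sprintf("Candidate set: %d models; top %d by AICc:\n",
              nrow(object$models), n_top))
  print(utils::head(object$models, n_top), row.names = FALSE, digits = 4)
  cat("\nModel-averaged coefficients:\n")
  print(object)
  invisible(object)
}

#' @export
coef.lek_modavg <- function(object, ...) {
  stats::setNames(object$average$estimate, object$average$predictor)
}

#' @export
confint.lek_modavg <- function(object, parm = NULL, level = NULL, ...) {
  avg <- object$average
  if (!is.null(level) && level != object$level) {
    q <- stats::qnorm(1 - (1 - level) / 2)
    avg$lower <- avg$estimate - q * avg$se
    avg$upper <- avg$estimate + q * avg$se
  }
  out <- as.matrix(avg[, c("lower", "upper")])
  rownames(out) <- avg$predictor
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Dot-and-interval plot of model-averaged coefficients
#'
#' Coefficients whose confidence interval excludes zero are drawn filled
#' (statistically significant effect on the postfire trend); intervals
#' overlapping zero are drawn grey.
#'
#' @param x a [aicc_average()] result.
#' @param ... unused.
#' @export
plot.lek_modavg <- function(x, ...) {
  avg <- x$average
  k <- nrow(avg)
  sig <- avg$lower > 0 | avg$upper < 0
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  ypos <- rev(seq_len(k))  # first predictor on top
  graphics::plot(avg$estimate, ypos,
                 xlim = range(avg$lower, avg$upper, 0),
                 ylim = c(0.5, k + 0.5), pch = ifelse(sig, 16, 21),
                 col = ifelse(sig, "black", "grey50"),
                 bg = "white", yaxt = "n", xlab = "Standardised coefficient",
                 ylab = "", main = "Model-averaged habitat effects")
  graphics::segments(avg$lower, ypos, avg$upper, ypos,
                     col = ifelse(sig, "black", "grey50"), lwd = 2)
  graphics::axis(2, at = ypos, labels = avg$predictor, las = 1,
                 cex.axis = 0.8)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
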