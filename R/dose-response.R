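#' Construct a fibrosis-index dose-response model
#'
#' The FI-model is a deterministic probit-type sigmoid for the mean fibrosis
#' index of a population as a function of total dose:
#' \deqn{FI(D) = \tfrac{1}{2} A \{ 1 - \mathrm{erf}(\sqrt{\pi}\,\gamma\,(1 - D/ED_{50})) \}}
#' where `A` is the saturation constant (maximal attainable FI), `ed50` the
#' dose giving half-maximal FI, and `gamma` the maximum normalized
#' dose-response gradient (steepness). The model is deterministic: it describes
#' the mean FI of a group, not an incidence probability.
#'
#' @param A saturation constant, FI units; must be > 0. Default 7.20.
#' @param ed50 dose at half-maximal fibrosis, Gy; must be > 0.
#' @param gamma normalized dose-response gradient (dimensionless); must be > 0.
#' @param a_fixed logical; whether `A` was fixed rather than fitted.
#' @param se named numeric vector of standard errors for free parameters
#'   (may be `NULL` for a truth model).
#' @param adj_r2 adjusted R-squared of the fit (`NA` for a truth model).
#' @param n number of observations behind the fit (`NA` for a truth model).
#' @return An object of class `fi_model_fit`.
#' @seealso [predict_fi()], [inverse_dose()], [fit_fi_model()]
#' @export
fi_model <- function(A = 7.20, ed50, gamma, a_fixed = TRUE, se = NULL,
                     adj_r2 = NA_real_, n = NA_integer_) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(ed50), length(ed50) == 1L, is.finite(ed50),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (A <= 0) stop("saturation constant 'A' must be positive")
  if (ed50 <= 0) stop("'ed50' must be positive")
  if (gamma <= 0) stop("'gamma' must be positive")
  structure(
    list(A = A, ed50 = ed50, gamma = gamma, a_fixed = isTRUE(a_fixed),
         se = se, adj_r2 = adj_r2, n = n),
    class = "fi_model_fit"
  )
}

#' @export
print.fi_model_fit <- function(x, ...) {
  cat("FI-model (probit-type sigmoid)\n")
  cat(sprintf("  A     = %.4f FI units%s\n", x$A,
              if (x$a_fixed) " (fixed)" else ""))
  fmt <- function(par, name) {
    se <- if (!is.null(x$se) && name %in% names(x$se)) {
      sprintf(" ± %.4f", x$se[[name]])
    } else ""
    sprintf("%.4f%s", par, se)
  }
  cat(sprintf("  ED50  = %s Gy\n", fmt(x$ed50, "ed50")))
  cat(sprintf("  gamma = %s\n", fmt(x$gamma, "gamma")))
  if (!is.na(x$adj_r2)) cat(sprintf("  adj. R2 = %.4f (n = %d)\n", x$adj_r2, x$n))
  invisible(x)
}

#' Predict the fibrosis index at a total dose
#'
#' Evaluates the FI-model sigmoid. Strictly increasing in dose and bounded in
#' (0, A); at `D = ed50` it returns exactly `A / 2`.
#'
#' @param fit an `fi_model_fit` from [fi_model()] or [fit_fi_model()].
#' @param total_dose numeric vector of total doses, Gy.
#' @return Numeric vector of predicted FI values.
#' @examples
#' truth <- fi_model(A = 7.20, ed50 = 14.55, gamma = 1.64)
#' predict_fi(truth, c(0, 14.55, 20))
#' @export
predict_fi <- function(fit, total_dose) {
  stopifnot(inherits(fit, "fi_model_fit"), is.numeric(total_dose),
            all(is.finite(total_dose)))
  fi_curve(total_dose, A = fit$A, ed50 = fit$ed50, gamma = fit$gamma)
}

# sigmoid kernel shared by prediction and fitting
fi_curve <- function(D, A, ed50, gamma) {
  0.5 * A * (1 - pracma::erf(sqrt(pi) * gamma * (1 - D / ed50)))
}

#' Invert the FI-model: dose producing a given fibrosis index
#'
#' Closed-form inverse of [predict_fi()]:
#' \deqn{D(FI) = ED_{50}\left[1 - \mathrm{erf}^{-1}(1 - 2\,FI/A) / (\sqrt{\pi}\,\gamma)\right]}
#' Defined for `0 < fi < A`; the midpoint `fi = A/2` maps back to `ed50`.
#'
#' @param fit an `fi_model_fit`.
#' @param fi numeric vector of fibrosis-index values, each strictly inside
#'   `(0, A)`.
#' @return Numeric vector of total doses, Gy.
#' @export
inverse_dose <- function(fit, fi) {
  stopifnot(inherits(fit, "fi_model_fit"), is.numeric(fi), all(is.finite(fi)))
  if (any(fi <= 0) || any(fi >= fit$A)) {
    stop(sprintf("'fi' must lie strictly inside (0, A = %.4g)", fit$A))
  }
  fit$ed50 * (1 - pracma::erfinv(1 - 2 * fi / fit$A) / (sqrt(pi) * fit$gamma))
}

#' Fit the FI-model to dose / fibrosis-index data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the probit-type sigmoid.
#' By default the saturation constant `A` is held fixed (it is an empirical
#' ceiling determined outside the fit) and only `ed50` and `gamma` are free;
#' pass `fix_a = NULL` to fit all three parameters.
#'
#' Initialization is deterministic: the starting `ed50` is the linear
#' interpolation of the dose at which group-mean FI crosses `A/2` (falling back
#' to the median nonzero dose when the data do not cross), and the starting
#' `gamma` is 1. Bounds are `ed50` in (0, 10 * max dose] and `gamma` in (0, 20].
#'
#' @param doses numeric vector of total doses, Gy (per animal or per group).
#' @param fis numeric vector of observed FI values, same length, all >= 0.
#' @param fix_a value at which to fix `A` (default 7.20), or `NULL` to fit `A`.
#' @param group_means logical; if `TRUE`, collapse observations to dose-level
#'   means before fitting (unweighted per-animal fitting is the default).
#' @return An `fi_model_fit` with parameter standard errors (from the fit
#'   covariance) and adjusted R-squared.
#' @export
fit_fi_model <- function(doses, fis, fix_a = 7.20, group_means = FALSE) {
  stopifnot(is.numeric(doses), is.numeric(fis), length(doses) == length(fis),
            all(is.finite(doses)), all(is.finite(fis)))
  if (any(fis < 0)) stop("FI values must be non-negative")
  if (isTRUE(group_means)) {
    mu <- tapply(fis, doses, mean)
    doses <- as.numeric(names(mu))
    fis <- as.numeric(mu)
  }
  n_levels <- length(unique(doses))
  n_free <- if (is.null(fix_a)) 3L else 2L
  if (n_levels < max(3L, n_free + 1L)) {
    stop("need at least ", max(3L, n_free + 1L), " distinct dose levels")
  }
  if (max(fis) <= 0 || stats::sd(fis) == 0) {
    stop("no dose-response signal in FI values (constant or all-zero input)")
  }

  A0 <- if (is.null(fix_a)) max(fis) * 1.05 else fix_a
  ed50_0 <- init_ed50(doses, fis, A0)
  upper_ed50 <- 10 * max(doses)

  if (is.null(fix_a)) {
    form <- fis ~ fi_curve(doses, A, ed50, gamma)
    start <- list(A = A0, ed50 = ed50_0, gamma = 1)
    lower <- c(A = 1e-6, ed50 = 1e-6, gamma = 1e-6)
    upper <- c(A = Inf, ed50 = upper_ed50, gamma = 20)
  } else {
    A <- fix_a
    form <- fis ~ fi_curve(doses, A, ed50, gamma)
    start <- list(ed50 = ed50_0, gamma = 1)
    lower <- c(ed50 = 1e-6, gamma = 1e-6)
    upper <- c(ed50 = upper_ed50, gamma = 20)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("FI-model fit failed to converge: ",
                             conditionMessage(e))
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, length(est)), names(est))
  })
  A_hat <- if (is.null(fix_a)) est[["A"]] else fix_a
  pred <- fi_curve(doses, A_hat, est[["ed50"]], est[["gamma"]])
  fi_model(
    A = A_hat, ed50 = est[["ed50"]], gamma = est[["gamma"]],
    a_fixed = !is.null(fix_a), se = se,
    adj_r2 = adjusted_r2(fis, pred, n_free),
    n = length(fis)
  )
}

# dose at which group-mean FI first crosses A/2, by linear interpolation;
# falls back to the median nonzero dose when there is no crossing
init_ed50 <- function(doses, fis, A) {
  mu <- tapply(fis, doses, mean)
  d <- as.numeric(names(mu))
  ord <- order(d)
  d <- d[ord]; mu <- as.numeric(mu)[ord]
  half <- A / 2
  above <- which(mu >= half)
  if (length(above) == 0L || above[1] == 1L) {
    fallback <- stats::median(d[d > 0])
    return(if (is.finite(fallback) && fallback > 0) fallback else max(d) / 2)
  }
  i <- above[1]
  d[i - 1] + (half - mu[i - 1]) / (mu[i] - mu[i - 1]) * (d[i] - d[i - 1])
}

#' Adjusted R-squared for a (nonlinear) least-squares fit
#'
#' Uses the residual-versus-total convention:
#' `R2 = 1 - SSres/SStot`, `adjusted = 1 - (1 - R2)(n - 1)/(n - p - 1)` with
#' `p` free parameters. Stated explicitly because no single convention exists
#' for nonlinear fits.
#'
#' @param observed numeric vector of observations.
#' @param predicted numeric vector of fitted values, same length.
#' @param n_free_params number of free parameters `p` of the fit.
#' @return Adjusted R-squared (can be negative for fits worse than the mean).
#' @export
adjusted_r2 <- function(observed, predicted, n_free_params) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted),
            n_free_params >= 0)
  n <- length(observed)
  if (n < n_free_params + 2L) stop("need at least n_free_params + 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero total variance: R-squared undefined")
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_free_params - 1)
}
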