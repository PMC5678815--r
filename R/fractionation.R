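#' Dose schedule
#'
#' @param n_fractions number of (daily) fractions.
#' @param dose_per_fraction_gy dose per fraction d, Gy.
#' @param total_dose_gy total dose D, Gy; must equal `n * d` (checked to
#'   1e-9); derived when omitted.
#' @return An object of class `schedule` with fields `n`, `d`, `D`.
#' @export
schedule <- function(n_fractions, dose_per_fraction_gy,
                     total_dose_gy = n_fractions * dose_per_fraction_gy) {
  stopifnot(n_fractions >= 1, dose_per_fraction_gy > 0, total_dose_gy > 0)
  if (abs(total_dose_gy - n_fractions * dose_per_fraction_gy) > 1e-9) {
    stop(sprintf("inconsistent schedule: total %.6g Gy != %d x %.6g Gy",
                 total_dose_gy, as.integer(n_fractions), dose_per_fraction_gy))
  }
  structure(list(n = as.integer(n_fractions), d = dose_per_fraction_gy,
                 D = total_dose_gy), class = "schedule")
}

#' Fractionation sensitivity from one isoeffective pair of schedules
#'
#' Two schedules `(D1, d1)` and `(D2, d2)` producing the same biological
#' effect have equal biologically effective dose, `D1(1 + d1/(a/b)) =
#' D2(1 + d2/(a/b))`; solving for the ratio gives
#' \deqn{\alpha/\beta = (D_2 d_2 - D_1 d_1) / (D_1 - D_2).}
#'
#' With `d1 = d2` the isoeffect equality forces `D1 = D2` within the model;
#' real data violating this return `-d`, which is outside the model's
#' assumptions and is flagged with a warning.
#'
#' @param D1,d1 total dose and dose per fraction of the first schedule, Gy.
#' @param D2,d2 the same for the second schedule.
#' @return alpha/beta ratio, Gy.
#' @examples
#' alpha_beta_from_pair(14.55, 14.55, 27.7, 5.54)
#' @export
alpha_beta_from_pair <- function(D1, d1, D2, d2) {
  stopifnot(is.numeric(D1), is.numeric(d1), is.numeric(D2), is.numeric(d2))
  if (isTRUE(all(abs(D1 - D2) < 1e-12))) {
    stop("degenerate pair: D1 = D2 gives no fractionation contrast")
  }
  if (isTRUE(all(abs(d1 - d2) < 1e-12))) {
    warning("d1 = d2: schedules differ only in total dose; ",
            "the returned value (-d) is outside the isoeffect model")
  }
  (D2 * d2 - D1 * d1) / (D1 - D2)
}

#' alpha/beta profile across fibrosis-index levels
#'
#' For each FI level on the grid, obtains the isoeffective total doses of the
#' two arms from the inverse FI-model, then applies the isoeffect formula.
#' The profile shows how the apparent fractionation sensitivity varies with
#' the severity of the endpoint; its grid-wise mean and SD summarize it.
#'
#' @param fit_1fx FI-model of the single-fraction arm.
#' @param fit_nfx FI-model of the fractionated arm.
#' @param n_fractions number of fractions of the second arm.
#' @param fi_grid FI levels; default 0.05 to 7.15 by 0.05, truncated to lie
#'   strictly below both saturation constants.
#' @return Data frame (class `alpha_beta_profile`) with columns `fi`,
#'   `d1_gy`, `d2_gy` (doses per fraction), `D1_gy`, `D2_gy` (total doses)
#'   and `alpha_beta_gy`; attributes `mean_alpha_beta` and `sd_alpha_beta`
#'   carry the grid summary.
#' @export
alpha_beta_profile <- function(fit_1fx, fit_nfx, n_fractions = 5L,
                               fi_grid = seq(0.05, 7.15, by = 0.05)) {
  stopifnot(inherits(fit_1fx, "fi_model_fit"), inherits(fit_nfx, "fi_model_fit"),
            n_fractions >= 2)
  a_max <- min(fit_1fx$A, fit_nfx$A)
  if (any(fi_grid <= 0) || any(fi_grid >= a_max)) {
    stop(sprintf("FI grid must lie strictly inside (0, %.4g)", a_max))
  }
  D1 <- inverse_dose(fit_1fx, fi_grid)
  D2 <- inverse_dose(fit_nfx, fi_grid)
  d2 <- D2 / n_fractions
  ab <- (D2 * d2 - D1 * D1) / (D1 - D2)
  out <- data.frame(fi = fi_grid, d1_gy = D1, d2_gy = d2,
                    D1_gy = D1, D2_gy = D2, alpha_beta_gy = ab)
  attr(out, "mean_alpha_beta") <- mean(ab)
  attr(out, "sd_alpha_beta") <- stats::sd(ab)
  class(out) <- c("alpha_beta_profile", "data.frame")
  out
}

#' Fe plot: reciprocal total isoeffect dose versus dose per fraction
#'
#' Under the linear-quadratic model, isoeffective schedules satisfy
#' `1/D = (alpha + beta d) / E`, so the reciprocal total dose is exactly
#' linear in the dose per fraction and alpha/beta is the intercept/slope
#' ratio of the ordinary least-squares line.
#'
#' @param d numeric vector of doses per fraction, Gy (>= 2 distinct values).
#' @param D_total numeric vector of isoeffective total doses, Gy.
#' @return An object of class `fe_plot_fit` with `slope`, `intercept`,
#'   `alpha_beta`, the fitted `lm` object and the input points.
#' @examples
#' fe_plot(c(14.55, 5.54), c(14.55, 27.7))
#' @export
fe_plot <- function(d, D_total) {
  stopifnot(is.numeric(d), is.numeric(D_total), length(d) == length(D_total),
            all(D_total > 0))
  if (length(unique(d)) < 2L) {
    stop("rank-deficient Fe plot: need at least two distinct doses per fraction")
  }
  recip <- 1 / D_total
  fit <- stats::lm(recip ~ d)
  coefs <- stats::coef(fit)
  structure(
    list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
         alpha_beta = unname(coefs[1] / coefs[2]),
         lm = fit, points = data.frame(d = d, D_total = D_total)),
    class = "fe_plot_fit"
  )
}

#' Linear-quadratic fit on transformed fibrosis-index data
#'
#' Fits the LQ effect model with a free intercept to a transformed response:
#' `y = c - (alpha * D + beta * d * D)` where the default transform is
#' `-log10(FI)` (FI decreasing in effect once negated, so fibrosis increases
#' with LQ effect). FI values below `fi_floor` are floored before the log.
#' The link between the transform and the LQ effect is a modelling
#' convention; the ratio `alpha/beta` is invariant to the log base and is
#' the contract-level output.
#'
#' @param D numeric vector of total doses, Gy.
#' @param d numeric vector of doses per fraction, Gy (needs >= 2 distinct
#'   values to separate alpha from beta).
#' @param fis numeric vector of FI values.
#' @param transform function applied to the floored FI; default
#'   `function(fi) -log10(fi)`.
#' @param fi_floor lower floor applied to FI before the transform;
#'   default 0.05.
#' @return An object of class `lq_fit` with `alpha` (1/Gy), `beta` (1/Gy^2),
#'   `intercept`, `alpha_beta` (Gy) and the underlying `lm`.
#' @export
fit_lq <- function(D, d, fis, transform = function(fi) -log10(fi),
                   fi_floor = 0.05) {
  stopifnot(is.numeric(D), is.numeric(d), is.numeric(fis),
            length(D) == length(d), length(D) == length(fis))
  if (length(unique(paste(D, d))) < 3L) {
    stop("need at least 3 distinct schedules to fit the LQ model")
  }
  if (length(unique(d)) < 2L) {
    stop("collinear design: a single dose per fraction cannot separate ",
         "alpha from beta")
  }
  fi_f <- pmax(fis, fi_floor)
  if (any(fi_f <= 0)) stop("non-positive FI after flooring")
  y <- transform(fi_f)
  dD <- d * D
  fit <- stats::lm(y ~ D + dD)
  coefs <- stats::coef(fit)
  alpha <- -unname(coefs["D"])
  beta <- -unname(coefs["dD"])
  structure(
    list(alpha = alpha, beta = beta, intercept = unname(coefs[1]),
         alpha_beta = alpha / beta, lm = fit),
    class = "lq_fit"
  )
}

#' Isoeffect curve across fraction numbers
#'
#' For each fraction number `n`, solves the BED-equality quadratic
#' `n d (1 + d/(a/b)) = D_ref (1 + d_ref/(a/b))` for the dose per fraction
#' `d` (positive root), giving the schedule isoeffective with the reference.
#' Reflects the classic sparing property: as `n` grows, `d` falls and the
#' total dose `D` rises.
#'
#' @param alpha_beta fractionation sensitivity, Gy (> 0).
#' @param reference a [schedule()] defining the isoeffect level.
#' @param n_list integer vector of fraction numbers.
#' @return Data frame with columns `n`, `d_gy`, `D_gy`.
#' @export
isoeffect_curve <- function(alpha_beta, reference, n_list) {
  stopifnot(alpha_beta > 0, inherits(reference, "schedule"),
            all(n_list >= 1))
  E <- reference$D * (1 + reference$d / alpha_beta) # reference BED
  d <- vapply(n_list, function(n) {
    disc <- 1 + 4 * E / (n * alpha_beta)
    if (disc < 0) stop("no positive root for n = ", n)
    alpha_beta * (-1 + sqrt(disc)) / 2
  }, numeric(1))
  if (any(d <= 0)) stop("no positive root: isoeffect dose not attainable")
  data.frame(n = as.integer(n_list), d_gy = d, D_gy = n_list * d)
}

#' Fit an exponential decay
#'
#' Nonlinear least squares of `y = a * exp(-x / b) + c`, used to summarize
#' how the alpha/beta profile and isoeffect doses relax with their abscissa.
#' Starting values are taken from the data: `a0` the first-minus-last y,
#' `b0` a third of the x range, `c0` the last y. Zero-variance input returns
#' the flat fit (`a = 0`, `c = mean(y)`) directly.
#'
#' @param x,y numeric vectors (>= 4 points).
#' @return List with `a`, `b`, `c` and the `nls` object (`NULL` for the
#'   degenerate flat fit).
#' @export
fit_exp_decay <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 4L)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  if (stats::sd(y) == 0) {
    return(list(a = 0, b = diff(range(x)) / 3, c = mean(y), nls = NULL))
  }
  start <- list(a = ys[1] - ys[length(ys)],
                b = max(diff(range(x)) / 3, 1e-6),
                c = ys[length(ys)])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-x / b) + c, start = start,
                      lower = c(a = -Inf, b = 1e-9, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("exponential-decay fit failed to converge: ",
                             conditionMessage(e))
  )
  est <- stats::coef(fit)
  list(a = unname(est["a"]), b = unname(est["b"]), c = unname(est["c"]),
       nls = fit)
}
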