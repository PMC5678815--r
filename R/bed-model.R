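#' Biologically effective dose
#'
#' `BED = D (1 + d / (alpha/beta))` for total dose `D` delivered at dose per
#' fraction `d`. Equal BEDs define isoeffective schedules; BED is linear in
#' `D` at fixed `d` and never below the physical dose.
#'
#' @param D total dose, Gy (> 0); vectorized.
#' @param d dose per fraction, Gy (> 0, <= D).
#' @param alpha_beta fractionation sensitivity, Gy (> 0).
#' @return BED, Gy.
#' @examples
#' bed(14.55, 14.55, 4.49) # single-fraction ED50 of the fibrosis model
#' @export
bed <- function(D, d, alpha_beta) {
  stopifnot(is.numeric(D), is.numeric(d), is.numeric(alpha_beta))
  if (any(alpha_beta <= 0)) stop("'alpha_beta' must be positive")
  if (any(D <= 0) || any(d <= 0)) stop("doses must be positive")
  if (any(d > D + 1e-12)) stop("dose per fraction cannot exceed total dose")
  D * (1 + d / alpha_beta)
}

# four-parameter log-logistic (Hill-type) response in BED
bed_logistic_curve <- function(B, A1, A2, k, p) {
  A2 + (A1 - A2) / (1 + (B / k)^p)
}

#' Fit the fibrosis-index-versus-BED logistic
#'
#' Fits the four-parameter log-logistic
#' `FI(BED) = A2 + (A1 - A2) / (1 + (BED/k)^p)` by Levenberg-Marquardt least
#' squares. `A1` and `A2` are the lower/upper asymptotes (FI units), `k` the
#' BED at the midpoint `FI = (A1 + A2)/2`, and `p` the shape exponent.
#' Either asymptote may be fixed (e.g. `fix_a1 = 0`, `fix_a2 = 7.2`). The
#' threshold landmarks are derived by [extract_landmarks()] and attached.
#'
#' @param beds numeric vector of BED values, Gy (>= 5 points spanning the
#'   rise of the curve).
#' @param fis numeric vector of FI values.
#' @param fix_a1,fix_a2 optional values at which to fix the asymptotes.
#' @param normalize_axes passed to [extract_landmarks()].
#' @return An object of class `bed_logistic_fit` with `A1`, `A2`, `k`, `p`,
#'   `se`, `adj_r2`, landmark fields `bed_tr`, `bed_cutoff`, `bed_ed50`, and
#'   the BED range of the data.
#' @export
fit_bed_logistic <- function(beds, fis, fix_a1 = NULL, fix_a2 = NULL,
                             normalize_axes = FALSE) {
  stopifnot(is.numeric(beds), is.numeric(fis), length(beds) == length(fis),
            all(is.finite(beds)), all(is.finite(fis)), all(beds >= 0))
  if (length(unique(beds)) < 5L) {
    stop("need at least 5 distinct BED values spanning the rise of the curve")
  }
  if (stats::sd(fis) == 0) stop("constant FI: nothing to fit")
  pos <- beds > 0
  k0 <- stats::approx(sort(fis[pos]), sort(beds[pos]),
                      xout = (min(fis) + max(fis)) / 2, ties = mean,
                      rule = 2)$y
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(beds[pos])
  start <- c(A1 = min(fis), A2 = max(fis), k = k0, p = 3)
  lower <- c(A1 = -Inf, A2 = -Inf, k = 1e-6, p = 1e-2)
  upper <- c(A1 = Inf, A2 = Inf, k = Inf, p = 50)
  fixed <- character(0)
  if (!is.null(fix_a1)) fixed <- c(fixed, "A1")
  if (!is.null(fix_a2)) fixed <- c(fixed, "A2")
  free <- setdiff(names(start), fixed)
  full_par <- function(par) {
    th <- c(par, A1 = fix_a1, A2 = fix_a2)
    th[c("A1", "A2", "k", "p")]
  }
  resid_fn <- function(par) {
    th <- full_par(par)
    fis - bed_logistic_curve(beds, th[["A1"]], th[["A2"]], th[["k"]],
                             th[["p"]])
  }
  # nls.lm rather than nlsLM: the latter rebuilds an nls object through
  # numericDeriv, whose relative step underflows when a parameter (here
  # typically A1) converges to 0, spuriously reporting a singular gradient
  out <- minpack.lm::nls.lm(par = start[free], fn = resid_fn,
                            lower = lower[free], upper = upper[free],
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(out$info %in% 1:4)) {
    stop("BED logistic fit failed to converge: ", out$message)
  }
  est <- out$par
  get <- function(nm, fixv) if (nm %in% names(est)) est[[nm]] else fixv
  A1_hat <- get("A1", fix_a1); A2_hat <- get("A2", fix_a2)
  if (A2_hat <= A1_hat) stop("fit degenerate: upper asymptote not above lower")
  se <- tryCatch({
    s <- summary(out)$coefficients[, "Std. Error"]
    stats::setNames(as.numeric(s), names(est))
  }, error = function(e) stats::setNames(rep(NA_real_, length(est)),
                                         names(est)))
  pred <- bed_logistic_curve(beds, A1_hat, A2_hat, est[["k"]], est[["p"]])
  out <- structure(
    list(A1 = A1_hat, A2 = A2_hat, k = est[["k"]], p = est[["p"]],
         fixed = fixed, se = se,
         adj_r2 = adjusted_r2(fis, pred, length(est)),
         bed_range = range(beds), n = length(fis)),
    class = "bed_logistic_fit"
  )
  lm <- extract_landmarks(out, normalize_axes = normalize_axes)
  out$bed_tr <- lm$bed_tr
  out$bed_cutoff <- lm$bed_cutoff
  out$bed_ed50 <- lm$bed_ed50
  out
}

#' Manually assemble a BED logistic fit
#'
#' For evaluating landmark geometry at chosen parameters without data.
#'
#' @param A1,A2 lower and upper asymptotes, FI units (`A2 > A1`).
#' @param k BED at the midpoint, Gy (> 0).
#' @param p shape exponent (> 0).
#' @param bed_range BED range the landmark search should consider.
#' @return A `bed_logistic_fit` (without landmarks attached).
#' @export
bed_logistic <- function(A1, A2, k, p, bed_range = c(0, 2 * k)) {
  stopifnot(A2 > A1, k > 0, p > 0)
  structure(
    list(A1 = A1, A2 = A2, k = k, p = p, fixed = character(0), se = NULL,
         adj_r2 = NA_real_, bed_range = bed_range, n = NA_integer_),
    class = "bed_logistic_fit"
  )
}

#' Predict FI from BED under a fitted logistic
#'
#' @param fit a `bed_logistic_fit`.
#' @param beds numeric vector of BED values, Gy.
#' @return Predicted FI values.
#' @export
predict_bed_fi <- function(fit, beds) {
  stopifnot(inherits(fit, "bed_logistic_fit"))
  bed_logistic_curve(beds, fit$A1, fit$A2, fit$k, fit$p)
}

#' Threshold landmarks of the FI-versus-BED logistic
#'
#' Three landmarks characterize the curve:
#' * `bed_cutoff` — the BED of maximum slope; for the log-logistic with
#'   `p > 1` this has the closed form `k ((p - 1)/(p + 1))^(1/p)`.
#' * `bed_tr` — the fibrosis-initiation threshold, defined as the point of
#'   maximum (signed, geometric) curvature
#'   `kappa = f'' / (1 + f'^2)^(3/2)` on the rising toe below `bed_cutoff`,
#'   located by a dense grid scan with golden-section refinement.
#' * `bed_ed50` — the BED giving half-maximal FI (`A2/2`); equal to `k` when
#'   `A1 = 0`, otherwise solved from the model in closed form.
#'
#' Curvature is computed in raw (Gy, FI) coordinates by default. Because
#' curvature is not scale-invariant, an alternative convention normalizing
#' both axes to `[0, 1]` over the search range is provided; the landmark
#' values depend on this choice, which is therefore surfaced as an argument
#' rather than hidden.
#'
#' @param fit a `bed_logistic_fit`.
#' @param normalize_axes logical; compute curvature on axes normalized to
#'   `[0, 1]` (default `FALSE`, raw Gy and FI units).
#' @param grid_n number of grid points for the landmark search; default 4096.
#' @param tol absolute refinement tolerance, Gy; default 1e-6.
#' @return List with `bed_tr`, `bed_cutoff`, `bed_ed50` (Gy). With `p <= 1`
#'   there is no interior slope maximum: `bed_cutoff` and `bed_tr` are `NA`
#'   with a warning.
#' @export
extract_landmarks <- function(fit, normalize_axes = FALSE, grid_n = 4096,
                              tol = 1e-6) {
  stopifnot(inherits(fit, "bed_logistic_fit"))
  A1 <- fit$A1; A2 <- fit$A2; k <- fit$k; p <- fit$p
  # half-maximal FI = A2/2: solve A2 + (A1-A2)/(1+u) = A2/2 for u = (B/k)^p
  bed_ed50 <- if (abs(A1) < 1e-12) {
    k
  } else if (A2 > 2 * A1) {
    k * ((A2 - 2 * A1) / A2)^(1 / p)
  } else {
    NA_real_
  }
  if (p <= 1) {
    warning("p <= 1: the slope has no interior maximum; ",
            "threshold landmarks undefined")
    return(list(bed_tr = NA_real_, bed_cutoff = k * 0 + NA_real_,
                bed_ed50 = bed_ed50))
  }
  bed_cutoff <- k * ((p - 1) / (p + 1))^(1 / p)

  upper <- 1.5 * max(fit$bed_range[2], k)
  sx <- if (normalize_axes) upper else 1
  sy <- if (normalize_axes) (A2 - A1) else 1
  curv <- function(B) {
    u <- (B / k)^p
    up <- p * u / B
    upp <- p * (p - 1) * u / B^2
    g1 <- -up / (1 + u)^2
    g2 <- (-upp * (1 + u) + 2 * up^2) / (1 + u)^3
    f1 <- (A1 - A2) * g1 * (sx / sy)      # d(FI/sy) / d(B/sx)
    f2 <- (A1 - A2) * g2 * (sx^2 / sy)
    f2 / (1 + f1^2)^(3 / 2)
  }
  # grid scan over the rising toe, then local refinement
  grid <- seq(upper / grid_n, bed_cutoff, length.out = grid_n)
  kv <- curv(grid)
  i <- which.max(kv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(curv, lower = lo, upper = hi, maximum = TRUE,
                         tol = tol)
  list(bed_tr = opt$maximum, bed_cutoff = bed_cutoff, bed_ed50 = bed_ed50)
}

#' @export
print.bed_logistic_fit <- function(x, ...) {
  cat("FI-vs-BED log-logistic fit\n")
  cat(sprintf("  A1 = %.4f, A2 = %.4f FI units%s\n", x$A1, x$A2,
              if (length(x$fixed)) paste0(" (fixed: ",
                                          paste(x$fixed, collapse = ", "), ")")
              else ""))
  cat(sprintf("  k  = %.3f Gy, p = %.3f\n", x$k, x$p))
  if (!is.null(x$bed_tr)) {
    cat(sprintf("  landmarks: BED_Tr = %.2f, cutoff = %.2f, BED_ED50 = %.2f Gy\n",
                x$bed_tr, x$bed_cutoff, x$bed_ed50))
  }
  if (!is.na(x$adj_r2)) cat(sprintf("  adj. R2 = %.4f (n = %d)\n", x$adj_r2, x$n))
  invisible(x)
}
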