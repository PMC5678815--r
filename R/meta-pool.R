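#' Pool alpha/beta estimates across studies
#'
#' Fixed-effect inverse-variance pooling of per-study alpha/beta estimates:
#' weights `w_i = 1/se_i^2`, pooled mean `sum(w_i x_i)/sum(w_i)`, pooled SE
#' `1/sqrt(sum(w_i))`. Because published syntheses do not always state their
#' weighting, the unweighted mean and SD of the study estimates are always
#' co-reported.
#'
#' @param studies data frame with at least `label`, `alpha_beta_gy` and
#'   `se_gy` columns (optional `endpoint`, `strain`, `followup` are carried
#'   through to [forest_table()]); all SEs must be positive.
#' @return An object of class `pooled_alpha_beta`: `mean_gy`, `se_gy`
#'   (inverse-variance), `unweighted_mean_gy`, `unweighted_sd_gy`, `n_studies`
#'   and the study table with weights attached.
#' @examples
#' studies <- data.frame(label = c("a", "b"), alpha_beta_gy = c(4, 5),
#'                       se_gy = c(1, 1))
#' pool_fixed(studies)
#' @export
pool_fixed <- function(studies) {
  stopifnot(is.data.frame(studies),
            all(c("label", "alpha_beta_gy", "se_gy") %in% names(studies)))
  if (nrow(studies) < 1L) stop("need at least one study to pool")
  if (any(!is.finite(studies$se_gy)) || any(studies$se_gy <= 0)) {
    stop("all study standard errors must be positive")
  }
  x <- studies$alpha_beta_gy
  w <- 1 / studies$se_gy^2
  studies$weight_pct <- 100 * w / sum(w)
  structure(
    list(mean_gy = sum(w * x) / sum(w),
         se_gy = 1 / sqrt(sum(w)),
         unweighted_mean_gy = mean(x),
         unweighted_sd_gy = if (nrow(studies) > 1L) stats::sd(x) else NA_real_,
         n_studies = nrow(studies),
         studies = studies),
    class = "pooled_alpha_beta"
  )
}

#' Forest-plot table for pooled alpha/beta estimates
#'
#' One row per study plus a final pooled row, each with the estimate, its
#' 95\% interval (`estimate +/- 1.96 SE`) and the inverse-variance weight in
#' percent (weights sum to 100).
#'
#' @param pooled a `pooled_alpha_beta` from [pool_fixed()].
#' @return Data frame with columns `label`, `alpha_beta_gy`, `se_gy`,
#'   `lower95_gy`, `upper95_gy`, `weight_pct`.
#' @export
forest_table <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_alpha_beta"))
  s <- pooled$studies
  z <- stats::qnorm(0.975)
  rows <- data.frame(
    label = as.character(s$label),
    alpha_beta_gy = s$alpha_beta_gy,
    se_gy = s$se_gy,
    lower95_gy = s$alpha_beta_gy - z * s$se_gy,
    upper95_gy = s$alpha_beta_gy + z * s$se_gy,
    weight_pct = s$weight_pct,
    stringsAsFactors = FALSE
  )
  pooled_row <- data.frame(
    label = "Pooled (fixed effect)",
    alpha_beta_gy = pooled$mean_gy,
    se_gy = pooled$se_gy,
    lower95_gy = pooled$mean_gy - z * pooled$se_gy,
    upper95_gy = pooled$mean_gy + z * pooled$se_gy,
    weight_pct = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(rows, pooled_row)
}

#' @export
print.pooled_alpha_beta <- function(x, ...) {
  cat(sprintf("Pooled alpha/beta over %d studies\n", x$n_studies))
  cat(sprintf("  inverse-variance: %.2f +/- %.2f Gy (mean +/- SE)\n",
              x$mean_gy, x$se_gy))
  cat(sprintf("  unweighted:       %.2f +/- %.2f Gy (mean +/- SD)\n",
              x$unweighted_mean_gy, x$unweighted_sd_gy))
  invisible(x)
}
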