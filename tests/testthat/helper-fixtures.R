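# Published fit parameters used throughout the tests: saturation A = 7.20 FI
# units; single-fraction ED50 = 14.55 Gy, gamma = 1.64; five-fraction
# ED50 = 27.7 Gy, gamma = 1.41.
fit_1fx <- function() fi_model(A = 7.20, ed50 = 14.55, gamma = 1.64)
fit_5fx <- function() fi_model(A = 7.20, ed50 = 27.7, gamma = 1.41)
truth_models <- function() list(`1fx` = fit_1fx(), `5fx` = fit_5fx())

# independent erf/erfinv route via the normal CDF, used as oracle against the
# implementation's pracma route
erf_oracle <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfinv_oracle <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)

# independent connected-component oracle: iterative 6-neighbour dilation of
# the seed within the admissible set until a fixed point (no shared code with
# the package's breadth-first region growing)
grow_oracle <- function(admissible, seed) {
  dims <- dim(admissible)
  lab <- array(FALSE, dims)
  lab[seed[1], seed[2], seed[3]] <- TRUE
  shift <- function(a, axis, by) {
    idx <- lapply(dims, seq_len)
    src <- idx
    src[[axis]] <- src[[axis]] - by
    keep <- src[[axis]] >= 1 & src[[axis]] <= dims[axis]
    out <- array(FALSE, dims)
    dst <- idx
    dst[[axis]] <- idx[[axis]][keep]
    src[[axis]] <- src[[axis]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    grown <- lab
    for (axis in 1:3) for (by in c(-1L, 1L)) {
      grown <- grown | shift(lab, axis, by)
    }
    grown <- grown & admissible
    if (identical(grown, lab)) return(lab)
    lab <- grown
  }
}

# small phantom suite spanning geometry, spacing and fibrotic content
phantom_suite <- function() {
  list(
    phantom_spec(shape = c(24L, 24L, 24L), spacing_mm = c(0.5, 0.5, 0.5),
                 lung_voxel_count = 1000L, fibrotic_fraction = 0, seed = 1L),
    phantom_spec(shape = c(32L, 24L, 20L), spacing_mm = c(0.5, 0.5, 0.6),
                 lung_voxel_count = 700L, fibrotic_fraction = 0.25, seed = 2L),
    phantom_spec(shape = c(20L, 20L, 20L), spacing_mm = c(0.4, 0.4, 0.4),
                 body_hu = -1000, lung_hu = -600, fibrotic_hu = -200,
                 lung_voxel_count = 500L, fibrotic_fraction = 0.5, seed = 3L),
    phantom_spec(shape = c(16L, 16L, 16L), spacing_mm = c(1, 1, 1),
                 lung_voxel_count = 1L, fibrotic_fraction = 0, seed = 4L)
  )
}
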