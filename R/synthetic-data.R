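#' Study design for a fractionation dose-escalation trial
#'
#' Describes a multi-arm whole-thorax irradiation experiment: each arm has a
#' fixed number of daily fractions and a series of dose-per-fraction levels
#' (including a 0 Gy sham control), with the same number of animals per dose
#' group and a single late endpoint.
#'
#' The default reproduces the two-arm C57BL/6 design this package models:
#' a single-fraction arm at 0, 10.5, 12.5, 14.5, 17.5, 20 Gy and a
#' five-fraction arm at 0, 2, 4, 6, 7, 8.5 Gy per fraction, 12 mice per dose
#' group, endpoint at 24 weeks.
#'
#' @param arms named list; each element is a list with `n_fractions` (positive
#'   integer) and `dose_per_fraction_levels` (Gy, must include 0).
#' @param animals_per_group positive integer.
#' @param endpoint_weeks positive integer.
#' @return An object of class `study_design`.
#' @export
study_design <- function(
    arms = list(
      `1fx` = list(n_fractions = 1L,
                   dose_per_fraction_levels = c(0, 10.5, 12.5, 14.5, 17.5, 20)),
      `5fx` = list(n_fractions = 5L,
                   dose_per_fraction_levels = c(0, 2, 4, 6, 7, 8.5))
    ),
    animals_per_group = 12L,
    endpoint_weeks = 24L) {
  stopifnot(is.list(arms), length(arms) >= 1L, !is.null(names(arms)),
            animals_per_group >= 1L, endpoint_weeks >= 1L)
  for (nm in names(arms)) {
    a <- arms[[nm]]
    if (!is.numeric(a$n_fractions) || a$n_fractions < 1) {
      stop("arm '", nm, "': n_fractions must be >= 1")
    }
    lv <- a$dose_per_fraction_levels
    if (!is.numeric(lv) || any(lv < 0)) {
      stop("arm '", nm, "': dose levels must be non-negative")
    }
    if (!any(lv == 0)) stop("arm '", nm, "' must contain a 0 Gy control level")
  }
  structure(list(arms = arms,
                 animals_per_group = as.integer(animals_per_group),
                 endpoint_weeks = as.integer(endpoint_weeks)),
            class = "study_design")
}

#' Noise and reference conventions for synthetic cohorts
#'
#' The per-animal noise model is additive Gaussian on the fibrosis index,
#' truncated at 0 — a synthetic convention (a single interpretable noise
#' knob), not an empirical estimate. Reference means and the defaults here
#' (sd 5\% of each mean) are likewise synthetic conventions for a healthy
#' adult mouse lung.
#'
#' @param fi_sd standard deviation of additive FI noise, FI units (>= 0).
#' @param ref_volume_mm3 reference mean lung volume, mm3 (> 0).
#' @param ref_mean_hu reference mean lung density, HU.
#' @param seed integer seed; every generator call is deterministic given it.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fi_sd = 0.2, ref_volume_mm3 = 400, ref_mean_hu = -550,
                       seed = 1L) {
  stopifnot(is.numeric(fi_sd), length(fi_sd) == 1L)
  if (fi_sd < 0) stop("'fi_sd' must be non-negative")
  if (ref_volume_mm3 <= 0) stop("'ref_volume_mm3' must be positive")
  structure(list(fi_sd = fi_sd, ref_volume_mm3 = ref_volume_mm3,
                 ref_mean_hu = ref_mean_hu, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a cohort from known dose-response truths
#'
#' For every animal, the true FI is the arm's FI-model evaluated at the
#' animal's total dose; the observed FI adds Gaussian noise truncated at 0.
#' Lung volume and mean HU columns are back-filled so that [fibrosis_index()]
#' under the relative convention recomputes exactly the observed FI, using the
#' symmetric split `delta_hu = delta_v = FI` (so their geometric mean is FI):
#' the imaging-free and imaging-full paths are mutually consistent by
#' construction. Back-filled columns are bookkeeping, not physical scans.
#'
#' @param design a [study_design()].
#' @param truth named list of [fi_model()] objects, one per arm in `design`.
#' @param noise a [noise_spec()]; its `seed` makes the draw reproducible.
#' @return A cohort data frame (class `cohort_table`) with columns
#'   `mouse_id`, `arm`, `n_fractions`, `dose_per_fraction_gy`,
#'   `total_dose_gy`, `timepoint_weeks`, `lung_volume_mm3`, `mean_lung_hu`,
#'   `fi`.
#' @examples
#' truth <- list(`1fx` = fi_model(7.20, 14.55, 1.64),
#'               `5fx` = fi_model(7.20, 27.7, 1.41))
#' cohort <- simulate_cohort(study_design(), truth, noise_spec(seed = 7))
#' table(cohort$arm)
#' @export
simulate_cohort <- function(design, truth, noise = noise_spec()) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_spec"))
  missing_arms <- setdiff(names(design$arms), names(truth))
  if (length(missing_arms) > 0) {
    stop("no FI-model truth supplied for arm(s): ",
         paste(missing_arms, collapse = ", "))
  }
  set.seed(noise$seed)
  rows <- list()
  id <- 0L
  for (arm_name in names(design$arms)) {
    arm <- design$arms[[arm_name]]
    fit <- truth[[arm_name]]
    stopifnot(inherits(fit, "fi_model_fit"))
    for (d in arm$dose_per_fraction_levels) {
      D <- arm$n_fractions * d
      true_fi <- predict_fi(fit, D)
      obs <- pmax(0, true_fi + stats::rnorm(design$animals_per_group,
                                            0, noise$fi_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("m%04d", id + seq_along(obs)),
        arm = arm_name,
        n_fractions = as.integer(arm$n_fractions),
        dose_per_fraction_gy = d,
        total_dose_gy = D,
        timepoint_weeks = design$endpoint_weeks,
        lung_volume_mm3 = backfill_volume(obs, noise),
        mean_lung_hu = backfill_hu(obs, noise),
        fi = obs,
        stringsAsFactors = FALSE
      )
      id <- id + design$animals_per_group
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# invert the relative-convention deltas at scale 1 so that fibrosis_index
# recomputes the stored FI exactly: delta_hu = delta_v = fi
backfill_volume <- function(fi, noise) noise$ref_volume_mm3 * (1 - fi)
backfill_hu <- function(fi, noise) noise$ref_mean_hu + fi * abs(noise$ref_mean_hu)

#' Simulate a sham-irradiated reference cohort
#'
#' Generates `n` unirradiated animals whose lung volume and mean HU are drawn
#' around the reference means of `noise` (Gaussian, sd a stated fraction of
#' each mean), for use as the age-matched comparison cohort of the fibrosis
#' index.
#'
#' @param n number of animals (>= 1).
#' @param noise a [noise_spec()].
#' @param rel_sd relative standard deviation applied to both reference means;
#'   default 0.05.
#' @return A `cohort_table` of `n` sham records (arm `"reference"`, 0 Gy,
#'   `fi = 0`).
#' @export
make_reference_cohort <- function(n, noise = noise_spec(), rel_sd = 0.05) {
  if (!is.numeric(n) || n < 1) stop("'n' must be at least 1")
  n <- as.integer(n)
  set.seed(noise$seed)
  out <- data.frame(
    mouse_id = sprintf("ref%04d", seq_len(n)),
    arm = "reference",
    n_fractions = 0L,
    dose_per_fraction_gy = 0,
    total_dose_gy = 0,
    timepoint_weeks = 0L,
    lung_volume_mm3 = stats::rnorm(n, noise$ref_volume_mm3,
                                   rel_sd * noise$ref_volume_mm3),
    mean_lung_hu = stats::rnorm(n, noise$ref_mean_hu,
                                rel_sd * abs(noise$ref_mean_hu)),
    fi = 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Summarize a reference cohort
#'
#' @param cohort a `cohort_table` (typically from [make_reference_cohort()]).
#' @return List with `mean_volume_mm3`, `mean_hu` and `n` — the reference
#'   summary consumed by [fibrosis_index()].
#' @export
reference_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("lung_volume_mm3", "mean_lung_hu") %in% names(cohort)))
  list(mean_volume_mm3 = mean(cohort$lung_volume_mm3),
       mean_hu = mean(cohort$mean_lung_hu),
       n = nrow(cohort))
}

#' Specification of a CT-like voxel phantom
#'
#' A rectangular volume of `body_hu` containing a single 6-connected
#' quasi-spherical "lung" of exactly `lung_voxel_count` voxels at `lung_hu`,
#' of which a fraction is replaced by denser fibrotic voxels. The lung HU must
#' lie inside the segmentation window (-900..-100 HU) and the body HU outside
#' it, so seeded region growing recovers the region exactly.
#'
#' @param shape integer length-3 voxel counts.
#' @param spacing_mm numeric length-3 voxel sizes, mm.
#' @param body_hu,lung_hu,fibrotic_hu HU values; defaults 0, -500, -200.
#' @param lung_voxel_count number of lung voxels (<= total voxels).
#' @param fibrotic_fraction fraction of lung voxels set to `fibrotic_hu`,
#'   in `[0, 1]`.
#' @param seed integer seed (placement of fibrotic voxels).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing_mm = c(0.5, 0.5, 0.5),
                         body_hu = 0, lung_hu = -500, fibrotic_hu = -200,
                         lung_voxel_count = 1000L, fibrotic_fraction = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing_mm) == 3L,
            all(spacing_mm > 0), fibrotic_fraction >= 0,
            fibrotic_fraction <= 1)
  if (lung_hu < -900 || lung_hu > -100) {
    stop("'lung_hu' must lie inside the segmentation window [-900, -100] HU")
  }
  if (body_hu >= -900 && body_hu <= -100) {
    stop("'body_hu' must lie outside the segmentation window [-900, -100] HU")
  }
  if (lung_voxel_count < 1 || lung_voxel_count > prod(shape)) {
    stop("'lung_voxel_count' must be between 1 and the total voxel count")
  }
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 body_hu = body_hu, lung_hu = lung_hu,
                 fibrotic_hu = fibrotic_hu,
                 lung_voxel_count = as.integer(lung_voxel_count),
                 fibrotic_fraction = fibrotic_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a voxel phantom with exact ground truth
#'
#' Builds the phantom described by a [phantom_spec()]: the lung region is the
#' set of the `lung_voxel_count` voxels nearest the volume centre (which is
#' always 6-connected, since any voxel's axis-step toward the centre is
#' strictly nearer), and `round(fibrotic_fraction * count)` of them, chosen
#' uniformly at the spec's seed, are set to `fibrotic_hu`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [voxel_volume()]) and `truth`: exact
#'   `lung_voxel_count`, `fibrotic_voxel_count`, `volume_mm3`, `mean_hu`,
#'   `seed_point` (a voxel guaranteed inside the lung) and `lung_mask`.
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  centre <- (dims + 1) / 2
  # squared distance to centre for every voxel, ties broken by linear index
  ax <- (seq_len(dims[1]) - centre[1])^2
  ay <- (seq_len(dims[2]) - centre[2])^2
  az <- (seq_len(dims[3]) - centre[3])^2
  d2 <- outer(outer(ax, ay, "+"), az, "+")
  ord <- order(as.vector(d2), seq_along(d2))
  lung_idx <- ord[seq_len(spec$lung_voxel_count)]
  hu <- array(spec$body_hu, dims)
  hu[lung_idx] <- spec$lung_hu
  n_fib <- round(spec$fibrotic_fraction * spec$lung_voxel_count)
  if (n_fib > 0) {
    set.seed(spec$seed)
    fib_idx <- sample(lung_idx, n_fib)
    hu[fib_idx] <- spec$fibrotic_hu
  }
  mask <- array(FALSE, dims)
  mask[lung_idx] <- TRUE
  seed_point <- as.integer(arrayInd(lung_idx[1], dims))
  list(
    volume = voxel_volume(hu, spec$spacing_mm),
    truth = list(
      lung_voxel_count = spec$lung_voxel_count,
      fibrotic_voxel_count = as.integer(n_fib),
      volume_mm3 = spec$lung_voxel_count * prod(spec$spacing_mm),
      mean_hu = mean(hu[lung_idx]),
      seed_point = seed_point,
      lung_mask = mask
    )
  )
}
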