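#' Construct a voxel volume
#'
#' A CT-like 3D array of Hounsfield-unit (HU) values with per-axis voxel
#' spacing in mm. Volumes are treated as axis-aligned with 0-based voxel
#' coordinates never exposed; all functions here index in R's 1-based array
#' convention.
#'
#' @param hu 3D numeric array of HU values (all finite).
#' @param spacing_mm numeric length-3 vector of voxel sizes, mm, all > 0.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(hu, spacing_mm) {
  stopifnot(is.array(hu), length(dim(hu)) == 3L, all(is.finite(hu)),
            is.numeric(spacing_mm), length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  structure(list(hu = hu, spacing_mm = as.numeric(spacing_mm)),
            class = "voxel_volume")
}

#' Read / write voxel volumes as NIfTI-1
#'
#' Voxel spacing is taken from (written to) the NIfTI header pixdim.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [voxel_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname read_volume
#' @param volume a `voxel_volume` (or, for masks, a logical array wrapped by
#'   the caller) to serialize.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(volume$hu)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Segment the lung by seeded 3D region growing
#'
#' Grows the connected region of voxels inside the HU window
#' `[lower_hu, upper_hu]` that contains the seed point, using 6-connectivity
#' (face neighbours) by default. An optional exclusion mask is subtracted from
#' the grown region afterwards; it stands in for the manual resection of the
#' trachea and primary bronchi that a human operator would perform.
#'
#' @param volume a [voxel_volume()].
#' @param lower_hu,upper_hu HU window for aerated-to-fibrotic lung tissue;
#'   defaults -900 and -100 HU.
#' @param seed_point integer length-3 voxel index (1-based) inside the window.
#' @param exclusion_mask optional logical array of the volume's shape; `TRUE`
#'   voxels are removed from the result.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return An object of class `lung_mask`: logical array `mask` plus
#'   provenance (seed point, HU window, connectivity).
#' @export
segment_lung <- function(volume, lower_hu = -900, upper_hu = -100,
                         seed_point, exclusion_mask = NULL,
                         connectivity = 6) {
  stopifnot(inherits(volume, "voxel_volume"),
            is.numeric(seed_point), length(seed_point) == 3L,
            connectivity %in% c(6, 26))
  if (lower_hu >= upper_hu) stop("'lower_hu' must be below 'upper_hu'")
  dims <- dim(volume$hu)
  seed_point <- as.integer(seed_point)
  if (any(seed_point < 1L) || any(seed_point > dims)) {
    stop("seed point outside the volume")
  }
  seed_hu <- volume$hu[seed_point[1], seed_point[2], seed_point[3]]
  if (seed_hu < lower_hu || seed_hu > upper_hu) {
    stop(sprintf("seed voxel HU (%.1f) outside window [%.0f, %.0f]",
                 seed_hu, lower_hu, upper_hu))
  }
  in_window <- volume$hu >= lower_hu & volume$hu <= upper_hu
  mask <- flood_fill3d(in_window, seed_point, connectivity)
  if (!is.null(exclusion_mask)) {
    stopifnot(is.logical(exclusion_mask),
              identical(dim(exclusion_mask), dims))
    mask <- mask & !exclusion_mask
  }
  if (!any(mask)) stop("empty segmentation after applying the exclusion mask")
  structure(
    list(mask = mask, seed_point = seed_point,
         hu_window = c(lower_hu, upper_hu), connectivity = connectivity),
    class = "lung_mask"
  )
}

# breadth-first flood fill over a logical 3D array, frontier-vectorized
flood_fill3d <- function(admissible, seed, connectivity) {
  dims <- dim(admissible)
  offsets <- if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
          c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  visited <- array(FALSE, dims)
  frontier <- matrix(seed, nrow = 1)
  visited[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(i) {
      sweep(frontier, 2, offsets[i, ], "+")
    }))
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[!duplicated(cand), , drop = FALSE]
    ok <- admissible[cand] & !visited[cand]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

#' Volume and density metrics inside a lung mask
#'
#' @param volume a [voxel_volume()].
#' @param mask a `lung_mask` from [segment_lung()], or a logical array of the
#'   volume's shape.
#' @return An object of class `lung_scan_metrics` with `volume_mm3`
#'   (voxel count times voxel volume), `mean_hu` (arithmetic mean HU inside
#'   the mask) and `voxel_count`.
#' @export
lung_metrics <- function(volume, mask) {
  stopifnot(inherits(volume, "voxel_volume"))
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stopifnot(is.logical(m), identical(dim(m), dim(volume$hu)))
  count <- sum(m)
  if (count == 0) stop("empty segmentation: no voxels in mask")
  structure(
    list(volume_mm3 = count * prod(volume$spacing_mm),
         mean_hu = mean(volume$hu[m]),
         voxel_count = count),
    class = "lung_scan_metrics"
  )
}

#' Peak position of the smoothed HU histogram (PPSH)
#'
#' Histogram diagnostic against density/volume confounding: emphysema shifts
#' the lung HU mode toward air, pleural effusion toward fluid, whereas
#' fibrosis both shifts and narrows it. The masked HU values are binned at
#' `bin_width_hu`, smoothed with a centred moving average of width
#' `smooth_window_hu` (partial windows at the edges are averaged over the bins
#' actually present, so adding a constant count to every bin never moves the
#' peak), and the peak is the bin centre of the global maximum; ties break
#' toward the lowest HU.
#'
#' @param volume a [voxel_volume()].
#' @param mask a `lung_mask` or logical array.
#' @param bin_width_hu histogram bin width, HU (> 0); default 10.
#' @param smooth_window_hu moving-average window, HU (>= bin width); default 50.
#' @return An object of class `ppsh_result`: `peak_hu`, `histogram`
#'   (data frame of bin centres, raw and smoothed counts), `smooth_window_hu`,
#'   and a `degenerate` flag set when all masked HU are equal.
#' @export
ppsh <- function(volume, mask, bin_width_hu = 10, smooth_window_hu = 50) {
  stopifnot(inherits(volume, "voxel_volume"),
            bin_width_hu > 0, smooth_window_hu >= bin_width_hu)
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stopifnot(is.logical(m), identical(dim(m), dim(volume$hu)))
  if (!any(m)) stop("empty segmentation: no voxels in mask")
  hu <- volume$hu[m]
  degenerate <- length(unique(hu)) == 1L
  if (degenerate) {
    warning("all masked HU values are equal; returning the single-bin peak")
    centre <- hu[1]
    return(structure(
      list(peak_hu = centre,
           histogram = data.frame(hu = centre, count = length(hu),
                                  smoothed = length(hu)),
           smooth_window_hu = smooth_window_hu, degenerate = TRUE),
      class = "ppsh_result"
    ))
  }
  lo <- floor(min(hu) / bin_width_hu) * bin_width_hu
  hi <- ceiling(max(hu) / bin_width_hu) * bin_width_hu
  breaks <- seq(lo, hi, by = bin_width_hu)
  counts <- as.numeric(table(cut(hu, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  centres <- breaks[-length(breaks)] + bin_width_hu / 2
  half <- max(0L, floor(round(smooth_window_hu / bin_width_hu) / 2))
  nb <- length(counts)
  smoothed <- vapply(seq_len(nb), function(i) {
    mean(counts[max(1L, i - half):min(nb, i + half)])
  }, numeric(1))
  peak_i <- which(smoothed == max(smoothed))[1] # ties -> lowest HU bin
  structure(
    list(peak_hu = centres[peak_i],
         histogram = data.frame(hu = centres, count = counts,
                                smoothed = smoothed),
         smooth_window_hu = smooth_window_hu, degenerate = FALSE),
    class = "ppsh_result"
  )
}

#' Fibrosis index from lung metrics
#'
#' The fibrosis index is the geometric mean of the relative increase in mean
#' lung density and the relative decrease in lung volume against an
#' age-matched reference cohort:
#' \deqn{FI = \sqrt{\Delta HU \uparrow \times \Delta V \downarrow}}
#' A density increase reflects collagen deposition and hyper-cellularity; the
#' volume loss the restrictive nature of fibrosis. When either delta is
#' non-positive the pattern is not fibrotic (e.g. emphysema or effusion may
#' dominate) and FI is clamped to 0 with a flag.
#'
#' Two conventions are provided. Under `"relative"` (default) the deltas are
#' dimensionless fractions of the reference means,
#' `delta_hu = scale * (HU_t - HU_ref) / |HU_ref|` and
#' `delta_v = scale * (V_ref - V_t) / V_ref`. Under `"direct"` the caller
#' supplies precomputed deltas (a list with `delta_hu` and `delta_v`), which
#' is how externally normalized FI values enter the pipeline; the downstream
#' dose-response mathematics operate on FI values regardless of convention.
#'
#' @param treated a `lung_scan_metrics` (relative convention) or a list with
#'   `delta_hu`, `delta_v` (direct convention).
#' @param reference a reference summary: list with `mean_volume_mm3` and
#'   `mean_hu` (see [reference_summary()]); ignored under `"direct"`.
#' @param convention `"relative"` or `"direct"`.
#' @param scale multiplicative constant applied to both relative deltas;
#'   default 1.
#' @return An object of class `fibrosis_score`: `delta_hu`, `delta_v`, `fi`,
#'   and `non_fibrotic` flag.
#' @export
fibrosis_index <- function(treated, reference = NULL,
                           convention = c("relative", "direct"), scale = 1) {
  convention <- match.arg(convention)
  if (convention == "relative") {
    stopifnot(inherits(treated, "lung_scan_metrics") ||
                (is.list(treated) && all(c("volume_mm3", "mean_hu") %in%
                                           names(treated))))
    if (is.null(reference)) stop("the relative convention needs a reference summary")
    v_ref <- reference$mean_volume_mm3
    hu_ref <- reference$mean_hu
    if (!is.finite(v_ref) || v_ref <= 0) stop("reference volume must be positive")
    if (!is.finite(hu_ref) || hu_ref == 0) {
      stop("reference mean HU must be nonzero under the relative convention")
    }
    delta_hu <- scale * (treated$mean_hu - hu_ref) / abs(hu_ref)
    delta_v <- scale * (v_ref - treated$volume_mm3) / v_ref
  } else {
    stopifnot(is.list(treated), all(c("delta_hu", "delta_v") %in% names(treated)))
    delta_hu <- treated$delta_hu
    delta_v <- treated$delta_v
  }
  non_fibrotic <- delta_hu <= 0 || delta_v <= 0
  fi <- if (non_fibrotic) 0 else sqrt(delta_hu * delta_v)
  structure(
    list(delta_hu = delta_hu, delta_v = delta_v, fi = fi,
         non_fibrotic = non_fibrotic, convention = convention, scale = scale),
    class = "fibrosis_score"
  )
}
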