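cohort_columns <- c("mouse_id", "arm", "n_fractions", "dose_per_fraction_gy",
                    "total_dose_gy", "timepoint_weeks", "lung_volume_mm3",
                    "mean_lung_hu", "fi")

#' Read and validate a cohort table
#'
#' Reads the per-animal CSV schema (`mouse_id, arm, n_fractions,
#' dose_per_fraction_gy, total_dose_gy, timepoint_weeks, lung_volume_mm3,
#' mean_lung_hu, fi`), checks column presence and types, and enforces the
#' dose bookkeeping `total = n_fractions * dose_per_fraction` on every row
#' (both are stored so that neither is derived silently). Rows failing
#' validation are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(cohort_columns, c("mouse_id", "arm"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("cohort parse error: column '", cl, "' is not numeric")
    }
  }
  validate_cohort(df)
  df <- df[, cohort_columns]
  class(df) <- c("cohort_table", "data.frame")
  df
}

validate_cohort <- function(df) {
  bad_dose <- which(abs(df$total_dose_gy -
                          df$n_fractions * df$dose_per_fraction_gy) > 1e-6)
  if (length(bad_dose) > 0) {
    stop("cohort consistency error: total_dose_gy != n_fractions x ",
         "dose_per_fraction_gy on row(s) ",
         paste(utils::head(bad_dose, 5), collapse = ", "))
  }
  bad_fi <- which(!is.finite(df$fi) | df$fi < 0)
  if (length(bad_fi) > 0) {
    stop("cohort validation error: non-finite or negative FI on row(s) ",
         paste(utils::head(bad_fi, 5), collapse = ", "))
  }
  invisible(df)
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort),
            all(cohort_columns %in% names(cohort)))
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted models to JSON
#'
#' Writes the FI-model parameters (and fit metadata) as a small JSON object;
#' `read_fi_fit()` restores the `fi_model_fit`.
#'
#' @param fit an `fi_model_fit`.
#' @param path JSON file path.
#' @export
write_fi_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fi_model_fit"))
  jsonlite::write_json(
    list(A = fit$A, gamma = fit$gamma, ed50 = fit$ed50,
         a_fixed = fit$a_fixed, se = as.list(fit$se),
         adj_r2 = fit$adj_r2, n = fit$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fi_fit
#' @export
read_fi_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fi_model(A = x$A, ed50 = x$ed50, gamma = x$gamma, a_fixed = x$a_fixed,
           se = unlist(x$se), adj_r2 = x$adj_r2 %||% NA_real_,
           n = x$n %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for the end-to-end fibrosis pipeline
#'
#' Collects every knob of the analysis in one validated object so a run is
#' reproducible from its configuration alone.
#'
#' @param design a [study_design()].
#' @param truth named list of [fi_model()] truths, one per arm (synthetic
#'   runs), or `NULL` when `cohort` is supplied.
#' @param cohort optional pre-existing `cohort_table` (skips simulation).
#' @param noise a [noise_spec()] (carries the seed and reference means).
#' @param fix_a saturation constant held fixed during per-arm fits.
#' @param fi_floor FI floor for the LQ log transform.
#' @param fi_grid FI grid for the alpha/beta profile.
#' @param alpha_beta optional fixed alpha/beta for the BED mapping; when
#'   `NULL` the profile mean is used.
#' @param fix_a1,fix_a2 asymptote handling for the BED logistic.
#' @param normalize_axes curvature convention for [extract_landmarks()].
#' @param out_dir optional output directory; when set, the report tables are
#'   written there as CSV/JSON.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            truth = NULL, cohort = NULL,
                            noise = noise_spec(),
                            fix_a = 7.20, fi_floor = 0.05,
                            fi_grid = seq(0.05, 7.15, by = 0.05),
                            alpha_beta = NULL,
                            fix_a1 = 0, fix_a2 = NULL,
                            normalize_axes = FALSE,
                            out_dir = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_spec"))
  if (is.null(truth) && is.null(cohort)) {
    stop("supply either per-arm truth models (synthetic run) or a cohort")
  }
  structure(
    list(design = design, truth = truth, cohort = cohort, noise = noise,
         fix_a = fix_a, fi_floor = fi_floor, fi_grid = fi_grid,
         alpha_beta = alpha_beta, fix_a1 = fix_a1, fix_a2 = fix_a2,
         normalize_axes = normalize_axes, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the end-to-end fibrosis analysis
#'
#' Orchestrates the full chain: simulate (or ingest) the cohort, fit the
#' FI-model per arm, derive the alpha/beta profile, Fe plot and LQ fits,
#' map doses to BED and fit the BED logistic with its threshold landmarks.
#' Requires at least two arms with distinct fractionation for the
#' alpha/beta stages. Reruns with the same configuration reproduce the
#' numbers exactly.
#'
#' @param config a [pipeline_config()].
#' @return A list report: `cohort`, `fits` (per arm), `profile`,
#'   `alpha_beta_gy`, `fe`, `lq` (per arm), `bed_fit`, plus the config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$design, config$truth, config$noise)
  } else {
    validate_cohort(cohort)
  }

  arms <- split(cohort[cohort$arm != "reference", ],
                cohort$arm[cohort$arm != "reference"])
  fits <- lapply(arms, function(a) {
    fit_fi_model(a$total_dose_gy, a$fi, fix_a = config$fix_a)
  })

  n_frac <- vapply(arms, function(a) max(a$n_fractions), numeric(1))
  if (length(unique(n_frac)) < 2L) {
    stop("alpha/beta estimation requires two arms with different ",
         "fractionation")
  }
  single <- names(which(n_frac == min(n_frac)))[1]
  multi <- names(which(n_frac == max(n_frac)))[1]

  a_max <- min(vapply(fits, function(f) f$A, numeric(1)))
  grid <- config$fi_grid[config$fi_grid > 0 & config$fi_grid < a_max]
  profile <- alpha_beta_profile(fits[[single]], fits[[multi]],
                                n_fractions = n_frac[[multi]],
                                fi_grid = grid)
  ab <- config$alpha_beta %||% attr(profile, "mean_alpha_beta")

  mid <- a_max / 2
  fe <- fe_plot(
    d = c(inverse_dose(fits[[single]], mid) / n_frac[[single]],
          inverse_dose(fits[[multi]], mid) / n_frac[[multi]]),
    D_total = c(inverse_dose(fits[[single]], mid),
                inverse_dose(fits[[multi]], mid))
  )

  # per-arm LQ fits (d varies across an arm's dose levels, so alpha and beta
  # separate); sham rows are excluded ahead of the log transform
  lq <- lapply(arms, function(a) {
    irr <- a[a$total_dose_gy > 0, ]
    tryCatch(
      fit_lq(irr$total_dose_gy, irr$dose_per_fraction_gy, irr$fi,
             fi_floor = config$fi_floor),
      error = function(e) NULL
    )
  })
  lq_joint <- {
    irr <- cohort[cohort$total_dose_gy > 0 & cohort$arm != "reference", ]
    fit_lq(irr$total_dose_gy, irr$dose_per_fraction_gy, irr$fi,
           fi_floor = config$fi_floor)
  }

  irr <- cohort[cohort$total_dose_gy > 0 & cohort$arm != "reference", ]
  beds <- bed(irr$total_dose_gy, irr$dose_per_fraction_gy, ab)
  bed_fit <- fit_bed_logistic(c(rep(0, sum(cohort$total_dose_gy == 0)), beds),
                              c(cohort$fi[cohort$total_dose_gy == 0], irr$fi),
                              fix_a1 = config$fix_a1, fix_a2 = config$fix_a2,
                              normalize_axes = config$normalize_axes)

  report <- list(cohort = cohort, fits = fits, profile = profile,
                 alpha_beta_gy = ab, fe = fe, lq = lq, lq_joint = lq_joint,
                 bed_fit = bed_fit, config = config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(out_dir, "cohort.csv"))
  for (nm in names(report$fits)) {
    write_fi_fit(report$fits[[nm]], file.path(out_dir,
                                              paste0("fit_", nm, ".json")))
  }
  utils::write.csv(as.data.frame(report$profile),
                   file.path(out_dir, "alpha_beta_profile.csv"),
                   row.names = FALSE)
  bf <- report$bed_fit
  jsonlite::write_json(
    list(alpha_beta_gy = report$alpha_beta_gy,
         fe_alpha_beta_gy = report$fe$alpha_beta,
         lq_joint_alpha_beta_gy = report$lq_joint$alpha_beta,
         bed = list(A1 = bf$A1, A2 = bf$A2, k = bf$k, p = bf$p,
                    bed_tr_gy = bf$bed_tr, bed_cutoff_gy = bf$bed_cutoff,
                    bed_ed50_gy = bf$bed_ed50, adj_r2 = bf$adj_r2)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
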