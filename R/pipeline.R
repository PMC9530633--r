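#' Default pipeline configuration
#'
#' Defaults mirror the analysis this package implements: K = 11 full-image
#' clusters, K2 = 7 thrombus clusters, thrombus-area adequacy threshold
#' 0.22 for scores 4-5, IMR cut 40 U, MVO cut 1.55%, NNLS unmixing,
#' 999 permutations.
#'
#' @return a `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    cubes = character(0),        # paths to ENVI cubes; or use `simulate`
    basis = NULL,                # path to basis CSV; NULL = synthetic library
    cohort = NULL,               # path to cohort CSV
    output_dir = "results/run",
    simulate = NULL,             # list(n_samples, height, width, noise_sd, seed)
    preprocess = "none",
    K = 11L, K2 = 7L, seed = 0L, n_restarts = 25L,
    pooled = TRUE,
    thrombus_ids = NULL,         # explicit override; NULL = automated selection
    sim_threshold = 0.98,
    unmix_mode = "nnls",
    area_threshold = 0.22,
    eligible_scores = 4:5,
    imr_cut = 40, mvo_cut = 1.55,
    targets = c("imr", "mvo"),
    models = c("linear", "power", "exp", "sat_exp"),
    n_starts = 20L, n_perm = 999L
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on
#' [default_run_config()], and checks every constraint at once: referenced
#' input files must exist, K/K2/seeds must be positive integers, thresholds
#' in range. All violations are reported together in a single error.
#'
#' @param config path to a YAML config file, or a named list of overrides.
#' @return a validated `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- default_run_config()
  unknown <- setdiff(names(config), names(cfg))
  for (nm in intersect(names(config), names(cfg))) cfg[[nm]] <- config[[nm]]
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  for (nm in c("K", "K2", "seed", "n_restarts", "n_starts", "n_perm")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v))
      errs <- c(errs, paste0(nm, " must be a single integer"))
    else cfg[[nm]] <- as.integer(v)
  }
  if (is.numeric(cfg$K) && cfg$K < 1) errs <- c(errs, "K must be >= 1")
  if (is.numeric(cfg$K2) && cfg$K2 < 1) errs <- c(errs, "K2 must be >= 1")
  if (!is.numeric(cfg$area_threshold) || cfg$area_threshold < 0 ||
      cfg$area_threshold > 1)
    errs <- c(errs, "area_threshold must be in [0, 1]")
  if (!all(cfg$targets %in% c("imr", "mvo")))
    errs <- c(errs, "targets must be a subset of {imr, mvo}")
  if (!all(cfg$models %in% c("linear", "power", "exp", "sat_exp")))
    errs <- c(errs, "unknown model family in `models`")
  if (!cfg$preprocess %in% c("none", "per_pixel_norm"))
    errs <- c(errs, "preprocess must be 'none' or 'per_pixel_norm'")
  if (!cfg$unmix_mode %in% c("nnls", "ols"))
    errs <- c(errs, "unmix_mode must be 'nnls' or 'ols'")
  for (p in cfg$cubes)
    if (!file.exists(sub("\\.(hdr|bsq)$", ".hdr", p)))
      errs <- c(errs, paste0("cube not found: ", p))
  for (nm in c("basis", "cohort"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      errs <- c(errs, paste0(nm, " file not found: ", cfg[[nm]]))
  if (length(cfg$cubes) == 0 && is.null(cfg$simulate))
    errs <- c(errs, "no input cubes and no `simulate` block")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg
}

#' Run the full thrombus-characterisation pipeline
#'
#' Stages: load (or simulate) cubes and basis spectra, optional
#' preprocessing, pooled K-means over all samples' pixels, thrombus-cluster
#' identification (automatic or override), per-sample thrombus mask and
#' area fraction, pooled K2-means k-fractions, per-pixel unmixing of the
#' first sample, join with the cohort table, adequacy threshold filter,
#' dichotomisation, and regression of each requested target on the
#' k-fractions. All artefacts are written under `config$output_dir`
#' (`kfractions.csv`, `audit.csv`, `fits_<target>.csv`, `report.txt`) and
#' the run is deterministic given the config's seeds.
#'
#' When the cohort table carries its own `f_*` and `area_fraction` columns
#' (as a simulated cohort does) those feed the regressions; otherwise the
#' image-derived k-fractions are joined on `patient_id`/`sample_id`.
#'
#' @param config a `run_config` (see [validate_config()]).
#' @return a run report list: per-stage counts, the k-fractions table, the
#'   audit table, and the fit tables per target. Invisibly writes CSVs.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("pipeline start: K=%d K2=%d seed=%d restarts=%d preprocess=%s unmix=%s",
      cfg$K, cfg$K2, cfg$seed, cfg$n_restarts, cfg$preprocess, cfg$unmix_mode)

  # --- inputs ------------------------------------------------------------
  basis <- if (is.null(cfg$basis)) make_basis_spectra(seed = cfg$seed)
           else read_basis_library(cfg$basis)
  if (length(cfg$cubes)) {
    cubes <- lapply(cfg$cubes, read_cube)
  } else {
    sim <- cfg$simulate
    n_samples <- sim$n_samples %||% 2L
    cubes <- lapply(seq_len(n_samples), function(i) {
      sc <- demo_scene(sim$height %||% 48L, sim$width %||% 48L,
                       noise_sd = sim$noise_sd %||% 0.01,
                       seed = (sim$seed %||% cfg$seed) + i)
      make_cube(sc, basis, sample_id = sprintf("P%03d", i))$cube
    })
    say("simulated %d cubes (%s)", length(cubes),
        paste(dim(cubes[[1]])[1:2], collapse = "x"))
  }
  cubes <- lapply(cubes, preprocess_cube, mode = cfg$preprocess)
  grid <- cubes[[1]]$wavelengths
  basis <- resample_basis(basis, grid)
  say("loaded %d cubes, %d bands", length(cubes), length(grid))

  # --- pooled full-image clustering --------------------------------------
  pooled_px <- do.call(rbind, lapply(cubes, as_pixel_matrix))
  model_full <- fit_kmeans(pooled_px, cfg$K, seed = cfg$seed,
                           n_restarts = cfg$n_restarts, wavelengths = grid)
  say("K=%d pooled fit on %d pixels: SSE = %.6g", cfg$K, nrow(pooled_px),
      model_full$final_sse)
  th_ids <- identify_thrombus_clusters(model_full, basis,
                                       sim_threshold = cfg$sim_threshold,
                                       override = cfg$thrombus_ids)
  say("thrombus clusters: {%s}%s", paste(th_ids, collapse = ", "),
      if (is.null(cfg$thrombus_ids)) " (automated)" else " (override)")

  # --- masks, area fractions, pooled K2 k-fractions ----------------------
  labels <- lapply(cubes, assign_pixels, model = model_full)
  masks <- lapply(labels, mask_thrombus, thrombus_ids = th_ids)
  areas <- vapply(masks, thrombus_area_fraction, numeric(1))
  th_px <- do.call(rbind, lapply(seq_along(cubes), function(i) {
    as_pixel_matrix(cubes[[i]])[as.vector(t(masks[[i]])), , drop = FALSE]
  }))
  if (nrow(th_px) < cfg$K2)
    stop("pipeline stage k-fractions: only ", nrow(th_px),
         " thrombus pixels pooled, need >= K2 = ", cfg$K2, call. = FALSE)
  model_th <- if (cfg$pooled)
    fit_kmeans(th_px, cfg$K2, seed = cfg$seed, n_restarts = cfg$n_restarts,
               wavelengths = grid) else NULL
  profiles <- lapply(seq_along(cubes), function(i)
    kfractions(cubes[[i]], masks[[i]], K2 = cfg$K2, model = model_th,
               seed = cfg$seed, n_restarts = cfg$n_restarts))
  kf <- do.call(rbind, lapply(profiles, function(p) {
    row <- data.frame(sample_id = p$sample_id)
    for (j in seq_along(p$fractions)) row[[paste0("f_", j)]] <- p$fractions[j]
    row$n_pixels <- p$n_thrombus_pixels
    row$area_fraction <- p$area_fraction
    row
  }))
  utils::write.csv(kf, file.path(cfg$output_dir, "kfractions.csv"),
                   row.names = FALSE)
  say("k-fractions written for %d samples (pooled=%s)", nrow(kf), cfg$pooled)

  # --- unmixing of the first sample --------------------------------------
  cm <- fit_cube(cubes[[1]], basis, mode = cfg$unmix_mode)
  unmix_summary <- data.frame(
    coefficient = names(cm$maps),
    mean = vapply(cm$maps, mean, numeric(1)),
    max = vapply(cm$maps, max, numeric(1)))
  utils::write.csv(unmix_summary, file.path(cfg$output_dir, "unmix_summary.csv"),
                   row.names = FALSE)
  say("unmixed sample %s (%s): mean chi2/dof = %.4g", cm$sample_id, cm$mode,
      mean(cm$maps$chi2) / max(cm$dof, 1))

  # --- cohort join, threshold, regressions -------------------------------
  fits <- list(); audit <- NULL; kept_n <- NA_integer_
  if (!is.null(cfg$cohort)) {
    cohort <- utils::read.csv(cfg$cohort)
    if (!any(grepl("^f_[0-9]+$", names(cohort)))) {
      idc <- intersect(c("patient_id", "sample_id"), names(cohort))[1]
      cohort <- merge(cohort, kf, by.x = idc, by.y = "sample_id")
      say("joined image k-fractions onto cohort by %s", idc)
    } else {
      say("cohort carries its own k-fraction columns; used directly")
    }
    flt <- filter_successful(cohort, area_threshold = cfg$area_threshold,
                             eligible_scores = cfg$eligible_scores)
    audit <- flt$audit
    kept_n <- nrow(flt$records)
    utils::write.csv(audit, file.path(cfg$output_dir, "audit.csv"),
                     row.names = FALSE)
    say("threshold filter: kept %d / %d records (area >= %.2f, scores {%s})",
        kept_n, nrow(cohort), cfg$area_threshold,
        paste(cfg$eligible_scores, collapse = ","))
    kept <- dichotomize(flt$records, cfg$imr_cut, cfg$mvo_cut)
    for (tg in cfg$targets) {
      if (!tg %in% names(kept) || all(is.na(kept[[tg]]))) next
      tab <- compare_models(kept, tg, n_starts = cfg$n_starts,
                            seed = cfg$seed, n_perm = cfg$n_perm)
      fits[[tg]] <- tab
      utils::write.csv(tab[, c("model", "r2", "p_value", "n", "converged",
                               "notable")],
                       file.path(cfg$output_dir, paste0("fits_", tg, ".csv")),
                       row.names = FALSE)
      say("%s: best family %s (R2 = %.3f, n = %d); %d/%d fitted", tg,
          tab$model[1], tab$r2[1], tab$n[1], sum(!is.na(tab$r2)), nrow(tab))
    }
  }
  report <- list(n_cubes = length(cubes), K = cfg$K, K2 = cfg$K2,
                 thrombus_ids = th_ids, area_fractions = areas,
                 kfractions = kf, audit = audit, kept_n = kept_n,
                 fits = fits, log = log_lines)
  writeLines(log_lines, file.path(cfg$output_dir, "report.txt"))
  say("pipeline done; artefacts in %s", cfg$output_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
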