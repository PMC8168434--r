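#' Process one patient visit from files to a lesion record
#'
#' Runs the per-visit estimation chain: variable-flip-angle T1 mapping,
#' signal-to-concentration conversion, AIF extraction from the aorta mask,
#' voxelwise extended Tofts fitting inside the lesion mask, co-occurrence
#' texture of the Ktrans map, and ROI summarization.
#'
#' @param dyn_path,vfa_path,lesion_mask_path,aorta_mask_path NIfTI file paths.
#' @param params An [acq_params()].
#' @param patient_id,visit,group Metadata copied into the record.
#' @param conversion `"linear"` (default) or `"exact"` concentration method.
#' @param texture_map Which parameter map feeds the texture stage
#'   (default `"ktrans"`).
#' @param n_levels Gray levels for the texture stage.
#' @param linear_only Use the fast linear Tofts estimate only.
#' @return A `lesion_record` row (see [summarize_lesion()]).
#' @export
process_visit <- function(dyn_path, vfa_path, lesion_mask_path,
                          aorta_mask_path, params,
                          patient_id = "P000", visit = "post", group = "CR",
                          conversion = c("linear", "exact"),
                          texture_map = "ktrans", n_levels = 32,
                          linear_only = FALSE) {
  conversion <- match.arg(conversion)
  dyn <- read_dynamic(dyn_path, params)
  vfa <- read_volume(vfa_path)
  if (length(dim(vfa)) != 4L ||
      dim(vfa)[4] != length(params$flip_angles_t1)) {
    stop("process_visit: VFA file '", vfa_path, "' must hold one volume per ",
         "configured flip angle", call. = FALSE)
  }
  d3 <- dim(dyn$signal)[1:3]
  lesion_mask <- read_mask(lesion_mask_path, d3, dyn_path)
  aorta_mask <- read_mask(aorta_mask_path, d3, dyn_path)
  vols <- lapply(seq_len(dim(vfa)[4]), function(k) {
    array(vfa[, , , k], d3)
  })
  t10 <- vfa_t1_fit(vols, params$flip_angles_t1, params)
  conc <- signal_to_concentration(dyn, t10, params, method = conversion)
  aif <- extract_aif(conc, aorta_mask, params$hematocrit)
  pk <- fit_map(conc, lesion_mask, aif, linear_only = linear_only)
  tex <- lesion_texture(pk[[texture_map]], lesion_mask & pk$fit_ok,
                        n_levels = n_levels)
  summarize_lesion(pk, tex, lesion_mask, patient_id, visit, group)
}

#' Process a simulated or on-disk cohort into a feature table
#'
#' Applies [process_visit()] to every row of a cohort manifest (as written by
#' [make_cohort()]) and pivots the records with [build_table()].
#'
#' @param manifest Cohort manifest data.frame, or the path of a
#'   `manifest.csv`.
#' @param dir Directory the manifest's file paths are relative to; defaults
#'   to the manifest's own directory.
#' @param params An [acq_params()].
#' @param ... Passed to [process_visit()] (conversion, texture settings...).
#' @param verbose Print one line per processed visit.
#' @return A `feature_table`.
#' @export
process_cohort <- function(manifest, dir = NULL, params = acq_params(), ...,
                           verbose = FALSE) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else if (is.null(dir)) {
    dir <- attr(manifest, "out_dir")
    if (is.null(dir)) stop("process_cohort: supply `dir`", call. = FALSE)
  }
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (verbose) {
      message("processing ", row$patient_id, " / ", row$visit)
    }
    process_visit(file.path(dir, row$dynamic), file.path(dir, row$vfa),
                  file.path(dir, row$lesion_mask),
                  file.path(dir, row$aorta_mask),
                  params, patient_id = row$patient_id, visit = row$visit,
                  group = row$class, ...)
  })
  build_table(do.call(rbind, recs))
}

## checksum of a set of files, used for stage skipping
.stage_checksum <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(NA_character_)
  paste(unname(tools::md5sum(sort(paths))), collapse = "")
}

#' Run the full pipeline end to end
#'
#' Orchestrates simulate (optional) -> per-visit estimation -> feature table
#' -> statistics, with stage-level resumability: a stage is skipped when its
#' outputs exist and the checksums of its inputs are unchanged since the
#' previous run (state kept in `run_state.json` under `out_dir`).
#'
#' @param out_dir Working directory for all outputs.
#' @param simulate If `TRUE`, generate a phantom cohort first; otherwise
#'   `cohort_dir` must hold a `manifest.csv` and its volumes.
#' @param n_cr,n_pr,noise_sd,seed Passed to [make_cohort()] when simulating.
#' @param cohort_dir Directory of an existing cohort (ignored when
#'   `simulate = TRUE`).
#' @param params An [acq_params()].
#' @param ... Passed to [process_cohort()].
#' @param verbose Log each stage.
#' @return List with `table` (the `feature_table`), `report` (an
#'   `analysis_report`), and `stages_run` (character vector of executed
#'   stage names).
#' @export
run_all <- function(out_dir, simulate = TRUE, n_cr = 16, n_pr = 16,
                    noise_sd = NULL, seed = 1, cohort_dir = NULL,
                    params = acq_params(), ..., verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(out_dir, "run_state.json")
  state <- if (file.exists(state_path)) {
    jsonlite::read_json(state_path, simplifyVector = TRUE)
  } else list()
  stages_run <- character(0)
  log <- function(...) if (verbose) message("[run_all] ", ...)

  # stage 1: cohort (simulate or locate)
  if (simulate) {
    cohort_dir <- file.path(out_dir, "cohort")
    manifest_path <- file.path(cohort_dir, "manifest.csv")
    sim_key <- paste(n_cr, n_pr, format(noise_sd), seed, sep = "|")
    if (!file.exists(manifest_path) || !identical(state$sim_key, sim_key)) {
      log("simulating cohort (", n_cr, " CR + ", n_pr, " PR)")
      make_cohort(n_cr, n_pr, noise_sd = noise_sd, seed = seed,
                  out_dir = cohort_dir, params = params)
      state$sim_key <- sim_key
      stages_run <- c(stages_run, "simulate")
    } else log("cohort up to date; skipping simulate")
  } else {
    if (is.null(cohort_dir)) stop("run_all: supply cohort_dir", call. = FALSE)
    manifest_path <- file.path(cohort_dir, "manifest.csv")
    if (!file.exists(manifest_path)) {
      stop("run_all: no manifest.csv in ", cohort_dir, call. = FALSE)
    }
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)

  # stage 2: per-visit estimation -> feature table
  table_path <- file.path(out_dir, "features.csv")
  input_files <- c(manifest_path,
                   file.path(cohort_dir,
                             unlist(manifest[, c("dynamic", "vfa",
                                                 "lesion_mask", "aorta_mask")])))
  fit_key <- .stage_checksum(input_files)
  if (!file.exists(table_path) || !identical(state$fit_key, fit_key)) {
    log("fitting ", nrow(manifest), " visits")
    tab <- process_cohort(manifest, dir = cohort_dir, params = params, ...,
                          verbose = verbose)
    write_feature_table(tab, table_path)
    state$fit_key <- fit_key
    stages_run <- c(stages_run, "fit")
  } else {
    log("feature table up to date; skipping fit")
    tab <- read_feature_table(table_path)
  }

  # stage 3: statistics
  report_path <- file.path(out_dir, "report.json")
  stats_key <- .stage_checksum(table_path)
  if (!file.exists(report_path) || !identical(state$stats_key, stats_key)) {
    log("running statistics stage")
    report <- run_full_analysis(tab)
    write_report_json(report, report_path)
    state$stats_key <- stats_key
    stages_run <- c(stages_run, "stats")
  } else {
    log("report up to date; skipping stats")
    report <- run_full_analysis(tab)  # cheap; reconstruct the rich object
  }
  jsonlite::write_json(state, state_path, auto_unbox = TRUE)
  list(table = tab, report = report, stages_run = stages_run)
}

#' Serialize an analysis report to JSON
#'
#' Writes the screening table, retained features, model coefficient table,
#' per-feature and combined-model ROC summaries and DeLong comparisons.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  roc_min <- function(r) {
    if (is.null(r)) return(NULL)
    list(auc = r$auc, ci95 = r$ci95, cutoff = r$cutoff,
         sensitivity = r$sensitivity, specificity = r$specificity)
  }
  out <- list(
    screen = report$screen,
    significant = report$significant,
    retained = report$retained,
    model = if (!is.null(report$model)) {
      cbind(term = rownames(report$model$terms), report$model$terms)
    },
    roc_single = lapply(report$roc_single, roc_min),
    roc_model = roc_min(report$roc_model),
    model_variants = as.list(report$model_variants),
    delong = as.list(report$delong)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
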