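PIPELINE_STAGES <- c("simulate", "render", "segment", "quantify",
                     "classify", "dose_response", "report")

#' Run the analysis pipeline from a single JSON config
#'
#' Orchestrates simulate -> (render -> segment) -> quantify -> classify ->
#' dose_response -> report as a contiguous subsequence of stages, persisting
#' every intermediate file under `out_dir` so any stage can later resume
#' from the CSVs alone. Identical config + seed yields identical output
#' checksums.
#'
#' The JSON config has per-module sections: `simulation` (fields of
#' [sim_config()]), optional `render` (arguments of [render_movie()]),
#' `segmentation` ([segmentation_params()]), `linking`
#' ([linking_params()]), `quantify` ([quantify_cohort()] arguments) and
#' `classify` ([classify_traces()] arguments).
#'
#' @param config_path path to the JSON config.
#' @param stages contiguous subsequence of
#'   `simulate, render, segment, quantify, classify, dose_response, report`.
#' @param out_dir output directory, created if needed.
#' @return The run manifest (also written to `manifest.json`), invisibly:
#'   config snapshot, seed, stages, per-stage cell counts, output files
#'   with md5 checksums, and timestamps.
#' @export
run_pipeline <- function(config_path,
                         stages = c("simulate", "quantify", "classify",
                                    "dose_response", "report"),
                         out_dir = ".") {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  pos <- match(stages, PIPELINE_STAGES)
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("`stages` must be in pipeline order.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, as.list(raw$simulation %||% list()))
  counts <- list()
  log_stage <- function(stage, n_in, n_out, note = "") {
    message(sprintf("[%s] n_in=%s n_out=%s %s", stage, n_in, n_out, note))
    counts[[stage]] <<- list(n_in = n_in, n_out = n_out, note = note)
  }
  path <- function(f) file.path(out_dir, f)
  need <- function(f, stage, producer) {
    if (!file.exists(path(f))) {
      abort(sprintf("stage '%s' requires %s; run '%s' first or place the file in `out_dir`.",
                    stage, f, producer))
    }
  }

  if ("simulate" %in% stages) {
    ts <- simulate_cohort(cfg)
    write_trace_set(ts, path("traces.csv"))
    log_stage("simulate", cfg$n_cells, dplyr::n_distinct(ts$cell_id))
  }
  if ("render" %in% stages) {
    need("traces.csv", "render", "simulate")
    ts <- read_trace_set(path("traces.csv"), stim_time = cfg$stim_time)
    rargs <- as.list(raw$render %||% list())
    rargs$enabled <- NULL
    mv <- do.call(render_movie, c(list(trace_set = ts), rargs,
                                  list(seed = cfg$seed)))
    write_movie_stack(mv, path("movie"))
    log_stage("render", dplyr::n_distinct(ts$cell_id), dim(mv$nluc)[3],
              "frames rendered")
  }
  if ("segment" %in% stages) {
    if (!dir.exists(path("movie"))) {
      abort("stage 'segment' requires movie/; run 'render' first or place the TIFFs in `out_dir`.")
    }
    mv <- read_movie_stack(path("movie"), cycle_time = cfg$cycle_time,
                           stim_time = cfg$stim_time)
    sp <- do.call(segmentation_params, as.list(raw$segmentation %||% list()))
    lp <- do.call(linking_params, as.list(raw$linking %||% list()))
    seg <- segment_movie(mv, sp)
    trj <- track(seg$detections, lp)
    readr::write_csv(trj, path("trajectories.csv"))
    ts <- extract_traces(mv, trj, sp)
    write_trace_set(ts, path("traces.csv"))
    log_stage("segment", nrow(seg$detections),
              dplyr::n_distinct(ts$cell_id), "tracked cells quantified")
  }
  if ("quantify" %in% stages) {
    need("traces.csv", "quantify", "simulate")
    ts <- read_trace_set(path("traces.csv"), stim_time = cfg$stim_time)
    qargs <- as.list(raw$quantify %||% list())
    qargs$crosstalk_coeff <- qargs$crosstalk_coeff %||% cfg$crosstalk_coeff
    feats <- do.call(quantify_cohort, c(list(traces = ts), qargs))
    readr::write_csv(feats, path("features.csv"))
    stats_fields <- c("smad_peak_time", "nc_response", "nc_fold_change",
                      "ctgf_response", "ctgf_init_time", "return_time")
    readr::write_csv(cohort_stats(feats[!feats$excluded, ], stats_fields),
                     path("cohort_stats.csv"))
    log_stage("quantify", dplyr::n_distinct(ts$cell_id), nrow(feats),
              sprintf("%d excluded", sum(feats$excluded)))
  }
  if ("classify" %in% stages) {
    need("traces.csv", "classify", "simulate")
    ts <- read_trace_set(path("traces.csv"), stim_time = cfg$stim_time)
    feats <- if (file.exists(path("features.csv"))) {
      readr::read_csv(path("features.csv"), show_col_types = FALSE)
    }
    cargs <- as.list(raw$classify %||% list())
    cargs$seed <- cargs$seed %||% cfg$seed
    cargs$crosstalk_coeff <- cargs$crosstalk_coeff %||% cfg$crosstalk_coeff
    cr <- do.call(classify_traces,
                  c(list(traces = ts, features = feats), cargs))
    readr::write_csv(tidy(cr), path("labels.csv"))
    if (!is.null(cr$counts)) readr::write_csv(cr$counts, path("contingency.csv"))
    jsonlite::write_json(as.list(glance(cr)), path("cluster_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("classify", dplyr::n_distinct(ts$cell_id), nrow(tidy(cr)))
  }
  if ("dose_response" %in% stages) {
    need("features.csv", "dose_response", "quantify")
    feats <- readr::read_csv(path("features.csv"), show_col_types = FALSE)
    ok <- feats[!feats$excluded, ]
    readr::write_csv(dose_profile(ok), path("dose_profile.csv"))
    corr <- list(amplitude = amplitude_correlation(ok),
                 timing = timing_correlation(ok))
    jsonlite::write_json(corr, path("correlations.json"), digits = NA,
                         dataframe = "rows", na = "null")
    log_stage("dose_response", nrow(ok), nrow(dose_profile(ok)))
  }
  if ("report" %in% stages) {
    report_run(out_dir)
    log_stage("report", NA, NA)
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json"))
  manifest <- list(
    config = unclass(cfg), seed = cfg$seed, stages = stages,
    counts = counts,
    files = as.list(tools::md5sum(file.path(out_dir, files))) |>
      setNames(files),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Collects cohort statistics, class fractions per condition (with the
#' chi-squared fraction test when more than one condition is present) and
#' correlation tables from a [run_pipeline()] output directory into
#' `report.txt`. Sections whose inputs are missing are listed as absent
#' rather than failing.
#'
#' @param out_dir a pipeline output directory.
#' @return A list of the assembled sections, invisibly.
#' @export
report_run <- function(out_dir = ".") {
  path <- function(f) file.path(out_dir, f)
  lines <- c("== pipeline report ==", "")
  sections <- list()

  if (file.exists(path("cohort_stats.csv"))) {
    cs <- readr::read_csv(path("cohort_stats.csv"), show_col_types = FALSE)
    sections$cohort_stats <- cs
    lines <- c(lines, "-- cohort statistics --",
               utils::capture.output(as.data.frame(cs)), "")
  } else {
    lines <- c(lines, "-- cohort statistics: absent (run quantify) --", "")
  }

  if (file.exists(path("contingency.csv"))) {
    cont <- readr::read_csv(path("contingency.csv"), show_col_types = FALSE)
    sections$contingency <- cont
    lines <- c(lines, "-- class counts per condition --",
               utils::capture.output(as.data.frame(cont)))
    cond_cols <- setdiff(names(cont), c("label", "n"))
    conds <- do.call(paste, cont[cond_cols])
    if (dplyr::n_distinct(conds) >= 2 && dplyr::n_distinct(cont$label) >= 2) {
      ft <- fraction_test(data.frame(condition = conds, label = cont$label,
                                     n = cont$n))
      sections$fraction_test <- glance(ft)
      lines <- c(lines, sprintf("chi-squared = %.4g, df = %d, p = %.4g",
                                ft$statistic, ft$dof, ft$p_value))
    } else {
      lines <- c(lines, "(single condition; no fraction test)")
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "-- class counts: absent (run classify) --", "")
  }

  if (file.exists(path("correlations.json"))) {
    corr <- jsonlite::read_json(path("correlations.json"),
                                simplifyVector = TRUE)
    sections$correlations <- corr
    lines <- c(lines, "-- correlations --",
               utils::capture.output(corr), "")
  } else {
    lines <- c(lines, "-- dose/correlation section: absent --", "")
  }

  if (is.null(sections$cohort_stats) && is.null(sections$contingency)) {
    lines <- c(lines, "(empty run: no quantified outputs, zero counts)")
  }
  writeLines(lines, path("report.txt"))
  invisible(sections)
}
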