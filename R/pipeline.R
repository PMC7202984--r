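# Orchestration of the full analysis over perioperative situations A-D.

#' Describe one perioperative situation
#'
#' A situation is a labelled 30-min selection: preoperative (A);
#' postoperative on respirator (B); post-extubation (C); next morning (D).
#' Its data come from exactly one of a simulation config, an in-memory
#' recording, or a recording directory on disk.
#'
#' @param label Situation label, e.g. `"A"`.
#' @param sim A [sim_config()] to simulate the recording from.
#' @param recording A `circ_recording`.
#' @param path Directory holding a recording written by [write_recording()].
#' @param segment_start Start (s) of the analysed segment within the
#'   recording (default 0).
#' @param ventilation Is the patient mechanically ventilated (situation B)?
#' @return A list of class `"circ_situation"`.
#' @export
situation <- function(label, sim = NULL, recording = NULL, path = NULL,
                      segment_start = 0, ventilation = FALSE) {
  sources <- !vapply(list(sim, recording, path), is.null, logical(1))
  if (sum(sources) != 1) {
    abort("give exactly one of `sim`, `recording`, `path`.")
  }
  structure(list(label = label, sim = sim, recording = recording,
                 path = path, segment_start = segment_start,
                 ventilation = ventilation),
            class = "circ_situation")
}

#' Assemble a pipeline configuration
#'
#' @param situations List of [situation()]s with unique labels.
#' @param wavelet A [wavelet_config()].
#' @param segment_length Length of the analysed selection, s (default 1,800).
#' @param fs_out Uniform series rate, Hz (default 10).
#' @param outlier_k Outlier threshold for beat screening.
#' @param pairs Variable pairs for cross-wavelet and cross-correlation
#'   analysis; defaults to (iAmp, iSBP) and (iSBP, iHR).
#' @param ccf_max_lag Largest CCF displacement, s; `NULL` (default) uses
#'   half the period of the pair's dominant spectral peak, so lags are
#'   sought within one half-cycle of the shared oscillation.
#' @param peak_conf Confidence level for [find_spectral_peaks()].
#' @param loess_spans Spans for [loess_decompose()] of each series.
#' @param seed Seed for the surrogate significance null.
#' @return A list of class `"circ_pipeline_config"`.
#' @export
pipeline_config <- function(situations,
                            wavelet = wavelet_config(),
                            segment_length = 1800,
                            fs_out = 10, outlier_k = 4,
                            pairs = list(c("iAmp", "iSBP"), c("iSBP", "iHR")),
                            ccf_max_lag = NULL,
                            peak_conf = 0.99,
                            loess_spans = c(0.3, 0.06, 0.012),
                            seed = 1L) {
  if (!length(situations)) abort("`situations` must not be empty.")
  labels <- vapply(situations, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("situation labels must be unique.")
  structure(list(situations = situations, wavelet = wavelet,
                 segment_length = segment_length, fs_out = fs_out,
                 outlier_k = outlier_k, pairs = pairs,
                 ccf_max_lag = ccf_max_lag,
                 peak_conf = peak_conf,
                 loess_spans = loess_spans, seed = as.integer(seed)),
            class = "circ_pipeline_config")
}

situation_recording <- function(sit, segment_length) {
  rec <- if (!is.null(sit$sim)) generate_recording(sit$sim)$recording
         else if (!is.null(sit$recording)) sit$recording
         else read_recording(sit$path)
  if (rec$duration > segment_length + 1e-9 || sit$segment_start > 0) {
    rec <- select_segment(rec, sit$segment_start, segment_length)
  }
  rec
}

#' Run the full analysis pipeline
#'
#' For every situation: obtain the recording (simulate, reuse or read),
#' select the 30-min segment, extract the uniform series, compute each
#' variable's wavelet spectrum, average power and peaks, then cross-wavelet
#' spectra and cross-correlation lags for the configured variable pairs.  A
#' failing situation is recorded with its error message and the run
#' continues.  The run is deterministic given the seeds in the configuration.
#'
#' @param config A [pipeline_config()], or a path to a YAML file readable by
#'   [read_pipeline_config()].
#' @return A `circ_report`: per-situation results plus the processing log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "circ_pipeline_config"))
  withr::with_seed(config$seed, run_pipeline_impl(config))
}

run_pipeline_impl <- function(config) {
  null_cache <- new.env(parent = emptyenv())
  results <- lapply(config$situations, function(sit) {
    tryCatch(
      analyse_situation(sit, config, null_cache),
      error = function(e) list(label = sit$label, failed = TRUE,
                               error = conditionMessage(e))
    )
  })
  names(results) <- vapply(config$situations, `[[`, character(1), "label")
  structure(list(situations = results, config = config),
            class = "circ_report")
}

analyse_situation <- function(sit, config, null_cache) {
  rec <- situation_recording(sit, config$segment_length)
  ext <- extract_series(rec, fs_out = config$fs_out, k = config$outlier_k)
  series <- ext$series

  spectra <- lapply(series, morlet_cwt, config = config$wavelet)
  avg <- lapply(spectra, average_power)
  peaks <- dplyr::bind_rows(lapply(names(avg), function(v) {
    pk <- find_spectral_peaks(avg[[v]], conf = config$peak_conf)
    if (nrow(pk)) dplyr::mutate(pk, variable = v, .before = 1) else NULL
  }))

  pair_vars <- unique(unlist(config$pairs))
  pair_vars <- pair_vars[pair_vars %in% names(series)]
  aligned <- if (length(pair_vars) >= 2) align_series(series[pair_vars]) else list()

  pair_results <- list()
  for (pair in config$pairs) {
    if (!all(pair %in% names(aligned))) next
    ab <- aligned[pair]
    n_ab <- nrow(ab[[1]])
    # surrogate nulls depend on series length only weakly; reuse any cached
    # null within 2% of this length
    null <- NULL
    for (key in ls(null_cache)) {
      if (abs(null_cache[[key]]$n - n_ab) / n_ab <= 0.02) {
        null <- null_cache[[key]]
        break
      }
    }
    if (is.null(null)) {
      null <- cw_null(n_ab, 1 / config$fs_out, config$wavelet)
      null_cache[[paste0("n", n_ab)]] <- null
    }
    xwt <- cross_wavelet(ab[[1]], ab[[2]], config$wavelet, null = null)
    max_lag <- config$ccf_max_lag
    if (is.null(max_lag)) {
      pk <- peaks[peaks$variable %in% pair, ]
      max_lag <- if (nrow(pk)) min(pk$period[which.max(pk$power)] / 2,
                                   config$segment_length / 4) else 30
    }
    ccf <- cross_correlation(ab[[1]], ab[[2]], max_lag = max_lag)
    pair_results[[paste(pair, collapse = "-")]] <-
      list(pair = pair, xwt = xwt, ccf = ccf)
  }

  list(label = sit$label, failed = FALSE, ventilation = sit$ventilation,
       series = series, avg_spectra = avg, peaks = peaks,
       pairs = pair_results, log = ext$log,
       seed = rec$meta$seed %||% NA_integer_)
}

#' @export
print.circ_report <- function(x, ...) {
  cat("<circ_report> situations:",
      paste(names(x$situations), collapse = ", "), "\n")
  for (s in x$situations) {
    if (isTRUE(s$failed)) {
      cat("  ", s$label, ": FAILED (", s$error, ")\n", sep = "")
    } else {
      cat("  ", s$label, ": ", nrow(s$peaks), " spectral peak(s); pairs: ",
          paste(names(s$pairs), collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tabulate which spectral peaks of a baseline situation persist elsewhere
#'
#' For every peak detected in the baseline situation's average spectra,
#' records whether the same variable shows a peak within one voice step
#' (one grid step of the log2 period grid) in each other situation — an
#' explicit, configurable proxy for the visual judgement of an oscillation
#' being "lost" after an intervention.
#'
#' @param report A `circ_report`.
#' @param baseline Label of the reference situation.
#' @param others Labels to compare against (default: all other situations).
#' @return A tibble with `variable`, `period`, `situation`, `retained`.
#' @export
compare_situations <- function(report, baseline, others = NULL) {
  stopifnot(inherits(report, "circ_report"))
  labels <- names(report$situations)
  others <- others %||% setdiff(labels, baseline)
  if (!baseline %in% labels || !all(others %in% labels)) {
    abort("unknown situation label.")
  }
  base <- report$situations[[baseline]]
  if (isTRUE(base$failed)) abort("baseline situation failed.")
  step <- 1 / report$config$wavelet$voices_per_octave
  out <- list()
  for (i in seq_len(nrow(base$peaks))) {
    v <- base$peaks$variable[i]
    p <- base$peaks$period[i]
    for (lab in others) {
      other <- report$situations[[lab]]
      if (isTRUE(other$failed)) next
      op <- other$peaks[other$peaks$variable == v, ]
      out[[length(out) + 1]] <- tibble(
        variable = v, period = p, situation = lab,
        retained = nrow(op) > 0 &&
          any(abs(log2(op$period / p)) <= step + 1e-9)
      )
    }
  }
  if (!length(out)) return(tibble(variable = character(), period = numeric(),
                                  situation = character(), retained = logical()))
  dplyr::bind_rows(out)
}
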