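# Plain-text readers and writers: recordings as delimited channels with a
# key-value sidecar, series and result tables as TSV.

write_keyvals <- function(x, path) {
  lines <- vapply(names(x), function(k) paste0(k, ": ", x[[k]]), character(1))
  writeLines(lines, path)
}

read_keyvals <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

#' Write / read a raw recording as delimited text with a metadata sidecar
#'
#' `signals.tsv` holds one column per channel plus `time`; `meta.txt` is a
#' key-value sidecar with the sampling rate, channel units, seed and a
#' one-line echo of the generating configuration.  The ground-truth ledger,
#' when given, is written alongside as `ledger_beats.tsv` and
#' `ledger_episodes.tsv`.
#'
#' @param recording A `circ_recording`.
#' @param dir Output directory (created if needed).
#' @param ledger Optional `circ_ledger` to store with the recording.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, ledger = NULL) {
  stopifnot(inherits(recording, "circ_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(recording$signals, file.path(dir, "signals.tsv"),
                   progress = FALSE)
  channels <- setdiff(names(recording$signals), "time")
  meta <- list(
    fs = recording$fs,
    duration = recording$duration,
    channels = paste(channels, collapse = ","),
    units = paste(recording$units[channels], collapse = ","),
    seed = recording$meta$seed %||% NA,
    config = paste(deparse(recording$meta$config, width.cutoff = 500),
                   collapse = " ")
  )
  write_keyvals(meta, file.path(dir, "meta.txt"))
  if (!is.null(ledger)) {
    readr::write_tsv(ledger$beats, file.path(dir, "ledger_beats.tsv"),
                     progress = FALSE)
    readr::write_tsv(ledger$noise_episodes,
                     file.path(dir, "ledger_episodes.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- read_keyvals(file.path(dir, "meta.txt"))
  signals <- readr::read_tsv(file.path(dir, "signals.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  channels <- strsplit(meta$channels, ",")[[1]]
  units <- stats::setNames(strsplit(meta$units, ",")[[1]], channels)
  structure(list(signals = signals, fs = as.numeric(meta$fs),
                 duration = as.numeric(meta$duration), units = units,
                 meta = list(seed = suppressWarnings(as.integer(meta$seed)))),
            class = "circ_recording")
}

#' Write / read a uniform series as two-column delimited text
#'
#' @param series A `circ_series`.
#' @param path Output file (`time_s`, `value` columns, tab-separated).
#' @export
write_series <- function(series, path) {
  readr::write_tsv(tibble(time_s = series$time, value = series$value), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param fs Sampling rate to attach on read, Hz.
#' @param name Series name to attach on read.
#' @export
read_series <- function(path, fs = 10, name = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_series(tibble(time = df$time_s, value = df$value), fs = fs, name = name)
}

#' Write the tabular products of a pipeline run
#'
#' One subdirectory per situation: average spectra (`avgspec_<var>.tsv`),
#' detected peaks, per-pair CCF curves, cross-wavelet significance masks
#' (0/1 matrices with a time header row and period first column) and the
#' processing log.
#'
#' @param report A `circ_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "circ_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in report$situations) {
    sdir <- file.path(dir, paste0("situation_", s$label))
    dir.create(sdir, showWarnings = FALSE)
    if (isTRUE(s$failed)) {
      writeLines(s$error, file.path(sdir, "FAILED.txt"))
      next
    }
    for (v in names(s$avg_spectra)) {
      readr::write_tsv(tibble(period_s = s$avg_spectra[[v]]$period,
                              avg_power = s$avg_spectra[[v]]$power),
                       file.path(sdir, paste0("avgspec_", v, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(s$peaks, file.path(sdir, "peaks.tsv"), progress = FALSE)
    readr::write_tsv(s$log, file.path(sdir, "log.tsv"), progress = FALSE)
    for (nm in names(s$pairs)) {
      pr <- s$pairs[[nm]]
      readr::write_tsv(as_tibble(pr$ccf),
                       file.path(sdir, paste0("ccf_", nm, ".tsv")),
                       progress = FALSE)
      mask <- cbind(period_s = pr$xwt$periods,
                    as.data.frame(pr$xwt$significant * 1L))
      names(mask)[-1] <- as.character(round(pr$xwt$times, 3))
      readr::write_tsv(as_tibble(mask),
                       file.path(sdir, paste0("xwt_significant_", nm, ".tsv")),
                       progress = FALSE)
    }
  }
  invisible(dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: a `situations` list (each entry a
#' `label` plus either a `preset` name / `sim` parameter block, or a `path`
#' to a recording directory, with optional `segment_start` and
#' `ventilation`), and optional `wavelet`, `segment_length`, `fs_out`,
#' `outlier_k`, `pairs`, `ccf_max_lag`, `peak_prominence`, `loess_spans`,
#' `seed` entries.  Simulation blocks may include a `modulations` list with
#' `period`, `targets`, `depth`, `lead_lag` fields.
#'
#' @param path YAML file path.
#' @return A `circ_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$situations)) abort("config must define `situations`.")
  sits <- lapply(y$situations, function(s) {
    sim <- NULL
    if (!is.null(s$preset)) {
      sim <- sim_preset(s$preset, seed = s$seed %||% y$seed %||% 1L)
    } else if (!is.null(s$sim)) {
      args <- s$sim
      if (!is.null(args$modulations)) {
        args$modulations <- lapply(args$modulations, function(m) {
          modulation_spec(m$period, unlist(m$targets),
                          depth = unlist(m$depth),
                          lead_lag = unlist(m$lead_lag) %||% 0)
        })
      }
      if (!is.null(args$respiration)) {
        args$respiration <- do.call(resp_spec, args$respiration)
      }
      sim <- do.call(sim_config, args)
    }
    situation(s$label, sim = sim, path = s$path,
              segment_start = s$segment_start %||% 0,
              ventilation = isTRUE(s$ventilation))
  })
  wav <- if (is.null(y$wavelet)) wavelet_config() else
    do.call(wavelet_config, y$wavelet)
  args <- list(situations = sits, wavelet = wav)
  for (k in c("segment_length", "fs_out", "outlier_k", "ccf_max_lag",
              "peak_prominence", "loess_spans", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$pairs)) args$pairs <- lapply(y$pairs, unlist)
  do.call(pipeline_config, args)
}
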