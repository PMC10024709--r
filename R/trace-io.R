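# Plain-text trace formats and the packaged fixture generator. All files are
# CSV; traces use the dialect "t_ms,Vm_mV" with stimulus times carried in a
# leading comment line.

#' Write / read a voltage trace as CSV
#'
#' Dialect: optional comment line `# stim_times_ms=50,1050,...`, header
#' `t_ms,Vm_mV`, then one row per sample. On read, uniform sampling is
#' verified (max grid jitter below 1e-6 ms).
#'
#' @param trace a `voltage_trace`.
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `voltage_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(trace$stim_times))
    writeLines(sprintf("# stim_times_ms=%s",
                       paste(format(trace$stim_times, trim = TRUE),
                             collapse = ",")), con)
  writeLines("t_ms,Vm_mV", con)
  writeLines(sprintf("%.10g,%.10g", trace$t, trace$Vm), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  lines <- readLines(path)
  stims <- numeric()
  while (length(lines) && startsWith(lines[1], "#")) {
    if (grepl("^# stim_times_ms=", lines[1]))
      stims <- as.numeric(strsplit(sub("^# stim_times_ms=", "", lines[1]),
                                   ",")[[1]])
    lines <- lines[-1]
  }
  if (!length(lines) || lines[1] != "t_ms,Vm_mV")
    stop("missing 't_ms,Vm_mV' header in ", path)
  df <- utils::read.csv(textConnection(lines))
  if (nrow(df) < 2) stop("trace needs at least two samples: ", path)
  dts <- diff(df$t_ms)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-6)
  if (length(bad))
    stop(sprintf("non-uniform sampling grid in %s (first offending index: %d)",
                 path, bad[1]))
  voltage_trace(df$t_ms, df$Vm_mV, dt, stims)
}

#' Write a current trace as CSV (`t_ms,I_pApF`)
#' @param trace a `current_trace`.
#' @param path file path.
#' @export
write_current <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(t_ms = trace$t, I_pApF = trace$I), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort biomarker table as CSV
#' @param table a `cohort_table` data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  missing <- setdiff(biomarker_columns(), names(out))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Emit the deterministic synthetic fixture set
#'
#' Writes, under `outdir`: one atrial and one ventricular preset DC trace
#' under each of the four IK1 formulations (8 traces), a 46-cell cohort
#' biomarker CSV, and the default atrial titration table; plus a manifest
#' listing every file with its MD5 hash. All content is synthetic and fully
#' determined by `seed`.
#'
#' @param outdir writable output directory (created if needed).
#' @param seed master seed.
#' @param protocol pacing protocol used for the traces.
#' @param cohort_n cohort size.
#' @return (invisibly) the manifest data frame (`file`, `md5`), also written
#'   to `manifest.csv`.
#' @export
write_fixture_suite <- function(outdir, seed = 1L,
                                protocol = stim_protocol(n_beats = 8,
                                                         discard_beats = 3),
                                cohort_n = 46) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  cells <- list(atrial = make_preset("atrial", seed = seed),
                ventricular = make_preset("ventricular", seed = seed + 1L))
  for (ph in names(cells)) {
    for (fm in c("ventr", "atr", "test1", "test2")) {
      dc <- run_dc(cells[[ph]], ik1_config(fm, scaling_DC = 1), protocol)
      f <- file.path(outdir, sprintf("trace_%s_%s.csv", ph, fm))
      write_trace(dc$voltage, f)
      files <- c(files, f)
    }
  }
  cohort <- generate_cohort(cohort_n, atrial_fraction = 0.5, seed = seed)
  tab <- cohort_biomarkers(cohort, protocol = protocol)
  f <- file.path(outdir, "cohort_biomarkers.csv")
  write_cohort_csv(tab, f)
  files <- c(files, f)
  tt <- titrate_gk1(cells$atrial, "atr", protocol = protocol)
  f <- file.path(outdir, "titration_atr.csv")
  utils::write.csv(as.data.frame(tt), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
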