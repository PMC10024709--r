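# Virtual dynamic clamp: couples an IK1 formulation to the virtual cell at
# 5 kHz (0.2 ms zero-order hold, one-sample latency), with real-time-like
# formulation switching, AP-clamp playback, and conductance titration.

seg_row <- function(cfg, start_sample = 0L) {
  k <- ik1_constants(cfg$formulation)
  type <- if (cfg$formulation == "atr") 2 else 1
  G <- ik1_g_eff(cfg)
  c(start_sample, type, G,
    if (isTRUE(k$gated)) k$xinf_mid else 144.59,
    if (isTRUE(k$gated)) k$rk1_mid else 105.8,
    if (isTRUE(k$gated)) k$rk1_slope else 9.493)
}

#' Open a dynamic-clamp session
#'
#' A session is the executable plan of one DC recording: a cell, a pacing
#' protocol, an initial IK1 formulation, and any scheduled formulation
#' switches. Execute it with [run_dc()].
#'
#' @param cell a [make_preset()] virtual cell.
#' @param cfg the initial [ik1_config()].
#' @param protocol a [stim_protocol()].
#' @return an object of class `dc_session`.
#' @export
dc_session <- function(cell, cfg, protocol = stim_protocol()) {
  stopifnot(inherits(cell, "virtual_cell"), inherits(cfg, "ik1_config"),
            inherits(protocol, "stim_protocol"))
  structure(list(cell = cell, cfg = cfg, protocol = protocol,
                 switches = list(),
                 log = sprintf("t=0 ms: formulation %s, scaling %.3g",
                               cfg$formulation, cfg$scaling_DC)),
            class = "dc_session")
}

#' Schedule an in-run formulation switch
#'
#' The new formulation takes over at the first sampling instant at or after
#' `at_ms`; its gate (if any) is re-initialized to the steady state at the
#' instantaneous membrane potential, as a real-time module swap would do.
#'
#' @param session a [dc_session()].
#' @param new_cfg the [ik1_config()] to switch to.
#' @param at_ms switch time, ms from the start of the recording.
#' @return the updated session (run it with [run_dc()]).
#' @export
switch_formulation <- function(session, new_cfg, at_ms) {
  stopifnot(inherits(session, "dc_session"), inherits(new_cfg, "ik1_config"))
  if (!is.numeric(at_ms) || at_ms < 0) stop("`at_ms` must be >= 0")
  session$switches <- c(session$switches,
                        list(list(cfg = new_cfg, at_ms = at_ms)))
  session$log <- c(session$log,
                   sprintf("t=%g ms: switch to formulation %s, scaling %.3g",
                           at_ms, new_cfg$formulation, new_cfg$scaling_DC))
  session
}

#' Run the virtual dynamic-clamp loop
#'
#' The injected IK1 is recomputed once per 0.2 ms sample from the most recent
#' membrane potential and held constant within the interval (zero-order hold,
#' emulating a 5 kHz real-time loop); gated formulations carry their gate
#' state across samples. With `scaling_DC = 0` the voltage trace is bitwise
#' identical to [simulate_ap()] under the same solver settings.
#'
#' @param x a `virtual_cell` (with `cfg` supplied) or a [dc_session()].
#' @param cfg the [ik1_config()] to inject (cell interface only).
#' @param protocol a [stim_protocol()].
#' @param ... passed to the integrator: `dt`, `dt_internal`, `noise_sd`,
#'   `seed`, `continuous`.
#' @return list with elements `voltage` (`voltage_trace`), `current`
#'   (`current_trace`, the injected IK1, outward positive) and `log`.
#' @export
run_dc <- function(x, ...) UseMethod("run_dc")

#' @rdname run_dc
#' @export
run_dc.virtual_cell <- function(x, cfg, protocol = stim_protocol(), ...) {
  run_dc(dc_session(x, cfg, protocol), ...)
}

#' @rdname run_dc
#' @export
run_dc.dc_session <- function(x, ...) {
  dt <- list(...)$dt
  if (is.null(dt)) dt <- 0.2
  segs <- rbind(seg_row(x$cfg, 0L))
  for (sw in x$switches)
    segs <- rbind(segs, seg_row(sw$cfg, as.integer(ceiling(sw$at_ms / dt))))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  ctx <- sprintf("DC run (%s, scaling %.3g)",
                 x$cfg$formulation, x$cfg$scaling_DC)
  out <- run_sim(x$cell, x$protocol, segments = segs, context = ctx, ...)
  out$log <- x$log
  out
}

#' AP-clamp playback of an IK1 formulation
#'
#' Drives the formulation with a fixed recorded voltage trace and reads out
#' the current it would pass, sample by sample; gated formulations integrate
#' their gate (Rush-Larsen) along the trace, starting from steady state at
#' the first sample.
#'
#' @param cfg an [ik1_config()].
#' @param trace a uniformly sampled `voltage_trace`.
#' @return a `current_trace` aligned with `trace` (outward positive).
#' @export
ap_clamp <- function(cfg, trace) {
  stopifnot(inherits(cfg, "ik1_config"), inherits(trace, "voltage_trace"))
  dts <- diff(trace$t)
  if (length(dts) && max(abs(dts - trace$dt)) > 1e-6)
    stop("`trace` must be uniformly sampled for AP-clamp playback")
  V <- trace$Vm
  if (cfg$formulation == "atr") {
    I <- ik1_atr(V, cfg)
  } else {
    k <- ik1_constants(cfg$formulation)
    n <- length(V)
    I <- numeric(n)
    xk1 <- xk1_inf(V[1], cfg$Ko, k$xinf_mid)
    for (i in seq_len(n)) {
      I[i] <- ik1_g_eff(cfg) * sqrt(cfg$Ko) * xk1 *
        rk1(V[i], cfg$Ko, k$rk1_mid, k$rk1_slope) * (V[i] - cfg$EK)
      if (i < n) {
        xi <- xk1_inf(V[i], cfg$Ko, k$xinf_mid)
        xk1 <- xi + (xk1 - xi) * exp(-trace$dt / xk1_tau(V[i]))
      }
    }
  }
  current_trace(trace$t, I, trace$dt)
}

#' Titrate the injected IK1 conductance
#'
#' One DC run per scaling value, with the tracked AP biomarkers (diastolic
#' potential under DC, APD90, APD20/APD90, APA) aggregated as the median over
#' the analyzed beats. Default grids follow the published titration design:
#' 0.2 to 1 in 0.05 steps for the atrial formulation and 0.4 to 2 in 0.1
#' steps for the ventricular one (17 points each). A per-point simulation
#' failure is recorded and flagged; the table is still returned.
#'
#' @param cell a `virtual_cell`.
#' @param formulation `"atr"` or `"ventr"`.
#' @param grid increasing scaling values; `NULL` for the formulation default.
#' @param protocol a [stim_protocol()].
#' @param ... passed to [run_dc()].
#' @return a `titration_table` data frame (one row per grid point, columns
#'   `scaling`, `G_nSpF`, `E_diast`, `APD90`, `APD20_APD90`, `APA`, `ok`)
#'   with attributes `formulation` and `G_base`.
#' @export
titrate_gk1 <- function(cell, formulation = c("atr", "ventr"), grid = NULL,
                        protocol = stim_protocol(), ...) {
  formulation <- match.arg(formulation)
  if (is.null(grid))
    grid <- if (formulation == "atr") seq(0.2, 1, by = 0.05)
            else seq(0.4, 2, by = 0.1)
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be non-empty and strictly increasing")
  G_base <- ik1_config(formulation)$G_base
  rows <- lapply(grid, function(s) {
    cfg <- ik1_config(formulation, scaling_DC = s)
    res <- tryCatch({
      dc <- run_dc(cell, cfg, protocol, ...)
      bm <- extract_biomarkers(dc$voltage,
                               discard_beats = protocol$discard_beats)
      data.frame(scaling = s, G_nSpF = s * G_base, E_diast = bm$E_diast_DC,
                 APD90 = bm$APD90, APD20_APD90 = bm$ratio_20_90,
                 APA = bm$APA, ok = TRUE)
    }, error = function(e) {
      warning(sprintf("titration point scaling=%.3g failed: %s",
                      s, conditionMessage(e)), call. = FALSE)
      data.frame(scaling = s, G_nSpF = s * G_base, E_diast = NA_real_,
                 APD90 = NA_real_, APD20_APD90 = NA_real_, APA = NA_real_,
                 ok = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "formulation") <- formulation
  attr(out, "G_base") <- G_base
  class(out) <- c("titration_table", "data.frame")
  out
}

#' Detect the critical conductance on a titration table
#'
#' The critical conductance is defined here as the smallest grid value from
#' which every tracked biomarker changes by less than `rel_tol` (relative)
#' between all consecutive remaining grid points — a plateau criterion. The
#' quantitative stabilisation rule is this package's own definition (the
#' titration design gives grids, not a threshold) and is configurable.
#'
#' Changes are measured relative to each biomarker's own magnitude, except
#' for the triangulation ratio APD20/APD90, which is bounded by 1 and is
#' therefore measured on the unit scale (an absolute change of `rel_tol`).
#'
#' @param table a `titration_table` from [titrate_gk1()] (or any data frame
#'   with the same biomarker columns and a `scaling` column; >= 3 usable
#'   rows). Failed points (`ok = FALSE`) are ignored.
#' @param rel_tol relative plateau tolerance (default 0.03).
#' @param G_base base conductance used to convert scaling to nS/pF; defaults
#'   to the table's `G_base` attribute.
#' @return list of class `critical_gk1`: `converged`, `scaling`,
#'   `conductance` (nS/pF; `NA` if no plateau was found — not an error).
#' @export
find_critical_gk1 <- function(table, rel_tol = 0.03,
                              G_base = attr(table, "G_base")) {
  cols <- c("E_diast", "APD90", "APD20_APD90", "APA")
  stopifnot(all(cols %in% names(table)))
  tab <- if ("ok" %in% names(table)) table[table$ok, , drop = FALSE] else table
  if (nrow(tab) < 3) stop("need >= 3 usable grid points")
  m <- nrow(tab)
  relchg <- sapply(cols, function(cl) {
    x <- tab[[cl]]
    scale_floor <- if (cl == "APD20_APD90") 1 else 1e-9
    abs(diff(x)) / pmax(abs(x[-m]), scale_floor)
  })
  relchg <- matrix(relchg, nrow = m - 1)
  stable_from <- NA_integer_
  for (k in seq_len(m - 1)) {
    if (all(relchg[k:(m - 1), ] < rel_tol)) { stable_from <- k; break }
  }
  if (is.na(stable_from))
    return(structure(list(converged = FALSE, scaling = NA_real_,
                          conductance = NA_real_, rel_tol = rel_tol),
                     class = "critical_gk1"))
  s <- tab$scaling[stable_from]
  structure(list(converged = TRUE, scaling = s,
                 conductance = if (is.null(G_base)) NA_real_ else s * G_base,
                 rel_tol = rel_tol),
            class = "critical_gk1")
}

#' @export
print.critical_gk1 <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "critical G_K1: scaling %.3g (%.3g nS/pF), plateau tolerance %.1f%%\n",
      x$scaling, x$conductance, 100 * x$rel_tol))
  else
    cat(sprintf("no plateau found at tolerance %.1f%%\n", 100 * x$rel_tol))
  invisible(x)
}
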