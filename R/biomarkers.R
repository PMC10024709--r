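# Extraction of the nine per-cell electrical biomarkers from paced voltage
# traces, and beat-to-beat repolarization variability (STV, Poincare pairs).

#' Extract action-potential biomarkers from a paced voltage trace
#'
#' Computes the per-cell electrical biomarkers from the analyzed (typically
#' dynamic-clamp) recording: diastolic potential, APD90/APD50/APD20 and their
#' triangulation ratio, maximal upstroke velocity, and AP amplitude. Values
#' are computed per beat and aggregated by the median across analyzed beats
#' (robust to a single anomalous beat). Per-beat conventions:
#' \itemize{
#'   \item diastolic potential = mean Vm over the 10-to-1 ms window before
#'     the stimulus;
#'   \item AP onset fiducial = the instant of maximal forward-difference
#'     dV/dt in the upstroke (configurable alternative: crossing of
#'     `onset_threshold` mV);
#'   \item APDx = time from the onset fiducial to the first downward
#'     crossing of `V_peak - (x/100) * APA` after the peak, located by
#'     linear interpolation between samples;
#'   \item a beat must overshoot 0 mV to count as an AP; a beat whose
#'     repolarization never reaches the 90 percent level within its cycle is
#'     excluded with a warning.
#' }
#'
#' @param trace the analyzed `voltage_trace` (its own diastolic potential is
#'   reported as `E_diast_DC`).
#' @param trace_no_dc optional companion no-injection trace of the same cell;
#'   supplies the unassisted `E_diast` (recorded `NA` when absent).
#' @param Cm cell membrane capacitance, pF (metadata carried from the cell).
#' @param discard_beats initial beats excluded as transient.
#' @param fiducial `"dVdt_max"` (default) or `"threshold"`.
#' @param onset_threshold mV, used when `fiducial = "threshold"`.
#' @return an object of class `ap_biomarkers`: the nine biomarker fields
#'   (`Cm`, `E_diast`, `E_diast_DC`, `APD90`, `APD50`, `APD20`,
#'   `ratio_20_90`, `dVdt_max`, `APA`) plus a `per_beat` data frame.
#' @export
extract_biomarkers <- function(trace, trace_no_dc = NULL, Cm = NA_real_,
                               discard_beats = 5,
                               fiducial = c("dVdt_max", "threshold"),
                               onset_threshold = -20) {
  stopifnot(inherits(trace, "voltage_trace"))
  fiducial <- match.arg(fiducial)
  stims <- trace$stim_times
  if (length(stims) <= discard_beats)
    stop("trace has no analyzable beat after transient discard")
  stims_used <- stims[-seq_len(discard_beats)]
  if (discard_beats == 0) stims_used <- stims
  period <- if (length(stims) > 1) stats::median(diff(stims))
            else max(trace$t) - stims
  t <- trace$t; V <- trace$Vm; dt <- trace$dt

  beat_rows <- lapply(seq_along(stims_used), function(k) {
    s <- stims_used[k]
    win <- which(t >= s & t < s + period)
    if (length(win) < 10) return(NULL)
    pre <- which(t >= s - 10 & t <= s - 1)
    e_d <- mean(V[pre])
    i_peak <- win[which.max(V[win])]
    v_peak <- V[i_peak]
    if (v_peak < 0) return("no_ap")
    up <- win[1]:i_peak
    if (length(up) < 2) return("no_ap")
    dv <- diff(V[up]) / dt  # mV/ms = V/s
    j <- which.max(dv)
    dvdt_max <- dv[j]
    t0 <- if (fiducial == "dVdt_max") t[up[j]] else {
      cr <- which(V[up[-length(up)]] < onset_threshold &
                  V[up[-1]] >= onset_threshold)[1]
      if (is.na(cr)) t[up[j]] else t[up[cr]]
    }
    apa <- v_peak - e_d
    apd_at <- function(x) {
      thr <- v_peak - (x / 100) * apa
      seg <- i_peak:(win[length(win)] - 1)
      cr <- which(V[seg] > thr & V[seg + 1] <= thr)[1]
      if (is.na(cr)) return(NA_real_)
      j0 <- seg[cr]
      tc <- t[j0] + dt * (V[j0] - thr) / (V[j0] - V[j0 + 1])
      tc - t0
    }
    apd90 <- apd_at(90)
    if (is.na(apd90)) {
      warning(sprintf(
        "beat %d: repolarization never reached the 90%% level; excluded", k),
        call. = FALSE)
      return(NULL)
    }
    data.frame(beat = k, E_diast = e_d, V_peak = v_peak, APA = apa,
               dVdt_max = dvdt_max, APD90 = apd90, APD50 = apd_at(50),
               APD20 = apd_at(20))
  })
  if (all(vapply(beat_rows, function(x) identical(x, "no_ap") || is.null(x),
                 logical(1))) &&
      any(vapply(beat_rows, function(x) identical(x, "no_ap"), logical(1))))
    stop("no AP detected: no beat overshoots 0 mV")
  beat_rows <- Filter(function(x) is.data.frame(x), beat_rows)
  if (!length(beat_rows))
    stop("no AP detected: no analyzable beat in trace")
  pb <- do.call(rbind, beat_rows)
  pb$ratio_20_90 <- pb$APD20 / pb$APD90

  e_no_dc <- NA_real_
  if (!is.null(trace_no_dc)) {
    stopifnot(inherits(trace_no_dc, "voltage_trace"))
    st0 <- trace_no_dc$stim_times
    st0 <- if (length(st0) > discard_beats) st0[-seq_len(discard_beats)] else st0
    e_no_dc <- stats::median(vapply(st0, function(s) {
      pre <- which(trace_no_dc$t >= s - 10 & trace_no_dc$t <= s - 1)
      mean(trace_no_dc$Vm[pre])
    }, numeric(1)))
  }

  med <- function(x) stats::median(x, na.rm = TRUE)
  structure(list(
    Cm = Cm, E_diast = e_no_dc, E_diast_DC = med(pb$E_diast),
    APD90 = med(pb$APD90), APD50 = med(pb$APD50), APD20 = med(pb$APD20),
    ratio_20_90 = med(pb$ratio_20_90), dVdt_max = med(pb$dVdt_max),
    APA = med(pb$APA), per_beat = pb, fiducial = fiducial
  ), class = "ap_biomarkers")
}

#' @export
print.ap_biomarkers <- function(x, ...) {
  cat(sprintf(
    "AP biomarkers (%d beats, onset fiducial: %s)\n",
    nrow(x$per_beat), x$fiducial))
  cat(sprintf("  E_diast %s mV | E_diast(DC) %.1f mV | APA %.1f mV | dV/dt_max %.1f V/s\n",
              ifelse(is.na(x$E_diast), "NA", sprintf("%.1f", x$E_diast)),
              x$E_diast_DC, x$APA, x$dVdt_max))
  cat(sprintf("  APD90 %.1f | APD50 %.1f | APD20 %.1f ms | APD20/APD90 %.3f\n",
              x$APD90, x$APD50, x$APD20, x$ratio_20_90))
  invisible(x)
}

#' Short-term variability of APD90
#'
#' `STV = sum(|APD_(n+1) - APD_n|) / (n_beats * sqrt(2))` over `n_beats`
#' consecutive differences — the mean orthogonal deviation from the identity
#' line of the Poincare plot of consecutive APDs. A series of
#' `n_beats + 1` values is required so that the divisor matches the number
#' of differences exactly.
#'
#' @param apd_values consecutive-beat APD90 values, ms (length
#'   `n_beats + 1`).
#' @param n_beats number of consecutive differences (default 30).
#' @return list of class `stv_result`: `stv` (ms) and `poincare_pairs`
#'   (data frame `APD_n`, `APD_n1` with `n_beats` rows).
#' @export
stv <- function(apd_values, n_beats = 30) {
  if (length(apd_values) != n_beats + 1)
    stop(sprintf("`apd_values` must contain exactly n_beats + 1 = %d values, got %d",
                 n_beats + 1, length(apd_values)))
  d <- diff(apd_values)
  structure(list(
    stv = sum(abs(d)) / (n_beats * sqrt(2)),
    poincare_pairs = data.frame(APD_n = apd_values[-(n_beats + 1)],
                                APD_n1 = apd_values[-1])
  ), class = "stv_result")
}

#' Linear STV vs APD90 regression with a 95 percent confidence band
#'
#' Ordinary least squares of STV on APD90 with the standard t-based
#' confidence band of the fitted line at each abscissa.
#'
#' @param points data frame (or 2-column matrix) with APD90 (ms) in the
#'   first column and STV (ms) in the second; >= 3 points.
#' @param band_n number of abscissas at which the band is evaluated.
#' @return list: `slope`, `intercept`, `model` (the `lm` fit) and `band`
#'   (data frame `APD90`, `fit`, `lwr`, `upr`).
#' @export
stv_apd_regression <- function(points, band_n = 50) {
  points <- as.data.frame(points)
  if (nrow(points) < 3) stop("need >= 3 (APD90, STV) points")
  names(points)[1:2] <- c("APD90", "STV")
  if (stats::var(points$APD90) == 0)
    stop("APD90 values have zero variance; regression undefined")
  fit <- stats::lm(STV ~ APD90, data = points)
  xs <- seq(min(points$APD90), max(points$APD90), length.out = band_n)
  pr <- stats::predict(fit, newdata = data.frame(APD90 = xs),
                       interval = "confidence", level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       model = fit,
       band = data.frame(APD90 = xs, fit = pr[, "fit"], lwr = pr[, "lwr"],
                         upr = pr[, "upr"]))
}
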