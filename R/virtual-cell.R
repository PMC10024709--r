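# Synthetic immature-cardiomyocyte surrogate: a minimal Hodgkin-Huxley-style
# membrane model standing in for patched hiPSC-CM. Units throughout: time ms,
# potential mV, current density pA/pF, conductance nS/pF.

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Build a virtual immature-cardiomyocyte parameter set
#'
#' Presets emulate the two dominant hiPSC-CM phenotypes as they present in
#' standard culture: a deliberately weak native inward rectifier leaves the
#' unassisted diastolic potential depolarized (circa -70 to -50 mV), the
#' atrial preset expresses the ultrarapid delayed rectifier (`g_Kur > 0`,
#' fast phase-1 repolarization, triangular AP), and the ventricular preset
#' has a larger L-type-like plateau conductance with `g_Kur = 0`. Parameters
#' receive multiplicative log-normal jitter (CV `cv`, default 0.15) so that
#' seeded cohorts are heterogeneous but reproducible.
#'
#' @param phenotype `"atrial"` or `"ventricular"`.
#' @param maturity in `[0, 1]`; scales the native IK1 conductance (higher
#'   maturity, slightly more negative unassisted diastolic potential).
#' @param seed integer seed controlling the parameter jitter.
#' @param cv coefficient of variation of the log-normal jitter.
#' @return an object of class `virtual_cell`.
#' @export
make_preset <- function(phenotype = c("atrial", "ventricular"),
                        maturity = 0.5, seed = 1L, cv = 0.15) {
  phenotype <- match.arg(phenotype)
  if (!is.numeric(maturity) || maturity < 0 || maturity > 1)
    stop("`maturity` must lie in [0, 1]")
  base <- if (phenotype == "atrial") {
    list(Cm = 70, g_Na = 2.4, g_CaL = 0.18, g_Krep = 0.03, g_Kur = 0.06,
         tau_f = 150, tau_n = 60)
  } else {
    list(Cm = 70, g_Na = 2.0, g_CaL = 0.38, g_Krep = 0.06, g_Kur = 0,
         tau_f = 200, tau_n = 150)
  }
  base$g_K1_native <- 0.036 + 0.036 * maturity
  base$g_leak <- 0.03
  base$E_leak <- -20
  sdlog <- sqrt(log(1 + cv^2))
  cell <- with_preserved_seed(seed, {
    jit <- function(x) if (x > 0)
      x * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else x
    out <- lapply(base[c("Cm", "g_Na", "g_CaL", "g_Krep", "g_Kur",
                         "tau_f", "tau_n")], jit)
    # the background conductances share one density factor: their ratio,
    # which sets the unassisted diastolic potential, stays controlled by
    # maturity rather than by independent jitter
    dens <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    out$g_K1_native <- base$g_K1_native * dens
    out$g_leak <- base$g_leak * dens
    out$E_leak <- base$E_leak + stats::rnorm(1, 0, 2)
    out
  })
  cell$phenotype <- phenotype
  cell$maturity <- maturity
  cell$seed <- as.integer(seed)
  structure(cell, class = "virtual_cell")
}

#' @export
print.virtual_cell <- function(x, ...) {
  cat(sprintf("virtual cell: %s preset (maturity %.2f, seed %d)\n",
              x$phenotype, x$maturity, x$seed))
  cat(sprintf("  Cm %.1f pF; g_Na %.2f, g_CaL %.3f, g_Krep %.3f, g_Kur %.3f,",
              x$Cm, x$g_Na, x$g_CaL, x$g_Krep, x$g_Kur))
  cat(sprintf(" g_K1 %.3f, g_leak %.3f nS/pF; E_leak %.1f mV\n",
              x$g_K1_native, x$g_leak, x$E_leak))
  invisible(x)
}

#' Pacing protocol
#'
#' Square suprathreshold current pulses at a fixed rate; the first
#' `discard_beats` beats are dropped from analysis as the diastolic
#' transient.
#'
#' @param frequency pacing rate, Hz.
#' @param pulse_amplitude depolarizing stimulus, pA/pF.
#' @param pulse_duration pulse width, ms.
#' @param n_beats number of stimulated beats.
#' @param discard_beats initial beats excluded from analysis.
#' @param first_stim_ms time of the first stimulus, ms.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(frequency = 1.0, pulse_amplitude = 30,
                          pulse_duration = 3, n_beats = 15,
                          discard_beats = 5, first_stim_ms = 50) {
  if (frequency <= 0) stop("`frequency` must be > 0 (Hz)")
  if (n_beats <= discard_beats || discard_beats < 0)
    stop("need `n_beats` > `discard_beats` >= 0")
  structure(list(frequency = frequency, pulse_amplitude = pulse_amplitude,
                 pulse_duration = pulse_duration, n_beats = n_beats,
                 discard_beats = discard_beats, first_stim_ms = first_stim_ms),
            class = "stim_protocol")
}

stim_times <- function(protocol) {
  period <- 1000 / protocol$frequency
  protocol$first_stim_ms + period * (seq_len(protocol$n_beats) - 1)
}

voltage_trace <- function(t, Vm, dt, stim_times = numeric()) {
  stopifnot(length(t) == length(Vm))
  structure(list(t = t, Vm = Vm, dt = dt, stim_times = stim_times),
            class = "voltage_trace")
}

current_trace <- function(t, I, dt) {
  stopifnot(length(t) == length(I))
  structure(list(t = t, I = I, dt = dt), class = "current_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage trace: %d samples at dt %.3g ms (%.1f s), %d stimuli\n",
              length(x$t), x$dt, max(x$t) / 1000, length(x$stim_times)))
  cat(sprintf("  Vm range [%.1f, %.1f] mV\n", min(x$Vm), max(x$Vm)))
  invisible(x)
}

# Shared simulation core. `segments` is the injection schedule matrix consumed
# by the compiled loop (NULL for no injection); the same code path is used
# with and without injection so that a zero-conductance run is bitwise
# identical to an uninjected one.
run_sim <- function(cell, protocol, segments = NULL, injected = NULL,
                    dt = 0.2, dt_internal = 0.02, noise_sd = 0, seed = NULL,
                    Ko = 4.0, EK = -94.7, T = 308.15, V0 = -60,
                    continuous = FALSE, context = "simulation") {
  stopifnot(inherits(cell, "virtual_cell"), inherits(protocol, "stim_protocol"))
  if (dt_internal > dt) stop("`dt_internal` must be <= the sampling step")
  n_sub <- max(1L, as.integer(round(dt / dt_internal)))
  onsets <- stim_times(protocol)
  period <- 1000 / protocol$frequency
  duration <- protocol$first_stim_ms + period * protocol$n_beats
  n_samples <- as.integer(round(duration / dt)) + 1L
  if (is.null(segments))
    segments <- matrix(c(0, 0, 0, 144.59, 105.8, 9.493), nrow = 1)
  noise <- numeric(0)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n_samples, 0, noise_sd)
             else with_preserved_seed(seed, stats::rnorm(n_samples, 0, noise_sd))
  }
  cellp <- unlist(cell[c("g_Na", "g_CaL", "g_Krep", "g_Kur", "g_K1_native",
                         "g_leak", "E_leak", "tau_f", "tau_n")])
  res <- sim_cell_cpp(cellp, Ko, EK, T, dt, n_samples, n_sub,
                      onsets, protocol$pulse_duration,
                      protocol$pulse_amplitude, segments, noise, V0,
                      continuous, injected)
  if (!res$ok) {
    t_err <- (res$err_sample - 1) * dt
    beat <- sum(onsets <= t_err)
    stop(sprintf("%s diverged at beat %d (t = %.1f ms)", context, beat, t_err))
  }
  t <- (seq_len(n_samples) - 1) * dt
  list(voltage = voltage_trace(t, res$V, dt, onsets),
       current = current_trace(t, res$I, dt))
}

#' Simulate paced action potentials of a virtual cell
#'
#' Integrates the membrane equation
#' `dV/dt = -(I_Na + I_CaL + I_Krep + I_Kur + I_K1,native + I_leak + I_inj) + I_stim`
#' (all currents in pA/pF, outward positive) with exponential gate updates at
#' `dt_internal` and returns the voltage sampled on the 5 kHz (0.2 ms)
#' acquisition grid.
#'
#' @param cell a [make_preset()] virtual cell.
#' @param protocol a [stim_protocol()].
#' @param injected optional function `f(V, t)` returning an extra injected
#'   current (pA/pF), evaluated once per sample and held (zero-order hold).
#'   For IK1 injection use [run_dc()], which carries gating state.
#' @param dt output sampling step, ms (default 0.2 = 5 kHz).
#' @param dt_internal integration substep, ms (must divide `dt`; <= 0.2).
#' @param noise_sd standard deviation of a per-sample held membrane current
#'   noise, pA/pF (default 0: deterministic).
#' @param seed seed for the noise stream (ignored when `noise_sd = 0`).
#' @return a `voltage_trace` (fields `t`, `Vm`, `dt`, `stim_times`).
#' @export
simulate_ap <- function(cell, protocol = stim_protocol(), injected = NULL,
                        dt = 0.2, dt_internal = 0.02, noise_sd = 0,
                        seed = NULL) {
  run_sim(cell, protocol, segments = NULL, injected = injected, dt = dt,
          dt_internal = dt_internal, noise_sd = noise_sd, seed = seed)$voltage
}

#' Generate a reproducible cohort of virtual cells
#'
#' Emulates a recording campaign over a mixed differentiation: exactly
#' `round(n * atrial_fraction)` atrial presets, the rest ventricular, each
#' with its own jitter seed and a maturity drawn uniformly from
#' `maturity_range`.
#'
#' @param n number of cells (>= 1).
#' @param atrial_fraction fraction of atrial presets, in `[0, 1]`.
#' @param maturity_range length-2 interval within `[0, 1]`.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return list of `virtual_cell` objects with names `cell_01`, ...
#' @export
generate_cohort <- function(n, atrial_fraction = 0.5,
                            maturity_range = c(0.3, 0.8), seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  if (atrial_fraction < 0 || atrial_fraction > 1)
    stop("`atrial_fraction` must lie in [0, 1]")
  n_atr <- round(n * atrial_fraction)
  phen <- c(rep("atrial", n_atr), rep("ventricular", n - n_atr))
  draws <- with_preserved_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    mat = stats::runif(n, maturity_range[1], maturity_range[2])
  ))
  cells <- lapply(seq_len(n), function(i)
    make_preset(phen[i], maturity = draws$mat[i], seed = draws$seeds[i]))
  names(cells) <- sprintf("cell_%02d", seq_len(n))
  cells
}

#' Apply fractional block of the ultrarapid delayed rectifier
#'
#' Emulates 4-aminopyridine superfusion: `g_Kur` is scaled by
#' `1 - block_fraction`, everything else untouched. A 50 uM dose is mapped to
#' a 0.9 fractional block by default in the examples and pipeline; the paper
#' gives the dose, not the fraction, so the mapping is configurable here.
#'
#' @param cell a `virtual_cell`.
#' @param block_fraction in `[0, 1]`.
#' @return the modified `virtual_cell`.
#' @export
apply_ikur_block <- function(cell, block_fraction) {
  stopifnot(inherits(cell, "virtual_cell"))
  if (block_fraction < 0 || block_fraction > 1)
    stop("`block_fraction` must lie in [0, 1]")
  cell$g_Kur <- cell$g_Kur * (1 - block_fraction)
  cell
}
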