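#' Configure an in-silico IK1 formulation
#'
#' Builds the parameter set for one of the four inward-rectifier potassium
#' current (IK1) formulations used in dynamic-clamp injection:
#' \describe{
#'   \item{`"ventr"`}{the O'Hara-Rudy human ventricular formulation
#'     (time-dependent gate `xK1` plus instantaneous rectification `RK1`),
#'     base conductance 1.908 nS/pF;}
#'   \item{`"atr"`}{the Koivumaki/Nygren human atrial formulation
#'     (instantaneous, weakly rectifying), base conductance 0.7 nS/pF;}
#'   \item{`"test1"`}{a hybrid that moves the ventricular I/V peak to the
#'     atrial position by shifting the `xK1` steady-state midpoint
#'     (144.59 -> 57.836), fixed conductance 6.417 nS/pF;}
#'   \item{`"test2"`}{a hybrid that moves the ventricular I/V decay onto the
#'     atrial one by widening the rectification sigmoid (midpoint
#'     105.8 -> 135.8 mV, slope 9.493 -> 15.493 mV), fixed conductance
#'     6.258 nS/pF.}
#' }
#'
#' The effective conductance is `G_base * scaling_DC` for the ventricular and
#' atrial formulations; the two test variants use their printed absolute
#' conductances and ignore `scaling_DC`.
#'
#' @param formulation one of `"ventr"`, `"atr"`, `"test1"`, `"test2"`.
#' @param scaling_DC dimensionless conductance scaling factor, >= 0.
#' @param Ko external potassium concentration, mM.
#' @param EK potassium reversal potential, mV. Fixed at -94.7 mV (set from the
#'   recording solutions, not recomputed by Nernst).
#' @param T absolute temperature, K (recordings at 35 C).
#' @param G_base base conductance in nS/pF; defaults to the formulation's
#'   printed value.
#' @return an object of class `ik1_config`.
#' @examples
#' cfg <- ik1_config("atr", scaling_DC = 1)
#' ik1_current(-71, cfg)
#' @export
ik1_config <- function(formulation = c("ventr", "atr", "test1", "test2"),
                       scaling_DC = 1.0, Ko = 4.0, EK = -94.7, T = 308.15,
                       G_base = NULL) {
  formulation <- match.arg(formulation)
  defaults <- c(ventr = 1.908, atr = 0.7, test1 = 6.417, test2 = 6.258)
  if (is.null(G_base)) G_base <- unname(defaults[formulation])
  if (!is.numeric(G_base) || length(G_base) != 1L || G_base <= 0)
    stop("`G_base` must be a single positive conductance (nS/pF)")
  if (!is.numeric(scaling_DC) || length(scaling_DC) != 1L || scaling_DC < 0)
    stop("`scaling_DC` must be a single value >= 0")
  if (!is.numeric(Ko) || Ko <= 0) stop("`Ko` must be > 0 (mM)")
  if (!is.numeric(T) || T <= 0) stop("`T` must be > 0 (K)")
  structure(
    list(formulation = formulation, G_base = G_base, scaling_DC = scaling_DC,
         Ko = Ko, EK = EK, T = T, F = 96485, R = 8.314),
    class = "ik1_config"
  )
}

#' @export
print.ik1_config <- function(x, ...) {
  cat(sprintf("IK1 configuration: %s\n", x$formulation))
  cat(sprintf("  G_base %.3f nS/pF, scaling_DC %.3f -> effective %.3f nS/pF\n",
              x$G_base, x$scaling_DC, ik1_g_eff(x)))
  cat(sprintf("  Ko %.1f mM, EK %.1f mV, T %.2f K\n", x$Ko, x$EK, x$T))
  invisible(x)
}

#' Effective injected conductance of a configuration
#'
#' `G_base * scaling_DC` for the ventricular/atrial formulations; the fixed
#' printed conductance for the two test variants (no scaling applied).
#'
#' @param cfg an [ik1_config()].
#' @return conductance, nS/pF.
#' @export
ik1_g_eff <- function(cfg) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (cfg$formulation %in% c("ventr", "atr")) cfg$G_base * cfg$scaling_DC
  else cfg$G_base
}

# Formulation-specific sigmoid constants. The test variants inherit the
# ventricular structure with one constant swapped each.
ik1_constants <- function(formulation) {
  switch(formulation,
    ventr = list(gated = TRUE,  xinf_mid = 144.59, rk1_mid = 105.8, rk1_slope = 9.493),
    test1 = list(gated = TRUE,  xinf_mid = 57.836, rk1_mid = 105.8, rk1_slope = 9.493),
    test2 = list(gated = TRUE,  xinf_mid = 144.59, rk1_mid = 135.8, rk1_slope = 15.493),
    atr   = list(gated = FALSE, xinf_mid = NA_real_, rk1_mid = NA_real_, rk1_slope = NA_real_),
    stop("unknown formulation: ", formulation)
  )
}

#' Steady-state activation of the ventricular IK1 gate
#'
#' Boltzmann steady state of the slow IK1 gate, with a potassium-dependent
#' midpoint and slope. `xinf_mid` is 144.59 for the ventricular formulation
#' and 57.836 for the test1 variant.
#'
#' @param V membrane potential, mV (vectorised).
#' @param Ko external potassium, mM.
#' @param xinf_mid midpoint constant, mV.
#' @return open fraction in (0, 1), decreasing in `V`.
#' @export
xk1_inf <- function(V, Ko = 4.0, xinf_mid = 144.59) {
  if (!is.numeric(Ko) || Ko <= 0) stop("`Ko` must be > 0 (mM)")
  1 / (1 + exp(-(V + 2.5538 * Ko + xinf_mid) / (1.5692 * Ko + 3.8115)))
}

#' Time constant of the ventricular IK1 gate
#'
#' @param V membrane potential, mV (vectorised).
#' @return time constant, ms (strictly positive).
#' @export
xk1_tau <- function(V) {
  122.2 / (exp(-(V + 127.2) / 20.36) + exp((V + 236.8) / 69.33))
}

#' Advance the IK1 gate by one exponential (Rush-Larsen) step
#'
#' Exact update of the linear gate relaxation
#' `dx/dt = (x_inf - x)/tau` over `dt` at fixed voltage:
#' `x <- x_inf + (x - x_inf) * exp(-dt/tau)`.
#'
#' @param xk1 current open fraction in `[0, 1]`.
#' @param V membrane potential, mV.
#' @param dt time step, ms (>= 0).
#' @param cfg an [ik1_config()]; supplies `Ko` and the formulation's midpoint.
#' @return updated open fraction in `[0, 1]`.
#' @export
update_gate <- function(xk1, V, dt, cfg) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (!is.numeric(dt) || any(dt < 0)) stop("`dt` must be >= 0 (ms)")
  if (any(xk1 < 0 | xk1 > 1)) stop("`xk1` must lie in [0, 1]")
  k <- ik1_constants(cfg$formulation)
  mid <- if (isTRUE(k$gated)) k$xinf_mid else 144.59
  xi <- xk1_inf(V, cfg$Ko, mid)
  xi + (xk1 - xi) * exp(-dt / xk1_tau(V))
}

#' Instantaneous inward rectification factor
#'
#' Voltage-dependent suppression of outward IK1 at depolarized potentials.
#' The ventricular formulation uses midpoint 105.8 mV and slope 9.493 mV;
#' test2 widens these to 135.8 mV and 15.493 mV.
#'
#' @param V membrane potential, mV (vectorised).
#' @param Ko external potassium, mM.
#' @param rk1_mid,rk1_slope sigmoid constants, mV.
#' @return rectification factor in (0, 1), decreasing in `V`.
#' @export
rk1 <- function(V, Ko = 4.0, rk1_mid = 105.8, rk1_slope = 9.493) {
  if (!is.numeric(Ko) || Ko <= 0) stop("`Ko` must be > 0 (mM)")
  1 / (1 + exp((V + rk1_mid - 2.6 * Ko) / rk1_slope))
}

#' Ventricular (O'Hara-Rudy) IK1 current density
#'
#' `I = G * sqrt(Ko) * xK1 * RK1 * (V - EK)`, outward positive.
#'
#' @param V membrane potential, mV (vectorised).
#' @param xk1 gate open fraction; defaults to its steady state at `V`.
#' @param cfg an [ik1_config()] with `formulation = "ventr"`.
#' @return current density, pA/pF.
#' @export
ik1_ventr <- function(V, xk1 = NULL, cfg = ik1_config("ventr")) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (cfg$formulation != "ventr")
    stop("`cfg` must use the 'ventr' formulation, got '", cfg$formulation, "'")
  if (is.null(xk1)) xk1 <- xk1_inf(V, cfg$Ko)
  ik1_g_eff(cfg) * sqrt(cfg$Ko) * xk1 * rk1(V, cfg$Ko) * (V - cfg$EK)
}

#' Atrial (Koivumaki/Nygren) IK1 current density
#'
#' Instantaneous (no gate):
#' `I = G * Ko^0.4457 * (V - EK) / (1 + exp(1.5 * (V - EK + 3.6) * F/(R*T*1000)))`,
#' with `V` in mV (hence the factor 1000 in the exponent), outward positive.
#'
#' @param V membrane potential, mV (vectorised).
#' @param cfg an [ik1_config()] with `formulation = "atr"`.
#' @return current density, pA/pF.
#' @export
ik1_atr <- function(V, cfg = ik1_config("atr")) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (cfg$formulation != "atr")
    stop("`cfg` must use the 'atr' formulation, got '", cfg$formulation, "'")
  expo <- 1.5 * (V - cfg$EK + 3.6) * cfg$F / (cfg$R * cfg$T * 1000)
  ik1_g_eff(cfg) * cfg$Ko^0.4457 * (V - cfg$EK) / (1 + exp(expo))
}

#' Hybrid test-variant IK1 current density
#'
#' Both variants follow the ventricular structure
#' `I = G * sqrt(Ko) * xK1 * RK1 * (V - EK)` with one constant replaced:
#' test1 shifts the gate midpoint (57.836), test2 widens the rectification
#' sigmoid (135.8 mV / 15.493 mV). Their conductances are fixed (6.417 and
#' 6.258 nS/pF) and not scaled by `scaling_DC`.
#'
#' @param V membrane potential, mV (vectorised).
#' @param xk1 gate open fraction; defaults to the variant's steady state.
#' @param cfg an [ik1_config()] with `formulation` `"test1"` or `"test2"`.
#' @return current density, pA/pF.
#' @export
ik1_variant <- function(V, xk1 = NULL, cfg) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (!cfg$formulation %in% c("test1", "test2"))
    stop("`cfg` must use formulation 'test1' or 'test2', got '",
         cfg$formulation, "'")
  k <- ik1_constants(cfg$formulation)
  if (is.null(xk1)) xk1 <- xk1_inf(V, cfg$Ko, k$xinf_mid)
  ik1_g_eff(cfg) * sqrt(cfg$Ko) * xk1 *
    rk1(V, cfg$Ko, k$rk1_mid, k$rk1_slope) * (V - cfg$EK)
}

#' Evaluate any IK1 formulation
#'
#' Dispatches on `cfg$formulation`. For gated formulations `xk1 = NULL`
#' evaluates at gating steady state (the convention for I/V relationships).
#'
#' @inheritParams ik1_variant
#' @return current density, pA/pF (outward positive; exactly 0 at `V = EK`).
#' @export
ik1_current <- function(V, cfg, xk1 = NULL) {
  stopifnot(inherits(cfg, "ik1_config"))
  switch(cfg$formulation,
    ventr = ik1_ventr(V, xk1, cfg),
    atr   = ik1_atr(V, cfg),
    ik1_variant(V, xk1, cfg)
  )
}

#' Steady-state current/voltage relationship
#'
#' Evaluates the formulation on a uniform voltage grid with gated
#' formulations at `xk1_inf(V)`.
#'
#' @param cfg an [ik1_config()].
#' @param v_min,v_max grid limits, mV (`v_min < v_max`).
#' @param dv grid spacing, mV (> 0).
#' @return an `iv_curve`: data frame with columns `V_mV`, `I_pApF` and a
#'   `formulation` attribute.
#' @export
steady_iv <- function(cfg, v_min = -150, v_max = 0, dv = 0.5) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (!is.numeric(dv) || dv <= 0) stop("`dv` must be > 0 (mV)")
  if (v_min >= v_max) stop("`v_min` must be < `v_max` (empty voltage grid)")
  V <- seq(v_min, v_max, by = dv)
  out <- data.frame(V_mV = V, I_pApF = ik1_current(V, cfg))
  attr(out, "formulation") <- cfg$formulation
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Locate the outward peak of the steady-state I/V relation
#'
#' Grid argmax of the outward current over a search window, ties broken
#' toward the most negative voltage. The default window `[EK, -40]` mV
#' excludes the depolarized limb where weakly rectified variants rise again.
#'
#' @param cfg an [ik1_config()].
#' @param dv grid spacing, mV (> 0).
#' @param window length-2 search window, mV.
#' @return list with `V_peak` (mV) and `I_peak` (pA/pF).
#' @export
iv_peak <- function(cfg, dv = 0.01, window = c(cfg$EK, -40)) {
  stopifnot(inherits(cfg, "ik1_config"))
  if (!is.numeric(dv) || dv <= 0) stop("`dv` must be > 0 (mV)")
  V <- seq(window[1], window[2], by = dv)
  I <- ik1_current(V, cfg)
  i <- which.max(I)  # first maximum = most negative on an increasing grid
  list(V_peak = V[i], I_peak = I[i])
}

#' Write / read an I/V curve as two-column CSV
#'
#' Plain CSV with header `V_mV,I_pApF`; the formulation tag travels in a
#' leading comment line.
#'
#' @param iv an `iv_curve` from [steady_iv()].
#' @param path file path.
#' @return `write_iv_csv()` returns `path` invisibly; `read_iv_csv()` an
#'   `iv_curve`.
#' @export
write_iv_csv <- function(iv, path) {
  stopifnot(inherits(iv, "iv_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# formulation=%s", attr(iv, "formulation")), con)
  writeLines("V_mV,I_pApF", con)
  writeLines(sprintf("%.10g,%.10g", iv$V_mV, iv$I_pApF), con)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  lines <- readLines(path)
  tag <- NA_character_
  if (length(lines) && startsWith(lines[1], "# formulation=")) {
    tag <- sub("^# formulation=", "", lines[1])
    lines <- lines[-1]
  }
  if (!length(lines) || lines[1] != "V_mV,I_pApF")
    stop("expected header 'V_mV,I_pApF' in ", path)
  out <- utils::read.csv(textConnection(lines))
  if (is.unsorted(out$V_mV, strictly = TRUE))
    stop("voltage grid must be strictly increasing in ", path)
  attr(out, "formulation") <- tag
  class(out) <- c("iv_curve", "data.frame")
  out
}
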