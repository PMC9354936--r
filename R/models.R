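#' Parameters of the 3-D conductance-based leaky integrate-and-fire model
#'
#' A leaky integrate-and-fire neuron with an excitatory and an inhibitory
#' synaptic conductance. State order is `[u, w, v]` with the membrane
#' potential `v` last: `u` is the inhibitory conductance (nS/cm^2), `w` the
#' excitatory conductance (nS/cm^2), `v` the potential (mV). Derivatives
#' are per millisecond. Defaults:
#' `g_l` 0.03 nS/cm^2, `V_l` -70.6 mV, `V_e` 0 mV, `V_i` -75 mV, `C` 281
#' pF/cm^2, `tau_e` 2.728 ms, `tau_i` 10.49 ms, refractory period 2 ms,
#' threshold -50.4 mV, reset -70.6 mV.
#'
#' @param g_l,V_l,V_e,V_i,C,tau_e,tau_i,tau_ref,threshold,reset model
#'   constants (see above for units).
#' @return a named list of parameters.
#' @export
cond3d_params <- function(g_l = 0.03, V_l = -70.6, V_e = 0.0, V_i = -75,
                          C = 281, tau_e = 2.728, tau_i = 10.49,
                          tau_ref = 2e-3, threshold = -50.4, reset = -70.6) {
  if (C <= 0 || tau_e <= 0 || tau_i <= 0)
    stop("C, tau_e and tau_i must be positive")
  if (!(V_i < threshold && threshold < V_e))
    stop("expected V_i < threshold < V_e")
  list(g_l = g_l, V_l = V_l, V_e = V_e, V_i = V_i, C = C, tau_e = tau_e,
       tau_i = tau_i, tau_ref = tau_ref, threshold = threshold,
       reset = reset)
}

#' Conductance-LIF derivative
#'
#' `v' = (-g_l (v - V_l) - w (v - V_e) - u (v - V_i)) / C`,
#' `w' = -w / tau_e`, `u' = -u / tau_i`, all per millisecond.
#'
#' @param y state `[u, w, v]` as a vector, or a matrix with one state per
#'   row.
#' @param params a [cond3d_params()] list.
#' @return derivative in the same shape as `y`.
#' @examples
#' cond3d_derivative(c(0, 0, -70.6)) # fixed point at the leak reversal
#' @export
cond3d_derivative <- function(y, params = cond3d_params()) {
  p <- params
  if (is.matrix(y)) {
    u <- y[, 1L]; w <- y[, 2L]; v <- y[, 3L]
    cbind(-u / p$tau_i, -w / p$tau_e,
          (-p$g_l * (v - p$V_l) - w * (v - p$V_e) - u * (v - p$V_i)) / p$C)
  } else {
    u <- y[1L]; w <- y[2L]; v <- y[3L]
    c(-u / p$tau_i, -w / p$tau_e,
      (-p$g_l * (v - p$V_l) - w * (v - p$V_e) - u * (v - p$V_i)) / p$C)
  }
}

#' Standard grid for the conductance-LIF population
#'
#' The grid spans `u, w` in `[-0.2, 5.2]` nS/cm^2 and `v` in `[-80, -40]`
#' mV — the region that contains all significant probability mass in the
#' single-population experiments — with threshold -50.4 mV and reset -70.6
#' mV, a 1 ms time step and ms-based model time.
#'
#' @param resolution integer vector of cell counts for `(u, w, v)`.
#' @param base,extent grid placement overrides.
#' @return a [grid_spec()].
#' @export
cond3d_grid <- function(resolution = c(50, 50, 50),
                        base = c(-0.2, -0.2, -80),
                        extent = c(5.4, 5.4, 40)) {
  grid_spec(base = base, extent = extent, resolution = resolution,
            threshold = -50.4, reset = -70.6, timescale = 1e-3,
            time_step = 1e-3)
}

#' Parameters of the Hodgkin-Huxley model
#'
#' Classic sodium/potassium spiking dynamics with state order
#' `[h, n, m, v]` (membrane potential last): `h` sodium inactivation, `n`
#' potassium activation, `m` sodium activation, `v` potential (mV).
#' Derivatives are per millisecond. Defaults: `g_l` 0.5, `g_k` 30, `g_na`
#' 100 mS/cm^2; `V_k` -90, `V_na` 50, `V_l` -65, `V_t` -63 mV; `C` 1
#' uF/cm^2.
#'
#' @param g_l,g_k,g_na,V_k,V_na,V_l,V_t,C model constants.
#' @return a named list of parameters.
#' @export
hh_params <- function(g_l = 0.5, g_k = 30, g_na = 100, V_k = -90,
                      V_na = 50, V_l = -65, V_t = -63, C = 1.0) {
  if (g_l <= 0 || g_k <= 0 || g_na <= 0 || C <= 0)
    stop("conductances and capacitance must be positive")
  list(g_l = g_l, g_k = g_k, g_na = g_na, V_k = V_k, V_na = V_na,
       V_l = V_l, V_t = V_t, C = C)
}

# x / (exp(x) - 1) evaluated stably through its removable singularity at 0
xexpm1 <- function(x) {
  out <- ifelse(abs(x) < 1e-9, 1 - x / 2, x / expm1(x))
  out
}

#' Hodgkin-Huxley gating rate functions
#'
#' The alpha/beta rates (per ms) as functions of the potential `v` (mV).
#' The printed expressions for `alpha_m`, `alpha_n` and `beta_m` are 0/0 at
#' isolated potentials; they are evaluated through their analytic limits
#' (e.g. `alpha_m(V_t + 13) = 0.32 * 4 = 1.28`).
#'
#' @param v membrane potential (mV), vectorized.
#' @param params a [hh_params()] list.
#' @return a list with vectors `alpha_m`, `alpha_n`, `alpha_h`, `beta_m`,
#'   `beta_n`, `beta_h`.
#' @export
hh_rates <- function(v, params = hh_params()) {
  Vt <- params$V_t
  list(alpha_m = 0.32 * 4 * xexpm1((13 - v + Vt) / 4),
       alpha_n = 0.032 * 5 * xexpm1((15 - v + Vt) / 5),
       alpha_h = 0.128 * exp((17 - v + Vt) / 18),
       beta_m = 0.28 * 5 * xexpm1((v - Vt - 40) / 5),
       beta_n = 0.5 * exp((10 - v + Vt) / 40),
       beta_h = 4 / (1 + exp((40 - v + Vt) / 5)))
}

#' Hodgkin-Huxley derivative
#'
#' `C v' = -g_k n^4 (v - V_k) - g_na m^3 h (v - V_na) - g_l (v - V_l)` and
#' `x' = alpha_x(v) (1 - x) - beta_x(v) x` for the gating variables
#' `x in {m, n, h}`, per millisecond.
#'
#' @param y state `[h, n, m, v]` as a vector or matrix (rows = states).
#' @param params a [hh_params()] list.
#' @return derivative in the same shape as `y`.
#' @export
hh_derivative <- function(y, params = hh_params()) {
  p <- params
  vec <- !is.matrix(y)
  if (vec) y <- matrix(y, nrow = 1L)
  h <- y[, 1L]; n <- y[, 2L]; m <- y[, 3L]; v <- y[, 4L]
  r <- hh_rates(v, p)
  dv <- (-p$g_k * n^4 * (v - p$V_k) - p$g_na * m^3 * h * (v - p$V_na) -
           p$g_l * (v - p$V_l)) / p$C
  out <- cbind(r$alpha_h * (1 - h) - r$beta_h * h,
               r$alpha_n * (1 - n) - r$beta_n * n,
               r$alpha_m * (1 - m) - r$beta_m * m,
               dv, deparse.level = 0)
  dimnames(out) <- NULL
  if (vec) out[1L, ] else out
}

#' Standard grid for the Hodgkin-Huxley population
#'
#' Gating variables span `[-0.1, 1.1]` and the potential `[-100, 60]` mV.
#' The model has no intrinsic reset; to read out a population firing rate
#' the grid carries a spike-detection threshold at -10 mV with reset -65 mV
#' and no shift of the gating variables, so mass crossing the spike upstroke
#' is counted and returned near rest with its gating state preserved.
#'
#' @param resolution integer vector of cell counts for `(h, n, m, v)`.
#' @param threshold,reset spike-detection threshold and reset (mV).
#' @return a [grid_spec()].
#' @export
hh_grid <- function(resolution = c(50, 50, 50, 50), threshold = -10,
                    reset = -65) {
  grid_spec(base = c(-0.1, -0.1, -0.1, -100),
            extent = c(1.2, 1.2, 1.2, 160), resolution = resolution,
            threshold = threshold, reset = reset, timescale = 1e-3,
            time_step = 1e-3)
}
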