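#' Direct Monte Carlo simulation of a spiking population
#'
#' Simulates `n_neurons` independent neurons following the model ODE under
#' Poisson spike input, for validating the population density solution.
#' Each time step every non-refractory neuron is Euler-integrated over `dt`
#' (with the same number of substeps the matrix generator uses, so
#' comparisons measure discretization error, not integrator mismatch), then
#' receives `Poisson(rate * num_connections * dt)` spikes per input, each
#' shifting its state by the input's jump vector; neurons whose potential
#' exceeds the threshold are reset and held at the reset state for
#' `tau_ref` seconds. The run is reproducible under a fixed seed.
#'
#' @param deriv model derivative (vector or matrix form, model units per
#'   model time unit).
#' @param start initial state vector (all neurons start there).
#' @param inputs `NULL` or data.frame with columns `rate` (Hz),
#'   `num_connections`, `efficacy`, `dimension` (0-based); each row is an
#'   independent Poisson input causing a jump of `efficacy` in `dimension`.
#' @param t_end simulated time (s).
#' @param dt time step (s).
#' @param n_neurons population size.
#' @param threshold,reset threshold and reset potentials (last dimension);
#'   `threshold = NULL` disables the reset mechanism.
#' @param reset_shift additive per-dimension state change on reset.
#' @param tau_ref refractory period (s).
#' @param timescale seconds per model time unit (1e-3 for ms-based models).
#' @param substeps Euler sub-intervals per step.
#' @param seed RNG seed.
#' @return list with `time` (s), `rates` (Hz per step), `averages` (matrix,
#'   one column per state dimension, means over all neurons).
#' @export
monte_carlo_simulate <- function(deriv, start, inputs = NULL, t_end, dt,
                                 n_neurons = 10000L, threshold = NULL,
                                 reset = NULL, reset_shift = NULL,
                                 tau_ref = 0, timescale = 1e-3,
                                 substeps = 10L, seed = 1L) {
  if (n_neurons < 1L) stop("n_neurons must be >= 1")
  set.seed(seed)
  n_dims <- length(start)
  vd <- as_vectorized_deriv(deriv, n_dims,
                            probe = rbind(start, start, deparse.level = 0))
  state <- matrix(rep(as.numeric(start), each = n_neurons),
                  nrow = n_neurons, ncol = n_dims)
  if (is.null(reset_shift)) reset_shift <- numeric(n_dims)
  n_steps <- as.integer(round(t_end / dt))
  n_ref <- as.integer(round(tau_ref / dt))
  refrac <- integer(n_neurons)
  h <- (dt / timescale) / substeps
  rates <- numeric(n_steps)
  averages <- matrix(NA_real_, nrow = n_steps, ncol = n_dims)
  has_inputs <- !is.null(inputs) && nrow(inputs) > 0L
  for (s in seq_len(n_steps)) {
    active <- refrac == 0L
    if (any(active)) {
      sub <- state[active, , drop = FALSE]
      for (k in seq_len(substeps)) sub <- sub + h * vd(sub)
      if (has_inputs) {
        lambda <- inputs$rate * inputs$num_connections * dt
        for (r in seq_len(nrow(inputs))) {
          counts <- rpois(nrow(sub), lambda[r])
          d <- as.integer(inputs$dimension[r]) + 1L
          sub[, d] <- sub[, d] + counts * inputs$efficacy[r]
        }
      }
      state[active, ] <- sub
    }
    if (!is.null(threshold)) {
      fired <- active & state[, n_dims] > threshold
      rates[s] <- sum(fired) / (n_neurons * dt)
      if (any(fired)) {
        state[fired, n_dims] <- reset
        state[fired, ] <- state[fired, , drop = FALSE] +
          matrix(reset_shift, nrow = sum(fired), ncol = n_dims, byrow = TRUE)
        refrac[fired] <- n_ref
      }
    }
    held <- refrac > 0L
    if (any(held)) refrac[held] <- refrac[held] - 1L
    averages[s, ] <- colMeans(state)
  }
  list(time = seq_len(n_steps) * dt, rates = rates, averages = averages)
}

#' Finite-size hybrid simulation through the precomputed transitions
#'
#' A list of `M` grid coordinates represents `M` individual neurons. Each
#' step every coordinate moves to one of its cell's transition targets with
#' probability equal to the transition proportion; then a Poisson number of
#' input spikes is sampled per neuron and the jump transition is applied
#' that many times, each jump choosing a target offset with probability
#' equal to its mass fraction. Coordinates in the threshold layer are
#' counted (rate = count / (M dt)), moved to their reset cells and held
#' for the refractory period. Exactly `M` coordinates exist at all times.
#'
#' @param tm the population's `transition_matrix`.
#' @param start initial state vector.
#' @param inputs as in [monte_carlo_simulate()].
#' @param t_end,dt simulated time and step (s).
#' @param M number of neurons.
#' @param tau_ref refractory period (s).
#' @param seed RNG seed.
#' @return list with `time`, `rates`, `averages` (cell-center based), and
#'   `occupancy` (per-cell visit mass, averaged over the final quarter of
#'   the run).
#' @export
finite_size_simulate <- function(tm, start, inputs = NULL, t_end,
                                 dt = tm$grid$time_step, M = 1000L,
                                 tau_ref = 0, seed = 1L) {
  if (!inherits(tm, "transition_matrix")) stop("expected a transition_matrix")
  if (M < 1L) stop("M must be >= 1")
  set.seed(seed)
  grid <- tm$grid
  nc <- n_cells(grid)
  Tt <- methods::as(tm$Tt, "CsparseMatrix")
  coords <- rep(locate_cell(grid, start), M) # 0-based flat
  n_steps <- as.integer(round(t_end / dt))
  n_ref <- as.integer(round(tau_ref / dt))
  refrac <- integer(M)
  has_thr <- !is.na(grid$threshold_value)
  if (has_thr) {
    mapping <- build_reset_mapping(grid)
    reset_map <- rep(NA_integer_, nc)
    reset_map[mapping$source + 1L] <- mapping$target
  }
  jts <- if (!is.null(inputs) && nrow(inputs) > 0L)
    lapply(seq_len(nrow(inputs)), function(r)
      jump_transition(grid, inputs$efficacy[r],
                      dimension = as.integer(inputs$dimension[r])))
  else list()
  rates <- numeric(n_steps)
  averages <- matrix(NA_real_, nrow = n_steps, ncol = grid$n_dims)
  occupancy <- numeric(nc)
  occ_from <- max(1L, n_steps - n_steps %/% 4L)
  for (s in seq_len(n_steps)) {
    active <- which(refrac == 0L)
    if (length(active)) {
      # deterministic move: per occupied cell, a multinomial draw over the
      # cell's transition targets
      cells <- coords[active] + 1L
      tab <- table(cells)
      newc <- coords
      for (ci in seq_along(tab)) {
        j <- as.integer(names(tab)[ci])
        cnt <- as.integer(tab[ci])
        kk <- (Tt@p[j] + 1L):Tt@p[j + 1L]
        tgt <- Tt@i[kk]
        pr <- Tt@x[kk]
        drawn <- if (length(tgt) == 1L) rep(tgt, cnt) else
          tgt[sample.int(length(tgt), cnt, replace = TRUE, prob = pr)]
        newc[active[cells == j]] <- drawn
      }
      coords <- newc
      # shot noise: per neuron Poisson spike counts, each spike one draw
      # from the jump transition
      if (length(jts)) {
        multi <- multi_index(grid, coords)
        for (r in seq_along(jts)) {
          lam <- inputs$rate[r] * inputs$num_connections[r] * dt
          counts <- rpois(length(active), lam)
          tot <- sum(counts)
          if (tot == 0L) next
          jt <- jts[[r]]
          who <- rep(active, counts)
          pick <- sample.int(length(jt$fractions), tot, replace = TRUE,
                             prob = jt$fractions)
          for (d in seq_len(grid$n_dims)) {
            offd <- jt$offsets[pick, d]
            if (all(offd == 0L)) next
            add <- rowsum(offd, group = who)
            ids <- as.integer(rownames(add))
            multi[ids, d] <- pmin(pmax(multi[ids, d] + add, 0L),
                                  grid$resolution[d] - 1L)
          }
        }
        coords <- flat_index(grid, multi)
      }
    }
    if (has_thr) {
      over <- which(refrac == 0L & !is.na(reset_map[coords + 1L]))
      rates[s] <- length(over) / (M * dt)
      if (length(over)) {
        coords[over] <- reset_map[coords[over] + 1L]
        refrac[over] <- n_ref
      }
    }
    held <- refrac > 0L
    if (any(held)) refrac[held] <- refrac[held] - 1L
    centers <- cell_centers(grid, coords)
    averages[s, ] <- colMeans(centers)
    if (s >= occ_from)
      occupancy <- occupancy + tabulate(coords + 1L, nbins = nc)
    stopifnot(length(coords) == M)
  }
  span <- n_steps - occ_from + 1L
  list(time = seq_len(n_steps) * dt, rates = rates, averages = averages,
       occupancy = occupancy / (span * M))
}

#' Mean absolute error between two equally sampled traces
#'
#' @param trace_a,trace_b equal-length numeric vectors sampled at the same
#'   times.
#' @return mean of `|a - b|`.
#' @examples
#' mean_abs_error(c(1, 2), c(1.5, 2.5)) # 0.5
#' @export
mean_abs_error <- function(trace_a, trace_b) {
  if (length(trace_a) != length(trace_b))
    stop("traces must have equal length")
  mean(abs(trace_a - trace_b))
}
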