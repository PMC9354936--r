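#' Initialize a population as a Dirac delta
#'
#' All probability mass (1.0) is placed in the cell containing
#' `start_point`; cells are half-open so a point exactly on a shared edge
#' belongs to the cell whose lower edge it sits on.
#'
#' @param grid a [grid_spec()].
#' @param start_point numeric state vector inside the grid.
#' @return an object of class `population_state`: list with `mass` (vector
#'   over cells), `queue` (refractory entries, each
#'   `list(release_step, mass)`), `rate` (Hz), `history` (completed-step
#'   rates) and `step` (completed step counter).
#' @export
initialize_state <- function(grid, start_point) {
  stopifnot_grid(grid)
  flat <- tryCatch(locate_cell(grid, start_point),
                   error = function(e) stop("start point outside grid: ",
                                            conditionMessage(e)))
  mass <- numeric(n_cells(grid))
  mass[flat + 1L] <- 1
  structure(list(mass = mass, queue = list(), rate = 0,
                 history = numeric(0), step = 0L),
            class = "population_state")
}

total_mass <- function(state) {
  state_queue <- if (length(state$queue))
    sum(vapply(state$queue, function(q) sum(q$mass), 0)) else 0
  sum(state$mass) + state_queue
}

#' Transfer above-threshold mass to the reset cells
#'
#' Sums the probability mass in the threshold-layer cells, removes it, and
#' either deposits it immediately in the mapped reset cells (`tau_ref = 0`)
#' or enqueues it for release `round(tau_ref / dt)` steps later, during
#' which the mass is held at its reset target ("held constant at the reset
#' potential"). The population firing rate for this step is that mass
#' divided by `dt`. Total mass (including the refractory queue) is
#' conserved.
#'
#' @param state a [initialize_state()] object.
#' @param grid a [grid_spec()].
#' @param mapping a [build_reset_mapping()] data.frame.
#' @param dt time step (s).
#' @param tau_ref refractory period (s).
#' @return list with updated `state` and the step's `rate` (Hz).
#' @export
threshold_reset <- function(state, grid, mapping, dt, tau_ref = 0) {
  src <- mapping$source + 1L
  m <- state$mass[src]
  mstar <- sum(m)
  rate <- mstar / dt
  if (mstar > 0) {
    state$mass[src] <- 0
    rel <- numeric(length(state$mass))
    agg <- rowsum(m, group = mapping$target)
    rel[as.integer(rownames(agg)) + 1L] <- agg
    n_ref <- as.integer(round(tau_ref / dt))
    if (n_ref <= 0L) {
      state$mass <- state$mass + rel
    } else {
      state$queue[[length(state$queue) + 1L]] <-
        list(release_step = state$step + n_ref, mass = rel)
    }
  }
  state$rate <- rate
  list(state = state, rate = rate)
}

#' Mass-weighted population average of a state variable
#'
#' The mass-weighted mean of cell-center coordinates along one dimension.
#' Refractory mass is counted at its reset-target cell, where the state is
#' held.
#'
#' @param grid a [grid_spec()].
#' @param state a `population_state` (or a plain mass vector).
#' @param dim 0-based dimension index.
#' @return scalar average in model units.
#' @export
population_average <- function(grid, state, dim) {
  stopifnot_grid(grid)
  dim <- as.integer(dim)
  if (dim < 0L || dim >= grid$n_dims) stop("dim out of range")
  mass <- if (inherits(state, "population_state")) state$mass else state
  if (inherits(state, "population_state") && length(state$queue))
    for (q in state$queue) mass <- mass + q$mass
  coord <- cell_center_coord(grid, dim)
  tot <- sum(mass)
  if (tot <= 0) return(NA_real_)
  sum(mass * coord) / tot
}

# center coordinate along one 0-based dimension for every flat cell index
cell_center_coord <- function(grid, dim) {
  d <- dim + 1L
  stride <- prod(grid$resolution[seq_len(grid$n_dims) > d]) # dims after d
  idx <- ((0:(n_cells(grid) - 1L)) %/% stride) %% grid$resolution[d]
  grid$base[d] + (idx + 0.5) * grid$cell_width[d]
}

#' Advance one population by a single time step
#'
#' Order of operations: (1) deterministic transition matrix, (2) master
#' equation over all inputs, (3) refractory releases due this step, (4)
#' threshold-reset. Total mass (state plus queue) is conserved.
#'
#' @param state a `population_state`.
#' @param tm the population's `transition_matrix`.
#' @param inputs list of inputs for [solve_master_equation()].
#' @param mapping [build_reset_mapping()] data.frame (or `NULL` for a model
#'   without threshold-reset).
#' @param dt time step (s).
#' @param tau_ref refractory period (s).
#' @param master_steps master-equation Euler iterations.
#' @return updated `population_state` (fields `rate`, `history`, `step`
#'   refreshed).
#' @export
step_node <- function(state, tm, inputs, mapping, dt = tm$grid$time_step,
                      tau_ref = 0, master_steps = 10L) {
  grid <- tm$grid
  state$step <- state$step + 1L
  state$mass <- apply_deterministic(tm, state$mass)
  if (length(inputs))
    state$mass <- solve_master_equation(state$mass, grid, inputs, dt,
                                        master_steps)
  if (length(state$queue)) {
    due <- vapply(state$queue, function(q) q$release_step <= state$step, TRUE)
    for (q in state$queue[due]) state$mass <- state$mass + q$mass
    state$queue <- state$queue[!due]
  }
  if (!is.null(mapping)) {
    tr <- threshold_reset(state, grid, mapping, dt, tau_ref)
    state <- tr$state
  } else {
    state$rate <- 0
  }
  state$history <- c(state$history, state$rate)
  state
}

#' Define a population node
#'
#' @param name node name.
#' @param matrix the node's `transition_matrix` (from
#'   [generate_deterministic_matrix()] or [read_matrix_file()]).
#' @param start starting state vector (Dirac delta position).
#' @param tau_ref refractory period (s).
#' @return a `population_node` list.
#' @export
population_node <- function(name, matrix, start, tau_ref = 0) {
  if (!inherits(matrix, "transition_matrix"))
    stop("matrix must be a transition_matrix")
  structure(list(name = name, matrix = matrix, start = as.numeric(start),
                 tau_ref = tau_ref),
            class = "population_node")
}

#' Simulate a network of populations coupled by average firing rates
#'
#' Every time step each node applies its deterministic transition matrix,
#' solves the Poisson master equation for all of its (delayed) inputs,
#' releases refractory mass that is due, and performs the threshold-reset
#' that defines its firing rate. Populations interact via their average
#' firing rates: the delivered rate of a connection at step `s` is the
#' source node's rate from completed step `s - 1 - delay/dt` (the previous
#' step for zero delay, so there is no instantaneous algebraic loop)
#' multiplied by `num_connections`. External drives are constant-rate
#' Poisson inputs. The whole solution path is deterministic.
#'
#' @param nodes list of [population_node()]s.
#' @param connections `NULL` or data.frame with columns `source`, `target`
#'   (node names), `num_connections`, `efficacy`, `delay` (s), `dimension`
#'   (0-based index of the jumped variable).
#' @param externals `NULL` or data.frame with columns `target`, `rate`
#'   (Hz), `num_connections`, `efficacy`, `dimension`.
#' @param t_end simulated time (s).
#' @param master_steps master-equation iterations per step (the
#'   `master_steps` run parameter).
#' @param record_interval interval (s) for rate/average records; must be a
#'   multiple of the time step.
#' @param snapshot_times numeric times (s) at which to store full density
#'   snapshots.
#' @return list with `time`, `rates` (matrix, one column per node),
#'   `averages` (per node, matrix with one column per state dimension),
#'   `snapshots` (per node, list of mass vectors named by time),
#'   `mass_error` (max per-step deviation of total mass from 1).
#' @export
run_network <- function(nodes, connections = NULL, externals = NULL, t_end,
                        master_steps = 10L, record_interval = NULL,
                        snapshot_times = NULL) {
  if (inherits(nodes, "population_node")) nodes <- list(nodes)
  names(nodes) <- vapply(nodes, function(nd) nd$name, "")
  nn <- length(nodes)
  dt <- nodes[[1L]]$matrix$grid$time_step
  for (nd in nodes)
    if (abs(nd$matrix$grid$time_step - dt) > 1e-15)
      stop("all nodes must share the same time step")
  if (is.null(record_interval)) record_interval <- dt
  rec_every <- as.integer(round(record_interval / dt))
  if (rec_every < 1L) stop("record_interval must be >= the time step")
  n_steps <- as.integer(round(t_end / dt))
  check_endpoint <- function(x, what) {
    bad <- setdiff(unique(x), names(nodes))
    if (length(bad)) stop("unknown node name in ", what, ": ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(connections) && nrow(connections)) {
    check_endpoint(connections$source, "connections")
    check_endpoint(connections$target, "connections")
  }
  if (!is.null(externals) && nrow(externals))
    check_endpoint(externals$target, "externals")

  states <- lapply(nodes, function(nd)
    initialize_state(nd$matrix$grid, nd$start))
  mappings <- lapply(nodes, function(nd) {
    g <- nd$matrix$grid
    if (is.na(g$threshold_value)) NULL else build_reset_mapping(g)
  })
  # prebuilt jump matrices + rate lookups per target node
  node_inputs <- lapply(names(nodes), function(tgt) {
    inp <- list()
    g <- nodes[[tgt]]$matrix$grid
    if (!is.null(externals) && nrow(externals)) {
      for (r in which(externals$target == tgt)) {
        dimn <- as.integer(externals$dimension[r])
        if (dimn < 0L || dimn >= g$n_dims)
          stop("external drive dimension out of range for node ", tgt)
        jt <- jump_transition(g, externals$efficacy[r], dimension = dimn)
        inp[[length(inp) + 1L]] <- list(
          type = "external",
          rate = externals$rate[r] * externals$num_connections[r],
          M = methods::as(jump_matrix(g, jt), "CsparseMatrix"))
      }
    }
    if (!is.null(connections) && nrow(connections)) {
      for (r in which(connections$target == tgt)) {
        dimn <- as.integer(connections$dimension[r])
        if (dimn < 0L || dimn >= g$n_dims)
          stop("connection dimension out of range for node ", tgt)
        jt <- jump_transition(g, connections$efficacy[r], dimension = dimn)
        inp[[length(inp) + 1L]] <- list(
          type = "connection", source = connections$source[r],
          num_connections = connections$num_connections[r],
          delay_steps = as.integer(round(connections$delay[r] / dt)),
          M = methods::as(jump_matrix(g, jt), "CsparseMatrix"))
      }
    }
    inp
  })
  names(node_inputs) <- names(nodes)

  rate_hist <- matrix(0, nrow = n_steps + 1L, ncol = nn,
                      dimnames = list(NULL, names(nodes)))
  n_rec <- n_steps %/% rec_every
  rates_out <- matrix(NA_real_, nrow = n_rec, ncol = nn,
                      dimnames = list(NULL, names(nodes)))
  avgs_out <- lapply(nodes, function(nd)
    matrix(NA_real_, nrow = n_rec, ncol = nd$matrix$grid$n_dims))
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    as.integer(round(snapshot_times / dt))
  snapshots <- lapply(nodes, function(nd) list())
  mass_error <- 0

  for (s in seq_len(n_steps)) {
    for (k in seq_len(nn)) {
      inputs <- list()
      for (inp in node_inputs[[k]]) {
        if (inp$type == "external") {
          inputs[[length(inputs) + 1L]] <- list(rate = inp$rate, M = inp$M)
        } else {
          idx <- s - 1L - inp$delay_steps
          r <- if (idx >= 1L) rate_hist[idx + 1L, inp$source] else 0
          inputs[[length(inputs) + 1L]] <-
            list(rate = r * inp$num_connections, M = inp$M)
        }
      }
      states[[k]] <- step_node(states[[k]], nodes[[k]]$matrix, inputs,
                               mappings[[k]], dt, nodes[[k]]$tau_ref,
                               master_steps)
      rate_hist[s + 1L, k] <- states[[k]]$rate
      mass_error <- max(mass_error, abs(total_mass(states[[k]]) - 1))
    }
    if (s %% rec_every == 0L) {
      rec <- s %/% rec_every
      for (k in seq_len(nn)) {
        rates_out[rec, k] <- states[[k]]$rate
        g <- nodes[[k]]$matrix$grid
        for (d in seq_len(g$n_dims))
          avgs_out[[k]][rec, d] <- population_average(g, states[[k]], d - 1L)
      }
    }
    if (s %in% snap_steps) {
      for (k in seq_len(nn)) {
        snapshots[[k]][[sprintf("%.6f", s * dt)]] <- states[[k]]$mass
      }
    }
  }
  names(avgs_out) <- names(nodes)
  names(snapshots) <- names(nodes)
  list(time = seq_len(n_rec) * rec_every * dt, rates = rates_out,
       averages = avgs_out, snapshots = snapshots, mass_error = mass_error,
       states = states)
}

#' Marginal density over a subset of dimensions
#'
#' Sums the probability mass over all other dimensions; used for the 1-D
#' and 2-D projections of density snapshots.
#'
#' @param grid a [grid_spec()].
#' @param mass mass vector over cells.
#' @param dims 0-based dimension indices to keep (length 1 or 2).
#' @return an array over the kept dimensions, with cell-center coordinates
#'   in `dimnames`.
#' @export
density_marginal <- function(grid, mass, dims) {
  stopifnot_grid(grid)
  dims <- as.integer(dims)
  if (any(dims < 0L) || any(dims >= grid$n_dims)) stop("dims out of range")
  arr <- array(mass, dim = rev(grid$resolution)) # last dim fastest
  keep_rev <- grid$n_dims - dims # position in reversed dim order
  out <- apply(arr, keep_rev, sum)
  if (is.null(dim(out))) out <- array(out, dim = length(out))
  dn <- lapply(dims, function(d)
    sprintf("%g", grid$base[d + 1L] +
              (seq_len(grid$resolution[d + 1L]) - 0.5) *
              grid$cell_width[d + 1L]))
  dimnames(out) <- dn
  out
}
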