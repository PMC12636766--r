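#' Simulation configuration
#'
#' Bundles the lattice geometry, thermodynamic parameters, network, and
#' scheduling. One sweep attempts one Kawasaki exchange per lattice site,
#' with each inclusion's `mobility` translation attempts interleaved at
#' random points within the sweep, followed by one reaction pass over the
#' post-movement contacts.
#'
#' @param network A `network_spec`.
#' @param L Lattice side length.
#' @param tau Rescaled temperature `T / Tc`.
#' @param m_target Target magnetization.
#' @param J,J_int Couplings; see [thermo_params()].
#' @param sweeps Total sweep count.
#' @param burn_in Sweeps discarded when computing steady-state statistics;
#'   defaults to half of `sweeps`.
#' @param record_every Trace recording cadence in sweeps.
#' @param snapshot_every Snapshot cadence in sweeps (0 = no snapshots).
#' @param seed Master integer seed for the run.
#' @param log_events Record every reaction firing (memory-heavy on long
#'   runs).
#' @return A `sim_config` object.
#' @export
sim_config <- function(network, L = 64L, tau = 1, m_target = 0, J = 1,
                       J_int = J, sweeps = 2e5, burn_in = NULL,
                       record_every = 100L, snapshot_every = 0L, seed = 1L,
                       log_events = FALSE) {
  stopifnot(inherits(network, "network_spec"))
  sweeps <- as.integer(sweeps)
  burn_in <- as.integer(burn_in %||% (sweeps %/% 2L))
  if (sweeps < 0L) stop("sweeps must be >= 0")
  if (burn_in < 0L || (sweeps > 0L && burn_in >= sweeps)) {
    stop("burn_in must lie in [0, sweeps)")
  }
  if (record_every < 1L) stop("record_every must be >= 1")
  structure(
    list(network = network, L = as.integer(L),
         thermo = thermo_params(tau = tau, J = J, J_int = J_int,
                                m_target = m_target),
         sweeps = sweeps, burn_in = burn_in,
         record_every = as.integer(record_every),
         snapshot_every = as.integer(snapshot_every),
         seed = as.integer(seed), log_events = isTRUE(log_events)),
    class = "sim_config"
  )
}

#' Run one simulation
#'
#' Initializes the lattice from the config seed, executes the configured
#' number of sweeps (lipid exchanges, interleaved inclusion moves, one
#' reaction pass per sweep), and records per-(component, state) counts and
#' energies on the configured cadence. Bit-reproducible for a fixed config
#' and seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_result`: list with `trace` (tibble: sweep, component,
#'   state, count), `energies` (tibble: sweep, e_mem, e_int), `final_state`,
#'   `snapshots` (list of `lattice_state`, if enabled), `events` (tibble, if
#'   `log_events`), `acceptance`, and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  th <- config$thermo
  state0 <- init_lattice(config$L, th$m_target, config$network,
                         seed = derive_seed(config$seed, 1L))
  res <- cpp_run(state_to_cpp(state0), net_to_cpp(config$network),
                 th$tau, th$J, th$J_int, th$Tc_bare,
                 config$sweeps, config$record_every, config$snapshot_every,
                 TRUE, TRUE, length(config$network$rules) > 0L,
                 config$log_events, derive_seed(config$seed, 2L))
  comps <- config$network$components
  slot_comp <- unlist(lapply(comps, function(cmp) {
    rep(cmp$name, length(cmp$states))
  }), use.names = FALSE)
  slot_state <- unlist(lapply(comps, function(cmp) names(cmp$states)),
                       use.names = FALSE)
  nrec <- length(res$rec_sweep)
  trace <- tibble::tibble(
    sweep = rep(res$rec_sweep, each = length(slot_comp)),
    component = rep(slot_comp, nrec),
    state = rep(slot_state, nrec),
    count = as.integer(t(res$counts))
  )
  energies <- tibble::tibble(sweep = res$rec_sweep, e_mem = res$e_mem,
                             e_int = res$e_int)
  snapshots <- lapply(res$snapshots, function(s) {
    st <- state_from_cpp(s, state0)
    attr(st, "sweep") <- s$sweep
    st
  })
  events <- if (config$log_events && nrow(res$events) > 0L) {
    rl <- res$events
    tibble::tibble(sweep = rl[, 1L], rule = rl[, 2L], actor = rl[, 3L],
                   substrate = rl[, 4L])
  } else {
    tibble::tibble(sweep = integer(), rule = integer(), actor = integer(),
                   substrate = integer())
  }
  structure(
    list(trace = trace, energies = energies,
         final_state = state_from_cpp(res$state, state0),
         initial_state = state0, snapshots = snapshots, events = events,
         acceptance = res$acc, config = config),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_result> L=%d tau=%.3g m=%.3g, %d sweeps (%d records)\n",
    cfg$L, cfg$thermo$tau, cfg$thermo$m_target, cfg$sweeps,
    length(unique(x$trace$sweep))))
  cat(sprintf("  steady-state target activity f_A = %.4f\n",
              steady_state_activity(x)))
  invisible(x)
}

#' Apply one reaction pass to a lattice state
#'
#' Computes contacts on the current configuration and fires matching rules:
#' each contacting (actor, substrate) pair matching a rule fires with the
#' rule's rate; on firing the substrate's state becomes the product state
#' and, if the new state has a different boundary preference, its boundary
#' spins switch immediately (the detailed-balance-violating step). Eligible
#' rules for one pair run in randomized order and a substrate is modified at
#' most once per pass. No movement occurs.
#'
#' @param state A `lattice_state` whose network has rules.
#' @param seed Integer seed for the reaction stream.
#' @return List with `state` (updated) and `events` (tibble: rule, actor,
#'   substrate).
#' @export
apply_reactions <- function(state, seed = 1L) {
  stopifnot(inherits(state, "lattice_state"))
  if (is.null(state$network)) stop("state has no network")
  res <- cpp_run(state_to_cpp(state), net_to_cpp(state$network),
                 1, 1, 1, tc_onsager(1),
                 1L, 0L, 0L, FALSE, FALSE, TRUE, TRUE, as.integer(seed))
  ev <- res$events
  list(
    state = state_from_cpp(res$state, state),
    events = tibble::tibble(rule = ev[, 2L], actor = ev[, 3L],
                            substrate = ev[, 4L])
  )
}

#' Scan a parameter axis with seeded replicates
#'
#' Runs independent replicates of a base configuration across a grid of
#' values of one parameter (`tau`, `m_target`, or `radius`, the latter
#' applied to every component) and reports the steady-state active-target
#' fraction for each run. Replicate seeds are derived from the master seed by
#' a counter scheme, so the table is reproducible and replicates are
#' independent.
#'
#' @param config A [sim_config()] used as the template.
#' @param axis One of `"tau"`, `"m_target"`, `"radius"`.
#' @param values Numeric vector of axis values.
#' @param replicates Replicates per value.
#' @param seed Master seed for the scan (defaults to the config seed).
#' @return A tibble: `axis`, `value`, `replicate`, `seed`, `f_A`.
#' @export
run_scan <- function(config, axis = c("tau", "m_target", "radius"), values,
                     replicates = 3L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  axis <- match.arg(axis)
  seed <- as.integer(seed %||% config$seed)
  rows <- vector("list", length(values) * replicates)
  n <- 0L
  for (a in seq_along(values)) {
    for (k in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- derive_seed(seed, a * 1000L + k)
      v <- values[a]
      if (axis == "tau") {
        cfg$thermo$tau <- v
      } else if (axis == "m_target") {
        cfg$thermo$m_target <- v
      } else {
        cfg$network$components <- lapply(cfg$network$components, function(cmp) {
          cmp$radius <- as.integer(v)
          cmp
        })
      }
      res <- run_simulation(cfg)
      n <- n + 1L
      rows[[n]] <- tibble::tibble(
        axis = axis, value = v, replicate = k, seed = cfg$seed,
        f_A = steady_state_activity(res)
      )
    }
  }
  do.call(rbind, rows)
}
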