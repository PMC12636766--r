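#' Thermodynamic parameters
#'
#' The membrane couples lipid pairs with `J` and inclusion-boundary/lipid
#' pairs with `J_int`. Temperature enters as the rescaled temperature
#' `tau = T / Tc` relative to the bare-membrane critical temperature, taken
#' as the exact square-lattice value `Tc = 2 J / log(1 + sqrt(2))` (with
#' `k_B = 1`), so `beta = 1 / (tau * Tc)`.
#'
#' @param tau Rescaled temperature, `> 0`.
#' @param J Lipid-lipid coupling (energy units).
#' @param J_int Inclusion-boundary/lipid coupling; defaults to `J`.
#' @param m_target Target magnetization (mean lipid spin) in `[-1, 1]`.
#' @param Tc_bare Bare critical temperature used to convert `tau` to `beta`;
#'   defaults to [tc_onsager()].
#' @return A `thermo_params` object.
#' @export
thermo_params <- function(tau = 1, J = 1, J_int = J, m_target = 0,
                          Tc_bare = tc_onsager(J)) {
  if (tau <= 0) stop("tau must be > 0")
  if (abs(m_target) > 1) stop("|m_target| must be <= 1")
  structure(
    list(tau = tau, J = J, J_int = J_int, m_target = m_target,
         Tc_bare = Tc_bare),
    class = "thermo_params"
  )
}

#' Exact critical temperature of the square-lattice Ising model
#'
#' `Tc = 2 J / log(1 + sqrt(2))`, approximately `2.269 J` (with `k_B = 1`).
#'
#' @param J Nearest-neighbour coupling.
#' @return Critical temperature in energy units.
#' @export
tc_onsager <- function(J = 1) {
  2 * J / log(1 + sqrt(2))
}

#' Initialize a lattice state
#'
#' Places the network's inclusions uniformly at random without overlap, then
#' fills the remaining sites with lipids at an exact integer composition:
#' `round((1 + m_target) / 2 * n_lipid)` spins up (half away from zero),
#' uniformly shuffled. Kawasaki dynamics conserve this composition exactly
#' thereafter.
#'
#' @param L Lattice side length (the lattice is `L x L`, periodic).
#' @param m_target Target magnetization in `[-1, 1]`.
#' @param network Optional `network_spec`; `NULL` gives a lipid-only lattice.
#' @param seed Integer seed; the state is reproducible from it.
#' @param max_tries Placement attempts per inclusion before giving up.
#' @return A `lattice_state`: list with `L`, `spins` (L x L integer matrix,
#'   0 on inclusion sites), `occupancy` (L x L integer matrix, 0 = lipid,
#'   `k` = inclusion id), `inclusions` (data frame: id, component, state,
#'   cx, cy), and the `network`.
#' @export
init_lattice <- function(L, m_target = 0, network = NULL, seed = NULL,
                         max_tries = 2000L) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  if (abs(m_target) > 1) stop("|m_target| must be <= 1")
  with_seed(seed, {
    occ <- matrix(0L, L, L)
    inc <- list()
    if (!is.null(network)) {
      stopifnot(inherits(network, "network_spec"))
      id <- 0L
      for (cmp in network$components) {
        fp <- rasterize_disk(cmp$radius)
        for (k in seq_len(cmp$count)) {
          id <- id + 1L
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            cx <- sample.int(L, 1L)
            cy <- sample.int(L, 1L)
            xs <- (cx - 1L + fp$offsets[, 1L]) %% L + 1L
            ys <- (cy - 1L + fp$offsets[, 2L]) %% L + 1L
            sites <- cbind(xs, ys)
            if (all(occ[sites] == 0L)) {
              occ[sites] <- id
              inc[[id]] <- data.frame(
                id = id, component = cmp$name, state = cmp$initial_state,
                cx = cx, cy = cy, stringsAsFactors = FALSE
              )
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("could not place inclusion ", k, " of component '",
                 cmp$name, "' after ", max_tries, " attempts; ",
                 "increase L or reduce counts/radii")
          }
        }
      }
    }
    spins <- matrix(0L, L, L)
    lipid <- occ == 0L
    n_lip <- sum(lipid)
    if (n_lip > 0L) {
      n_up <- as.integer(round_half_away((1 + m_target) / 2 * n_lip))
      v <- c(rep(1L, n_up), rep(-1L, n_lip - n_up))
      spins[lipid] <- sample(v)
    }
    inclusions <- if (length(inc)) {
      do.call(rbind, inc)
    } else {
      data.frame(id = integer(), component = character(), state = character(),
                 cx = integer(), cy = integer(), stringsAsFactors = FALSE)
    }
    structure(
      list(L = L, spins = spins, occupancy = occ, inclusions = inclusions,
           network = network),
      class = "lattice_state"
    )
  })
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d, %d lipid sites, %d inclusions\n",
              x$L, x$L, sum(x$occupancy == 0L), nrow(x$inclusions)))
  if (sum(x$occupancy == 0L) > 0L) {
    cat(sprintf("  magnetization m = %.4f\n", magnetization(x)))
  }
  invisible(x)
}

#' Magnetization of a lattice state
#'
#' Mean Ising spin over lipid sites only; inclusion sites carry no lipid spin
#' and are excluded. Conserved exactly under Kawasaki dynamics and inclusion
#' moves.
#'
#' @param state A `lattice_state`.
#' @return Mean lipid spin in `[-1, 1]`.
#' @export
magnetization <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  lipid <- state$occupancy == 0L
  if (!any(lipid)) stop("state has no lipid sites")
  mean(state$spins[lipid])
}

#' Membrane Hamiltonian
#'
#' `H_mem = -J * sum over nearest-neighbour lipid-lipid pairs of s_i s_j`
#' with periodic boundaries. Pairs involving an inclusion site are excluded
#' here; they belong to [hamiltonian_int()].
#'
#' @param state A `lattice_state`.
#' @param params A [thermo_params()] (only `J`/`J_int` are used here).
#' @return Energy (scalar).
#' @export
hamiltonian_mem <- function(state, params = thermo_params()) {
  e <- cpp_total_energy(state_to_cpp(state), net_for_state(state),
                        params$J, params$J_int)
  e$mem
}

#' Inclusion-boundary interaction Hamiltonian
#'
#' `H_int = -J_int * sum` over pairs of an inclusion boundary site and a
#' four-adjacent lipid of `b_i * s_adj`, plus `-J_int * b_i * b_j` for each
#' adjacent boundary pair of two distinct inclusions. Interior disk sites
#' carry no spin and contribute nothing.
#'
#' @inheritParams hamiltonian_mem
#' @return Energy (scalar).
#' @export
hamiltonian_int <- function(state, params = thermo_params()) {
  e <- cpp_total_energy(state_to_cpp(state), net_for_state(state),
                        params$J, params$J_int)
  e$int
}

#' Run Kawasaki spin-exchange sweeps
#'
#' One sweep makes `L^2` exchange attempts: a site is drawn uniformly at
#' random, then one of its four neighbours; if both are lipids with unequal
#' spins the swap is accepted with the Metropolis probability
#' `min(1, exp(-beta * dE))`, where `dE` includes lipid-lipid and
#' lipid-inclusion-boundary terms. Spin counts are conserved exactly.
#' Inclusions do not move and no reactions fire.
#'
#' @param state A `lattice_state`.
#' @param params A [thermo_params()].
#' @param sweeps Number of sweeps to run.
#' @param seed Integer seed for the move stream.
#' @return The updated `lattice_state`, with an `"acceptance"` attribute
#'   (attempt and accept counts).
#' @export
kawasaki_sweep <- function(state, params = thermo_params(), sweeps = 1L,
                           seed = 1L) {
  res <- cpp_run(state_to_cpp(state), net_for_state(state),
                 params$tau, params$J, params$J_int, params$Tc_bare,
                 as.integer(sweeps), 0L, 0L,
                 TRUE, FALSE, FALSE, FALSE, as.integer(seed))
  out <- state_from_cpp(res$state, state)
  attr(out, "acceptance") <- res$acc
  out
}

#' Export a lattice snapshot to plain-text files
#'
#' Writes the spin grid (lipid spins +1/-1; inclusion-occupied sites coded
#' `10 + type index`) as a headerless CSV, and a JSON sidecar with metadata
#' (lattice size, magnetization, inclusion table, and any supplied extras
#' such as tau, sweep index or seed).
#'
#' @param state A `lattice_state`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param meta Named list of extra metadata stored in the sidecar.
#' @return Invisibly, the two file paths.
#' @export
export_snapshot <- function(state, prefix, meta = list()) {
  stopifnot(inherits(state, "lattice_state"))
  grid <- state$spins
  if (nrow(state$inclusions) > 0L) {
    type_idx <- match(state$inclusions$component,
                      names(state$network$components))
    occ <- state$occupancy
    sel <- occ > 0L
    grid[sel] <- 10L + type_idx[occ[sel]]
  }
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.table(grid, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- c(list(L = state$L,
                 magnetization = if (any(state$occupancy == 0L)) {
                   magnetization(state)
                 } else {
                   NA_real_
                 },
                 inclusions = state$inclusions),
            meta)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(csv, json))
}

# --- internal: state marshalling ------------------------------------------

# A minimal network stand-in for states created without one (lipid-only), so
# the C++ engine always receives a type table.
net_for_state <- function(state) {
  if (!is.null(state$network)) return(net_to_cpp(state$network))
  list(types = list(), rules = list(
    actor_type = integer(), actor_state = integer(), sub_type = integer(),
    sub_state = integer(), product_state = integer(), rate = numeric(),
    sign = integer()
  ), type_names = character(), state_names = list())
}

state_to_cpp <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  inc <- state$inclusions
  if (nrow(inc) > 0L) {
    cn <- names(state$network$components)
    type_idx <- match(inc$component, cn)
    state_idx <- vapply(seq_len(nrow(inc)), function(i) {
      match(inc$state[i], names(state$network$components[[type_idx[i]]]$states))
    }, integer(1))
  } else {
    type_idx <- integer()
    state_idx <- integer()
  }
  list(L = state$L, spins = as.integer(state$spins),
       inc_type = as.integer(type_idx), inc_cx = as.integer(inc$cx),
       inc_cy = as.integer(inc$cy), inc_state = as.integer(state_idx))
}

# Rebuild a lattice_state from the engine's export, inheriting network and
# component/state labels from a template state.
state_from_cpp <- function(cst, template) {
  L <- cst$L
  spins <- matrix(cst$spins, L, L)
  occ <- matrix(cst$occ, L, L)
  inc <- template$inclusions
  if (nrow(inc) > 0L) {
    inc$cx <- cst$inc_cx
    inc$cy <- cst$inc_cy
    cn <- names(template$network$components)
    for (i in seq_len(nrow(inc))) {
      cmp <- template$network$components[[match(inc$component[i], cn)]]
      inc$state[i] <- names(cmp$states)[cst$inc_state[i]]
    }
  }
  structure(
    list(L = L, spins = spins, occupancy = occ, inclusions = inc,
         network = template$network),
    class = "lattice_state"
  )
}

# Invariant checks used by tests: occupancy/inclusion-registry consistency
# and the lipid/inclusion partition of sites.
validate_state <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  L <- state$L
  occ2 <- matrix(0L, L, L)
  if (nrow(state$inclusions) > 0L) {
    for (i in seq_len(nrow(state$inclusions))) {
      cmp <- state$network$components[[state$inclusions$component[i]]]
      fp <- rasterize_disk(cmp$radius)
      xs <- (state$inclusions$cx[i] - 1L + fp$offsets[, 1L]) %% L + 1L
      ys <- (state$inclusions$cy[i] - 1L + fp$offsets[, 2L]) %% L + 1L
      sites <- cbind(xs, ys)
      if (any(occ2[sites] != 0L)) stop("inclusion footprints overlap")
      occ2[sites] <- state$inclusions$id[i]
    }
  }
  if (!identical(occ2, state$occupancy)) {
    stop("occupancy map inconsistent with inclusion registry")
  }
  if (any(state$spins[state$occupancy != 0L] != 0L)) {
    stop("inclusion sites must carry no lipid spin")
  }
  if (any(!state$spins[state$occupancy == 0L] %in% c(-1L, 1L))) {
    stop("lipid sites must carry spin +1 or -1")
  }
  invisible(TRUE)
}

# Nonconserved single-spin-flip (Glauber-type) sweeps. Internal testing
# dynamics only: samples the unconstrained ensemble, where closed-form
# critical results for the bare membrane apply. Production dynamics are
# Kawasaki.
glauber_sweeps <- function(state, params = thermo_params(), sweeps = 1L,
                           record_every = 0L, seed = 1L) {
  res <- cpp_run(state_to_cpp(state), net_for_state(state),
                 params$tau, params$J, params$J_int, params$Tc_bare,
                 as.integer(sweeps), as.integer(record_every), 0L,
                 TRUE, FALSE, FALSE, FALSE, as.integer(seed), TRUE)
  out <- state_from_cpp(res$state, state)
  attr(out, "energies") <- tibble::tibble(sweep = res$rec_sweep,
                                          e_mem = res$e_mem,
                                          e_int = res$e_int)
  out
}
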