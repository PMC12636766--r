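# Shared fixtures: small networks and states built in code.

# Single-species network with one mobile probe inclusion (no reactions).
probe_network <- function(radius = 0L, b = 1L, count = 1L, mobility = 1) {
  network_spec(
    components = list(
      component_type("probe", c(on = as.integer(b)), radius = radius,
                     count = count, mobility = mobility)
    ),
    rules = list(), target = "probe", active_state = "on"
  )
}

# Magnetization that realizes exactly `n_up` up spins among `n_lip` lipids.
m_for_counts <- function(n_up, n_lip) 2 * n_up / n_lip - 1

# A lattice with inclusions at hand-picked centres (overrides random
# placement), for deterministic geometry tests.
place_lattice <- function(L, network, centers, m_target = 0, seed = 1L,
                          states = NULL) {
  st <- init_lattice(L, m_target, network, seed = seed)
  stopifnot(nrow(st$inclusions) == nrow(centers))
  occ <- matrix(0L, L, L)
  for (i in seq_len(nrow(centers))) {
    cmp <- network$components[[st$inclusions$component[i]]]
    fp <- rasterize_disk(cmp$radius)
    xs <- (centers[i, 1] - 1L + fp$offsets[, 1L]) %% L + 1L
    ys <- (centers[i, 2] - 1L + fp$offsets[, 2L]) %% L + 1L
    stopifnot(all(occ[cbind(xs, ys)] == 0L))
    occ[cbind(xs, ys)] <- i
    st$inclusions$cx[i] <- as.integer(centers[i, 1])
    st$inclusions$cy[i] <- as.integer(centers[i, 2])
    if (!is.null(states)) st$inclusions$state[i] <- states[i]
  }
  # refill lipids at the same composition
  n_lip <- sum(occ == 0L)
  n_up <- as.integer(round((1 + m_target) / 2 * n_lip))
  spins <- matrix(0L, L, L)
  set.seed(seed)
  spins[occ == 0L] <- sample(c(rep(1L, n_up), rep(-1L, n_lip - n_up)))
  st$spins <- spins
  st$occupancy <- occ
  st
}

# Independent brute-force energy oracle: naive double loop over all periodic
# bonds of an explicit lattice_state, no shared code with the engine.
brute_energy <- function(state, J = 1, J_int = 1) {
  L <- state$L
  occ <- state$occupancy
  # interaction field: lipid spin, boundary preference, or 0 (interior)
  fld <- state$spins
  bdy <- matrix(FALSE, L, L)
  if (nrow(state$inclusions) > 0L) {
    for (i in seq_len(nrow(state$inclusions))) {
      cmp <- state$network$components[[state$inclusions$component[i]]]
      b <- cmp$states[[state$inclusions$state[i]]]
      fp <- rasterize_disk(cmp$radius)
      xs <- (state$inclusions$cx[i] - 1L + fp$offsets[, 1L]) %% L + 1L
      ys <- (state$inclusions$cy[i] - 1L + fp$offsets[, 2L]) %% L + 1L
      fld[cbind(xs, ys)] <- ifelse(fp$boundary, b, 0L)
      bdy[cbind(xs, ys)[fp$boundary, , drop = FALSE]] <- TRUE
    }
  }
  e_mem <- 0
  e_int <- 0
  for (x in seq_len(L)) {
    for (y in seq_len(L)) {
      for (d in list(c(1L, 0L), c(0L, 1L))) {
        x2 <- (x - 1L + d[1]) %% L + 1L
        y2 <- (y - 1L + d[2]) %% L + 1L
        o1 <- occ[x, y]
        o2 <- occ[x2, y2]
        if (o1 == 0L && o2 == 0L) {
          e_mem <- e_mem - J * state$spins[x, y] * state$spins[x2, y2]
        } else if (o1 != o2) {
          e_int <- e_int - J_int * fld[x, y] * fld[x2, y2]
        }
      }
    }
  }
  list(mem = e_mem, int = e_int)
}
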