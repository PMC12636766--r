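#' Exhaustive Boltzmann enumeration of a tiny lattice system
#'
#' Enumerates every spin placement at fixed composition (and, if a single
#' inclusion is present, every inclusion position), computes each
#' configuration's energy with an independent naive bond-sum implementation
#' (pure R, no shared code with the sampler), and returns normalized
#' Boltzmann probabilities. Used as the equilibrium oracle against which the
#' Monte Carlo samplers are validated.
#'
#' Configuration keys encode the inclusion centre and the up-spin bitmask so
#' they match the keys reported by [sample_configurations()].
#'
#' @param L Lattice side length (state space must stay enumerable).
#' @param n_up Number of `+1` lipid spins (fixed composition).
#' @param tau,J,J_int Thermodynamic parameters as in [thermo_params()].
#' @param inclusion Optional `list(radius =, b =)` describing one inclusion;
#'   all `L^2` centre positions are enumerated.
#' @param max_states Hard bound on the configuration count.
#' @return An `enumerated_ensemble`: list with `table` (tibble: key, energy,
#'   prob), `Z`, `beta`, and the system description.
#' @export
enumerate_boltzmann <- function(L, n_up, tau = 1, J = 1, J_int = J,
                                inclusion = NULL, max_states = 1e7) {
  L <- as.integer(L)
  nsite <- L * L
  if (nsite > 40L) stop("configuration keys require L*L <= 40")
  beta <- 1 / (tau * tc_onsager(J))
  # periodic bonds, 0-based column-major site indexing (matches the sampler)
  x <- (seq_len(nsite) - 1L) %% L
  y <- (seq_len(nsite) - 1L) %/% L
  right <- ((x + 1L) %% L) + y * L + 1L
  down <- x + ((y + 1L) %% L) * L + 1L
  bonds <- rbind(cbind(seq_len(nsite), right), cbind(seq_len(nsite), down))

  centers <- if (is.null(inclusion)) NA_integer_ else seq_len(nsite)
  fp <- if (is.null(inclusion)) NULL else rasterize_disk(inclusion$radius)
  M <- nsite - (if (is.null(inclusion)) 0L else fp$n_sites)
  if (n_up < 0L || n_up > M) stop("n_up outside [0, lipid site count]")
  n_states <- length(centers) * choose(M, n_up)
  if (n_states > max_states) {
    stop("state space has ", format(n_states, big.mark = ","),
         " configurations, above the enforced bound of ", max_states)
  }

  keys <- numeric(0)
  energies <- numeric(0)
  pow2 <- 2^(0:(nsite - 1))
  for (ct in centers) {
    if (is.null(inclusion)) {
      fsite <- integer(0)
      fbdy <- logical(0)
    } else {
      cx <- (ct - 1L) %% L
      cy <- (ct - 1L) %/% L
      fx <- (cx + fp$offsets[, 1L]) %% L
      fy <- (cy + fp$offsets[, 2L]) %% L
      fsite <- fx + fy * L + 1L
      fbdy <- fp$boundary
      if (anyDuplicated(fsite)) stop("inclusion wraps onto itself; increase L")
    }
    lipid <- setdiff(seq_len(nsite), fsite)
    cmb <- utils::combn(length(lipid), n_up)
    K <- ncol(cmb)
    S <- matrix(0, nsite, K)
    S[lipid, ] <- -1
    if (n_up > 0L) {
      S[cbind(as.vector(lipid[cmb]), rep(seq_len(K), each = n_up))] <- 1
    }
    E <- numeric(K)
    is_fp <- logical(nsite)
    is_fp[fsite] <- TRUE
    bval <- integer(nsite)
    if (length(fsite)) bval[fsite[fbdy]] <- inclusion$b
    for (bnd in seq_len(nrow(bonds))) {
      u <- bonds[bnd, 1L]
      v <- bonds[bnd, 2L]
      if (!is_fp[u] && !is_fp[v]) {
        E <- E - J * S[u, ] * S[v, ]
      } else if (is_fp[u] && !is_fp[v]) {
        if (bval[u] != 0L) E <- E - J_int * bval[u] * S[v, ]
      } else if (!is_fp[u] && is_fp[v]) {
        if (bval[v] != 0L) E <- E - J_int * bval[v] * S[u, ]
      }
      # both in the (single) inclusion: no contribution
    }
    kspin <- as.vector(crossprod(S == 1, pow2))
    cpart <- if (is.null(inclusion)) 0 else (ct - 1) * 2^nsite
    keys <- c(keys, cpart + kspin)
    energies <- c(energies, E)
  }
  w <- exp(-beta * (energies - min(energies)))
  Z <- sum(w)
  tab <- tibble::tibble(key = keys, energy = energies, prob = w / Z)
  structure(
    list(table = tab, Z = Z * exp(-beta * min(energies)), beta = beta,
         L = L, n_up = n_up, inclusion = inclusion,
         n_states = length(keys)),
    class = "enumerated_ensemble"
  )
}

#' @export
print.enumerated_ensemble <- function(x, ...) {
  cat(sprintf(
    "<enumerated_ensemble> L=%d, %d up spins, %s inclusion: %d states\n",
    x$L, x$n_up, if (is.null(x$inclusion)) "no" else "one", x$n_states))
  invisible(x)
}

#' Sample configuration frequencies with the Monte Carlo engine
#'
#' Runs movement-only sweeps (Kawasaki exchanges, and inclusion translation
#' moves if present) and tabulates the configuration key after every sweep.
#' Keys match [enumerate_boltzmann()], so the output feeds directly into
#' [compare_to_sampler()].
#'
#' @param state A small `lattice_state` (`L^2 <= 40`).
#' @param params A [thermo_params()].
#' @param sweeps Number of sweeps (one sample per sweep).
#' @param seed Integer seed.
#' @param move_inclusions Attempt inclusion moves each sweep.
#' @return Tibble with `key` and `count`.
#' @export
sample_configurations <- function(state, params = thermo_params(),
                                  sweeps = 1e6, seed = 1L,
                                  move_inclusions = TRUE) {
  res <- cpp_sample_keys(state_to_cpp(state), net_for_state(state),
                         params$tau, params$J, params$J_int, params$Tc_bare,
                         as.integer(sweeps), move_inclusions,
                         as.integer(seed))
  tibble::tibble(key = res$key, count = res$count)
}

#' Compare sampled frequencies with the enumeration oracle
#'
#' Total-variation distance `TV = 1/2 * sum |p_exact - p_sampled|` over the
#' union of configuration keys, with a report of the worst-discrepancy
#' states.
#'
#' @param ensemble An `enumerated_ensemble`.
#' @param sampled Tibble with `key` and `count` (from
#'   [sample_configurations()]) or a named count vector.
#' @param n_worst Number of worst states to report.
#' @return List with `tv`, `n_sampled`, and `worst` (tibble).
#' @export
compare_to_sampler <- function(ensemble, sampled, n_worst = 10L) {
  stopifnot(inherits(ensemble, "enumerated_ensemble"))
  if (!is.data.frame(sampled)) {
    sampled <- tibble::tibble(key = as.numeric(names(sampled)),
                              count = as.numeric(sampled))
  }
  bad <- setdiff(sampled$key, ensemble$table$key)
  if (length(bad)) {
    stop("sampled keys outside the enumerated state space (first: ",
         format(bad[1], digits = 22), ")")
  }
  n <- sum(sampled$count)
  q <- sampled$count / n
  idx <- match(sampled$key, ensemble$table$key)
  p <- ensemble$table$prob
  diffs <- p
  diffs[idx] <- diffs[idx] - q
  tv <- sum(abs(diffs)) / 2
  ord <- order(abs(diffs), decreasing = TRUE)[seq_len(min(n_worst,
                                                          length(diffs)))]
  q_full <- numeric(length(p))
  q_full[idx] <- q
  worst <- tibble::tibble(
    key = ensemble$table$key[ord], p_exact = p[ord], p_sampled = q_full[ord],
    abs_diff = abs(diffs)[ord]
  )
  list(tv = tv, n_sampled = n, worst = worst)
}
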