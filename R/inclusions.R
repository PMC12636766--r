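#' Rasterize a disk-shaped inclusion
#'
#' The footprint of a radius-`r` disk is every integer offset `(dx, dy)` with
#' `dx^2 + dy^2 <= r^2`; the boundary is the subset of footprint sites with
#' at least one four-neighbour outside the footprint. For `r = 0` the
#' footprint is the single centre site (and is its own boundary), so a
#' radius-0 inclusion is geometrically a single lattice site.
#'
#' @param r Non-negative integer radius (lattice units).
#' @return List with `offsets` (n x 2 integer matrix of `(dx, dy)`),
#'   `boundary` (logical vector flagging boundary offsets), `n_sites`, and
#'   `n_boundary`.
#' @export
rasterize_disk <- function(r) {
  r <- as.integer(r)
  if (r < 0L) stop("r must be >= 0")
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  inside <- function(a, b) a^2 + b^2 <= r^2
  boundary <- !(inside(g$dx + 1L, g$dy) & inside(g$dx - 1L, g$dy) &
                  inside(g$dx, g$dy + 1L) & inside(g$dx, g$dy - 1L))
  list(offsets = cbind(dx = as.integer(g$dx), dy = as.integer(g$dy)),
       boundary = boundary, n_sites = nrow(g), n_boundary = sum(boundary))
}

#' Attempt one inclusion translation move
#'
#' Proposes a unit translation of one inclusion in a random (or given)
#' lattice direction. The move is rejected outright if the translated
#' footprint overlaps another inclusion; otherwise lipids on the leading edge
#' are relocated to the vacated trailing-edge sites through a deterministic
#' mirror mapping (an involution, so forward and reverse proposals are
#' symmetric and detailed balance holds), the total energy change over all
#' affected bonds is computed, and the move is accepted with
#' `min(1, exp(-beta * dE))`. Spin counts are conserved.
#'
#' @param state A `lattice_state`.
#' @param inc_id Inclusion id (row of `state$inclusions`).
#' @param params A [thermo_params()].
#' @param direction `NULL` for a random direction, or 1-4 for `+x`, `-x`,
#'   `+y`, `-y`.
#' @param seed Integer seed.
#' @return List with `accepted` (logical) and `state` (the possibly updated
#'   `lattice_state`).
#' @export
inclusion_move <- function(state, inc_id, params = thermo_params(),
                           direction = NULL, seed = 1L) {
  res <- cpp_inclusion_attempt(state_to_cpp(state), net_for_state(state),
                               params$tau, params$J, params$J_int,
                               params$Tc_bare, as.integer(inc_id),
                               as.integer(direction %||% -1L),
                               as.integer(seed))
  list(accepted = res$accepted, state = state_from_cpp(res$state, state))
}

#' Detect contacting inclusion pairs
#'
#' Two inclusions are in contact when some footprint site of one is
#' four-adjacent to some footprint site of the other (diagonal adjacency does
#' not count). Each unordered pair is reported once.
#'
#' @param state A `lattice_state`.
#' @return A tibble with columns `i`, `j` (inclusion ids, `i < j`).
#' @export
detect_contacts <- function(state) {
  m <- cpp_contacts(state_to_cpp(state), net_for_state(state))
  tibble::tibble(i = m[, 1L], j = m[, 2L])
}
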