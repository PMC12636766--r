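#' Define a PPI component species
#'
#' A component type is a disk-shaped membrane inclusion species: its lattice
#' radius, the number of copies placed in the membrane, its diffusive mobility
#' (translation attempts per Monte Carlo sweep), and its internal states. Each
#' state carries a boundary preference `b` in `{+1, -1}`: the uniform spin
#' value of the disk's boundary sites, encoding partitioning into the ordered
#' (`+1`) or disordered (`-1`) phase. A state-dependent boundary preference is
#' what makes partition-switching reactions possible.
#'
#' @param name Component name (string).
#' @param states Named integer vector mapping state label to boundary
#'   preference, e.g. `c(inactive = 1, active = 1)`. Values must be +1 or -1.
#' @param radius Disk radius in lattice units (non-negative integer). Radius 0
#'   is a single-site inclusion.
#' @param count Number of copies placed in the lattice.
#' @param mobility Translation attempts per sweep (`C`); fractional values are
#'   realized stochastically each sweep.
#' @param initial_state State label assigned at initialization (defaults to
#'   the first state).
#' @return A `component_type` object.
#' @export
component_type <- function(name, states, radius = 0L, count = 1L,
                           mobility = 0.1, initial_state = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("`states` must be a named vector (state label -> boundary preference)")
  }
  states <- vapply(states, as.integer, integer(1))
  if (!all(states %in% c(-1L, 1L))) {
    stop("boundary preferences must be +1 or -1 (component '", name, "')")
  }
  radius <- as.integer(radius)
  count <- as.integer(count)
  if (radius < 0L) stop("radius must be >= 0 (component '", name, "')")
  if (count < 1L) stop("count must be >= 1 (component '", name, "')")
  if (mobility < 0) stop("mobility must be >= 0 (component '", name, "')")
  initial_state <- initial_state %||% names(states)[1L]
  if (!initial_state %in% names(states)) {
    stop("initial_state '", initial_state, "' is not a state of '", name, "'")
  }
  structure(
    list(name = name, states = states, radius = radius, count = count,
         mobility = mobility, initial_state = initial_state),
    class = "component_type"
  )
}

#' Define a contact reaction rule
#'
#' When an actor inclusion (in a given state) is four-adjacent to a substrate
#' inclusion (in a given state), the substrate's state is changed to
#' `product_state` with probability `rate` per contacting pair per sweep. The
#' actor is never changed by firing. `activity_sign` records whether the rule
#' pushes the tracked target towards activity (+1) or away from it (-1); it is
#' used only by [sign_predict()].
#'
#' @param actor,actor_state Acting component name and state label.
#' @param substrate,substrate_state Substrate component name and its
#'   pre-reaction state label.
#' @param product_state Substrate state after firing.
#' @param rate Firing probability per contacting pair per sweep, in `[0, 1]`.
#' @param activity_sign `+1` (activating) or `-1` (deactivating).
#' @return A `reaction_rule` object.
#' @export
reaction_rule <- function(actor, actor_state, substrate, substrate_state,
                          product_state, rate = 1, activity_sign = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  activity_sign <- as.integer(activity_sign)
  if (!activity_sign %in% c(-1L, 1L)) stop("activity_sign must be +1 or -1")
  structure(
    list(actor = actor, actor_state = actor_state, substrate = substrate,
         substrate_state = substrate_state, product_state = product_state,
         rate = rate, activity_sign = activity_sign),
    class = "reaction_rule"
  )
}

#' Assemble a PPI network specification
#'
#' @param components List of [component_type()] objects.
#' @param rules List of [reaction_rule()] objects (may be empty).
#' @param target Name of the component whose active fraction `f_A` is tracked.
#' @param active_state State label of `target` counted as "active".
#' @return A validated `network_spec` object.
#' @export
network_spec <- function(components, rules = list(), target,
                         active_state = "active") {
  if (length(components) == 0L) stop("components: must declare at least one component")
  if (inherits(components, "component_type")) components <- list(components)
  if (inherits(rules, "reaction_rule")) rules <- list(rules)
  nm <- vapply(components, function(x) x$name, character(1))
  if (anyDuplicated(nm)) stop("components: duplicated component name")
  names(components) <- nm
  if (!target %in% nm) stop("target: '", target, "' is not a declared component")
  if (!active_state %in% names(components[[target]]$states)) {
    stop("active_state: '", active_state, "' is not a state of target '",
         target, "'")
  }
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    where <- paste0("rules[", k, "]")
    for (side in c("actor", "substrate")) {
      cn <- r[[side]]
      st <- r[[paste0(side, "_state")]]
      if (!cn %in% nm) stop(where, ".", side, ": unknown component '", cn, "'")
      if (!st %in% names(components[[cn]]$states)) {
        stop(where, ".", side, "_state: '", st, "' is not a state of '", cn, "'")
      }
    }
    if (!r$product_state %in% names(components[[r$substrate]]$states)) {
      stop(where, ".product_state: '", r$product_state,
           "' is not a state of '", r$substrate, "'")
    }
  }
  structure(
    list(components = components, rules = rules, target = target,
         active_state = active_state),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> target:", x$target, "(active state:", x$active_state, ")\n")
  for (cmp in x$components) {
    cat(sprintf("  %-12s r=%d count=%d C=%.3g states: %s\n", cmp$name,
                cmp$radius, cmp$count, cmp$mobility,
                paste0(names(cmp$states), "(b=", cmp$states, ")",
                       collapse = ", ")))
  }
  for (r in x$rules) {
    cat(sprintf("  %s[%s] + %s[%s] -> %s[%s]  rate=%.3g sign=%+d\n",
                r$actor, r$actor_state, r$substrate, r$substrate_state,
                r$substrate, r$product_state, r$rate, r$activity_sign))
  }
  invisible(x)
}

#' Load a network specification from YAML
#'
#' Reads a declarative network file (components with per-state boundary
#' preferences, reaction rules, tracked target) and validates it. The format
#' round-trips losslessly through [write_network()].
#'
#' @param path Path to a YAML network file.
#' @return A `network_spec`.
#' @seealso [static_partitioning_network()], [partition_switching_network()]
#'   for the bundled example networks.
#' @export
load_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$components) || length(doc$components) == 0L) {
    stop("components: must declare at least one component (", path, ")")
  }
  comps <- lapply(doc$components, function(cl) {
    if (is.null(cl$name)) stop("components[*].name: missing")
    if (is.null(cl$states) || length(cl$states) == 0L) {
      stop("components[", cl$name, "].states: missing")
    }
    for (s in cl$states) {
      if (is.null(s$name) || is.null(s$boundary_pref)) {
        stop("components[", cl$name, "].states: each state needs ",
             "`name` and `boundary_pref`")
      }
    }
    sts <- vapply(cl$states, function(s) as.integer(s$boundary_pref),
                  integer(1))
    names(sts) <- vapply(cl$states, function(s) s$name, character(1))
    component_type(
      name = cl$name, states = sts,
      radius = cl$radius %||% 0L, count = cl$count %||% 1L,
      mobility = cl$mobility %||% 0.1,
      initial_state = cl$initial_state %||% NULL
    )
  })
  rules <- lapply(doc$rules %||% list(), function(rl) {
    need <- c("actor", "actor_state", "substrate", "substrate_state",
              "product_state")
    miss <- need[!need %in% names(rl)]
    if (length(miss)) stop("rules[*].", miss[1], ": missing")
    reaction_rule(rl$actor, rl$actor_state, rl$substrate, rl$substrate_state,
                  rl$product_state, rate = rl$rate %||% 1,
                  activity_sign = rl$activity_sign %||% 1L)
  })
  if (is.null(doc$target)) stop("target: missing")
  network_spec(comps, rules, target = doc$target,
               active_state = doc$active_state %||% "active")
}

#' Write a network specification to YAML
#'
#' @param network A `network_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "network_spec"))
  doc <- list(
    components = lapply(unname(network$components), function(cmp) {
      list(name = cmp$name, radius = cmp$radius, count = cmp$count,
           mobility = cmp$mobility, initial_state = cmp$initial_state,
           states = lapply(seq_along(cmp$states), function(k) {
             list(name = names(cmp$states)[k],
                  boundary_pref = unname(cmp$states[k]))
           }))
    }),
    rules = lapply(network$rules, function(r) {
      list(actor = r$actor, actor_state = r$actor_state,
           substrate = r$substrate, substrate_state = r$substrate_state,
           product_state = r$product_state, rate = r$rate,
           activity_sign = r$activity_sign)
    }),
    target = network$target,
    active_state = network$active_state
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Bundled network: static partitioning activator/inactivator/target cascade
#'
#' The canonical three-component cascade: an activator that partitions into
#' the disordered phase, and an inactivator and two-state target that both
#' partition into the ordered phase. Contact with the activator switches the
#' target inactive -> active; contact with the inactivator switches it back.
#' Partitioning is static (both target states prefer order), so inclusion and
#' lipid configurations remain an equilibrium ensemble while the activity
#' dynamics are driven.
#'
#' @param n_activators,n_inactivators,n_targets Copy numbers.
#' @param radius Disk radius applied to all three components.
#' @param rate Firing probability per contacting pair per sweep.
#' @param mobility Translation attempts per sweep per inclusion.
#' @return A `network_spec`.
#' @export
static_partitioning_network <- function(n_activators = 10L,
                                        n_inactivators = 10L,
                                        n_targets = 20L, radius = 0L,
                                        rate = 1, mobility = 0.1) {
  network_spec(
    components = list(
      component_type("activator", c(on = -1L), radius = radius,
                     count = n_activators, mobility = mobility),
      component_type("inactivator", c(on = 1L), radius = radius,
                     count = n_inactivators, mobility = mobility),
      component_type("target", c(inactive = 1L, active = 1L),
                     radius = radius, count = n_targets, mobility = mobility,
                     initial_state = "inactive")
    ),
    rules = list(
      reaction_rule("activator", "on", "target", "inactive", "active",
                    rate = rate, activity_sign = +1L),
      reaction_rule("inactivator", "on", "target", "active", "inactive",
                    rate = rate, activity_sign = -1L)
    ),
    target = "target", active_state = "active"
  )
}

#' Bundled network: partition-switching cascade
#'
#' Like [static_partitioning_network()], but activation also switches the
#' target's domain preference (palmitoylation-like): the inactive target
#' prefers the disordered phase (`b = -1`) while the active target prefers
#' the ordered phase (`b = +1`). Here both the activator and the inactivator
#' prefer order. Because the boundary preference changes at a rate that
#' ignores the surrounding lipid configuration, this network drives the
#' spatial configuration out of equilibrium and can form kinetically trapped
#' "pocket" domains (see [detect_pockets()]).
#'
#' @inheritParams static_partitioning_network
#' @return A `network_spec`.
#' @export
partition_switching_network <- function(n_activators = 10L,
                                        n_inactivators = 10L,
                                        n_targets = 20L, radius = 0L,
                                        rate = 1, mobility = 0.1) {
  network_spec(
    components = list(
      component_type("activator", c(on = 1L), radius = radius,
                     count = n_activators, mobility = mobility),
      component_type("inactivator", c(on = 1L), radius = radius,
                     count = n_inactivators, mobility = mobility),
      component_type("target", c(inactive = -1L, active = 1L),
                     radius = radius, count = n_targets, mobility = mobility,
                     initial_state = "inactive")
    ),
    rules = list(
      reaction_rule("activator", "on", "target", "inactive", "active",
                    rate = rate, activity_sign = +1L),
      reaction_rule("inactivator", "on", "target", "active", "inactive",
                    rate = rate, activity_sign = -1L)
    ),
    target = "target", active_state = "active"
  )
}

#' Diagrammatic sign-product prediction of the temperature response
#'
#' For each rule, the contact sign is `+1` if actor and (pre-reaction)
#' substrate state partition into different phases — their contact rate then
#' increases with the rescaled temperature as domains dissolve — and `-1` if
#' they share a phase. Multiplying by the rule's activity sign gives the
#' rule's contribution to the slope of target activity versus temperature.
#' If all rules agree, that common sign predicts the slope of the target's
#' activity with respect to the rescaled temperature; otherwise the diagram
#' is indeterminate.
#'
#' @param network A `network_spec` with at least one rule.
#' @return A `sign_prediction`: list with `prediction` (`+1L`, `-1L`, or
#'   `NA` if indeterminate), `indeterminate`, and a per-rule breakdown.
#' @export
sign_predict <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  if (length(network$rules) == 0L) stop("network has no rules to analyse")
  rows <- lapply(network$rules, function(r) {
    actor_pref <- network$components[[r$actor]]$states[[r$actor_state]]
    sub_pref <- network$components[[r$substrate]]$states[[r$substrate_state]]
    if (is.null(actor_pref) || is.null(sub_pref) ||
        is.na(actor_pref) || is.na(sub_pref)) {
      stop("rule ", r$actor, "->", r$substrate,
           ": state without a boundary preference")
    }
    contact_sign <- if (actor_pref == sub_pref) -1L else 1L
    tibble::tibble(
      actor = r$actor, substrate = r$substrate,
      substrate_state = r$substrate_state,
      activity_sign = r$activity_sign, contact_sign = contact_sign,
      product = contact_sign * r$activity_sign
    )
  })
  rows <- do.call(rbind, rows)
  products <- unique(rows$product)
  prediction <- if (length(products) == 1L) products else NA_integer_
  structure(
    list(prediction = prediction, indeterminate = is.na(prediction),
         rules = rows),
    class = "sign_prediction"
  )
}

#' @export
print.sign_prediction <- function(x, ...) {
  if (x$indeterminate) {
    cat("<sign_prediction> indeterminate (pathway products disagree)\n")
  } else {
    cat(sprintf(
      "<sign_prediction> activity slope vs rescaled temperature: %+d\n",
      x$prediction))
  }
  print(x$rules)
  invisible(x)
}

# --- internal: marshal a network_spec for the C++ engine -------------------

# Integer-indexed view of a network: types with state tables, rules with
# 1-based type/state indices. Order of types follows network$components.
net_to_cpp <- function(network) {
  comps <- network$components
  type_names <- names(comps)
  state_names <- lapply(comps, function(cmp) names(cmp$states))
  types <- lapply(comps, function(cmp) {
    list(radius = cmp$radius, mobility = cmp$mobility,
         bpref = as.integer(unname(cmp$states)))
  })
  n <- length(network$rules)
  rules <- list(
    actor_type = integer(n), actor_state = integer(n), sub_type = integer(n),
    sub_state = integer(n), product_state = integer(n), rate = numeric(n),
    sign = integer(n)
  )
  for (k in seq_len(n)) {
    r <- network$rules[[k]]
    at <- match(r$actor, type_names)
    st <- match(r$substrate, type_names)
    rules$actor_type[k] <- at
    rules$actor_state[k] <- match(r$actor_state, state_names[[at]])
    rules$sub_type[k] <- st
    rules$sub_state[k] <- match(r$substrate_state, state_names[[st]])
    rules$product_state[k] <- match(r$product_state, state_names[[st]])
    rules$rate[k] <- r$rate
    rules$sign[k] <- r$activity_sign
  }
  list(types = unname(types), rules = rules, type_names = type_names,
       state_names = unname(state_names))
}
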