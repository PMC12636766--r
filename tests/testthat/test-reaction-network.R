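# Network spec validation, YAML round-trip, reactions, sign predictor.

test_that("network validation reports offending fields", {
  expect_error(network_spec(list(), list(), target = "x"), "components")
  expect_error(
    network_spec(list(component_type("a", c(on = 1L))),
                 list(reaction_rule("a", "on", "zz", "on", "on")),
                 target = "a", active_state = "on"),
    "substrate.*zz")
  expect_error(
    network_spec(list(component_type("a", c(on = 1L))),
                 list(reaction_rule("a", "off", "a", "on", "on")),
                 target = "a", active_state = "on"),
    "actor_state")
  expect_error(reaction_rule("a", "on", "b", "on", "on", rate = 1.5), "rate")
  expect_error(component_type("a", c(on = 2L)), "\\+1 or -1")
})

test_that("bundled networks load from YAML and round-trip losslessly", {
  p1 <- system.file("extdata", "static_partitioning_network.yaml",
                    package = "critppi")
  net <- load_network(p1)
  expect_s3_class(net, "network_spec")
  expect_identical(net, static_partitioning_network())
  expect_identical(net$target, "target")
  expect_identical(net$components$activator$states[["on"]], -1L)

  p5 <- system.file("extdata", "partition_switching_network.yaml",
                    package = "critppi")
  net5 <- load_network(p5)
  expect_identical(net5, partition_switching_network())
  expect_identical(net5$components$target$states,
                   c(inactive = -1L, active = 1L))

  tmp <- file.path(tempdir(), "rt.yaml")
  write_network(net5, tmp)
  expect_identical(load_network(tmp), net5)

  bad <- file.path(tempdir(), "bad.yaml")
  writeLines("components: []\ntarget: x", bad)
  expect_error(load_network(bad), "components")
})

test_that("sign products predict the temperature response", {
  # activator in the opposite phase from inactivator and target: all
  # pathway products positive -> activity rises with temperature
  expect_identical(sign_predict(static_partitioning_network())$prediction, 1L)
  # partition switching: both pathways still have positive product
  expect_identical(sign_predict(partition_switching_network())$prediction, 1L)

  # disagreeing pathways are indeterminate
  net <- network_spec(
    list(component_type("a", c(on = -1L)),
         component_type("i", c(on = -1L)),
         component_type("t", c(inactive = 1L, active = 1L),
                        initial_state = "inactive")),
    list(reaction_rule("a", "on", "t", "inactive", "active",
                       activity_sign = 1L),
         reaction_rule("i", "on", "t", "active", "inactive",
                       activity_sign = -1L)),
    target = "t")
  pred <- sign_predict(net)
  expect_true(pred$indeterminate)
  expect_identical(sort(unique(pred$rules$product)), c(-1L, 1L))
})

test_that("sign prediction is invariant under phase-label exchange", {
  for (net in list(static_partitioning_network(),
                   partition_switching_network())) {
    swapped <- net
    swapped$components <- lapply(net$components, function(cmp) {
      cmp$states <- -cmp$states
      cmp
    })
    expect_identical(sign_predict(swapped)$prediction,
                     sign_predict(net)$prediction)
  }
})

test_that("a contact fires its rule and updates the substrate state", {
  net <- static_partitioning_network(n_activators = 1L, n_inactivators = 1L,
                                     n_targets = 1L)
  # activator (id 1) adjacent to target (id 3); inactivator (id 2) far away
  st <- place_lattice(8, net, rbind(c(4, 4), c(8, 8), c(4, 5)))
  out <- apply_reactions(st, seed = 2)
  expect_identical(out$state$inclusions$state[3], "active")
  expect_identical(out$state$inclusions$state[1], "on")  # actor unchanged
  expect_identical(nrow(out$events), 1L)
  # firing moves nothing and changes no spins
  expect_identical(out$state$spins, st$spins)
  expect_identical(out$state$occupancy, st$occupancy)

  # no contacts -> no state changes
  st2 <- place_lattice(8, net, rbind(c(2, 2), c(8, 8), c(5, 5)))
  out2 <- apply_reactions(st2, seed = 2)
  expect_identical(out2$state$inclusions$state, st2$inclusions$state)
  expect_identical(nrow(out2$events), 0L)
})

test_that("partition switching flips the target boundary preference", {
  net <- partition_switching_network(n_activators = 1L, n_inactivators = 1L,
                                     n_targets = 1L)
  st <- place_lattice(8, net, rbind(c(4, 4), c(8, 8), c(4, 5)))
  expect_equal(net$components$target$states[[st$inclusions$state[3]]], -1L)
  out <- apply_reactions(st, seed = 1)
  expect_identical(out$state$inclusions$state[3], "active")
  expect_equal(net$components$target$states[["active"]], 1L)
  # the new boundary field takes effect immediately: the engine's
  # interaction energy agrees with the brute oracle evaluated on the
  # post-reaction state (which reads the active-state preference)
  expect_identical(out$state$spins, st$spins)
  expect_equal(hamiltonian_int(out$state), brute_energy(out$state)$int)
})

test_that("a substrate is modified at most once per sweep", {
  # target touching both an activator and an inactivator with rate 1:
  # whichever eligible rule fires first wins, and the substrate cannot be
  # flipped back in the same pass. From 'inactive' only activation matches.
  net <- static_partitioning_network(n_activators = 1L, n_inactivators = 1L,
                                     n_targets = 1L)
  for (seed in 1:10) {
    st <- place_lattice(8, net, rbind(c(4, 4), c(4, 6), c(4, 5)))
    out <- apply_reactions(st, seed = seed)
    expect_identical(out$state$inclusions$state[3], "active")
    expect_identical(nrow(out$events), 1L)
  }
})

test_that("static-partitioning reactions leave the configuration untouched", {
  # with static boundary preferences the state labels are passive: the
  # movement trajectory is bit-identical with reactions on or off
  net_on <- static_partitioning_network(n_activators = 3L,
                                        n_inactivators = 3L, n_targets = 6L)
  net_off <- net_on
  net_off$rules <- list()
  mk <- function(net) {
    sim_config(net, L = 24, tau = 1.05, sweeps = 300, seed = 31,
               record_every = 100)
  }
  a <- run_simulation(mk(net_on))
  b <- run_simulation(mk(net_off))
  expect_identical(a$final_state$spins, b$final_state$spins)
  expect_identical(a$final_state$inclusions$cx, b$final_state$inclusions$cx)
  expect_identical(a$final_state$inclusions$cy, b$final_state$inclusions$cy)
})

test_that("replaying the event log reproduces the final states", {
  net <- partition_switching_network(n_activators = 3L, n_inactivators = 3L,
                                     n_targets = 6L)
  cfg <- sim_config(net, L = 24, tau = 0.95, sweeps = 400, seed = 17,
                    record_every = 100, log_events = TRUE)
  res <- run_simulation(cfg)
  expect_gt(nrow(res$events), 0L)
  states <- res$initial_state$inclusions$state
  rules <- cfg$network$rules
  for (e in seq_len(nrow(res$events))) {
    states[res$events$substrate[e]] <- rules[[res$events$rule[e]]]$product_state
  }
  expect_identical(states, res$final_state$inclusions$state)
})
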