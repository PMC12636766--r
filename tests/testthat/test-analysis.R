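# Steady-state activity, logistic fits, correlations, pockets.

make_trace <- function(active_counts, total = 10L) {
  n <- length(active_counts)
  tibble::tibble(
    sweep = rep(seq_len(n) * 10L, each = 2L),
    component = "target",
    state = rep(c("active", "inactive"), n),
    count = as.integer(rbind(active_counts, total - active_counts))
  )
}

test_that("steady-state activity averages post-burn-in records", {
  net <- static_partitioning_network()
  expect_equal(steady_state_activity(make_trace(rep(10L, 6)), 0,
                                     network = net), 1)
  expect_equal(steady_state_activity(make_trace(rep(c(0L, 10L), 5)), 0,
                                     network = net), 0.5)
  # recount oracle on an arbitrary trace
  counts <- c(3L, 7L, 2L, 9L, 5L, 8L)
  tr <- make_trace(counts)
  expect_equal(steady_state_activity(tr, burn_in = 30, network = net),
               mean(counts[3:6] / 10))
  expect_error(steady_state_activity(tr, burn_in = 1000, network = net),
               "burn_in")
})

test_that("logistic fits recover exact parameters and flag degeneracy", {
  tau <- seq(0.85, 1.4, length.out = 12)
  truth <- list(L = 0.1, R = 0.9, dt = 0.05, tau0 = 1.02)
  f <- (truth$R - truth$L) / 2 * tanh((tau - truth$tau0) / (2 * truth$dt)) +
    (truth$R + truth$L) / 2
  fit <- fit_logistic(tau, f)
  expect_true(fit$converged)
  expect_equal(fit$L_asym, truth$L, tolerance = 1e-6)
  expect_equal(fit$R_asym, truth$R, tolerance = 1e-6)
  expect_equal(fit$delta_tau, truth$dt, tolerance = 1e-6)
  expect_equal(fit$tau0, truth$tau0, tolerance = 1e-6)

  flat <- fit_logistic(tau, rep(0.3, 12))
  expect_true(flat$unidentifiable)
  expect_equal(flat$L_asym, 0.3)
  expect_equal(flat$R_asym, 0.3)
  expect_true(is.na(flat$delta_tau))

  expect_error(fit_logistic(c(1, 1.1, 1.2), c(0, .5, 1)), "4 distinct")
})

test_that("fitted curves can be evaluated", {
  tau <- seq(0.8, 1.4, length.out = 10)
  f <- 0.4 * tanh((tau - 1.05) / 0.1) / 2 + 0.5
  fit <- fit_logistic(tau, f)
  expect_equal(predict(fit, tau), f, tolerance = 1e-5)
})

# synthetic snapshots: point inclusions of two types at given positions
synth_snapshot <- function(L, pos_a, pos_b) {
  net <- network_spec(
    list(component_type("A", c(on = 1L), count = max(nrow(pos_a), 1L)),
         component_type("B", c(on = 1L), count = max(nrow(pos_b), 1L))),
    list(), target = "A", active_state = "on")
  occ <- matrix(0L, L, L)
  n_a <- nrow(pos_a)
  inc <- data.frame(
    id = seq_len(n_a + nrow(pos_b)),
    component = c(rep("A", n_a), rep("B", nrow(pos_b))),
    state = "on",
    cx = c(pos_a[, 1], pos_b[, 1]), cy = c(pos_a[, 2], pos_b[, 2]),
    stringsAsFactors = FALSE
  )
  occ[cbind(inc$cx, inc$cy)] <- inc$id
  spins <- matrix(-1L, L, L)
  spins[occ != 0L] <- 0L
  structure(list(L = L, spins = spins, occupancy = occ, inclusions = inc,
                 network = net), class = "lattice_state")
}

test_that("self-correlation peaks at zero distance", {
  sn <- synth_snapshot(16, cbind(5, 5), cbind(12, 12))
  prof <- cross_correlation(list(sn), "A", "A")
  expect_equal(prof$correlation[prof$r == 0], 16 * 16)  # 1 / density
  expect_true(all(prof$correlation[prof$r > 0] == 0))
})

test_that("independently placed types are uncorrelated", {
  set.seed(71)
  L <- 32
  snaps <- lapply(1:150, function(k) {
    sites <- sample.int(L * L, 32)
    xy <- cbind((sites - 1L) %% L + 1L, (sites - 1L) %/% L + 1L)
    synth_snapshot(L, xy[1:16, , drop = FALSE], xy[17:32, , drop = FALSE])
  })
  # per-snapshot profiles give a standard error per radial bin; uniform
  # placement should sit at 1 within 3 standard errors everywhere
  profs <- vapply(snaps, function(sn) {
    cross_correlation(list(sn), "A", "B", max_radius = 10)$correlation
  }, numeric(nrow(cross_correlation(snaps[1], "A", "B", max_radius = 10))))
  r <- cross_correlation(snaps[1], "A", "B", max_radius = 10)$r
  mu <- rowMeans(profs)
  se <- apply(profs, 1, sd) / sqrt(ncol(profs))
  away <- r >= 1
  expect_true(all(abs(mu[away] - 1) <= 3 * se[away]))
  expect_lt(abs(mean(mu[away]) - 1), 0.02)
  expect_error(cross_correlation(snaps, "A", "Z"), "absent")
})

test_that("structural pocket detection follows its definition", {
  net <- partition_switching_network(n_activators = 1L, n_inactivators = 1L,
                                     n_targets = 3L)
  L <- 12
  # hand-built snapshot: one ordered cluster holding 3 active targets and
  # the activator; the inactivator sits isolated in the disordered sea
  occ <- matrix(0L, L, L)
  spins <- matrix(-1L, L, L)
  spins[4:8, 4:8] <- 1L  # ordered cluster
  inc <- data.frame(
    id = 1:5,
    component = c("activator", "inactivator", "target", "target", "target"),
    state = c("on", "on", "active", "active", "active"),
    cx = c(5L, 11L, 6L, 7L, 5L), cy = c(5L, 11L, 6L, 5L, 7L),
    stringsAsFactors = FALSE
  )
  occ[cbind(inc$cx, inc$cy)] <- inc$id
  spins[occ != 0L] <- 0L
  sn <- structure(list(L = L, spins = spins, occupancy = occ,
                       inclusions = inc, network = net),
                  class = "lattice_state")
  res <- detect_pockets(list(sn, sn, sn), T_persist = 3)
  expect_identical(res$n_events, 1L)
  expect_identical(res$events$persistence, 3L)

  # same geometry but the inactivator sits inside the cluster: no pocket
  inc2 <- inc
  inc2$cx[2] <- 8L
  inc2$cy[2] <- 8L
  occ2 <- matrix(0L, L, L)
  occ2[cbind(inc2$cx, inc2$cy)] <- inc2$id
  spins2 <- matrix(-1L, L, L)
  spins2[4:8, 4:8] <- 1L
  spins2[occ2 != 0L] <- 0L
  sn2 <- structure(list(L = L, spins = spins2, occupancy = occ2,
                        inclusions = inc2, network = net),
                   class = "lattice_state")
  res2 <- detect_pockets(list(sn2, sn2, sn2), T_persist = 3)
  expect_identical(res2$n_events, 0L)

  # a cluster must persist to count
  res3 <- detect_pockets(list(sn, sn2, sn2), T_persist = 2)
  expect_identical(res3$n_events, 0L)
})

test_that("distributional outlier flagging uses the replicate MAD", {
  f <- c(0.11, 0.10, 0.12, 0.09, 0.11, 0.10, 0.85)
  flags <- flag_activity_outliers(f, k = 5)
  expect_identical(which(flags), 7L)
  expect_warning(res <- detect_pockets(NULL, activity = f), "snapshots")
  expect_identical(which(res$outliers), 7L)
})

test_that("activity histograms cover the data", {
  set.seed(9)
  f <- c(stats::rbeta(40, 2, 8), 0.9)
  h <- bin_activity(f)
  expect_identical(sum(h$count), 41L)
})
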