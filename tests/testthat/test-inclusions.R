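# Disk inclusions: rasterization, boundary coupling, moves, contacts.

test_that("disk rasterization matches the offset-enumeration rule", {
  d0 <- rasterize_disk(0)
  expect_identical(d0$n_sites, 1L)
  expect_identical(unname(d0$offsets[1, ]), c(0L, 0L))
  expect_true(all(d0$boundary))

  # plus-shape: 5 sites; the centre's four neighbours are all in the
  # footprint, so only the 4 arms are boundary sites
  d1 <- rasterize_disk(1)
  expect_identical(d1$n_sites, 5L)
  expect_identical(d1$n_boundary, 4L)

  # independent enumeration for r = 3
  g <- expand.grid(-3:3, -3:3)
  expect_identical(rasterize_disk(3)$n_sites, sum(g[, 1]^2 + g[, 2]^2 <= 9))
  expect_identical(rasterize_disk(3)$n_sites, 29L)
})

test_that("boundary-exterior bond count is non-decreasing in radius", {
  n_bonds <- vapply(0:5, function(r) {
    fp <- rasterize_disk(r)
    inside <- function(a, b) a^2 + b^2 <= r^2
    sum(vapply(seq_len(fp$n_sites), function(k) {
      o <- fp$offsets[k, ]
      sum(!c(inside(o[1] + 1, o[2]), inside(o[1] - 1, o[2]),
             inside(o[1], o[2] + 1), inside(o[1], o[2] - 1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(n_bonds) >= 0))
})

test_that("boundary Hamiltonian matches hand counts and the brute oracle", {
  # single point inclusion with b = +1 in an all-up membrane: 4 bonds of -1
  net <- probe_network(radius = 0L, b = 1L)
  st <- place_lattice(5, net, cbind(3, 3), m_target = 1)
  expect_equal(hamiltonian_int(st), -4)
  expect_equal(hamiltonian_int(st, thermo_params(J_int = 0)), 0)

  # random small configurations, mixed radii and preferences
  for (seed in 1:4) {
    net <- network_spec(
      list(component_type("a", c(on = -1L), radius = 1L, count = 1L),
           component_type("b", c(on = 1L), radius = 0L, count = 2L)),
      list(), target = "b", active_state = "on")
    st <- init_lattice(8, 0.25, net, seed = seed)
    be <- brute_energy(st)
    expect_equal(hamiltonian_int(st), be$int)
    expect_equal(hamiltonian_mem(st), be$mem)
  }
})

test_that("energies are invariant under global flip and translation", {
  net <- network_spec(
    list(component_type("a", c(on = -1L), radius = 1L, count = 1L),
         component_type("b", c(on = 1L), radius = 2L, count = 1L)),
    list(), target = "b", active_state = "on")
  st <- init_lattice(10, 0.2, net, seed = 8)
  e_mem <- hamiltonian_mem(st)
  e_int <- hamiltonian_int(st)

  # global spin flip combined with flipping every boundary preference
  flipped <- st
  flipped$spins <- -st$spins
  flipped$network$components <- lapply(st$network$components, function(cmp) {
    cmp$states <- -cmp$states
    cmp
  })
  expect_equal(hamiltonian_mem(flipped), e_mem)
  expect_equal(hamiltonian_int(flipped), e_int)

  # rigid translation of the whole configuration (periodic)
  sh <- st
  sh$spins <- st$spins[c(4:10, 1:3), c(2:10, 1)]
  sh$occupancy <- st$occupancy[c(4:10, 1:3), c(2:10, 1)]
  sh$inclusions$cx <- (st$inclusions$cx - 4L) %% 10L + 1L
  sh$inclusions$cy <- (st$inclusions$cy - 2L) %% 10L + 1L
  expect_equal(hamiltonian_mem(sh), e_mem)
  expect_equal(hamiltonian_int(sh), e_int)
})

test_that("translation moves respect excluded volume and free diffusion", {
  net <- probe_network(radius = 1L, count = 2L, mobility = 1)
  # two r = 1 disks with centres 3 apart: moving one towards the other
  # would overlap and must be rejected
  st <- place_lattice(9, net, rbind(c(3, 5), c(6, 5)))
  res <- inclusion_move(st, 1, thermo_params(tau = 1), direction = 1)
  expect_false(res$accepted)
  expect_identical(res$state$inclusions$cx, st$inclusions$cx)

  # with J = J_int = 0 every non-overlapping proposal is accepted
  for (dir in c(2, 3, 4)) {
    res <- inclusion_move(st, 1, thermo_params(tau = 1, J = 0, J_int = 0),
                          direction = dir)
    expect_true(res$accepted)
  }
})

test_that("moves conserve composition and keep footprints disjoint", {
  net <- network_spec(
    list(component_type("a", c(on = -1L), radius = 1L, count = 3L,
                        mobility = 1),
         component_type("b", c(on = 1L), radius = 2L, count = 2L,
                        mobility = 1)),
    list(), target = "b", active_state = "on")
  cfg <- sim_config(net, L = 16, tau = 1.1, sweeps = 200, seed = 5,
                    record_every = 50)
  res <- run_simulation(cfg)
  expect_silent(critppi:::validate_state(res$final_state))
  expect_equal(sum(res$final_state$spins == 1L),
               sum(res$initial_state$spins == 1L))
  expect_equal(sum(res$final_state$spins == -1L),
               sum(res$initial_state$spins == -1L))
})

test_that("contact detection is four-adjacency of footprints", {
  net <- probe_network(radius = 0L, count = 2L)
  st <- place_lattice(6, net, rbind(c(2, 2), c(2, 3)))
  expect_identical(nrow(detect_contacts(st)), 1L)

  st <- place_lattice(6, net, rbind(c(2, 2), c(3, 3)))  # diagonal
  expect_identical(nrow(detect_contacts(st)), 0L)

  # r = 1 disks with centres 3 apart along an axis: extents touch
  net1 <- probe_network(radius = 1L, count = 2L)
  st <- place_lattice(10, net1, rbind(c(3, 5), c(6, 5)))
  cts <- detect_contacts(st)
  expect_identical(nrow(cts), 1L)
  expect_identical(c(cts$i, cts$j), c(1L, 2L))

  # centres 4 apart: a lipid row separates them
  st <- place_lattice(10, net1, rbind(c(3, 5), c(7, 5)))
  expect_identical(nrow(detect_contacts(st)), 0L)
})
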