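test_that("reaction_rate implements the three rate laws", {
  r_irrev <- list(kind = "mass_irrev", kf = 2, kb = 0,
                  reactants = list(sp(A = 1, B = 1)),
                  products = list(sp(C = 1)))
  expect_equal(reaction_rate(r_irrev, sp(A = 3, B = 4, C = 0)), 24)
  expect_equal(reaction_rate(r_irrev, sp(A = 0, B = 4, C = 0)), 0)

  # second-order in one species
  r_sq <- list(kind = "mass_irrev", kf = 1, kb = 0,
               reactants = list(sp(A = 2)), products = list(sp(C = 1)))
  expect_equal(reaction_rate(r_sq, sp(A = 3, C = 0)), 9)

  r_rev <- list(kind = "mass_rev", kf = 1, kb = 1,
                reactants = list(sp(A = 1)), products = list(sp(C = 1)))
  expect_equal(reaction_rate(r_rev, sp(A = 5, C = 5)), 0)

  r_mm <- list(kind = "michaelis_menten", kf = 0, kb = 0, vmax = 333,
               km = 266, reactants = list(sp(S = 1)),
               products = list(sp(P = 1)))
  expect_equal(reaction_rate(r_mm, sp(S = 266, P = 0)), 166.5) # Vmax/2 at Km

  expect_error(reaction_rate(r_irrev, sp(A = 1, C = 0)), "B")
})

test_that("assembled derivatives follow net stoichiometry and conserve closed pairs", {
  net <- tiny_network(c("A", "B"),
                      list(list(id = 1, from = sp(A = 1), to = sp(B = 1),
                                kf = 0.3)))
  rhs <- assemble_rhs(net)
  d <- rhs(sp(A = 10, B = 1))
  expect_equal(d[["A"]], -3)
  expect_equal(d[["B"]], 3)

  rev_net <- tiny_network(c("A", "B"),
                          list(list(id = 1, from = sp(A = 1), to = sp(B = 1),
                                    kf = 2, kb = 0.5, reversible = TRUE)))
  rhs2 <- assemble_rhs(rev_net)
  for (s in list(sp(A = 1, B = 1), sp(A = 7, B = 0.1), sp(A = 0, B = 4))) {
    d2 <- rhs2(s)
    expect_equal(d2[["A"]] + d2[["B"]], 0)
  }
})

test_that("first-order decay matches the closed form to high accuracy", {
  net <- tiny_network(c("A", "B"),
                      list(list(id = 1, from = sp(A = 1), to = sp(B = 1),
                                kf = 0.1)))
  traj <- simulate_network(net, state_tbl(A = 100, B = 0),
                           solver_settings(horizon = 10, output_step = 0.5))
  a10 <- traj$A[traj$time_s == 10]
  expect_equal(a10, 100 * exp(-0.1 * 10), tolerance = 1e-6)
  # mass conservation along the way
  expect_equal(traj$A + traj$B, rep(100, nrow(traj)), tolerance = 1e-8)
})

test_that("reversible binding relaxes to the equilibrium quadratic", {
  # E + I = EI with Ki = koff/kon = 1000 nM, I0 = 1000 >> E0 = 1
  rates <- ki_to_rate_constants(1000, koff_ref = 0.1)
  net <- tiny_network(c("E", "I", "EI"),
                      list(list(id = 1, from = sp(E = 1, I = 1),
                                to = sp(EI = 1), kf = rates$kon,
                                kb = rates$koff, reversible = TRUE)))
  traj <- simulate_network(net, state_tbl(E = 1, I = 1000, EI = 0),
                           solver_settings(horizon = 200, output_step = 1))
  bound <- traj$EI[nrow(traj)] / 1
  expect_equal(bound, 0.4999, tolerance = 0.001 / 0.4999)
})

test_that("all-zero rate constants leave the trajectory at its initial state", {
  net <- tiny_network(c("A", "B"),
                      list(list(id = 1, from = sp(A = 1), to = sp(B = 1),
                                kf = 0)))
  traj <- simulate_network(net, state_tbl(A = 5, B = 2),
                           solver_settings(horizon = 50, output_step = 5))
  expect_true(all(traj$A == 5))
  expect_true(all(traj$B == 2))
})

test_that("the G-protein activation pair alone conserves total G over the horizon", {
  full <- crosstalk_network()
  r23 <- full$reactions[full$reactions$id == 23, ]
  net <- tiny_network(c("G", "G-a"), list())
  net$reactions <- r23
  settings <- solver_settings(horizon = 600, output_step = 1)
  traj <- simulate_network(net, state_tbl(G = 10, `G-a` = 0), settings)
  total <- traj$G + traj$`G-a`
  expect_true(all(abs(total - 10) <= settings$abs_tol))
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle on small networks", {
  # network 1: A -> B -> C chain, hand-written derivative for the oracle
  net1 <- tiny_network(c("A", "B", "C"),
                       list(list(id = 1, from = sp(A = 1), to = sp(B = 1),
                                 kf = 0.5),
                            list(id = 2, from = sp(B = 1), to = sp(C = 1),
                                 kf = 0.2)))
  f1 <- function(y) c(A = -0.5 * y[["A"]],
                      B = 0.5 * y[["A"]] - 0.2 * y[["B"]],
                      C = 0.2 * y[["B"]])
  # network 2: reversible dimer-style binding plus degradation and a
  # Michaelis-Menten conversion
  net2 <- tiny_network(c("E", "I", "EI", "P"),
                       list(list(id = 1, from = sp(E = 1, I = 1),
                                 to = sp(EI = 1), kf = 0.01, kb = 0.3,
                                 reversible = TRUE),
                            list(id = 2, from = sp(EI = 1), to = sp(P = 1),
                                 kind = "michaelis_menten", vmax = 2,
                                 km = 5),
                            list(id = 3, from = sp(P = 1),
                                 to = sp(), kf = 0.05)))
  f2 <- function(y) {
    v1 <- 0.01 * y[["E"]] * y[["I"]] - 0.3 * y[["EI"]]
    v2 <- 2 * y[["EI"]] / (5 + y[["EI"]])
    v3 <- 0.05 * y[["P"]]
    c(E = -v1, I = -v1, EI = v1 - v2, P = v2 - v3)
  }
  cases <- list(
    list(net = net1, f = f1, y0 = c(A = 100, B = 0, C = 0)),
    list(net = net2, f = f2, y0 = c(E = 10, I = 50, EI = 0, P = 0))
  )
  for (cs in cases) {
    traj <- simulate_network(cs$net, cs$y0,
                             solver_settings(horizon = 20, output_step = 1))
    oracle <- rk4_integrate(cs$f, cs$y0, h = 1e-3, horizon = 20,
                            keep_every = 1000L)
    for (s in names(cs$y0)) {
      got <- traj[[s]]
      ref <- oracle$values[, s]
      scale <- pmax(abs(ref), 1e-8)
      expect_lt(max(abs(got - ref) / scale), 1e-4)
    }
  }
})

test_that("integration is deterministic: identical inputs give identical serialized output", {
  net <- crosstalk_network()
  init <- default_initial_conditions()
  settings <- solver_settings(horizon = 60, output_step = 0.5)
  t1 <- simulate_network(net, init, settings)
  t2 <- simulate_network(net, init, settings)
  expect_identical(serialize(as.data.frame(t1), NULL),
                   serialize(as.data.frame(t2), NULL))
})

test_that("halving the tolerances moves reported exposures by less than 0.1%", {
  net <- crosstalk_network()
  init <- default_initial_conditions()
  loose <- simulate_network(net, init,
                            solver_settings(horizon = 300, output_step = 0.5))
  tight <- simulate_network(net, init,
                            solver_settings(horizon = 300, output_step = 0.5,
                                            rel_tol = 5e-9, abs_tol = 5e-11))
  keys <- c("AKT", "pAKT", "GSK3B", "pGSK3B")
  rel <- abs(exposure(tight, keys) - exposure(loose, keys)) /
    exposure(tight, keys)
  expect_true(all(rel < 0.001))
})

test_that("incomplete or negative initial states are rejected with the species named", {
  net <- crosstalk_network()
  init <- default_initial_conditions()
  expect_error(simulate_network(net, init[-1, ]), "missing species: I")
  bad <- init
  bad$concentration_nM[bad$species == "AKT"] <- -1
  expect_error(simulate_network(net, bad), "negative initial.*AKT")
})

test_that("trajectory CSV round-trips through the writer and reader", {
  net <- pi3k_only_network()
  init <- default_initial_conditions()
  init <- init[init$species %in% net$species$name, ]
  traj <- simulate_network(net, init,
                           solver_settings(horizon = 10, output_step = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(names(back), names(traj))
  expect_equal(as.data.frame(back), as.data.frame(traj), tolerance = 1e-12,
               ignore_attr = TRUE)
})
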