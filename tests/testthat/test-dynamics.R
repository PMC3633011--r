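test_that("mass-action terms follow the input stoichiometry", {
  sys1 <- derive_odes(parse_reactions("R1 A -> B ; kf=k")$net, c(k = 2))
  tm <- ode_terms(sys1)
  expect_equal(tm$coefficient[tm$species == "A"], -2)
  expect_equal(tm$coefficient[tm$species == "B"], 2)
  expect_true(all(tm$monomial == "A"))

  sys2 <- derive_odes(parse_reactions("R1 A + B -> C ; kf=k")$net, c(k = 3))
  rhs <- oncolevel:::.ode_rhs(sys2, c(A = 2, B = 5, C = 0), 0)
  expect_equal(rhs, c(-30, -30, 30))

  pten <- build_pten_subnet()
  sys3 <- derive_odes(pten$net, pten$params)
  tm3 <- ode_terms(sys3)
  r42 <- tm3[tm3$transition == "R:42", ]
  expect_setequal(r42$species, c("Pip3:Pten", "Pip2", "Pten"))
  expect_equal(r42$coefficient[r42$species == "Pip3:Pten"],
               -pten$params[["k69"]])
  expect_equal(r42$coefficient[r42$species == "Pip2"], pten$params[["k69"]])
  expect_true(all(r42$monomial == "Pip3:Pten"))

  expect_error(derive_odes(pten$net, pten$params[-1]), "missing rate")
})

test_that("integration reproduces the unimolecular closed form", {
  sys <- derive_odes(parse_reactions("R1 A -> B ; kf=k")$net, c(k = 1, A = 1))
  traj <- integrate_odes(sys, c(0, 0.5, 1, 2))
  expect_equal(traj$amounts[, "A"], exp(-c(0, 0.5, 1, 2)), tolerance = 1e-8)
  expect_equal(traj$amounts[, "B"], 1 - exp(-c(0, 0.5, 1, 2)),
               tolerance = 1e-8)
})

test_that("timed events inject and scale species at the scheduled times", {
  net <- parse_reactions("R1 EGF + R -> C ; kf=k")$net
  sys <- derive_odes(net, c(k = 1e-4, EGF = 0, R = 50, C = 0))
  ev <- event_schedule(c(1500, 2500, 3500), rep("add", 3), rep("EGF", 3),
                       rep(7, 3))
  traj <- integrate_odes(sys, seq(0, 5000, by = 100), events = ev)
  for (tt in c(1500, 2500, 3500)) {
    i <- which(traj$times == tt)
    pre <- traj$events$pre[traj$events$time == tt]
    expect_equal(unname(traj$amounts[i, "EGF"] - pre), 7, tolerance = 1e-9)
  }

  ev2 <- event_schedule(100, "scale", "R", 0)
  traj2 <- integrate_odes(sys, seq(0, 400, by = 10),
                          x0 = c(EGF = 30, R = 50, C = 0), events = ev2)
  after <- traj2$times >= 100
  expect_true(all(traj2$amounts[after, "R"] <= 1e-8))
  # no R, no further complex formation
  c_at_100 <- traj2$amounts[traj2$times == 100, "C"]
  expect_equal(unname(traj2$amounts[nrow(traj2$amounts), "C"]),
               unname(c_at_100), tolerance = 1e-8)

  expect_error(event_schedule(1, "scale", "R", 1.5), "\\[0, 1\\]")
  expect_error(integrate_odes(sys, 0:10,
                              events = event_schedule(20, "add", "EGF", 1)),
               "within the integration window")
})

test_that("semiflow reduction removes one equation per semiflow and is exact", {
  pten <- build_pten_subnet()
  pten$net$initial_marking <- as_marking(pten$net,
                                         c(Pip3 = 80, Pten = 60, Pip2 = 40))
  sys <- derive_odes(pten$net, pten$params)
  flows <- p_semiflows(pten$net)
  red <- reduce_odes(sys, flows)
  expect_equal(n_equations(sys), 6L)
  expect_equal(n_equations(red), 4L)

  tg <- seq(0, 150, by = 1)
  full <- integrate_odes(sys, tg)
  reduced <- integrate_odes(red, tg)
  rel <- abs(full$amounts - reduced$amounts) / pmax(1, abs(full$amounts))
  expect_lt(max(rel), 1e-6)

  # no semiflows: unchanged
  open <- derive_odes(parse_reactions("R1 A -> B ; kf=k")$net, c(k = 1))
  expect_identical(reduce_odes(open, list()), open)

  # both semiflows forced onto one variable: no free pick remains
  one_place_flows <- list(flows[[1]], flows[[1]])
  f2 <- flows[[1]]
  f2$support <- "Pten:Pip2:Pip3"
  f2$coefficients[] <- 0
  f2$coefficients["Pten:Pip2:Pip3"] <- 1
  expect_error(reduce_odes(sys, list(f2, f2)), "already fully eliminated")
})

test_that("P-invariants are conserved along deterministic trajectories", {
  set.seed(5)
  for (seed in 1:5) {
    gen <- random_conservative_net(6, 9, list(c(1, 1, 2, 0, 0, 0),
                                              c(0, 0, 0, 1, 1, 1)),
                                   seed = seed)
    sys <- derive_odes(gen$net, gen$params)
    traj <- integrate_odes(sys, seq(0, 5, length.out = 51))
    rep <- verify_invariants(p_semiflows(gen$net), traj, rel_tol = 1e-8)
    expect_true(all(rep$pass), label = paste("seed", seed))
  }
})

test_that("the stochastic simulator is seed-reproducible and finds the right equilibrium", {
  net <- parse_reactions("R1 A <-> B ; kf=kf ; kb=kb")$net
  params <- c(kf = 1, kb = 3)
  s1 <- ssa_simulate(net, params, c(A = 1000, B = 0), t_end = 10, seed = 99)
  s2 <- ssa_simulate(net, params, c(A = 1000, B = 0), t_end = 10, seed = 99)
  expect_identical(s1$amounts, s2$amounts)

  # equilibrium fraction A = kb/(kf+kb) = 3/4; average the late plateau
  # over independent runs and compare at 3 standard errors
  runs <- vapply(1:50, function(s) {
    tr <- ssa_simulate(net, params, c(A = 1000, B = 0), t_end = 10, seed = s,
                       n_samples = 21L)
    mean(tr$amounts[11:21, "A"]) / 1000
  }, 0)
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 0.75), 3 * se + 1e-12)
})

test_that("binomial propensities handle multiplicity-2 inputs", {
  net <- parse_reactions("R1 A + A -> B ; kf=k")$net
  # with a single A the dimerization must never fire
  tr <- ssa_simulate(net, c(k = 100), c(A = 1, B = 0), t_end = 5, seed = 1)
  expect_true(all(tr$amounts[, "B"] == 0))
  tr2 <- ssa_simulate(net, c(k = 100), c(A = 2, B = 0), t_end = 5, seed = 1)
  expect_equal(unname(tr2$amounts[nrow(tr2$amounts), "B"]), 1)
})
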