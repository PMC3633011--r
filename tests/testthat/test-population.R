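zero_params <- function(...) {
  population_params(Psy = 0, Pasy = 0, omega_csc = 0, omega_pc = 0,
                    gamma_pc = 0, eta1 = 0, eta2 = 0, eta3 = 0,
                    d1 = 0, d2 = 0, d3 = 0, ...)
}

test_that("the population right-hand side is linear and homogeneous", {
  pp <- zero_params()
  st <- c(5, 1:7, 100)
  expect_true(all(population_rhs(st, pp) == 0))

  only_eta3 <- zero_params()
  only_eta3$eta3 <- 0.3
  st2 <- c(0, 0, 0, 0, 0, 0, 0, 1, 0)
  d <- population_rhs(st2, only_eta3)
  expect_equal(unname(d[c("PC7", "TC")]), c(-0.3, 0.3))
  expect_true(all(d[setdiff(names(d), c("PC7", "TC"))] == 0))

  set.seed(17)
  pp2 <- population_params(omega_csc = 0.3, omega_pc = 0.7, gamma_pc = 0.1)
  for (i in 1:20) {
    s <- stats::runif(9, 0, 100)
    expect_equal(population_rhs(2 * s, pp2, t = 3),
                 2 * population_rhs(s, pp2, t = 3))
    a <- stats::runif(1, 0, 5)
    s2 <- stats::runif(9, 0, 100)
    expect_equal(population_rhs(s + a * s2, pp2),
                 population_rhs(s, pp2) + a * population_rhs(s2, pp2))
  }
  expect_error(population_rhs(c(-1, rep(0, 8)), pp2), "negative")
})

test_that("terminal differentiation follows the two-compartment closed form", {
  pp <- zero_params()
  pp$eta3 <- 0.002
  P <- 500
  init <- c(CSC = 0, PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0, PC5 = 0, PC6 = 0,
            PC7 = P, TC = 0)
  tg <- seq(0, 2000, by = 10)
  traj <- simulate_population(pp, init, tg)
  expect_equal(traj$amounts[, "TC"], P * (1 - exp(-0.002 * tg)),
               tolerance = 1e-8)
})

test_that("asymptotic growth matches the dominant eigenvalue", {
  pp <- population_params()
  traj <- simulate_population(pp, t_grid = seq(0, 6000, by = 20))
  lam <- max(Re(eigen(population_matrix(pp))$values))
  n <- nrow(traj$amounts)
  tot <- rowSums(traj$amounts)
  slope <- (log(tot[n]) - log(tot[n - 50])) /
    (traj$times[n] - traj$times[n - 50])
  expect_equal(slope, lam, tolerance = 1e-4)
})

test_that("pure death decays every compartment monotonically", {
  pp <- zero_params()
  pp$d1 <- 0.1; pp$d2 <- 0.1; pp$d3 <- 0.1
  init <- stats::setNames(rep(10, 9), c("CSC", paste0("PC", 1:7), "TC"))
  traj <- simulate_population(pp, init, seq(0, 50, by = 1))
  for (sp in colnames(traj$amounts)) {
    expect_true(all(diff(traj$amounts[, sp]) <= 1e-10), label = sp)
  }
})

test_that("the maturation chain fills in hierarchical order from CSC", {
  pp <- population_params(gamma_pc = 0, omega_csc = 0.05, omega_pc = 0.05,
                          eta1 = 0.02, eta2 = 0.02, eta3 = 0.02,
                          d1 = 0, d2 = 0, d3 = 0)
  init <- c(CSC = 10, PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0, PC5 = 0,
            PC6 = 0, PC7 = 0, TC = 0)
  traj <- simulate_population(pp, init, seq(0, 400, by = 0.5))
  first_pos <- vapply(paste0("PC", 1:7), function(sp) {
    i <- which(traj$amounts[, sp] > 1e-6)[1]
    traj$times[i]
  }, 0)
  expect_true(all(diff(first_pos) >= 0))
})

test_that("the spheroid-derived initial composition integrates without negativity", {
  traj <- simulate_population(population_params(),
                              t_grid = seq(0, 6000, by = 20))
  expect_true(all(traj$amounts >= 0))
  expect_equal(unname(traj$amounts[1, c("CSC", "TC")]), c(15, 985))
})

test_that("growth onset finds the first threshold crossing", {
  flat <- oncolevel:::new_trajectory(0:10, matrix(5, 11, 1), "TC")
  expect_true(is.na(growth_onset(flat)))

  tg <- seq(0, 5, by = 0.001)
  expo <- oncolevel:::new_trajectory(tg, matrix(exp(tg), ncol = 1), "TC")
  expect_equal(growth_onset(expo, threshold_ratio = 10), log(10),
               tolerance = 2e-3)
  expect_error(growth_onset(expo, species = "PC1"), "lacks compartment")
})

test_that("parameter validation enforces probability and sign constraints", {
  expect_error(population_params(Psy = 0.7, Pasy = 0.5), "Psy \\+ Pasy")
  expect_error(population_params(eta1 = -1), "non-negative")
  expect_silent(population_params(Psy = 0.4, Pasy = 0.4))
})
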