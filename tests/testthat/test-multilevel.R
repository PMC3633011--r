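# Coupled-model runs are kept on short horizons here; the full 6000-unit
# vaccination experiments run in the acceptance suite.

test_that("the Pten subnet builder reproduces its five reference reactions", {
  pten <- build_pten_subnet()
  expect_setequal(pten$net$places,
                  c("Pip3", "Pten", "Pip3:Pten", "Pip2", "Pten:Pip2",
                    "Pten:Pip2:Pip3"))
  expect_length(pten$net$transitions, 8L)
  expect_equal(sum(pten$reactions$reversible), 3L)
  expect_true(is_covered(pten$net)$covered)
})

test_that("rate functions multiply three normalized target trajectories", {
  sp <- c("cyclinD", "NFkB", "pBAD")
  flat <- oncolevel:::new_trajectory(0:10, matrix(rep(c(4, 8, 2), each = 11),
                                                 11, 3), sp)
  spec <- coupling_spec(c(cyclinD = "cyclinD", nfkb = "NFkB", bad = "pBAD"),
                        scale = 0.05)
  w <- make_rate_function(flat, spec)
  expect_equal(w(c(0, 5, 10, 20)), rep(0.05, 4))

  doubled <- flat
  doubled$amounts[, "cyclinD"] <- 2 * doubled$amounts[, "cyclinD"]
  # doubling a target trajectory relative to an unchanged baseline doubles
  # the product pointwise
  base_val <- flat$amounts[1, "cyclinD"]
  w2 <- make_rate_function(doubled, coupling_spec(spec$targets, scale = 0.05))
  # baseline renormalizes, so scale against explicit identity transform
  w_id <- make_rate_function(flat, coupling_spec(
    spec$targets, transforms = c("identity", "normalize_to_baseline",
                                 "normalize_to_baseline"), scale = 0.05))
  w2_id <- make_rate_function(doubled, coupling_spec(
    spec$targets, transforms = c("identity", "normalize_to_baseline",
                                 "normalize_to_baseline"), scale = 0.05))
  expect_equal(w2_id(3), 2 * w_id(3))

  zero <- flat
  zero$amounts[, "NFkB"] <- 0
  expect_error(make_rate_function(zero, spec), "zero baseline")

  recip <- coupling_spec(spec$targets,
                         transforms = c("normalize_to_baseline",
                                        "normalize_to_baseline",
                                        "reciprocal_normalized"),
                         scale = 0.05)
  wr <- make_rate_function(flat, recip)
  expect_equal(wr(0), 0.05)
})

test_that("constant coupling reduces the pipeline to the plain population model", {
  pten <- build_pten_subnet()
  # a molecular "net" already at steady state: every trajectory constant
  part <- list(net = pten$net, params = pten$params)
  part$net$initial_marking <- as_marking(part$net, c(Pten = 10, Pip2 = 20))
  part <- equilibrate_net(part, t_relax = 2000)
  tg <- seq(0, 1500, by = 10)
  spec <- coupling_spec(c(a = "Pten", b = "Pip2", c = "Pten:Pip2"),
                        scale = 0.02)
  model <- coupled_model(
    csc = part, pc = part,
    coupling = list(csc = spec, pc = coupling_spec(spec$targets, scale = 0.04)),
    population_params = population_params(),
    schedules = list(csc = event_schedule(), pc = event_schedule())
  )
  res <- run_coupled(model, tg)
  expect_equal(res$omega_csc(c(0, 700, 1500)), rep(0.02, 3), tolerance = 1e-6)
  direct <- simulate_population(population_params(), t_grid = tg)
  rel <- abs(res$population$amounts - direct$amounts) /
    pmax(1, abs(direct$amounts))
  expect_lt(max(rel), 1e-4)
})

test_that("demo net structure honours its configuration flags", {
  demo <- build_demo_erbb2_net()
  expect_true(all(c("cyclinD", "NFkB", "pBAD") %in% demo$net$places))
  expect_true(all(demo$targets %in% demo$net$places))
  expect_error(build_demo_erbb2_net(portions = c("A", "B")), "portion C")

  # without synthesis/degradation every place is conserved somewhere
  closed <- build_demo_erbb2_net(turnover = FALSE)
  cov <- is_covered(closed$net)
  expect_true(cov$covered)

  # without portion E, TLR2 machinery is absent and TLR2 events are rejected
  no_e <- build_demo_erbb2_net(portions = c("A", "B", "C", "D"))
  expect_false(any(grepl("TLR2", no_e$net$places)))
  sys <- derive_odes(no_e$net, no_e$params)
  expect_error(
    integrate_odes(sys, seq(0, 100, by = 10),
                   events = event_schedule(50, "scale", "TLR2", 0.1)),
    "unknown species")
})

test_that("removing ErbB2 lowers the cyclinD response to an EGF injection", {
  tg <- seq(0, 1200, by = 10)
  run_with_erbb2 <- function(erbb2_amount) {
    part <- build_demo_erbb2_net()
    part$params["ErbB2"] <- erbb2_amount
    part$net$initial_marking["ErbB2"] <- erbb2_amount
    # receptor synthesis would regrow the pool; remove it for this contrast
    part$params["a15"] <- 0
    part <- equilibrate_net(part, t_relax = 3000)
    sys <- derive_odes(part$net, part$params)
    ev <- event_schedule(200, "add", "EGF", 100)
    integrate_odes(sys, tg, events = ev, rtol = 1e-6, atol = 1e-8)
  }
  with_r <- run_with_erbb2(200)
  without_r <- run_with_erbb2(0)
  peak_with <- max(with_r$amounts[, "cyclinD"])
  peak_without <- max(without_r$amounts[, "cyclinD"])
  expect_lt(peak_without, peak_with)
})

test_that("vaccination retention is monotone in the population outcome", {
  tg <- seq(0, 2500, by = 25)
  run_rho <- function(rho) {
    m <- build_demo_coupled_model()
    sp <- receptor_species(m$csc$net, "ErbB2")
    sched <- event_schedule(rep(500, length(sp)), rep("scale", length(sp)),
                            sp, rep(rho, length(sp)))
    m$schedules <- list(csc = sched, pc = sched)
    run_coupled(m, tg)$population$amounts[length(tg), "TC"]
  }
  tc_low <- run_rho(0.05)
  tc_high <- run_rho(0.5)
  tc_none <- run_rho(1)
  expect_lte(tc_low, tc_high)
  expect_lte(tc_high, tc_none)
})

test_that("TLR2 vaccination leaves omega_pc unchanged when PCs carry no TLR2", {
  tg <- seq(0, 2000, by = 20)
  base <- build_demo_coupled_model(tlr2_pc = 0)
  r0 <- run_coupled(base, tg)
  vacc <- build_demo_coupled_model(tlr2_pc = 0)
  tl_csc <- receptor_species(vacc$csc$net, "TLR2")
  tl_pc <- receptor_species(vacc$pc$net, "TLR2")
  vacc$schedules <- list(
    csc = event_schedule(rep(500, length(tl_csc)), rep("scale", length(tl_csc)),
                         tl_csc, rep(0.1, length(tl_csc))),
    pc = event_schedule(rep(500, length(tl_pc)), rep("scale", length(tl_pc)),
                        tl_pc, rep(0.1, length(tl_pc))))
  r1 <- run_coupled(vacc, tg)
  ts <- seq(600, 2000, by = 100)
  expect_equal(r1$omega_pc(ts), r0$omega_pc(ts), tolerance = 1e-6)
})

test_that("the full-network loader reports structural counts", {
  dir <- withr::local_tempdir()
  rxn <- file.path(dir, "mini.rxn")
  par <- file.path(dir, "mini.tsv")
  writeLines(c("R:1 A + B <-> A:B ; kf=k1 ; kb=k2",
               "R:2 A:B -> C + B ; kf=k3",
               "R:3 C -> A ; kf=k4"), rxn)
  writeLines(c("name\tvalue", "k1\t0.1", "k2\t0.2", "k3\t0.3", "k4\t0.4",
               "A\t5", "B\t3"), par)
  full <- load_full_network(rxn, par)
  expect_equal(full$n_places, 4L)
  expect_equal(full$n_transitions, 4L)
  expect_equal(full$n_reactions, 3L)
  expect_equal(full$n_parameters, 6L)
  expect_equal(full$net$initial_marking[["A"]], 5)
  expect_error(load_full_network(par, par), "failed to parse")
})
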