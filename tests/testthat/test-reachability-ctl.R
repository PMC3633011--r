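pten_rg <- function() {
  reachability_graph(build_pten_subnet()$net, c(Pip3 = 1, Pten = 1))
}

test_that("reachability graphs enumerate exactly the reachable markings", {
  rg <- pten_rg()
  expect_equal(nrow(rg$states), 4L)
  expect_equal(nrow(rg$edges), 5L)
  expect_length(rg$deadlocks, 0L)

  ab <- parse_reactions("R1 A <-> B ; kf=k1 ; kb=k2")$net
  rg2 <- reachability_graph(ab, c(A = 1))
  expect_equal(nrow(rg2$states), 2L)
  expect_equal(nrow(rg2$edges), 2L)

  rg3 <- reachability_graph(ab, c(A = 0))
  expect_equal(nrow(rg3$states), 1L)
  expect_equal(nrow(rg3$edges), 0L)
  expect_identical(rg3$deadlocks, 1L)

  expect_error(reachability_graph(ab, c(A = 5), max_states = 3L), "exceeds")
  expect_error(reachability_graph(ab, c(A = 0.5)), "integer")
})

test_that("CTL parser handles the query grammar and rejects fused operators", {
  f <- parse_ctl("EF(Pten:Pip2 > 0)")
  expect_identical(f$op, "EF")
  expect_identical(f$f$place, "Pten:Pip2")

  g <- parse_ctl("EG((Pten => EF !Pten) & (!Pten => EF Pten))")
  expect_identical(g$op, "EG")
  expect_identical(g$f$op, "and")
  # bare place sugar
  expect_identical(g$f$lhs$lhs, list(op = "atom", place = "Pten",
                                     cmp = ">", value = 0L))

  u <- parse_ctl("E[A1 U (B2 >= 2)]")
  expect_identical(u$op, "EU")
  expect_identical(u$rhs$cmp, ">=")

  expect_error(parse_ctl("AXG p"), "path\\s+quantifier")
  expect_error(parse_ctl("G p"), "path quantifier")
  expect_error(parse_ctl("EF(p"), "expected")
  expect_error(parse_ctl("EF p) q"), "trailing")
  expect_error(parse_ctl("EF q", places = c("a", "b")), "unknown place")
  # unicode forms are accepted
  h <- parse_ctl("EG((Pten ⇒ EF ¬Pten) ∧ (¬Pten ⇒ EF Pten))")
  expect_identical(oncolevel:::.ctl_deparse(h), oncolevel:::.ctl_deparse(g))
})

test_that("fixed-point model checking matches hand-derived truths", {
  rg <- pten_rg()
  expect_true(check_ctl(rg, "EF(Pten:Pip2 > 0)")$holds)
  expect_true(check_ctl(rg, "EG((Pten => EF !Pten) & (!Pten => EF Pten))")$holds)
  expect_false(check_ctl(rg, "EF(Pten:Pip2 > 1)")$holds)
  expect_true(check_ctl(rg, "AG(Pip3 <= 1)")$holds)

  # chain: terminal deadlock, token must arrive
  chain <- toy_bounded_net("chain", 3)
  rgc <- reachability_graph(chain)
  expect_identical(rgc$deadlocks, 3L)
  expect_true(check_ctl(rgc, "AF(P3 > 0)")$holds)
  expect_true(check_ctl(rgc, "EG(P3 = 0) | AF(P3 > 0)")$holds)

  # fork: both branches reachable, neither inevitable
  fork <- toy_bounded_net("fork", 2)
  rgf <- reachability_graph(fork)
  expect_equal(nrow(rgf$states), 3L)
  expect_true(check_ctl(rgf, "EF branch1")$holds)
  expect_true(check_ctl(rgf, "EF branch2")$holds)
  expect_false(check_ctl(rgf, "AF branch1")$holds)
})

test_that("checker agrees with the path-enumeration oracle on random instances", {
  set.seed(23)
  rgs <- list(pten_rg(),
              reachability_graph(toy_bounded_net("fork", 3)),
              reachability_graph(toy_bounded_net("chain", 4)),
              reachability_graph(toy_bounded_net("cycle", 5)))
  pten2 <- build_pten_subnet()$net
  rgs[[5]] <- reachability_graph(pten2, c(Pip3 = 2, Pten = 2))
  for (rg in rgs) {
    places <- colnames(rg$states)
    for (i in 1:15) {
      f <- random_ctl(places, depth = 3L)
      got <- check_ctl(rg, f)
      want <- ctl_oracle(rg, f)
      expect_identical(got$satisfying, want$satisfying,
                       label = oncolevel:::.ctl_deparse(f))
    }
  }
})

test_that("CTL dualities and EF monotonicity hold state-wise", {
  set.seed(31)
  rg <- reachability_graph(build_pten_subnet()$net, c(Pip3 = 2, Pten = 1))
  places <- colnames(rg$states)
  for (i in 1:20) {
    f <- random_ctl(places, depth = 2L)
    ag <- check_ctl(rg, structure(list(op = "AG", f = f),
                                  class = "ctl_formula"))$satisfying
    not_ef_not <- check_ctl(rg, structure(
      list(op = "not", f = list(op = "EF", f = list(op = "not", f = f))),
      class = "ctl_formula"))$satisfying
    expect_identical(ag, not_ef_not)

    af <- check_ctl(rg, structure(list(op = "AF", f = f),
                                  class = "ctl_formula"))$satisfying
    not_eg_not <- check_ctl(rg, structure(
      list(op = "not", f = list(op = "EG", f = list(op = "not", f = f))),
      class = "ctl_formula"))$satisfying
    expect_identical(af, not_eg_not)

    sat_f <- check_ctl(rg, f)$satisfying
    sat_ef <- check_ctl(rg, structure(list(op = "EF", f = f),
                                      class = "ctl_formula"))$satisfying
    expect_true(all(sat_f %in% sat_ef))
  }
})
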