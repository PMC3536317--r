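test_that("tumor-free equilibrium has the published coordinates", {
  tf <- tumor_free_equilibrium(table1)
  expect_true(tf$feasible)
  expect_equal(tf$state[["I"]], 0.4 / 0.29, tolerance = 1e-12)
  expect_equal(round(tf$state[["I"]], 9), 1.379310345)
  expect_equal(tf$state[["H"]], 0.7 / 0.3, tolerance = 1e-12)
  expect_lt(tf$residual, 1e-10)
})

test_that("estrogen tumor-free state follows the closed form and the
           estrogen-level admissibility condition", {
  p <- estro_defaults
  tf <- tumor_free_equilibrium(p, "estrogen")
  E <- p[["pi_src"]] / p[["theta"]]
  expect_equal(tf$state[["E"]], E)
  expect_equal(tf$state[["H"]], (p[["alpha1"]] - p[["sigma1"]] * E) /
                 p[["beta1"]])
  expect_equal(tf$state[["I"]],
               p[["s"]] * (E + p[["upsilon"]]) /
                 (p[["mu"]] * (E + p[["upsilon"]]) + p[["sigma3"]] * E))
  expect_true(condition_flag(tf, "E_le_alpha1_over_sigma1"))
  # with a positive source the state is only a pseudo-equilibrium: the
  # sigma2*H*E transfer seeds tumor at T = 0, so the residual is nonzero
  expect_false(tf$feasible)
  expect_gt(tf$residual, 1e-10)
  # a source large enough that pi/theta > alpha1/sigma1 fails admissibility
  big <- default_estrogen_params(pi_src = 3)
  expect_false(condition_flag(tumor_free_equilibrium(big, "estrogen"),
                              "E_le_alpha1_over_sigma1"))
})

test_that("admissibility of the estrogen tumor-free coordinates is
           equivalent to pi/theta <= alpha1/sigma1 over random draws", {
  set.seed(11)
  for (k in 1:300) {
    p <- sample_parameter_set(model = "estrogen")
    tf <- tumor_free_equilibrium(p, "estrogen")
    lhs <- condition_flag(tf, "E_le_alpha1_over_sigma1")
    rhs <- p[["pi_src"]] / p[["theta"]] <= p[["alpha1"]] / p[["sigma1"]]
    expect_identical(lhs, rhs)
    expect_identical(all(tf$state >= 0), rhs)
  }
})

test_that("type 2 dead state is always a feasible fixed point", {
  set.seed(12)
  for (k in 1:50) {
    p <- sample_parameter_set(model = "estrogen_free")
    d2 <- dead_equilibria(p)[[1]]
    expect_identical(d2$label, "dead2")
    expect_true(d2$feasible)
    expect_equal(d2$state[["I"]], p[["s"]] / p[["mu"]], tolerance = 1e-12)
    expect_lt(d2$residual, 1e-10)
  }
})

test_that("type 1 dead state follows the immune-balance quadratic", {
  # Table 1: u2 = mu + omega*gamma3 - rho = 0.12 > 0, so no real positive
  # root exists and the state is infeasible
  d <- dead_equilibria(table1)
  d1 <- Filter(function(e) e$label == "dead1", d)[[1]]
  expect_false(d1$feasible)
  expect_false(condition_flag(d1, "mu_plus_omega_gamma3_lt_rho"))
  expect_equal(d1$conditions$margin[
    d1$conditions$name == "mu_plus_omega_gamma3_lt_rho"], -0.12,
    tolerance = 1e-12)
  # strong immune response: rho = 1.0 gives real roots; compare the
  # primary (+sqrt) branch against a brute-force sign-scan of the
  # quadratic over T in [0, 100]
  p <- validate_params(replace(stats::setNames(as.numeric(table1),
                                               names(table1)),
                              "rho", 1.0), "estrogen_free")
  u1 <- 0.1; u2 <- 0.29 + 0.3 * 0.1 - 1.0; u3 <- 0.29 * 0.3
  qf <- function(Tm) u1 * Tm^2 + u2 * Tm + u3
  grid <- seq(0, 100, by = 1e-4)
  sgn <- sign(qf(grid))
  flips <- which(diff(sgn) != 0)
  expect_gte(length(flips), 2)
  scan_roots <- grid[flips]
  d1p <- Filter(function(e) e$label == "dead1" && e$branch == "primary",
                dead_equilibria(p))[[1]]
  expect_lt(min(abs(d1p$state[["T"]] - scan_roots)), 2e-4)
  expect_equal(d1p$state[["T"]], (-u2 + sqrt(u2^2 - 4 * u1 * u3)) / (2 * u1),
               tolerance = 1e-12)
})

test_that("dead1 feasibility implies the printed existence conditions", {
  set.seed(13)
  examined <- 0
  for (k in 1:300) {
    p <- sample_parameter_set(model = "estrogen_free")
    d1s <- Filter(function(e) e$label == "dead1", dead_equilibria(p))
    for (d1 in d1s) {
      examined <- examined + 1
      u2 <- p[["mu"]] + p[["omega"]] * p[["gamma3"]] - p[["rho"]]
      if (isTRUE(d1$feasible)) {
        expect_lt(u2, 0)
        expect_gt(u2^2, 4 * p[["gamma3"]] * p[["omega"]] * p[["mu"]])
      }
      # real-root reporting must agree with the sign conditions
      if (u2 >= 0 || u2^2 < 4 * p[["gamma3"]] * p[["omega"]] * p[["mu"]])
        expect_false(isTRUE(d1$feasible))
    }
  }
  expect_gt(examined, 300)
})

test_that("coexisting equilibrium matches a brute-force grid search", {
  # Table 1 values: the scalar tumor equation has no root in
  # (0, alpha2/beta2] (immune control wins) — verify against a dense scan
  p <- table1
  I_of <- function(Tm) 0.4 / (0.29 - 0.2 * Tm / (0.3 + Tm) + 0.1 * Tm)
  gap <- function(Tm) Tm - (0.98 - 0.9 * I_of(Tm)) / 0.4
  grid <- seq(1e-6, 2.45, by = 1e-6)
  expect_true(all(sign(gap(grid)) == 1))     # no sign change anywhere
  cx <- coexisting_equilibrium(p)
  expect_false(cx$feasible)
  expect_false(condition_flag(cx, "no_root_in_bracket"))
  # aggressive tumor (alpha2 = 2 > resistance) with weakened competition
  # (delta1 = 0.2, so the host coordinate stays positive at the root):
  # a root exists; compare with grid minimisation of |gap|
  raw2 <- stats::setNames(as.numeric(table1), names(table1))
  raw2["alpha2"] <- 2.0; raw2["delta1"] <- 0.2
  p2 <- validate_params(raw2, "estrogen_free")
  I2 <- function(Tm) 0.4 / (0.29 - 0.2 * Tm / (0.3 + Tm) + 0.1 * Tm)
  gap2 <- function(Tm) Tm - (2.0 - 0.9 * I2(Tm)) / 0.4
  grid2 <- seq(1e-6, 5, by = 1e-6)
  Tbrute <- grid2[which.min(abs(gap2(grid2)))]
  cx2 <- coexisting_equilibrium(p2)
  expect_true(cx2$feasible)
  expect_equal(cx2$state[["T"]], Tbrute, tolerance = 1e-5)
  expect_lt(cx2$residual, 1e-10)
  # host coordinate from the first balance equation
  expect_equal(cx2$state[["H"]],
               (0.7 - 0.2 * cx2$state[["T"]]) / 0.3, tolerance = 1e-10)
})

test_that("coexistence requires tumor net growth to beat host net growth", {
  # alpha2/beta2 < alpha1/delta1 makes the positivity condition fail
  raw <- stats::setNames(as.numeric(table1), names(table1))
  raw["alpha2"] <- 0.2       # alpha2/beta2 = 0.5 < alpha1/delta1 = 0.7
  p <- validate_params(raw, "estrogen_free")
  cx <- coexisting_equilibrium(p)
  expect_false(condition_flag(cx, "net_tumor_growth_ge_host"))
})

test_that("every feasible equilibrium zeroes the vector field", {
  set.seed(14)
  for (model in c("estrogen_free", "estrogen")) {
    for (k in 1:40) {
      p <- sample_parameter_set(model = model)
      for (eq in all_equilibria(p, model)) {
        if (isTRUE(eq$feasible)) expect_lt(eq$residual, 1e-10)
      }
    }
  }
})

test_that("with pi = 0 the estrogen model's equilibria coincide with the
           core model's at the boosted tumor growth rate", {
  p0 <- raw_estrogen_params(pi_src = 0)
  alpha3 <- p0[["alpha3"]]
  raw <- stats::setNames(as.numeric(table1), names(table1))
  raw["alpha2"] <- alpha3
  pef <- validate_params(raw, "estrogen_free")
  eqs_es <- all_equilibria(p0, "estrogen")
  eqs_ef <- all_equilibria(pef, "estrogen_free")
  for (lab in c("tumor_free", "dead2")) {
    a <- Filter(function(e) e$label == lab, eqs_es)[[1]]
    b <- Filter(function(e) e$label == lab, eqs_ef)[[1]]
    expect_equal(unname(a$state[c("H", "T", "I")]), unname(b$state),
                 tolerance = 1e-10)
    expect_equal(a$state[["E"]], 0)
  }
})

test_that("all_equilibria composes the pieces in fixed order", {
  eqs <- all_equilibria(table1)
  labs <- vapply(eqs, function(e) e$label, character(1))
  expect_identical(labs[1:2], c("tumor_free", "dead2"))
  expect_true(all(c("dead1", "coexisting") %in% labs))
  feas <- vapply(eqs, function(e) e$feasible, logical(1))
  expect_identical(labs[feas], c("tumor_free", "dead2"))
  expect_error(all_equilibria(c(table1[-1], mu = -1), "estrogen_free"))
})
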