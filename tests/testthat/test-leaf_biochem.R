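test_that("C3 rates match a direct hand evaluation and their limits", {
  b <- leaf_biochem(Vcmax = 50, J = 100, Rl = 0.5, kinetics = kin_ci)
  # hand evaluation of the two formulas at Cx = 300
  Km <- 404.9 * (1 + 210 / 278.4)
  Ac_hand <- 50 * (300 - 42.75) / (300 + Km) - 0.5
  Aj_hand <- 100 * (300 - 42.75) / (4 * 300 + 8 * 42.75) - 0.5
  r <- c3_rates(300, b)
  expect_equal(r$Ac, Ac_hand, tolerance = 1e-12)
  expect_equal(r$Aj, Aj_hand, tolerance = 1e-12)
  expect_equal(r$An, min(Ac_hand, Aj_hand), tolerance = 1e-12)

  # compensation point: zero gross assimilation
  expect_equal(c3_rates(kin_ci$GammaStar25, b)$An, -0.5, tolerance = 1e-12)
  # Michaelis-Menten limit at large Cx with saturating J
  b_sat <- leaf_biochem(Vcmax = 50, J = Inf, Rl = 0.5, kinetics = kin_ci)
  expect_equal(c3_rates(1e7, b_sat)$An, 50 - 0.5, tolerance = 1e-3)
})

test_that("electron transport follows the non-rectangular hyperbola", {
  expect_identical(electron_transport(0, 100), 0)
  expect_equal(electron_transport(1e5, 100), 100, tolerance = 0.01)
  # Blackman limit: theta -> 1 and alpha*Qa < Jmax gives J = alpha*Qa
  expect_equal(electron_transport(100, 1000, alpha = 0.3, theta_curv = 1),
               30, tolerance = 1e-9)
  expect_error(electron_transport(100, 100, theta_curv = 0), "theta_curv")
  expect_error(electron_transport(100, 100, theta_curv = 1.5), "theta_curv")
})

test_that("C4 rates have the PEP half-saturation and saturation limits", {
  b <- leaf_biochem(Vcmax = 40, J = Inf, Vpmax = 60, Rl = 0,
                    kinetics = kin_cc, Kp = 80)
  expect_equal(c4_rates(80, b)$Ap, 30, tolerance = 1e-12)  # Cm = Kp
  expect_equal(c4_rates(55, leaf_biochem(Vcmax = 400, J = Inf, Vpmax = 60,
                                         Rl = 0, kinetics = kin_cc,
                                         Kp = 80))$Ap,
               55 * 60 / 135, tolerance = 1e-12)
  expect_equal(round(55 * 60 / 135, 2), 24.44)
  # saturation: An independent of Vpmax at large Cm
  r_hi <- c4_rates(1e6, b)
  expect_equal(r_hi$An, 40, tolerance = 1e-3)
  expect_identical(r_hi$limitation, "rubisco")
})

test_that("finite-gm solution reduces to the direct rates at gm = Inf", {
  b <- leaf_biochem(Vcmax = 60, J = 120, Rl = 0.6, kinetics = kin_cc)
  for (ci in c(100, 300, 800)) {
    direct <- c3_rates(ci, b)
    s <- solve_an_at_ci(ci, Inf, b, "C3")
    expect_equal(s$An, direct$An, tolerance = 1e-12)
    expect_equal(s$Cx, ci)
  }
  # any finite gm draws down Cx and An when An > 0
  s_fin <- solve_an_at_ci(300, 0.15, b, "C3")
  expect_lt(s_fin$An, c3_rates(300, b)$An)
  expect_lt(s_fin$Cx, 300)
  expect_gt(s_fin$Cx, 0)
  # Fick consistency
  expect_equal(s_fin$An, 0.15 * (300 - s_fin$Cx), tolerance = 1e-9)
})

test_that("quadratic solution agrees with the fixed-point oracle", {
  set.seed(7)
  for (i in 1:200) {
    vc <- runif(1, 20, 120)
    b <- leaf_biochem(Vcmax = vc, J = runif(1, 1, 2.5) * vc,
                      Rl = runif(1, 0, 2), kinetics = kin_cc)
    ci <- runif(1, 60, 1200)
    gm <- runif(1, 0.05, 1)
    s <- solve_an_at_ci(ci, gm, b, "C3")
    expect_equal(s$An, fixed_point_an(ci, gm, b, "C3"), tolerance = 1e-3)
  }
})

test_that("An is continuous in Ci across the limitation switch", {
  b <- leaf_biochem(Vcmax = 50, J = 100, Rl = 0.5, kinetics = kin_cc)
  ci <- seq(50, 1200, by = 1)
  an <- vapply(ci, function(x) solve_an_at_ci(x, 0.2, b, "C3")$An, numeric(1))
  expect_true(all(diff(an) >= -1e-9))        # non-decreasing demand curve
  expect_lt(max(abs(diff(an))), 0.5)         # no jump at the inflection
})

test_that("the inflection Ci decreases with the Jmax/Vcmax ratio", {
  set.seed(11)
  inflection_ci <- function(ratio, vc = 60) {
    b <- leaf_biochem(Vcmax = vc, J = ratio * vc, Rl = 0.5, kinetics = kin_cc)
    ci <- seq(50, 1500, by = 2)
    lim <- vapply(ci, function(x) solve_an_at_ci(x, 0.3, b, "C3")$limitation,
                  character(1))
    if (all(lim == "rubp")) return(min(ci))
    ci[max(which(lim == "rubisco"))]
  }
  for (i in 1:20) {
    r1 <- runif(1, 1.2, 1.6)
    r2 <- r1 + runif(1, 0.2, 0.6)
    expect_lte(inflection_ci(r1), inflection_ci(r2))
  }
})
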