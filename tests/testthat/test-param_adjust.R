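test_that("the simulated demand curve matches direct rate evaluation", {
  curve <- simulate_anci(40, 76, Rl = 0.44, grid = seq(45, 1500, by = 5))
  b <- leaf_biochem(Vcmax = 40, J = 76, Rl = 0.44, kinetics = kin_ci)
  i300 <- which(curve$ci == 300)
  expect_equal(curve$an[i300], c3_rates(300, b)$An, tolerance = 1e-12)
  # -Rl at the compensation point
  curve_g <- simulate_anci(40, 76, 0.44, grid = c(kin_ci$GammaStar25, 300, 600))
  expect_equal(curve_g$an[1], -0.44, tolerance = 1e-12)
  # concave, saturating shape
  an <- function(ci) curve$an[which(curve$ci == ci)]
  expect_lt(an(1500) - an(1400), an(400) - an(300))
  expect_true(all(diff(curve$an) > -1e-12))
  expect_error(simulate_anci(40, 76, 0.44, grid = seq(100, 2500, 100)), "grid")
  expect_error(simulate_anci(40, 76, 0.44, kinetics = kin_cc), "Ci-based")
})

test_that("Fick conversion produces the expected Cc and gm pattern", {
  curve <- structure(data.frame(ci = c(260, 300), an = c(9, 10),
                                cx = c(260, 300),
                                limitation = "rubisco"),
                     class = c("an_ci_curve", "data.frame"))
  cc <- to_cc_curve(curve, gm_max25 = 0.1)
  expect_equal(cc$cx[2], 300 - 10 / 0.1)
  # infinite gm leaves the curve unchanged
  cc_inf <- to_cc_curve(curve, gm_max25 = Inf)
  expect_identical(cc_inf$cx, curve$ci)
  # Ci response: gm varies non-monotonically with max near Ci = 100
  full <- simulate_anci(40, 76, 0.44)
  ccr <- to_cc_curve(full, 0.1, use_ci_response = TRUE)
  expect_equal(ccr$ci[which.max(ccr$gm)], 100, tolerance = 10)
  expect_lt(ccr$gm[nrow(ccr)], max(ccr$gm))
  # too small a gm drives Cc negative
  expect_error(to_cc_curve(full, 0.005), "negative Cc")
})

test_that("refitting with non-limiting gm recovers the generating parameters", {
  # within one kinetics set the conversion + refit is the identity at gm -> Inf
  b <- leaf_biochem(Vcmax = 40, J = 76, Rl = 0.44, kinetics = kin_cc)
  grid <- seq(45, 1500, by = 5)
  curve <- structure(data.frame(ci = grid, an = c3_rates(grid, b)$An,
                                cx = grid, limitation = "x"),
                     class = c("an_ci_curve", "data.frame"))
  fit <- fit_cc_params(to_cc_curve(curve, 1e4), kin_cc,
                       init = c(Vcmax25 = 40, Jmax25 = 76), Rl = 0.44)
  expect_equal(fit$Vcmax25_cc / 40, 1, tolerance = 1e-3)
  expect_equal(fit$Jmax25_cc / 76, 1, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-3)
})

test_that("adjusted capacities exceed apparent ones, Vcmax more than Jmax", {
  c3 <- Filter(function(p) p$pathway == "C3", registry)
  tab <- adjust_pft_table(c3)
  expect_true(all(tab$Vcmax25_Cc >= tab$Vcmax25_Ci))
  rel_v <- (tab$Vcmax25_Cc - tab$Vcmax25_Ci) / tab$Vcmax25_Ci
  rel_j <- (tab$Jmax25_Cc - tab$Jmax25_Ci) / tab$Jmax25_Ci
  expect_true(all(rel_v > rel_j))
  # ratio falls relative to the apparent ratio when gm has no Ci response
  expect_true(all(tab$ratio_Cc <= tab$Jmax25_Ci / tab$Vcmax25_Ci))
})

test_that("the Ci response of gm inflates Jmax in the refit (ExpC vs Exp)", {
  exp_fit <- adjust_c3(52.7, 100.1, 0.078, Rl = 0.011 * 52.7)
  expc_fit <- adjust_c3(52.7, 100.1, 0.074, Rl = 0.011 * 52.7,
                        use_ci_response = TRUE)
  expect_gt(expc_fit$Jmax25_cc, exp_fit$Jmax25_cc)
})

test_that("fit quality degrades as gm decreases", {
  rmse <- vapply(c(0.3, 0.15, 0.1, 0.06),
                 function(g) adjust_c3(52.7, 100.1, g, Rl = 0.5)$rmse,
                 numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("the refit shifts the limitation switch to lower Ci", {
  inflection <- function(Vc, J, Rl, gm, kin) {
    b <- leaf_biochem(Vcmax = Vc, J = J, Rl = Rl, kinetics = kin)
    ci <- seq(50, 1500, by = 2)
    lim <- vapply(ci, function(x) solve_an_at_ci(x, gm, b, "C3")$limitation,
                  character(1))
    ci[max(which(lim == "rubisco"))]
  }
  a <- adjust_c3(52.7, 100.1, 0.078, Rl = 0.011 * 52.7)
  ci_imp <- inflection(52.7, 100.1, 0.011 * 52.7, Inf, kin_ci)
  ci_exp <- inflection(a$Vcmax25_cc, a$Jmax25_cc, 0.011 * 52.7, 0.078, kin_cc)
  expect_lt(ci_exp, ci_imp)
})

test_that("C4 refit is the identity at non-limiting gm and decreases with gm", {
  a_inf <- adjust_c4(60, gm_max25 = 1e6)
  expect_equal(a_inf$Vpmax25_cm, 60, tolerance = 1e-3)
  sweep <- vapply(c(0.739, 1.5, 3, 10), function(g)
    adjust_c4(60, g)$Vpmax25_cm, numeric(1))
  expect_true(all(diff(sweep) < 0))
  expect_error(adjust_c4(60, gm_max25 = 0.3), "negative Cm")
})

test_that("adjust_pft rewrites capacities, basis and respiration fraction", {
  p <- adjust_pft(registry[["ENF"]], "Exp")
  expect_identical(p$basis, "Cc")
  expect_gt(p$Vcmax25, registry[["ENF"]]$Vcmax25)
  # absolute Rl is preserved
  expect_equal(p$Rl_frac * p$Vcmax25,
               registry[["ENF"]]$Rl_frac * registry[["ENF"]]$Vcmax25,
               tolerance = 1e-9)
  # idempotent on already-adjusted parameters
  expect_identical(adjust_pft(p, "Exp"), p)
  p4 <- adjust_pft(registry[["C4C"]], "Exp")
  expect_gt(p4$Vpmax25, 60)
})
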