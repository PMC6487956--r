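test_that("Medlyn stomatal conductance has its closed-form properties", {
  expect_identical(medlyn_gs(0, 400, 1), 0.005)
  expect_identical(medlyn_gs(-2, 400, 1), 0.005)
  expect_equal(medlyn_gs(10, 400, 1, g0 = 0, g1 = 4), 0.2, tolerance = 1e-12)
  # doubling Ca at fixed An halves gs - g0
  g1v <- medlyn_gs(10, 400, 1) - 0.005
  g2v <- medlyn_gs(10, 800, 1) - 0.005
  expect_equal(g2v, g1v / 2, tolerance = 1e-12)
})

test_that("converged leaf state satisfies both Fick's-law identities", {
  pft <- adjust_pft(registry[["DBF"]], "Exp")
  for (v in c("Exp", "ExpC", "ExpL", "ExpCL")) {
    env <- env_state(Tl = 22, Qa = 1200, Ca = 410, D = 1.2, theta = 0.25)
    s <- solve_leaf(env, pft, v)
    expect_equal(s$An, s$gm * (s$Ci - s$Cx), tolerance = 1e-4)
    expect_equal(s$An, s$gs / 1.6 * (env$Ca - s$Ci), tolerance = 1e-3)
    expect_true(s$Cx >= 0 && s$Cx <= s$Ci && s$Ci <= env$Ca)
  }
  # implicit version: site CO2 equals Ci
  s_imp <- solve_leaf(env_state(), registry[["DBF"]], "Imp")
  expect_identical(s_imp$Cx, s_imp$Ci)
})

test_that("darkness returns the residual-conductance respiration state", {
  s <- solve_leaf(env_state(Qa = 0), registry[["ENF"]], "Imp")
  expect_identical(s$gs, 0.005)
  expect_lt(s$An, 0)
  expect_identical(s$iterations, 0L)
})

test_that("a non-limiting gm reproduces the implicit model", {
  pft_ci <- registry[["ENF"]]
  # adjust with gm = 1e4: capacities barely change, model runs on Cc kinetics
  pft_adj <- adjust_pft(pft_ci, "Exp", gm_max25 = 1e4)
  for (Tl in c(15, 25)) {
    env <- env_state(Tl = Tl, Qa = 1500, Ca = 400, D = 1)
    a_imp <- solve_leaf(env, pft_ci, "Imp")$An
    a_exp <- solve_leaf(env, pft_adj, "Exp", gm_override = 1e4)$An
    expect_equal(a_exp, a_imp, tolerance = 0.01)
  }
})

test_that("Ci/Ca is conserved across Ca when g0 = 0", {
  pft <- adjust_pft(registry[["C3G"]], "Exp")
  pft$g0 <- 0
  s4 <- solve_leaf(env_state(Ca = 400), pft, "Exp")
  s6 <- solve_leaf(env_state(Ca = 600), pft, "Exp")
  expect_equal(s4$Ci / 400, s6$Ci / 600, tolerance = 0.005)
  expect_gte(s6$An, s4$An)   # monotone CO2 fertilization
})

test_that("the iWUE response to eCO2 is version-invariant at g0 = 0", {
  set.seed(3)
  base <- registry[["DBF"]]
  base$g0 <- 0
  for (i in 1:5) {
    env_a <- env_state(Tl = runif(1, 12, 30), Qa = runif(1, 600, 1800),
                       Ca = 400, D = runif(1, 0.6, 2.5), theta = 0.3)
    env_e <- env_a; env_e$Ca <- 600
    resp <- vapply(c("Imp", "Exp", "ExpC", "ExpL", "ExpCL"), function(v) {
      p <- if (v == "Imp") base else adjust_pft(base, v)
      sa <- solve_leaf(env_a, p, v)
      se <- solve_leaf(env_e, p, v)
      co2_response(sa$An / sa$gs, se$An / se$gs)
    }, numeric(1))
    expect_lt(max(resp) - min(resp), 1)
  }
})

test_that("C4 leaves show no An response but strong gs closure under eCO2", {
  pft <- adjust_pft(registry[["C4C"]], "Exp")
  env_a <- env_state(Tl = 25, Qa = 1500, Ca = 400, D = 1.5)
  env_e <- env_a; env_e$Ca <- 600
  sa <- solve_leaf(env_a, pft, "Exp")
  se <- solve_leaf(env_e, pft, "Exp")
  expect_lt(abs(co2_response(sa$An, se$An)), 2)
  expect_lt(co2_response(sa$gs, se$gs), -10)
})

test_that("relative CO2 response follows the defining formula", {
  expect_identical(co2_response(5, 5), 0)
  expect_identical(co2_response(5, 10), 100)
  expect_equal(co2_response(23.1, 26.4), 14.29, tolerance = 1e-3)
  expect_error(co2_response(0, 1), "zero ambient")
})

test_that("the paired-window Ci sensitivity metric behaves on known curves", {
  flat <- data.frame(ci = seq(100, 600, 10), an = 8)
  expect_equal(delta_an_ci_ranges(flat), 0)
  lin <- data.frame(ci = seq(100, 600, 10), an = seq(100, 600, 10) / 10)
  expect_equal(delta_an_ci_ranges(lin), 50, tolerance = 1e-9)
  short <- data.frame(ci = seq(250, 400, 10), an = 8)
  expect_error(delta_an_ci_ranges(short), "range")
})

test_that("explicit-vs-implicit Ci-sensitivity contrast changes sign with temperature", {
  # An-Ci curves from leaf simulations at fixed Ci, saturating light
  curve_at <- function(Tl, version, pft) {
    kin <- resolve_kinetics(version)$kinetics
    gmt <- resolve_kinetics("Exp")$gm_temp
    ci <- seq(100, 700, by = 10)
    gm <- if (version == "Imp") Inf else
      pft$gm_max25 * f_temperature(Tl + 273.15, gmt)
    b <- leaf_biochem(Vcmax = pft$Vcmax25, J = pft$Jmax25,
                      Rl = pft$Rl_frac * pft$Vcmax25, kinetics = kin)
    an <- vapply(ci, function(x) solve_an_at_ci(x, gm, b, "C3")$An, numeric(1))
    data.frame(ci = ci, an = an)
  }
  base <- pft_params("DBF", "C3", gm_max25 = 0.1, Vcmax25 = 40, Jmax25 = 76,
                     Rl_frac = 0.44 / 40)
  adj <- adjust_pft(base, "Exp")
  contrast <- function(Tl) {
    delta_an_ci_ranges(curve_at(Tl, "Exp", adj)) -
      delta_an_ci_ranges(curve_at(Tl, "Imp", base))
  }
  expect_gt(contrast(15), 0)   # explicit more CO2-sensitive when cool
  expect_lt(contrast(35), 0)   # and less when hot
})
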