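# shared fixtures
registry <- load_pft_registry()
kin_ci <- resolve_kinetics("Imp")$kinetics
kin_cc <- resolve_kinetics("Exp")$kinetics

# independent supply/demand oracle: damped fixed-point iteration on the
# carboxylation-site CO2 (never touches the quadratic path)
fixed_point_an <- function(Ci, gm, b, pathway = "C3",
                           tol = 1e-8, max_iter = 5000) {
  rate <- function(Cx) {
    r <- if (pathway == "C3") c3_rates(Cx, b) else c4_rates(Cx, b)
    r$An
  }
  Cx <- Ci
  for (i in seq_len(max_iter)) {
    Cx_new <- Ci - rate(Cx) / gm
    Cx_new <- max(0, Cx_new)
    if (abs(Cx_new - Cx) < tol) break
    Cx <- Cx + 0.2 * (Cx_new - Cx)
  }
  rate(Cx)
}
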