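test_that("the linearized pipeline recovers planted two-state parameters from a clean curve", {
  # Tm = 337.35 K = 64.2 C, dHm = 120 kcal/mol
  curve <- synth_melting_curve(Tm_C = 64.2, dHm = 120)
  out <- linearized_stability(curve)
  expect_equal(out$fit$Tm_K, 337.35, tolerance = 0.1 / 337.35)
  expect_equal(out$fit$dHm_kcal_mol, 120, tolerance = 0.02)
  expect_equal(out$fit$dSm_kcal_mol_K,
               out$fit$dHm_kcal_mol / out$fit$Tm_K, tolerance = 1e-12)
})

test_that("the stability profile obeys the two-state relations exactly", {
  curve <- synth_melting_curve(Tm_C = 60, dHm = 100)
  prof <- linearized_stability(curve)$profile
  expect_equal(prof$fU + prof$fF, rep(1, nrow(prof)))
  masked <- prof[prof$in_mask, ]
  expect_equal(masked$K, masked$fU / (1 - masked$fU), tolerance = 1e-12)
  expect_equal(masked$dG_kcal_mol,
               -1.987e-3 * masked$temp_K * log(masked$K), tolerance = 1e-12)
  expect_true(all(masked$fU >= 0.15 & masked$fU <= 0.85))

  # at the temperature where the signal is midway between baselines,
  # fU = 0.5, K = 1, dG = 0 (interpolated on the clean curve)
  mid_T <- approx(masked$fU, masked$temp_C, xout = 0.5)$y
  mid_dG <- approx(masked$temp_C, masked$dG_kcal_mol, xout = mid_T)$y
  expect_lt(abs(mid_dG), 1e-4)
})

test_that("free energy follows -RT ln K with R = 1.987e-3 kcal/(mol K)", {
  # hand value: fU = 0.75 at 298.15 K -> K = 3, dG = -(1.987e-3)(298.15) ln 3
  K <- 0.75 / (1 - 0.75)
  expect_equal(K, 3)
  dG <- -1.987e-3 * 298.15 * log(K)
  expect_equal(dG, -0.6509, tolerance = 1e-4)
})

test_that("Gibbs-Helmholtz extrapolation matches hand arithmetic", {
  fit <- list(Tm_K = 337.35, dHm_kcal_mol = 100)
  expect_equal(gibbs_helmholtz(fit, 337.35), 0)
  expect_equal(gibbs_helmholtz(fit, 337.35, dCp = 2.5), 0)
  expect_equal(gibbs_helmholtz(fit, 298.15), 100 * (1 - 298.15 / 337.35),
               tolerance = 1e-12)
  expect_equal(gibbs_helmholtz(fit, 298.15), 11.62, tolerance = 1e-3)
  # a positive dCp lowers dG below the dCp = 0 line for all T < Tm
  for (TK in c(280, 298.15, 320, 335)) {
    expect_lt(gibbs_helmholtz(fit, TK, dCp = 1), gibbs_helmholtz(fit, TK))
  }
})

test_that("dG vanishes at the fitted Tm for both fitting routes", {
  curve <- synth_melting_curve(Tm_C = 58.3, dHm = 95)
  lin <- linearized_stability(curve)$fit
  nls_ <- fit_two_state(curve)
  expect_equal(gibbs_helmholtz(lin, lin$Tm_K), 0, tolerance = 1e-9)
  expect_equal(gibbs_helmholtz(nls_, nls_$Tm_K), 0, tolerance = 1e-9)
})

test_that("the direct nonlinear fit round-trips generator parameters", {
  bl <- list(aF = -22, bF = 0.03, aU = -5, bU = 0.06)
  curve <- synth_melting_curve(Tm_C = 55.4, dHm = 110, baselines = bl)
  fit <- fit_two_state(curve)
  expect_equal(fit$Tm_C, 55.4, tolerance = 1e-3)
  expect_equal(fit$dHm_kcal_mol, 110, tolerance = 110 * 1e-3)
  expect_equal(fit$baselines$aF, bl$aF, tolerance = abs(bl$aF) * 1e-3)

  lin <- linearized_stability(curve)$fit
  expect_lt(abs(fit$Tm_C - lin$Tm_C), 0.2)
})

test_that("curves without a transition are rejected", {
  flat <- melting_curve(seq(25, 90, 0.5), rep(-10, 131))
  expect_error(fit_two_state(flat), "initialize|degenerate|transition")
  sloped <- melting_curve(seq(25, 90, 0.5), -10 + 0.02 * seq(25, 90, 0.5))
  expect_error(linearized_stability(sloped), "degenerate|transition")
})

test_that("noisy replicate fits recover the planted Tm without bias", {
  fitted <- vapply(1:100, function(sd) {
    curve <- synth_melting_curve(Tm_C = 64.2, dHm = 120, noise_sd = 0.02,
                                 seed = sd)
    linearized_stability(curve)$fit$Tm_C
  }, numeric(1))
  expect_lt(abs(mean(fitted) - 64.2), 0.3)
  expect_lt(sd(fitted), 0.5)
})

test_that("shifting the planted Tm shifts the fitted Tm by the same amount", {
  base <- linearized_stability(synth_melting_curve(Tm_C = 55))$fit$Tm_C
  for (delta in c(2, 5, 8)) {
    shifted <- linearized_stability(synth_melting_curve(Tm_C = 55 + delta))$fit$Tm_C
    expect_equal(shifted - base, delta, tolerance = 0.05)
  }
})

test_that("chemical midpoints are recovered from linear-extrapolation curves", {
  fit <- chem_midpoint(synth_chem_curve(Cm_M = 2.2, m = 3))
  expect_equal(fit$Cm_M, 2.2, tolerance = 0.02 / 2.2)
  expect_equal(fit$m_kcal_mol_M, 3, tolerance = 0.01)

  fit2 <- chem_midpoint(synth_chem_curve(Cm_M = 1.75, m = 3))
  expect_equal(fit2$Cm_M, 1.75, tolerance = 0.02 / 1.75)

  # with flat baselines the fitted midpoint is where the signal crosses midway
  flatbl <- list(aF = 1, bF = 0, aU = 0.2, bU = 0)
  cur <- synth_chem_curve(Cm_M = 1.4, m = 4, baselines = flatbl)
  mid_c <- approx(cur$signal, cur$conc_M, xout = 0.6)$y
  fit3 <- chem_midpoint(cur)
  expect_equal(fit3$Cm_M, mid_c, tolerance = 1e-3)

  expect_error(chem_midpoint(data.frame(conc_M = seq(0, 3, 0.1),
                                        signal = rep(1, 31))),
               "transition")
})

test_that("variant comparisons report dTm and ddG bookkeeping", {
  wt <- linearized_stability(synth_melting_curve(Tm_C = 64.2))$fit
  expect_equal(compare_variants(wt, wt),
               list(dTm_C = 0, ddG_kcal_mol = 0, temp_C = 25))

  m4b <- linearized_stability(synth_melting_curve(Tm_C = 49.9))$fit
  cmp <- compare_variants(wt, m4b)
  expect_equal(cmp$dTm_C, -14.3, tolerance = 0.01)
  expect_lt(cmp$ddG_kcal_mol, 0)

  # printed extrapolated stabilities: 11.8 vs 4.9 kcal/mol at 25 C
  expect_equal(compare_variants(11.8, 4.9)$ddG_kcal_mol, -6.9)

  wt10 <- linearized_stability(synth_melting_curve(Tm_C = 55.1, ph = 10))$fit
  expect_warning(compare_variants(wt, wt10), "pH")
})
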