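test_that("cumulative receiver amount adds back withdrawn aliquots", {
  zero <- cumulative_receiver_amount(
    data.frame(time_min = 15, conc_uM = 0, sampled_volume_ml = 0.1), 1)
  expect_equal(zero, 0)
  two <- cumulative_receiver_amount(
    data.frame(time_min = c(15, 30), conc_uM = c(1.0, 1.5),
               sampled_volume_ml = c(0.1, 0.1)), 1)
  expect_equal(two, c(1.0, 1.5 * 1 + 1.0 * 0.1))
  expect_error(cumulative_receiver_amount(
    data.frame(time_min = 15, conc_uM = -1, sampled_volume_ml = 0.1), 1),
    "negative concentration")
  expect_error(cumulative_receiver_amount(
    data.frame(time_min = 15, conc_uM = 1, sampled_volume_ml = 1.5), 1),
    "sampled volume")
})

test_that("cumulative amount matches the oracle's true transferred mass", {
  pair <- make_pair(5.4, cv = 0)
  for (dir in c("a2b", "b2a")) {
    exp <- pair[[dir]]
    cum <- cumulative_receiver_amount(exp$receiver_samples,
                                      exp$receiver_volume)
    expect_equal(cum, pair$exact[[dir]]$cum_true, tolerance = 1e-6)
  }
})

test_that("donor AUC is trapezoidal and guards the single-sample case", {
  expect_equal(donor_auc(data.frame(time_min = c(0, 60), conc_uM = c(2, 2),
                                    sampled_volume_ml = 0)), 120)
  expect_equal(donor_auc(data.frame(time_min = c(0, 60), conc_uM = c(2, 1.6),
                                    sampled_volume_ml = 0)), 108)
  one <- data.frame(time_min = 0, conc_uM = 2, sampled_volume_ml = 0)
  expect_error(donor_auc(one, t_end = 60), "constant-donor")
  expect_equal(donor_auc(one, t_end = 60, allow_constant_donor = TRUE), 120)
})

test_that("trapezoid donor AUC tracks the exact integral for a depleting donor", {
  # appreciable depletion, donor sampled at the four receiver times too
  tr <- transwell_truth(papp_a2b_true = 4e-6, papp_b2a_true = 8e-6,
                        cv_assay = 0)
  ex <- fetalkp:::.simulate_direction(tr, "B2A")
  expect_lt(ex$donor_true[2] / ex$donor_true[1], 0.97) # really depleting
  auc2 <- donor_auc(data.frame(time_min = c(0, 60), conc_uM = ex$donor_true,
                               sampled_volume_ml = 0.01))
  expect_equal(auc2, ex$donor_auc_exact, tolerance = 0.02)
})

test_that("apparent permeability arithmetic and homogeneity", {
  expect_equal(apparent_permeability(1.2, 120, 1.12), 1.2 / (120 * 60 * 1.12))
  p1 <- apparent_permeability(1.2, 120, 1.12)
  expect_equal(apparent_permeability(1.2, 240, 1.12), p1 / 2)
  # invariant to uniform rescaling of all concentrations (ratio estimator)
  expect_equal(apparent_permeability(10 * 1.2, 10 * 120, 1.12), p1)
  expect_error(apparent_permeability(1.2, 0, 1.12), "> 0")
})

test_that("programmed passive Papp is recovered from simulated data", {
  # passive (inhibited) pair at the darunavir permeability, 7-45 min schedule
  tr <- transwell_truth(papp_a2b_true = 1.19e-5, papp_b2a_true = 1.19e-5,
                        receiver_times = c(7, 15, 30, 45), cv_assay = 0)
  pair <- simulate_transwell_pair(tr)
  est <- papp_from_experiment(pair$a2b)
  expect_equal(est$papp, 1.19e-5, tolerance = 0.05)
})

test_that("efflux ratio recovers programmed ratios and checks pairing", {
  sym <- make_pair(1, cv = 0)
  expect_equal(efflux_ratio(sym$a2b, sym$b2a)$er, 1, tolerance = 0.02)
  qnd <- make_pair(11.1, cv = 0)
  expect_equal(efflux_ratio(qnd$a2b, qnd$b2a)$er, 11.1, tolerance = 0.1)
  expect_error(efflux_ratio(qnd$b2a, qnd$a2b), "direction mismatch")
  other <- make_pair(2, cv = 0)
  other$b2a$drug <- "OTHER"
  expect_error(efflux_ratio(other$a2b, other$b2a), "drug mismatch")
})

test_that("sampled-volume correction strictly reduces estimator bias", {
  pair <- make_pair(5.4, cv = 0)
  true_a2b <- pair$exact$papp_a2b_true
  corr <- papp_from_experiment(pair$a2b, correct_sampling = TRUE)$papp
  raw <- papp_from_experiment(pair$a2b, correct_sampling = FALSE)$papp
  expect_lt(raw, corr) # omitting the correction biases downward
  expect_lt(abs(corr - true_a2b), abs(raw - true_a2b))
})

test_that("donor-AUC denominator beats the C0 denominator for a depleting donor", {
  # strong depletion in the B->A direction: the AUC denominator corrects for
  # it, the time-zero-concentration denominator does not
  est <- function(exp, denom) {
    cum <- cumulative_receiver_amount(exp$receiver_samples,
                                      exp$receiver_volume)
    t_end <- max(exp$receiver_samples$time_min)
    auc <- if (denom == "auc") donor_auc(exp$donor_samples, t_end)
    else exp$donor_samples$conc_uM[1] * t_end
    apparent_permeability(cum[length(cum)], auc, exp$insert_area)
  }
  for (draw in c(0.1, 0.45)) {
    pair <- make_pair(5.4, papp_a2b = 3.7e-6, cv = 0,
                      receiver_draw_ml = draw)
    true_b2a <- pair$exact$papp_b2a_true
    expect_lt(pair$b2a$donor_samples$conc_uM[2] /
                pair$b2a$donor_samples$conc_uM[1], 0.95) # donor depletes
    expect_lt(abs(est(pair$b2a, "auc") - true_b2a),
              abs(est(pair$b2a, "c0") - true_b2a))
  }
})

test_that("inhibitor-sensitive efflux ratio is a plain difference", {
  expect_equal(pgp_mediated_er(5.42, 0.85)$er_pgp, 4.57)
  expect_equal(pgp_mediated_er(95.37, 1.02)$er_pgp, 94.35)
  expect_equal(pgp_mediated_er(1, 1)$er_pgp, 0)
  expect_true(pgp_mediated_er(0.8, 1.0)$negative)
})

test_that("QC gate flags leaky monolayers and weak transporter activity", {
  expect_true(qc_gate(1e-6, 11.1)$pass)
  g1 <- qc_gate(3e-6, 11.1)
  expect_false(g1$pass)
  expect_identical(g1$reasons, "leaky_monolayer")
  g2 <- qc_gate(1e-6, 6.9)
  expect_false(g2$pass)
  expect_identical(g2$reasons, "weak_transporter_activity")
  expect_true(qc_gate()$pass) # nothing measured, nothing gated
})
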