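test_that("self-consistency: noiseless data return the generating clearance", {
  tr <- drv_with_kpuu(0.16)
  truth <- clinical_truth(tr$params, tr$regimen, n_dyads = 6,
                          cv_residual = 0,
                          cv_pop = c(v_maternal = 0, cl_maternal = 0, ka = 0),
                          seed = 3)
  obs <- simulate_clinical(truth)
  base <- example_params("drv_gw38")
  fit <- fit_clpm(obs, base$params, base$regimen)
  expect_equal(fit$cl_pm_hat, tr$params$cl_pm, tolerance = 0.01)
  expect_equal(fit$aafe_at_fit, 1, tolerance = 0.001)
  expect_equal(fit$kpuu_invivo, 0.16, tolerance = 0.01)
  expect_true(fit$convergence)
})

test_that("passive-only truth lands at the lower bound with no efflux signal", {
  base <- example_params("drv_gw38")
  truth <- clinical_truth(base$params, base$regimen, n_dyads = 6,
                          cv_residual = 0,
                          cv_pop = c(v_maternal = 0, cl_maternal = 0, ka = 0),
                          seed = 5)
  obs <- simulate_clinical(truth)
  fit <- fit_clpm(obs, base$params, base$regimen)
  expect_equal(fit$cl_pm_hat, 0)
  expect_equal(fit$aafe_at_fit, fit$aafe_passive_only)
  expect_equal(fit$kpuu_invivo, 1, tolerance = 0.01)
})

test_that("the AAFE objective is unimodal on the screening grid", {
  tr <- drv_with_kpuu(0.16)
  truth <- clinical_truth(tr$params, tr$regimen, n_dyads = 12,
                          cv_residual = 0.2, seed = 11)
  obs <- simulate_clinical(truth)
  base <- example_params("drv_gw38")
  fit <- fit_clpm(obs, base$params, base$regimen)
  expect_true(fit$unimodal)
  g <- fit$grid$aafe
  i <- which.min(g)
  if (i > 1) expect_true(all(diff(g[1:i]) <= 1e-9))
  if (i < length(g)) expect_true(all(diff(g[i:length(g)]) >= -1e-9))
})

test_that("ratio fitting is invariant to per-dyad scaling of UV and MP", {
  tr <- drv_with_kpuu(0.16)
  truth <- clinical_truth(tr$params, tr$regimen, n_dyads = 8,
                          cv_residual = 0.15, seed = 23)
  obs <- simulate_clinical(truth)
  base <- example_params("drv_gw38")
  fit1 <- fit_clpm(obs, base$params, base$regimen)
  scaled <- obs
  set.seed(99)
  s <- exp(rnorm(nrow(obs), 0, 0.5)) # arbitrary per-dyad maternal scale
  scaled$uv_mg_per_l <- scaled$uv_mg_per_l * s
  scaled$mp_mg_per_l <- scaled$mp_mg_per_l * s
  fit2 <- fit_clpm(scaled, base$params, base$regimen)
  expect_equal(fit2$cl_pm_hat, fit1$cl_pm_hat, tolerance = 1e-6)
  expect_equal(fit2$aafe_at_fit, fit1$aafe_at_fit, tolerance = 1e-9)
})

test_that("hypothesis comparison contrasts efflux against passive-only", {
  tr <- drv_with_kpuu(0.15)
  truth <- clinical_truth(tr$params, tr$regimen, n_dyads = 12,
                          cv_residual = 0.2, seed = 7)
  obs <- simulate_clinical(truth)
  base <- example_params("drv_gw38")
  cmp <- compare_hypotheses(obs, base$params, base$regimen)
  expect_gt(cmp$aafe_ratio, 3)
  expect_false(cmp$low_information)

  # passive truth: no gain from invoking efflux
  truth0 <- clinical_truth(base$params, base$regimen, n_dyads = 8,
                           cv_residual = 0.1, seed = 9)
  cmp0 <- compare_hypotheses(simulate_clinical(truth0), base$params,
                             base$regimen)
  expect_lt(abs(cmp0$aafe_ratio - 1), 0.2)

  # single observation: computed but flagged
  one <- simulate_clinical(truth)[1, ]
  cmp1 <- compare_hypotheses(one, base$params, base$regimen)
  expect_true(cmp1$low_information)
})

test_that("early-only observations raise a low-information warning", {
  tr <- drv_with_kpuu(0.3)
  truth <- clinical_truth(tr$params, tr$regimen, n_dyads = 4,
                          window = c(0.05, 0.9), cv_residual = 0, seed = 2,
                          cv_pop = c(v_maternal = 0, cl_maternal = 0, ka = 0))
  obs <- simulate_clinical(truth)
  base <- example_params("drv_gw38")
  expect_warning(fit_clpm(obs, base$params, base$regimen),
                 "before distribution equilibrium")
})
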