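test_that("passive scaling is surface-area times term, capped by flow", {
  sc <- gestational_scalers(20, 0.39, 0.60, 27.5)
  out <- scale_clpd(121, sc)
  expect_equal(out$intrinsic, 121 * 0.39)
  expect_equal(out$effective, 27.5)
  id <- gestational_scalers(38, 1, 1, 1000)
  expect_equal(scale_clpd(121, id)$effective, 121)
  # exhaustive small grid: effective is always the min of the two branches
  for (cl in c(10, 50, 121)) for (r in c(0.2, 0.39, 1)) for (q in c(5, 27.5, 60)) {
    s <- gestational_scalers(30, r, 1, q)
    expect_equal(scale_clpd(cl, s)$effective, min(cl * r, q))
  }
})

test_that("efflux scaling follows total transporter abundance", {
  sc <- gestational_scalers(20, 0.39, 0.60, 27.5)
  expect_equal(round(scale_clpgp(612, sc)), 367)
  expect_equal(round(scale_clpgp(1029, sc)), 617)
  expect_equal(scale_clpgp(612, gestational_scalers(38, 1, 1, 45)), 612)
})

test_that("GA table interpolation and extrapolation guard", {
  sc <- ga_scalers_at(29)
  expect_equal(sc$surface_area_ratio, mean(c(0.39, 1)))
  expect_equal(sc$q_placenta_maternal, mean(c(27.5, 45)))
  expect_warning(ga_scalers_at(16), "outside the tabulated range")
  bad <- default_ga_table()[, c("gw", "sa_ratio")]
  expect_error(ga_scalers_at(30, bad), "missing column")
})

test_that("term scalers reproduce the term simulation", {
  tr <- drv_with_kpuu(0.3)
  sc <- gestational_scalers(38, 1, 1, tr$params$q_placenta_maternal)
  pj <- project_kpuu_at_ga(tr$params, sc, tr$regimen,
                           v_placenta = tr$params$v_placenta,
                           v_fetal = tr$params$v_fetal)
  expect_equal(pj$kpuu_ga, pj$kpuu_term, tolerance = 1e-9)
  expect_equal(pj$auc_maternal_ratio, 1, tolerance = 1e-9)
})

test_that("uncapped synthetic drug: GA Kp,uu falls when passive falls faster", {
  # permeability-limited drug (no flow cap at either age)
  ex <- example_params("drv_gw38")
  p <- ex$params
  p$cl_int_pd_placenta <- 20
  p$cl_pm <- 20 * (1 / 0.4 - 1) # term kpuu 0.4
  sc <- gestational_scalers(20, 0.4, 0.6, p$q_placenta_maternal,
                            p$q_umbilical)
  pj <- project_kpuu_at_ga(p, sc, ex$regimen, v_placenta = 0.17, v_fetal = 1)
  expect_lt(pj$kpuu_ga, pj$kpuu_term)
  expect_equal(pj$kpuu_ga, kpuu_steady_state(pj$params_ga), tolerance = 0.005)
})

test_that("Kp,uu is monotone nondecreasing in the surface-area ratio", {
  ex <- example_params("drv_gw38")
  p <- ex$params
  p$cl_int_pd_placenta <- 60
  p$cl_pm <- 120
  k <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(r) {
    sc <- gestational_scalers(30, r, 0.6, p$q_placenta_maternal)
    kpuu_steady_state(params_at_ga(p, sc))
  }, numeric(1))
  expect_true(all(diff(k) >= 0))
  expect_true(any(diff(k) > 0))
})

test_that("Kp,uu depends only on the efflux-to-passive clearance ratio when uncapped", {
  ex <- example_params("drv_gw38")
  p <- ex$params
  p$cl_int_pd_placenta <- 10; p$cl_pm <- 25
  k1 <- kpuu_steady_state(p)
  p2 <- p
  p2$cl_int_pd_placenta <- 30; p2$cl_pm <- 75 # joint x3, still uncapped
  expect_equal(kpuu_steady_state(p2), k1, tolerance = 1e-12)
  sim1 <- kpuu_from_simulation(simulate_mf_pbpk(p, ex$regimen))$kpuu
  sim2 <- kpuu_from_simulation(simulate_mf_pbpk(p2, ex$regimen))$kpuu
  expect_equal(sim2, sim1, tolerance = 0.005)
})

test_that("Kp,uu is continuous across the perfusion-cap boundary", {
  ex <- example_params("drv_gw38")
  p <- ex$params
  p$cl_pm <- 100
  q <- p$q_placenta_maternal
  term_cl <- 121
  r_star <- q / term_cl # cap engages exactly here
  k <- function(r) {
    sc <- gestational_scalers(30, r, 1, q)
    kpuu_steady_state(params_at_ga(p, sc))
  }
  expect_equal(k(r_star * 0.999), k(r_star * 1.001), tolerance = 1e-3)
  # and the cap engages exactly when intrinsic exceeds the flow
  expect_equal(scale_clpd(term_cl, gestational_scalers(30, r_star * 1.01, 1,
                                                       q))$effective, q)
  intr <- scale_clpd(term_cl, gestational_scalers(30, r_star * 0.99, 1, q))
  expect_lt(intr$effective, q)
  expect_equal(intr$effective, intr$intrinsic)
})
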