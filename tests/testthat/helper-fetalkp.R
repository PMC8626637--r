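# shared fixture builders (all fixtures are generated in code)

# synthetic bidirectional pair with a programmed permeability ratio.
# absolute permeabilities are kept low enough that the receiver stays in
# sink condition in BOTH directions (the A->B back-flux coefficient is the
# large B->A permeability, so high-ER settings need small absolute Papp).
make_pair <- function(ratio, cv = 0, seed = 1L,
                      papp_a2b = min(1e-7, 5e-6 / ratio),
                      times = c(15, 30, 45, 60), ...) {
  simulate_transwell_pair(transwell_truth(
    papp_a2b_true = papp_a2b, papp_b2a_true = ratio * papp_a2b,
    cv_assay = cv, seed = seed, receiver_times = times, ...))
}

# darunavir-like term parameter set with a chosen true steady-state Kp,uu
drv_with_kpuu <- function(kpuu) {
  ex <- example_params("drv_gw38")
  p <- ex$params
  cl_eff <- effective_pd_clearance(p$cl_int_pd_placenta, p$q_placenta_maternal)
  p$cl_pm <- cl_eff * (1 / kpuu - 1)
  list(params = p, regimen = ex$regimen)
}

# printed reference table used by the verification tests: per-experiment
# REF and Kp,uu values as published (2-decimal)
printed_reference <- function() {
  data.frame(
    drug = rep(c("DEX", "BET", "DRV", "LPV"), each = 4L),
    experiment = rep(1:4, 4L),
    ref = c(0.14, 0.12, 0.08, 0.13,
            0.14, 0.12, 0.08, 0.13,
            0.14, 0.12, 0.08, 0.13,
            0.12, 0.13, 0.13, 0.16),
    kpuu = c(0.61, 0.66, 0.63, 0.61,
             0.56, 0.65, 0.62, 0.53,
             0.15, 0.17, 0.25, 0.16,
             0.08, 0.08, 0.09, 0.08))
}
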