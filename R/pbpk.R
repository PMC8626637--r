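#' Maternal-fetal PBPK parameter set
#'
#' Parameters of the compact maternal-fetal model: a gut depot (first-order
#' absorption `ka` after a lag `tlag`, bioavailability `f_oral` applied at
#' absorption), a lumped maternal central compartment with systemic clearance
#' `cl_maternal * induction_scalar`, a placental tissue compartment and a
#' fetal compartment. Unbound drug exchanges maternal <-> placenta through
#' the passive diffusion clearance capped by the maternal placental blood
#' flow, and placenta <-> fetus through the same intrinsic clearance capped
#' by the umbilical flow. The active efflux clearance `cl_pm` returns drug
#' from placental tissue to maternal plasma (apical efflux); active
#' maternal-to-placenta and fetal-to-placenta transport are fixed at zero.
#' Fetal elimination defaults to zero (negligible fetal hepatic clearance).
#'
#' @param ka First-order absorption rate (1/h).
#' @param tlag Absorption lag (h).
#' @param f_oral Oral bioavailability fraction in (0, 1].
#' @param v_maternal Maternal central volume (l).
#' @param cl_maternal Maternal systemic clearance (l/h), pre-induction.
#' @param induction_scalar Fold-change on `cl_maternal` for pregnancy
#'   (default 1).
#' @param fu_m,fu_f Unbound fractions in maternal and fetal plasma, (0, 1].
#' @param fu_placenta Unbound fraction in placental tissue (default 1:
#'   placental binding is typically unreported).
#' @param q_placenta_maternal Maternal placental blood flow (l/h).
#' @param q_umbilical Umbilical blood flow (l/h).
#' @param cl_int_pd_placenta Intrinsic bidirectional passive diffusion
#'   clearance across the placenta (l/h).
#' @param cl_pm Intrinsic placental-to-maternal active efflux clearance
#'   (l/h), acting on unbound placental concentration.
#' @param v_placenta Placental tissue volume (l).
#' @param v_fetal Fetal distribution volume (l).
#' @param fetal_cl Fetal elimination clearance (l/h), default 0.
#' @param gw Gestational week the parameter set describes.
#' @return Object of class `pbpk_params`.
#' @export
pbpk_params <- function(ka, tlag = 0, f_oral = 1, v_maternal, cl_maternal,
                        induction_scalar = 1, fu_m, fu_f, fu_placenta = 1,
                        q_placenta_maternal, q_umbilical = q_placenta_maternal,
                        cl_int_pd_placenta, cl_pm = 0, v_placenta,
                        v_fetal, fetal_cl = 0, gw = 38) {
  p <- list(ka = ka, tlag = tlag, f_oral = f_oral, v_maternal = v_maternal,
            cl_maternal = cl_maternal, induction_scalar = induction_scalar,
            fu_m = fu_m, fu_f = fu_f, fu_placenta = fu_placenta,
            q_placenta_maternal = q_placenta_maternal,
            q_umbilical = q_umbilical,
            cl_int_pd_placenta = cl_int_pd_placenta, cl_pm = cl_pm,
            v_placenta = v_placenta, v_fetal = v_fetal, fetal_cl = fetal_cl,
            gw = gw)
  nonneg <- c("ka", "tlag", "v_maternal", "cl_maternal", "q_placenta_maternal",
              "q_umbilical", "cl_int_pd_placenta", "cl_pm", "v_placenta",
              "v_fetal", "fetal_cl")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a nonnegative number", nm))
  for (nm in c("f_oral", "fu_m", "fu_f", "fu_placenta"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must be a fraction in (0, 1]", nm))
  if (p$v_maternal <= 0 || p$v_fetal <= 0 || p$v_placenta <= 0)
    stop("volumes must be > 0")
  structure(p, class = "pbpk_params")
}

#' Multiple oral dose regimen
#'
#' @param dose_mg Dose (mg).
#' @param interval_h Dosing interval (h).
#' @param n_doses Number of doses (>= 1).
#' @return Object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_mg, interval_h, n_doses) {
  stopifnot(dose_mg > 0, interval_h > 0, n_doses >= 1)
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = as.integer(n_doses), route = "oral"),
            class = "dose_regimen")
}

#' Effective (flow-capped) placental passive diffusion clearance
#'
#' When the intrinsic passive diffusion clearance exceeds the adjacent blood
#' flow, transfer becomes perfusion-limited and the flow is the operative
#' clearance: `min(cl_int_pd, q_flow)`.
#'
#' @param cl_int_pd Intrinsic passive diffusion clearance (l/h).
#' @param q_flow Adjacent blood flow (l/h).
#' @return Effective clearance (l/h).
#' @export
effective_pd_clearance <- function(cl_int_pd, q_flow) {
  stopifnot(all(cl_int_pd >= 0), all(q_flow >= 0))
  pmin(cl_int_pd, q_flow)
}

#' Scale placental passive clearance from a reference drug
#'
#' Passive diffusion clearance scales with membrane permeability, so the in
#' vivo placental passive clearance of a drug can be anchored to a reference
#' drug with a known in vivo value (midazolam: 500 l/h, Papp 4.9e-5 cm/s):
#' `cl = ref_cl * papp_drug / papp_ref`.
#'
#' @param papp_drug Apparent (passive) permeability of the drug (cm/s).
#' @param ref_cl In vivo placental passive clearance of the reference (l/h).
#' @param papp_ref Apparent permeability of the reference drug (cm/s).
#' @return Intrinsic passive diffusion clearance (l/h).
#' @export
scale_passive_from_reference <- function(papp_drug, ref_cl = 500,
                                         papp_ref = 4.9e-5) {
  stopifnot(papp_ref > 0, ref_cl >= 0, papp_drug >= 0)
  ref_cl * papp_drug / papp_ref
}

# state order used throughout: gut, maternal, placenta, fetal, eliminated (mg)
.pbpk_matrix <- function(p) {
  cl_m <- p$cl_maternal * p$induction_scalar
  cl1 <- effective_pd_clearance(p$cl_int_pd_placenta, p$q_placenta_maternal)
  cl2 <- effective_pd_clearance(p$cl_int_pd_placenta, p$q_umbilical)
  km <- p$fu_m / p$v_maternal       # unbound maternal conc per mg
  kp <- p$fu_placenta / p$v_placenta
  kf <- p$fu_f / p$v_fetal
  M <- matrix(0, 5, 5)
  M[1, 1] <- -p$ka
  M[2, 1] <- p$ka
  M[2, 2] <- -cl_m / p$v_maternal - cl1 * km
  M[2, 3] <- (cl1 + p$cl_pm) * kp
  M[3, 2] <- cl1 * km
  M[3, 3] <- -(cl1 + p$cl_pm + cl2) * kp
  M[3, 4] <- cl2 * kf
  M[4, 3] <- cl2 * kp
  M[4, 4] <- -(cl2 + p$fetal_cl) * kf
  M[5, 2] <- cl_m / p$v_maternal
  M[5, 4] <- p$fetal_cl * kf
  M
}

#' Simulate the maternal-fetal PBPK model under multiple oral dosing
#'
#' Integrates the linear ODE system with `deSolve::lsoda` (analytic constant
#' Jacobian, tight tolerances), superposing doses as events that deposit
#' `f_oral * dose` into the gut depot at each dose time plus the absorption
#' lag. Reports maternal plasma, placental tissue and fetal (umbilical vein)
#' concentrations, the UV/MP ratio, and a mass-balance diagnostic
#' (drug in system + eliminated vs total absorbed input).
#'
#' @param params A [pbpk_params()].
#' @param regimen A [dose_regimen()].
#' @param dt_out Output grid spacing (h).
#' @param extra_times Additional output times (h) to include exactly.
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `mf_pbpk_sim` with element `profiles`
#'   (`data.frame`: time_h, gut_mg, maternal_mg_per_l, placenta_mg_per_l,
#'   fetal_mg_per_l, eliminated_mg, uvmp_ratio), plus `params`, `regimen`,
#'   `mass_balance_error` (max relative deviation after the first dose).
#' @export
simulate_mf_pbpk <- function(params, regimen, dt_out = 0.1,
                             extra_times = NULL, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "pbpk_params"), inherits(regimen, "dose_regimen"))
  t_end <- regimen$n_doses * regimen$interval_h
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h + params$tlag
  dose_times <- round(dose_times[dose_times < t_end], 6)
  # rounding to 1e-6 h keeps event times exactly on the output grid and
  # avoids near-duplicate TOUT values the integrator cannot step between
  times <- sort(unique(round(c(seq(0, t_end, by = dt_out), t_end, dose_times,
                               extra_times), 6)))
  M <- .pbpk_matrix(params)
  rhs <- function(t, y, parms) list(as.vector(parms %*% y))
  jac <- function(t, y, parms) parms
  ev <- data.frame(var = "gut", time = dose_times,
                   value = params$f_oral * regimen$dose_mg, method = "add")
  y0 <- c(gut = 0, maternal = 0, placenta = 0, fetal = 0, eliminated = 0)
  out <- try(deSolve::lsoda(y0, times, rhs, parms = M, jacfunc = jac,
                            jactype = "fullusr", rtol = rtol, atol = atol,
                            maxsteps = 1e5, events = list(data = ev)), silent = TRUE)
  bad <- function(o) inherits(o, "try-error") ||
    any(!is.finite(o[, -1])) || min(o[, -1]) < -1e-8
  if (bad(out)) { # tighten and retry once
    out <- try(deSolve::lsoda(y0, times, rhs, parms = M, jacfunc = jac,
                              jactype = "fullusr", rtol = rtol * 1e-2,
                              atol = atol * 1e-2, maxsteps = 1e6,
                              events = list(data = ev)),
               silent = TRUE)
    if (bad(out))
      stop("integrator failure (non-finite or negative states); ",
           "check parameter magnitudes")
  }
  out <- as.data.frame(unclass(out))
  # the output row at a dose time is the pre-event state, so count strictly
  dosed <- params$f_oral * regimen$dose_mg *
    vapply(out$time, function(t) sum(dose_times < t - 1e-9), numeric(1))
  total <- out$gut + out$maternal + out$placenta + out$fetal + out$eliminated
  post <- dosed > 0
  mbe <- if (any(post)) max(abs(total[post] - dosed[post]) / dosed[post]) else 0
  profiles <- data.frame(
    time_h = out$time,
    gut_mg = out$gut,
    maternal_mg_per_l = out$maternal / params$v_maternal,
    placenta_mg_per_l = out$placenta / params$v_placenta,
    fetal_mg_per_l = out$fetal / params$v_fetal,
    eliminated_mg = out$eliminated)
  profiles$uvmp_ratio <- ifelse(profiles$maternal_mg_per_l > 0,
                                profiles$fetal_mg_per_l /
                                  profiles$maternal_mg_per_l, NA_real_)
  structure(list(profiles = profiles, params = params, regimen = regimen,
                 mass_balance_error = mbe),
            class = "mf_pbpk_sim")
}

#' @export
print.mf_pbpk_sim <- function(x, ...) {
  cat(sprintf("m-f PBPK simulation: %d x %g mg q%gh, GW%g\n",
              x$regimen$n_doses, x$regimen$dose_mg, x$regimen$interval_h,
              x$params$gw))
  cat(sprintf("  %d output times to %g h; mass-balance error %.2e\n",
              nrow(x$profiles), max(x$profiles$time_h), x$mass_balance_error))
  invisible(x)
}

.interval_auc <- function(time, conc, lo, hi) {
  keep <- time >= lo - 1e-9 & time <= hi + 1e-9
  tt <- time[keep]; cc <- conc[keep]
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Kp,uu from a steady-state simulation
#'
#' Ratio of fetal to maternal unbound plasma AUC over the final dosing
#' interval: `(fu_f * AUC_fetal) / (fu_m * AUC_maternal)`. Errors unless the
#' simulation has reached steady state (last-interval maternal and fetal
#' AUCs within `ss_tol` of the previous interval).
#'
#' @param sim A [simulate_mf_pbpk()] result.
#' @param ss_tol Steady-state convergence tolerance (default 0.02).
#' @return List `kpuu`, `auc_maternal_ss`, `auc_fetal_ss` (total
#'   concentration AUCs, mg.h/l), `ss_converged`.
#' @export
kpuu_from_simulation <- function(sim, ss_tol = 0.02) {
  stopifnot(inherits(sim, "mf_pbpk_sim"))
  tau <- sim$regimen$interval_h
  n <- sim$regimen$n_doses
  if (n < 2L) stop("need at least 2 dosing intervals to assess steady state")
  pr <- sim$profiles
  auc_m <- vapply(c(n - 1L, n), function(i)
    .interval_auc(pr$time_h, pr$maternal_mg_per_l, (i - 1) * tau, i * tau),
    numeric(1))
  auc_f <- vapply(c(n - 1L, n), function(i)
    .interval_auc(pr$time_h, pr$fetal_mg_per_l, (i - 1) * tau, i * tau),
    numeric(1))
  rel <- function(x) abs(x[2] - x[1]) / x[2]
  converged <- rel(auc_m) < ss_tol && rel(auc_f) < ss_tol
  if (!converged)
    stop(sprintf(paste0("steady state not reached (maternal interval-AUC ",
                        "change %.1f%%, fetal %.1f%%): simulate more doses"),
                 100 * rel(auc_m), 100 * rel(auc_f)))
  p <- sim$params
  list(kpuu = (p$fu_f * auc_f[2]) / (p$fu_m * auc_m[2]),
       auc_maternal_ss = auc_m[2], auc_fetal_ss = auc_f[2],
       ss_converged = converged)
}

#' Closed-form steady-state Kp,uu of the placental topology
#'
#' At periodic steady state with no fetal elimination, the average net
#' placenta-to-fetus flux over a dosing interval is zero, so the average
#' unbound fetal concentration equals the average unbound placental
#' concentration; the placental mass balance then gives
#' `Kp,uu = cl_eff_mp / (cl_eff_mp + cl_pm)`, where `cl_eff_mp` is the
#' flow-capped maternal-side passive clearance. Kp,uu therefore depends only
#' on the ratio of active efflux to (capped) passive clearance, not on
#' maternal disposition, dose or the fetal-side exchange rate.
#'
#' @param params A [pbpk_params()] (requires `fetal_cl = 0`).
#' @return The analytic steady-state Kp,uu.
#' @export
kpuu_steady_state <- function(params) {
  stopifnot(inherits(params, "pbpk_params"))
  if (params$fetal_cl != 0)
    stop("closed form assumes negligible fetal elimination (fetal_cl = 0)")
  cl1 <- effective_pd_clearance(params$cl_int_pd_placenta,
                                params$q_placenta_maternal)
  cl1 / (cl1 + params$cl_pm)
}

#' Absolute average fold error
#'
#' `AAFE = 10 ^ mean(|log10(pred / obs)|)`; 1 means perfect agreement, 2
#' means two-fold average deviation irrespective of direction.
#'
#' @param predicted,observed Paired positive values of equal length.
#' @return AAFE (>= 1).
#' @export
aafe <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 1)
  if (any(predicted <= 0) || any(observed <= 0))
    stop("AAFE requires strictly positive values")
  10^mean(abs(log10(predicted / observed)))
}

#' Log-normally perturb maternal system parameters
#'
#' Draws one population realization of the maternal system parameters
#' (`v_maternal`, `cl_maternal`, `ka`) with log-normal inter-individual
#' variability at the given CVs, leaving drug- and placenta-specific
#' parameters untouched. Used for virtual-population intervals and for
#' synthetic dyad generation.
#'
#' @param params A [pbpk_params()].
#' @param cv Named CV vector for any of `v_maternal`, `cl_maternal`, `ka`
#'   (default 30% each).
#' @return A perturbed `pbpk_params` (draws from the current RNG stream).
#' @export
perturb_maternal_params <- function(params,
                                    cv = c(v_maternal = 0.3,
                                           cl_maternal = 0.3, ka = 0.3)) {
  stopifnot(inherits(params, "pbpk_params"))
  p <- unclass(params)
  for (nm in names(cv)) {
    if (cv[[nm]] < 0) stop("CVs must be >= 0")
    if (cv[[nm]] == 0) next
    sdlog <- sqrt(log(1 + cv[[nm]]^2))
    p[[nm]] <- p[[nm]] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  class(p) <- "pbpk_params"
  p
}

#' Illustrative maternal-fetal parameter sets
#'
#' Ready-made parameter sets for a darunavir-like, lopinavir-like and
#' dexamethasone-like drug at term (GW38) and GW20, with placental passive
#' clearances anchored to the midazolam reference and flow caps at the
#' gestational-age placental blood flow. Maternal disposition values are
#' illustrative literature-magnitude numbers (the model consumes maternal
#' parameters as configuration; they shape exposure, not Kp,uu).
#'
#' @param which One of `"drv_gw38"`, `"drv_gw20"`, `"lpv_gw38"`,
#'   `"lpv_gw20"`, `"dex_gw38"`.
#' @return A list with elements `params` ([pbpk_params()]) and `regimen`
#'   ([dose_regimen()]).
#' @export
example_params <- function(which = c("drv_gw38", "drv_gw20", "lpv_gw38",
                                     "lpv_gw20", "dex_gw38")) {
  which <- match.arg(which)
  base <- list(
    drv_gw38 = list(ka = 0.4, tlag = 1.3, f_oral = 0.82, v_maternal = 130,
                    cl_maternal = 10, induction_scalar = 1.1, fu_m = 0.06,
                    fu_f = 0.12, q = 45,
                    cl_pd = scale_passive_from_reference(1.19e-5),
                    v_placenta = 0.64, v_fetal = 5, gw = 38,
                    dose = 600, tau = 12),
    lpv_gw38 = list(ka = 0.6, tlag = 1.5, f_oral = 0.7, v_maternal = 60,
                    cl_maternal = 6, induction_scalar = 1.5, fu_m = 0.01,
                    fu_f = 0.02, q = 45,
                    cl_pd = scale_passive_from_reference(1.25e-5),
                    v_placenta = 0.64, v_fetal = 5, gw = 38,
                    dose = 400, tau = 12),
    dex_gw38 = list(ka = 1.2, tlag = 0.25, f_oral = 0.8, v_maternal = 70,
                    cl_maternal = 15, induction_scalar = 1, fu_m = 0.3,
                    fu_f = 0.4, q = 45,
                    cl_pd = scale_passive_from_reference(2.5e-5),
                    v_placenta = 0.64, v_fetal = 5, gw = 38,
                    dose = 6, tau = 12))
  base$drv_gw20 <- utils::modifyList(base$drv_gw38, list(
    q = 27.5, cl_pd = base$drv_gw38$cl_pd * 0.39, v_placenta = 0.17,
    v_fetal = 1, gw = 20))
  base$lpv_gw20 <- utils::modifyList(base$lpv_gw38, list(
    q = 27.5, cl_pd = base$lpv_gw38$cl_pd * 0.39, v_placenta = 0.17,
    v_fetal = 1, gw = 20))
  b <- base[[which]]
  list(params = pbpk_params(ka = b$ka, tlag = b$tlag, f_oral = b$f_oral,
                            v_maternal = b$v_maternal,
                            cl_maternal = b$cl_maternal,
                            induction_scalar = b$induction_scalar,
                            fu_m = b$fu_m, fu_f = b$fu_f,
                            q_placenta_maternal = b$q, q_umbilical = b$q,
                            cl_int_pd_placenta = b$cl_pd, cl_pm = 0,
                            v_placenta = b$v_placenta, v_fetal = b$v_fetal,
                            gw = b$gw),
       regimen = dose_regimen(b$dose, b$tau, 16L))
}
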