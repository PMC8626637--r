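#' Ground truth for a synthetic Transwell experiment pair
#'
#' Defines the physics of a simulated bidirectional assay: true directional
#' apparent permeabilities, chamber geometry, the sampling schedule of the
#' protocol (100 ul receiver draws replaced with blank buffer, 10 ul donor
#' draws at the start and end), and a multiplicative assay noise CV.
#'
#' @param papp_a2b_true,papp_b2a_true True apparent permeabilities (cm/s).
#' @param donor_conc0 Donor concentration at time zero (uM; default 2).
#' @param insert_area Insert area (cm^2).
#' @param apical_volume,basal_volume Chamber volumes (ml; defaults 0.5 / 1).
#' @param receiver_times Receiver sampling times (min; default 15/30/45/60).
#' @param receiver_draw_ml Receiver aliquot volume (ml, replaced with blank).
#' @param donor_draw_ml Donor aliquot volume (ml, not replaced).
#' @param cv_assay Multiplicative measurement CV (log-normal, mean 1).
#' @param seed Integer seed.
#' @param drug Label for the generated experiments.
#' @return Object of class `transwell_truth`.
#' @export
transwell_truth <- function(papp_a2b_true, papp_b2a_true, donor_conc0 = 2,
                            insert_area = 1.12, apical_volume = 0.5,
                            basal_volume = 1,
                            receiver_times = c(15, 30, 45, 60),
                            receiver_draw_ml = 0.1, donor_draw_ml = 0.01,
                            cv_assay = 0.05, seed = 1L, drug = "SYN") {
  stopifnot(papp_a2b_true > 0, papp_b2a_true > 0, donor_conc0 > 0,
            cv_assay >= 0, all(diff(receiver_times) > 0),
            all(receiver_times > 0))
  structure(list(papp_a2b_true = papp_a2b_true,
                 papp_b2a_true = papp_b2a_true, donor_conc0 = donor_conc0,
                 insert_area = insert_area, apical_volume = apical_volume,
                 basal_volume = basal_volume, receiver_times = receiver_times,
                 receiver_draw_ml = receiver_draw_ml,
                 donor_draw_ml = donor_draw_ml, cv_assay = cv_assay,
                 seed = as.integer(seed), drug = drug),
            class = "transwell_truth")
}

# exact piecewise-linear-ODE propagation of one directional run.
# state: (C_D, C_R, m_cum, aucc_D); draws are handled as discrete events,
# so the solution between events is a matrix exponential.
.simulate_direction <- function(truth, direction) {
  a <- truth$insert_area
  if (direction == "A2B") {
    v_d <- truth$apical_volume; v_r <- truth$basal_volume
    p_f <- truth$papp_a2b_true; p_b <- truth$papp_b2a_true
  } else {
    v_d <- truth$basal_volume; v_r <- truth$apical_volume
    p_f <- truth$papp_b2a_true; p_b <- truth$papp_a2b_true
  }
  # per-minute transfer coefficients (cm/s -> ml/min through 60*A)
  kf <- 60 * a * p_f
  kb <- 60 * a * p_b
  make_m <- function(vd) {
    matrix(c(-kf / vd,  kb / vd, 0, 0,
             kf / v_r, -kb / v_r, 0, 0,
             kf,       -kb,       0, 0,
             1,          0,       0, 0),
           nrow = 4, byrow = TRUE)
  }
  # t = 0: donor sampled (10 ul, not replaced) -> donor volume shrinks
  x <- c(truth$donor_conc0, 0, 0, 0)
  vd_now <- v_d - truth$donor_draw_ml
  M <- make_m(vd_now)
  t_now <- 0
  times <- truth$receiver_times
  receiver_true <- numeric(length(times))
  cum_true <- numeric(length(times))
  withdrawn_mass <- 0
  for (k in seq_along(times)) {
    E <- as.matrix(Matrix::expm(M * (times[k] - t_now)))
    x <- as.vector(E %*% x)
    t_now <- times[k]
    receiver_true[k] <- x[2]
    cum_true[k] <- x[3]
    # draw + blank replacement dilutes the receiver, volume unchanged
    withdrawn_mass <- withdrawn_mass + truth$receiver_draw_ml * x[2]
    x[2] <- x[2] * (v_r - truth$receiver_draw_ml) / v_r
  }
  donor_true <- c(truth$donor_conc0, x[1])
  list(receiver_true = receiver_true, donor_true = donor_true,
       cum_true = cum_true, donor_auc_exact = x[4],
       donor_volume_end = vd_now, mass_check =
         vd_now * x[1] + v_r * x[2] + withdrawn_mass +
         truth$donor_draw_ml * truth$donor_conc0)
}

#' Simulate a bidirectional Transwell experiment pair
#'
#' Event-driven two-compartment simulation of both assay directions with
#' exact handling of every sampling event (receiver draws replaced with
#' blank buffer; donor draws shrinking the donor volume), returning measured
#' concentrations with multiplicative log-normal noise alongside the exact
#' noiseless bookkeeping (true cumulative transferred mass per time point,
#' the exact donor concentration integral, and the programmed
#' permeabilities) for oracle comparisons.
#'
#' @param truth A [transwell_truth()].
#' @return List with `a2b` and `b2a` ([transwell_experiment()]s carrying the
#'   noisy measurements) and `exact` (per-direction noiseless state).
#' @export
simulate_transwell_pair <- function(truth) {
  stopifnot(inherits(truth, "transwell_truth"))
  set.seed(truth$seed)
  noisy <- function(x) {
    if (truth$cv_assay == 0) return(x)
    sdlog <- sqrt(log(1 + truth$cv_assay^2))
    x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  }
  build <- function(direction) {
    ex <- .simulate_direction(truth, direction)
    v_d <- if (direction == "A2B") truth$apical_volume else truth$basal_volume
    v_r <- if (direction == "A2B") truth$basal_volume else truth$apical_volume
    t_end <- max(truth$receiver_times)
    exp <- transwell_experiment(
      drug = truth$drug, direction = direction,
      insert_area = truth$insert_area, donor_volume = v_d,
      receiver_volume = v_r,
      receiver_samples = data.frame(
        time_min = truth$receiver_times,
        conc_uM = noisy(ex$receiver_true),
        sampled_volume_ml = truth$receiver_draw_ml),
      donor_samples = data.frame(
        time_min = c(0, t_end),
        conc_uM = noisy(ex$donor_true),
        sampled_volume_ml = truth$donor_draw_ml),
      replicate_id = sprintf("synthetic-seed%d", truth$seed))
    list(exp = exp, exact = ex)
  }
  a <- build("A2B")
  b <- build("B2A")
  list(a2b = a$exp, b2a = b$exp,
       exact = list(a2b = a$exact, b2a = b$exact,
                    papp_a2b_true = truth$papp_a2b_true,
                    papp_b2a_true = truth$papp_b2a_true,
                    er_true = truth$papp_b2a_true / truth$papp_a2b_true))
}

#' Ground truth for a synthetic maternal-fetal dyad study
#'
#' Emulates sparse cord-blood sampling: each dyad contributes one
#' (UV, MP) concentration pair drawn at a uniform-random time within the
#' steady-state dosing interval (cord samples occur at delivery, effectively
#' random within the interval), from a maternal parameter set perturbed by
#' log-normal inter-individual variability, with multiplicative log-normal
#' residual error on each measured concentration.
#'
#' @param params Generating [pbpk_params()] (including the true `cl_pm`).
#' @param regimen [dose_regimen()] taken to steady state.
#' @param n_dyads Number of maternal-fetal dyads.
#' @param window Sampling window (h after the final dose), default
#'   `c(1, interval_h)`.
#' @param cv_residual Residual CV applied to each concentration (default 0.2).
#' @param cv_pop Named maternal population CVs (see
#'   [perturb_maternal_params()]).
#' @param seed Integer seed.
#' @return Object of class `clinical_truth`.
#' @export
clinical_truth <- function(params, regimen, n_dyads = 12L,
                           window = c(1, regimen$interval_h),
                           cv_residual = 0.2,
                           cv_pop = c(v_maternal = 0.3, cl_maternal = 0.3,
                                      ka = 0.3),
                           seed = 1L) {
  stopifnot(inherits(params, "pbpk_params"), inherits(regimen, "dose_regimen"),
            n_dyads >= 1, cv_residual >= 0, length(window) == 2L,
            window[1] >= 0, window[2] <= regimen$interval_h,
            window[2] > window[1])
  structure(list(params = params, regimen = regimen,
                 n_dyads = as.integer(n_dyads), window = window,
                 cv_residual = cv_residual, cv_pop = cv_pop,
                 seed = as.integer(seed)),
            class = "clinical_truth")
}

#' Simulate sparse UV/MP dyad observations
#'
#' @param truth A [clinical_truth()].
#' @param dt_out Simulation output spacing (h).
#' @return `data.frame` (`dyad_id`, `time_after_dose_h`, `uv_mg_per_l`,
#'   `mp_mg_per_l`) with attributes `kpuu_true` (the generating steady-state
#'   Kp,uu of the nominal parameter set) and `truth`.
#' @export
simulate_clinical <- function(truth, dt_out = 0.5) {
  stopifnot(inherits(truth, "clinical_truth"))
  set.seed(truth$seed)
  reg <- truth$regimen
  t0 <- (reg$n_doses - 1) * reg$interval_h
  sdlog <- sqrt(log(1 + truth$cv_residual^2))
  rows <- vector("list", truth$n_dyads)
  for (i in seq_len(truth$n_dyads)) {
    p_i <- perturb_maternal_params(truth$params, truth$cv_pop)
    t_obs <- stats::runif(1, truth$window[1], truth$window[2])
    sim <- simulate_mf_pbpk(p_i, reg, dt_out = dt_out,
                            extra_times = t0 + t_obs)
    pr <- sim$profiles
    j <- which.min(abs(pr$time_h - (t0 + t_obs)))
    eps <- if (truth$cv_residual > 0)
      stats::rlnorm(2, -sdlog^2 / 2, sdlog) else c(1, 1)
    rows[[i]] <- data.frame(
      dyad_id = sprintf("dyad%02d", i),
      time_after_dose_h = t_obs,
      uv_mg_per_l = pr$fetal_mg_per_l[j] * eps[1],
      mp_mg_per_l = pr$maternal_mg_per_l[j] * eps[2])
  }
  out <- do.call(rbind, rows)
  attr(out, "kpuu_true") <- kpuu_steady_state(truth$params)
  attr(out, "truth") <- truth
  out
}
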