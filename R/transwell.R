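#' Construct a Transwell bidirectional transport experiment
#'
#' Represents one directional run of a polarized-monolayer Transwell assay:
#' a donor compartment dosed with drug at time zero and a receiver compartment
#' sampled repeatedly, with each receiver draw replaced by blank buffer.
#' Apical-to-basal (`"A2B"`) runs have the apical chamber as donor (0.5 ml by
#' convention in a 12-well format) and the basal chamber as receiver (1 ml);
#' `"B2A"` runs are the reverse.
#'
#' @param drug Drug label.
#' @param direction `"A2B"` or `"B2A"`.
#' @param inhibitor `"none"`, `"pgp_inhibitor"` or `"bcrp_inhibitor"`.
#' @param insert_area Membrane area in cm^2 (default 1.12, standard 12-well
#'   polyester insert).
#' @param donor_volume,receiver_volume Compartment volumes in ml.
#' @param receiver_samples `data.frame` with columns `time_min`, `conc_uM`,
#'   `sampled_volume_ml` and optionally `replaced_with_blank` (default TRUE).
#' @param donor_samples `data.frame` with columns `time_min`, `conc_uM`,
#'   `sampled_volume_ml`; must include a time-zero sample.
#' @param ly_papp Lucifer yellow apparent permeability (cm/s) for the
#'   monolayer-integrity gate, or `NA` when not measured.
#' @param replicate_id Free-text replicate/experiment label.
#'
#' @return An object of class `transwell_experiment`.
#' @export
transwell_experiment <- function(drug, direction, inhibitor = "none",
                                 insert_area = 1.12,
                                 donor_volume = if (direction == "A2B") 0.5 else 1,
                                 receiver_volume = if (direction == "A2B") 1 else 0.5,
                                 receiver_samples, donor_samples,
                                 ly_papp = NA_real_, replicate_id = "1") {
  direction <- match.arg(direction, c("A2B", "B2A"))
  inhibitor <- match.arg(inhibitor, c("none", "pgp_inhibitor", "bcrp_inhibitor"))
  receiver_samples <- as.data.frame(receiver_samples)
  donor_samples <- as.data.frame(donor_samples)
  .check_sample_frame(receiver_samples, "receiver")
  .check_sample_frame(donor_samples, "donor")
  if (is.null(receiver_samples$replaced_with_blank))
    receiver_samples$replaced_with_blank <- TRUE
  if (abs(donor_samples$time_min[1]) > 1e-9)
    stop("first donor sample must be at time 0")
  if (any(receiver_samples$sampled_volume_ml >= receiver_volume))
    stop("sampled volume must be smaller than the receiver volume")
  if (any(donor_samples$sampled_volume_ml >= donor_volume))
    stop("sampled volume must be smaller than the donor volume")
  stopifnot(insert_area > 0, donor_volume > 0, receiver_volume > 0)
  structure(
    list(drug = drug, direction = direction, inhibitor = inhibitor,
         insert_area = insert_area, donor_volume = donor_volume,
         receiver_volume = receiver_volume,
         receiver_samples = receiver_samples, donor_samples = donor_samples,
         ly_papp = ly_papp, replicate_id = as.character(replicate_id)),
    class = "transwell_experiment")
}

.check_sample_frame <- function(df, what) {
  need <- c("time_min", "conc_uM", "sampled_volume_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s samples are missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  if (nrow(df) < 1L) stop(sprintf("%s samples are empty", what))
  if (any(diff(df$time_min) <= 0))
    stop(sprintf("%s sample times must be strictly increasing", what))
  if (any(df$time_min < 0)) stop(sprintf("%s sample times must be >= 0", what))
  if (any(df$conc_uM < 0))
    stop(sprintf("negative concentration in %s samples (data-quality error)", what))
  if (any(df$sampled_volume_ml < 0))
    stop(sprintf("negative sampled volume in %s samples", what))
  invisible(df)
}

#' Cumulative receiver amount with sampled-volume correction
#'
#' Receiver draws physically remove drug and are replaced with blank buffer,
#' so the concentration measured at sample k reflects only the mass still in
#' the chamber. The cumulative transported amount adds back every previously
#' withdrawn aliquot:
#' `cum_k = V_R * C_k + sum_{j<k} v_j * C_j`.
#'
#' Units are micromolar x ml (= nmol); the unit boundary to cm/s is crossed
#' only in [apparent_permeability()].
#'
#' @param samples `data.frame` with `time_min`, `conc_uM`, `sampled_volume_ml`.
#' @param receiver_volume Receiver chamber volume (ml).
#' @return Numeric vector of cumulative amounts (uM.ml), one per sample.
#' @export
cumulative_receiver_amount <- function(samples, receiver_volume) {
  samples <- as.data.frame(samples)
  .check_sample_frame(samples, "receiver")
  if (any(samples$sampled_volume_ml >= receiver_volume))
    stop("sampled volume must be smaller than the receiver volume")
  conc <- samples$conc_uM
  v <- samples$sampled_volume_ml
  withdrawn <- c(0, cumsum(conc * v)[-length(conc)])
  receiver_volume * conc + withdrawn
}

#' Donor-compartment AUC by the linear trapezoid rule
#'
#' Using the donor AUC (rather than the time-zero donor concentration) as the
#' denominator of the permeability estimator corrects for depletion of drug in
#' the donor compartment during the experiment.
#'
#' @param samples Donor sample `data.frame` (`time_min`, `conc_uM`).
#' @param t_end End of the integration window (min). Must be covered by the
#'   sampling; defaults to the last donor sample time.
#' @param allow_constant_donor With a single donor sample the AUC is undefined;
#'   set `TRUE` to explicitly enable the constant-donor fallback `C0 * t_end`.
#' @return AUC in uM.min.
#' @export
donor_auc <- function(samples, t_end = NULL, allow_constant_donor = FALSE) {
  samples <- as.data.frame(samples)
  if (any(samples$conc_uM < 0)) stop("negative donor concentration")
  tt <- samples$time_min
  cc <- samples$conc_uM
  if (is.null(t_end)) t_end <- tt[length(tt)]
  if (length(tt) < 2L) {
    if (!allow_constant_donor)
      stop("only one donor sample: enable the constant-donor fallback ",
           "explicitly (allow_constant_donor = TRUE) to use C0 * t_end")
    return(cc[1] * t_end)
  }
  if (tt[1] > 0 || tt[length(tt)] < t_end - 1e-9)
    stop("donor samples must span [0, t_end]")
  keep <- tt <= t_end + 1e-9
  tt <- tt[keep]; cc <- cc[keep]
  if (tt[length(tt)] < t_end - 1e-9) { # interpolate the right edge
    i <- length(tt)
    c_end <- stats::approx(samples$time_min, samples$conc_uM, xout = t_end)$y
    tt <- c(tt, t_end); cc <- c(cc, c_end)
  }
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Apparent permeability from cumulative transport and donor exposure
#'
#' `P_app = cA(R) / (AUC_D * A)`: cumulative receiver amount divided by the
#' donor concentration-time integral and the insert area, converted to cm/s.
#' Because the membrane area is identical in both directions this equals the
#' directional apparent intrinsic clearance per unit area. When the donor is
#' constant it reduces to the familiar slope-based estimator.
#'
#' @param cum_amount_final Final cumulative receiver amount (uM.ml).
#' @param donor_auc Donor AUC over the same window (uM.min).
#' @param area Insert area (cm^2).
#' @return Apparent permeability in cm/s.
#' @export
apparent_permeability <- function(cum_amount_final, donor_auc, area) {
  if (any(c(cum_amount_final, donor_auc, area) <= 0))
    stop("cumulative amount, donor AUC and area must all be > 0")
  cum_amount_final / (donor_auc * 60 * area)
}

#' Apparent permeability of one directional experiment
#'
#' @param exp A [transwell_experiment()].
#' @param correct_sampling Apply the sampled-volume correction (default TRUE;
#'   FALSE exists for diagnosing the bias of the uncorrected estimator).
#' @param method `"cumulative"` (final cumulative amount over the full-window
#'   donor AUC) or `"slope"` (regression of cumulative amount on time through
#'   the origin, divided by the time-average donor concentration; a linearity
#'   diagnostic).
#' @return List with `papp` (cm/s), `cum_amounts`, `donor_auc`,
#'   `n_timepoints`.
#' @export
papp_from_experiment <- function(exp, correct_sampling = TRUE,
                                 method = c("cumulative", "slope")) {
  stopifnot(inherits(exp, "transwell_experiment"))
  method <- match.arg(method)
  rs <- exp$receiver_samples
  cum <- if (correct_sampling) {
    cumulative_receiver_amount(rs, exp$receiver_volume)
  } else {
    exp$receiver_volume * rs$conc_uM
  }
  t_end <- rs$time_min[nrow(rs)]
  auc <- donor_auc(exp$donor_samples, t_end = t_end)
  papp <- if (method == "cumulative") {
    apparent_permeability(cum[length(cum)], auc, exp$insert_area)
  } else {
    slope <- stats::coef(stats::lm(cum ~ 0 + rs$time_min))[[1]] # uM.ml/min
    slope / ((auc / t_end) * 60 * exp$insert_area)
  }
  list(papp = papp, cum_amounts = cum, donor_auc = auc,
       n_timepoints = nrow(rs))
}

#' Efflux ratio from a bidirectional experiment pair
#'
#' `ER = P_app(B->A) / P_app(A->B)`. The pair must share drug and inhibitor
#' state. QC flags: monolayer integrity from Lucifer yellow permeability and,
#' when a control ER (e.g. quinidine for P-gp) is supplied, transporter
#' activity.
#'
#' @param exp_a2b,exp_b2a The two directional [transwell_experiment()]s.
#' @param control_er Efflux ratio of the positive-control substrate measured
#'   in the same experiment, or `NA` (gate then reported as not evaluated).
#' @param correct_sampling,method Passed to [papp_from_experiment()].
#' @return Object of class `efflux_ratio_result`: `papp_a2b`, `papp_b2a`,
#'   `er`, `qc_ly_pass`, `qc_control_pass`, `n_timepoints_used`.
#' @export
efflux_ratio <- function(exp_a2b, exp_b2a, control_er = NA_real_,
                         correct_sampling = TRUE,
                         method = c("cumulative", "slope")) {
  stopifnot(inherits(exp_a2b, "transwell_experiment"),
            inherits(exp_b2a, "transwell_experiment"))
  if (exp_a2b$direction != "A2B" || exp_b2a$direction != "B2A")
    stop("direction mismatch: expected an A2B and a B2A experiment")
  if (!identical(exp_a2b$drug, exp_b2a$drug))
    stop("drug mismatch between the two directions")
  if (!identical(exp_a2b$inhibitor, exp_b2a$inhibitor))
    stop("inhibitor-state mismatch between the two directions")
  method <- match.arg(method)
  a <- papp_from_experiment(exp_a2b, correct_sampling, method)
  b <- papp_from_experiment(exp_b2a, correct_sampling, method)
  ly <- suppressWarnings(max(exp_a2b$ly_papp, exp_b2a$ly_papp, na.rm = TRUE))
  if (!is.finite(ly)) ly <- NA_real_
  gate <- qc_gate(ly_papp = ly, control_er = control_er)
  structure(
    list(drug = exp_a2b$drug, inhibitor = exp_a2b$inhibitor,
         papp_a2b = a$papp, papp_b2a = b$papp, er = b$papp / a$papp,
         qc_ly_pass = if (is.na(ly)) NA else !("leaky_monolayer" %in% gate$reasons),
         qc_control_pass = if (is.na(control_er)) NA else
           !("weak_transporter_activity" %in% gate$reasons),
         qc = gate,
         n_timepoints_used = min(a$n_timepoints, b$n_timepoints)),
    class = "efflux_ratio_result")
}

#' @export
print.efflux_ratio_result <- function(x, ...) {
  cat(sprintf("Efflux ratio (%s, inhibitor: %s)\n", x$drug, x$inhibitor))
  cat(sprintf("  Papp A->B: %.3g cm/s   Papp B->A: %.3g cm/s   ER = %.3g\n",
              x$papp_a2b, x$papp_b2a, x$er))
  cat(sprintf("  QC: LY %s, control %s\n",
              ifelse(is.na(x$qc_ly_pass), "not evaluated",
                     ifelse(x$qc_ly_pass, "pass", "FAIL")),
              ifelse(is.na(x$qc_control_pass), "not evaluated",
                     ifelse(x$qc_control_pass, "pass", "FAIL"))))
  invisible(x)
}

#' Transporter-mediated component of the efflux ratio
#'
#' The inhibitor-sensitive efflux ratio: ER measured without inhibitor minus
#' ER measured with a specific inhibitor (tariquidar for P-gp). Near zero for
#' non-substrates; negative values are allowed but flagged.
#'
#' @param er_no_inhibitor,er_inhibitor Efflux ratios (> 0).
#' @return List `er_without_inhibitor`, `er_with_inhibitor`, `er_pgp`,
#'   `negative` flag.
#' @export
pgp_mediated_er <- function(er_no_inhibitor, er_inhibitor) {
  stopifnot(er_no_inhibitor > 0, er_inhibitor > 0)
  d <- er_no_inhibitor - er_inhibitor
  list(er_without_inhibitor = er_no_inhibitor,
       er_with_inhibitor = er_inhibitor,
       er_pgp = d, negative = d < 0)
}

#' Quality-control gate for a Transwell experiment
#'
#' An experiment is usable only when the monolayer is tight (Lucifer yellow
#' `P_app < 2e-6` cm/s) and the positive-control substrate shows robust
#' transporter activity (control ER > 7).
#'
#' @param ly_papp Lucifer yellow apparent permeability (cm/s); `NA` skips the
#'   gate.
#' @param control_er Positive-control efflux ratio; `NA` skips the gate.
#' @param ly_threshold,control_threshold Gate thresholds (defaults 2e-6 cm/s
#'   and 7).
#' @return List with `pass` (logical) and `reasons` (character vector, empty
#'   on pass).
#' @export
qc_gate <- function(ly_papp = NA_real_, control_er = NA_real_,
                    ly_threshold = 2e-6, control_threshold = 7) {
  reasons <- character()
  if (!is.na(ly_papp) && ly_papp >= ly_threshold)
    reasons <- c(reasons, "leaky_monolayer")
  if (!is.na(control_er) && control_er <= control_threshold)
    reasons <- c(reasons, "weak_transporter_activity")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
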