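#' Transporter abundance measurement
#'
#' Abundance of a transporter protein per mg of total homogenate protein,
#' measured by targeted quantitative proteomics either in the in vitro cell
#' line or in placental tissue.
#'
#' @param system `"cell_line"`, `"placenta_term"` or `"placenta_ga"`.
#' @param mean Mean abundance (pmol per mg homogenate protein), > 0.
#' @param sd Standard deviation (same units), >= 0.
#' @param n Number of measurements.
#' @param experiment_id Label, or `"pooled"`.
#' @return Object of class `abundance_measurement`.
#' @export
abundance_measurement <- function(system = c("cell_line", "placenta_term",
                                             "placenta_ga"),
                                  mean, sd = 0, n = 1L,
                                  experiment_id = "pooled") {
  system <- match.arg(system)
  stopifnot(is.numeric(mean), mean > 0, sd >= 0, n >= 1)
  structure(list(system = system, mean = mean, sd = sd, n = as.integer(n),
                 experiment_id = experiment_id),
            class = "abundance_measurement")
}

.abundance_mean <- function(x) {
  if (inherits(x, "abundance_measurement")) x$mean else as.numeric(x)
}

#' Relative expression factor (REF)
#'
#' Ratio of in vivo (placental) to in vitro (cell line) transporter abundance
#' per mg total homogenate protein. REF scales transport activity measured in
#' an overexpressing cell line to the tissue.
#'
#' @param in_vivo,in_vitro [abundance_measurement()]s or bare numbers
#'   (pmol/mg homogenate protein), both > 0.
#' @return List of class `ref_estimate`: `ref`, `in_vivo_abundance`,
#'   `in_vitro_abundance`.
#' @export
compute_ref <- function(in_vivo, in_vitro) {
  vv <- .abundance_mean(in_vivo)
  vt <- .abundance_mean(in_vitro)
  if (!is.finite(vv) || !is.finite(vt) || vv <= 0 || vt <= 0)
    stop("abundances must be positive")
  structure(list(ref = vv / vt, in_vivo_abundance = vv,
                 in_vitro_abundance = vt),
            class = "ref_estimate")
}

#' Predicted fetal Kp,uu from a REF-scaled efflux ratio
#'
#' At steady state, with negligible fetal elimination, the fetal-to-maternal
#' unbound exposure ratio of an apically effluxed drug is
#' `Kp,uu = 1 / (1 + REF * ER_pgp)`: the in vitro transporter-mediated efflux
#' ratio, scaled to tissue abundance by the REF, sits on top of passive
#' diffusion. A non-substrate (`ER_pgp = 0`) has Kp,uu = 1 exactly.
#'
#' @param ref A [compute_ref()] result or a bare positive number.
#' @param er_pgp Transporter-mediated efflux ratio, >= 0.
#' @param negative_er `"clamp"` (warn and treat a negative ER as 0, the
#'   non-substrate case) or `"strict"` (raise).
#' @return Kp,uu in (0, 1].
#' @export
predict_kpuu <- function(ref, er_pgp, negative_er = c("clamp", "strict")) {
  negative_er <- match.arg(negative_er)
  r <- if (inherits(ref, "ref_estimate")) ref$ref else as.numeric(ref)
  stopifnot(r > 0)
  if (any(er_pgp < 0)) {
    if (negative_er == "strict") stop("negative transporter-mediated ER")
    warning("negative transporter-mediated ER clamped to 0 (non-substrate)")
    er_pgp <- pmax(er_pgp, 0)
  }
  1 / (1 + r * er_pgp)
}

#' Invert the Kp,uu relation back to an efflux ratio
#'
#' @param kpuu Kp,uu in (0, 1].
#' @param ref REF (> 0).
#' @return The `er_pgp` that [predict_kpuu()] maps to `kpuu`.
#' @export
er_from_kpuu <- function(kpuu, ref) {
  stopifnot(kpuu > 0, kpuu <= 1, ref > 0)
  (1 / kpuu - 1) / ref
}

#' Monte-Carlo 90% interval for the predicted Kp,uu
#'
#' Propagates the experimental variability of the transporter-mediated efflux
#' ratio and of the two abundance measurements into the Kp,uu prediction by
#' seeded Monte-Carlo. Marginals are independent normals truncated at zero
#' (ER) or at a small positive floor (abundances); truncation keeps every
#' draw in the physically admissible domain. With all SDs zero the interval
#' degenerates to the point estimate.
#'
#' @param er_mean,er_sd Mean and SD of the transporter-mediated ER.
#' @param invitro_mean,invitro_sd Cell-line abundance (pmol/mg).
#' @param invivo_mean,invivo_sd Tissue abundance (pmol/mg).
#' @param n_draws Number of draws (>= 1e4).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param floor Lower truncation bound for the abundance marginals.
#' @return Named numeric `c(low, high)`: 5th and 95th percentiles.
#' @export
kpuu_ci_montecarlo <- function(er_mean, er_sd, invitro_mean, invitro_sd,
                               invivo_mean, invivo_sd, n_draws = 1e5,
                               seed = 1L, floor = 1e-6) {
  stopifnot(er_sd >= 0, invitro_sd >= 0, invivo_sd >= 0, n_draws >= 1e4)
  if (er_sd == 0 && invitro_sd == 0 && invivo_sd == 0) {
    point <- predict_kpuu(invivo_mean / invitro_mean, max(er_mean, 0))
    return(c(low = point, high = point))
  }
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  er <- .rtruncnorm(n_draws, er_mean, er_sd, lower = 0)
  vt <- .rtruncnorm(n_draws, invitro_mean, invitro_sd, lower = floor)
  vv <- .rtruncnorm(n_draws, invivo_mean, invivo_sd, lower = floor)
  k <- 1 / (1 + (vv / vt) * er)
  q <- stats::quantile(k, c(0.05, 0.95), names = FALSE)
  c(low = q[1], high = q[2])
}

.Random.seed.exists <- function() exists(".Random.seed", envir = globalenv())

# inverse-CDF sampler for a normal truncated below at `lower`
.rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' Summarize a Kp,uu prediction over independent experiments
#'
#' Each experiment contributes its own transporter-mediated ER and its own
#' in vitro abundance (measured in the same run, so REF is matched to the ER
#' it scales). The point estimate is the arithmetic mean of the
#' per-experiment Kp,uu values; an alternative estimator (Kp,uu of the mean
#' ER and mean REF) is also reported because the two differ for strong
#' substrates. The 90% interval is by [kpuu_ci_montecarlo()] over the pooled
#' experiment-level variability.
#'
#' @param per_experiment `data.frame` with columns `er_pgp` and
#'   `invitro_abundance` (pmol/mg), one row per experiment.
#' @param in_vivo [abundance_measurement()] (or number) for the tissue;
#'   `in_vivo_sd` is used when a bare number is given.
#' @param in_vivo_sd SD of the tissue abundance (ignored when `in_vivo` is an
#'   `abundance_measurement`).
#' @param n_draws,seed Monte-Carlo settings for the interval.
#' @return Object of class `kpuu_prediction`: `kpuu_point`, `kpuu_point_alt`,
#'   `ci90_low`, `ci90_high`, `ft_pgp`, `per_experiment` table, `seed`.
#' @export
summarize_prediction <- function(per_experiment, in_vivo, in_vivo_sd = 0,
                                 n_draws = 1e5, seed = 1L) {
  per_experiment <- as.data.frame(per_experiment)
  stopifnot(all(c("er_pgp", "invitro_abundance") %in% names(per_experiment)))
  if (inherits(in_vivo, "abundance_measurement")) {
    invivo_mean <- in_vivo$mean; invivo_sd <- in_vivo$sd
  } else {
    invivo_mean <- as.numeric(in_vivo); invivo_sd <- in_vivo_sd
  }
  ref <- invivo_mean / per_experiment$invitro_abundance
  kp <- 1 / (1 + ref * pmax(per_experiment$er_pgp, 0))
  per <- cbind(per_experiment, ref = ref, kpuu = kp)
  point <- mean(kp)
  # alternative estimator: Kp,uu of the mean ER and mean REF
  alt <- 1 / (1 + mean(ref) * max(mean(per_experiment$er_pgp), 0))
  n <- nrow(per_experiment)
  if (n >= 2L) {
    ci <- kpuu_ci_montecarlo(
      er_mean = mean(per_experiment$er_pgp),
      er_sd = stats::sd(per_experiment$er_pgp),
      invitro_mean = mean(per_experiment$invitro_abundance),
      invitro_sd = stats::sd(per_experiment$invitro_abundance),
      invivo_mean = invivo_mean, invivo_sd = invivo_sd,
      n_draws = n_draws, seed = seed)
  } else {
    ci <- c(low = NA_real_, high = NA_real_)
  }
  structure(list(kpuu_point = point, kpuu_point_alt = alt,
                 ci90_low = unname(ci["low"]), ci90_high = unname(ci["high"]),
                 ft_pgp = 1 - point, per_experiment = per,
                 in_vivo_abundance = invivo_mean, in_vivo_sd = invivo_sd,
                 n_experiments = n, seed = as.integer(seed)),
            class = "kpuu_prediction")
}

#' @export
print.kpuu_prediction <- function(x, ...) {
  cat(sprintf("Predicted fetal Kp,uu: %.2f", x$kpuu_point))
  if (!is.na(x$ci90_low))
    cat(sprintf(" (CI90 %.2f-%.2f)", x$ci90_low, x$ci90_high))
  cat(sprintf("  [mean-ER estimator: %.2f]\n", x$kpuu_point_alt))
  cat(sprintf("ft,P-gp = 1 - Kp,uu = %.2f;  %d experiments, in vivo abundance %.2f pmol/mg\n",
              x$ft_pgp, x$n_experiments, x$in_vivo_abundance))
  print(x$per_experiment, digits = 3)
  invisible(x)
}

#' Reference bidirectional Transwell measurements for four P-gp substrates
#'
#' Published per-experiment efflux ratios (without and with the P-gp inhibitor
#' tariquidar) and matched in vitro P-gp abundances for dexamethasone (DEX),
#' betamethasone (BET), darunavir (DRV) and lopinavir (LPV), measured in
#' hMDR1-MDCK cells with the canine P-gp knocked out; four independent
#' experiments per drug, each run in triplicate. The matching term-placenta
#' P-gp abundance is 0.16 +/- 0.07 pmol per mg homogenate protein (carried as
#' attributes `invivo_mean` and `invivo_sd`).
#'
#' @return `data.frame` with columns `drug`, `experiment`,
#'   `er_no_inhibitor`, `er_inhibitor`, `invitro_abundance_pmol_mg`.
#' @export
pgp_reference_experiments <- function() {
  df <- data.frame(
    drug = rep(c("DEX", "BET", "DRV", "LPV"), each = 4L),
    experiment = rep(1:4, times = 4L),
    er_no_inhibitor = c(5.42, 5.37, 8.33, 5.65,
                        6.56, 5.64, 8.64, 7.66,
                        40.43, 41.83, 37.86, 41.73,
                        95.37, 90.07, 75.63, 76.57),
    er_inhibitor = c(0.85, 1.04, 1.35, 0.90,
                     0.95, 1.07, 1.03, 0.92,
                     0.82, 1.48, 1.12, 1.06,
                     1.02, 1.29, 1.64, 1.30),
    invitro_abundance_pmol_mg = c(1.16, 1.34, 1.92, 1.20,
                                  1.16, 1.34, 1.92, 1.20,
                                  1.16, 1.34, 1.92, 1.20,
                                  1.30, 1.20, 1.20, 0.99))
  attr(df, "invivo_mean") <- 0.16
  attr(df, "invivo_sd") <- 0.07
  df
}
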