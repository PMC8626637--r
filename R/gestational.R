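#' Gestational-age scalers for placental clearances
#'
#' Bundle of the quantities that change placental transfer with gestational
#' age: the placental surface-area ratio relative to term (scales passive
#' diffusion), the total-placental transporter abundance ratio relative to
#' term (scales active efflux), and the gestational-age blood flows that cap
#' passive transfer.
#'
#' @param gw Gestational week.
#' @param surface_area_ratio Placental surface area as a fraction of term.
#' @param total_pgp_abundance_ratio Total placental P-gp abundance as a
#'   fraction of term.
#' @param q_placenta_maternal,q_umbilical Blood flows at this GA (l/h).
#' @return Object of class `gestational_scalers`.
#' @export
gestational_scalers <- function(gw, surface_area_ratio,
                                total_pgp_abundance_ratio,
                                q_placenta_maternal,
                                q_umbilical = q_placenta_maternal) {
  stopifnot(surface_area_ratio > 0, total_pgp_abundance_ratio > 0,
            q_placenta_maternal >= 0, q_umbilical >= 0)
  structure(list(gw = gw, surface_area_ratio = surface_area_ratio,
                 total_pgp_abundance_ratio = total_pgp_abundance_ratio,
                 q_placenta_maternal = q_placenta_maternal,
                 q_umbilical = q_umbilical),
            class = "gestational_scalers")
}

#' Default gestational-age physiology table
#'
#' Two anchor rows: term (GW38; flows 45 l/h, ratios 1) and GW20 (flow
#' 27.5 l/h, total-abundance ratio 0.60, surface-area ratio 0.39 -- the
#' surface-area ratio is derived by back-calculation from published term/GW20
#' passive-clearance pairs, not itself a printed value). Users supply their
#' own table for other physiologies.
#'
#' @return `data.frame` with columns `gw`, `sa_ratio`, `abundance_ratio`,
#'   `q_mp_lph`, `q_uv_lph`, `v_placenta_l`, `v_fetal_l`.
#' @export
default_ga_table <- function() {
  data.frame(
    gw = c(20, 38),
    sa_ratio = c(0.39, 1),
    abundance_ratio = c(0.60, 1),
    q_mp_lph = c(27.5, 45),
    q_uv_lph = c(27.5, 45),
    v_placenta_l = c(0.17, 0.64),
    v_fetal_l = c(1, 5))
}

#' Interpolate gestational-age scalers from a physiology table
#'
#' Linear interpolation between table rows; outside `[min(gw), max(gw)]` the
#' edge row is used with an extrapolation warning (fetal physiology is not
#' reliably tabulated before GW20).
#'
#' @param gw Target gestational week.
#' @param table A table shaped like [default_ga_table()].
#' @return A [gestational_scalers()] with attribute `"volumes"` =
#'   `c(v_placenta_l, v_fetal_l)`.
#' @export
ga_scalers_at <- function(gw, table = default_ga_table()) {
  table <- as.data.frame(table)
  need <- c("gw", "sa_ratio", "abundance_ratio", "q_mp_lph", "q_uv_lph")
  if (!all(need %in% names(table)))
    stop("GA table is missing column(s): ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (gw < min(table$gw) || gw > max(table$gw))
    warning(sprintf("GW%g is outside the tabulated range [%g, %g]: using %s",
                    gw, min(table$gw), max(table$gw),
                    "the edge row (extrapolation)"))
  ip <- function(col) stats::approx(table$gw, table[[col]], xout = gw,
                                    rule = 2)$y
  sc <- gestational_scalers(gw, ip("sa_ratio"), ip("abundance_ratio"),
                            ip("q_mp_lph"), ip("q_uv_lph"))
  vols <- c(v_placenta_l = if ("v_placenta_l" %in% names(table))
    ip("v_placenta_l") else NA_real_,
    v_fetal_l = if ("v_fetal_l" %in% names(table)) ip("v_fetal_l")
    else NA_real_)
  attr(sc, "volumes") <- vols
  sc
}

#' Scale the placental passive diffusion clearance to a gestational age
#'
#' Passive diffusion clearance tracks placental surface area:
#' `intrinsic = term * sa_ratio`; the operative clearance is capped by the
#' GA maternal placental flow: `effective = min(intrinsic, q)`.
#'
#' @param term_cl_int_pd Term intrinsic passive clearance (l/h).
#' @param scalers A [gestational_scalers()].
#' @return List `intrinsic`, `effective` (l/h).
#' @export
scale_clpd <- function(term_cl_int_pd, scalers) {
  stopifnot(term_cl_int_pd > 0, inherits(scalers, "gestational_scalers"))
  intrinsic <- term_cl_int_pd * scalers$surface_area_ratio
  list(intrinsic = intrinsic,
       effective = effective_pd_clearance(intrinsic,
                                          scalers$q_placenta_maternal))
}

#' Scale the placental efflux clearance to a gestational age
#'
#' Active efflux tracks the total transporter abundance of the whole
#' placenta: `term * abundance_ratio`.
#'
#' @param term_cl_pm Term efflux clearance (l/h).
#' @param scalers A [gestational_scalers()].
#' @return Scaled efflux clearance (l/h).
#' @export
scale_clpgp <- function(term_cl_pm, scalers) {
  stopifnot(term_cl_pm > 0, inherits(scalers, "gestational_scalers"))
  term_cl_pm * scalers$total_pgp_abundance_ratio
}

#' Rebuild a term parameter set at another gestational age
#'
#' @param params_term Term [pbpk_params()].
#' @param scalers A [gestational_scalers()]; when produced by
#'   [ga_scalers_at()] its volume attribute is applied too.
#' @param v_placenta,v_fetal Optional explicit GA volumes (l).
#' @return A `pbpk_params` at the target GA.
#' @export
params_at_ga <- function(params_term, scalers, v_placenta = NULL,
                         v_fetal = NULL) {
  stopifnot(inherits(params_term, "pbpk_params"),
            inherits(scalers, "gestational_scalers"))
  p <- unclass(params_term)
  p$cl_int_pd_placenta <- params_term$cl_int_pd_placenta *
    scalers$surface_area_ratio
  p$cl_pm <- params_term$cl_pm * scalers$total_pgp_abundance_ratio
  p$q_placenta_maternal <- scalers$q_placenta_maternal
  p$q_umbilical <- scalers$q_umbilical
  vols <- attr(scalers, "volumes")
  if (!is.null(v_placenta)) p$v_placenta <- v_placenta
  else if (!is.null(vols) && is.finite(vols[["v_placenta_l"]]))
    p$v_placenta <- vols[["v_placenta_l"]]
  if (!is.null(v_fetal)) p$v_fetal <- v_fetal
  else if (!is.null(vols) && is.finite(vols[["v_fetal_l"]]))
    p$v_fetal <- vols[["v_fetal_l"]]
  p$gw <- scalers$gw
  class(p) <- "pbpk_params"
  p
}

#' Project the steady-state Kp,uu to another gestational age
#'
#' Rescales the term clearances (surface area for passive, total transporter
#' abundance for efflux), applies GA flows and volumes, simulates to steady
#' state at the GA and at term, and reports the GA Kp,uu together with the
#' GA-to-term ratios of the maternal and fetal steady-state AUCs.
#'
#' @param params_term Term [pbpk_params()] including the term `cl_pm` (from
#'   a fit or from an ER-REF prediction via [er_from_kpuu()] arithmetic).
#' @param scalers A [gestational_scalers()].
#' @param regimen [dose_regimen()] used for both simulations.
#' @param ... Passed to [params_at_ga()].
#' @return List `kpuu_ga`, `kpuu_term`, `auc_maternal_ratio`,
#'   `auc_fetal_ratio` (GA / term), `sim_ga`, `params_ga`.
#' @export
project_kpuu_at_ga <- function(params_term, scalers, regimen, ...) {
  p_ga <- params_at_ga(params_term, scalers, ...)
  sim_term <- simulate_mf_pbpk(params_term, regimen, dt_out = 0.1)
  sim_ga <- simulate_mf_pbpk(p_ga, regimen, dt_out = 0.1)
  k_term <- kpuu_from_simulation(sim_term)
  k_ga <- kpuu_from_simulation(sim_ga)
  list(kpuu_ga = k_ga$kpuu, kpuu_term = k_term$kpuu,
       auc_maternal_ratio = k_ga$auc_maternal_ss / k_term$auc_maternal_ss,
       auc_fetal_ratio = k_ga$auc_fetal_ss / k_term$auc_fetal_ss,
       sim_ga = sim_ga, params_ga = p_ga)
}
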