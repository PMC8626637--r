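#' Write Transwell experiments to a long-format plate CSV
#'
#' One row per (compartment, time point). Columns carry explicit units:
#' `time_min`, `conc_uM`, `sampled_volume_ml`.
#'
#' @param experiments List of [transwell_experiment()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(experiments, path) {
  if (inherits(experiments, "transwell_experiment"))
    experiments <- list(experiments)
  rows <- lapply(experiments, function(e) {
    rbind(
      data.frame(drug = e$drug, experiment_id = e$replicate_id,
                 direction = e$direction, inhibitor = e$inhibitor,
                 compartment = "receiver", time_min = e$receiver_samples$time_min,
                 conc_uM = e$receiver_samples$conc_uM,
                 sampled_volume_ml = e$receiver_samples$sampled_volume_ml,
                 well = "w1"),
      data.frame(drug = e$drug, experiment_id = e$replicate_id,
                 direction = e$direction, inhibitor = e$inhibitor,
                 compartment = "donor", time_min = e$donor_samples$time_min,
                 conc_uM = e$donor_samples$conc_uM,
                 sampled_volume_ml = e$donor_samples$sampled_volume_ml,
                 well = "w1"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load Transwell experiments from a long-format plate CSV
#'
#' Expects columns `drug`, `experiment_id`, `direction` (`A2B`/`B2A`),
#' `inhibitor` (`none`/`pgp_inhibitor`/`bcrp_inhibitor`), `compartment`
#' (`donor`/`receiver`), `time_min`, `conc_uM`, `sampled_volume_ml`, `well`.
#' Replicate wells within one experiment are averaged at the concentration
#' level before any permeability computation. Hard validation errors name
#' the offending row.
#'
#' @param path CSV path.
#' @param layout List of geometry defaults: `insert_area` (cm^2),
#'   `apical_volume`, `basal_volume` (ml); optionally `qc`, a `data.frame`
#'   with `experiment_id`, `ly_papp` to attach monolayer QC values.
#' @return Named list of [transwell_experiment()]s, keyed
#'   `drug/experiment_id/direction/inhibitor`.
#' @export
load_plate_csv <- function(path, layout = list()) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  layout <- utils::modifyList(
    list(insert_area = 1.12, apical_volume = 0.5, basal_volume = 1,
         qc = NULL), layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "experiment_id", "direction", "inhibitor", "compartment",
            "time_min", "conc_uM", "sampled_volume_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$well)) df$well <- "w1"
  bad <- which(!df$direction %in% c("A2B", "B2A"))
  if (length(bad)) stop("unknown direction token at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$inhibitor %in% c("none", "pgp_inhibitor", "bcrp_inhibitor"))
  if (length(bad)) stop("unknown inhibitor token at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$conc_uM < 0)
  if (length(bad)) stop("negative concentration at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  key <- interaction(df$drug, df$experiment_id, df$direction, df$inhibitor,
                     drop = TRUE, sep = "/")
  out <- list()
  for (k in levels(key)) {
    g <- df[key == k, ]
    # average replicate wells at the concentration level
    agg <- function(comp) {
      gg <- g[g$compartment == comp, ]
      if (!nrow(gg)) return(NULL)
      stats::aggregate(cbind(conc_uM, sampled_volume_ml) ~ time_min,
                       data = gg, FUN = mean)
    }
    rec <- agg("receiver"); don <- agg("donor")
    if (is.null(rec) || is.null(don))
      stop("experiment ", k, " lacks donor or receiver rows")
    dir <- g$direction[1]
    ly <- NA_real_
    if (!is.null(layout$qc)) {
      m <- match(g$experiment_id[1], layout$qc$experiment_id)
      if (!is.na(m)) ly <- layout$qc$ly_papp[m]
    }
    out[[k]] <- tryCatch(
      transwell_experiment(
        drug = g$drug[1], direction = dir, inhibitor = g$inhibitor[1],
        insert_area = layout$insert_area,
        donor_volume = if (dir == "A2B") layout$apical_volume else layout$basal_volume,
        receiver_volume = if (dir == "A2B") layout$basal_volume else layout$apical_volume,
        receiver_samples = rec, donor_samples = don, ly_papp = ly,
        replicate_id = as.character(g$experiment_id[1])),
      error = function(e) stop("experiment ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

#' Efflux-ratio table from a set of loaded experiments
#'
#' Pairs the two directions within each (drug, experiment, inhibitor) cell,
#' computes the efflux ratio, then differences the inhibitor states into the
#' transporter-mediated ER per experiment.
#'
#' @param experiments Named list from [load_plate_csv()].
#' @param control_er Optional positive-control ER applied to all QC gates.
#' @return `data.frame` with one row per drug x experiment:
#'   `er_no_inhibitor`, `er_inhibitor`, `er_pgp`, `papp_a2b_cm_s`,
#'   `papp_b2a_cm_s` (no-inhibitor pair), `qc_pass`.
#' @export
er_table <- function(experiments, control_er = NA_real_) {
  meta <- do.call(rbind, lapply(names(experiments), function(k) {
    e <- experiments[[k]]
    data.frame(key = k, drug = e$drug, experiment_id = e$replicate_id,
               direction = e$direction, inhibitor = e$inhibitor)
  }))
  cells <- unique(meta[, c("drug", "experiment_id")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$drug[i]; ex <- cells$experiment_id[i]
    pick <- function(inh, dir) {
      j <- which(meta$drug == d & meta$experiment_id == ex &
                   meta$inhibitor == inh & meta$direction == dir)
      if (length(j) != 1L) return(NULL)
      experiments[[meta$key[j]]]
    }
    er_of <- function(inh) {
      a <- pick(inh, "A2B"); b <- pick(inh, "B2A")
      if (is.null(a) || is.null(b)) return(NULL)
      efflux_ratio(a, b, control_er = control_er)
    }
    er0 <- er_of("none")
    if (is.null(er0)) return(NULL)
    er1 <- er_of("pgp_inhibitor")
    data.frame(drug = d, experiment_id = ex,
               er_no_inhibitor = er0$er,
               er_inhibitor = if (is.null(er1)) NA_real_ else er1$er,
               er_pgp = if (is.null(er1)) NA_real_ else
                 pgp_mediated_er(er0$er, er1$er)$er_pgp,
               papp_a2b_cm_s = er0$papp_a2b, papp_b2a_cm_s = er0$papp_b2a,
               qc_pass = isTRUE(er0$qc$pass) ||
                 (is.na(er0$qc_ly_pass) && is.na(er0$qc_control_pass)))
  })
  do.call(rbind, rows)
}

.file_hash <- function(path) unname(tools::md5sum(path))

#' Run manifest for an output directory
#'
#' Records what produced the outputs: the command, an md5 of the canonical
#' JSON of the configuration, md5 hashes of every input file, the seed, the
#' package version and a timestamp. Re-running with an identical manifest
#' (ignoring the timestamp) reproduces identical numeric outputs.
#'
#' @param command Command label.
#' @param config Configuration list.
#' @param input_files Character vector of input paths.
#' @param seed Integer seed.
#' @return Manifest list.
#' @export
run_manifest <- function(command, config, input_files = character(),
                         seed = NA_integer_) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  on.exit(unlink(tf))
  list(command = command,
       config_hash = .file_hash(tf),
       input_hashes = as.list(stats::setNames(
         vapply(input_files, .file_hash, character(1)),
         basename(input_files))),
       seed = seed,
       package_version = as.character(utils::packageVersion("fetalkp")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the end-to-end prediction pipeline
#'
#' Stages: (1) `er` -- reduce plate data to per-experiment efflux ratios;
#' (2) `kpuu` -- join in vitro abundances, compute REF-scaled per-experiment
#' and mean Kp,uu with a Monte-Carlo 90% interval; (3) optionally `simulate`
#' a maternal-fetal parameter set and, when observations are supplied, `fit`
#' the placental efflux clearance; (4) optionally `scale_ga` the result to
#' another gestational age. Writes `er_results.csv`,
#' `kpuu_predictions.csv`, `report.json` and `manifest.json` to `out_dir`.
#' Any stage failure aborts with a stage-tagged message.
#'
#' @param config Configuration list, or path to a JSON file with the same
#'   structure: `plate` (`file`, optional `layout`, optional `control_er`),
#'   `abundance` (`file` with columns `drug`, `experiment_id`,
#'   `invitro_abundance_pmol_mg`; `invivo_mean`, `invivo_sd`), `seed`,
#'   optional `pbpk` (`params`, `regimen`, optional `obs_file`, optional
#'   `bracket`), optional `ga` (`gw`, optional `table_file`).
#' @param out_dir Output directory (created if absent).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  inputs <- character()

  ## stage er
  ert <- stage("er", {
    if (is.null(config$plate$file)) stop("config$plate$file is required")
    inputs <<- c(inputs, config$plate$file)
    exps <- load_plate_csv(config$plate$file,
                           layout = config$plate$layout %||% list())
    er_table(exps, control_er = config$plate$control_er %||% NA_real_)
  })
  utils::write.csv(ert, file.path(out_dir, "er_results.csv"),
                   row.names = FALSE)

  ## stage kpuu
  preds <- stage("kpuu", {
    ab <- config$abundance
    if (is.null(ab$file)) stop("config$abundance$file is required")
    if (!file.exists(ab$file)) stop("abundance file not found: ", ab$file)
    inputs <<- c(inputs, ab$file)
    abd <- utils::read.csv(ab$file, stringsAsFactors = FALSE)
    need <- c("drug", "experiment_id", "invitro_abundance_pmol_mg")
    if (!all(need %in% names(abd)))
      stop("abundance file missing column(s): ",
           paste(setdiff(need, names(abd)), collapse = ", "))
    merged <- merge(ert, abd, by = c("drug", "experiment_id"))
    if (!nrow(merged)) stop("no overlap between ER table and abundances")
    lapply(split(merged, merged$drug), function(g) {
      summarize_prediction(
        data.frame(er_pgp = g$er_pgp,
                   invitro_abundance = g$invitro_abundance_pmol_mg),
        in_vivo = ab$invivo_mean, in_vivo_sd = ab$invivo_sd %||% 0,
        seed = seed)
    })
  })
  kp_tab <- do.call(rbind, lapply(names(preds), function(d) {
    p <- preds[[d]]
    data.frame(drug = d, kpuu_mean = p$kpuu_point,
               kpuu_mean_alt = p$kpuu_point_alt,
               ci90_low = p$ci90_low, ci90_high = p$ci90_high,
               ft_pgp = p$ft_pgp, n_experiments = p$n_experiments)
  }))
  utils::write.csv(kp_tab, file.path(out_dir, "kpuu_predictions.csv"),
                   row.names = FALSE)

  report <- list(
    seed = seed,
    er = ert,
    kpuu = kp_tab,
    per_experiment = lapply(preds, function(p) p$per_experiment))

  ## optional PBPK stages
  if (!is.null(config$pbpk)) {
    pb <- config$pbpk
    sim_res <- stage("simulate", {
      params <- do.call(pbpk_params, pb$params)
      regimen <- do.call(dose_regimen, pb$regimen)
      sim <- simulate_mf_pbpk(params, regimen)
      k <- kpuu_from_simulation(sim)
      list(params = params, regimen = regimen,
           kpuu_sim = k$kpuu, auc_maternal_ss = k$auc_maternal_ss,
           auc_fetal_ss = k$auc_fetal_ss,
           mass_balance_error = sim$mass_balance_error)
    })
    report$simulate <- sim_res[c("kpuu_sim", "auc_maternal_ss",
                                 "auc_fetal_ss", "mass_balance_error")]
    if (!is.null(pb$obs_file)) {
      report$fit <- stage("fit", {
        inputs <- c(inputs, pb$obs_file)
        obs <- utils::read.csv(pb$obs_file, stringsAsFactors = FALSE)
        fit <- fit_clpm(obs, sim_res$params, sim_res$regimen,
                        bracket = pb$bracket %||% c(0.1, 1e5))
        fit[c("cl_pm_hat", "aafe_at_fit", "aafe_passive_only",
              "kpuu_invivo", "n_obs", "convergence")]
      })
    }
    if (!is.null(config$ga)) {
      report$scale_ga <- stage("scale_ga", {
        tab <- if (!is.null(config$ga$table_file)) {
          inputs <- c(inputs, config$ga$table_file)
          utils::read.csv(config$ga$table_file)
        } else default_ga_table()
        sc <- ga_scalers_at(config$ga$gw, tab)
        p_term <- sim_res$params
        if (!is.null(report$fit)) p_term$cl_pm <- report$fit$cl_pm_hat
        pj <- project_kpuu_at_ga(p_term, sc, sim_res$regimen)
        pj[c("kpuu_ga", "kpuu_term", "auc_maternal_ratio",
             "auc_fetal_ratio")]
      })
    }
  }

  manifest <- run_manifest("run_pipeline", config, unique(inputs), seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
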