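# End-to-end orchestration: simulate -> mask -> metrics -> point-process
# fit -> cohort assembly -> regressions / biomarker scan, with a JSON
# config, deterministic seeding, stage skipping, and a hashed manifest.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    outdir = "emphymap-run",
    simulate = list(n_subjects = 20L, n_imaging_subjects = 5L,
                    subject = list(n_slices = 4L, k_rate = 15, w = 80,
                                   sigma = 2.5, noise_share = 0.2)),
    thresholds = list(laa = -950, gas_trapping = -856),
    min_lung_voxels = 100L,
    connectivity = "faces",
    power_law = list(x_min_policy = "fixed", method = "discrete-MLE",
                     x_min = 1L),
    mcmc = list(n_iter = 1500L, burn_in = 500L, thin = 5L),
    ridge_method = "KGM",
    fdr = 0.10)
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults))
      stop("unknown config key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be an object")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a JSON file (or takes a list), fills defaults, and checks
#' vocabulary-valued fields. Unknown keys are errors, and a configuration
#' without a seed is rejected before any stage runs: every stochastic
#' stage must be reproducible.
#'
#' @param config Path to a JSON config file, or a named list.
#' @param quiet Suppress the echo of the filled configuration.
#' @return Object of class `run_config` (the filled configuration list).
#' @export
validate_config <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("'config' must be a file path or a list")
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$seed)) stop("config must specify an integer 'seed'")
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$connectivity %in% c("faces", "faces-edges", "faces-edges-corners"))
    stop("invalid 'connectivity': ", cfg$connectivity)
  if (!cfg$power_law$x_min_policy %in% c("fixed", "ks"))
    stop("invalid power_law 'x_min_policy': ", cfg$power_law$x_min_policy)
  if (!cfg$power_law$method %in% c("discrete-MLE", "continuous-MLE"))
    stop("invalid power_law 'method': ", cfg$power_law$method)
  if (!cfg$ridge_method %in% c("KGM", "HK", "HKB", "LW", "KAM", "KMED",
                               "MK-max", "MK-gm"))
    stop("invalid 'ridge_method': ", cfg$ridge_method)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("'fdr' must be in (0, 1)")
  if (cfg$mcmc$burn_in >= cfg$mcmc$n_iter)
    stop("mcmc burn_in must be smaller than n_iter")
  cfg <- structure(cfg, class = "run_config")
  if (!quiet) {
    message("run configuration (defaults filled):")
    message(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE))
  }
  cfg
}

#' Write a configuration back to JSON
#'
#' Round-trips losslessly through [validate_config()].
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: cohort simulation, imaging-subject
#' simulation, masking + whole-lung metrics (%LAA, D, NJC), per-slice
#' point-process fits aggregated to subject level, covariate-adjusted
#' univariate and ridge regressions on the cohort, and the biomarker scan.
#' Stages whose outputs already exist under the same configuration hash
#' are skipped. Every artifact is listed in `manifest.json` with its MD5
#' hash; any stage failure aborts with the failing stage named.
#'
#' @param config A `run_config` from [validate_config()], a list, or a
#'   JSON path.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config, quiet = TRUE)
  cfg <- config
  hash <- config_hash(cfg)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message("[emphymap] ", ...)
  prev <- file.path(out, "manifest.json")
  prev_hash <- if (file.exists(prev))
    tryCatch(jsonlite::read_json(prev)$config_hash, error = function(e) NULL)
  fresh <- !identical(prev_hash, hash)
  up_to_date <- function(paths) !fresh && all(file.exists(paths))
  run_stage <- function(name, outputs, fun) {
    if (up_to_date(outputs)) {
      note("stage '", name, "' up to date; skipped")
      return(invisible(NULL))
    }
    note("stage '", name, "' running")
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- cohort simulation -------------------------------------------------
  cohort_csv <- file.path(out, "cohort.csv")
  markers_csv <- file.path(out, "markers.csv")
  lloq_csv <- file.path(out, "lloq.csv")
  run_stage("cohort", c(cohort_csv, markers_csv, lloq_csv), function() {
    sim <- simulate_cohort(cohort_spec(n_subjects = cfg$simulate$n_subjects),
                           seed = cfg$seed)
    utils::write.csv(sim$cohort, cohort_csv, row.names = FALSE)
    utils::write.csv(sim$biomarkers, markers_csv, row.names = FALSE)
    utils::write.csv(sim$lloq, lloq_csv, row.names = FALSE)
  })

  # --- imaging subjects, masks, whole-lung + point-process metrics -------
  metrics_tsv <- file.path(out, "imaging_metrics.tsv")
  sim_dir <- file.path(out, "sim")
  run_stage("imaging", metrics_tsv, function() {
    dir.create(sim_dir, showWarnings = FALSE)
    ss <- cfg$simulate$subject
    sub_spec <- subject_sim_spec(n_slices = ss$n_slices, k_rate = ss$k_rate,
                                 w = ss$w, sigma = ss$sigma,
                                 noise_share = ss$noise_share)
    chain <- sncp_chain(n_iter = cfg$mcmc$n_iter, burn_in = cfg$mcmc$burn_in,
                        thin = cfg$mcmc$thin)
    rows <- lapply(seq_len(cfg$simulate$n_imaging_subjects), function(i) {
      sub_seed <- (cfg$seed + 1000L * i) %% .Machine$integer.max
      sub <- simulate_subject(sub_spec, seed = sub_seed)
      id <- sprintf("I%03d", i)
      write_volume(sub$ct, file.path(sim_dir, paste0(id, "_ct.nii.gz")))
      write_volume(sub$lung, file.path(sim_dir, paste0(id, "_lung.nii.gz")))
      laa <- make_threshold_mask(sub$ct, sub$lung, cfg$thresholds$laa)
      write_volume(laa, file.path(sim_dir, paste0(id, "_laa.nii.gz")))
      pct <- compute_pct_laa(laa, sub$lung)
      lab <- label_connected_components(laa, cfg$connectivity)
      pl <- fit_power_law(cluster_size_distribution(lab),
                          x_min_policy = cfg$power_law$x_min_policy,
                          method = cfg$power_law$method,
                          x_min = cfg$power_law$x_min)
      jc <- compute_join_counts(laa, sub$lung, cfg$connectivity)
      pats <- extract_slice_patterns(laa, sub$lung, cfg$min_lung_voxels)
      sums <- lapply(seq_along(pats), function(k)
        summarize_slice(fit_sncp_slice(pats[[k]], chain = chain,
                                       seed = sub_seed + k), pats[[k]]))
      prof <- aggregate_subject(sums, subject_id = id,
                                scalars = list(pct_laa = pct, d = pl$d,
                                               njc = jc$njc))
      data.frame(subject_id = id, pct_laa = pct, d = pl$d, njc = jc$njc,
                 nc = prof$nc_rate, acs = prof$acs,
                 pct_diffuse = prof$pct_diffuse, aca = prof$aca,
                 n_slices = prof$n_slices)
    })
    utils::write.table(do.call(rbind, rows), metrics_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })

  # --- regressions -------------------------------------------------------
  uni_tsv <- file.path(out, "univariate.tsv")
  ridge_tsv <- file.path(out, "ridge.tsv")
  adjr2_tsv <- file.path(out, "adj_r2.tsv")
  run_stage("regress", c(uni_tsv, ridge_tsv, adjr2_tsv), function() {
    cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
    tabs <- cohort_regressions(cohort, ridge_method = cfg$ridge_method)
    utils::write.table(tabs$univariate, uni_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(tabs$ridge, ridge_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(tabs$adj_r2, adjr2_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })

  # --- biomarker scan ----------------------------------------------------
  scan_tsv <- file.path(out, "biomarker_scan.tsv")
  run_stage("biomarkers", scan_tsv, function() {
    cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
    raw <- utils::read.csv(markers_csv, stringsAsFactors = FALSE)
    lloq <- utils::read.csv(lloq_csv, stringsAsFactors = FALSE)
    scan <- run_ehp_biomarker_scan(cohort, preprocess_biomarkers(raw, lloq),
                                   fdr = cfg$fdr)
    utils::write.table(scan$results, scan_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })

  artifacts <- c(cohort_csv, markers_csv, lloq_csv, metrics_tsv,
                 uni_tsv, ridge_tsv, adjr2_tsv, scan_tsv,
                 list.files(sim_dir, full.names = TRUE))
  artifacts <- artifacts[file.exists(artifacts)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("emphymap")),
    config = unclass(cfg),
    config_hash = hash,
    seed = cfg$seed,
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("pipeline complete: ", length(artifacts), " artifacts in ", out)
  invisible(manifest)
}

#' Univariate and ridge regression tables for a cohort
#'
#' For each clinical outcome: one covariate-adjusted univariate model per
#' metric; one ridge model over {%LAA, D, NJC, ACS}; and the adjusted-R^2
#' comparison of that ridge model against the one without ACS.
#'
#' @param cohort Cohort data frame (see [simulate_cohort()]).
#' @param outcomes Character vector of outcome columns.
#' @param metrics Character vector of metric columns.
#' @param ridge_method Ridge-k estimator tag.
#' @return List of data frames: `univariate`, `ridge`, `adj_r2`.
#' @export
cohort_regressions <- function(cohort,
                               outcomes = c("fev1", "fvc", "fev1_fvc", "frc",
                                            "frc_tlc", "mwd6", "sgrq",
                                            "pct_gt"),
                               metrics = c("pct_laa", "d", "njc", "acs", "nc",
                                           "pct_diffuse", "aca"),
                               ridge_method = "KGM") {
  covs <- covariate_frame(cohort)
  z <- as.data.frame(lapply(cohort[metrics], function(x) log_standardize(x)$z))
  uni <- do.call(rbind, lapply(outcomes, function(o) {
    do.call(rbind, lapply(metrics, function(m) {
      r <- fit_univariate(cohort[[o]], z[[m]], covs)
      data.frame(outcome = o, metric = m, coef = r$coef, se = r$se,
                 p_value = r$p_value, r_squared = r$r_squared, n = r$n)
    }))
  }))
  four <- c("pct_laa", "d", "njc", "acs")
  ridge <- do.call(rbind, lapply(outcomes, function(o) {
    X <- data.frame(z[four], covs)
    cc <- stats::complete.cases(data.frame(y = cohort[[o]], X))
    k <- estimate_ridge_k(scale(as.matrix(X[cc, ])), cohort[[o]][cc],
                          method = ridge_method)
    fit <- fit_ridge(cohort[[o]][cc], X[cc, ], k = k)
    co <- fit$coefficients[fit$coefficients$term %in% four, ]
    data.frame(outcome = o, term = co$term, estimate = co$estimate,
               se = co$se, p_value = co$p_value, k = fit$k,
               k_method = ridge_method, adj_r_squared = fit$adj_r_squared)
  }))
  adjr2 <- do.call(rbind, lapply(outcomes, function(o) {
    g <- adjusted_r2_gain(cohort[[o]],
                          data.frame(z[four], covs),
                          data.frame(z[c("pct_laa", "d", "njc")], covs),
                          method = ridge_method)
    data.frame(outcome = o, adj_r2_reduced = g$adj_r2_reduced,
               adj_r2_full = g$adj_r2_full, gain = g$gain)
  }))
  list(univariate = uni, ridge = ridge, adj_r2 = adjr2)
}
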