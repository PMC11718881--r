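#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for recognised fields
#' @return named list
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' @keywords internal
stage_seeds <- function(master, stages) {
  set.seed(master)
  setNames(sample.int(2^31 - 2, length(stages)), stages)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> association -> permutation nulls ->
#' network metrics -> dominance -> synchrony -> space use -> kinship
#' from one configuration list, writing `report.json` plus labelled
#' CSV matrices and a plain-text log to the output directory. Every
#' stochastic stage is seeded from a per-stage substream derived from
#' the master seed, so a rerun with the same configuration is
#' reproducible end to end. Stages whose inputs are absent (e.g. no
#' event file, matrices given without scans) are skipped with a notice
#' in the log.
#'
#' Recognised fields: `seed`; `n_perm` (default 1000); `alpha`
#' (weighted-degree tuning, default 0.5); `preferred_alpha`,
#' `avoided_alpha` (dyad thresholds 0.05/0.95); `output_dir`; either a
#' `simulate` block (arguments for [synth_config()]) or input paths
#' `scans`, `pairs`, `events`, `obslog`, `pedigree`; `use_fixtures =
#' TRUE` analyses the packaged worked-example matrices instead of scan
#' data; `cutover_day` splits enclosure-availability periods.
#'
#' @param config named list (or path handled by
#'   [read_pipeline_config()])
#' @return invisibly, the report list
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  n_perm <- config$n_perm %||% 1000
  alpha <- config$alpha %||% 0.5
  pa <- config$preferred_alpha %||% 0.05
  av <- config$avoided_alpha %||% 0.95
  if (pa <= 0 || pa >= 1 || av <= 0 || av >= 1)
    stop("classification thresholds must lie in (0, 1)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  seed <- config$seed %||% 1
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- stage_seeds(seed, c("simulate", "null_models", "network",
                               "dominance", "synchrony"))
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  say("master seed: %d; n_perm: %d; wd alpha: %.2f", seed, n_perm, alpha)

  scans <- events <- log <- NULL
  report <- list(config = list(seed = seed, n_perm = n_perm, alpha = alpha,
                               preferred_alpha = pa, avoided_alpha = av,
                               permutation_scheme = "cumulative day-restricted swap chain, no burn-in",
                               bsi_denominator = "jaccard (per-activity)"))
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seeds[["simulate"]]
    sim <- do.call(synth_config, sim_args)
    gen <- synth_generate(sim)
    scans <- gen$scans; events <- gen$events; log <- gen$log
    report$truth <- list(
      membership = as.list(gen$truth$true_partition$membership))
    say("simulate: %d individuals, %d scans", length(scans$ids),
        n_scan_samples(scans))
  } else if (!is.null(config$scans)) {
    scans <- read_scan_dataset(config$scans, config$pairs)
    say("loaded scans: %d records", nrow(scans$scans))
    if (!is.null(config$events)) events <- read_events(config$events)
    if (!is.null(config$obslog))
      log <- obs_log(read.csv(config$obslog, stringsAsFactors = FALSE))
  }

  ai <- NULL
  if (!is.null(scans)) {
    ai <- association_matrix(scans)
    report$association <- list(ai = ai,
                               mean_ai = mean(offdiag_values(ai)),
                               cv_ai = cv_statistic(ai))
    say("association: mean AI %.3f", report$association$mean_ai)
    cvres <- datastream_permute(scans, n_perm = n_perm,
                                seed = seeds[["null_models"]])
    cls <- classify_dyads(scans, n_perm = n_perm,
                          seed = seeds[["null_models"]],
                          preferred_alpha = pa, avoided_alpha = av)
    report$null_models <- list(
      cv_test = list(observed = cvres$observed_stat, p = cvres$p_value,
                     n_perm = cvres$n_perm, seed = cvres$seed),
      dyads = list(n_preferred = sum(cls$dyads$label == "preferred"),
                   n_avoided = sum(cls$dyads$label == "avoided")))
    write.csv(cls$dyads, file.path(out_dir, "dyad_classification.csv"),
              row.names = FALSE)
    say("null models: CV %.3f, p = %.3f", cvres$observed_stat, cvres$p_value)
  } else if (isTRUE(config$use_fixtures)) {
    ai <- load_fixture("ai")
    report$association <- list(ai = ai,
                               mean_ai = mean(offdiag_values(ai)),
                               cv_ai = cv_statistic(ai))
    say("fixtures-only mode: scan-level stages skipped")
  }

  if (!is.null(ai)) {
    part <- detect_communities(ai, seed = seeds[["network"]])
    pq <- partition_pvalue(ai, part, n_perm = min(n_perm, 200),
                           seed = seeds[["network"]])
    wd <- weighted_degree(ai, alpha = alpha)
    as_wd <- assortment_continuous(ai, wd, n_node_perm = n_perm,
                                   seed = seeds[["network"]])
    report$network <- list(
      strength = as.list(node_strength(ai)),
      weighted_degree = as.list(wd),
      partition = part,
      modularity_p = pq$p_value,
      assortment_wd = list(ac = as_wd$ac, p = as_wd$p_value))
    say("network: %d communities, Q = %.3f (p = %.3f)",
        length(unique(part$membership)), part$modularity, pq$p_value)
  }

  if (!is.null(events) && nrow(events) && !is.null(log)) {
    rates <- interaction_rate_matrix(events, log, "affiliative",
                                     ids = scans$ids)
    wm <- win_matrix(events, ids = scans$ids)
    report$interaction <- list(affil_rates = rates,
                               composition = summarise_events(events)$by_role)
    if (sum(dyad_values(wm)) > 0) {
      dom <- landau_h_prime(wm, n_rand = n_perm, seed = seeds[["dominance"]])
      report$dominance <- list(win_matrix = wm,
                               davids_scores = as.list(dom$davids_scores),
                               h_prime = dom$h_prime,
                               p_linearity = dom$p_linearity)
      say("dominance: h' = %.3f (p = %.3f)", dom$h_prime, dom$p_linearity)
    }
  } else {
    say("no events/obslog: dominance and interaction-rate stages skipped")
  }

  if (!is.null(scans)) {
    bs <- bsi_null(scans, n_perm = min(n_perm, 500),
                   seed = seeds[["synchrony"]])
    report$synchrony <- list(
      bsi = bs$observed,
      mean_bsi = bs$mean_result$observed_stat,
      mean_p = bs$mean_result$p_value)
    if (!is.null(report$network)) {
      cs <- cluster_synchrony(bs$observed, report$network$partition,
                              n_perm = n_perm, seed = seeds[["synchrony"]])
      report$synchrony$within_mean <- cs$within_mean
      report$synchrony$between_mean <- cs$between_mean
      report$synchrony$difference_p <- cs$p_value
    }
    tb <- time_budget(scans)
    write.csv(tb, file.path(out_dir, "time_budget.csv"), row.names = FALSE)
    if (any(!is.na(scans$scans$zone) & scans$scans$zone != "")) {
      sp <- space_use_profile(scans)
      report$space_use <- list(spi = as.list(sp$spi))
      write.csv(sp$ei, file.path(out_dir, "electivity.csv"),
                row.names = FALSE)
    }
    if (!is.null(report$network)) {
      mt <- scan_model_table(scans, report$network$partition,
                             cutover_day = config$cutover_day)
      write.csv(mt, file.path(out_dir, "scan_model_table.csv"),
                row.names = FALSE)
    }
    say("synchrony: mean BSI %.3f (p = %.3f)",
        report$synchrony$mean_bsi, report$synchrony$mean_p)
  }

  if (!is.null(config$pedigree)) {
    ped <- read_pedigree(config$pedigree)
    kin_ids <- if (!is.null(scans)) intersect(scans$ids, ped$id) else ped$id
    kin <- kinship_matrix(ped, kin_ids)
    report$kinship <- list(kinship = kin)
    if (!is.null(ai) && setequal(dyad_ids(ai), kin_ids)) {
      mt <- mantel_test(ai, kin, n_perm = n_perm,
                        seed = seeds[["network"]])
      report$kinship$mantel_ai_r <- mt$observed_stat
      report$kinship$mantel_ai_p <- mt$p_value
    }
    say("kinship: %d individuals", length(kin_ids))
  }

  write_report(report, file.path(out_dir, "report.json"))
  say("report written")
  invisible(report)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
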