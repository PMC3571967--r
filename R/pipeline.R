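#' Run the full stress-transcriptome pipeline on synthetic data
#'
#' Chains every stage — simulation, detection filtering, log/baseline
#' transformation, single-factor differential-expression calls, the
#' interaction screen, longitudinal model-based clustering under both
#' nitrogen regimes, and the trend comparison — from a single
#' configuration, returning all intermediate results plus the summary
#' tables and a machine-readable run report.
#'
#' @param config a [sim_config()] (or path to a YAML config file).
#' @param detection_threshold raw-signal detection threshold (default 20).
#' @param fc_de fold-change filter for the single-factor calls (default 2).
#' @param fc_interaction fold-change prescreen for the interaction stage
#'   (default 2).
#' @param fc_cluster_opt,fc_cluster_lim profile prescreen thresholds for
#'   the clustering stage under optimal (default 3) and limiting
#'   (default 2) nitrogen.
#' @param alpha FDR / significance level (default 0.05).
#' @param G_range candidate component counts for BIC selection
#'   (default 1..8).
#' @param n_restarts EM restarts per fit (default 10).
#' @param cluster_organ organ used for the clustering and trend stages
#'   (default: the first simulated organ); DE and interaction stages run
#'   on every simulated organ.
#' @return list with elements `sim`, `detected`, `log2b`, `de`,
#'   `interaction`, `fit_opt`, `fit_lim`, `profiles_opt`, `profiles_lim`,
#'   `paired`, `trend`, `trend_summary`, `de_table`, `interaction_table`, `report`.
#' @export
run_pipeline <- function(config = sim_config(),
                         detection_threshold = 20,
                         fc_de = 2, fc_interaction = 2,
                         fc_cluster_opt = 3, fc_cluster_lim = 2,
                         alpha = 0.05, G_range = 1:8, n_restarts = 10L,
                         cluster_organ = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  sim <- simulate_stress_experiment(config)
  meta <- sim$metadata
  organs <- config$organs
  if (is.null(cluster_organ)) cluster_organ <- organs[1L]

  detected <- detection_filter(sim$raw, meta, detection_threshold)
  log2b <- log_and_baseline(sim$raw[detected, , drop = FALSE])

  de <- lapply(stats::setNames(organs, organs), function(o) {
    lapply(stats::setNames(c("nitrogen", "mild_water", "severe_water"),
                           c("nitrogen", "mild_water", "severe_water")),
           function(cmp) de_call(log2b, meta, o, cmp, fc_de, alpha))
  })

  inter <- do.call(rbind, lapply(organs, function(o) {
    interaction_scan(log2b, meta, o, fc_interaction, alpha)
  }))

  profiles_opt <- condition_profiles(log2b, meta, cluster_organ, "optimal")
  profiles_lim <- condition_profiles(log2b, meta, cluster_organ, "limiting")
  keep_opt <- prescreen_profiles(profiles_opt, fc_cluster_opt)
  keep_lim <- prescreen_profiles(profiles_lim, fc_cluster_lim)

  fit_opt <- longmix_select(profiles_opt[keep_opt, , drop = FALSE],
                            G = G_range, n_restarts = n_restarts,
                            seed = config$seed)
  fit_lim <- longmix_select(profiles_lim[keep_lim, , drop = FALSE],
                            G = G_range, n_restarts = n_restarts,
                            seed = config$seed + 1L)

  paired <- paired_profile_set(profiles_opt, profiles_lim,
                               fc_cluster_opt, fc_cluster_lim)
  groups <- stats::setNames(fit_opt$cluster, keep_opt)
  trend <- detect_trend_change(paired, groups = groups,
                               seed = config$seed + 2L,
                               n_restarts = n_restarts)
  trend_summary <- summarize_trends(trend)

  tab1 <- stress_response_table(de, chip_total = config$n_entities)
  tab4 <- interaction_response_table(inter, alpha)

  report <- run_report(
    counts = c(input = config$n_entities,
               detected = length(detected),
               cluster_prescreen_opt = length(keep_opt),
               trend_qualifying = trend_summary$n_qualifying,
               trend_different = trend_summary$n_different),
    params = list(detection_threshold = detection_threshold,
                  fc_de = fc_de, fc_interaction = fc_interaction,
                  fc_cluster_opt = fc_cluster_opt,
                  fc_cluster_lim = fc_cluster_lim, alpha = alpha,
                  G_range = range(G_range), n_restarts = n_restarts,
                  cluster_organ = cluster_organ),
    seed = config$seed)

  list(sim = sim, detected = detected, log2b = log2b, de = de,
       interaction = inter, profiles_opt = profiles_opt,
       profiles_lim = profiles_lim, fit_opt = fit_opt, fit_lim = fit_lim,
       paired = paired, trend = trend, trend_summary = trend_summary,
       de_table = tab1, interaction_table = tab4, report = report)
}
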