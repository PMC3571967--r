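#' Simulation configuration for the factorial stress design
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate the study design the package targets: three organs,
#' two nitrogen regimes, five ordered water conditions and three biological
#' replicates (90 arrays when all organs are simulated), with log2-scale
#' Gaussian replicate noise, planted water-response trajectory clusters,
#' planted nitrogen-by-water interaction effects on the 2x2
#' (nitrogen x optimal/severe water) subdesign, and a fraction of entities
#' whose trajectory shape swaps between nitrogen regimes.
#'
#' @param n_entities number of entities (probe sets) to simulate.
#' @param organs organ labels; any subset of leaf/root/stem (the planted
#'   signal is shared across organs).
#' @param n_replicates replicates per condition (>= 2).
#' @param n_clusters number of planted trajectory shapes (1..8).
#' @param cluster_amplitude amplitude of the trajectory shapes, log2 units.
#' @param noise_sigma SD of i.i.d. Gaussian replicate noise, log2 units.
#' @param frac_interaction fraction of entities with a planted
#'   nitrogen-by-water interaction.
#' @param interaction_effect size of the planted interaction cell-mean
#'   contrast, log2 units (planted as a cross-over pattern with zero
#'   marginal means, so the 2x2 contrast equals this value exactly when
#'   `noise_sigma = 0`).
#' @param frac_trend_change fraction of entities whose trajectory shape
#'   differs between nitrogen regimes (a different planted cluster id).
#' @param frac_nitrogen fraction of entities with a planted nitrogen main
#'   effect.
#' @param nitrogen_effect size of the planted nitrogen main effect, log2
#'   units (random sign per entity).
#' @param baseline_mean mean per-entity baseline expression, log2 units.
#' @param baseline_spread half-width of the uniform per-entity baseline
#'   spread around `baseline_mean`, log2 units.
#' @param raw_floor floor applied to the raw-scale (linear intensity)
#'   export.
#' @param seed RNG seed (integer < 2^31).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_entities = 2000L,
                       organs = c("leaf", "root", "stem"),
                       n_replicates = 3L,
                       n_clusters = 4L,
                       cluster_amplitude = 3,
                       noise_sigma = 0.25,
                       frac_interaction = 0.05,
                       interaction_effect = 1.5,
                       frac_trend_change = 0.1,
                       frac_nitrogen = 0.05,
                       nitrogen_effect = 2,
                       baseline_mean = 8,
                       baseline_spread = 2,
                       raw_floor = 1.0,
                       seed = 1L) {
  cfg <- list(n_entities = as.integer(n_entities),
              organs = as.character(organs),
              n_replicates = as.integer(n_replicates),
              n_clusters = as.integer(n_clusters),
              cluster_amplitude = cluster_amplitude,
              noise_sigma = noise_sigma,
              frac_interaction = frac_interaction,
              interaction_effect = interaction_effect,
              frac_trend_change = frac_trend_change,
              frac_nitrogen = frac_nitrogen,
              nitrogen_effect = nitrogen_effect,
              baseline_mean = baseline_mean,
              baseline_spread = baseline_spread,
              raw_floor = raw_floor,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_entities >= cfg$n_clusters, cfg$n_clusters >= 1L)
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  fr <- c(cfg$frac_interaction, cfg$frac_trend_change, cfg$frac_nitrogen)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!all(cfg$organs %in% c("leaf", "root", "stem"))) {
    stop("organs must be a subset of leaf/root/stem")
  }
  if (abs(cfg$seed) >= 2^31) stop("seed must be a 32-bit integer")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys missing from the file take their `sim_config()` defaults.
#' @param path YAML file of `sim_config` key-value pairs.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Library of planted water-response trajectory shapes
#'
#' Returns `n_clusters` distinct mean trajectories over the five ordered
#' water conditions (optimal, mild stress, severe stress, rewatered 2 h,
#' rewatered 5 h), scaled so that the pairwise L2 distance between any two
#' shapes is at least `amplitude / 2`. The base library holds five canonical
#' responses: flat, monotone decrease, monotone increase, stress-induction
#' with recovery, and stress-repression with recovery. Requests beyond the
#' base library are met by adding seeded smooth perturbations (reported via
#' a message).
#'
#' @param n_clusters number of shapes, 1..8.
#' @param amplitude shape amplitude in log2 units.
#' @param seed seed for the perturbation stream (only used when
#'   `n_clusters > 5`).
#' @return `n_clusters` x 5 matrix of mean trajectories (log2 units).
#' @export
make_cluster_shapes <- function(n_clusters, amplitude, seed = 1L) {
  if (n_clusters < 1L || n_clusters > 8L) stop("n_clusters must be in 1..8")
  base <- rbind(
    flat   = c(0, 0, 0, 0, 0),
    down   = c(0, -0.25, -0.5, -0.75, -1),
    up     = c(0, 0.25, 0.5, 0.75, 1),
    peak   = c(0, 0.5, 1, 0.25, 0),
    trough = c(0, -0.5, -1, -0.25, 0)
  )
  shapes <- base * amplitude
  if (n_clusters > nrow(base)) {
    message("extending the shape library with ", n_clusters - nrow(base),
            " seeded smooth perturbation(s)")
    set.seed(seed)
    k <- 0L
    while (nrow(shapes) < n_clusters && k < 100L) {
      k <- k + 1L
      parent <- shapes[sample.int(nrow(base), 1L), ]
      phase <- stats::runif(1L, 0, 2 * pi)
      freq <- sample(1:2, 1L)
      cand <- parent + 0.75 * amplitude * sin(freq * pi * (0:4) / 4 + phase)
      cand <- cand - cand[1L]  # anchor at the optimal-water condition
      d <- apply(shapes, 1L, function(s) sqrt(sum((s - cand)^2)))
      if (all(d >= amplitude / 2)) {
        shapes <- rbind(shapes, extra = cand)
      }
    }
    if (nrow(shapes) < n_clusters) {
      stop("could not generate ", n_clusters, " shapes with pairwise L2 ",
           "distance >= amplitude/2")
    }
  }
  shapes <- shapes[seq_len(n_clusters), , drop = FALSE]
  colnames(shapes) <- WATER_LEVELS
  shapes
}

#' Simulate a factorial nitrogen-by-water stress expression experiment
#'
#' Generates a raw-intensity and a log2-scale expression matrix with the
#' full factorial column layout (organ x nitrogen x water x replicate), the
#' matching sample metadata, and a ground-truth object recording every
#' planted label. Per entity and condition the log2 mean is
#' baseline + trajectory shape (nitrogen-specific for trend-change
#' entities) + nitrogen main effect + interaction term, and replicates add
#' i.i.d. Gaussian noise. The raw matrix is `2^log2`, floored at
#' `config$raw_floor`. Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `raw` (entities x samples intensity matrix,
#'   scale `"raw"`), `log2` (same layout, scale `"log2"`), `metadata`
#'   (sample table), and `truth` (see Details).
#' @details `truth` contains `labels` (per-entity planted cluster ids under
#'   each nitrogen regime, interaction / trend-change / nitrogen-effect
#'   flags, baselines), `profile_optN` / `profile_limN` (absolute log2
#'   condition-mean 5-vectors), `centered_optN` / `centered_limN` (the same
#'   profiles after the per-entity median-baseline centering the
#'   preprocessing applies, so sigma = 0 runs reproduce them exactly), the
#'   shape library, and the config echo.
#' @export
simulate_stress_experiment <- function(config = sim_config()) {
  cfg <- validate_sim_config(unclass(config))
  n <- cfg$n_entities
  set.seed(cfg$seed)

  shapes <- make_cluster_shapes(cfg$n_clusters, cfg$cluster_amplitude,
                                seed = cfg$seed)
  baseline <- cfg$baseline_mean +
    stats::runif(n, -cfg$baseline_spread, cfg$baseline_spread)
  cluster_opt <- sample.int(cfg$n_clusters, n, replace = TRUE)
  is_trend <- stats::runif(n) < cfg$frac_trend_change & cfg$n_clusters > 1L
  cluster_lim <- cluster_opt
  if (any(is_trend)) {
    # shape swap: a different cluster id under limiting nitrogen
    cluster_lim[is_trend] <- vapply(cluster_opt[is_trend], function(g) {
      sample(setdiff(seq_len(cfg$n_clusters), g), 1L)
    }, integer(1L))
  }
  is_inter <- stats::runif(n) < cfg$frac_interaction
  is_nitro <- stats::runif(n) < cfg$frac_nitrogen
  n_effect <- ifelse(is_nitro, cfg$nitrogen_effect *
                       sample(c(-1, 1), n, replace = TRUE), 0)

  # condition means: 10 columns = (optimal N, limiting N) x water 1..5
  mean_opt <- baseline + shapes[cluster_opt, , drop = FALSE]
  mean_lim <- baseline + n_effect + shapes[cluster_lim, , drop = FALSE]
  # cross-over interaction on the (N x {optimal, severe water}) cells:
  # +e/4 on concordant cells, -e/4 on discordant, zero marginal means
  e4 <- ifelse(is_inter, cfg$interaction_effect / 4, 0)
  mean_opt[, 1L] <- mean_opt[, 1L] + e4
  mean_opt[, 3L] <- mean_opt[, 3L] - e4
  mean_lim[, 1L] <- mean_lim[, 1L] - e4
  mean_lim[, 3L] <- mean_lim[, 3L] + e4

  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      water = seq_along(WATER_LEVELS),
                      nitrogen = NITROGEN_LEVELS,
                      organ = cfg$organs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("organ", "nitrogen", "water", "replicate")]
  meta$sample_id <- sprintf("%s_%sN_W%d_r%d", meta$organ,
                            substr(meta$nitrogen, 1L, 3L), meta$water,
                            meta$replicate)
  n_samp <- nrow(meta)

  entity_ids <- sprintf("ent_%05d", seq_len(n))
  means <- matrix(0, n, n_samp)
  opt_cols <- meta$nitrogen == "optimal"
  means[, opt_cols] <- mean_opt[, meta$water[opt_cols], drop = FALSE]
  means[, !opt_cols] <- mean_lim[, meta$water[!opt_cols], drop = FALSE]
  log2_mat <- means + matrix(stats::rnorm(n * n_samp, 0, cfg$noise_sigma),
                             n, n_samp)
  dimnames(log2_mat) <- list(entity_ids, meta$sample_id)
  expr_scale(log2_mat) <- "log2"

  raw <- pmax(2^log2_mat, cfg$raw_floor)
  expr_scale(raw) <- "raw"

  # center the noiseless condition means exactly as log_and_baseline()
  # centers the data, so sigma = 0 runs match the truth bit-for-bit
  med <- apply(means, 1L, stats::median)
  centered_opt <- mean_opt - med
  centered_lim <- mean_lim - med
  dimnames(mean_opt) <- dimnames(mean_lim) <- dimnames(centered_opt) <-
    dimnames(centered_lim) <- list(entity_ids, WATER_LEVELS)

  labels <- data.frame(entity_id = entity_ids,
                       cluster_opt = cluster_opt,
                       cluster_lim = cluster_lim,
                       is_interaction = is_inter,
                       is_trend_change = is_trend,
                       is_nitrogen = is_nitro,
                       nitrogen_effect = n_effect,
                       baseline = baseline,
                       stringsAsFactors = FALSE)
  truth <- list(labels = labels,
                profile_optN = mean_opt, profile_limN = mean_lim,
                centered_optN = centered_opt, centered_limN = centered_lim,
                shapes = shapes, config = cfg)
  class(truth) <- "synthetic_truth"

  list(raw = raw, log2 = log2_mat,
       metadata = meta[, c("sample_id", "organ", "nitrogen", "water",
                           "replicate")],
       truth = truth)
}

#' Write a simulated experiment to TSV files
#'
#' Writes the raw expression matrix, the sample metadata and the planted
#' truth labels as tab-separated files under `dir`.
#' @param sim result of [simulate_stress_experiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("expression_raw.tsv", "metadata.tsv",
                            "truth.tsv"))
  write_expression_tsv(sim$raw, paths[1L])
  utils::write.table(sim$metadata, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$labels, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read / write an expression matrix as TSV
#'
#' Rows are entity ids, columns sample ids; the first column holds the
#' entity id.
#' @param x expression matrix.
#' @param path file path.
#' @param scale scale flag to attach on read (`"raw"`, `"log2"`,
#'   `"log2-baselined"`).
#' @return `read_expression_tsv` returns the matrix with its scale
#'   attribute set; `write_expression_tsv` returns the path invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(entity_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, scale = "raw") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expr_scale(m) <- scale
  m
}
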