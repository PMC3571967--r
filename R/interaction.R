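#' Four-way fold-change prescreen on the 2x2 nitrogen-by-water subdesign
#'
#' For one organ, computes the four pairwise linear fold changes over the
#' 2x2 subdesign (optimal/limiting nitrogen x optimal water/severe
#' drought): water response under optimal N, nitrogen response under
#' optimal water, nitrogen response under severe drought, and water
#' response under limiting N. An entity is retained when its largest fold
#' change reaches the threshold in at least one of the four comparisons.
#'
#' @param x log2-scale expression matrix.
#' @param metadata sample metadata.
#' @param organ organ to analyse.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @return list with `fc` (data.frame: entity_id, fc_W_optN, fc_N_optW,
#'   fc_N_sevW, fc_W_limN, fc_max — all linear, >= 1) and `retained`
#'   (entity ids with `fc_max >= fc_threshold`).
#' @export
prescreen_fourway <- function(x, metadata, organ, fc_threshold = 2) {
  cells <- list(
    optN_optW = list(organ = organ, nitrogen = "optimal", water = 1L),
    optN_sevW = list(organ = organ, nitrogen = "optimal", water = 3L),
    limN_optW = list(organ = organ, nitrogen = "limiting", water = 1L),
    limN_sevW = list(organ = organ, nitrogen = "limiting", water = 3L))
  cols <- lapply(cells, function(cc) do.call(select_samples,
                                             c(list(metadata), cc)))
  nrep <- vapply(cols, length, integer(1L))
  if (any(nrep < 2L)) {
    stop("missing or under-replicated cell(s): ",
         paste(names(cells)[nrep < 2L], collapse = ", "))
  }
  cm <- vapply(cols, function(s) rowMeans(x[, s, drop = FALSE]),
               numeric(nrow(x)))
  fc <- data.frame(
    entity_id = rownames(x),
    fc_W_optN = 2^abs(cm[, "optN_optW"] - cm[, "optN_sevW"]),
    fc_N_optW = 2^abs(cm[, "optN_optW"] - cm[, "limN_optW"]),
    fc_N_sevW = 2^abs(cm[, "optN_sevW"] - cm[, "limN_sevW"]),
    fc_W_limN = 2^abs(cm[, "limN_optW"] - cm[, "limN_sevW"]),
    row.names = NULL, stringsAsFactors = FALSE)
  fc$fc_max <- pmax(fc$fc_W_optN, fc$fc_N_optW, fc$fc_N_sevW, fc$fc_W_limN)
  list(fc = fc, retained = fc$entity_id[fc$fc_max >= fc_threshold])
}

#' Two-way ANOVA with type-III sums of squares
#'
#' Fits `value ~ nitrogen * water` with sum-to-zero effect coding and
#' returns partial (type-III) F-tests for the nitrogen main effect, the
#' water main effect and their interaction, via [car::Anova()]. Unbalanced
#' replicate counts are supported as long as every cell is non-empty; on
#' balanced data the results coincide with sequential (type-I) sums of
#' squares.
#'
#' @param values numeric response (one entity's log2 signals).
#' @param nitrogen,water factors (or coercible) of the same length; each
#'   must have exactly 2 levels here (the 2x2 subdesign).
#' @return data.frame with rows `nitrogen`, `water`, `nitrogen:water` and
#'   columns `sum_sq`, `df`, `F`, `p`.
#' @export
anova2_type3 <- function(values, nitrogen, water) {
  nitrogen <- factor(nitrogen)
  water <- factor(water)
  if (any(table(nitrogen, water) == 0L)) stop("empty design cell")
  if (length(values) - nlevels(nitrogen) * nlevels(water) < 1L) {
    stop("no residual degrees of freedom")
  }
  dat <- data.frame(y = values, n = nitrogen, w = water)
  out <- data.frame(term = c("nitrogen", "water", "nitrogen:water"),
                    sum_sq = NA_real_, df = NA_real_, F = NA_real_,
                    p = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (nlevels(nitrogen) == 1L || nlevels(water) == 1L) {
    # single-level collapse: one-way model on the remaining factor
    fac <- if (nlevels(water) == 1L) "n" else "w"
    fit <- stats::lm(stats::reformulate(fac, "y"), data = dat)
    aa <- stats::anova(fit)
    row <- if (fac == "n") 1L else 2L
    out[row, 2:5] <- c(aa[fac, "Sum Sq"], aa[fac, "Df"],
                       aa[fac, "F value"], aa[fac, "Pr(>F)"])
    return(out)
  }
  fit <- stats::lm(y ~ n * w, data = dat,
                   contrasts = list(n = "contr.sum", w = "contr.sum"))
  aa <- car::Anova(fit, type = 3)
  rows <- c("n", "w", "n:w")
  out$sum_sq <- aa[rows, "Sum Sq"]
  out$df <- aa[rows, "Df"]
  out$F <- aa[rows, "F value"]
  out$p <- aa[rows, "Pr(>F)"]
  out
}

#' Classify one entity from its ANOVA and pairwise-test p-values
#'
#' Applies the factorial-response rules: an entity is
#' nitrogen-/water-/interaction-responsive when the corresponding
#' BH-adjusted ANOVA p-value is at most `alpha`; it is *exclusively*
#' interaction-responsive when additionally neither pairwise nitrogen
#' t-test nor pairwise water t-test is significant (adjusted p > `alpha`) —
#' its variation over the 2x2 subdesign is explained by the interaction of
#' nitrogen and water status alone.
#'
#' @param p_N_anova,p_W_anova,p_NxW_anova BH-adjusted ANOVA p-values.
#' @param p_N_ttest,p_W_ttest BH-adjusted marginal two-group t-test
#'   p-values (see [interaction_scan()]).
#' @param alpha significance level (default 0.05).
#' @return logical vector: `nitrogen_responsive`, `water_responsive`,
#'   `interaction_responsive`, `exclusive_interaction`.
#' @export
classify_interaction <- function(p_N_anova, p_W_anova, p_NxW_anova,
                                 p_N_ttest, p_W_ttest, alpha = 0.05) {
  ps <- c(p_N_anova, p_W_anova, p_NxW_anova, p_N_ttest, p_W_ttest)
  if (any(is.na(ps))) stop("missing p-value")
  inter <- p_NxW_anova <= alpha
  c(nitrogen_responsive = p_N_anova <= alpha,
    water_responsive = p_W_anova <= alpha,
    interaction_responsive = inter,
    exclusive_interaction = inter && p_N_ttest > alpha && p_W_ttest > alpha)
}

#' Interaction screen for one organ
#'
#' The full two-stage interaction analysis on the 2x2 subdesign: fold
#' change prescreen ([prescreen_fourway()]), per-entity two-way type-III
#' ANOVA plus a marginal equal-variance t-test per factor (each factor's
#' two groups pooled over the other factor),
#' Benjamini-Hochberg correction applied separately to each p-value family
#' within the organ, and classification via [classify_interaction()].
#' Pooling the factor t-tests over the other factor means a pure
#' cross-over interaction — opposite water responses under the two
#' nitrogen regimes, zero marginal means — is left non-significant by
#' both t-tests and so can be flagged as exclusively
#' interaction-responsive.
#'
#' @inheritParams prescreen_fourway
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per retained entity: the adjusted
#'   p-values (`p_N_anova`, `p_W_anova`, `p_NxW_anova`, `p_N_ttest`,
#'   `p_W_ttest`) and the four classification flags.
#' @export
interaction_scan <- function(x, metadata, organ, fc_threshold = 2,
                             alpha = 0.05) {
  pre <- prescreen_fourway(x, metadata, organ, fc_threshold)
  keep <- pre$retained
  if (length(keep) == 0L) {
    warning("no entity passed the fold-change prescreen for ", organ)
    return(data.frame())
  }
  cells <- list(
    optN_optW = list(organ = organ, nitrogen = "optimal", water = 1L),
    optN_sevW = list(organ = organ, nitrogen = "optimal", water = 3L),
    limN_optW = list(organ = organ, nitrogen = "limiting", water = 1L),
    limN_sevW = list(organ = organ, nitrogen = "limiting", water = 3L))
  cols <- lapply(cells, function(cc) do.call(select_samples,
                                             c(list(metadata), cc)))
  samp <- unlist(cols, use.names = FALSE)
  nfac <- factor(rep(c("optimal", "optimal", "limiting", "limiting"),
                     vapply(cols, length, integer(1L))),
                 levels = NITROGEN_LEVELS)
  wfac <- factor(rep(c("optimal", "severe", "optimal", "severe"),
                     vapply(cols, length, integer(1L))),
                 levels = c("optimal", "severe"))
  xs <- x[keep, samp, drop = FALSE]

  an <- t(vapply(seq_len(nrow(xs)), function(i) {
    a <- anova2_type3(xs[i, ], nfac, wfac)
    stats::setNames(a$p, a$term)
  }, numeric(3L)))

  # factor-level two-group t-tests over the 2x2 subdesign: each factor's
  # samples pooled across the other factor, so a pure cross-over
  # interaction (zero marginal means) stays non-significant here
  tt <- list(
    N = row_ttest(x[keep, c(cols$limN_optW, cols$limN_sevW), drop = FALSE],
                  x[keep, c(cols$optN_optW, cols$optN_sevW), drop = FALSE]),
    W = row_ttest(x[keep, c(cols$optN_sevW, cols$limN_sevW), drop = FALSE],
                  x[keep, c(cols$optN_optW, cols$limN_optW), drop = FALSE]))

  adj <- function(p) benjamini_hochberg(p, alpha)$p_adj
  p_N_anova <- adj(an[, "nitrogen"])
  p_W_anova <- adj(an[, "water"])
  p_NxW_anova <- adj(an[, "nitrogen:water"])
  p_N_ttest <- adj(tt$N$p_value)
  p_W_ttest <- adj(tt$W$p_value)

  flags <- t(mapply(classify_interaction, p_N_anova, p_W_anova, p_NxW_anova,
                    p_N_ttest, p_W_ttest, MoreArgs = list(alpha = alpha)))
  data.frame(entity_id = keep, organ = organ,
             p_N_anova = p_N_anova, p_W_anova = p_W_anova,
             p_NxW_anova = p_NxW_anova,
             p_N_ttest = p_N_ttest, p_W_ttest = p_W_ttest,
             nitrogen_responsive = flags[, "nitrogen_responsive"],
             water_responsive = flags[, "water_responsive"],
             interaction_responsive = flags[, "interaction_responsive"],
             exclusive_interaction = flags[, "exclusive_interaction"],
             row.names = NULL, stringsAsFactors = FALSE)
}
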