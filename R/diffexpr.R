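#' Per-entity log2 fold change between two conditions
#'
#' Computes, for every entity, the difference of mean log2 signals between
#' two sample groups (GeneSpring convention: mean of logs, not log of mean
#' ratios), together with the linear fold change (>= 1) and its direction.
#'
#' @param x log2-scale expression matrix.
#' @param metadata sample metadata.
#' @param groupA,groupB lists of design selectors passed to
#'   [select_samples()] (e.g. `list(organ = "leaf", nitrogen = "optimal",
#'   water = 2)`). `groupA` is the treatment, `groupB` the control.
#' @return data.frame with `entity_id`, `log2_fc` (mean A - mean B),
#'   `fc_linear` (`2^|log2_fc|`), `direction` (`"up"`, `"down"`, `"none"`).
#' @export
fold_change <- function(x, metadata, groupA, groupB) {
  if (!expr_scale(x) %in% c("log2", "log2-baselined")) {
    stop("fold_change() expects log2-scale values")
  }
  a <- do.call(select_samples, c(list(metadata), groupA))
  b <- do.call(select_samples, c(list(metadata), groupB))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each condition needs >= 2 replicates (got ", length(a), " and ",
         length(b), ")")
  }
  lfc <- rowMeans(x[, a, drop = FALSE]) - rowMeans(x[, b, drop = FALSE])
  data.frame(entity_id = rownames(x),
             log2_fc = lfc,
             fc_linear = 2^abs(lfc),
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Unpaired equal-variance (pooled) t-test
#'
#' Two-sided Student t-test with pooled variance, the classical
#' equal-variance unpaired test. When the pooled variance is exactly zero
#' the convention is p = 1 if the group means are also equal; zero variance
#' with unequal means is an error (degenerate input).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic` (t), `p_value` (two-sided), `df`.
#' @export
ttest_equal_var <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2L))
    }
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

# vectorised pooled t-test over matrix rows (same convention as
# ttest_equal_var); returns data.frame(statistic, p_value)
row_ttest <- function(ma, mb) {
  na <- ncol(ma); nb <- ncol(mb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  ss_a <- rowSums((ma - mean_a)^2); ss_b <- rowSums((mb - mean_b)^2)
  df <- na + nb - 2L
  pooled <- (ss_a + ss_b) / df
  se <- sqrt(pooled * (1 / na + 1 / nb))
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- pooled == 0
  if (any(zero)) {
    eq <- zero & abs(mean_a - mean_b) < 1e-12
    t[eq] <- 0; p[eq] <- 1
    if (any(zero & !eq)) stop("zero pooled variance with unequal means")
  }
  data.frame(statistic = t, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha FDR level used for the rejection set (default 0.05).
#' @return list with `p_adj` (same order as `p`) and `reject` (logical,
#'   `p_adj <= alpha`).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = adj, reject = adj <= alpha)
}

#' Single-factor differential-expression call
#'
#' The paper-style single-factor screen for one organ: filter entities on a
#' linear fold change >= `fc_threshold` between the two conditions, then
#' test the surviving family with the equal-variance t-test and
#' Benjamini-Hochberg correction at FDR `alpha` (filter-then-test; the BH
#' family is the set of fold-change survivors). A `test-then-filter` order
#' is available for sensitivity analysis (BH over all entities, FC filter
#' applied afterwards).
#'
#' Comparisons:
#' \describe{
#'   \item{`nitrogen`}{limiting vs optimal nitrogen at optimal water.}
#'   \item{`mild_water`}{mild water stress vs optimal water, optimal N.}
#'   \item{`severe_water`}{severe water stress vs optimal water, optimal N.}
#' }
#'
#' @param x log2-scale expression matrix (detection filter already
#'   applied).
#' @param metadata sample metadata.
#' @param organ organ to analyse.
#' @param comparison one of `"nitrogen"`, `"mild_water"`, `"severe_water"`.
#' @param fc_threshold linear fold-change filter (default 2).
#' @param alpha FDR level (default 0.05).
#' @param order `"filter-then-test"` (default) or `"test-then-filter"`.
#' @return data.frame with one row per entity: `entity_id`, `comparison`,
#'   `log2_fc`, `fc_linear`, `in_family`, `p_raw`, `p_adj` (NA outside the
#'   tested family), `significant`.
#' @export
de_call <- function(x, metadata, organ,
                    comparison = c("nitrogen", "mild_water", "severe_water"),
                    fc_threshold = 2, alpha = 0.05,
                    order = c("filter-then-test", "test-then-filter")) {
  comparison <- match.arg(comparison)
  order <- match.arg(order)
  grp <- switch(comparison,
    nitrogen = list(A = list(organ = organ, nitrogen = "limiting", water = 1L),
                    B = list(organ = organ, nitrogen = "optimal", water = 1L)),
    mild_water = list(A = list(organ = organ, nitrogen = "optimal", water = 2L),
                      B = list(organ = organ, nitrogen = "optimal", water = 1L)),
    severe_water = list(A = list(organ = organ, nitrogen = "optimal", water = 3L),
                        B = list(organ = organ, nitrogen = "optimal", water = 1L)))
  fc <- fold_change(x, metadata, grp$A, grp$B)
  a <- do.call(select_samples, c(list(metadata), grp$A))
  b <- do.call(select_samples, c(list(metadata), grp$B))
  res <- data.frame(entity_id = fc$entity_id, comparison = comparison,
                    log2_fc = fc$log2_fc, fc_linear = fc$fc_linear,
                    in_family = abs(fc$log2_fc) >= log2(fc_threshold),
                    p_raw = NA_real_, p_adj = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  fam <- if (order == "filter-then-test") res$in_family else
    rep(TRUE, nrow(res))
  if (!any(fam)) {
    warning("empty fold-change family for ", organ, "/", comparison)
    return(res)
  }
  tt <- row_ttest(x[fam, a, drop = FALSE], x[fam, b, drop = FALSE])
  res$p_raw[fam] <- tt$p_value
  res$p_adj[fam] <- benjamini_hochberg(tt$p_value, alpha)$p_adj
  res$significant <- res$in_family & !is.na(res$p_adj) & res$p_adj <= alpha
  res
}

#' Exclusive-region counts of overlapping entity sets
#'
#' Partitions the union of k >= 2 sets into the 2^k - 1 exclusive Venn
#' regions and counts each.
#'
#' @param sets named list of >= 2 character vectors.
#' @return named integer vector; names are `&`-joined set names (e.g.
#'   `"leaf&root"` is the region in leaf and root but no other set).
#'   Counts sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("S", seq_along(sets))
  }
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  k <- length(sets)
  all_regions <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(names(sets), sz, paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}
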