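#' Pair profiles measured under both nitrogen regimes
#'
#' Intersects the two fold-change prescreens — by default FC >= 3 under
#' optimal nitrogen and the deliberately relaxed FC >= 2 under limiting
#' nitrogen — and stacks, for every qualifying entity, its two 5-point
#' water-response profiles (one per nitrogen regime) into a single
#' observation matrix for the two-component trend comparison.
#'
#' @param profiles_opt,profiles_lim entities x 5 log2 profile matrices for
#'   the optimal- and limiting-nitrogen regimes (shared row names).
#' @param fc_opt,fc_lim linear fold-change prescreen thresholds.
#' @return list with `entities` (qualifying ids), `observations`
#'   (2k x 5 matrix), `entity` and `nitrogen` (tags for each observation
#'   row), and `n_excluded` (entities present in only one profile set).
#' @export
paired_profile_set <- function(profiles_opt, profiles_lim,
                               fc_opt = 3, fc_lim = 2) {
  common <- intersect(rownames(profiles_opt), rownames(profiles_lim))
  n_excluded <- length(union(rownames(profiles_opt),
                             rownames(profiles_lim))) - length(common)
  if (n_excluded > 0L) {
    message(n_excluded, " entity(ies) present under only one nitrogen ",
            "regime were excluded")
  }
  keep_opt <- prescreen_profiles(profiles_opt[common, , drop = FALSE], fc_opt)
  keep_lim <- prescreen_profiles(profiles_lim[common, , drop = FALSE], fc_lim)
  ids <- intersect(keep_opt, keep_lim)
  obs <- rbind(profiles_opt[ids, , drop = FALSE],
               profiles_lim[ids, , drop = FALSE])
  list(entities = ids, observations = obs,
       entity = rep(ids, 2L),
       nitrogen = rep(NITROGEN_LEVELS, each = length(ids)),
       n_excluded = n_excluded)
}

#' Flag genes whose water-response trajectory differs between nitrogen
#' regimes
#'
#' Within each stratum (by default the optimal-nitrogen cluster groups,
#' matching how trajectories were grouped in the first clustering pass), a
#' two-component mixture is fitted to the stacked optimal- and
#' limiting-nitrogen profiles. A gene whose two profiles land in different
#' MAP components follows a different trend under limiting nitrogen
#' (`different_trend = TRUE`); flags are invariant to component
#' relabeling.
#'
#' @param paired result of [paired_profile_set()].
#' @param groups named integer vector of optimal-N cluster labels (names =
#'   entity ids) defining the strata; `NULL` or `global = TRUE` runs one
#'   fit over all observations.
#' @param global run a single global two-component fit instead of
#'   per-cluster fits.
#' @param seed RNG seed for the mixture fits.
#' @param min_confidence if non-`NULL`, additionally require max
#'   responsibility >= this value for both observations before flagging.
#' @param model covariance family passed to [longmix()]; the default
#'   `"auto"` uses the unconstrained family in strata with at least 30
#'   observations (where a full per-component 5x5 covariance is
#'   estimable and can stretch over heterogeneous divergent
#'   trajectories) and the diagonal family in smaller strata.
#' @param ... further arguments to [longmix()].
#' @return data.frame: `entity_id`, `parent_group`, `optN_component`,
#'   `limN_component`, `confidence` (smaller of the two max
#'   responsibilities), `different_trend`.
#' @export
detect_trend_change <- function(paired, groups = NULL, global = FALSE,
                                seed = 1L, min_confidence = NULL,
                                model = c("auto", "unconstrained",
                                          "shared", "diagonal"), ...) {
  model <- match.arg(model)
  ids <- paired$entities
  if (length(ids) == 0L) {
    return(data.frame(entity_id = character(0), parent_group = integer(0),
                      optN_component = integer(0),
                      limN_component = integer(0),
                      confidence = numeric(0),
                      different_trend = logical(0)))
  }
  strata <- if (global || is.null(groups)) {
    stats::setNames(rep(1L, length(ids)), ids)
  } else {
    if (!all(ids %in% names(groups))) {
      stop("groups must cover every qualifying entity")
    }
    groups[ids]
  }
  k <- length(ids)
  res <- lapply(sort(unique(strata)), function(s) {
    members <- ids[strata[ids] == s]
    rows <- c(match(members, ids), k + match(members, ids))
    obs <- paired$observations[rows, , drop = FALSE]
    m <- length(members)
    if (nrow(obs) < 4L) {
      warning("stratum ", s, " has fewer than 4 observations; its ",
              m, " entity(ies) pass through unflagged")
      return(data.frame(entity_id = members, parent_group = s,
                        optN_component = NA_integer_,
                        limN_component = NA_integer_,
                        confidence = NA_real_,
                        different_trend = FALSE,
                        stringsAsFactors = FALSE))
    }
    stratum_model <- if (model == "auto") {
      if (nrow(obs) >= 30L) "unconstrained" else "diagonal"
    } else model
    fit <- longmix(obs, G = 2L, model = stratum_model, seed = seed + s, ...)
    map <- fit$cluster
    conf <- apply(fit$z, 1L, max)
    opt_c <- map[seq_len(m)]
    lim_c <- map[m + seq_len(m)]
    confidence <- pmin(conf[seq_len(m)], conf[m + seq_len(m)])
    flag <- opt_c != lim_c
    if (!is.null(min_confidence)) flag <- flag & confidence >= min_confidence
    data.frame(entity_id = members, parent_group = s,
               optN_component = opt_c, limN_component = lim_c,
               confidence = confidence, different_trend = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize a trend-comparison run
#'
#' @param results data.frame from [detect_trend_change()], or the counts
#'   directly via `n_qualifying` / `n_different`.
#' @param n_qualifying,n_different optional explicit counts (used when
#'   `results` is missing), e.g. counts printed in a report.
#' @return list: `n_qualifying`, `n_different`, `percent_different`
#'   (one decimal; `NA` when nothing qualifies).
#' @export
summarize_trends <- function(results = NULL, n_qualifying = NULL,
                             n_different = NULL) {
  if (!is.null(results)) {
    n_qualifying <- nrow(results)
    n_different <- sum(results$different_trend)
  }
  pct <- if (n_qualifying == 0L) NA_real_ else
    round(100 * n_different / n_qualifying, 1L)
  list(n_qualifying = n_qualifying, n_different = n_different,
       percent_different = pct)
}
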