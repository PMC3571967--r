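#' Relative water content from leaf-disc weights
#'
#' `RWC (%) = 100 * (FW - DW) / (TW - DW)` from fresh, turgid and dry
#' weights. Values outside `[0, 100]` (fresh weight outside the dry-turgid
#' range) trigger a warning but are returned unclamped, since small
#' measurement noise can push a fully turgid or fully dry disc past the
#' bounds.
#'
#' @param FW fresh weight (g).
#' @param TW turgid weight (g).
#' @param DW dry weight (g).
#' @return relative water content in percent.
#' @export
rwc <- function(FW, TW, DW) {
  if (any(TW <= DW)) stop("turgid weight must exceed dry weight")
  if (any(FW < DW | FW > TW)) {
    warning("fresh weight outside [dry, turgid] range; returning unclamped")
  }
  100 * (FW - DW) / (TW - DW)
}

#' Values relative to a reference-group mean
#'
#' Expresses measurements (e.g. plant dry weights under stress) relative to
#' the mean of a reference group (e.g. the corresponding optimal
#' treatment).
#'
#' @param values numeric measurements.
#' @param reference numeric reference measurements (non-empty, positive
#'   mean).
#' @return `values / mean(reference)`.
#' @export
relative_to_reference <- function(values, reference) {
  if (length(reference) == 0L) stop("empty reference group")
  m <- mean(reference)
  if (m <= 0) stop("reference mean must be positive")
  values / m
}

#' Entity count as a percentage of the chip
#'
#' @param count number of entities (0..`chip_total`).
#' @param chip_total entities on the array (default [CHIP_TOTAL]).
#' @return percentage rounded to one decimal (round-half-even).
#' @export
percent_of_chip <- function(count, chip_total = CHIP_TOTAL) {
  if (any(count < 0 | count > chip_total)) {
    stop("count must lie in [0, chip_total]")
  }
  round(100 * count / chip_total, 1L)
}

#' Single-factor summary table (per-organ DE counts)
#'
#' Tabulates significant-entity counts per organ for the nitrogen
#' comparison and the two water-stress comparisons. The water `total`
#' column is the *union* of the mild- and severe-stress significant sets
#' (an entity responding to both stresses is counted once), not the column
#' sum. Chip percentages accompany the totals.
#'
#' @param de_results named list (by organ) of named lists (by comparison:
#'   `nitrogen`, `mild_water`, `severe_water`) of [de_call()] results.
#' @param chip_total entities on the array.
#' @return data.frame, one row per organ plus a `Total` row; columns
#'   `nitrogen`, `mild`, `severe`, `water_total`, `water_total_pct`.
#' @export
stress_response_table <- function(de_results, chip_total = CHIP_TOTAL) {
  organs <- names(de_results)
  sig_ids <- function(res) {
    if (is.null(res)) character(0) else res$entity_id[res$significant]
  }
  rows <- lapply(organs, function(o) {
    ni <- sig_ids(de_results[[o]]$nitrogen)
    mi <- sig_ids(de_results[[o]]$mild_water)
    se <- sig_ids(de_results[[o]]$severe_water)
    tot <- union(mi, se)
    data.frame(organ = o, nitrogen = length(ni), mild = length(mi),
               severe = length(se), water_total = length(tot),
               water_total_pct = percent_of_chip(length(tot), chip_total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(organ = "Total",
                      nitrogen = sum(out$nitrogen),
                      mild = sum(out$mild), severe = sum(out$severe),
                      water_total = NA_integer_,
                      water_total_pct = NA_real_,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Factorial-response summary table (per-organ interaction counts)
#'
#' Tabulates, per organ, the entities whose variation over the 2x2
#' nitrogen-by-water subdesign is explained by nitrogen, water, or their
#' interaction (BH-adjusted ANOVA p <= alpha), with exclusive counts in
#' parentheses in the printed layout: for the main effects, significant
#' for that factor only; for the interaction, the pairwise-test rule of
#' [classify_interaction()].
#'
#' @param interaction_results data.frame from [interaction_scan()]
#'   (possibly row-bound across organs).
#' @param alpha significance level used for the exclusive main-effect
#'   counts (default 0.05).
#' @return data.frame with columns `organ`, `nitrogen`,
#'   `nitrogen_exclusive`, `water`, `water_exclusive`, `interaction`,
#'   `interaction_exclusive`, `n_prescreened`.
#' @export
interaction_response_table <- function(interaction_results, alpha = 0.05) {
  organs <- unique(interaction_results$organ)
  rows <- lapply(organs, function(o) {
    r <- interaction_results[interaction_results$organ == o, ]
    data.frame(
      organ = o,
      nitrogen = sum(r$nitrogen_responsive),
      nitrogen_exclusive = sum(r$nitrogen_responsive &
                                 !r$water_responsive &
                                 !r$interaction_responsive),
      water = sum(r$water_responsive),
      water_exclusive = sum(r$water_responsive & !r$nitrogen_responsive &
                              !r$interaction_responsive),
      interaction = sum(r$interaction_responsive),
      interaction_exclusive = sum(r$exclusive_interaction),
      n_prescreened = nrow(r),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Machine-readable run report
#'
#' Collects per-stage entity counts, parameters and seeds into a list
#' suitable for JSON export; counts along a filter chain must be
#' nonincreasing.
#'
#' @param counts named numeric vector of per-stage entity counts, in
#'   pipeline order (e.g. input, detected, prescreened, significant).
#' @param params named list of parameters used.
#' @param seed RNG seed of the run.
#' @return list of class `run_report`.
#' @export
run_report <- function(counts, params = list(), seed = NA_integer_) {
  chain <- counts[!is.na(counts)]
  if (any(diff(chain) > 0)) {
    stop("stage counts must be nonincreasing along the filter chain")
  }
  structure(list(counts = as.list(counts), params = params, seed = seed,
                 version = as.character(utils::packageVersion("stressmix")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_report")
}

#' Write a run report as JSON
#' @param report a [run_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
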