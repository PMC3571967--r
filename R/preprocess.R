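#' Log-transform and baseline an expression matrix
#'
#' Converts a raw linear-intensity matrix to log2 and centers each entity to
#' its median across all samples (baseline transformation to the median),
#' so each output row has median zero. A floor is applied to the raw values
#' first.
#'
#' @param x raw-scale expression matrix (scale attribute `"raw"`).
#' @param floor intensity floor applied before the log (default 1.0).
#' @param baseline `"per-entity-median"` (default) centers each row to its
#'   median; `"none"` returns plain log2 values.
#' @return matrix with scale `"log2-baselined"` (or `"log2"` when
#'   `baseline = "none"`).
#' @export
log_and_baseline <- function(x, floor = 1.0,
                             baseline = c("per-entity-median", "none")) {
  baseline <- match.arg(baseline)
  if (expr_scale(x) != "raw") {
    stop("log_and_baseline() expects a raw-scale matrix; got scale '",
         expr_scale(x), "'")
  }
  x2 <- pmax(x, floor)
  if (any(x2 <= 0)) {
    bad <- rownames(x)[which(rowSums(x2 <= 0) > 0L)[1L]]
    stop("non-positive values after flooring for entity ", bad)
  }
  lg <- log2(x2)
  if (baseline == "per-entity-median") {
    lg <- lg - apply(lg, 1L, stats::median)
    expr_scale(lg) <- "log2-baselined"
  } else {
    expr_scale(lg) <- "log2"
  }
  lg
}

#' Detection filter on raw signal intensities
#'
#' Retains an entity if there is at least one condition (unique
#' organ x nitrogen x water combination) in which every replicate's raw
#' signal exceeds the threshold — the "above `threshold` in 100% of the
#' replicate values in at least one condition" rule.
#'
#' @param x raw-scale expression matrix.
#' @param metadata sample metadata.
#' @param threshold detection threshold in signal intensity units
#'   (default 20); values must be strictly greater unless
#'   `strict = FALSE`, which uses `>=`.
#' @param strict logical; strict inequality (default TRUE).
#' @return character vector of retained entity ids.
#' @export
detection_filter <- function(x, metadata, threshold = 20, strict = TRUE) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (expr_scale(x) != "raw") stop("detection_filter() expects raw scale")
  if (nrow(x) == 0L) return(character(0))
  check_metadata(x, metadata)
  cond <- interaction(metadata$organ, metadata$nitrogen, metadata$water,
                      drop = TRUE)
  pass_any <- rep(FALSE, nrow(x))
  for (cc in levels(cond)) {
    cols <- metadata$sample_id[cond == cc]
    sub <- x[, cols, drop = FALSE]
    ok <- if (strict) rowSums(sub > threshold) == length(cols) else
      rowSums(sub >= threshold) == length(cols)
    pass_any <- pass_any | ok
  }
  rownames(x)[pass_any]
}

#' Replicate-median condition profiles over the water series
#'
#' For one organ x nitrogen stratum, collapses replicates to the median at
#' each of the five ordered water conditions, giving each entity a 5-point
#' longitudinal water-response profile. The median is used as it is less
#' sensitive to outliers than the mean; an even replicate count yields the
#' midpoint of the two central values.
#'
#' @param x log2-baselined expression matrix.
#' @param metadata sample metadata.
#' @param organ,nitrogen stratum selectors.
#' @return entities x 5 matrix of log2 profiles, columns ordered
#'   optimal, mild, severe, rewatered 2 h, rewatered 5 h.
#' @export
condition_profiles <- function(x, metadata, organ, nitrogen) {
  if (!expr_scale(x) %in% c("log2", "log2-baselined")) {
    stop("condition_profiles() expects log2-scale values")
  }
  check_metadata(x, metadata)
  keep <- metadata[metadata$organ == organ & metadata$nitrogen == nitrogen, ]
  present <- sort(unique(keep$water))
  miss <- setdiff(seq_along(WATER_LEVELS), present)
  if (length(miss) > 0L) {
    stop("missing water condition(s) for ", organ, "/", nitrogen, ": ",
         paste(miss, collapse = ", "))
  }
  prof <- vapply(seq_along(WATER_LEVELS), function(w) {
    cols <- keep$sample_id[keep$water == w]
    apply(x[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(x)))
  prof <- matrix(prof, nrow = nrow(x))
  dimnames(prof) <- list(rownames(x), WATER_LEVELS)
  prof
}

#' Optional quantile normalization of a raw intensity matrix
#'
#' Forces identical intensity distributions across arrays
#' (via [limma::normalizeQuantiles()]); off by default in the pipeline,
#' for matrices that arrive without between-array normalization.
#'
#' @param x raw-scale expression matrix.
#' @return quantile-normalized matrix, scale `"raw"`.
#' @export
quantile_normalize <- function(x) {
  if (expr_scale(x) != "raw") stop("quantile_normalize() expects raw scale")
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop("quantile_normalize() needs the limma package")
  }
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  expr_scale(out) <- "raw"
  out
}
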