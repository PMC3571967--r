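#' @keywords internal
"_PACKAGE"

# Water-condition coding used throughout: the five ordered treatments of the
# drought/recovery series. Index 1..5 is the longitudinal order.
WATER_LEVELS <- c("optimal", "mild", "severe", "rewater_2h", "rewater_5h")
NITROGEN_LEVELS <- c("optimal", "limiting")

#' Number of measured entities on the expression chip
#'
#' Default chip size used when expressing entity counts as a fraction of the
#' array (46,784 probe sets).
#' @export
CHIP_TOTAL <- 46784L

log_sum_exp <- function(m) {
  # row-wise log(sum(exp(m))) for a matrix of log-densities
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Select sample ids matching design factors
#'
#' @param metadata sample metadata (`sample_id`, `organ`, `nitrogen`,
#'   `water`, `replicate`).
#' @param organ,nitrogen,water optional values to match (`water` is the
#'   condition index 1..5); `NULL` matches everything.
#' @return character vector of sample ids.
#' @export
select_samples <- function(metadata, organ = NULL, nitrogen = NULL,
                           water = NULL) {
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(organ)) keep <- keep & metadata$organ %in% organ
  if (!is.null(nitrogen)) keep <- keep & metadata$nitrogen %in% nitrogen
  if (!is.null(water)) keep <- keep & metadata$water %in% water
  metadata$sample_id[keep]
}

expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "raw" else sc
}

`expr_scale<-` <- function(x, value) {
  attr(x, "scale") <- value
  x
}

check_metadata <- function(matrix, metadata) {
  stopifnot(is.matrix(matrix), is.data.frame(metadata))
  missing <- setdiff(colnames(matrix), metadata$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
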