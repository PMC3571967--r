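#' @export
print.longmix <- function(x, ...) {
  cat("Longitudinal Gaussian mixture (modified-Cholesky covariance)\n")
  cat(sprintf("  G = %d components, model = %s, n = %d profiles of length %d\n",
              x$G, x$model, x$n_obs, x$d))
  cat(sprintf("  log-likelihood = %.3f, params = %d, BIC = %.3f\n",
              x$loglik, x$n_params, x$bic))
  cat(sprintf("  converged: %s after %d EM iteration(s)\n",
              ifelse(x$converged, "yes", "no"), x$iter))
  invisible(x)
}

#' @export
summary.longmix <- function(object, ...) {
  out <- list(G = object$G, model = object$model, n_obs = object$n_obs,
              loglik = object$loglik, bic = object$bic,
              n_params = object$n_params, converged = object$converged,
              weights = object$weights, means = object$means,
              sizes = tabulate(object$cluster, object$G),
              mean_resp = vapply(seq_len(object$G), function(g) {
                idx <- object$cluster == g
                if (!any(idx)) NA_real_ else mean(object$z[idx, g])
              }, numeric(1L)),
              selection = object$selection)
  class(out) <- "summary.longmix"
  out
}

#' @export
print.summary.longmix <- function(x, ...) {
  cat(sprintf("Gaussian mixture, G = %d (%s), n = %d\n", x$G, x$model,
              x$n_obs))
  cat(sprintf("log-likelihood %.3f, %d parameters, BIC %.3f\n", x$loglik,
              x$n_params, x$bic))
  tab <- data.frame(size = x$sizes, weight = round(x$weights, 4),
                    mean_responsibility = round(x$mean_resp, 4))
  rownames(tab) <- paste0("group", seq_len(x$G))
  print(tab)
  cat("component mean trajectories:\n")
  print(round(x$means, 3))
  if (!is.null(x$selection)) {
    cat("model selection (BIC, larger is better):\n")
    print(x$selection, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.longmix <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       T = object$T, D = object$D, Sigma = object$Sigma)
}

#' @export
logLik.longmix <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Posterior classification of profiles under a fitted mixture
#'
#' @param object a `longmix` fit.
#' @param newdata profile matrix; defaults to the training data.
#' @param type `"class"` for MAP labels, `"responsibility"` for the full
#'   posterior matrix.
#' @param ... unused.
#' @return integer labels or an n x G responsibility matrix.
#' @export
predict.longmix <- function(object, newdata = NULL,
                            type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else as.matrix(newdata)
  es <- estep(x, object[c("weights", "means", "T", "D")])
  if (type == "class") max.col(es$z) else es$z
}

#' @export
fitted.longmix <- function(object, ...) {
  object$means[object$cluster, , drop = FALSE]
}

#' @export
residuals.longmix <- function(object, ...) {
  object$data - fitted(object)
}

#' Draw profiles from a fitted mixture
#'
#' @param object a `longmix` fit.
#' @param nsim number of profiles to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return nsim x d matrix with a `component` attribute giving the drawn
#'   component of each row.
#' @export
simulate.longmix <- function(object, nsim = object$n_obs, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- sample.int(object$G, nsim, replace = TRUE, prob = object$weights)
  x <- t(vapply(g, function(k) {
    L <- t(chol(object$Sigma[[k]]))
    object$means[k, ] + drop(L %*% stats::rnorm(object$d))
  }, numeric(object$d)))
  attr(x, "component") <- g
  x
}

#' Trajectory panels of a fitted profile mixture
#'
#' One panel per mixture component showing the member profiles (grey, or
#' colored by up/down subgroup when `split_pair` is given) with the
#' component mean trajectory overlaid in black.
#'
#' @param x a `longmix` fit.
#' @param split_pair optional ordered condition-index pair for
#'   [split_up_down()] coloring (blue up, red down).
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.longmix <- function(x, split_pair = NULL,
                         xlab = "water condition",
                         ylab = "log2 expression", ...) {
  op <- graphics::par(mfrow = c(1L, x$G), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sub <- if (!is.null(split_pair)) {
    split_up_down(x$cluster, x$data, split_pair)
  }
  for (g in seq_len(x$G)) {
    idx <- which(x$cluster == g)
    cols <- if (is.null(sub)) "grey70" else
      ifelse(sub[idx] == "up", "steelblue", "indianred")
    graphics::matplot(t(x$data[idx, , drop = FALSE]), type = "l", lty = 1,
                      col = cols, xlab = xlab, ylab = ylab,
                      main = sprintf("group %d (n = %d)", g, length(idx)),
                      ...)
    graphics::lines(x$means[g, ], lwd = 3, col = "black")
  }
  invisible(x)
}
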