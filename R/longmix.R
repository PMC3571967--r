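#' Modified Cholesky factorization of a covariance matrix
#'
#' Factors a symmetric positive-definite covariance as
#' `solve(Sigma) = t(T) %*% solve(diag(D)) %*% T` with `T` unit
#' lower-triangular (generalized autoregressive coefficients) and `D` a
#' positive diagonal (innovation variances) — the natural covariance
#' parameterization for ordered longitudinal measurements: row k of `T`
#' regresses measurement k on its predecessors.
#'
#' @param sigma symmetric positive-definite matrix.
#' @return list with `T` (unit lower-triangular matrix) and `D` (numeric
#'   vector of innovation variances).
#' @export
modified_cholesky <- function(sigma) {
  L <- t(chol(sigma))            # sigma = L %*% t(L)
  Dvec <- diag(L)^2
  Tm <- sqrt(Dvec) * forwardsolve(L, diag(nrow(L)))  # D^{1/2} L^{-1}
  dimnames(Tm) <- dimnames(sigma)
  list(T = Tm, D = Dvec)
}

# Sigma from its modified Cholesky factors: Sigma = T^{-1} D T^{-T}
mc_reconstruct <- function(Tm, Dvec) {
  Linv <- Tm / sqrt(Dvec)        # rows scaled: D^{-1/2} T = L^{-1}
  L <- forwardsolve(Linv, diag(nrow(Tm)))
  L %*% t(L)
}

# log N(x; mu, Sigma) for rows of X, Sigma given by (T, D): the quadratic
# form is ||D^{-1/2} T (x - mu)||^2 and log|Sigma| = sum(log D) since
# det(T) = 1. No matrix inversion.
ldens_chol <- function(X, mu, Tm, Dvec) {
  d <- length(mu)
  C <- sweep(X, 2L, mu)
  Q <- C %*% t(Tm)
  quad <- Q^2 %*% (1 / Dvec)
  drop(-0.5 * (d * log(2 * pi) + sum(log(Dvec))) - 0.5 * quad)
}

#' Gaussian density under the modified-Cholesky parameterization
#'
#' Evaluates the multivariate normal density `N(x; mu, Sigma)` where
#' `solve(Sigma) = t(T) %*% diag(1/D) %*% T`, without forming or inverting
#' `Sigma`.
#'
#' @param x numeric vector, or matrix with observations in rows.
#' @param mu mean vector.
#' @param T unit lower-triangular matrix.
#' @param D positive innovation variances (vector or diagonal matrix).
#' @param log return the log-density?
#' @return density value(s).
#' @export
gaussian_density_cholesky <- function(x, mu, T, D, log = FALSE) {
  if (is.matrix(D)) D <- diag(D)
  if (any(D <= 0)) stop("innovation variances must be positive")
  if (any(abs(diag(T) - 1) > 1e-12) || any(T[upper.tri(T)] != 0)) {
    stop("T must be unit lower-triangular")
  }
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  ld <- ldens_chol(X, mu, T, D)
  if (log) ld else exp(ld)
}

# one M-step from responsibilities; returns component parameters
mstep <- function(x, z, model, ridge) {
  n <- nrow(x); d <- ncol(x); G <- ncol(z)
  nk <- colSums(z)
  weights <- nk / n
  means <- t(vapply(seq_len(G), function(g) colSums(z[, g] * x) / nk[g],
                    numeric(d)))
  scatter <- function(g) {
    C <- sweep(x, 2L, means[g, ])
    crossprod(sqrt(z[, g]) * C) / nk[g]
  }
  sig <- switch(model,
    unconstrained = lapply(seq_len(G), scatter),
    shared = {
      S <- Reduce(`+`, lapply(seq_len(G), function(g) scatter(g) * nk[g])) / n
      rep(list(S), G)
    },
    diagonal = lapply(seq_len(G), function(g) {
      C <- sweep(x, 2L, means[g, ])
      diag(pmax(colSums(z[, g] * C^2) / nk[g], ridge), d)
    }))
  Tm <- vector("list", G); Dv <- vector("list", G)
  for (g in seq_len(G)) {
    s <- sig[[g]]
    fac <- NULL
    for (try in 0:6) {
      fac <- tryCatch(modified_cholesky(s), error = function(e) NULL)
      if (!is.null(fac)) break
      s <- s + diag(ridge * 10^try, d)
    }
    if (is.null(fac)) stop("covariance factorization failed")
    fac$D <- pmax(fac$D, ridge)            # innovation-variance floor
    Tm[[g]] <- fac$T; Dv[[g]] <- fac$D
    sig[[g]] <- mc_reconstruct(fac$T, fac$D)
  }
  list(weights = weights, means = means, T = Tm, D = Dv, Sigma = sig)
}

# E-step: responsibilities (via log-sum-exp) and observed-data loglik
estep <- function(x, par) {
  G <- length(par$T)
  lp <- vapply(seq_len(G), function(g) {
    log(par$weights[g]) + ldens_chol(x, par$means[g, ], par$T[[g]],
                                     par$D[[g]])
  }, numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  lse <- log_sum_exp(lp)
  list(z = exp(lp - lse), loglik = sum(lse))
}

cov_params <- function(model, G, d) {
  switch(model,
         unconstrained = G * d * (d + 1) / 2,
         shared = d * (d + 1) / 2,
         diagonal = G * d)
}

#' Fit a Gaussian mixture model for longitudinal expression profiles
#'
#' Model-based clustering of short ordered expression trajectories (here,
#' 5-point water-response profiles) with a finite mixture of multivariate
#' Gaussians whose component covariances are handled through the modified
#' Cholesky decomposition, fitted by expectation-maximization. Each restart
#' initializes hard labels with a seeded k-means partition followed by one
#' M-step; the best converged restart (highest observed-data
#' log-likelihood) is returned. The observed-data log-likelihood is
#' nondecreasing across EM iterations; the iteration trace is kept for
#' auditing.
#'
#' @param x numeric matrix, observations in rows (profiles x conditions).
#' @param G number of mixture components (>= 1).
#' @param model covariance family: `"unconstrained"` (full per-component
#'   covariance, default), `"shared"` (one covariance for all components),
#'   `"diagonal"` (independent conditions, per-component variances).
#' @param n_restarts number of seeded initializations (default 10; `G = 1`
#'   has a closed form and ignores this).
#' @param max_iter maximum EM iterations (default 1000).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param seed integer seed; restart r uses sub-seed `seed + r`.
#' @param ridge floor on innovation variances (default 1e-6).
#' @return an object of class `longmix`: weights, means (G x d), `T` and
#'   `D` modified-Cholesky factors and reconstructed `Sigma` per component,
#'   responsibilities `z`, MAP `cluster`, `loglik`, `trace`, `n_params`,
#'   `bic` (`2*loglik - n_params*log(n)`; larger is better), `converged`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(250), 50), matrix(rnorm(250, 3), 50))
#' fit <- longmix(x, G = 2, n_restarts = 2, seed = 1)
#' table(fit$cluster)
#' @export
longmix <- function(x, G, model = c("unconstrained", "shared", "diagonal"),
                    n_restarts = 10L, max_iter = 1000L, tol = 1e-8,
                    seed = NULL, ridge = 1e-6) {
  model <- match.arg(model)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (G < 1L) stop("G must be >= 1")
  if (G > n) stop("G (", G, ") exceeds the number of profiles (", n, ")")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 2000L, 1L)
  n_params <- (G - 1) + G * d + cov_params(model, G, d)

  fit_one <- function(z0, sub_seed) {
    par <- mstep(x, z0, model, ridge)
    trace <- numeric(0)
    converged <- FALSE
    collapsed <- FALSE
    es <- NULL
    for (it in seq_len(max_iter)) {
      es <- estep(x, par)
      trace <- c(trace, es$loglik)
      if (any(colSums(es$z) < 1)) { collapsed <- TRUE; break }
      k <- length(trace)
      if (k >= 2L && abs(trace[k] - trace[k - 1L]) /
            (abs(trace[k]) + 1e-12) < tol) {
        converged <- TRUE
        break
      }
      if (k >= 3L) {
        # Aitken acceleration: stop when the projected asymptotic
        # log-likelihood is within tol of the current one
        a <- (trace[k] - trace[k - 1L]) / (trace[k - 1L] - trace[k - 2L])
        if (is.finite(a) && a < 1) {
          ll_inf <- trace[k - 1L] + (trace[k] - trace[k - 1L]) / (1 - a)
          if (abs(ll_inf - trace[k]) < tol * (abs(trace[k]) + 1)) {
            converged <- TRUE
            break
          }
        }
      }
      par <- mstep(x, es$z, model, ridge)
    }
    list(par = par, z = es$z, loglik = trace[length(trace)], trace = trace,
         converged = converged, collapsed = collapsed,
         iter = length(trace), seed = sub_seed)
  }

  init_z <- function(sub_seed, random = FALSE) {
    set.seed(sub_seed)
    lab <- if (random || G == 1L) sample.int(G, n, replace = TRUE) else {
      km <- tryCatch(stats::kmeans(x, centers = G, nstart = 1L),
                     error = function(e) NULL)
      if (is.null(km)) sample.int(G, n, replace = TRUE) else km$cluster
    }
    # guard: every component needs at least one observation
    miss <- setdiff(seq_len(G), unique(lab))
    if (length(miss) > 0L) lab[sample.int(n, length(miss))] <- miss
    z <- matrix(0, n, G)
    z[cbind(seq_len(n), lab)] <- 1
    z
  }

  if (G == 1L) {
    # closed form: MLE mean and covariance in a single M-step
    z <- matrix(1, n, 1L)
    par <- mstep(x, z, model, ridge)
    es <- estep(x, par)
    best <- list(par = par, z = es$z, loglik = es$loglik,
                 trace = es$loglik, converged = TRUE, collapsed = FALSE,
                 iter = 1L, seed = seed, restart = 1L)
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      sub_seed <- seed + r
      fit <- fit_one(init_z(sub_seed), sub_seed)
      attempt <- 0L
      while (fit$collapsed && attempt < 3L) {
        # component collapse: retry this restart from random labels
        attempt <- attempt + 1L
        sub2 <- sub_seed + 1000L * attempt
        message("longmix: component collapse in restart ", r,
                "; re-initializing (attempt ", attempt, ")")
        fit <- fit_one(init_z(sub2, random = TRUE), sub2)
      }
      fit$restart <- r
      if (!fit$collapsed &&
          (is.null(best) || fit$loglik > best$loglik)) best <- fit
    }
    if (is.null(best)) stop("all restarts collapsed; reduce G")
  }

  out <- list(G = G, model = model, d = d, n_obs = n,
              weights = best$par$weights, means = best$par$means,
              T = best$par$T, D = best$par$D, Sigma = best$par$Sigma,
              z = best$z, cluster = max.col(best$z),
              loglik = best$loglik, trace = best$trace,
              n_params = n_params,
              bic = 2 * best$loglik - n_params * log(n),
              converged = best$converged, iter = best$iter,
              seed = seed, restart = best$restart,
              data = x, call = match.call())
  class(out) <- "longmix"
  out
}

#' Select the number of mixture components by BIC
#'
#' Fits [longmix()] for each candidate number of groups and returns the fit
#' maximizing `BIC = 2*loglik - n_params*log(n)` (larger is better — note
#' the sign convention). The per-G table is attached as `$selection`.
#'
#' @param x profile matrix.
#' @param G candidate component counts (default 1..8).
#' @param ... passed to [longmix()].
#' @return the best `longmix` fit, with a `selection` data.frame
#'   (`G`, `loglik`, `n_params`, `bic`, `converged`).
#' @export
longmix_select <- function(x, G = 1:8, ...) {
  fits <- lapply(G, function(g) {
    tryCatch(longmix(x, G = g, ...), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1L), "error")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1L))
    stop("all fits failed:\n", paste0("  G=", G, ": ", msgs, collapse = "\n"))
  }
  sel <- data.frame(
    G = G[ok],
    loglik = vapply(fits[ok], `[[`, numeric(1L), "loglik"),
    n_params = vapply(fits[ok], `[[`, numeric(1L), "n_params"),
    bic = vapply(fits[ok], `[[`, numeric(1L), "bic"),
    converged = vapply(fits[ok], `[[`, logical(1L), "converged"))
  best <- fits[ok][[which.max(sel$bic)]]
  best$selection <- sel
  best
}

#' Fold-change prescreen on water-response profiles
#'
#' Retains an entity when its log2 change under mild or severe water stress
#' relative to optimal water reaches the linear threshold:
#' `|profile[2] - profile[1]| >= log2(fc)` or
#' `|profile[3] - profile[1]| >= log2(fc)`.
#'
#' @param profiles entities x 5 log2 profile matrix
#'   (see [condition_profiles()]).
#' @param fc_threshold linear fold-change threshold.
#' @return character vector of retained entity ids.
#' @export
prescreen_profiles <- function(profiles, fc_threshold) {
  keep <- abs(profiles[, 2L] - profiles[, 1L]) >= log2(fc_threshold) |
    abs(profiles[, 3L] - profiles[, 1L]) >= log2(fc_threshold)
  rownames(profiles)[keep]
}

#' A-posteriori up/down subgrouping of mixture clusters
#'
#' The mixture is symmetric — up- and down-regulated trajectories of the
#' same shape share a cluster — so for display each cluster is split by the
#' sign of the change between two conditions: `up` when
#' `profile[split_pair[1]] > profile[split_pair[2]]`, otherwise `down`
#' (ties fall to `down`, with a message). The conventional pairs are (2, 1)
#' — mild stress vs optimal water — for optimal-nitrogen runs and (3, 2)
#' for limiting-nitrogen runs.
#'
#' @param cluster integer MAP cluster labels.
#' @param profiles matrix of profiles (rows aligned with `cluster`).
#' @param split_pair ordered pair of condition indices.
#' @return factor with levels `up`, `down`.
#' @export
split_up_down <- function(cluster, profiles, split_pair = c(2L, 1L)) {
  if (length(split_pair) != 2L || any(split_pair < 1L) ||
      any(split_pair > ncol(profiles))) {
    stop("split_pair must be two condition indices in 1..",
         ncol(profiles))
  }
  diff <- profiles[, split_pair[1L]] - profiles[, split_pair[2L]]
  if (any(diff == 0)) message(sum(diff == 0), " tie(s) assigned to 'down'")
  factor(ifelse(diff > 0, "up", "down"), levels = c("up", "down"))
}
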