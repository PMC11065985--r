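#' Feature matrix for segment clustering
#'
#' Assembles the clustering features — vessel segment diameter and vessel
#' segment length (um) — one row per segment, optionally log10-transformed
#' (both quantities are positive and span orders of magnitude in a vascular
#' tree) and standardized to zero mean / unit variance. The transform is
#' recorded so it can be undone.
#'
#' @param table Segment table with columns `id`, `diameter_um`, `length_um`.
#' @param log_transform Apply log10 first (requires positive values).
#' @param standardize Center and scale each column afterwards.
#' @return Numeric matrix (n x 2) with columns `diameter`, `length`,
#'   rownames = segment ids, and a `transform` attribute recording the
#'   applied operations.
#' @export
build_features <- function(table, log_transform = TRUE, standardize = TRUE) {
  if (nrow(table) == 0L) stop("empty segment table")
  X <- cbind(diameter = table$diameter_um, length = table$length_um)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (log_transform) {
    if (any(X <= 0))
      stop("log transform requires positive diameters and lengths")
    X <- log10(X)
  }
  ctr <- c(0, 0); scl <- c(1, 1)
  if (standardize && nrow(X) > 1L) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  rownames(X) <- table$id
  attr(X, "transform") <- list(log10 = log_transform,
                               standardize = standardize,
                               center = ctr, scale = scl)
  X
}

#' Covariance parameterizations available for GMM fitting
#'
#' Named by the E/V convention: volume/shape equal (E) or varying (V)
#' across components; `I` spherical, a second letter for diagonal/full.
#' @return Character vector of constellation names.
#' @export
gmm_constellations <- function() c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

gmm_cov_params <- function(constellation, k, d) {
  switch(constellation,
    EII = 1,
    VII = k,
    EEI = d,
    VVI = k * d,
    EEE = d * (d + 1) / 2,
    VVV = k * d * (d + 1) / 2,
    stop("unknown constellation: ", constellation))
}

# k-means++-style seeding: responsibilities = hard assignment to the
# nearest of k centers chosen with distance-proportional probability.
kmeanspp_resp <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, nrow = k, ncol = ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- colSums((t(X) - centers[1, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (any(!is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      pick <- sample.int(n, 1, prob = p)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
    }
  }
  dmat <- vapply(seq_len(k), function(j) colSums((t(X) - centers[j, ])^2),
                 numeric(n))
  assign <- max.col(-matrix(dmat, nrow = n), ties.method = "first")
  resp <- matrix(1e-10, nrow = n, ncol = k)
  resp[cbind(seq_len(n), assign)] <- 1
  resp / rowSums(resp)
}

#' Fit a Gaussian mixture model by EM
#'
#' Expectation-maximization under one of six covariance parameterizations
#' (see [gmm_constellations]), restarted from `n_init` k-means++-style
#' seedings and keeping the best log-likelihood. Convergence is declared
#' when the relative log-likelihood change drops below `tol`. Singular
#' covariances are ridge-regularized (a warning is issued). The fit is
#' deterministic for a fixed `seed`.
#'
#' The Bayesian information criterion is used in the maximize convention,
#' `BIC = 2 logL - p log(n)`: larger is better.
#'
#' @param X Numeric feature matrix (n x d), e.g. from [build_features].
#' @param k Number of mixture components (1 <= k <= n).
#' @param constellation Covariance parameterization name.
#' @param seed Integer seed for the initializations.
#' @param n_init Number of EM restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @return A `vt_gmm` object with weights, means, covariances,
#'   log-likelihood, parameter count and BIC.
#' @export
fit_gmm <- function(X, k, constellation = "VVV", seed = 1L, n_init = 10L,
                    tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of observations")
  constellation <- match.arg(constellation, gmm_constellations())
  set.seed(seed)
  best <- NULL
  n_degenerate <- 0L
  for (rep in seq_len(max(1L, n_init))) {
    resp <- if (k == 1L) matrix(1, n, 1) else kmeanspp_resp(X, k)
    fit <- cpp_gmm_em(X, resp, match(constellation, gmm_constellations()),
                      as.integer(max_iter), tol, 1e-6)
    # a component carried by fewer than d + 1 points is a likelihood
    # spike (EM singularity), not a cluster: reject that restart
    if (k > 1L && fit$n_min < d + 1) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (k == 1L) break  # closed form; restarts are identical
  }
  if (is.null(best))
    stop("all ", n_degenerate, " EM restarts collapsed onto degenerate ",
         "components (k = ", k, " is too large for this data)")
  if (isTRUE(best$ridged))
    warning("singular covariance encountered; ridge regularization applied")
  p <- (k - 1) + k * d + gmm_cov_params(constellation, k, d)
  bic <- 2 * best$loglik - p * log(n)
  structure(list(k = as.integer(k), constellation = constellation,
                 weights = as.numeric(best$weights), means = best$means,
                 cov = best$cov, loglik = best$loglik, p = p, bic = bic,
                 n = n, d = d, iter = best$iter,
                 transform = attr(X, "transform"), seed = seed),
            class = "vt_gmm")
}

#' @export
print.vt_gmm <- function(x, ...) {
  cat(sprintf("<vt_gmm> k = %d, constellation %s, n = %d\n",
              x$k, x$constellation, x$n))
  cat(sprintf("  logLik %.4f, %d parameters, BIC %.4f\n",
              x$loglik, x$p, x$bic))
  invisible(x)
}

#' @export
summary.vt_gmm <- function(object, ...) {
  cat(sprintf("Gaussian mixture: %d component(s), %s covariance, n = %d\n",
              object$k, object$constellation, object$n))
  cat(sprintf("logLik %.4f | parameters %d | BIC %.4f (2logL - p log n)\n",
              object$loglik, object$p, object$bic))
  for (j in seq_len(object$k)) {
    cat(sprintf("  component %d: weight %.3f, mean (%s)\n", j,
                object$weights[j],
                paste(sprintf("%.4g", object$means[j, ]), collapse = ", ")))
  }
  invisible(object)
}

#' @export
logLik.vt_gmm <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n, class = "logLik")
}

gmm_log_dens <- function(object, X) {
  n <- nrow(X); d <- ncol(X)
  logp <- matrix(0, n, object$k)
  for (j in seq_len(object$k)) {
    S <- object$cov[, , j]
    R <- chol(S)
    logdet <- 2 * sum(log(diag(R)))
    Xc <- sweep(X, 2, object$means[j, ])
    q <- rowSums((Xc %*% solve(R))^2)
    logp[, j] <- log(object$weights[j]) -
      0.5 * (d * log(2 * pi) + logdet + q)
  }
  logp
}

#' Posterior component membership of a fitted mixture
#'
#' @param object A `vt_gmm`.
#' @param newdata Feature matrix (defaults must be supplied; the model does
#'   not store its training data).
#' @param type `"class"` for hard labels, `"posterior"` for the full
#'   responsibility matrix.
#' @param ... Unused.
#' @export
predict.vt_gmm <- function(object, newdata, type = c("class", "posterior"),
                           ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  logp <- gmm_log_dens(object, X)
  if (type == "class") {
    cls <- max.col(logp, ties.method = "first")
    names(cls) <- rownames(X)
    cls
  } else {
    mx <- apply(logp, 1, max)
    w <- exp(logp - mx)
    w / rowSums(w)
  }
}

#' Draw samples from a fitted Gaussian mixture
#'
#' @param object A `vt_gmm`.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix (`nsim` x d) with a `component` attribute.
#' @export
simulate.vt_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  out <- matrix(0, nsim, object$d)
  for (j in unique(comp)) {
    idx <- which(comp == j)
    R <- chol(object$cov[, , j])
    Z <- matrix(stats::rnorm(length(idx) * object$d), ncol = object$d)
    out[idx, ] <- sweep(Z %*% R, 2, object$means[j, ], "+")
  }
  attr(out, "component") <- comp
  out
}

#' @export
plot.vt_gmm <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    data <- simulate(x, 500, seed = 1)
  }
  cls <- predict(x, data)
  graphics::plot(data[, 1], data[, 2], col = cls, pch = 16, cex = 0.6,
                 xlab = "feature 1", ylab = "feature 2", ...)
  graphics::points(x$means[, 1], x$means[, 2], pch = 3, cex = 2, lwd = 2)
  invisible(x)
}

#' BIC model selection over cluster counts and constellations
#'
#' Fits every (k, constellation) pair and returns the fit maximizing
#' `BIC = 2 logL - p log(n)` together with the full BIC table. Failed cells
#' are recorded in the table (NA bic) rather than aborting, unless every
#' cell fails. Deterministic given `seed`.
#'
#' @param X Feature matrix.
#' @param k_range Cluster counts to try (default 1 to 9).
#' @param constellations Covariance parameterizations to try (default all
#'   six, see [gmm_constellations]).
#' @param seed Integer seed.
#' @param n_init,tol Passed to [fit_gmm].
#' @return List with `best` (a `vt_gmm`) and `bic_table` (data.frame with
#'   k, constellation, loglik, p, bic, error).
#' @export
select_gmm <- function(X, k_range = 1:9,
                       constellations = gmm_constellations(), seed = 1L,
                       n_init = 10L, tol = 1e-6) {
  if (length(constellations) == 0L) stop("no constellations given")
  rows <- list()
  best <- NULL
  for (k in k_range) {
    for (cs in constellations) {
      cell_seed <- seed + 1009L * k + 31L * match(cs, gmm_constellations())
      fit <- tryCatch(
        suppressWarnings(fit_gmm(X, k, cs, seed = cell_seed,
                                 n_init = n_init, tol = tol)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          k = k, constellation = cs, loglik = NA_real_, p = NA_real_,
          bic = NA_real_, error = conditionMessage(fit))
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          k = k, constellation = cs, loglik = fit$loglik, p = fit$p,
          bic = fit$bic, error = NA_character_)
        if (is.null(best) || fit$bic > best$bic) best <- fit
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(best)) stop("all GMM fits failed")
  list(best = best, bic_table = tab)
}
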