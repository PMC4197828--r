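#' Fit a volume-varying shared-shape Gaussian mixture by EM
#'
#' Fits the K-component multivariate Gaussian mixture with unequal
#' proportions and covariances constrained to Sigma_k = lambda_k * C, where C
#' is a shared symmetric positive-definite orientation/shape matrix with unit
#' determinant and the lambda_k are component-specific volumes. The E-step is
#' the standard Gaussian posterior; the constrained M-step is solved by inner
#' alternation on (lambda, C): given the weighted scatter matrices W_k,
#' lambda_k <- trace(C^-1 W_k) / (n_k d), then C <- sum_k W_k / lambda_k
#' rescaled to unit determinant, iterated to convergence. Each EM run starts
#' from a k-means++ seeding; the best of `n_starts` runs by log-likelihood is
#' returned.
#'
#' Local optima are handled by the short-run strategy: every start runs for
#' `short_iter` iterations, and only the start with the best log-likelihood
#' is continued to convergence.
#'
#' @param X Numeric matrix, n observations x d dimensions.
#' @param K Number of components (>= 1). `K = 1` is solved in closed form.
#' @param n_starts Number of k-means++ initialisations (default 10).
#' @param seed Integer seed for the initialisations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations for the final run.
#' @param short_iter EM iterations given to each trial start (default 25).
#' @return Object of class `mixture_model`: `K`, `proportions`, `means`
#'   (K x d), `volumes`, `shape` (det-1 matrix C), `loglik`, `loglik_trace`,
#'   `n_params`, `bic`, `n`, `d`.
#' @export
fit_vee_em <- function(X, K, n_starts = 10, seed = 1L, tol = 1e-8,
                       max_iter = 500, short_iter = 25) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(K >= 1, n > K * d, all(is.finite(X)))

  if (K == 1) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / n
    lambda <- det(S)^(1 / d)
    C <- S / lambda
    ll <- sum(dmvnorm_vee_log(X, mu, lambda, C))
    return(new_mixture_model(1, 1, matrix(mu, 1), lambda, C, ll, ll, n, d))
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(em_one_start(X, K, tol, short_iter),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("all EM starts failed for K = ", K)
  # continue the winning start to convergence
  final <- em_loop(X, K, best$z, tol, max_iter, best$C)
  trace <- c(best$trace, final$trace)
  new_mixture_model(K, final$pi, final$mu, final$lambda, final$C,
                    final$loglik, trace, n, d)
}

new_mixture_model <- function(K, pi, mu, lambda, C, loglik, trace, n, d) {
  m <- (K - 1) + K * d + K + (d * (d + 1) / 2 - 1)
  structure(list(K = K, proportions = as.numeric(pi),
                 means = unname(as.matrix(mu)), volumes = as.numeric(lambda),
                 shape = unname(C), loglik = loglik,
                 loglik_trace = as.numeric(trace), n_params = m,
                 bic = -2 * loglik + m * log(n), n = n, d = d),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Gaussian mixture (volumes free, shared shape/orientation):\n",
      " K =", x$K, " d =", x$d, " n =", x$n, "\n",
      " loglik =", format(x$loglik), " BIC =", format(x$bic),
      " (", x$n_params, "free parameters )\n")
  invisible(x)
}

# log N(x; mu, lambda * C) with det(C) = 1, vectorised over rows of X
dmvnorm_vee_log <- function(X, mu, lambda, C) {
  d <- ncol(X)
  L <- chol(C)
  Y <- forwardsolve(t(L), t(sweep(X, 2, mu)))
  q <- colSums(Y^2)
  -d / 2 * log(2 * pi * lambda) - q / (2 * lambda)
}

# n x K matrix of log pi_k + log N(x_i; mu_k, lambda_k C)
vee_log_dens <- function(X, pi, mu, lambda, C) {
  K <- length(pi)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    out[, k] <- log(pi[k]) + dmvnorm_vee_log(X, mu[k, ], lambda[k], C)
  out
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Posterior component probabilities under a fitted mixture
#'
#' @param model A `mixture_model`.
#' @param X Data matrix compatible with the model's dimension.
#' @return n x K matrix of conditional probabilities; rows sum to 1.
#' @export
posterior_probs <- function(model, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == model$d)
  ld <- vee_log_dens(X, model$proportions, model$means, model$volumes,
                     model$shape)
  z <- exp(ld - logsumexp_rows(ld))
  z / rowSums(z)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in seq_len(K)[-1]) {
    p <- d2 / sum(d2)
    centers[k, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

# constrained M-step: inner alternation on (lambda, C); W is a list of the
# K weighted scatter matrices, nk the component weights
mstep_vee <- function(W, nk, d, C0, lambda_floor = 1e-8,
                      inner_tol = 1e-8, inner_max = 100) {
  K <- length(W)
  C <- C0
  lambda <- rep(1, K)
  for (it in seq_len(inner_max)) {
    Cinv <- chol2inv(chol(C))
    new_lambda <- vapply(seq_len(K),
                         function(k) sum(Cinv * W[[k]]) / (nk[k] * d),
                         numeric(1))
    if (any(new_lambda < lambda_floor)) return(NULL)   # collapsed component
    M <- Reduce(`+`, lapply(seq_len(K), function(k) W[[k]] / new_lambda[k]))
    M <- (M + t(M)) / 2
    detM <- det(M)
    if (!is.finite(detM) || detM <= 0) return(NULL)
    newC <- M / detM^(1 / d)
    delta <- max(abs(new_lambda - lambda) / pmax(new_lambda, 1e-12))
    lambda <- new_lambda
    C <- newC
    if (delta < inner_tol) break
  }
  list(lambda = lambda, C = C)
}

em_one_start <- function(X, K, tol, max_iter) {
  centers <- kmeanspp_centers(X, K)
  # hard initial assignment to nearest seed
  d2 <- sapply(seq_len(K), function(k) rowSums(sweep(X, 2, centers[k, ])^2))
  z <- matrix(0, nrow(X), K)
  z[cbind(seq_len(nrow(X)), max.col(-d2))] <- 1
  em_loop(X, K, z, tol, max_iter, diag(ncol(X)))
}

em_loop <- function(X, K, z, tol, max_iter, Ccur) {
  n <- nrow(X); d <- ncol(X)
  pi <- mu <- lambda <- C <- NULL
  ll_old <- -Inf
  trace <- numeric(0)
  reinit_used <- FALSE

  for (iter in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < d)) {
      if (reinit_used) stop("component collapsed")
      reinit_used <- TRUE
      k_bad <- which(nk < d)
      for (k in k_bad) {          # reseed the empty component on one point
        i <- sample.int(n, 1)
        z[i, ] <- 0; z[i, k] <- 1
      }
      nk <- colSums(z)
      if (any(nk < 1)) stop("component collapsed")
    }
    pi <- nk / n
    mu <- sweep(crossprod(z, X), 1, nk, "/")
    W <- lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2, mu[k, ])
      crossprod(Xc * sqrt(z[, k]))
    })
    ms <- mstep_vee(W, nk, d, Ccur)
    if (is.null(ms)) {
      if (reinit_used) stop("component collapsed (volume floor)")
      reinit_used <- TRUE
      k_bad <- which.min(nk)
      i <- sample.int(n, max(d + 1, 5))
      z[i, ] <- 0; z[i, k_bad] <- 1
      next
    }
    lambda <- ms$lambda; C <- ms$C; Ccur <- C

    ld <- vee_log_dens(X, pi, mu, lambda, C)
    lse <- logsumexp_rows(ld)
    ll <- sum(lse)
    trace <- c(trace, ll)
    z <- exp(ld - lse)
    z <- z / rowSums(z)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1e-3)) break
    ll_old <- ll
  }
  list(pi = pi, mu = mu, lambda = lambda, C = C, z = z,
       loglik = trace[length(trace)], trace = trace)
}

#' Select the number of mixture components by BIC
#'
#' Fits the constrained mixture for each K in `K_range` and returns the model
#' minimising BIC = -2 loglik + m log(n), with the full BIC trace attached.
#'
#' @param X Data matrix.
#' @param K_range Candidate component counts (default 2:40).
#' @param ... Passed to [fit_vee_em()].
#' @return The best `mixture_model`, with attribute `bic_trace` (data frame
#'   K, loglik, n_params, bic; NA rows for K values that failed to fit).
#' @export
select_K <- function(X, K_range = 2:40, ...) {
  stopifnot(length(K_range) >= 1)
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    fits[[i]] <- tryCatch(fit_vee_em(X, K_range[i], ...),
                          error = function(e) {
                            warning("K = ", K_range[i], " failed: ",
                                    conditionMessage(e))
                            NULL
                          })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no component number could be fitted")
  trace <- data.frame(
    K = K_range,
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik, 1),
    n_params = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n_params, 1),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 1))
  best <- fits[[which.min(trace$bic)]]
  attr(best, "bic_trace") <- trace
  best
}

#' Threshold-MAP assignment with misclassification control
#'
#' Observations are assigned to the component with the highest conditional
#' (posterior) probability, but only when that probability exceeds a
#' threshold tau. Tau is fixed so that as many observations as possible are
#' classified under the constraint that the estimated proportion of
#' misassigned observations among the classified — the mean posterior
#' probability of not belonging to the MAP component, a Bayesian-FDR
#' analogue — stays at or below `alpha`. Candidate thresholds are the
#' distinct max-posterior values; the comparison is strict (`> tau`).
#'
#' @param model A fitted `mixture_model`.
#' @param X Data matrix the model applies to.
#' @param alpha Misclassification control level (default 0.05).
#' @return Object of class `map_assignment`: `posterior` (n x K), `map`,
#'   `max_posterior`, `classified`, `tau`, `alpha`, `fap` (estimated
#'   misassignment proportion among the classified) and
#'   `expected_misassigned` (= fap x number classified).
#' @export
threshold_map_assign <- function(model, X, alpha = 0.05) {
  z <- posterior_probs(model, X)
  maxp <- apply(z, 1, max)
  map <- max.col(z, ties.method = "first")

  v <- sort(unique(maxp), decreasing = TRUE)
  # classified set j = {maxp >= v[j]}; the matching strict threshold tau is
  # the next distinct value below (0 when every observation is kept)
  ord <- order(maxp, decreasing = TRUE)
  cum_miss <- cumsum(1 - maxp[ord])
  set_size <- match(v, maxp[ord])                # first index of each value
  set_size <- c(set_size[-1] - 1, length(maxp))  # size of each nested set
  fap_j <- cum_miss[set_size] / set_size
  feasible <- which(fap_j <= alpha)

  if (!length(feasible)) {
    warning("no threshold satisfies the misclassification constraint; ",
            "nothing classified")
    tau <- v[1]
    classified <- rep(FALSE, length(maxp))
    fap <- NA_real_
  } else {
    j <- max(feasible)                           # largest feasible set
    tau <- if (j == length(v)) 0 else v[j + 1]
    classified <- maxp > tau
    fap <- fap_j[j]
  }
  structure(list(posterior = z, map = map, max_posterior = maxp,
                 classified = classified, tau = tau, alpha = alpha,
                 fap = fap,
                 expected_misassigned = if (is.na(fap)) 0 else fap * sum(classified)),
            class = "map_assignment")
}

#' @export
print.map_assignment <- function(x, ...) {
  cat("Threshold-MAP assignment: ", sum(x$classified), "/",
      length(x$map), " classified (tau = ", format(x$tau, digits = 4),
      ", alpha = ", x$alpha, ", estimated misassigned = ",
      format(x$expected_misassigned, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Per-cluster expression-profile and interpretability summary
#'
#' For each cluster and each comparison: quartiles (linear interpolation
#' between order statistics), whiskers at Q1 - 1.5 (Q3 - Q1) and
#' Q3 + 1.5 (Q3 - Q1), the values outside the whiskers, and the percentage
#' of member genes differentially expressed in that comparison. A cluster is
#' flagged *interpretable* when more than `interpretable_fraction` of its
#' genes are differentially expressed in at least one comparison.
#'
#' @param assignment A `map_assignment`.
#' @param X The clustered matrix (rows matching the assignment).
#' @param de_flags Logical matrix, same rows as `X`, columns = comparisons.
#' @param interpretable_fraction DE fraction a cluster must exceed (default 0.5).
#' @return List of class `cluster_summary` with `profiles` (one row per
#'   cluster x comparison: quartiles, whiskers, n_outliers, de_percent) and
#'   `clusters` (cluster, size, max_de_percent, interpretable, low_n).
#' @export
summarise_clusters <- function(assignment, X, de_flags,
                               interpretable_fraction = 0.5) {
  stopifnot(inherits(assignment, "map_assignment"),
            nrow(X) == length(assignment$map),
            nrow(de_flags) == nrow(X))
  if (!any(assignment$classified)) stop("no classified observations")
  X <- as.matrix(X)
  comps <- colnames(X)
  if (is.null(comps)) comps <- sprintf("dim%d", seq_len(ncol(X)))
  cl <- assignment$map[assignment$classified]
  Xc <- X[assignment$classified, , drop = FALSE]
  Dc <- de_flags[assignment$classified, , drop = FALSE]

  rows <- list()
  clus <- sort(unique(cl))
  for (k in clus) {
    member <- cl == k
    for (j in seq_along(comps)) {
      v <- Xc[member, j]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      wl <- q[1] - 1.5 * iqr; wh <- q[3] + 1.5 * iqr
      rows[[length(rows) + 1]] <- data.frame(
        cluster = k, comparison = comps[j], n = sum(member),
        q1 = q[1], median = q[2], q3 = q[3],
        whisker_low = wl, whisker_high = wh,
        n_outliers = sum(v < wl | v > wh),
        de_percent = 100 * mean(Dc[member, j]), stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(clus, function(k) {
    p <- profiles[profiles$cluster == k, ]
    data.frame(cluster = k, size = p$n[1],
               max_de_percent = max(p$de_percent),
               interpretable = max(p$de_percent) > 100 * interpretable_fraction,
               low_n = p$n[1] < 4, stringsAsFactors = FALSE)
  }))
  structure(list(profiles = profiles, clusters = agg),
            class = "cluster_summary")
}
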