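#' Fit a soft-margin SVDD sphere with a similarity-coefficient kernel
#'
#' Solves the support vector domain description dual
#' \deqn{\max_\beta \sum_i \beta_i K_{ii} - \sum_{ij} \beta_i \beta_j
#'       K_{ij} \quad \mathrm{s.t.}\ 0 \le \beta_i \le C_s,\ \sum_i
#'       \beta_i = 1,}
#' the smallest enclosing sphere of the data in the kernel feature space.
#' Samples with \eqn{0 < \beta_i < C_s} lie on the sphere (boundary
#' support vectors); samples at \eqn{\beta_i = C_s} are outside it
#' (bounded support vectors, outliers). Any similarity coefficient can
#' act as the kernel; because similarity coefficients are not guaranteed
#' positive semidefinite, the Gram matrix's smallest eigenvalue is checked
#' and, when it falls below \code{-1e-8 * trace}, a diagonal jitter of its
#' magnitude is added to keep the dual concave (the jitter used is
#' reported in the result).
#'
#' The dual is solved by sequential minimal pairwise updates that preserve
#' \eqn{\sum\beta = 1}: at each step the pair with the largest KKT
#' violation is updated analytically and clipped to the box. Iteration
#' stops when the maximal violation drops below \code{tol}.
#'
#' @param x Binary fingerprint matrix or [fpset].
#' @param kernel Similarity coefficient id or name.
#' @param cs Soft-margin upper bound \eqn{C_s} on the multipliers;
#'   requires \code{n * cs >= 1} for feasibility.
#' @param tol KKT convergence tolerance.
#' @param max_updates Cap on pairwise updates.
#' @param sv_tol Numerical threshold separating multipliers from the box
#'   edges when classifying support vectors.
#' @return An object of class \code{"svdd"}: \code{multipliers},
#'   \code{boundary_svs}, \code{bounded_svs} (index vectors),
#'   \code{radius_sq}, \code{offset} (\eqn{\beta^T K \beta}),
#'   \code{kernel}, \code{cs}, \code{jitter}, \code{n_updates},
#'   \code{kkt_gap} and the training data \code{X}.
#' @seealso [sphere_distance_sq()], [svc_labels()], [svc_representatives()]
#' @export
svdd_fit <- function(x, kernel = "C10", cs = 0.5, tol = 1e-6,
                     max_updates = 1e5, sv_tol = 1e-6) {
  X <- .as_bits(x)
  .check_bits(X)
  n <- nrow(X)
  stopifnot(cs > 0)
  if (n * cs < 1) {
    stop("infeasible: n * cs must be >= 1 so that sum(beta) = 1 fits in ",
         "the box", call. = FALSE)
  }
  kernel <- coef_info(kernel)$id
  K <- similarity_matrix(kernel, X, X)
  K <- (K + t(K)) / 2
  jitter <- 0
  if (n > 1L) {
    ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    tr <- sum(diag(K))
    if (ev_min < -1e-8 * max(tr, 1)) {
      jitter <- abs(ev_min)
      diag(K) <- diag(K) + jitter
    }
  }
  beta <- rep(1 / n, n)
  g <- diag(K) - 2 * drop(K %*% beta)   # dual gradient
  n_up <- 0L
  repeat {
    up_ok <- beta < cs - 1e-12
    dn_ok <- beta > 1e-12
    p <- which(up_ok)[which.max(g[up_ok])]
    q <- which(dn_ok)[which.min(g[dn_ok])]
    gap <- g[p] - g[q]
    if (!length(p) || !length(q) || gap < tol || n_up >= max_updates) break
    denom <- 2 * (K[p, p] + K[q, q] - 2 * K[p, q])
    delta <- if (denom > 1e-12) gap / denom else Inf
    delta <- min(delta, cs - beta[p], beta[q])
    if (delta <= 0) break
    beta[p] <- beta[p] + delta
    beta[q] <- beta[q] - delta
    g <- g - 2 * delta * (K[, p] - K[, q])
    n_up <- n_up + 1L
  }
  offset <- drop(crossprod(beta, K %*% beta))
  r2_all <- diag(K) - 2 * drop(K %*% beta) + offset
  boundary <- which(beta > sv_tol & beta < cs - sv_tol)
  bounded <- which(beta >= cs - sv_tol)
  radius_sq <- if (length(boundary)) {
    stats::median(r2_all[boundary])
  } else if (length(bounded)) {
    ## all support vectors at the bound: sphere shrinks to the interior
    max(r2_all[beta <= sv_tol], 0)
  } else {
    max(r2_all)
  }
  radius_sq <- max(radius_sq, 0)
  structure(list(multipliers = beta, boundary_svs = boundary,
                 bounded_svs = bounded, radius_sq = radius_sq,
                 offset = offset, kernel = kernel, cs = cs,
                 jitter = jitter, n_updates = n_up,
                 kkt_gap = if (length(gap) && is.finite(gap)) gap else 0,
                 X = X),
            class = "svdd")
}

#' @export
print.svdd <- function(x, ...) {
  cat("SVDD sphere (kernel ", x$kernel, ", Cs = ", x$cs, ")\n", sep = "")
  cat(sprintf("  %d samples: %d boundary SVs, %d bounded SVs (outliers)\n",
              nrow(x$X), length(x$boundary_svs), length(x$bounded_svs)))
  cat(sprintf("  squared radius: %.6g   KKT gap: %.2e   jitter: %.2e\n",
              x$radius_sq, x$kkt_gap, x$jitter))
  invisible(x)
}

#' Squared kernel-space distance to the SVDD sphere centre
#'
#' \eqn{R^2(z) = K(z, z) - 2\sum_i \beta_i K(x_i, z) + \sum_{ij} \beta_i
#' \beta_j K(x_i, x_j)}. Points with \eqn{R^2(z) \le R^2} lie inside the
#' sphere contour. \code{z} may contain real-valued rows (segment
#' interpolation points), evaluated with the soft-count kernel extension.
#'
#' @param object A fitted \code{"svdd"}.
#' @param z Query matrix (rows = points) or single vector.
#' @return Numeric vector of squared distances.
#' @export
sphere_distance_sq <- function(object, z) {
  stopifnot(inherits(object, "svdd"))
  if (is.null(dim(z))) z <- matrix(as.numeric(z), nrow = 1L)
  kzz <- diag(similarity_matrix(object$kernel, z, z))
  cross <- similarity_matrix(object$kernel, z, object$X)
  drop(kzz - 2 * cross %*% object$multipliers + object$offset)
}

#' Cluster labels from a fitted SVDD sphere
#'
#' Two non-outlier samples belong to the same cluster when the path
#' between them stays inside the sphere contour:
#' \code{n_segment_points} evenly spaced interior points (endpoints
#' excluded) are tested with [sphere_distance_sq()] against
#' \code{radius_sq + tol}. Cluster labels are the connected components of
#' the resulting adjacency graph; bounded support vectors (outliers) are
#' attached to the cluster of their most similar non-outlier sample.
#'
#' The default interpolation walks the Hamming path: the bits on which
#' the endpoints differ are flipped progressively (in index order), so
#' every tested point is itself a binary fingerprint and its kernel
#' self-similarity stays at the coefficient's maximum. Convex
#' (\code{"linear"}) interpolation with soft-count kernel evaluation is
#' available for comparison, but match-based kernels depress the soft
#' self-similarity of fractional points, which systematically shrinks
#' their sphere distance and over-merges clusters.
#'
#' @param object A fitted \code{"svdd"}.
#' @param n_segment_points Interior points tested per segment.
#' @param tol Slack added to the squared radius.
#' @param interpolation \code{"hamming"} (default) or \code{"linear"}.
#' @return Integer cluster label per training sample.
#' @export
svc_labels <- function(object, n_segment_points = 10, tol = 1e-6,
                       interpolation = c("hamming", "linear")) {
  stopifnot(inherits(object, "svdd"), n_segment_points >= 1)
  interpolation <- match.arg(interpolation)
  X <- object$X
  n <- nrow(X)
  inside <- setdiff(seq_len(n), object$bounded_svs)
  r2max <- object$radius_sq + tol
  ts <- seq_len(n_segment_points) / (n_segment_points + 1)
  segment <- function(xi, xj) {
    if (interpolation == "linear") {
      outer(1 - ts, xi) + outer(ts, xj)
    } else {
      diffs <- which(xi != xj)
      seg <- matrix(xi, length(ts), length(xi), byrow = TRUE)
      for (s in seq_along(ts)) {
        nf <- round(ts[s] * length(diffs))
        if (nf > 0L) {
          seg[s, diffs[seq_len(nf)]] <- xj[diffs[seq_len(nf)]]
        }
      }
      seg
    }
  }
  adj <- matrix(FALSE, n, n)
  if (length(inside) > 1L) {
    pairs <- utils::combn(inside, 2L)
    for (col in seq_len(ncol(pairs))) {
      i <- pairs[1L, col]; j <- pairs[2L, col]
      seg <- segment(X[i, ], X[j, ])
      if (all(sphere_distance_sq(object, seg) <= r2max)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  labels <- integer(n)
  comp <- 0L
  for (s in inside) {
    if (labels[s] == 0L) {
      comp <- comp + 1L
      queue <- s
      labels[s] <- comp
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- intersect(which(adj[v, ]), inside)
        nb <- nb[labels[nb] == 0L]
        labels[nb] <- comp
        queue <- c(queue, nb)
      }
    }
  }
  if (length(object$bounded_svs) && length(inside)) {
    S <- similarity_matrix(object$kernel,
                           X[object$bounded_svs, , drop = FALSE],
                           X[inside, , drop = FALSE])
    nearest <- inside[max.col(S, ties.method = "first")]
    labels[object$bounded_svs] <- labels[nearest]
  } else if (length(object$bounded_svs)) {
    labels[object$bounded_svs] <- 1L
  }
  labels
}

#' Hidden-node fingerprints selected by support vector clustering
#'
#' The cluster-bounding samples of the SVDD sphere: by default the
#' boundary support vectors only (\eqn{0 < \beta_i < C_s}); bounded
#' support vectors are outliers and do not bound a cluster, but can be
#' included with \code{include_bounded = TRUE}.
#'
#' @param object A fitted \code{"svdd"}.
#' @param include_bounded Also return bounded (outlier) support vectors.
#' @return \code{svc_representatives}: matrix of selected fingerprints;
#'   \code{svc_representative_index}: their row indices in the training
#'   data.
#' @export
svc_representatives <- function(object, include_bounded = FALSE) {
  idx <- svc_representative_index(object, include_bounded)
  object$X[idx, , drop = FALSE]
}

#' @rdname svc_representatives
#' @export
svc_representative_index <- function(object, include_bounded = FALSE) {
  stopifnot(inherits(object, "svdd"))
  idx <- object$boundary_svs
  if (include_bounded) idx <- sort(union(idx, object$bounded_svs))
  idx
}

#' Common hidden-node selection contract
#'
#' Dispatches to the three node selectors behind [wselm()] and returns
#' the selected binary rows plus their indices; useful for inspecting
#' what a given method would pick without fitting the output layer.
#'
#' @param x Binary fingerprint matrix or [fpset].
#' @param method \code{"random"}, \code{"kmeans"} or \code{"svc"}.
#' @param coef Similarity coefficient for the clustering geometry/kernel.
#' @param l,k,cs Method parameters as in [wselm()].
#' @param seed Integer seed.
#' @param include_bounded See [svc_representatives()].
#' @return List with \code{W} (binary matrix) and \code{index}.
#' @export
select_nodes <- function(x, method = c("random", "kmeans", "svc"),
                         coef = "C10", l = NULL, k = NULL, cs = 0.5,
                         seed = 1, include_bounded = FALSE) {
  method <- match.arg(method)
  X <- .as_bits(x)
  n <- nrow(X)
  switch(method,
    random = {
      if (is.null(l)) l <- n
      if (l < 1L || l > n) stop("l must be in 1..n", call. = FALSE)
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(as.integer(seed))
      idx <- sample.int(n, l)
      list(W = X[idx, , drop = FALSE], index = idx)
    },
    kmeans = {
      if (is.null(k)) k <- n
      km <- kmeans_representatives(X, k = k, coef = coef, seed = seed)
      list(W = km$representatives, index = km$representative_index)
    },
    svc = {
      fit <- svdd_fit(X, kernel = coef, cs = cs)
      idx <- svc_representative_index(fit, include_bounded)
      list(W = X[idx, , drop = FALSE], index = idx)
    })
}
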