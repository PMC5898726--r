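#' k-means hidden-node selection on binary fingerprints
#'
#' Lloyd-style k-means under the geometry of a similarity coefficient:
#' the distance between a sample and a centroid is \eqn{1 - s_{norm}},
#' where \eqn{s_{norm}} is the coefficient affinely rescaled to [0, 1]
#' (identity for coefficients already on [0, 1]). Centroids are
#' real-valued coordinate means; similarity of a binary sample to a real
#' centroid evaluates the coefficient formulas on fractional "soft"
#' contingency counts (see [similarity_matrix()]). Because hidden nodes
#' must be actual binary fingerprints, each cluster is finally represented
#' by its member sample most similar to the cluster centroid.
#'
#' Initialisation is greedy farthest-point seeding: the seeded generator
#' picks the first centre uniformly, and each subsequent centre is the
#' sample farthest (max-min distance) from those chosen so far, ties
#' broken by lowest index. An iteration that fails to decrease the
#' objective (sum of within-cluster distances) terminates the loop with
#' the previous state, so the reported objective trace is non-increasing.
#' A cluster left empty after assignment is re-seeded at the sample
#' farthest from its current centroid.
#'
#' @param x Binary fingerprint matrix or [fpset].
#' @param k Number of clusters, \code{1 <= k <= n}.
#' @param coef Similarity coefficient defining the geometry.
#' @param seed Integer seed (initialisation only; the rest is
#'   deterministic).
#' @param max_iter Iteration cap.
#' @return List with \code{representatives} (\code{k} binary rows, actual
#'   samples), \code{representative_index}, \code{assignments},
#'   \code{centroids} (real-valued), \code{n_iter} and \code{objective}
#'   (trace across iterations).
#' @export
kmeans_representatives <- function(x, k, coef = "C10", seed = 1,
                                   max_iter = 100) {
  X <- .as_bits(x)
  .check_bits(X)
  n <- nrow(X)
  if (k < 1L || k > n) {
    stop("k must be in 1..n (n = ", n, ")", call. = FALSE)
  }
  info <- coef_info(coef)
  dist_to <- function(centers) {
    ## rows = samples, cols = centers; distance = 1 - rescaled similarity
    s <- similarity_matrix(coef, X, centers)
    1 - (s - info$lo) / (info$hi - info$lo)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  centers_idx <- sample.int(n, 1L)
  if (k > 1L) {
    dmin <- dist_to(X[centers_idx, , drop = FALSE])[, 1L]
    for (j in 2L:k) {
      cand <- which.max(dmin)  # ties: lowest index
      centers_idx <- c(centers_idx, cand)
      dmin <- pmin(dmin, dist_to(X[cand, , drop = FALSE])[, 1L])
    }
  }
  centroids <- X[centers_idx, , drop = FALSE]
  assign_prev <- rep(0L, n)
  obj_trace <- numeric(0)
  state <- NULL
  for (iter in seq_len(max_iter)) {
    D <- dist_to(centroids)
    assignments <- max.col(-D, ties.method = "first")
    obj <- sum(D[cbind(seq_len(n), assignments)])
    if (length(obj_trace) && obj > obj_trace[length(obj_trace)] + 1e-12) {
      break  # mean-update worsened the similarity objective: keep previous
    }
    obj_trace <- c(obj_trace, obj)
    state <- list(assignments = assignments, centroids = centroids,
                  D = D, n_iter = iter)
    if (identical(assignments, assign_prev)) break
    assign_prev <- assignments
    for (j in seq_len(k)) {
      members <- which(assignments == j)
      if (length(members)) {
        centroids[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        ## re-seed empty cluster at the sample farthest from its centroid
        far <- which.max(D[cbind(seq_len(n), assignments)])
        centroids[j, ] <- X[far, ]
        assignments[far] <- j
      }
    }
  }
  assignments <- state$assignments
  ## final centroids: coordinate means of the accepted assignment, so the
  ## representative is the member closest to its cluster's mean
  centroids <- state$centroids
  for (j in seq_len(k)) {
    members <- which(assignments == j)
    if (length(members)) {
      centroids[j, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  rep_idx <- integer(k)
  S <- similarity_matrix(coef, X, centroids)
  for (j in seq_len(k)) {
    members <- which(assignments == j)
    if (!length(members)) members <- seq_len(n)
    rep_idx[j] <- members[which.max(S[members, j])]
  }
  list(representatives = X[rep_idx, , drop = FALSE],
       representative_index = rep_idx,
       assignments = assignments, centroids = centroids,
       n_iter = state$n_iter, objective = obj_trace)
}
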