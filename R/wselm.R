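#' Class-imbalance weights for a +1/-1 label vector
#'
#' Each training molecule receives a weight
#' \eqn{\gamma_i = \max(n_I, n_A)/n_A} if it is active and
#' \eqn{\max(n_I, n_A)/n_I} if inactive, so the minority class is
#' up-weighted to parity with the majority and all weights are >= 1.
#'
#' @param y Label vector coded +1 (active) / -1 (inactive); both classes
#'   must be present.
#' @return List with \code{gamma} (per-sample weights), \code{n_active},
#'   \code{n_inactive}.
#' @examples
#' class_weights(c(1, 1, -1, -1, -1, -1))
#' @export
class_weights <- function(y) {
  y <- .check_labels(y)
  n_a <- sum(y == 1)
  n_i <- sum(y == -1)
  if (n_a == 0L || n_i == 0L) {
    stop("both classes must be present to define imbalance weights",
         call. = FALSE)
  }
  top <- max(n_a, n_i)
  gamma <- ifelse(y == 1, top / n_a, top / n_i)
  list(gamma = gamma, n_active = n_a, n_inactive = n_i)
}

.check_labels <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(1, -1))) {
    stop("labels must be coded +1 (active) / -1 (inactive)", call. = FALSE)
  }
  y
}

#' Similarity-activation hidden-layer matrix
#'
#' The hidden layer of a WS-ELM has one node per hidden fingerprint
#' \code{w_j}; the activation of sample \code{x_i} at node \code{j} is the
#' similarity coefficient \code{s(x_i, w_j)} (replacing the usual
#' sigmoidal \code{g(w'x + b)}; there is no bias term).
#'
#' @param x Sample fingerprints (binary matrix or [fpset]).
#' @param w Hidden-node fingerprints (binary matrix, rows drawn from the
#'   training data).
#' @param coef Similarity coefficient id or name.
#' @return \code{n x l} activation matrix.
#' @export
hidden_matrix <- function(x, w, coef) {
  similarity_matrix(coef, x, w)
}

#' Solve the weighted ridge output layer
#'
#' Computes the output weights \eqn{\beta} solving
#' \deqn{(I/C + \hat H^T \hat H)\,\beta = \hat H^T(\gamma y),\qquad
#'       \hat H = \gamma \cdot H,}
#' i.e. the minimiser of \eqn{\|\hat H\beta - \gamma y\|_2^2 +
#' \|\beta\|_2^2 / C}. Row \code{i} of \code{H} is scaled by
#' \eqn{\gamma_i}, so samples enter the normal equations with effective
#' weight \eqn{\gamma_i^2} (\code{weighting = "squared"}, the default).
#' \code{weighting = "linear"} instead solves
#' \eqn{(I/C + H^T \Gamma H)\beta = H^T \Gamma y}, the variant in which
#' the weights enter linearly.
#'
#' The system is solved by a Cholesky factorisation of the symmetric
#' positive-definite ridge matrix, never by explicit inversion.
#'
#' @param h Hidden activation matrix (\code{n x l}).
#' @param y +1/-1 labels.
#' @param gamma Per-sample weights (e.g. from [class_weights()]); defaults
#'   to all ones.
#' @param C Positive ridge regularisation constant (larger = weaker
#'   penalty).
#' @param weighting \code{"squared"} (row-scaling, the default) or
#'   \code{"linear"}.
#' @return Numeric vector \code{beta} of length \code{ncol(h)}.
#' @export
solve_beta <- function(h, y, gamma = NULL, C = 1,
                       weighting = c("squared", "linear")) {
  weighting <- match.arg(weighting)
  h <- as.matrix(h)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(h), is.numeric(C), length(C) == 1L, C > 0)
  if (is.null(gamma)) gamma <- rep(1, nrow(h))
  stopifnot(length(gamma) == nrow(h), all(gamma > 0))
  l <- ncol(h)
  if (weighting == "squared") {
    hh <- gamma * h
    A <- crossprod(hh)
    rhs <- crossprod(hh, gamma * y)
  } else {
    A <- crossprod(h, gamma * h)
    rhs <- crossprod(h, gamma * y)
  }
  diag(A) <- diag(A) + 1 / C
  if (any(!is.finite(A)) || any(!is.finite(rhs))) {
    stop("non-finite values in the normal equations; check C and the ",
         "weights for overflow", call. = FALSE)
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    stop("ridge system numerically singular despite regularisation ",
         "(C = ", C, "); this indicates overflow in H or gamma",
         call. = FALSE)
  }
  beta <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  drop(beta)
}

#' Fit a weighted similarity extreme learning machine
#'
#' `wselm()` trains the screening model of this package: a single hidden
#' layer whose activations are fingerprint-similarity coefficients against
#' hidden-node fingerprints taken from the training data, and a
#' ridge-regularised, class-imbalance-weighted linear output layer (see
#' [solve_beta()]). The hidden nodes are chosen by one of three methods:
#'
#' \describe{
#'   \item{\code{"random"}}{(WS-ELM) \code{l} distinct training rows
#'     sampled uniformly without replacement with the given seed.}
#'   \item{\code{"kmeans"}}{(CWS-ELM, k-means) one representative training
#'     sample per cluster, the member closest to each cluster centroid
#'     under the coefficient's geometry; see [kmeans_representatives()].}
#'   \item{\code{"svc"}}{(CWS-ELM, support vector clustering) the boundary
#'     support vectors of an SVDD sphere fitted with the similarity
#'     coefficient as kernel; see [svdd_fit()]. The node count follows
#'     from \code{cs} rather than being set directly.}
#' }
#'
#' Clustering-based selection runs unsupervised on the full training set
#' (actives and inactives together). Scores are oriented so that higher
#' means more likely active.
#'
#' @param x Training fingerprints: an [fpset] (labels taken from it when
#'   \code{y} is missing) or a binary matrix.
#' @param y Labels coded +1/-1; both classes required.
#' @param coef Similarity coefficient id or name (default
#'   \code{"C10"}, Sokal/Sneath(1)).
#' @param method Hidden-node selection method.
#' @param C Ridge regularisation constant.
#' @param l Hidden-node count for \code{method = "random"} (default
#'   \code{nrow(x)}).
#' @param k Cluster count for \code{method = "kmeans"} (default
#'   \code{nrow(x)}).
#' @param cs SVDD soft-margin bound in (0, 1] for \code{method = "svc"}.
#' @param seed Integer seed for the stochastic parts (node sampling,
#'   k-means initialisation).
#' @param weighting Weighted-ridge variant, see [solve_beta()].
#' @param include_bounded For \code{"svc"}: also use bounded support
#'   vectors (outliers) as hidden nodes.
#' @param max_iter Iteration cap for k-means.
#' @return An object of class \code{"wselm"} with components \code{W}
#'   (hidden-node fingerprints), \code{beta}, \code{coef}, \code{C},
#'   \code{method}, \code{l} (node count), \code{node_frac}
#'   (\code{l/n} training fraction), \code{gamma} summary, \code{fitted}
#'   (training scores) and \code{selection} (method-specific details).
#' @seealso [predict.wselm()], [write_wselm()], [run_benchmark()]
#' @examples
#' fp <- generate_synthetic(n_active = 10, n_inactive = 60, m = 64, seed = 2)
#' fit <- wselm(fp, coef = "C03", method = "random", l = 30, C = 10, seed = 1)
#' fit
#' head(predict(fit, fp))
#' @export
wselm <- function(x, y = NULL, coef = "C10",
                  method = c("random", "kmeans", "svc"),
                  C = 1, l = NULL, k = NULL, cs = 0.5, seed = 1,
                  weighting = c("squared", "linear"),
                  include_bounded = FALSE, max_iter = 100) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  if (is.null(y) && inherits(x, "fpset")) y <- x$labels
  X <- .as_bits(x)
  .check_bits(X)
  y <- .check_labels(y)
  if (length(y) != nrow(X)) {
    stop("labels length does not match number of training molecules",
         call. = FALSE)
  }
  n <- nrow(X)
  if (n < 2L) stop("need at least two training molecules", call. = FALSE)
  cw <- class_weights(y)
  sel <- switch(method,
    random = {
      if (is.null(l)) l <- n
      if (l < 1L || l > n) {
        stop("hidden-node count l must be in 1..n (n = ", n, ")",
             call. = FALSE)
      }
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
      idx <- sample.int(n, l)
      list(W = X[idx, , drop = FALSE], index = idx)
    },
    kmeans = {
      if (is.null(k)) k <- n
      km <- kmeans_representatives(X, k = k, coef = coef, seed = seed,
                                   max_iter = max_iter)
      list(W = km$representatives, index = km$representative_index,
           kmeans = km)
    },
    svc = {
      fit <- svdd_fit(X, kernel = coef, cs = cs)
      idx <- svc_representative_index(fit, include_bounded = include_bounded)
      if (!length(idx)) {
        stop("SVC selected no hidden nodes (no boundary support vectors ",
             "at cs = ", cs, "); decrease cs or set include_bounded = TRUE",
             call. = FALSE)
      }
      list(W = X[idx, , drop = FALSE], index = idx, svdd = fit)
    })
  W <- sel$W
  H <- hidden_matrix(X, W, coef)
  beta <- solve_beta(H, y, gamma = cw$gamma, C = C, weighting = weighting)
  fitted <- drop(H %*% beta)
  out <- list(W = W, beta = beta, coef = coef_info(coef)$id,
              coef_name = coef_info(coef)$name,
              C = C, method = method, l = nrow(W),
              node_frac = nrow(W) / n, n_train = n,
              n_active = cw$n_active, n_inactive = cw$n_inactive,
              weighting = weighting, seed = seed,
              cs = if (method == "svc") cs else NULL,
              selection = sel[setdiff(names(sel), "W")],
              fitted = fitted, y = y,
              call = match.call())
  class(out) <- "wselm"
  out
}

#' Predict screening scores from a fitted WS-ELM
#'
#' Scores are \code{H(newdata) \%*\% beta} where \code{H} holds the
#' similarity activations of the new molecules against the model's hidden
#' nodes; higher score means more likely active. Prediction is
#' deterministic and row-order equivariant.
#'
#' @param object A fitted \code{"wselm"} model.
#' @param newdata Binary fingerprint matrix or [fpset] with the model's
#'   bit length.
#' @param ... Unused.
#' @return Numeric score vector, one value per molecule.
#' @export
predict.wselm <- function(object, newdata, ...) {
  X <- .as_bits(newdata)
  if (ncol(X) != ncol(object$W)) {
    stop("newdata bit length (", ncol(X), ") does not match the model (",
         ncol(object$W), ")", call. = FALSE)
  }
  drop(hidden_matrix(X, object$W, object$coef) %*% object$beta)
}

#' @export
coef.wselm <- function(object, ...) object$beta

#' @export
fitted.wselm <- function(object, ...) object$fitted

#' @export
residuals.wselm <- function(object, ...) object$y - object$fitted

#' @export
print.wselm <- function(x, ...) {
  label <- switch(x$method, random = "WS-ELM (random nodes)",
                  kmeans = "CWS-ELM (k-means nodes)",
                  svc = "CWS-ELM (SVC nodes)")
  cat(label, "with", x$coef, paste0("[", x$coef_name, "]"),
      "similarity activations\n")
  cat(sprintf("  hidden nodes: %d of %d training molecules (%.1f%%)\n",
              x$l, x$n_train, 100 * x$node_frac))
  if (!is.null(x$n_active)) {
    cat(sprintf("  ridge C: %g   class weights: gamma_active = %.3g, ",
                x$C, max(x$n_inactive, x$n_active) / x$n_active))
    cat(sprintf("gamma_inactive = %.3g\n",
                max(x$n_inactive, x$n_active) / x$n_inactive))
  } else {
    cat(sprintf("  ridge C: %g\n", x$C))
  }
  invisible(x)
}

#' @export
summary.wselm <- function(object, ...) {
  tr_auc <- auroc(object$fitted, object$y)
  out <- list(model = object, train_auroc = tr_auc,
              beta_norm = sqrt(sum(object$beta^2)),
              beta_range = range(object$beta))
  class(out) <- "summary.wselm"
  out
}

#' @export
print.summary.wselm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training AUROC: %.4f\n", x$train_auroc))
  cat(sprintf("  ||beta||_2: %.4g   beta range: [%.4g, %.4g]\n",
              x$beta_norm, x$beta_range[1], x$beta_range[2]))
  invisible(x)
}

#' Serialise a WS-ELM model to a text file
#'
#' Writes a plain-text representation (header fields, beta values, hidden
#' nodes as 0/1 strings) that [read_wselm()] restores exactly; used by the
#' command-line \code{screen} tool.
#'
#' @param object A fitted \code{"wselm"} model.
#' @param path Output path.
#' @export
write_wselm <- function(object, path) {
  stopifnot(inherits(object, "wselm"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("wselm-model 1",
               paste("coef", object$coef),
               paste("method", object$method),
               paste("weighting", object$weighting),
               paste("C", format(object$C, digits = 17)),
               paste("n_train", object$n_train),
               paste(c("beta", format(object$beta, digits = 17,
                                      trim = TRUE)), collapse = " ")),
             con)
  writeLines(apply(object$W, 1L,
                   function(r) paste(as.integer(r), collapse = "")), con)
  invisible(path)
}

#' @rdname write_wselm
#' @return \code{read_wselm} returns the restored \code{"wselm"} object
#'   (training-set fields such as fitted values are not stored and come
#'   back as \code{NULL}).
#' @export
read_wselm <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!grepl("^wselm-model 1", lines[1L])) {
    stop("not a wselm model file: ", path, call. = FALSE)
  }
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1L]
    sub(paste0("^", key, " "), "", ln)
  }
  beta <- as.numeric(strsplit(field("beta"), " ")[[1L]])
  w_lines <- lines[-seq_len(7L)]
  W <- matrix(as.numeric(unlist(strsplit(w_lines, ""))),
              nrow = length(w_lines), byrow = TRUE)
  cid <- field("coef")
  out <- list(W = W, beta = beta, coef = cid,
              coef_name = coef_info(cid)$name,
              C = as.numeric(field("C")), method = field("method"),
              l = nrow(W), n_train = as.integer(field("n_train")),
              node_frac = nrow(W) / as.integer(field("n_train")),
              weighting = field("weighting"))
  class(out) <- "wselm"
  out
}
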