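#' Train/test split following the MUV screening protocol
#'
#' Builds one random split for a target activity class: the training set
#' holds \code{n_active_train} randomly chosen target-class actives
#' (labelled +1) plus \code{n_train - n_active_train} molecules sampled
#' from the non-target pool (other classes' actives, treated as
#' inactives, together with the decoys), labelled -1. The test set is
#' everything else: the remaining target actives and the remaining
#' inactives. Train and test are disjoint by construction.
#'
#' @param actives [fpset] (or binary matrix) of active molecules across
#'   all classes.
#' @param inactives [fpset] (or binary matrix) of decoys.
#' @param active_class Class label per row of \code{actives};
#'   \code{NULL} treats all actives as the target class.
#' @param target Which class in \code{active_class} is screened for.
#' @param n_train Total training molecules (protocol default 170).
#' @param n_active_train Target actives in training (protocol default 10).
#' @param other_actives \code{"inactive"} (default): other classes'
#'   actives join the inactive pool; \code{"exclude"}: they are dropped
#'   entirely.
#' @param seed Integer seed.
#' @return List with [fpset]s \code{train} and \code{test}.
#' @export
make_split <- function(actives, inactives, active_class = NULL,
                       target = NULL, n_train = 170, n_active_train = 10,
                       other_actives = c("inactive", "exclude"), seed = 1) {
  other_actives <- match.arg(other_actives)
  a_ids <- if (inherits(actives, "fpset")) actives$ids else
    paste0("act", seq_len(nrow(.as_bits(actives))))
  i_ids <- if (inherits(inactives, "fpset")) inactives$ids else
    paste0("inact", seq_len(nrow(.as_bits(inactives))))
  A <- .as_bits(actives)
  I <- .as_bits(inactives)
  if (ncol(A) != ncol(I)) stop("bit lengths differ", call. = FALSE)
  if (is.null(active_class)) active_class <- rep("target", nrow(A))
  if (is.null(target)) target <- active_class[1L]
  is_target <- active_class == target
  if (sum(is_target) < n_active_train) {
    stop("target class has fewer than n_active_train = ", n_active_train,
         " actives", call. = FALSE)
  }
  if (n_active_train > n_train) {
    stop("n_active_train exceeds n_train", call. = FALSE)
  }
  pool_neg <- rbind(if (other_actives == "inactive") {
    A[!is_target, , drop = FALSE]
  }, I)
  pool_neg_ids <- c(if (other_actives == "inactive") a_ids[!is_target],
                    i_ids)
  n_neg_train <- n_train - n_active_train
  if (nrow(pool_neg) < n_neg_train + 1L) {
    stop("not enough inactive-pool molecules for the split", call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  pos_idx <- sample(which(is_target), n_active_train)
  neg_idx <- sample.int(nrow(pool_neg), n_neg_train)
  tr_bits <- rbind(A[pos_idx, , drop = FALSE],
                   pool_neg[neg_idx, , drop = FALSE])
  tr_lab <- c(rep(1L, n_active_train), rep(-1L, n_neg_train))
  te_pos <- setdiff(which(is_target), pos_idx)
  te_neg <- setdiff(seq_len(nrow(pool_neg)), neg_idx)
  te_bits <- rbind(A[te_pos, , drop = FALSE],
                   pool_neg[te_neg, , drop = FALSE])
  te_lab <- c(rep(1L, length(te_pos)), rep(-1L, length(te_neg)))
  list(train = fpset(tr_bits, labels = tr_lab,
                     ids = c(a_ids[pos_idx], pool_neg_ids[neg_idx])),
       test = fpset(te_bits, labels = te_lab,
                    ids = c(a_ids[te_pos], pool_neg_ids[te_neg])))
}

#' Hyper-parameter grids of the benchmarking protocol
#'
#' The protocol grids: ridge constant \code{C} over the 13 decades
#' \eqn{10^{-6} \ldots 10^{6}}; hidden-node count \code{l} (random
#' selection) and cluster count \code{k} (k-means) over \code{1..n_train};
#' SVDD bound \code{cs} over 0.1..1.0 in steps of 0.1. \code{l_values}
#' and \code{k_values} default to a thinned subset for tractable search;
#' pass explicit vectors for the full range.
#'
#' @param n_train Training-set size the node grids refer to.
#' @param l_values,k_values,C_values,cs_values Optional explicit grids.
#' @return List of grid vectors.
#' @export
default_grid <- function(n_train = 170, l_values = NULL, k_values = NULL,
                         C_values = NULL, cs_values = NULL) {
  if (is.null(C_values)) C_values <- 10^seq(-6, 6)
  if (is.null(l_values)) {
    l_values <- unique(pmax(1L, round(seq(0.1, 1, by = 0.1) * n_train)))
  }
  if (is.null(k_values)) k_values <- l_values
  if (is.null(cs_values)) cs_values <- seq(0.1, 1.0, by = 0.1)
  list(l_values = l_values, k_values = k_values, C_values = C_values,
       cs_values = cs_values)
}

#' Cross-validated grid search for WS-ELM hyper-parameters
#'
#' Five-fold stratified cross-validation on training AUROC: folds
#' preserve the positive count to within one (required -- with 10
#' positives in 170 molecules an unstratified fold can easily contain no
#' positives, leaving AUROC undefined). The grid is scanned in order of
#' increasing model size (\code{l}/\code{k}/\code{cs}) then increasing
#' \code{C}, and the first point attaining the maximal mean validation
#' AUROC is returned, so ties favour the simpler model.
#'
#' @param x Training fingerprints ([fpset] or binary matrix).
#' @param y +1/-1 labels (taken from \code{x} if missing).
#' @param coef Similarity coefficient.
#' @param method Node-selection method as in [wselm()].
#' @param grid List as from [default_grid()]; only the components the
#'   method uses are consulted.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed (fold shuffling and node sampling).
#' @param weighting Passed to [wselm()].
#' @return List: \code{best} (named list of selected parameters),
#'   \code{results} (data frame of all grid points with mean validation
#'   AUROC).
#' @export
cv_grid_search <- function(x, y = NULL, coef = "C10",
                           method = c("random", "kmeans", "svc"),
                           grid = default_grid(nrow(.as_bits(x))),
                           n_folds = 5, seed = 1,
                           weighting = c("squared", "linear")) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  if (is.null(y) && inherits(x, "fpset")) y <- x$labels
  X <- .as_bits(x)
  y <- .check_labels(y)
  folds <- .stratified_folds(y, n_folds, seed)
  size_values <- switch(method, random = grid$l_values,
                        kmeans = grid$k_values, svc = grid$cs_values)
  size_values <- sort(unique(size_values))
  if (method != "svc") {
    ## node counts are bounded by the smallest CV training partition
    min_fit <- min(vapply(seq_len(n_folds),
                          function(f) sum(folds != f), 0L))
    size_values <- size_values[size_values >= 1 & size_values <= min_fit]
  }
  C_values <- sort(grid$C_values)
  res <- expand.grid(size = size_values, C = C_values,
                     KEEP.OUT.ATTRS = FALSE)
  res$auroc <- NA_real_
  for (r in seq_len(nrow(res))) {
    aucs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- switch(method,
        random = wselm(X[tr, , drop = FALSE], y[tr], coef = coef,
                       method = "random", l = res$size[r], C = res$C[r],
                       seed = seed, weighting = weighting),
        kmeans = wselm(X[tr, , drop = FALSE], y[tr], coef = coef,
                       method = "kmeans", k = res$size[r], C = res$C[r],
                       seed = seed, weighting = weighting),
        svc = wselm(X[tr, , drop = FALSE], y[tr], coef = coef,
                    method = "svc", cs = res$size[r], C = res$C[r],
                    seed = seed, weighting = weighting))
      sc <- predict(fit, X[!tr, , drop = FALSE])
      aucs[f] <- auroc(sc, y[!tr])
    }
    res$auroc[r] <- mean(aucs)
  }
  best_row <- which.max(res$auroc)  # grid ordered simple-first; first max
  best <- list(C = res$C[best_row], auroc = res$auroc[best_row])
  best[[switch(method, random = "l", kmeans = "k", svc = "cs")]] <-
    res$size[best_row]
  names(res)[1L] <- switch(method, random = "l", kmeans = "k", svc = "cs")
  list(best = best, results = res)
}

## stratified fold ids: within each class, shuffled then dealt round-robin,
## so positive counts differ by at most one across folds
.stratified_folds <- function(y, n_folds, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in c(1, -1)) {
    idx <- which(y == cls)
    if (length(idx) < n_folds && cls == 1) {
      stop("fewer positives (", length(idx), ") than folds (", n_folds,
           "); stratification impossible", call. = FALSE)
    }
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Similarity-searching baseline scores
#'
#' Scores every test molecule by its mean similarity to the training
#' actives (the multi-query group similarity): the classical
#' ligand-based baseline, which uses no inactive information.
#'
#' @param train_actives Binary matrix or [fpset] of the training actives
#'   only.
#' @param test Test fingerprints.
#' @param coef Similarity coefficient.
#' @return Numeric score per test molecule.
#' @export
similarity_search_baseline <- function(train_actives, test, coef = "C10") {
  A <- .as_bits(train_actives)
  if (nrow(A) < 1L) stop("no training actives", call. = FALSE)
  rowMeans(similarity_matrix(coef, .as_bits(test), A))
}

#' Run the screening benchmark protocol
#'
#' For each method/coefficient combination and each of \code{n_runs}
#' random splits: tune hyper-parameters by [cv_grid_search()] on the
#' training set, refit on the full training set, score the test set, and
#' record hit rate, enrichment factor, AUROC and BEDROC together with the
#' tuned parameters and the hidden-node percentage. The
#' \code{"similarity"} method is the untuned similarity-searching
#' baseline. Per-run seeds are derived deterministically from
#' \code{master_seed}, so the whole protocol replays exactly.
#'
#' @param actives,inactives Fingerprints as in [make_split()].
#' @param methods Subset of \code{c("similarity", "random", "kmeans",
#'   "svc")}.
#' @param coefs Coefficient ids/names to evaluate.
#' @param n_runs Number of random splits (protocol default 10).
#' @param master_seed Integer master seed.
#' @param grid Hyper-parameter grid (see [default_grid()]).
#' @param n_train,n_active_train Split sizes (see [make_split()]).
#' @param fraction Top fraction for hit rate / EF.
#' @param alpha BEDROC early-recognition parameter.
#' @param n_folds CV folds.
#' @param active_class,target Forwarded to [make_split()].
#' @return Data frame with one row per (method, coef, run).
#' @seealso [aggregate_benchmark()]
#' @export
run_benchmark <- function(actives, inactives,
                          methods = c("similarity", "random", "kmeans",
                                      "svc"),
                          coefs = c("C03", "C10"), n_runs = 10,
                          master_seed = 1,
                          grid = default_grid(n_train),
                          n_train = 170, n_active_train = 10,
                          fraction = 0.01, alpha = 160.9, n_folds = 5,
                          active_class = NULL, target = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (run in seq_len(n_runs)) {
    run_seed <- (as.integer(master_seed) + 104729L * run) %% 2147483647L
    sp <- make_split(actives, inactives, active_class = active_class,
                     target = target, n_train = n_train,
                     n_active_train = n_active_train, seed = run_seed)
    tr <- sp$train; te <- sp$test
    for (coef in coefs) {
      cid <- coef_info(coef)$id
      for (method in methods) {
        if (method == "similarity") {
          sc <- similarity_search_baseline(
            tr$bits[tr$labels == 1L, , drop = FALSE], te, coef = cid)
          tuned <- list(); node_pct <- NA_real_
        } else {
          cv <- cv_grid_search(tr, coef = cid, method = method,
                               grid = grid, n_folds = n_folds,
                               seed = run_seed)
          tuned <- cv$best
          fit <- switch(method,
            random = wselm(tr, coef = cid, method = "random",
                           l = tuned$l, C = tuned$C, seed = run_seed),
            kmeans = wselm(tr, coef = cid, method = "kmeans",
                           k = tuned$k, C = tuned$C, seed = run_seed),
            svc = wselm(tr, coef = cid, method = "svc", cs = tuned$cs,
                        C = tuned$C, seed = run_seed))
          sc <- predict(fit, te)
          node_pct <- 100 * fit$node_frac
        }
        rs <- rank_screen(sc, te$labels)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, coef = cid, run = run,
          hit_rate = hit_rate(rs, fraction),
          ef = enrichment_factor(rs, fraction),
          auroc = auroc(sc, te$labels),
          bedroc = bedroc(rs, alpha),
          node_pct = node_pct,
          C = if (is.null(tuned$C)) NA_real_ else tuned$C,
          size = if (!is.null(tuned$l)) tuned$l else
                 if (!is.null(tuned$k)) tuned$k else
                 if (!is.null(tuned$cs)) tuned$cs else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a benchmark table to method/coefficient means
#'
#' @param results Data frame from [run_benchmark()].
#' @return Data frame of per-(method, coef) means of the metric columns.
#' @export
aggregate_benchmark <- function(results) {
  metrics <- c("hit_rate", "ef", "auroc", "bedroc", "node_pct")
  agg <- stats::aggregate(results[metrics],
                          by = results[c("method", "coef")],
                          FUN = mean)
  agg[order(agg$method, agg$coef), , drop = FALSE]
}
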