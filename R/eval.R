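#' Rank a scored screen
#'
#' Orders molecules by descending score; ties are broken by ascending
#' original index, so the ordering is total and deterministic (this
#' tie-break also decides inclusion at any top-fraction cut-off, making
#' every early-recognition metric bit-for-bit reproducible).
#'
#' @param scores Numeric screening scores (higher = more likely active).
#' @param labels +1/-1 activity labels, same length.
#' @return Object of class \code{"ranked_screen"}: \code{order}
#'   (permutation of indices), \code{ordered_labels}, \code{n},
#'   \code{n_actives}, plus the original \code{scores} and \code{labels}.
#' @export
rank_screen <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- .check_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (!length(scores)) stop("empty screen", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  structure(list(order = ord, ordered_labels = labels[ord],
                 n = length(scores), n_actives = sum(labels == 1),
                 scores = scores, labels = labels),
            class = "ranked_screen")
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat("Ranked screen:", x$n, "molecules,", x$n_actives, "actives\n")
  invisible(x)
}

.top_size <- function(rs, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  max(1L, round(fraction * rs$n))
}

#' Hit rate in the top fraction of a ranked screen
#'
#' The percentage of the maximum retrievable number of actives found in
#' the top \code{fraction} of the ranking: with a top window of
#' \code{n_top = round(fraction * n)} molecules (floor 1), the default
#' denominator is \code{min(n_actives, n_top)} -- the largest number of
#' actives the window could possibly hold -- so a perfect screen always
#' scores 100. Set \code{denominator = "n_actives"} for the plain recall
#' variant.
#'
#' @param rs A [rank_screen()] result.
#' @param fraction Top fraction of the database, e.g. 0.01.
#' @param denominator \code{"max_possible"} (default) or
#'   \code{"n_actives"}.
#' @return Percentage in [0, 100].
#' @export
hit_rate <- function(rs, fraction = 0.01,
                     denominator = c("max_possible", "n_actives")) {
  stopifnot(inherits(rs, "ranked_screen"))
  denominator <- match.arg(denominator)
  n_top <- .top_size(rs, fraction)
  hits <- sum(rs$ordered_labels[seq_len(n_top)] == 1)
  den <- switch(denominator,
                max_possible = min(rs$n_actives, n_top),
                n_actives = rs$n_actives)
  if (den == 0) stop("screen contains no actives", call. = FALSE)
  100 * hits / den
}

#' Enrichment factor at a top fraction
#'
#' Ratio of the active concentration in the top window to the active
#' concentration in the whole database:
#' \eqn{EF = (hits/n_{top}) / (n_A/n)}. Equals 1 in expectation for a
#' random ranking; the maximum is \eqn{n/n_A} (capped by the window).
#'
#' @inheritParams hit_rate
#' @return Non-negative scalar.
#' @export
enrichment_factor <- function(rs, fraction = 0.01) {
  stopifnot(inherits(rs, "ranked_screen"))
  if (rs$n_actives < 1) stop("screen contains no actives", call. = FALSE)
  n_top <- .top_size(rs, fraction)
  hits <- sum(rs$ordered_labels[seq_len(n_top)] == 1)
  (hits / n_top) / (rs$n_actives / rs$n)
}

#' Ratio of true positive to false positive rate at a top fraction
#'
#' TPR/FPR with the top window as the predicted-positive set. When the
#' window contains no inactives (FPR = 0) the ratio is reported as
#' \code{Inf}.
#'
#' @inheritParams hit_rate
#' @return Non-negative scalar, possibly \code{Inf}.
#' @export
tp_fp_ratio <- function(rs, fraction = 0.01) {
  stopifnot(inherits(rs, "ranked_screen"))
  n_top <- .top_size(rs, fraction)
  hits <- sum(rs$ordered_labels[seq_len(n_top)] == 1)
  n_inact <- rs$n - rs$n_actives
  if (rs$n_actives < 1 || n_inact < 1) {
    stop("both classes must be present", call. = FALSE)
  }
  tpr <- hits / rs$n_actives
  fpr <- (n_top - hits) / n_inact
  if (fpr == 0) {
    if (tpr == 0) 0 else Inf
  } else {
    tpr / fpr
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank handling of score ties:
#' the probability that a random active outranks a random inactive, ties
#' counting one half.
#'
#' @param scores Numeric scores (higher = more active).
#' @param labels +1/-1 labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- .check_labels(labels)
  scores <- as.numeric(scores)
  n_a <- sum(labels == 1)
  n_i <- sum(labels == -1)
  if (n_a == 0 || n_i == 0) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_a * (n_a + 1) / 2) / (n_a * n_i)
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Early-recognition metric that weights the rank of each active by
#' \eqn{e^{-\alpha r_i / n}}: large \eqn{\alpha} concentrates the weight
#' on the very top of the ranking (\eqn{\alpha = 160.9} corresponds to
#' the top 1% of the database). Computed via the robust initial
#' enhancement (RIE)
#' \deqn{RIE = \frac{\frac{1}{A}\sum_{i \in actives} e^{-\alpha r_i/n}}
#'   {\frac{1}{n}\,\frac{1 - e^{-\alpha}}{e^{\alpha/n} - 1}}}
#' and mapped to [0, 1] by the bounded transformation
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha (1 - R_a)}}, \qquad R_a = A/n.}
#'
#' @param rs A [rank_screen()] result with at least one active.
#' @param alpha Positive early-recognition parameter.
#' @return BEDROC score in [0, 1].
#' @export
bedroc <- function(rs, alpha = 160.9) {
  stopifnot(inherits(rs, "ranked_screen"), alpha > 0)
  n <- rs$n
  A <- rs$n_actives
  if (A < 1) stop("screen contains no actives", call. = FALSE)
  r_act <- which(rs$ordered_labels == 1)
  ra <- A / n
  rie <- (sum(exp(-alpha * r_act / n)) / A) /
    ((1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Cumulative enrichment curve over the top of a ranking
#'
#' @inheritParams hit_rate
#' @param max_fraction Fraction of the database covered by the curve.
#' @return Data frame with columns \code{rank} (1..n_top) and
#'   \code{cum_actives}.
#' @export
enrichment_curve <- function(rs, max_fraction = 0.01) {
  stopifnot(inherits(rs, "ranked_screen"))
  n_top <- .top_size(rs, max_fraction)
  data.frame(rank = seq_len(n_top),
             cum_actives = cumsum(rs$ordered_labels[seq_len(n_top)] == 1))
}

#' Plot an enrichment curve
#'
#' @param x A \code{"ranked_screen"} object.
#' @param max_fraction Fraction of the ranking shown.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ranked_screen <- function(x, max_fraction = 0.01, ...) {
  ec <- enrichment_curve(x, max_fraction)
  graphics::plot(ec$rank, ec$cum_actives, type = "s",
                 xlab = "rank position", ylab = "cumulative actives", ...)
  invisible(ec)
}
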