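#' Kendall's coefficient of concordance with tie correction
#'
#' Measures the agreement of \code{k} judges each ranking the same
#' \code{N} objects. With rank sums \eqn{R_i} and per-judge tie
#' correction \eqn{T_j = \sum (t^3 - t)} over that judge's groups of
#' \eqn{t} tied ranks, the tie-corrected coefficient is
#' \deqn{W = \frac{12 \sum_i (R_i - \bar R)^2}
#'   {k^2 (N^3 - N) - k \sum_j T_j},}
#' the standard Siegel--Castellan form; it reduces to the classic
#' uncorrected formula when no ties are present. Significance for
#' \eqn{N > 7} uses \eqn{\chi^2 = k (N - 1) W} with \eqn{N - 1} degrees
#' of freedom.
#'
#' @param ranks A \code{k x N} matrix: one row per judge, holding tied
#'   ranks of the \code{N} objects (shared ranks as averages, so each row
#'   sums to \code{N(N+1)/2}). See [ranks_from_table()] to build it from
#'   raw performance values.
#' @param correct Apply the tie correction (default TRUE).
#' @return Object of class \code{"kendall_w"}: \code{W}, \code{chi_sq},
#'   \code{dof}, \code{p_value}, \code{k}, \code{N}.
#' @examples
#' r <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 3, 2, 4))
#' kendall_w(r)
#' @export
kendall_w <- function(ranks, correct = TRUE) {
  ranks <- as.matrix(ranks)
  k <- nrow(ranks)
  N <- ncol(ranks)
  if (k < 2L || N < 2L) {
    stop("need at least 2 judges and 2 objects", call. = FALSE)
  }
  target <- N * (N + 1) / 2
  for (j in seq_len(k)) {
    r <- ranks[j, ]
    if (anyNA(r) || abs(sum(r) - target) > 1e-8 ||
        min(r) < 1 - 1e-8 || max(r) > N + 1e-8) {
      stop("row ", j, " is not a valid tied-rank vector of 1..", N,
           call. = FALSE)
    }
  }
  Ri <- colSums(ranks)
  S <- sum((Ri - mean(Ri))^2)
  corr <- if (correct) {
    sum(apply(ranks, 1L, function(r) {
      t <- table(r)
      sum(t^3 - t)
    }))
  } else 0
  denom <- k^2 * (N^3 - N) - k * corr
  if (denom <= 0) stop("degenerate rank matrix: all ranks tied",
                       call. = FALSE)
  W <- 12 * S / denom
  chi_sq <- k * (N - 1) * W
  structure(list(W = W, chi_sq = chi_sq, dof = N - 1L,
                 p_value = stats::pchisq(chi_sq, N - 1L,
                                         lower.tail = FALSE),
                 k = k, N = N),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (%d judges, %d objects)\n",
              x$W, x$k, x$N))
  cat(sprintf("  chi-squared = %.4f on %d df, p = %.3g\n",
              x$chi_sq, x$dof, x$p_value))
  invisible(x)
}

#' Rank a table of performance values per judge
#'
#' Converts a \code{k x N} matrix of raw values (rows = judges, e.g.
#' activity classes; columns = objects, e.g. methods) into the rank
#' matrix consumed by [kendall_w()]. Rank 1 is best.
#'
#' @param values Numeric \code{k x N} matrix or data frame.
#' @param higher_is_better If TRUE (default) the largest value gets
#'   rank 1.
#' @param ties \code{"average"} (default; tied values share their average
#'   rank, the convention matching the tie-corrected \code{W}) or
#'   \code{"sequential"} (ties broken by first occurrence, producing
#'   untied integer ranks).
#' @return A \code{k x N} rank matrix.
#' @examples
#' ranks_from_table(rbind(c(5, 3, 5), c(1, 2, 3)))
#' @export
ranks_from_table <- function(values, higher_is_better = TRUE,
                             ties = c("average", "sequential")) {
  ties <- match.arg(ties)
  values <- as.matrix(values)
  method <- if (ties == "average") "average" else "first"
  sgn <- if (higher_is_better) -1 else 1
  out <- t(apply(values, 1L, function(v) rank(sgn * v,
                                              ties.method = method)))
  dimnames(out) <- dimnames(values)
  out
}

#' Bundled MUV benchmark summary tables
#'
#' Returns one of the summary tables of the published MUV benchmark of
#' these screening methods, shipped with the package as plain CSV: the
#' per-class hit rates of similarity searching and WS-ELM for the 16
#' coefficients, the corresponding rank matrices, the WS-ELM/CWS-ELM
#' comparison (hit rates and hidden-node percentages for six
#' method/coefficient combinations) and its rank matrix. These are the
#' inputs for the concordance and correlation analyses reproduced by the
#' package's evaluation suite.
#'
#' @param which One of \code{"hitrate_simsearch"}, \code{"hitrate_wselm"},
#'   \code{"ranks_simsearch"}, \code{"ranks_wselm"},
#'   \code{"ranks_classifiers"}, \code{"cwselm_benchmark"}.
#' @return A data frame; the first column(s) identify the activity class
#'   (and, for \code{"cwselm_benchmark"}, the measure: hit_rate or
#'   node_pct).
#' @export
muv_table <- function(which = c("hitrate_simsearch", "hitrate_wselm",
                                "ranks_simsearch", "ranks_wselm",
                                "ranks_classifiers", "cwselm_benchmark")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("muv_", which, ".csv"),
                      package = "cwselm", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
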