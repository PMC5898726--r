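#' Registry of binary similarity and dissimilarity coefficients
#'
#' The package evaluates sixteen classical coefficients for pairs of binary
#' molecular fingerprints. Every coefficient is a function of the four
#' contingency counts of a pair of bit vectors: \code{a} bits set in both,
#' \code{b} set only in the first, \code{c} set only in the second and
#' \code{d} set in neither, with \code{a + b + c + d = m} (the bit length).
#'
#' Coefficients are addressable by id (\code{"C01"}\ldots\code{"C16"}) or by
#' common name (case-insensitive), e.g. \code{"Jaccard/Tanimoto"} or
#' \code{"tanimoto"}. C16 (Mean Manhattan) is a distance; all user-facing
#' similarity functions expose it in similarity orientation via
#' \eqn{s = 1 - d}.
#'
#' @return A data frame with one row per coefficient: \code{id},
#'   \code{name}, \code{family} (association, correlation or distance) and
#'   the theoretical output range \code{lo}, \code{hi} of the raw formula.
#' @examples
#' coef_registry()
#' @export
coef_registry <- function() {
  .coef_registry
}

.coef_registry <- data.frame(
  id = sprintf("C%02d", 1:16),
  name = c("Baroni-Urbani/Buser", "Hamman", "Jaccard/Tanimoto",
           "Kulczynski", "Cosine/Ochiai", "Roger/Tanimoto",
           "Russell/Rao", "Simple Match", "Simpson", "Sokal/Sneath(1)",
           "Sokal/Sneath(2)", "Sokal/Sneath(3)", "McConnaughey",
           "Pearson", "Yule", "Mean Manhattan"),
  family = c("association", "correlation", "association", "association",
             "association", "association", "association", "association",
             "association", "association", "association", "association",
             "correlation", "correlation", "correlation", "distance"),
  lo = c(0, -1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -1, -1, -1, 0),
  hi = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' Resolve a coefficient id or common name
#'
#' @param id Coefficient id (\code{"C01"}..\code{"C16"}) or common name,
#'   case-insensitive.
#' @return One row of [coef_registry()].
#' @examples
#' coef_info("tanimoto")
#' @export
coef_info <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  reg <- .coef_registry
  hit <- match(toupper(id), reg$id)
  if (is.na(hit)) hit <- match(tolower(id), tolower(reg$name))
  if (is.na(hit)) {
    stop("unknown similarity coefficient: '", id,
         "'; see coef_registry() for valid ids and names", call. = FALSE)
  }
  reg[hit, , drop = FALSE]
}

.coef_id <- function(id) coef_info(id)$id

#' Contingency counts of two binary fingerprints
#'
#' @param x,y Binary vectors (0/1) of equal length.
#' @return Named numeric vector \code{c(a, b, c, d)}: bits set in both, set
#'   only in \code{x}, set only in \code{y}, set in neither.
#' @examples
#' quad_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
quad_counts <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("fingerprints have different bit lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  .check_bits(x); .check_bits(y)
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  c(a = a, b = b, c = cc, d = length(x) - a - b - cc)
}

.check_bits <- function(x) {
  if (anyNA(x) || any(x != 0 & x != 1)) {
    stop("fingerprint bits must all be 0 or 1", call. = FALSE)
  }
  invisible(x)
}

## Elementwise evaluation of a coefficient on (possibly fractional)
## contingency counts. Inputs may be scalars, vectors or conforming
## matrices. Zero denominators return 0 (documented convention: degenerate
## all-zero patterns carry no structural signal, and a total deterministic
## ranking is required downstream).
.coef_eval <- function(id, a, b, cc, d) {
  m <- a + b + cc + d
  div0 <- function(num, den) {
    out <- num
    out[] <- 0
    ok <- is.finite(den) & den != 0
    out[ok] <- num[ok] / den[ok]
    out
  }
  ## guard tiny negative soft counts from floating point
  clamp0 <- function(z) { z[z < 0] <- 0; z }
  a <- clamp0(a); b <- clamp0(b); cc <- clamp0(cc); d <- clamp0(d)
  switch(id,
    C01 = { r <- sqrt(a * d); div0(r + a, r + a + b + cc) },
    C02 = div0(a + d - b - cc, m),
    C03 = div0(a, a + b + cc),
    C04 = 0.5 * (div0(a, a + b) + div0(a, a + cc)),
    C05 = div0(a, sqrt((a + b) * (a + cc))),
    C06 = div0(a + d, b + cc + m),
    C07 = div0(a, m),
    C08 = div0(a + d, m),
    C09 = div0(a, pmin(a + b, a + cc)),
    C10 = div0(a, a + 2 * b + 2 * cc),
    C11 = div0(2 * a + 2 * d, a + d + m),
    C12 = div0(a * d, sqrt((a + b) * (a + cc) * (d + b) * (d + cc))),
    C13 = div0(a * a - b * cc, (a + b) * (a + cc)),
    C14 = div0(a * d - b * cc, sqrt((a + b) * (a + cc) * (b + d) * (cc + d))),
    C15 = div0(a * d - b * cc, a * d + b * cc),
    C16 = div0(b + cc, m),
    stop("unknown coefficient id: ", id, call. = FALSE)
  )
}

#' Evaluate a coefficient formula on contingency counts
#'
#' Returns the raw value of the coefficient's formula. For C16 (Mean
#' Manhattan) this is the \emph{distance} \eqn{(b + c)/m}; the registry row
#' (\code{family == "distance"}) flags it, and [similarity()] returns the
#' converted similarity \eqn{1 - (b + c)/m} instead. A denominator of zero
#' yields 0, never an error, so that rankings remain total.
#'
#' @param id Coefficient id or name (see [coef_registry()]).
#' @param q Contingency counts as produced by [quad_counts()] (a named or
#'   positional numeric vector \code{(a, b, c, d)}).
#' @return The scalar coefficient value.
#' @examples
#' coefficient("C03", quad_counts(c(1, 1, 1, 1), c(1, 1, 1, 1)))
#' @export
coefficient <- function(id, q) {
  id <- .coef_id(id)
  q <- as.numeric(q)
  stopifnot(length(q) == 4L, all(is.finite(q)), all(q >= 0))
  .coef_eval(id, q[1L], q[2L], q[3L], q[4L])
}

#' Similarity between two binary fingerprints
#'
#' Computes \code{coefficient(id, quad_counts(x, y))}, with distance
#' coefficients converted to similarity orientation (\eqn{s = 1 - d}) so
#' that higher always means more similar.
#'
#' @inheritParams quad_counts
#' @inheritParams coefficient
#' @return Scalar similarity.
#' @examples
#' similarity("tanimoto", c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
similarity <- function(id, x, y) {
  info <- coef_info(id)
  s <- coefficient(info$id, quad_counts(x, y))
  if (info$family == "distance") 1 - s else s
}

#' Cross-similarity matrix between two sets of fingerprints
#'
#' Vectorised evaluation of a similarity coefficient between every row of
#' \code{x} and every row of \code{y}. The contingency counts are obtained
#' from matrix products, so \code{y} may also contain real-valued rows
#' (e.g. k-means centroids or sphere-contour segment points), in which case
#' the formulas are evaluated on fractional "soft" counts
#' \eqn{a = \sum_k x_k y_k} etc.
#'
#' @param id Coefficient id or name.
#' @param x A binary matrix (rows = fingerprints) or [fpset].
#' @param y A matrix with the same number of columns (binary or
#'   real-valued), or \code{NULL} for \code{x} itself.
#' @return A \code{nrow(x) x nrow(y)} matrix of similarities (distance
#'   coefficients converted to similarity orientation).
#' @export
similarity_matrix <- function(id, x, y = NULL) {
  info <- coef_info(id)
  x <- .as_bits(x, check = TRUE)
  y <- if (is.null(y)) x else .as_bits(y, check = FALSE)
  if (ncol(x) != ncol(y)) {
    stop("fingerprint sets have different bit lengths (", ncol(x), " vs ",
         ncol(y), ")", call. = FALSE)
  }
  m <- ncol(x)
  a <- x %*% t(y)
  rx <- rowSums(x)
  ry <- rowSums(y)
  b <- matrix(rx, nrow(x), nrow(y)) - a
  cc <- matrix(ry, nrow(x), nrow(y), byrow = TRUE) - a
  d <- m - a - b - cc
  s <- .coef_eval(info$id, a, b, cc, d)
  if (info$family == "distance") s <- 1 - s
  s
}

## coerce fpset / data.frame / vector to a numeric matrix of fingerprints;
## soft (fractional) values in [0, 1] are allowed when check = FALSE is not
## requested because centroids and segment points are valid queries
.as_bits <- function(x, check = TRUE) {
  if (inherits(x, "fpset")) x <- x$bits
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  storage.mode(x) <- "double"
  if (check && (anyNA(x) || any(x < 0 | x > 1))) {
    stop("fingerprint values must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Group similarity of a molecule against a set of query actives
#'
#' The score of a database molecule against a multi-molecule query is the
#' arithmetic mean of its pairwise similarities to each query molecule.
#' This is the scoring rule of similarity searching with multiple known
#' actives.
#'
#' @param id Coefficient id or name.
#' @param actives Binary matrix (rows = query fingerprints), list of
#'   binary vectors, or [fpset].
#' @param y A single binary fingerprint vector.
#' @return Scalar mean similarity.
#' @export
group_similarity <- function(id, actives, y) {
  if (is.list(actives) && !inherits(actives, "fpset") &&
      !is.data.frame(actives)) {
    actives <- do.call(rbind, actives)
  }
  actives <- .as_bits(actives)
  if (nrow(actives) < 1L) stop("empty query set", call. = FALSE)
  mean(similarity_matrix(id, actives, matrix(as.numeric(y), nrow = 1L)))
}

#' Pairwise similarity matrix of a fingerprint set
#'
#' @inheritParams similarity_matrix
#' @return Symmetric \code{n x n} similarity matrix; the diagonal holds
#'   each fingerprint's self-similarity.
#' @export
pairwise_matrix <- function(id, x) {
  similarity_matrix(id, x, NULL)
}

#' Mean pairwise similarity (MPS) of a fingerprint set
#'
#' The mean of the off-diagonal upper triangle of the pairwise similarity
#' matrix: the standard structural-diversity summary of an activity class.
#' Low MPS means a heterogeneous (hard-to-screen) set.
#'
#' @inheritParams similarity_matrix
#' @return Scalar MPS.
#' @export
mean_pairwise_similarity <- function(id, x) {
  x <- .as_bits(x)
  if (nrow(x) < 2L) stop("MPS needs at least two fingerprints", call. = FALSE)
  s <- pairwise_matrix(id, x)
  mean(s[upper.tri(s)])
}
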