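#' Generate a synthetic MUV-style fingerprint dataset
#'
#' Emulates the structure of the MUV virtual-screening benchmark: a small
#' set of actives drowned in a large decoy background (about 0.2% actives
#' at the defaults), fixed bit length, and a controllable degree of
#' structural coherence among the actives.
#'
#' Actives are generated from \code{n_scaffolds} random seed bit patterns
#' (each bit set with probability \code{seed_density}); every active copies
#' its scaffold pattern (assigned round-robin) with independent per-bit
#' flips at rate \code{flip_prob}. Inactives are independent
#' Bernoulli(\code{inactive_density}) bit vectors. Larger \code{flip_prob}
#' or more scaffolds lowers the within-active mean pairwise similarity;
#' the defaults put the active-class Tanimoto MPS near 0.18, inside the
#' 0.15--0.28 band typical of the MUV activity classes.
#'
#' @param n_active,n_inactive Class sizes (defaults: 30 actives, 15000
#'   decoys, the MUV per-class design).
#' @param m Bit length (default 1024).
#' @param n_scaffolds Number of distinct seed patterns among the actives.
#' @param seed_density Fraction of set bits in a seed pattern.
#' @param flip_prob Per-bit mutation rate applied to each active's copy of
#'   its scaffold.
#' @param inactive_density Set-bit fraction for decoys (defaults to
#'   \code{seed_density}).
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @return An [fpset] with actives first (+1) then inactives (-1).
#' @examples
#' fp <- generate_synthetic(n_active = 5, n_inactive = 20, m = 64, seed = 1)
#' fp
#' @export
generate_synthetic <- function(n_active = 30, n_inactive = 15000, m = 1024,
                               n_scaffolds = 4, seed_density = 0.10,
                               flip_prob = 0.04, inactive_density = NULL,
                               seed = 1) {
  stopifnot(n_active >= 0, n_inactive >= 0, m >= 1, n_scaffolds >= 1,
            seed_density >= 0, seed_density <= 1,
            flip_prob >= 0, flip_prob <= 1)
  if (is.null(inactive_density)) inactive_density <- seed_density
  stopifnot(inactive_density >= 0, inactive_density <= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  scaffolds <- matrix(as.numeric(stats::runif(n_scaffolds * m) < seed_density),
                      n_scaffolds, m)
  if (n_active > 0) {
    assign_sc <- rep_len(seq_len(n_scaffolds), n_active)
    act <- scaffolds[assign_sc, , drop = FALSE]
    flips <- matrix(stats::runif(n_active * m) < flip_prob, n_active, m)
    act <- abs(act - as.numeric(flips))
  } else {
    act <- matrix(numeric(0), 0, m)
  }
  inact <- matrix(as.numeric(stats::runif(n_inactive * m) < inactive_density),
                  n_inactive, m)
  bits <- rbind(act, inact)
  labels <- c(rep(1L, n_active), rep(-1L, n_inactive))
  ids <- c(sprintf("act%03d", seq_len(n_active)),
           sprintf("dec%05d", seq_len(n_inactive)))
  fp <- fpset(bits, labels = labels, ids = ids, fp_name = "synthetic")
  fp$scaffold <- if (n_active > 0) assign_sc else integer(0)
  fp
}

## save/restore the caller's RNG state so seeded generators do not
## perturb the global random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
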