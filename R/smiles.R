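#' Convert a SMILES file to binary fingerprints
#'
#' Thin adapter over the ChemmineOB / OpenBabel toolkit: each SMILES
#' structure is parsed and hashed into a fixed-length path-based binary
#' fingerprint (OpenBabel \code{"FP2"} by default, 1024 bits). This is an
#' adapter around an external toolkit, not a fingerprint implementation:
#' the exact bit patterns are whatever the toolkit produces, and differ
#' from other vendors' ECFP/FCFP implementations of the same molecules.
#' Fingerprints longer than \code{n_bits} are folded by OR-ing
#' \code{n_bits}-sized chunks.
#'
#' @param path A \code{.smi} file: one molecule per line, SMILES first,
#'   then an optional identifier, whitespace-separated.
#' @param fp_type OpenBabel fingerprint name (\code{"FP2"}, \code{"FP3"},
#'   \code{"FP4"}, \code{"MACCS"}).
#' @param n_bits Output bit length.
#' @param labels Optional +1/-1 labels aligned with the file rows;
#'   entries for skipped (unparseable) rows are dropped.
#' @return An [fpset]. Unparseable SMILES are skipped with a warning
#'   reporting the count; parsing requires the suggested packages
#'   ChemmineR/ChemmineOB.
#' @export
smiles_to_fingerprints <- function(path, fp_type = "FP2", n_bits = 1024,
                                   labels = NULL) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("smiles_to_fingerprints() needs the ChemmineOB package",
         call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty SMILES file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[\t ]+")
  smi <- vapply(toks, `[[`, "", 1L)
  ids <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) >= 2L) toks[[i]][[2L]] else paste0("mol", i)
  }, "")
  rows <- vector("list", length(smi))
  ok <- logical(length(smi))
  for (i in seq_along(smi)) {
    fp <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", paste0(smi[i], "\t", ids[i]),
        function(mol) ChemmineOB::fingerprint_OB(list(mol), fp_type)
      ))[[1L]],
      error = function(e) NULL)
    if (!is.null(fp) && length(fp) >= 1L) {
      rows[[i]] <- .fold_bits(as.numeric(fp), n_bits)
      ok[i] <- TRUE
    }
  }
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    warning(n_skip, " SMILES record(s) could not be parsed and were ",
            "skipped", call. = FALSE)
  }
  if (!any(ok)) stop("no SMILES record could be parsed", call. = FALSE)
  if (!is.null(labels)) labels <- labels[ok]
  fpset(do.call(rbind, rows[ok]), labels = labels, ids = ids[ok],
        fp_name = fp_type)
}

## fold a 0/1 vector to n_bits by OR of consecutive chunks (pad with 0)
.fold_bits <- function(v, n_bits) {
  if (length(v) < n_bits) v <- c(v, numeric(n_bits - length(v)))
  k <- ceiling(length(v) / n_bits)
  if (k > 1L) {
    v <- c(v, numeric(k * n_bits - length(v)))
    v <- as.numeric(colSums(matrix(v, nrow = k, byrow = TRUE)) > 0)
  }
  v
}
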