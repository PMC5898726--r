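#' Fingerprint set: binary fingerprints with ids and activity labels
#'
#' The universal input container of the package: \code{n} molecules by
#' \code{m} binary bits, with molecule identifiers and activity labels
#' coded +1 (active) / -1 (inactive). Labels may be \code{NA} for
#' unlabelled screening databases.
#'
#' @param bits Binary matrix, rows = molecules.
#' @param labels Integer vector of +1/-1 (or \code{NA}), recycled checks
#'   applied; \code{NULL} for all-\code{NA}.
#' @param ids Character identifiers; defaults to \code{mol1..moln}.
#' @param fp_name Name of the fingerprint type (e.g. \code{"ECFP_6"}).
#' @return An object of class \code{"fpset"}.
#' @examples
#' fp <- fpset(matrix(c(1, 0, 1, 1, 0, 0), 2, 3), labels = c(1, -1))
#' fp
#' @export
fpset <- function(bits, labels = NULL, ids = NULL, fp_name = "unknown") {
  if (is.null(dim(bits))) bits <- matrix(as.numeric(bits), nrow = 1L)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "double"
  .check_bits(bits)
  n <- nrow(bits)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") does not match number of ",
         "molecules (", n, ")", call. = FALSE)
  }
  if (!all(labels %in% c(1L, -1L) | is.na(labels))) {
    stop("labels must be +1, -1 or NA", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids length does not match", call. = FALSE)
  structure(list(ids = ids, bits = bits, labels = labels,
                 fp_name = fp_name),
            class = "fpset")
}

#' @export
print.fpset <- function(x, ...) {
  n_act <- sum(x$labels == 1L, na.rm = TRUE)
  n_inact <- sum(x$labels == -1L, na.rm = TRUE)
  cat("Fingerprint set (", x$fp_name, "): ", nrow(x$bits), " molecules x ",
      ncol(x$bits), " bits\n", sep = "")
  cat("  actives: ", n_act, "  inactives: ", n_inact,
      "  unlabelled: ", sum(is.na(x$labels)), "\n", sep = "")
  invisible(x)
}

#' @export
`[.fpset` <- function(x, i, ...) {
  fpset(x$bits[i, , drop = FALSE], labels = x$labels[i], ids = x$ids[i],
        fp_name = x$fp_name)
}

#' @export
as.matrix.fpset <- function(x, ...) x$bits

#' @export
dim.fpset <- function(x) dim(x$bits)

#' Read a delimited fingerprint table
#'
#' Each row describes one molecule: an identifier, an activity label and
#' the fingerprint, either as a single 0/1 string (\code{"10110..."}) or as
#' \code{m} separate 0/1 columns. Fields are whitespace- or tab-separated;
#' an optional header line starting with \code{id} is skipped. Label
#' tokens \code{1}, \code{+1}, \code{active} map to +1; \code{-1},
#' \code{0}, \code{inactive} map to -1; \code{NA} stays missing.
#'
#' @param path File path.
#' @param fp_name Fingerprint name stored in the result.
#' @return An [fpset].
#' @export
read_fingerprint_table <- function(path, fp_name = "unknown") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty fingerprint table: ", path, call. = FALSE)
  if (grepl("^\\s*id\\b", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    stop("row ", which(ncols < 3L)[1L],
         ": expected at least id, label and fingerprint", call. = FALSE)
  }
  if (length(unique(ncols)) != 1L) {
    stop("row ", which(ncols != ncols[1L])[1L],
         ": inconsistent number of fields", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  labels <- .parse_labels(vapply(parts, `[[`, "", 2L))
  if (ncols[1L] == 3L) {
    bitstr <- vapply(parts, `[[`, "", 3L)
    bad <- grepl("[^01]", bitstr)
    if (any(bad)) {
      stop("row ", which(bad)[1L], ": fingerprint string contains ",
           "characters other than 0/1", call. = FALSE)
    }
    len <- nchar(bitstr)
    if (length(unique(len)) != 1L) {
      stop("row ", which(len != len[1L])[1L],
           ": inconsistent fingerprint bit length", call. = FALSE)
    }
    bits <- matrix(as.numeric(unlist(strsplit(bitstr, ""))),
                   nrow = length(bitstr), byrow = TRUE)
  } else {
    cells <- lapply(parts, function(p) p[-(1:2)])
    vals <- suppressWarnings(lapply(cells, as.numeric))
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (anyNA(v) || any(v != 0 & v != 1)) {
        stop("row ", i, ": fingerprint bits must all be 0 or 1",
             call. = FALSE)
      }
    }
    bits <- do.call(rbind, vals)
  }
  fpset(bits, labels = labels, ids = ids, fp_name = fp_name)
}

.parse_labels <- function(tok) {
  tok <- tolower(trimws(tok))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("1", "+1", "active")] <- 1L
  out[tok %in% c("-1", "0", "inactive")] <- -1L
  bad <- !(tok %in% c("1", "+1", "active", "-1", "0", "inactive",
                      "na", "nan", ""))
  if (any(bad)) {
    stop("row ", which(bad)[1L], ": unknown label token '",
         tok[which(bad)[1L]], "'", call. = FALSE)
  }
  out
}

#' Write a fingerprint table
#'
#' Writes the tab-separated dialect read back by
#' [read_fingerprint_table()]: \code{id}, \code{label} (+1/-1/NA) and the
#' fingerprint as one 0/1 string. The round trip is lossless.
#'
#' @param fp An [fpset].
#' @param path Output file path.
#' @export
write_fingerprint_table <- function(fp, path) {
  stopifnot(inherits(fp, "fpset"))
  bitstr <- apply(fp$bits, 1L, function(r) paste(as.integer(r), collapse = ""))
  lab <- ifelse(is.na(fp$labels), "NA", as.character(fp$labels))
  writeLines(paste(fp$ids, lab, bitstr, sep = "\t"), path, useBytes = FALSE)
  invisible(path)
}

#' Write and read screening score tables
#'
#' The scored-molecule exchange format of the package (and of the
#' command-line \code{evaluate} tool): a tab-separated table with columns
#' \code{id}, \code{label}, \code{score}, in that order.
#'
#' @param ids Character molecule ids.
#' @param labels +1/-1 activity labels (NA allowed).
#' @param scores Numeric screening scores.
#' @param path File path.
#' @return \code{read_scores} returns a data frame with columns
#'   \code{id}, \code{label}, \code{score}.
#' @export
write_scores <- function(ids, labels, scores, path) {
  stopifnot(length(ids) == length(labels), length(ids) == length(scores))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("id\tlabel\tscore", con)
  lab <- ifelse(is.na(labels), "NA", as.character(as.integer(labels)))
  writeLines(paste(ids, lab, format(scores, digits = 17, trim = TRUE,
                                    scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "numeric"),
                         quote = "", comment.char = "", encoding = "UTF-8")
  names(d) <- c("id", "label", "score")
  d$label <- .parse_labels(d$label)
  d
}
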