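#' Construct a PSSM object
#'
#' An L x 20 matrix of log-odds scores, one row per residue of the protein,
#' columns in a fixed amino-acid order (PSI-BLAST native order by default).
#'
#' @param protein_id Protein identifier.
#' @param matrix Numeric L x 20 matrix; all entries must be finite.
#' @param alphabet_order Column order; defaults to [pssm_alphabet()].
#' @return An object of class `pssm`.
#' @export
pssm <- function(protein_id, matrix, alphabet_order = pssm_alphabet()) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 20L) stop("PSSM must have exactly 20 columns")
  if (length(alphabet_order) != 20L || anyDuplicated(alphabet_order)) {
    stop("alphabet_order must be 20 distinct residues")
  }
  if (!all(is.finite(matrix))) stop("PSSM entries must be finite")
  storage.mode(matrix) <- "double"
  colnames(matrix) <- alphabet_order
  structure(list(protein_id = protein_id, matrix = matrix,
                 alphabet_order = alphabet_order),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", x$protein_id, ": ", nrow(x$matrix), " x 20 (",
    if (inherits(x, "normalized_pssm")) "normalized" else "log-odds",
    ")\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: two header lines, then one row per
#' residue with position, residue letter, 20 log-odds columns, 20
#' weighted-percentage columns and two trailing statistics; a footer with
#' lambda/kappa values. Only the first 20 score columns are kept. The column
#' order is taken from the header line and recorded on the returned object.
#'
#' @param path Path to the ASCII PSSM file (or a character vector of lines
#'   via `lines`).
#' @param protein_id Identifier to attach; defaults to the file name.
#' @param lines Optional character vector of pre-read lines (overrides
#'   `path`).
#' @return A `pssm` object.
#' @export
parse_psiblast_pssm <- function(path = NULL, protein_id = NULL, lines = NULL) {
  if (is.null(lines)) {
    if (is.null(path)) stop("either path or lines must be given")
    if (!file.exists(path)) stop("PSSM file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  if (is.null(protein_id)) protein_id <- "unknown"

  # header: the first line consisting only of single residue letters
  header_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(nchar(toks) == 1L) &&
        all(toks %in% c(.AA, "B", "Z", "X", "*"))) {
      header_idx <- i
      break
    }
  }
  if (is.na(header_idx)) stop("not a PSI-BLAST ASCII PSSM: no column header found")
  header <- strsplit(trimws(lines[header_idx]), "\\s+")[[1]]
  alphabet_order <- header[1:20]

  rows <- list()
  seq_letters <- character(0)
  for (i in seq((header_idx + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- lines[i]
    if (!grepl("^\\s*[0-9]+\\s+[A-Za-z]", ln)) {
      if (length(rows) > 0L) break  # footer reached
      next
    }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 22L) {
      stop("PSSM parse error at line ", i, ": expected >= 20 score columns, found ",
           length(toks) - 2L)
    }
    scores <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(scores))) {
      stop("PSSM parse error at line ", i, ": non-numeric score column")
    }
    pos <- as.integer(toks[1])
    if (pos != length(rows) + 1L) {
      stop("PSSM parse error at line ", i, ": positions not consecutive (",
           pos, " after ", length(rows), ")")
    }
    rows[[length(rows) + 1L]] <- scores
    seq_letters <- c(seq_letters, toks[2])
  }
  if (length(rows) == 0L) stop("truncated PSSM file: no residue rows found")
  mat <- do.call(rbind, rows)
  out <- pssm(protein_id, mat, alphabet_order)
  attr(out, "sequence") <- paste(seq_letters, collapse = "")
  out
}

#' Write a PSSM in PSI-BLAST ASCII format
#'
#' Emits the `-out_ascii_pssm` dialect consumed by [parse_psiblast_pssm()].
#' Scores are printed with `%d` when integer-valued (as PSI-BLAST does),
#' otherwise with full precision.
#'
#' @param p A `pssm` object.
#' @param path Output path.
#' @param sequence Residue string for the letter column; defaults to the
#'   `sequence` attribute if present, else `"X"` per row.
#' @export
write_psiblast_pssm <- function(p, path, sequence = NULL) {
  stopifnot(inherits(p, "pssm"))
  mat <- p$matrix
  L <- nrow(mat)
  if (is.null(sequence)) sequence <- attr(p, "sequence")
  if (is.null(sequence)) sequence <- strrep("X", L)
  if (nchar(sequence) != L) stop("sequence length must match PSSM rows")

  fmt_score <- function(x) {
    if (all(mat == round(mat))) sprintf("%4d", as.integer(x))
    else sprintf("%8.4f", x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines(paste0(
    "Last position-specific scoring matrix computed, weighted observed ",
    "percentages rounded down, information per position, and relative ",
    "weight of gapless real matches to pseudocounts"), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", p$alphabet_order), collapse = " "), " ",
                    paste(sprintf("%3s", p$alphabet_order), collapse = " ")), con)
  for (i in seq_len(L)) {
    pct <- rep(0L, 20L)  # observed percentages: not modelled, zero-filled
    writeLines(paste0(
      sprintf("%5d %s ", i, substr(sequence, i, i)),
      paste(vapply(mat[i, ], fmt_score, ""), collapse = " "), " ",
      paste(sprintf("%3d", pct), collapse = " "),
      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines("", con)
  writeLines(c("                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176",
               "Standard Gapped      0.0410     0.2670",
               "PSI Ungapped         0.1337     0.3176",
               "PSI Gapped           0.0410     0.2670"), con)
  invisible(path)
}

#' Normalize a PSSM
#'
#' Maps raw log-odds scores to a bounded scale before feature extraction.
#' The default is the elementwise logistic transform
#' `f(x) = 1 / (1 + exp(-x))`, the convention of the PsePSSM literature;
#' entries land strictly in (0, 1) and the map is monotone. Alternatives:
#' `"identity"` (raw scores) and `"zscore"` (per-column standardization;
#' unbounded).
#'
#' @param p A `pssm` object.
#' @param method One of `"logistic"`, `"identity"`, `"zscore"`.
#' @return A `pssm` object additionally classed `normalized_pssm`, with a
#'   `normalization` field recording the method.
#' @export
normalize_pssm <- function(p, method = c("logistic", "identity", "zscore")) {
  stopifnot(inherits(p, "pssm"))
  method <- match.arg(method)
  mat <- p$matrix
  mat <- switch(method,
    logistic = 1 / (1 + exp(-mat)),
    identity = mat,
    zscore = {
      mu <- colMeans(mat)
      sd <- apply(mat, 2, stats::sd)
      sd[sd == 0] <- 1
      sweep(sweep(mat, 2, mu, "-"), 2, sd, "/")
    }
  )
  out <- p
  out$matrix <- mat
  out$normalization <- method
  class(out) <- c("normalized_pssm", "pssm")
  out
}
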