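#' Feature extraction configuration
#'
#' Bundles the tunable parameters of the four feature groups:
#'
#' * `lag_max`: maximum sequence lag of the PsePSSM descriptor (default 7).
#' * `window_flank`: flanking residues on each side of the mutation site in
#'   the conservation-score window (default 3, i.e. an `XXXCXXX` stretch).
#' * `neighbor_span`: sequence neighbors taken from each side of the site
#'   for the ordinal-label group (default 5).
#' * `normalization`: PSSM normalization fed to the PSSM-derived groups
#'   (`"logistic"` default; see [normalize_pssm()]).
#' * `neighbor_encoding`: `"ordinal"` (default; one integer label per
#'   neighbor, 20 residue codes plus a pad code) or `"onehot"`.
#' * `physchem_version`: version of [physchem_table()].
#'
#' At the defaults the assembled descriptor has
#' `(20 + 20*7) + 20*(2*3+1) + 2*5 + 9 = 160 + 140 + 10 + 9 = 319` entries.
#'
#' @param lag_max,window_flank,neighbor_span,normalization,neighbor_encoding,physchem_version
#'   See above.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(lag_max = 7L, window_flank = 3L,
                           neighbor_span = 5L,
                           normalization = "logistic",
                           neighbor_encoding = c("ordinal", "onehot"),
                           physchem_version = "1.0") {
  lag_max <- as.integer(lag_max)
  window_flank <- as.integer(window_flank)
  neighbor_span <- as.integer(neighbor_span)
  if (lag_max < 1L) stop("lag_max must be >= 1")
  if (window_flank < 0L) stop("window_flank must be >= 0")
  if (neighbor_span < 0L) stop("neighbor_span must be >= 0")
  neighbor_encoding <- match.arg(neighbor_encoding)
  normalization <- match.arg(normalization, c("logistic", "identity", "zscore"))
  structure(list(lag_max = lag_max, window_flank = window_flank,
                 neighbor_span = neighbor_span,
                 normalization = normalization,
                 neighbor_encoding = neighbor_encoding,
                 physchem_version = physchem_version,
                 physchem = physchem_table(physchem_version)),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config> lag_max=", x$lag_max, " window_flank=", x$window_flank,
      " neighbor_span=", x$neighbor_span, " normalization=", x$normalization,
      " neighbor_encoding=", x$neighbor_encoding, "\n", sep = "")
  invisible(x)
}

#' PsePSSM descriptor of a whole protein
#'
#' The pseudo-PSSM vector: the 20 per-column means of the (normalized) PSSM
#' followed, for each lag `g = 1..lag_max`, by the 20 lagged mean squared
#' column differences
#' `phi_j^g = (1/(L-g)) * sum_{i=1}^{L-g} (P[i,j] - P[i+g,j])^2`,
#' which capture the sequence-order correlation of conservation along the
#' chain. Total length `20 + 20*lag_max` (160 at the default lag 7).
#'
#' @param n A `pssm` (normally a `normalized_pssm`) or plain L x 20 matrix.
#' @param lag_max Maximum lag; must be strictly less than the row count.
#' @return Named numeric vector (`psepssm_mean_*`, `psepssm_lag<g>_*`).
#' @export
psepssm_vector <- function(n, lag_max = 7L) {
  mat <- if (inherits(n, "pssm")) n$matrix else as.matrix(n)
  ab <- if (inherits(n, "pssm")) n$alphabet_order else
    colnames(mat) %||% .AA
  L <- nrow(mat)
  lag_max <- as.integer(lag_max)
  if (lag_max >= L) {
    stop("lag_max (", lag_max, ") must be < sequence length (", L, ")")
  }
  means <- colMeans(mat)
  out <- numeric(20L + 20L * lag_max)
  out[1:20] <- means
  nm <- c(paste0("psepssm_mean_", ab))
  for (g in seq_len(lag_max)) {
    d <- mat[seq_len(L - g), , drop = FALSE] -
      mat[seq(g + 1L, L), , drop = FALSE]
    out[(20L * g + 1L):(20L * (g + 1L))] <- colSums(d * d) / (L - g)
    nm <- c(nm, paste0("psepssm_lag", g, "_", ab))
  }
  names(out) <- nm
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conservation scores of the mutation-site window
#'
#' Extracts the (normalized) PSSM rows of the mutation site and its
#' `window_flank` flanking residues on each side — the `XXXCXXX` stretch at
#' the default flank of 3 — and flattens them row-major. Rows falling
#' outside the sequence are zero-padded so the dimensionality
#' (`20 * (2*window_flank + 1)`; 140 at default) is fixed.
#'
#' @param n A `pssm` (normally normalized).
#' @param m A `mutation` validated against the PSSM's protein.
#' @param window_flank Flank size (default 3).
#' @return Named numeric vector (`neighborcs_p<offset>_<residue>`).
#' @export
neighbor_conservation_scores <- function(n, m, window_flank = 3L) {
  stopifnot(inherits(n, "pssm"), inherits(m, "mutation"))
  mat <- n$matrix
  ab <- n$alphabet_order
  L <- nrow(mat)
  window_flank <- as.integer(window_flank)
  offsets <- seq(-window_flank, window_flank)
  out <- numeric(0)
  nm <- character(0)
  for (o in offsets) {
    i <- m$pos + o
    row <- if (i >= 1L && i <= L) mat[i, ] else rep(0, 20L)
    out <- c(out, row)
    tag <- if (o < 0) paste0("m", -o) else if (o > 0) paste0("p", o) else "c0"
    nm <- c(nm, paste0("neighborcs_", tag, "_", ab))
  }
  names(out) <- nm
  out
}

#' Ordinal labels of the sequence neighbors
#'
#' Encodes the residues flanking the mutation site in the primary sequence:
#' `neighbor_span` positions to the left (outermost first) then
#' `neighbor_span` to the right (innermost first). Each label is the 0-based
#' index of the residue in the fixed alphabet order (0-19); positions beyond
#' either terminus get the pad label 20. With `encoding = "onehot"` each
#' neighbor becomes 21 indicator columns instead.
#'
#' @param seq Protein sequence (string).
#' @param m A validated `mutation`.
#' @param span Neighbors per side (default 5).
#' @param encoding `"ordinal"` (default) or `"onehot"`.
#' @return Named numeric vector, length `2*span` (ordinal) or `2*span*21`.
#' @export
sequence_neighbor_labels <- function(seq, m, span = 5L,
                                     encoding = c("ordinal", "onehot")) {
  stopifnot(inherits(m, "mutation"))
  encoding <- match.arg(encoding)
  res <- as_residue_string(seq)
  L <- nchar(res)
  span <- as.integer(span)
  if (span == 0L) return(stats::setNames(numeric(0), character(0)))
  positions <- c(m$pos - span:1, m$pos + 1:span)
  tags <- c(paste0("L", span:1), paste0("R", 1:span))
  labels <- vapply(positions, function(i) {
    if (i < 1L || i > L) return(20L)
    idx <- match(substr(res, i, i), .AA)
    if (is.na(idx)) stop("residue at position ", i, " not in the 20-letter alphabet")
    idx - 1L
  }, integer(1))
  if (encoding == "ordinal") {
    out <- as.numeric(labels)
    names(out) <- paste0("seqneighbor_", tags)
    return(out)
  }
  codes <- c(.AA, "pad")
  out <- numeric(length(labels) * 21L)
  nm <- character(length(labels) * 21L)
  for (k in seq_along(labels)) {
    block <- rep(0, 21L)
    block[labels[k] + 1L] <- 1
    out[((k - 1L) * 21L + 1L):(k * 21L)] <- block
    nm[((k - 1L) * 21L + 1L):(k * 21L)] <-
      paste0("seqneighbor_", tags[k], "_", codes)
  }
  names(out) <- nm
  out
}

#' Physicochemical descriptor of a substitution
#'
#' Nine values describing the amino-acid exchange, in fixed order:
#' net volume, net hydrophobicity, mutation type, net flexibility,
#' chemical property, size, polarity, hydrogen bond, and label
#' hydrophobicity. "Net" scales are `scale(mut) - scale(wt)`; categorical
#' attributes are the integer class code of the mutant residue (see
#' [physchem_table()]); "mutation type" is the chemical-class transition
#' code `7 * (class(wt) - 1) + class(mut)`.
#'
#' @param m A `mutation` (wild-type and mutant residues must differ).
#' @param table A physicochemical table from [physchem_table()].
#' @return Named numeric vector of length 9 (`physchem_*`).
#' @export
physicochemical_features <- function(m, table = physchem_table()) {
  stopifnot(inherits(m, "mutation"))
  if (!(m$wt %in% rownames(table)) || !(m$mut %in% rownames(table))) {
    stop("residue absent from physicochemical table: ",
         setdiff(c(m$wt, m$mut), rownames(table)))
  }
  wt <- table[m$wt, ]
  mu <- table[m$mut, ]
  out <- c(
    net_volume = mu$volume - wt$volume,
    net_hydrophobicity = mu$hydrophobicity - wt$hydrophobicity,
    mutation_type = 7 * (wt$chemical_class - 1) + mu$chemical_class,
    net_flexibility = mu$flexibility - wt$flexibility,
    chemical_class = mu$chemical_class,
    size_class = mu$size_class,
    polarity = mu$polarity,
    hbond = mu$hbond,
    hydrophobicity_label = mu$hydrophobicity_label
  )
  names(out) <- paste0("physchem_", names(out))
  out
}

#' Assemble the full feature vector for one mutation
#'
#' Concatenates the four groups in fixed order: PsePSSM of the whole protein,
#' conservation scores of the mutation-site window, sequence-neighbor labels,
#' and physicochemical descriptors of the substitution. The first three
#' groups depend only on the protein and the mutated position; only the
#' physicochemical block sees the mutant residue.
#'
#' @param seq Protein sequence (string).
#' @param p A `pssm` for the same protein (raw log-odds; normalization is
#'   applied according to `cfg`). A `normalized_pssm` is used as-is.
#' @param m A validated `mutation`.
#' @param cfg A [feature_config()].
#' @return Named numeric vector with attribute `groups` (character vector
#'   labelling each entry `psepssm` / `neighbor_cs` / `seq_neighbor` /
#'   `physchem`), class `feature_vector`.
#' @export
assemble_feature_vector <- function(seq, p, m, cfg = feature_config()) {
  stopifnot(inherits(cfg, "feature_config"))
  res <- as_residue_string(seq)
  if (!validate_mutation_against_sequence(res, m)) {
    stop("mutation ", format_mutation(m),
         " does not validate against the sequence")
  }
  if (inherits(p, "pssm") && nrow(p$matrix) != nchar(res)) {
    stop("PSSM row count (", nrow(p$matrix),
         ") does not match sequence length (", nchar(res), ")")
  }
  np <- if (inherits(p, "normalized_pssm")) p else
    normalize_pssm(p, cfg$normalization)
  v1 <- psepssm_vector(np, cfg$lag_max)
  v2 <- neighbor_conservation_scores(np, m, cfg$window_flank)
  v3 <- sequence_neighbor_labels(res, m, cfg$neighbor_span,
                                 cfg$neighbor_encoding)
  v4 <- physicochemical_features(m, cfg$physchem)
  out <- c(v1, v2, v3, v4)
  attr(out, "groups") <- c(rep("psepssm", length(v1)),
                           rep("neighbor_cs", length(v2)),
                           rep("seq_neighbor", length(v3)),
                           rep("physchem", length(v4)))
  class(out) <- "feature_vector"
  out
}

#' Feature table for a whole mutation dataset
#'
#' Applies [assemble_feature_vector()] to every record. Per-protein work
#' (normalization, PsePSSM) is computed once per protein and reused.
#'
#' @param ds A `mutation_dataset`.
#' @param pssms Named list of `pssm` objects keyed by protein id.
#' @param cfg A [feature_config()].
#' @return Numeric matrix, one row per record, with feature names as column
#'   names and attribute `groups` giving each column's feature group.
#' @export
featurize_dataset <- function(ds, pssms, cfg = feature_config()) {
  stopifnot(inherits(ds, "mutation_dataset"))
  rec <- ds$records
  missing_p <- setdiff(unique(rec$protein_id), names(pssms))
  if (length(missing_p)) {
    stop("no PSSM for proteins: ", paste(missing_p, collapse = ", "))
  }
  norm_cache <- list()
  pse_cache <- list()
  rows <- vector("list", nrow(rec))
  groups <- NULL
  for (i in seq_len(nrow(rec))) {
    pid <- rec$protein_id[i]
    seq <- ds$sequences[[pid]]
    if (is.null(norm_cache[[pid]])) {
      p <- pssms[[pid]]
      norm_cache[[pid]] <- if (inherits(p, "normalized_pssm")) p else
        normalize_pssm(p, cfg$normalization)
      pse_cache[[pid]] <- psepssm_vector(norm_cache[[pid]], cfg$lag_max)
    }
    np <- norm_cache[[pid]]
    m <- parse_mutation(rec$mutation[i])
    v2 <- neighbor_conservation_scores(np, m, cfg$window_flank)
    v3 <- sequence_neighbor_labels(seq, m, cfg$neighbor_span,
                                   cfg$neighbor_encoding)
    v4 <- physicochemical_features(m, cfg$physchem)
    v <- c(pse_cache[[pid]], v2, v3, v4)
    if (is.null(groups)) {
      groups <- c(rep("psepssm", length(pse_cache[[pid]])),
                  rep("neighbor_cs", length(v2)),
                  rep("seq_neighbor", length(v3)),
                  rep("physchem", length(v4)))
    }
    rows[[i]] <- v
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  attr(x, "groups") <- groups
  x
}

#' Write a feature table to CSV/TSV with schema header
#'
#' @param x Feature matrix from [featurize_dataset()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @export
write_feature_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
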