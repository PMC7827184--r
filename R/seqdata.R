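#' Parse a point-mutation specification
#'
#' Mutations are written in the usual `WposM` notation (e.g. `"R175H"`):
#' wild-type residue, 1-based sequence position, mutant residue.
#'
#' @param spec A single string matching `^[A-Z][0-9]+[A-Z]$`.
#' @return An object of class `mutation`: a list with elements `wt`, `pos`
#'   (integer, 1-based) and `mut`.
#' @examples
#' parse_mutation("R175H")
#' @export
parse_mutation <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec)) {
    stop("mutation spec must be a single string")
  }
  if (!grepl("^[A-Z][0-9]+[A-Z]$", spec)) {
    stop("malformed mutation spec: '", spec, "' (expected e.g. 'R175H')")
  }
  wt <- substr(spec, 1L, 1L)
  mut <- substr(spec, nchar(spec), nchar(spec))
  pos <- as.integer(substr(spec, 2L, nchar(spec) - 1L))
  if (!(wt %in% .AA) || !(mut %in% .AA)) {
    stop("mutation spec '", spec, "' uses a residue outside the 20-letter alphabet")
  }
  if (wt == mut) {
    stop("invalid mutation '", spec, "': wild-type and mutant residue are identical")
  }
  if (pos < 1L) stop("invalid mutation '", spec, "': position must be >= 1")
  structure(list(wt = wt, pos = pos, mut = mut), class = "mutation")
}

#' Format a mutation back to `WposM` notation
#'
#' Inverse of [parse_mutation()].
#'
#' @param m A `mutation` object.
#' @return A string such as `"R175H"`.
#' @export
format_mutation <- function(m) {
  stopifnot(inherits(m, "mutation"))
  paste0(m$wt, m$pos, m$mut)
}

#' @export
print.mutation <- function(x, ...) {
  cat("<mutation>", format_mutation(x), "\n")
  invisible(x)
}

#' Check a mutation against a protein sequence
#'
#' @param seq A protein sequence as a single string (or a `protein_sequence`).
#' @param m A `mutation` object.
#' @return `TRUE` iff `m$pos` lies within the sequence and the residue at
#'   that (1-based) position equals `m$wt`. Never throws; callers escalate.
#' @export
validate_mutation_against_sequence <- function(seq, m) {
  res <- as_residue_string(seq)
  if (m$pos < 1L || m$pos > nchar(res)) return(FALSE)
  substr(res, m$pos, m$pos) == m$wt
}

as_residue_string <- function(seq) {
  if (is.list(seq) && !is.null(seq$residues)) return(seq$residues)
  as.character(seq)
}

#' Construct a mutation dataset
#'
#' A mutation dataset couples a table of (protein, mutation, target) records
#' with the protein sequences they refer to. Targets are experimental ddG
#' values in kcal/mol (`target_kind = "ddg"`) or deep-mutational-scan
#' stability scores (`target_kind = "stability_score"`).
#'
#' @param records Data frame with columns `protein_id`, `mutation` (WposM
#'   strings), `target` (finite numeric) and `target_kind`.
#' @param sequences Named character vector mapping `protein_id` to residue
#'   strings.
#' @param validate If `TRUE` (default), every record is checked against its
#'   sequence with [validate_mutation_against_sequence()]; records containing
#'   `X` at the mutated site are permitted only when `allow_x = TRUE`
#'   (pre-filter state).
#' @param allow_x Allow `X` residues (before [filter_unknown_residues()]).
#' @return An object of class `mutation_dataset`.
#' @export
mutation_dataset <- function(records, sequences, validate = TRUE,
                             allow_x = FALSE) {
  need <- c("protein_id", "mutation", "target", "target_kind")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[, need]
  records$protein_id <- as.character(records$protein_id)
  records$mutation <- as.character(records$mutation)
  if (any(!is.finite(records$target))) stop("all targets must be finite")
  if (!all(records$target_kind %in% c("ddg", "stability_score"))) {
    stop("target_kind must be 'ddg' or 'stability_score'")
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be a named character vector")
  }
  missing_ids <- setdiff(unique(records$protein_id), names(sequences))
  if (length(missing_ids)) {
    stop("records refer to unknown proteins: ", paste(missing_ids, collapse = ", "))
  }
  if (validate) {
    for (i in seq_len(nrow(records))) {
      spec <- records$mutation[i]
      m <- if (allow_x) parse_mutation_lenient(spec) else parse_mutation(spec)
      seq <- sequences[[records$protein_id[i]]]
      ok <- m$pos >= 1L && m$pos <= nchar(seq) &&
        substr(seq, m$pos, m$pos) == m$wt
      if (!ok) {
        stop("record ", i, " (", records$protein_id[i], " ", spec,
             ") does not match its sequence")
      }
    }
  }
  structure(list(records = records, sequences = sequences),
            class = "mutation_dataset")
}

# like parse_mutation but tolerates 'X' as wt or mut (pre-filter datasets)
parse_mutation_lenient <- function(spec) {
  if (!grepl("^[A-Z][0-9]+[A-Z]$", spec)) {
    stop("malformed mutation spec: '", spec, "'")
  }
  list(wt = substr(spec, 1L, 1L),
       pos = as.integer(substr(spec, 2L, nchar(spec) - 1L)),
       mut = substr(spec, nchar(spec), nchar(spec)))
}

#' @export
print.mutation_dataset <- function(x, ...) {
  cat("<mutation_dataset> ", nrow(x$records), " records, ",
      length(x$sequences), " proteins\n", sep = "")
  invisible(x)
}

#' Remove records involving unknown ('X') residues
#'
#' Drops every record whose wild-type or mutant residue is `X`, or whose
#' sequence holds `X` at the mutated position. Order of the surviving
#' records is preserved; the number removed is reported via [message()].
#' Idempotent.
#'
#' @param ds A `mutation_dataset`.
#' @return A filtered `mutation_dataset`.
#' @export
filter_unknown_residues <- function(ds) {
  stopifnot(inherits(ds, "mutation_dataset"))
  rec <- ds$records
  if (nrow(rec) == 0L) {
    message("filter_unknown_residues: removed 0 of 0 records")
    return(ds)
  }
  keep <- vapply(seq_len(nrow(rec)), function(i) {
    m <- parse_mutation_lenient(rec$mutation[i])
    seq <- ds$sequences[[rec$protein_id[i]]]
    at <- substr(seq, m$pos, m$pos)
    m$wt != "X" && m$mut != "X" && at != "X"
  }, logical(1))
  message("filter_unknown_residues: removed ", sum(!keep), " of ",
          nrow(rec), " records")
  out <- ds
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Global-alignment sequence identity
#'
#' Percent identity between two protein sequences under Needleman-Wunsch
#' global alignment with match +1, mismatch 0, gap -1 (no separate gap-open
#' cost), the scheme this package fixes for its homology screen. The
#' denominator is the alignment length (gap columns included), making the
#' measure symmetric.
#'
#' @param a,b Protein sequences (strings or `protein_sequence` objects).
#' @return Percent identity in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) {
  sa <- as_residue_string(a)
  sb <- as_residue_string(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) {
    stop("sequence_identity requires non-empty sequences")
  }
  letters21 <- c(.AA, "X")
  submat <- diag(1, length(letters21))
  dimnames(submat) <- list(letters21, letters21)
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  100 * sum(p == s) / length(p)
}

#' Homology-aware train/test partition
#'
#' Splits a dataset by protein so that no test protein shares at least
#' `identity_threshold` percent global-alignment identity with any training
#' protein — the standard guard against homology leakage when estimating
#' generalization to unseen folds. The split is greedy: proteins are
#' shuffled by `seed` and added to the test pool while the pool stays below
#' the target record fraction and every pooled protein keeps identity below
#' the threshold against all remaining (training) proteins.
#'
#' @param ds A `mutation_dataset`.
#' @param test_fraction Target fraction of records in the test side (0-1).
#' @param identity_threshold Percent identity bound (default 30).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return List with elements `train` and `test`, both `mutation_dataset`s.
#' @export
homology_partition <- function(ds, test_fraction = 0.2,
                               identity_threshold = 30, seed = 1L) {
  stopifnot(inherits(ds, "mutation_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  if (!(identity_threshold > 0 && identity_threshold <= 100)) {
    stop("identity_threshold must be in (0, 100]")
  }
  ids <- unique(ds$records$protein_id)
  if (length(ids) < 2L) stop("need at least two proteins to partition")
  n_rec <- nrow(ds$records)
  counts <- table(ds$records$protein_id)

  idm <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i)) {
      v <- if (i == j) 100 else
        sequence_identity(ds$sequences[[ids[i]]], ds$sequences[[ids[j]]])
      idm[i, j] <- idm[j, i] <- v
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  order_ids <- sample(ids)

  test_ids <- character(0)
  test_n <- 0L
  for (id in order_ids) {
    cand <- c(test_ids, id)
    remaining <- setdiff(ids, cand)
    if (length(remaining) == 0L) next
    if ((test_n + counts[[id]]) / n_rec > test_fraction + 1e-9 &&
        length(test_ids) > 0L) next
    ok <- all(idm[cand, remaining, drop = FALSE] < identity_threshold)
    if (ok && (test_n + counts[[id]]) / n_rec <= test_fraction + 1e-9) {
      test_ids <- cand
      test_n <- test_n + counts[[id]]
    }
  }
  if (length(test_ids) == 0L) {
    # fall back: allow a single smallest-overshoot protein if none fit under
    # the fraction cap but the identity constraint is satisfiable
    for (id in order_ids) {
      remaining <- setdiff(ids, id)
      if (all(idm[id, remaining] < identity_threshold)) {
        test_ids <- id
        break
      }
    }
  }
  if (length(test_ids) == 0L) {
    stop("no valid homology-aware split exists: every protein has >= ",
         identity_threshold, "% identity to some other protein")
  }
  in_test <- ds$records$protein_id %in% test_ids
  list(
    train = subset_dataset(ds, !in_test),
    test = subset_dataset(ds, in_test)
  )
}

subset_dataset <- function(ds, keep) {
  rec <- ds$records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  seqs <- ds$sequences[unique(rec$protein_id)]
  structure(list(records = rec, sequences = seqs), class = "mutation_dataset")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped lines supported).
#' @return Named character vector of residue strings.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  # FASTA headers may carry descriptions; keep the first token as the id
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1L)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a mutation dataset from CSV
#'
#' The CSV dialect has header columns `protein_id`, `mutation`, `target`,
#' `target_kind`, one record per row; sequences come from a companion FASTA.
#'
#' @param csv_path Dataset CSV path.
#' @param fasta_path FASTA with every referenced protein.
#' @param allow_x Permit `X` residues (pre-filter datasets).
#' @return A `mutation_dataset`.
#' @export
read_dataset_csv <- function(csv_path, fasta_path, allow_x = FALSE) {
  rec <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  seqs <- read_fasta_sequences(fasta_path)
  mutation_dataset(rec, seqs, validate = TRUE, allow_x = allow_x)
}

#' Write a mutation dataset to CSV (+ FASTA)
#'
#' @param ds A `mutation_dataset`.
#' @param csv_path Output CSV path.
#' @param fasta_path Optional output FASTA path for the sequences.
#' @export
write_dataset_csv <- function(ds, csv_path, fasta_path = NULL) {
  utils::write.csv(ds$records, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(fasta_path)) write_fasta_sequences(ds$sequences, fasta_path)
  invisible(csv_path)
}

#' Read a mutation list file (one `WposM` per line)
#'
#' @param path Text file with one mutation spec per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return List of `mutation` objects, input order preserved.
#' @export
read_mutation_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_mutation)
}
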