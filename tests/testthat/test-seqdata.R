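test_that("mutation specs parse, format and reject invalid input", {
  m <- parse_mutation("R175H")
  expect_equal(m$wt, "R")
  expect_equal(m$pos, 175L)
  expect_equal(m$mut, "H")
  expect_equal(parse_mutation("A1G")$pos, 1L)

  # round trip over a spread of valid values
  for (spec in c("A1G", "W999C", "K10R", "G2A")) {
    expect_identical(format_mutation(parse_mutation(spec)), spec)
  }

  expect_error(parse_mutation("A5A"), "wild-type and mutant")
  expect_error(parse_mutation("175H"), "malformed")
  expect_error(parse_mutation("RH"), "malformed")
  expect_error(parse_mutation("B5G"), "alphabet")  # B not a standard residue
})

test_that("mutations validate against sequences positionally", {
  expect_true(validate_mutation_against_sequence("ACDEF", parse_mutation("A1G")))
  expect_false(validate_mutation_against_sequence("ACDEF", parse_mutation("C1G")))
  expect_false(validate_mutation_against_sequence("ACDEF", parse_mutation("A9G")))
  expect_true(validate_mutation_against_sequence("ACDEF", parse_mutation("F5A")))
})

test_that("unknown-residue filter drops X records, preserves order, idempotent", {
  seqs <- c(P1 = "ACDXF", P2 = "MKVLA")
  rec <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P2"),
    mutation = c("A1G", "X4A", "M1K", "K2R", "V3L"),
    target = c(0.1, 0.2, -0.3, 1.2, 0.5),
    target_kind = "ddg")
  ds <- mutation_dataset(rec, seqs, allow_x = TRUE)
  expect_message(f <- filter_unknown_residues(ds), "removed 1 of 5")
  expect_equal(nrow(f$records), 4L)
  expect_equal(f$records$mutation, c("A1G", "M1K", "K2R", "V3L"))

  # idempotent
  expect_message(f2 <- filter_unknown_residues(f), "removed 0 of 4")
  expect_identical(f2$records, f$records)

  # empty dataset is the identity
  empty <- mutation_dataset(rec[0, ], seqs)
  expect_message(fe <- filter_unknown_residues(empty), "0 of 0")
  expect_equal(nrow(fe$records), 0L)
})

test_that("sequence identity matches the global-alignment scheme", {
  expect_equal(sequence_identity("ACDE", "ACDE"), 100)
  # no gaps opened under match +1 / mismatch 0 / gap -1
  expect_equal(sequence_identity("ACDE", "ACDF"), 75)
  expect_equal(sequence_identity("AAAA", "WWWW"), 0)
  expect_error(sequence_identity("", "ACD"), "non-empty")
})

test_that("sequence identity is symmetric, bounded, 100 iff identical", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_sequence(sample(10:30, 1))
    b <- random_sequence(sample(10:30, 1))
    ab <- sequence_identity(a, b)
    expect_equal(ab, sequence_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 100)
    if (!identical(a, b)) expect_lt(ab, 100)
  }
})

test_that("homology partition separates proteins and respects identity", {
  set.seed(5)
  # 10 mutually dissimilar random proteins, 5 mutations each
  seqs <- setNames(vapply(1:10, function(i) random_sequence(40), ""),
                   paste0("P", 1:10))
  recs <- do.call(rbind, lapply(names(seqs), function(id) {
    pos <- sample(40, 5)
    wt <- vapply(pos, function(p) substr(seqs[[id]], p, p), "")
    mut <- vapply(wt, function(w) sample(setdiff(pssm_alphabet(), w), 1), "")
    data.frame(protein_id = id, mutation = paste0(wt, pos, mut),
               target = rnorm(5), target_kind = "ddg")
  }))
  ds <- mutation_dataset(recs, seqs)
  sp <- homology_partition(ds, test_fraction = 0.2,
                           identity_threshold = 30, seed = 9)
  test_ids <- unique(sp$test$records$protein_id)
  train_ids <- unique(sp$train$records$protein_id)

  expect_length(test_ids, 2L)
  expect_length(intersect(test_ids, train_ids), 0L)
  # union of records is the input record set
  all_specs <- sort(paste(recs$protein_id, recs$mutation))
  got <- sort(c(paste(sp$train$records$protein_id, sp$train$records$mutation),
                paste(sp$test$records$protein_id, sp$test$records$mutation)))
  expect_identical(got, all_specs)
  # identity constraint holds pairwise
  for (ti in test_ids) for (tr in train_ids) {
    expect_lt(sequence_identity(ds$sequences[[ti]], ds$sequences[[tr]]), 30)
  }

  # deterministic given seed
  sp2 <- homology_partition(ds, 0.2, 30, seed = 9)
  expect_identical(sp2$test$records, sp$test$records)

  # identical proteins are never split across sides
  seqs2 <- c(A = seqs[[1]], B = seqs[[1]], C = random_sequence(40))
  recs2 <- recs[recs$protein_id %in% c("P1", "P2", "P3"), ]
  recs2$protein_id <- rep(c("A", "B", "C"), each = 5)
  recs2$mutation <- unlist(lapply(c("A", "B", "C"), function(id) {
    pos <- sample(40, 5)
    wt <- vapply(pos, function(p) substr(seqs2[[id]], p, p), "")
    mut <- vapply(wt, function(w) sample(setdiff(pssm_alphabet(), w), 1), "")
    paste0(wt, pos, mut)
  }))
  ds2 <- mutation_dataset(recs2, seqs2)
  for (s in 1:5) {
    sp3 <- homology_partition(ds2, 0.34, 30, seed = s)
    tids <- unique(sp3$test$records$protein_id)
    expect_false(xor("A" %in% tids, "B" %in% tids))
  }

  # infeasible: all proteins mutually homologous
  seqs3 <- c(X1 = seqs[[1]], X2 = seqs[[1]])
  recs3 <- recs2[recs2$protein_id %in% c("A", "B"), ]
  recs3$protein_id <- rep(c("X1", "X2"), each = 5)
  ds3 <- mutation_dataset(recs3, seqs3, validate = FALSE)
  expect_error(homology_partition(ds3, 0.5, 30, seed = 1), "no valid")
})

test_that("FASTA and dataset CSV round-trip", {
  truth <- tiny_truth(seed = 3L)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "p.fasta")
  csv <- file.path(dir, "d.csv")
  write_dataset_csv(truth$dataset, csv, fa)
  back <- read_dataset_csv(csv, fa)
  expect_identical(back$sequences, truth$dataset$sequences)
  expect_equal(back$records$mutation, truth$dataset$records$mutation)
  expect_equal(back$records$target, truth$dataset$records$target,
               tolerance = 1e-12)
})

test_that("mutation list files read in order, skipping comments", {
  path <- withr::local_tempfile(lines = c("R175H", "", "# note", "A1G"))
  ml <- read_mutation_list(path)
  expect_length(ml, 2L)
  expect_identical(vapply(ml, format_mutation, ""), c("R175H", "A1G"))
})
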