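test_that("PsePSSM matches the naive double-loop definition", {
  set.seed(77)
  for (i in 1:10) {
    L <- sample(10:40, 1)
    mat <- random_normalized_matrix(L)
    lag <- sample(1:7, 1)
    got <- psepssm_vector(mat, lag)
    expect_equal(unname(got), as.numeric(naive_psepssm(mat, lag)),
                 tolerance = 1e-12)
  }
})

test_that("PsePSSM hand-computed cases and degenerate inputs", {
  # constant matrix: means = c, all lag terms 0
  mat <- matrix(0.3, 9, 20)
  v <- psepssm_vector(mat, 2)
  expect_equal(unname(v[1:20]), rep(0.3, 20))
  expect_equal(unname(v[21:60]), rep(0, 40))

  # L=2, one column (0,1), lag 1: mean 0.5, phi = (0-1)^2/(2-1) = 1
  mat2 <- matrix(0.5, 2, 20)
  mat2[, 1] <- c(0, 1)
  v2 <- psepssm_vector(mat2, 1)
  expect_equal(unname(v2[1]), 0.5)
  expect_equal(unname(v2[21]), 1)

  # lag >= L is rejected (denominator would be nonpositive)
  expect_error(psepssm_vector(matrix(0.5, 5, 20), 5), "lag_max")
  expect_error(psepssm_vector(matrix(0.5, 5, 20), 7), "lag_max")
})

test_that("window conservation scores extract and zero-pad correctly", {
  set.seed(12)
  mat <- random_normalized_matrix(7)
  p <- normalize_pssm(pssm("w", mat), "identity")

  # window covering the whole sequence equals the flattened matrix
  m4 <- parse_mutation(paste0(pssm_alphabet()[1], 4, pssm_alphabet()[2]))
  v <- neighbor_conservation_scores(p, m4, 3)
  expect_length(v, 140L)
  expect_equal(unname(v), as.vector(t(mat)), tolerance = 1e-15)

  # position 1: three zero rows then rows 1..4
  m1 <- parse_mutation(paste0(pssm_alphabet()[1], 1, pssm_alphabet()[2]))
  v1 <- neighbor_conservation_scores(p, m1, 3)
  expect_equal(unname(v1[1:60]), rep(0, 60))
  expect_equal(unname(v1[61:140]), as.vector(t(mat[1:4, ])), tolerance = 1e-15)

  # depends on the position, not on the mutant residue
  m4b <- parse_mutation(paste0(pssm_alphabet()[1], 4, pssm_alphabet()[5]))
  expect_identical(unname(neighbor_conservation_scores(p, m4b, 3)), unname(v))
})

test_that("sequence neighbor labels: order, padding, encoding", {
  seq <- "ACDEFGHIKLM"
  m <- parse_mutation("G6A")
  v <- sequence_neighbor_labels(seq, m, 5)
  expect_length(v, 10L)
  ab <- pssm_alphabet()
  # left outermost-first: A C D E F; right innermost-first: H I K L M
  expect_equal(unname(v),
               c(match(c("A", "C", "D", "E", "F"), ab),
                 match(c("H", "I", "K", "L", "M"), ab)) - 1)

  # position 1: five pad labels then residues 2..6
  v1 <- sequence_neighbor_labels(seq, parse_mutation("A1G"), 5)
  expect_equal(unname(v1[1:5]), rep(20, 5))
  expect_equal(unname(v1[6:10]), match(c("C", "D", "E", "F", "G"), ab) - 1)

  # one-hot switch expands to 21 indicators per neighbor
  vh <- sequence_neighbor_labels(seq, m, 5, encoding = "onehot")
  expect_length(vh, 10L * 21L)
  expect_equal(sum(vh), 10)
  expect_equal(unname(vh[match("A", ab)]), 1)  # leftmost neighbor is A
})

test_that("physicochemical features: order, antisymmetry, table lookups", {
  tab <- physchem_table()
  v <- physicochemical_features(parse_mutation("A2V"), tab)
  expect_length(v, 9L)
  expect_identical(names(v), paste0("physchem_",
    c("net_volume", "net_hydrophobicity", "mutation_type", "net_flexibility",
      "chemical_class", "size_class", "polarity", "hbond",
      "hydrophobicity_label")))
  # A -> V increases volume on the shipped scale
  expect_gt(v[["physchem_net_volume"]], 0)
  expect_equal(v[["physchem_net_volume"]], tab["V", "volume"] - tab["A", "volume"])

  # net components antisymmetric under G<->A swap
  ga <- physicochemical_features(parse_mutation("G1A"), tab)
  ag <- physicochemical_features(parse_mutation("A1G"), tab)
  for (comp in c("physchem_net_volume", "physchem_net_hydrophobicity",
                 "physchem_net_flexibility")) {
    expect_equal(ga[[comp]], -ag[[comp]])
  }

  # categorical blocks describe the mutant residue
  expect_equal(ga[["physchem_chemical_class"]], tab["A", "chemical_class"])
  expect_equal(ag[["physchem_chemical_class"]], tab["G", "chemical_class"])
  # mutation type distinguishes direction across chemical classes
  dk <- physicochemical_features(parse_mutation("D1K"), tab)
  kd <- physicochemical_features(parse_mutation("K1D"), tab)
  expect_false(dk[["physchem_mutation_type"]] == kd[["physchem_mutation_type"]])
  expect_equal(dk[["physchem_mutation_type"]],
               7 * (tab["D", "chemical_class"] - 1) + tab["K", "chemical_class"])
})

test_that("assembled vector has the contracted block structure", {
  set.seed(9)
  seq <- random_sequence(30)
  p <- synth_pssm(seq, conservation = 3, seed = 4)
  wt <- substr(seq, 12, 12)
  muts <- setdiff(pssm_alphabet(), wt)[1:2]
  m1 <- parse_mutation(paste0(wt, 12, muts[1]))
  m2 <- parse_mutation(paste0(wt, 12, muts[2]))

  v <- assemble_feature_vector(seq, p, m1)
  groups <- attr(v, "groups")
  expect_length(v, 319L)
  expect_equal(as.vector(table(factor(groups,
    levels = c("psepssm", "neighbor_cs", "seq_neighbor", "physchem")))),
    c(160L, 140L, 10L, 9L))
  # fixed group order
  expect_identical(unique(groups),
                   c("psepssm", "neighbor_cs", "seq_neighbor", "physchem"))

  # two mutations at one site share all but the physchem block
  v2 <- assemble_feature_vector(seq, p, m2)
  shared <- groups != "physchem"
  expect_identical(unclass(v)[shared], unclass(v2)[shared])
  expect_false(identical(unclass(v)[!shared], unclass(v2)[!shared]))

  # byte-identical on repeated calls
  expect_identical(unclass(v), unclass(assemble_feature_vector(seq, p, m1)))

  # invalid mutation is rejected
  bad_wt <- setdiff(pssm_alphabet(), substr(seq, 3, 3))[1]
  expect_error(assemble_feature_vector(seq, p,
    parse_mutation(paste0(bad_wt, 3, substr(seq, 3, 3)))), "validate")
})

test_that("feature lengths follow the closed forms across configurations", {
  set.seed(15)
  seq <- random_sequence(45)
  p <- synth_pssm(seq, conservation = 2, seed = 5)
  wt <- substr(seq, 20, 20)
  m <- parse_mutation(paste0(wt, 20, setdiff(pssm_alphabet(), wt)[1]))
  for (lag in c(1, 3, 7)) for (flank in c(0, 2, 3)) for (span in c(0, 2, 5)) {
    cfg <- feature_config(lag_max = lag, window_flank = flank,
                          neighbor_span = span)
    v <- assemble_feature_vector(seq, p, m, cfg)
    expect_length(v, (20 + 20 * lag) + 20 * (2 * flank + 1) + 2 * span + 9)
  }
  # one-hot encoding length
  cfg1 <- feature_config(neighbor_encoding = "onehot")
  expect_length(assemble_feature_vector(seq, p, m, cfg1),
                160 + 140 + 10 * 21 + 9)
})

test_that("featurize_dataset agrees with per-mutation assembly", {
  truth <- tiny_truth(seed = 6L)
  ds <- truth$dataset
  x <- featurize_dataset(ds, truth$pssms)
  expect_equal(nrow(x), nrow(ds$records))
  i <- 5L
  pid <- ds$records$protein_id[i]
  v <- assemble_feature_vector(ds$sequences[[pid]], truth$pssms[[pid]],
                               parse_mutation(ds$records$mutation[i]))
  expect_equal(unname(x[i, ]), as.numeric(v), tolerance = 1e-15)
  expect_identical(colnames(x), names(unclass(v)))
})
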