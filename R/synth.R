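#' Synthetic-data generator configuration
#'
#' Defines a self-contained synthetic study: random protein sequences,
#' per-protein log-odds profiles with tunable conservation, random single
#' substitutions, and targets generated as a known linear function of the
#' package's own feature encoding plus Gaussian noise. Because the signal
#' is known exactly, the best achievable test correlation has the closed
#' form `sd(signal) / sqrt(var(signal) + noise_sd^2)`, which downstream
#' parameter-recovery tests compare against.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of sequence lengths (uniform).
#' @param conservation Per-column conservation sharpness (> 0): how strongly
#'   the true residue dominates the column profile. Near 0 the profile
#'   collapses to the background (log-odds near 0); large values pin the
#'   maximum score to the true residue.
#' @param background Amino-acid background frequencies (length 20 in
#'   [pssm_alphabet()] order; default uniform 1/20).
#' @param n_mutations Mutations drawn per protein.
#' @param effect_weights Named numeric vector of true effect weights over
#'   feature schema names (defaults put all signal on the physicochemical
#'   group, scaled for ddG-like magnitudes of roughly 1 kcal/mol sd).
#' @param interaction Optional list `list(features = c(a, b), weight = w)`
#'   adding a multiplicative interaction term `w * x_a * x_b` to the signal
#'   (a nonlinear ground truth for model-selection tests).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol).
#' @param target_ceiling If non-`NULL`, overrides `noise_sd` so that the
#'   analytic correlation ceiling equals this value given the realized
#'   signal spread.
#' @param feature_cfg A [feature_config()] used to build the features.
#' @param seed Integer seed; everything downstream is a pure function of
#'   the configuration and this seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 10L, length_range = c(60L, 120L),
                         conservation = 3, background = rep(1 / 20, 20),
                         n_mutations = 50L,
                         effect_weights = c(physchem_net_volume = 0.012,
                                            physchem_net_hydrophobicity = 0.18,
                                            physchem_net_flexibility = 3.5),
                         interaction = NULL,
                         noise_sd = 0.5, target_ceiling = NULL,
                         feature_cfg = feature_config(), seed = 1L) {
  if (length(background) != 20L || any(background <= 0)) {
    stop("background must be 20 positive frequencies")
  }
  background <- background / sum(background)
  if (conservation <= 0) stop("conservation must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  min_len <- min(length_range)
  need <- max(2L * feature_cfg$window_flank + 1L,
              2L * feature_cfg$neighbor_span + 1L,
              feature_cfg$lag_max + 1L)
  if (min_len <= need) {
    stop("minimum sequence length must exceed ", need,
         " for the configured windows")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 conservation = conservation, background = background,
                 n_mutations = as.integer(n_mutations),
                 effect_weights = effect_weights,
                 interaction = interaction,
                 noise_sd = noise_sd, target_ceiling = target_ceiling,
                 feature_cfg = feature_cfg, seed = as.integer(seed)),
            class = "synth_config")
}

#' Synthetic PSSM for a sequence
#'
#' Draws a per-column amino-acid profile in which the true residue is
#' favored proportionally to `conservation` — the column profile is a
#' mixture `(background + conservation * (0.5 * e_true + 0.5 * d)) /
#' (1 + conservation)` with `d` a Dirichlet draw over the background — then
#' converts it to integer half-bit log-odds `round(2 * log2(p / background))`,
#' the scale PSI-BLAST prints. As `conservation` grows the maximum score of
#' every row lands on the true residue; as it vanishes all scores approach
#' the background-vs-background log-odds of 0.
#'
#' @param seq Protein sequence (string).
#' @param conservation Sharpness (> 0).
#' @param seed Integer seed; the matrix is deterministic given it.
#' @param background Background frequencies (length 20).
#' @param protein_id Identifier for the returned object.
#' @return A `pssm` with integer-valued scores and the sequence attached.
#' @export
synth_pssm <- function(seq, conservation = 3, seed = 1L,
                       background = rep(1 / 20, 20), protein_id = "synth") {
  res <- as_residue_string(seq)
  L <- nchar(res)
  background <- background / sum(background)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mat <- matrix(0, L, 20L)
  dirichlet_conc <- 20  # concentration of the noise component
  for (i in seq_len(L)) {
    true_idx <- match(substr(res, i, i), .AA)
    if (is.na(true_idx)) stop("non-standard residue at position ", i)
    g <- stats::rgamma(20L, shape = dirichlet_conc * background)
    d <- g / sum(g)
    e_true <- numeric(20L)
    e_true[true_idx] <- 1
    p <- (background + conservation * (0.5 * e_true + 0.5 * d)) /
      (1 + conservation)
    mat[i, ] <- round(2 * log2(p / background))
  }
  out <- pssm(protein_id, mat)
  attr(out, "sequence") <- res
  out
}

#' Generate a complete synthetic study with known ground truth
#'
#' Emits random proteins, per-protein synthetic PSSMs, random single
#' substitutions, the package's feature table for every mutation, and
#' targets `y = w . features + N(0, noise_sd^2)` using the configured true
#' weights. The analytic correlation ceiling
#' `sd(signal) / sqrt(var(signal) + noise_sd^2)` is recorded.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `synth_truth`: list with `dataset`
#'   (`mutation_dataset`), `pssms` (named list of `pssm`), `features`
#'   (record x feature matrix), `signal`, `weights`, `noise_sd`, `ceiling`,
#'   and `cfg`.
#' @export
synth_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  ids <- sprintf("SYN%03d", seq_len(cfg$n_proteins))
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                 cfg$n_proteins, replace = TRUE)
  sequences <- stats::setNames(vapply(lens, function(L) {
    paste(sample(.AA, L, replace = TRUE, prob = cfg$background),
          collapse = "")
  }, ""), ids)

  pssm_seeds <- sample.int(2^31 - 2, cfg$n_proteins)
  pssms <- stats::setNames(lapply(seq_along(ids), function(i) {
    synth_pssm(sequences[[i]], cfg$conservation, pssm_seeds[i],
               cfg$background, protein_id = ids[i])
  }), ids)

  recs <- vector("list", cfg$n_proteins)
  for (i in seq_along(ids)) {
    L <- lens[i]
    pos <- sample.int(L, cfg$n_mutations, replace = TRUE)
    wt <- vapply(pos, function(p) substr(sequences[[i]], p, p), "")
    mut <- vapply(wt, function(w) sample(setdiff(.AA, w), 1L), "")
    recs[[i]] <- data.frame(protein_id = ids[i],
                            mutation = paste0(wt, pos, mut),
                            target = 0, target_kind = "ddg",
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  ds <- mutation_dataset(records, sequences)

  x <- featurize_dataset(ds, pssms, cfg$feature_cfg)
  w <- cfg$effect_weights
  unknown <- setdiff(names(w), colnames(x))
  if (length(unknown)) {
    stop("effect weights reference unknown features: ",
         paste(unknown, collapse = ", "))
  }
  signal <- as.numeric(x[, names(w), drop = FALSE] %*% w)
  if (!is.null(cfg$interaction)) {
    fi <- cfg$interaction$features
    if (!all(fi %in% colnames(x))) {
      stop("interaction references unknown features: ",
           paste(setdiff(fi, colnames(x)), collapse = ", "))
    }
    signal <- signal + cfg$interaction$weight * x[, fi[1]] * x[, fi[2]]
  }

  noise_sd <- cfg$noise_sd
  if (!is.null(cfg$target_ceiling)) {
    cc <- cfg$target_ceiling
    if (!(cc > 0 && cc <= 1)) stop("target_ceiling must be in (0, 1]")
    noise_sd <- stats::sd(signal) * sqrt(1 / cc^2 - 1)
  }
  y <- signal + stats::rnorm(length(signal), sd = noise_sd)
  ds$records$target <- y

  ceiling <- stats::sd(signal) / sqrt(stats::var(signal) + noise_sd^2)
  structure(list(dataset = ds, pssms = pssms, features = x,
                 signal = signal, weights = w, noise_sd = noise_sd,
                 ceiling = ceiling, cfg = cfg),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> ", nrow(x$dataset$records), " records, ",
      length(x$pssms), " proteins; noise_sd=",
      signif(x$noise_sd, 3), ", analytic ceiling=",
      signif(x$ceiling, 3), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to a self-contained directory
#'
#' Emits `proteins.fasta`, one PSI-BLAST-style `.pssm` per protein,
#' `dataset.csv`, and `ground_truth.json` (weights, noise level, ceiling,
#' seed).
#'
#' @param truth A `synth_truth`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synth_dir <- function(truth, dir) {
  stopifnot(inherits(truth, "synth_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_sequences(truth$dataset$sequences,
                        file.path(dir, "proteins.fasta"))
  for (id in names(truth$pssms)) {
    write_psiblast_pssm(truth$pssms[[id]], file.path(dir, paste0(id, ".pssm")))
  }
  write_dataset_csv(truth$dataset, file.path(dir, "dataset.csv"))
  jsonlite::write_json(list(
    weights = as.list(truth$weights),
    noise_sd = truth$noise_sd,
    ceiling = truth$ceiling,
    seed = truth$cfg$seed
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a synthetic study directory back into memory
#'
#' @param dir Directory produced by [write_synth_dir()].
#' @return List with `dataset` (a `mutation_dataset`) and `pssms`.
#' @export
read_synth_dir <- function(dir) {
  ds <- read_dataset_csv(file.path(dir, "dataset.csv"),
                         file.path(dir, "proteins.fasta"))
  files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  pssms <- stats::setNames(lapply(files, parse_psiblast_pssm),
                           sub("\\.pssm$", "", basename(files)))
  list(dataset = ds, pssms = pssms)
}

#' Parameter-recovery experiment
#'
#' The end-to-end harness: generate a synthetic study, run the repeated
#' cross-validation protocol on its feature table, fit a model on the full
#' data, and compare the mean CV correlation with the analytic noise
#' ceiling and the grouped feature importances with the groups actually
#' carrying signal.
#'
#' @param cfg A [synth_config()].
#' @param model_cfg A [model_config()].
#' @param folds,repeats CV protocol size (defaults 5 and 2; at full scale
#'   the protocol uses 100 repeats).
#' @return An object of class `recovery_report`: list with `mean_cv_pcc`,
#'   `sd_cv_pcc`, `mean_cv_mse`, `mean_cv_mae`, `ceiling`,
#'   `group_importance`, `top_group`, `signal_groups`, `n`, plus the
#'   underlying `cv_report` and `synth_truth`.
#' @export
recovery_experiment <- function(cfg = synth_config(),
                                model_cfg = model_config(),
                                folds = 5L, repeats = 2L) {
  truth <- synth_dataset(cfg)
  x <- truth$features
  y <- truth$dataset$records$target
  cv <- repeated_cv(x, y, model_cfg, folds = folds, repeats = repeats,
                    seed = cfg$seed)
  fit <- ddg_fit(x, y, model_cfg)
  gi <- group_importance(fit)
  groups <- attr(x, "groups")
  signal_groups <- unique(groups[match(names(truth$weights), colnames(x))])
  structure(list(
    mean_cv_pcc = mean(cv$results$pcc),
    sd_cv_pcc = stats::sd(cv$results$pcc),
    mean_cv_mse = mean(cv$results$mse),
    mean_cv_mae = mean(cv$results$mae),
    ceiling = truth$ceiling,
    group_importance = gi,
    top_group = names(gi)[which.max(gi)],
    signal_groups = signal_groups,
    n = length(y),
    cv = cv, truth = truth, model = fit
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> n=", x$n, "\n", sep = "")
  cat(sprintf("  mean CV PCC %.3f (sd %.3f); analytic ceiling %.3f\n",
              x$mean_cv_pcc, x$sd_cv_pcc, x$ceiling))
  cat(sprintf("  mean CV MSE %.3f  MAE %.3f\n", x$mean_cv_mse, x$mean_cv_mae))
  gi <- sort(x$group_importance, decreasing = TRUE)
  cat("  group importance:", paste(sprintf("%s=%.3f", names(gi), gi),
                                   collapse = "  "), "\n")
  cat("  signal groups:", paste(x$signal_groups, collapse = ", "), "\n")
  invisible(x)
}
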