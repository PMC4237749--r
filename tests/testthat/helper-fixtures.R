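# Fixtures are built in code; no data files.

key_block <- function(n, antigens = 2) {
  per <- ceiling(n / antigens)
  ids <- rep(sprintf("TST%02d_A", seq_len(antigens)), each = per)[seq_len(n)]
  pos <- unlist(lapply(rle(ids)$lengths, seq_len))
  tibble::tibble(antigen_id = ids, chain = "A", position = pos,
                 aa = rep_len(c("A", "D", "K", "S", "G"), n))
}

# Residue tables with gaussian feature/score columns and a label column the
# first score column separates imperfectly (or perfectly when sep = Inf).
toy_tables <- function(n = 40, n_scores = 2, n_feats = 2, antigens = 4,
                       prevalence = 0.25, sep = 2, seed = 42) {
  withr::with_seed(seed, {
    keys <- key_block(n, antigens)
    label <- as.integer(runif(n) < prevalence)
    if (sum(label) == 0) label[1] <- 1L
    if (sum(label) == n) label[n] <- 0L
    scores <- sapply(seq_len(n_scores), function(j) {
      if (is.infinite(sep) && j == 1) as.numeric(label)
      else rnorm(n) + (if (j == 1) sep * label else 0.3 * label)
    })
    colnames(scores) <- paste0("s", seq_len(n_scores))
    feats <- sapply(seq_len(n_feats), function(j) rnorm(n) + 0.5 * label)
    colnames(feats) <- paste0("f", seq_len(n_feats))
    list(
      features = dplyr::bind_cols(keys, tibble::as_tibble(feats)),
      scores = dplyr::bind_cols(keys, tibble::as_tibble(scores)),
      labels = dplyr::bind_cols(keys, tibble::tibble(label = label))
    )
  })
}

toy_dataset <- function(...) {
  tabs <- toy_tables(...)
  assemble_dataset(tabs$features, tabs$scores, tabs$labels)
}

# Perfectly separable dataset: score column s1 equals the label.
separable_dataset <- function(n = 40, antigens = 4, prevalence = 0.3,
                              seed = 7) {
  toy_dataset(n = n, antigens = antigens, prevalence = prevalence,
              sep = Inf, seed = seed)
}

# Small paper-like generator configs for train/test experiments.
small_train_config <- function(seed) {
  preset_paperlike(n_antigens = 24L, residues_per_antigen = c(45L, 60L),
                   seed = seed)
}
small_test_config <- function(seed) {
  preset_paperlike(n_antigens = 15L, residues_per_antigen = c(150L, 170L),
                   seed = seed)
}

# Independent MCC oracle, straight from the definition.
mcc_direct <- function(TP, FP, TN, FN) {
  num <- TP * TN - FP * FN
  den <- sqrt((TP + FP) * (TP + FN)) * sqrt((TN + FP) * (TN + FN))
  if (den == 0) 0 else num / den
}

# AUC oracle via the Mann-Whitney rank identity.
auc_rank_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
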