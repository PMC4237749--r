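#' Confusion matrix of a binary prediction
#'
#' @param predicted,truth Equal-length integer 0/1 vectors.
#' @return A `confusion` object with fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have equal length")
  }
  stopifnot(all(predicted %in% c(0, 1)), all(truth %in% c(0, 1)))
  new_confusion(
    TP = sum(predicted == 1 & truth == 1),
    FP = sum(predicted == 1 & truth == 0),
    TN = sum(predicted == 0 & truth == 0),
    FN = sum(predicted == 0 & truth == 1)
  )
}

new_confusion <- function(TP, FP, TN, FN) {
  cells <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(cells < 0)) abort("confusion cells must be non-negative")
  structure(as.list(cells), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  TN %d  FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Performance measures from a confusion matrix
#'
#' Computes TPR (sensitivity), FPR, precision, accuracy, F-score, and the
#' Matthews correlation coefficient. Undefined ratios use fixed conventions:
#' precision is 0 when nothing is predicted positive, F-score is 0 when
#' TPR + precision = 0, and MCC is 0 when any factor of its denominator is 0.
#'
#' @param cm A `confusion` object.
#' @return One-row tibble with columns `tpr`, `fpr`, `precision`, `accuracy`,
#'   `fscore`, `mcc`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  TP <- as.numeric(cm$TP); FP <- as.numeric(cm$FP)
  TN <- as.numeric(cm$TN); FN <- as.numeric(cm$FN)
  n <- TP + FP + TN + FN
  tpr <- if (TP + FN == 0) 0 else TP / (TP + FN)
  fpr <- if (FP + TN == 0) 0 else FP / (FP + TN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  accuracy <- if (n == 0) 0 else (TP + TN) / n
  fscore <- if (tpr + precision == 0) 0 else 2 * tpr * precision / (tpr + precision)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
  tibble::tibble(tpr = tpr, fpr = fpr, precision = precision,
                 accuracy = accuracy, fscore = fscore, mcc = mcc)
}

#' F-score from TPR and precision
#'
#' Harmonic-mean identity used to recompute F-scores from published
#' sensitivity/precision pairs.
#'
#' @param tpr,precision Rates in \[0, 1\].
#' @return F-score (0 when both rates are 0).
#' @export
fscore_from_rates <- function(tpr, precision) {
  ifelse(tpr + precision == 0, 0, 2 * tpr * precision / (tpr + precision))
}

#' ROC curve and AUC
#'
#' Sweeps all distinct observed scores as thresholds (plus the two
#' all-positive / all-negative endpoints) and integrates by trapezoid.
#'
#' @param scores Numeric score vector (higher = more epitope-like).
#' @param truth Integer 0/1 vector with both classes present.
#' @return List with `points` (tibble of `fpr`, `tpr` ordered along the
#'   curve) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2) abort("truth contains a single class; ROC undefined")
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- tibble::tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- dplyr::arrange(pts, fpr, tpr)
  list(points = pts, auc = as.numeric(r$auc))
}

#' Cross-validation protocol specification
#'
#' @param n_folds Number of folds (>= 2, default 5).
#' @param n_repeats Number of repeated CVs (default 2, i.e. two 5-fold CVs).
#' @param stratified Balance epitope fraction across folds (default TRUE).
#' @param group_by_antigen Keep all residues of an antigen in one fold
#'   (default TRUE, preventing within-protein leakage).
#' @param seed Integer seed for fold assignment.
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(n_folds = 5L, n_repeats = 2L, stratified = TRUE,
                    group_by_antigen = TRUE, seed = 1L) {
  if (n_folds < 2) abort("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 stratified = stratified, group_by_antigen = group_by_antigen,
                 seed = as.integer(seed)),
            class = "cv_spec")
}

#' Fold assignment for (repeated) stratified grouped cross-validation
#'
#' Folds are disjoint and exhaustive. With `group_by_antigen`, whole antigens
#' are assigned to folds; stratification greedily balances the epitope count
#' (largest-positive-count group first, into the currently lightest fold),
#' which keeps the epitope fraction of each fold close to the global one.
#'
#' @param dataset An `epi_dataset`.
#' @param spec A [cv_spec()].
#' @return List of length `n_repeats`; each element an integer vector of fold
#'   ids (1..n_folds) per residue.
#' @export
make_folds <- function(dataset, spec = cv_spec()) {
  stopifnot(inherits(dataset, "epi_dataset"), inherits(spec, "cv_spec"))
  n <- length(dataset$labels)
  if (n == 0) abort("empty dataset")
  groups <- if (spec$group_by_antigen) dataset$keys$antigen_id else as.character(seq_len(n))
  gnames <- unique(groups)
  if (spec$n_folds > length(gnames)) {
    abort(sprintf("n_folds (%d) exceeds number of groups (%d)",
                  spec$n_folds, length(gnames)))
  }
  lapply(seq_len(spec$n_repeats), function(rep_i) {
    withr::with_seed(spec$seed + rep_i - 1L, {
      if (spec$stratified) {
        pos <- tapply(dataset$labels, groups, sum)[gnames]
        tot <- tapply(rep(1L, n), groups, sum)[gnames]
        ord <- sample(length(gnames)) # random tie order
        ord <- ord[order(-pos[ord], -tot[ord])]
        fold_pos <- numeric(spec$n_folds)
        fold_tot <- numeric(spec$n_folds)
        gfold <- integer(length(gnames))
        for (g in ord) {
          # fold whose positive count stays most balanced after adding the
          # group; ties go to the smallest fold
          spread <- vapply(seq_len(spec$n_folds), function(f) {
            trial <- fold_pos
            trial[f] <- trial[f] + pos[g]
            sd(trial)
          }, numeric(1))
          f <- order(spread, fold_tot)[1]
          gfold[g] <- f
          fold_pos[f] <- fold_pos[f] + pos[g]
          fold_tot[f] <- fold_tot[f] + tot[g]
        }
      } else {
        gfold <- sample(rep_len(seq_len(spec$n_folds), length(gnames)))
      }
      unname(gfold[match(groups, gnames)])
    })
  })
}

#' Cross-validate a meta-learning architecture
#'
#' For each repeat and fold: trains the architecture on the remaining folds,
#' predicts the held-out fold, and records all confusion-matrix measures plus
#' AUC. The overall performance is the mean over all fold results.
#'
#' @param dataset An `epi_dataset`.
#' @param arch An [arch_spec()].
#' @param spec A [cv_spec()].
#' @return An `epi_cv` object: list with `folds` (per-fold metric tibble) and
#'   `summary` (column means). Has [tidy()] and [glance()] methods.
#' @export
cross_validate <- function(dataset, arch, spec = cv_spec()) {
  assignments <- make_folds(dataset, spec)
  rows <- purrr::imap_dfr(assignments, function(fold_of, rep_i) {
    purrr::map_dfr(seq_len(spec$n_folds), function(f) {
      train <- dataset_subset(dataset, rows = fold_of != f)
      test <- dataset_subset(dataset, rows = fold_of == f)
      if (length(unique(train$labels)) < 2) {
        abort(sprintf("training split for repeat %d fold %d has a single class",
                      rep_i, f))
      }
      fit <- fit_architecture(train, arch)
      pred <- predict_meta(fit, test)
      m <- metrics(confusion(pred$label_hat, test$labels))
      m$auc <- if (length(unique(test$labels)) < 2) NA_real_ else
        roc_auc(pred$score, test$labels)$auc
      dplyr::bind_cols(tibble::tibble(repeat_id = rep_i, fold = f), m)
    })
  })
  summary <- dplyr::summarise(rows, dplyr::across(-c(repeat_id, fold),
                                                  ~ mean(.x, na.rm = TRUE)))
  structure(list(folds = rows, summary = summary, arch = arch, cv = spec),
            class = "epi_cv")
}

#' @export
print.epi_cv <- function(x, ...) {
  cat(sprintf("<epi_cv> %d fold results (%d repeat(s) x %d folds)\n",
              nrow(x$folds), x$cv$n_repeats, x$cv$n_folds))
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `epi_cv` object.
#' @param ... Unused.
#' @export
tidy.epi_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.epi_cv <- function(x, ...) x$summary

#' Paired two-sided t test on fold-matched metrics
#'
#' @param metric_a,metric_b Equal-length (>= 2) metric vectors paired by fold.
#' @return List with `t` and `p`. When the differences have zero variance the
#'   test is degenerate: a warning is raised and `p = 1` is returned (`t = 0`
#'   if the vectors are identical, `NA` otherwise).
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2) {
    abort("paired_ttest needs two equal-length vectors of length >= 2")
  }
  d <- metric_a - metric_b
  if (sd(d) == 0) {
    warn("zero variance of paired differences; t test degenerate")
    return(list(t = if (all(d == 0)) 0 else NA_real_, p = 1))
  }
  ht <- t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

.round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Reconstruct a confusion matrix from rounded published rates
#'
#' Given TPR, FPR, and precision as printed (rounded half-up to `decimals`
#' digits) and the class sizes P and N, searches all integer (TP, FP) pairs
#' whose rates round to the inputs. Additional printed rates (`accuracy`,
#' `fscore`, `mcc`) may be supplied to narrow the candidate set. Errors if no
#' candidate exists, or if several remain (listing them).
#'
#' @param tpr,fpr,precision Printed rates in \[0, 1\].
#' @param P,N Positive and negative class sizes.
#' @param decimals Printed precision (default 3).
#' @param accuracy,fscore,mcc Optional additional printed rates.
#' @return A `confusion` object (with TN = N - FP, FN = P - TP).
#' @export
reconstruct_confusion <- function(tpr, fpr, precision, P, N, decimals = 3L,
                                  accuracy = NULL, fscore = NULL, mcc = NULL) {
  stopifnot(P > 0, N > 0, tpr >= 0, tpr <= 1, fpr >= 0, fpr <= 1,
            precision >= 0, precision <= 1)
  TPs <- which(.round_half_up((0:P) / P, decimals) == tpr) - 1L
  FPs <- which(.round_half_up((0:N) / N, decimals) == fpr) - 1L
  if (length(TPs) == 0 || length(FPs) == 0) {
    abort("no integer counts round to the given TPR/FPR")
  }
  cand <- expand.grid(TP = TPs, FP = FPs)
  prec_of <- ifelse(cand$TP + cand$FP == 0, 0, cand$TP / (cand$TP + cand$FP))
  cand <- cand[.round_half_up(prec_of, decimals) == precision, , drop = FALSE]
  keep_rate <- function(cand, target, value_fun) {
    if (is.null(target) || nrow(cand) == 0) return(cand)
    vals <- vapply(seq_len(nrow(cand)), function(i) {
      value_fun(cand$TP[i], cand$FP[i])
    }, numeric(1))
    cand[.round_half_up(vals, decimals) == target, , drop = FALSE]
  }
  cand <- keep_rate(cand, accuracy, function(TP, FP) (TP + N - FP) / (P + N))
  cand <- keep_rate(cand, fscore, function(TP, FP) {
    m <- metrics(new_confusion(TP, FP, N - FP, P - TP)); m$fscore
  })
  cand <- keep_rate(cand, mcc, function(TP, FP) {
    m <- metrics(new_confusion(TP, FP, N - FP, P - TP)); m$mcc
  })
  if (nrow(cand) == 0) abort("no (TP, FP) pair is consistent with the given rates")
  if (nrow(cand) > 1) {
    abort(paste0(
      "multiple consistent (TP, FP) pairs: ",
      paste(sprintf("(%d, %d)", cand$TP, cand$FP), collapse = ", "),
      "; supply additional rates to disambiguate"
    ))
  }
  new_confusion(TP = cand$TP[1], FP = cand$FP[1],
                TN = N - cand$FP[1], FN = P - cand$TP[1])
}
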