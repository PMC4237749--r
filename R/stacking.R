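#' Meta-learning architecture specification
#'
#' Declarative description of a stacking or cascade hierarchy over the base
#' predictor scores and base features.
#'
#' @param kind `"stack2"` (one meta learner), `"stack3"` (three parallel
#'   level-1 meta learners arbitrated by a top learner), or `"cascade"`
#'   (sequential learners, each appending its prediction as a feature).
#' @param level1_learners Level-1 learners: for `stack3` exactly three of
#'   `"tree"`, `"knn"`, `"ann"`, `"svm"`; for `cascade` the full ordered
#'   sequence.
#' @param top_learner Top-level learner (default `"svm"`); for `stack2` this
#'   is the single meta learner.
#' @param use_score_block Include the base-tool score columns in the input
#'   block (default TRUE; FALSE gives the feature-based ablation variant).
#' @param include_base_features Include the base feature columns (default
#'   TRUE; FALSE gives the tool-based ablation variant).
#' @param include_base_tool_outputs_at_top For `stack3`: pass the raw base
#'   score columns to the top learner alongside base features and meta
#'   features (default TRUE).
#' @param meta_feature_form Form of meta features propagated between levels:
#'   `"probability"` (default), `"score"`, or `"label"`.
#' @param oof_folds Internal folds for out-of-fold meta features (>= 2,
#'   default 5).
#' @param seed Integer seed governing every random draw during fitting.
#' @param learner_control Named list of learner hyperparameter overrides
#'   (see the package vignette).
#' @return An `arch_spec` list.
#' @export
arch_spec <- function(kind = c("stack2", "stack3", "cascade"),
                      level1_learners = c("tree", "knn", "ann"),
                      top_learner = "svm",
                      use_score_block = TRUE,
                      include_base_features = TRUE,
                      include_base_tool_outputs_at_top = TRUE,
                      meta_feature_form = c("probability", "score", "label"),
                      oof_folds = 5L,
                      seed = 1L,
                      learner_control = list()) {
  kind <- match.arg(kind)
  meta_feature_form <- match.arg(meta_feature_form)
  bad <- setdiff(c(level1_learners, top_learner), .learner_names)
  if (length(bad) > 0) {
    abort(paste0("unknown learner name(s): ", paste(bad, collapse = ", ")))
  }
  if (kind == "stack3" && length(level1_learners) != 3) {
    abort("stack3 requires exactly 3 level-1 learners")
  }
  if (kind == "cascade" && anyDuplicated(level1_learners)) {
    abort("cascade order must not repeat a learner")
  }
  if (oof_folds < 2) abort("oof_folds must be >= 2")
  if (!use_score_block && !include_base_features) {
    abort("at least one of the score and feature blocks must be included")
  }
  structure(
    list(kind = kind, level1_learners = level1_learners,
         top_learner = top_learner, use_score_block = use_score_block,
         include_base_features = include_base_features,
         include_base_tool_outputs_at_top = include_base_tool_outputs_at_top,
         meta_feature_form = meta_feature_form,
         oof_folds = as.integer(oof_folds), seed = as.integer(seed),
         learner_control = learner_control),
    class = "arch_spec"
  )
}

#' Assemble the meta-learner input block
#'
#' Column block is the base-tool score columns (when `use_score_block`)
#' followed by the base feature columns (when `include_base_features`);
#' column order is deterministic and recorded in the fitted manifest.
#'
#' @param dataset An `epi_dataset`.
#' @param spec An [arch_spec()].
#' @return Numeric matrix with named columns.
#' @export
make_meta_input <- function(dataset, spec) {
  stopifnot(inherits(dataset, "epi_dataset"), inherits(spec, "arch_spec"))
  blocks <- list()
  if (spec$use_score_block) blocks <- c(blocks, list(dataset$scores))
  if (spec$include_base_features) blocks <- c(blocks, list(dataset$features))
  x <- do.call(cbind, blocks)
  if (is.null(x) || ncol(x) == 0) abort("meta input has no columns")
  x
}

new_fitted_meta <- function(spec, models, top_model, manifest) {
  structure(list(spec = spec, models = models, top_model = top_model,
                 manifest = manifest),
            class = "fitted_meta")
}

#' @export
print.fitted_meta <- function(x, ...) {
  cat(sprintf("<fitted_meta> %s", x$spec$kind))
  if (x$spec$kind == "stack2") {
    cat(sprintf(" (meta learner: %s)", x$spec$top_learner))
  } else if (x$spec$kind == "stack3") {
    cat(sprintf(" (level 1: %s; top: %s)",
                paste(x$spec$level1_learners, collapse = ", "),
                x$spec$top_learner))
  } else {
    cat(sprintf(" (order: %s)", paste(x$manifest$order, collapse = " -> ")))
  }
  cat(sprintf("\n  trained on %d residues, %d input column(s); seed %d\n",
              x$manifest$n_train, length(x$manifest$input_columns),
              x$spec$seed))
  invisible(x)
}

#' Fit a two-level stacking meta classifier
#'
#' A single meta learner (`spec$top_learner`) trained on the combined base
#' score/feature block; classification thresholds the predicted probability
#' at 0.5.
#'
#' @param dataset Assembled training `epi_dataset` with both classes present.
#' @param spec An [arch_spec()] with `kind = "stack2"`.
#' @return A `fitted_meta` object.
#' @export
fit_stack2 <- function(dataset, spec = arch_spec("stack2")) {
  stopifnot(inherits(spec, "arch_spec"))
  if (spec$kind != "stack2") abort("spec$kind must be \"stack2\"")
  x <- make_meta_input(dataset, spec)
  model <- .fit_learner(spec$top_learner, x, dataset$labels,
                        spec$learner_control, seed = spec$seed)
  new_fitted_meta(
    spec, models = list(), top_model = model,
    manifest = list(kind = "stack2", input_columns = colnames(x),
                    top_columns = colnames(x), n_train = nrow(x),
                    seed = spec$seed, threshold = 0.5)
  )
}

# Input block for the stack3 top learner: base features, optionally raw base
# scores, then the level-1 meta-feature columns.
.stack3_top_input <- function(dataset, spec, meta_cols) {
  blocks <- list()
  if (spec$include_base_features) blocks <- c(blocks, list(dataset$features))
  if (spec$include_base_tool_outputs_at_top && spec$use_score_block) {
    blocks <- c(blocks, list(dataset$scores))
  }
  blocks <- c(blocks, list(meta_cols))
  x <- do.call(cbind, blocks)
  if (ncol(meta_cols) == ncol(x)) return(x) # meta features only
  x
}

#' Fit a three-level stacking meta classifier
#'
#' The three level-1 meta learners are trained on the base block; their
#' out-of-fold predictions become three meta-feature columns for the top
#' learner, which also receives the base features (and, by default, the raw
#' base-tool scores). At prediction time the level-1 models refit on the full
#' training data supply the meta features.
#'
#' @param dataset Assembled training `epi_dataset`.
#' @param spec An [arch_spec()] with `kind = "stack3"`.
#' @return A `fitted_meta` object whose manifest records the out-of-fold
#'   bookkeeping (fold assignment and per-fold training indices) for leakage
#'   audits.
#' @export
fit_stack3 <- function(dataset, spec = arch_spec("stack3")) {
  stopifnot(inherits(spec, "arch_spec"))
  if (spec$kind != "stack3") abort("spec$kind must be \"stack3\"")
  if (spec$oof_folds < 2) abort("oof_folds must be >= 2")
  x1 <- make_meta_input(dataset, spec)
  y <- dataset$labels

  level1 <- list()
  audits <- list()
  meta_cols <- matrix(NA_real_, nrow = nrow(x1),
                      ncol = length(spec$level1_learners),
                      dimnames = list(NULL, paste0("meta_", spec$level1_learners)))
  for (i in seq_along(spec$level1_learners)) {
    nm <- spec$level1_learners[i]
    oof <- .oof_predict(nm, x1, y, spec$learner_control, spec$oof_folds,
                        seed = spec$seed + 100L * i)
    meta_cols[, i] <- .meta_feature_values(oof$oof, spec$meta_feature_form)
    level1[[nm]] <- .fit_learner(nm, x1, y, spec$learner_control,
                                 seed = spec$seed + 100L * i)
    audits[[nm]] <- list(fold_of = oof$fold_of, fold_models = oof$fold_models)
  }

  x_top <- .stack3_top_input(dataset, spec, meta_cols)
  top <- .fit_learner(spec$top_learner, x_top, y, spec$learner_control,
                      seed = spec$seed + 999L)
  new_fitted_meta(
    spec, models = level1, top_model = top,
    manifest = list(kind = "stack3", input_columns = colnames(x1),
                    top_columns = colnames(x_top),
                    meta_columns = colnames(meta_cols),
                    oof = audits, n_train = nrow(x1), seed = spec$seed,
                    threshold = 0.5)
  )
}

#' Predict per-residue epitope labels with a fitted meta classifier
#'
#' @param model A `fitted_meta` from [fit_stack2()], [fit_stack3()], or
#'   [fit_cascade()].
#' @param dataset An `epi_dataset` whose columns cover the training manifest
#'   (column order is realigned automatically).
#' @return Tibble with the residue key columns plus `score` (top-learner
#'   probability), `label_hat` (1 iff `score >= threshold_used`), and
#'   `threshold_used` (0.5).
#' @export
predict_meta <- function(model, dataset) {
  stopifnot(inherits(model, "fitted_meta"), inherits(dataset, "epi_dataset"))
  spec <- model$spec
  n <- nrow(dataset$keys)
  prob <- if (n == 0) {
    numeric(0)
  } else if (spec$kind == "stack2") {
    .predict_prob(model$top_model, make_meta_input(dataset, spec))
  } else if (spec$kind == "stack3") {
    x1 <- make_meta_input(dataset, spec)
    meta_cols <- vapply(spec$level1_learners, function(nm) {
      .meta_feature_values(.predict_prob(model$models[[nm]], x1),
                           spec$meta_feature_form)
    }, numeric(n))
    meta_cols <- matrix(meta_cols, nrow = n,
                        dimnames = list(NULL, paste0("meta_", spec$level1_learners)))
    .predict_prob(model$top_model, .stack3_top_input(dataset, spec, meta_cols))
  } else { # cascade
    x <- make_meta_input(dataset, spec)
    for (j in seq_along(model$manifest$order)) {
      nm <- model$manifest$order[j]
      p <- .predict_prob(model$models[[nm]], x)
      if (j == length(model$manifest$order)) {
        prob <- p
      } else {
        x <- cbind(x, .meta_feature_values(p, spec$meta_feature_form))
        colnames(x)[ncol(x)] <- paste0("meta_", nm)
      }
    }
    prob
  }
  thr <- model$manifest$threshold
  dplyr::bind_cols(
    dataset$keys,
    tibble::tibble(score = prob, label_hat = as.integer(prob >= thr),
                   threshold_used = thr)
  )
}

#' Fit any architecture described by an arch_spec
#'
#' Dispatches to [fit_stack2()], [fit_stack3()], or [fit_cascade()] (the
#' cascade order is `spec$level1_learners`).
#'
#' @param dataset Training `epi_dataset`.
#' @param spec An [arch_spec()].
#' @return A `fitted_meta` object.
#' @export
fit_architecture <- function(dataset, spec) {
  switch(spec$kind,
         stack2 = fit_stack2(dataset, spec),
         stack3 = fit_stack3(dataset, spec),
         cascade = fit_cascade(dataset, spec$level1_learners, spec))
}

#' Training manifest of a fitted meta classifier
#'
#' @param x A `fitted_meta`.
#' @param ... Unused.
#' @return Tibble of manifest entries: one row per input column with its role.
#' @export
tidy.fitted_meta <- function(x, ...) {
  man <- x$manifest
  base <- tibble::tibble(column = man$input_columns, role = "base_input")
  top <- tibble::tibble(column = man$top_columns %||% man$input_columns,
                        role = "top_input")
  dplyr::bind_rows(base, top)
}

#' One-row summary of a fitted meta classifier
#'
#' @param x A `fitted_meta`.
#' @param ... Unused.
#' @export
glance.fitted_meta <- function(x, ...) {
  tibble::tibble(
    kind = x$spec$kind,
    top_learner = x$spec$top_learner,
    n_train = x$manifest$n_train,
    n_input_columns = length(x$manifest$input_columns),
    oof_folds = x$spec$oof_folds,
    seed = x$spec$seed
  )
}
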