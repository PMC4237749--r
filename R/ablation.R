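#' Evaluation protocols for ablation analyses
#'
#' `eval_holdout()` trains on the training set and measures on a held-out
#' test set (how the published ablations were scored); `eval_cv()` measures
#' by cross-validation on the training set alone.
#'
#' @param test Held-out `epi_dataset`.
#' @return An `eval_protocol` list.
#' @export
eval_holdout <- function(test) {
  stopifnot(inherits(test, "epi_dataset"))
  structure(list(type = "holdout", test = test), class = "eval_protocol")
}

#' @rdname eval_holdout
#' @param cv A [cv_spec()].
#' @export
eval_cv <- function(cv = cv_spec()) {
  stopifnot(inherits(cv, "cv_spec"))
  structure(list(type = "cv", cv = cv), class = "eval_protocol")
}

# One-row metric record (incl. AUC) for an architecture under a protocol.
.evaluate_arch <- function(train, arch, protocol) {
  stopifnot(inherits(protocol, "eval_protocol"))
  if (protocol$type == "holdout") {
    fit <- fit_architecture(train, arch)
    test <- protocol$test
    pred <- predict_meta(fit, test)
    m <- metrics(confusion(pred$label_hat, test$labels))
    m$auc <- if (length(unique(test$labels)) < 2) NA_real_ else
      roc_auc(pred$score, test$labels)$auc
    m
  } else {
    cross_validate(train, arch, protocol$cv)$summary
  }
}

# Architecture restricted to a subset of base-tool columns; an empty subset
# yields the features-only model.
.arch_for_tools <- function(arch, train, tools) {
  if (length(tools) == 0) {
    if (!arch$include_base_features) {
      abort("cannot evaluate an empty model: no base tools left and base features excluded")
    }
    arch$use_score_block <- FALSE
    list(arch = arch, train = train)
  } else {
    list(arch = arch, train = dataset_subset(train, score_cols = tools))
  }
}

.eval_tool_subset <- function(train, arch, protocol, tools) {
  sub <- .arch_for_tools(arch, train, tools)
  prot <- protocol
  if (prot$type == "holdout" && length(tools) > 0) {
    prot$test <- dataset_subset(prot$test, score_cols = tools)
  } else if (prot$type == "holdout") {
    # features-only model predicts without the score block
  }
  .evaluate_arch(sub$train, sub$arch, prot)
}

new_ablation_trace <- function(steps, measure, start_record = NULL) {
  structure(list(steps = steps, measure = measure, start = start_record),
            class = "ablation_trace")
}

#' @export
print.ablation_trace <- function(x, ...) {
  dir <- if (all(x$steps$direction == "removed")) "backward elimination"
         else "forward selection"
  cat(sprintf("<ablation_trace> %s, %d step(s), measure = %s\n",
              dir, nrow(x$steps), x$measure))
  print(tidy(x))
  invisible(x)
}

#' Per-step records of an ablation trace
#'
#' Rows mirror the published ablation tables: the starting model first, then
#' one row per removed (`\\`) or added (`+`) component with the metrics of
#' the resulting meta classifier.
#'
#' @param x An `ablation_trace`.
#' @param ... Unused.
#' @export
tidy.ablation_trace <- function(x, ...) {
  out <- x$steps
  prefix <- ifelse(out$direction == "removed", "\\", "+")
  out$classifier <- paste0(prefix, out$component)
  if (!is.null(x$start)) {
    out <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(step = 0L, component = NA_character_,
                                      direction = NA_character_,
                                      classifier = "(start)"),
                       x$start),
      out
    )
  }
  dplyr::relocate(out, step, classifier)
}

#' Write an ablation trace as TSV
#'
#' @param trace An `ablation_trace`.
#' @param path Output path.
#' @export
write_ablation_trace <- function(trace, path) {
  readr::write_tsv(tidy(trace), path, progress = FALSE)
  invisible(path)
}

#' Greedy iterative backward elimination of base learners
#'
#' Starts from the meta classifier over all base learners. Each iteration
#' evaluates every single-component removal and removes the component whose
#' removal makes the measure worst (so the most influential component is
#' removed first), recording the metrics of the resulting classifier; the
#' final step leaves the features-only model. Candidate ties break
#' lexicographically by component name.
#'
#' @param train Training `epi_dataset`.
#' @param base_set Character vector of base-tool score columns to ablate.
#' @param arch An [arch_spec()].
#' @param protocol An [eval_holdout()] or [eval_cv()] protocol.
#' @param measure Metric column used for the greedy choice (default `"mcc"`).
#' @return An `ablation_trace`; `tidy()` yields the table, with the full
#'   model's record as step 0.
#' @export
backward_eliminate <- function(train, base_set, arch, protocol,
                               measure = "mcc") {
  if (length(base_set) < 1) abort("base_set must contain at least one component")
  missing <- setdiff(base_set, colnames(train$scores))
  if (length(missing) > 0) {
    abort(paste0("unknown base-tool column(s): ", paste(missing, collapse = ", ")))
  }
  start <- .eval_tool_subset(train, arch, protocol, sort(base_set))
  remaining <- sort(base_set)
  steps <- NULL
  step_i <- 0L
  while (length(remaining) >= 1) {
    step_i <- step_i + 1L
    cand <- purrr::map_dfr(remaining, function(b) {
      rec <- .eval_tool_subset(train, arch, protocol, setdiff(remaining, b))
      dplyr::bind_cols(tibble::tibble(component = b), rec)
    })
    worst <- which.min(cand[[measure]]) # first (lexicographic) on ties
    chosen <- cand$component[worst]
    steps <- dplyr::bind_rows(
      steps,
      dplyr::bind_cols(tibble::tibble(step = step_i, component = chosen,
                                      direction = "removed"),
                       cand[worst, setdiff(names(cand), "component")])
    )
    remaining <- setdiff(remaining, chosen)
  }
  new_ablation_trace(steps, measure, start_record = start)
}

#' Greedy iterative forward selection of base learners
#'
#' Starts from the meta classifier over `start_set` (possibly empty, i.e. the
#' features-only model) and repeatedly adds the candidate whose addition
#' maximizes the measure, recording the metrics after each addition.
#'
#' @param train Training `epi_dataset`.
#' @param start_set Base-tool columns always included (may be empty).
#' @param candidates Base-tool columns to add, disjoint from `start_set`.
#' @inheritParams backward_eliminate
#' @return An `ablation_trace` with the start model as step 0.
#' @export
forward_select <- function(train, start_set, candidates, arch, protocol,
                           measure = "mcc") {
  if (length(candidates) < 1) abort("candidates must contain at least one component")
  if (length(intersect(start_set, candidates)) > 0) {
    abort("candidates must be disjoint from start_set")
  }
  missing <- setdiff(c(start_set, candidates), colnames(train$scores))
  if (length(missing) > 0) {
    abort(paste0("unknown base-tool column(s): ", paste(missing, collapse = ", ")))
  }
  current <- sort(start_set)
  start <- .eval_tool_subset(train, arch, protocol, current)
  remaining <- sort(candidates)
  steps <- NULL
  step_i <- 0L
  while (length(remaining) >= 1) {
    step_i <- step_i + 1L
    cand <- purrr::map_dfr(remaining, function(b) {
      rec <- .eval_tool_subset(train, arch, protocol, sort(c(current, b)))
      dplyr::bind_cols(tibble::tibble(component = b), rec)
    })
    best <- which.max(cand[[measure]])
    chosen <- cand$component[best]
    steps <- dplyr::bind_rows(
      steps,
      dplyr::bind_cols(tibble::tibble(step = step_i, component = chosen,
                                      direction = "added"),
                       cand[best, setdiff(names(cand), "component")])
    )
    current <- sort(c(current, chosen))
    remaining <- setdiff(remaining, chosen)
  }
  new_ablation_trace(steps, measure, start_record = start)
}

#' Tool-only and feature-only block ablation
#'
#' Evaluates, under one protocol, the full meta classifier, the tool-based
#' variant (base-tool scores only), and the feature-based variant (base
#' features only).
#'
#' @param train Training `epi_dataset` with non-empty score and feature
#'   blocks.
#' @param arch An [arch_spec()] with both blocks enabled.
#' @param protocol An [eval_holdout()] or [eval_cv()] protocol.
#' @return Tibble with rows `full`, `tool_based`, `feature_based` and the
#'   metric columns.
#' @export
block_ablation <- function(train, arch, protocol) {
  if (ncol(train$scores) == 0 || ncol(train$features) == 0) {
    abort("block ablation needs both a score block and a feature block")
  }
  if (!arch$use_score_block || !arch$include_base_features) {
    abort("arch must include both blocks for block ablation")
  }
  tool_arch <- arch; tool_arch$include_base_features <- FALSE
  feat_arch <- arch; feat_arch$use_score_block <- FALSE
  purrr::map_dfr(
    list(full = arch, tool_based = tool_arch, feature_based = feat_arch),
    function(a) .evaluate_arch(train, a, protocol),
    .id = "model"
  )
}
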