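#' Fit a cascade generalization meta classifier
#'
#' Learners are composed sequentially: level `j` is trained on the base block
#' plus the meta-feature columns produced by levels `1..j-1`, and appends its
#' own prediction as a new column for the next level. During training the
#' appended columns are out-of-fold predictions (no learner's training-time
#' meta feature for a residue comes from a model that saw that residue); at
#' prediction time the full-data models are applied in sequence. The final
#' level's output is the classification.
#'
#' @param dataset Assembled training `epi_dataset`.
#' @param order Character vector of distinct learner names, applied from the
#'   first level to the top.
#' @param spec An [arch_spec()]; its `kind` is coerced to `"cascade"` and
#'   `level1_learners` to `order`.
#' @return A `fitted_meta` object; the manifest records the order and the
#'   out-of-fold bookkeeping per level.
#' @export
fit_cascade <- function(dataset, order = c("knn", "tree", "ann", "svm"),
                        spec = arch_spec("cascade", level1_learners = order)) {
  stopifnot(inherits(dataset, "epi_dataset"), inherits(spec, "arch_spec"))
  if (length(order) == 0) abort("cascade order must be non-empty")
  if (anyDuplicated(order)) abort("cascade order must not repeat a learner")
  bad <- setdiff(order, .learner_names)
  if (length(bad) > 0) {
    abort(paste0("unknown learner name(s): ", paste(bad, collapse = ", ")))
  }
  spec$kind <- "cascade"
  spec$level1_learners <- order

  x <- make_meta_input(dataset, spec)
  base_columns <- colnames(x)
  y <- dataset$labels
  models <- list()
  audits <- list()
  level_widths <- integer(length(order))

  for (j in seq_along(order)) {
    nm <- order[j]
    level_widths[j] <- ncol(x)
    models[[nm]] <- .fit_learner(nm, x, y, spec$learner_control,
                                 seed = spec$seed + 100L * j)
    if (j < length(order)) {
      oof <- .oof_predict(nm, x, y, spec$learner_control, spec$oof_folds,
                          seed = spec$seed + 100L * j)
      x <- cbind(x, .meta_feature_values(oof$oof, spec$meta_feature_form))
      colnames(x)[ncol(x)] <- paste0("meta_", nm)
      audits[[nm]] <- list(fold_of = oof$fold_of, fold_models = oof$fold_models,
                           input_columns = colnames(x)[-ncol(x)])
    }
  }

  new_fitted_meta(
    spec, models = models, top_model = models[[order[length(order)]]],
    manifest = list(kind = "cascade", order = order,
                    input_columns = base_columns,
                    level_widths = level_widths, oof = audits,
                    n_train = nrow(dataset$keys), seed = spec$seed,
                    threshold = 0.5)
  )
}

#' All sequential arrangements of a learner set
#'
#' @param learners Character vector of distinct learner names.
#' @return List of all `factorial(length(learners))` permutations
#'   (character vectors), in lexicographic order.
#' @export
enumerate_orders <- function(learners) {
  if (anyDuplicated(learners)) abort("learner names must be distinct")
  n <- length(learners)
  if (n == 0) return(list())
  learners <- sort(learners)
  if (n == 1) return(list(learners))
  out <- list()
  for (i in seq_len(n)) {
    rest <- enumerate_orders(learners[-i])
    out <- c(out, lapply(rest, function(p) c(learners[i], p)))
  }
  out
}

#' Exhaustive cascade order selection by cross-validation
#'
#' Evaluates every permutation of the learner set under the given CV
#' protocol and returns the order maximizing the chosen measure (ties broken
#' lexicographically, which is the enumeration order).
#'
#' @param dataset Training `epi_dataset`.
#' @param learners Distinct learner names to arrange.
#' @param cv A [cv_spec()].
#' @param measure Metric column to maximize (default `"mcc"`).
#' @param spec Base [arch_spec()] supplying flags, seed, and learner control.
#' @return List with `best_order` (character vector) and `table` (one row per
#'   permutation with its mean CV metrics).
#' @export
select_cascade_order <- function(dataset, learners = c("tree", "knn", "ann", "svm"),
                                 cv = cv_spec(), measure = "mcc",
                                 spec = arch_spec("cascade",
                                                  level1_learners = learners)) {
  orders <- enumerate_orders(learners)
  if (length(orders) == 0) abort("no learners supplied")
  tab <- purrr::map_dfr(orders, function(ord) {
    sp <- spec
    sp$kind <- "cascade"
    sp$level1_learners <- ord
    res <- cross_validate(dataset, sp, cv)
    dplyr::bind_cols(tibble::tibble(order = paste(ord, collapse = " -> ")),
                     res$summary)
  })
  best <- which.max(tab[[measure]])
  list(best_order = orders[[best]], table = tab, measure = measure)
}
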