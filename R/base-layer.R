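#' Specification of a base epitope predictor score column
#'
#' A base learner here is an external predictor consumed as a per-residue
#' score column, binarized at a tunable threshold.
#'
#' @param name Predictor name.
#' @param score_column Score column in the dataset (defaults to `name`).
#' @param grid Ordered numeric vector of candidate thresholds (see
#'   [make_grid()]).
#' @param threshold Current threshold (defaults to the grid midpoint until
#'   optimized).
#' @param category `"conformational"` or `"linear"`.
#' @return A `base_learner_spec` list.
#' @export
base_learner_spec <- function(name, score_column = name,
                              grid = make_grid(0, 1, 0.01),
                              threshold = NULL,
                              category = c("conformational", "linear")) {
  category <- match.arg(category)
  if (length(grid) == 0) abort("threshold grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) abort("threshold grid must be strictly increasing")
  threshold <- threshold %||% grid[ceiling(length(grid) / 2)]
  if (threshold < min(grid) || threshold > max(grid)) {
    abort("threshold must lie within the grid range")
  }
  structure(
    list(name = name, score_column = score_column, threshold = threshold,
         grid = grid, category = category),
    class = "base_learner_spec"
  )
}

#' Binarize scores at a threshold
#'
#' @param scores Numeric vector.
#' @param threshold Scalar threshold; a residue is called epitopic when its
#'   score is greater than or equal to the threshold.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(scores, threshold) {
  stopifnot(is.numeric(scores), length(threshold) == 1, is.finite(threshold))
  as.integer(scores >= threshold)
}

#' Arithmetic threshold grid
#'
#' Candidate thresholds `lo + step, lo + 2*step, ...` strictly inside
#' `(lo, hi)` when `endpoints = FALSE` (the default, matching the
#' 0.01, 0.02, ..., 0.99 enumeration used for tools scored on \[0, 1\]), or
#' including both endpoints when `endpoints = TRUE` (for tools whose printed
#' score range is an inclusive bound).
#'
#' @param lo,hi Range bounds, `lo < hi`.
#' @param step Positive increment, smaller than `hi - lo`.
#' @param endpoints Include `lo` and `hi` themselves?
#' @return Increasing numeric vector.
#' @export
make_grid <- function(lo, hi, step, endpoints = FALSE) {
  if (!(lo < hi)) abort("lo must be < hi")
  if (step <= 0 || step >= (hi - lo)) abort("step must be in (0, hi - lo)")
  k <- seq_len(floor((hi - lo) / step + 1e-9))
  inner <- lo + k * step
  inner <- inner[inner < hi - 1e-12]
  if (endpoints) c(lo, inner, hi) else inner
}

#' Optimize a binarization threshold by systematic grid search
#'
#' Evaluates every candidate threshold against the labels and returns the one
#' maximizing the chosen measure; ties go to the smallest threshold.
#'
#' @param scores Numeric score vector.
#' @param labels Integer 0/1 truth vector with both classes present.
#' @param grid Candidate thresholds (see [make_grid()]).
#' @param measure One of `"mcc"` (default), `"fscore"`, `"accuracy"`,
#'   `"precision"`, `"tpr"`.
#' @return List with `best_threshold`, `best_value`, and the full `table`
#'   (tibble of threshold and measure value).
#' @export
optimize_threshold <- function(scores, labels, grid = make_grid(0, 1, 0.01),
                               measure = c("mcc", "fscore", "accuracy",
                                           "precision", "tpr")) {
  measure <- match.arg(measure)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("labels contain a single class; threshold optimization undefined")
  }
  vals <- vapply(grid, function(t) {
    metrics(confusion(binarize(scores, t), labels))[[measure]]
  }, numeric(1))
  best <- which.max(vals) # which.max returns the first (smallest) maximizer
  list(
    best_threshold = grid[best],
    best_value = vals[best],
    table = tibble::tibble(threshold = grid, value = vals, measure = measure)
  )
}

#' Optimize thresholds for a set of base learners on a dataset
#'
#' @param dataset An `epi_dataset`.
#' @param specs List of [base_learner_spec()]s.
#' @param measure Measure to maximize (see [optimize_threshold()]).
#' @return Tibble with one row per learner: name, category, optimized
#'   threshold and achieved value, plus the updated specs as an attribute
#'   `"specs"`.
#' @export
tune_base_thresholds <- function(dataset, specs, measure = "mcc") {
  stopifnot(inherits(dataset, "epi_dataset"))
  rows <- purrr::map(specs, function(sp) {
    if (!sp$score_column %in% colnames(dataset$scores)) {
      abort(paste0("score column not in dataset: ", sp$score_column))
    }
    opt <- optimize_threshold(dataset$scores[, sp$score_column],
                              dataset$labels, sp$grid, measure)
    sp$threshold <- opt$best_threshold
    list(spec = sp,
         row = tibble::tibble(name = sp$name, category = sp$category,
                              threshold = opt$best_threshold,
                              value = opt$best_value, measure = measure))
  })
  out <- purrr::map_dfr(rows, "row")
  attr(out, "specs") <- purrr::map(rows, "spec")
  out
}
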