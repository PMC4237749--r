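.check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired complete observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input; correlation undefined")
  list(x = x, y = y)
}

#' Pearson correlation of two score vectors
#'
#' @param x,y Equal-length numeric vectors (pairwise-complete observations
#'   are used; each must have nonzero variance).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  v <- .check_cor_input(x, y)
  cor(v$x, v$y, method = "pearson")
}

#' Spearman rank correlation of two score vectors
#'
#' Equals the Pearson correlation of the average (mid) ranks, which is how
#' ties are resolved.
#'
#' @inheritParams pearson
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  v <- .check_cor_input(x, y)
  cor(v$x, v$y, method = "spearman")
}

#' Pairwise correlation matrix of predictor score columns
#'
#' @param scores Numeric matrix or data frame of per-residue scores, one
#'   column per predictor.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal, computed on
#'   pairwise-complete observations.
#' @export
correlation_matrix <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) abort("need at least 2 score columns")
  cor(scores, method = method, use = "pairwise.complete.obs")
}

#' Mean pairwise correlation within a predictor group
#'
#' Averages the `choose(k, 2)` off-diagonal entries of the correlation matrix
#' restricted to the named columns.
#'
#' @param mat Correlation matrix as from [correlation_matrix()].
#' @param group Character vector (length >= 2) of column names.
#' @return Mean off-diagonal correlation.
#' @export
group_mean <- function(mat, group) {
  missing <- setdiff(group, colnames(mat))
  if (length(missing) > 0) {
    abort(paste0("unknown column(s): ", paste(missing, collapse = ", ")))
  }
  if (length(group) < 2) abort("group must contain at least 2 columns")
  sub <- mat[group, group, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Agreement distribution of base-tool classifications
#'
#' For each residue, counts how many tools classified it correctly, and
#' tabulates those counts separately for epitope and nonepitope residues.
#' Each class histogram sums to the class size.
#'
#' @param binary_predictions 0/1 matrix, residues x tools.
#' @param truth Integer 0/1 vector of residue labels.
#' @return Tibble with columns `n_correct_tools` (0..n_tools), `class_label`
#'   (`"epitope"` / `"nonepitope"`), and `count`.
#' @export
agreement_distribution <- function(binary_predictions, truth) {
  binary_predictions <- as.matrix(binary_predictions)
  if (ncol(binary_predictions) < 1) abort("need at least one tool column")
  if (nrow(binary_predictions) != length(truth)) {
    abort("row count must match truth length")
  }
  correct <- binary_predictions == matrix(truth, nrow = length(truth),
                                          ncol = ncol(binary_predictions))
  n_correct <- rowSums(correct)
  levels <- 0:ncol(binary_predictions)
  purrr::map_dfr(c(epitope = 1L, nonepitope = 0L), function(cls) {
    counts <- table(factor(n_correct[truth == cls], levels = levels))
    tibble::tibble(n_correct_tools = levels, count = as.integer(counts))
  }, .id = "class_label")[, c("n_correct_tools", "class_label", "count")]
}

#' Plot an agreement distribution
#'
#' @param object Tibble from [agreement_distribution()].
#' @param ... Unused.
#' @return A ggplot: per-class bar charts of residues by the number of tools
#'   classifying them correctly.
#' @export
plot_agreement <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(n_correct_tools), y = count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~class_label, scales = "free_y") +
    ggplot2::labs(x = "number of tools classifying the residue correctly",
                  y = "residues") +
    ggplot2::theme_minimal()
}
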