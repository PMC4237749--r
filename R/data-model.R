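#' Read antigen sequences from a FASTA file
#'
#' Sequences are returned uppercase, named by their FASTA record id (the first
#' whitespace-delimited token of the header, e.g. `"1BZQ_A"`). Record order is
#' preserved. Duplicate ids are an error because antigen ids key every
#' residue-level table downstream.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector, one element per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">1BZQ_A", "MKV"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA record id(s): ", paste(dup, collapse = ", ")))
  }
  setNames(toupper(as.character(set)), ids)
}

.key_cols <- c("antigen_id", "chain", "position", "aa")

.standard_aa <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

.check_keys <- function(tbl, what) {
  missing <- setdiff(.key_cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(what, ": missing key column(s): ", paste(missing, collapse = ", ")))
  }
  keys <- paste(tbl$antigen_id, tbl$chain, tbl$position, sep = "\r")
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    shown <- head(gsub("\r", "/", dup), 5)
    abort(paste0(
      what, ": duplicate residue key(s): ", paste(shown, collapse = ", "),
      if (length(dup) > 5) sprintf(" (and %d more)", length(dup) - 5) else ""
    ))
  }
  bad_aa <- !(tbl$aa %in% c(.standard_aa, "X"))
  if (any(bad_aa)) {
    abort(paste0(
      what, ": non-standard amino-acid code(s): ",
      paste(unique(tbl$aa[bad_aa]), collapse = ", ")
    ))
  }
  invisible(tbl)
}

#' Read a residue-level table (features, scores, or labels)
#'
#' Tables are tab-separated with a header of the four key columns
#' `antigen_id`, `chain`, `position`, `aa` followed by one or more value
#' columns. Lines starting with `#` are comments; empty cells and `NA` are
#' missing values. Label tables must contain exactly the values 0 and 1.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"features"`, `"scores"`, `"labels"`; controls
#'   validation of the value columns.
#' @return A tibble keyed by residue, with numeric value columns (integer 0/1
#'   for labels).
#' @export
read_residue_table <- function(path, kind = c("features", "scores", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("residue table not found: ", path))
  tbl <- readr::read_tsv(
    path,
    comment = "#", na = c("", "NA"),
    col_types = readr::cols(
      antigen_id = readr::col_character(),
      chain = readr::col_character(),
      position = readr::col_integer(),
      aa = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  .check_keys(tbl, basename(path))
  value_cols <- setdiff(names(tbl), .key_cols)
  if (length(value_cols) == 0) {
    abort(paste0(basename(path), ": no value columns beyond the residue key"))
  }
  for (col in value_cols) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: non-numeric value in column '%s' at row %d: '%s'",
        basename(path), col, bad[1], raw[bad[1]]
      ))
    }
    if (kind == "labels") {
      out_of_range <- which(!is.na(num) & !(num %in% c(0, 1)))
      if (length(out_of_range) > 0) {
        abort(sprintf(
          "%s: label outside {0,1} in column '%s' at row %d: %s",
          basename(path), col, out_of_range[1], raw[out_of_range[1]]
        ))
      }
      num <- as.integer(num)
    }
    tbl[[col]] <- num
  }
  tbl
}

#' Write a residue-level table as TSV
#'
#' Inverse of [read_residue_table()]: values round-trip exactly (full decimal
#' precision, `NA` for missing).
#'
#' @param tbl Residue table (tibble with key columns first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(tbl, path) {
  .check_keys(tbl, "write_residue_table")
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Assemble a residue dataset from feature, score, and label tables
#'
#' Joins the three tables on the residue key (antigen, chain, position, amino
#' acid), keeping the intersection of keys. Residues with any missing value in
#' the retained columns are dropped (`missing_policy = "drop_residue"`, the
#' default) or trigger an error (`"fail"`). The exclusion report records what
#' was dropped and why.
#'
#' @param features,scores,labels Residue tables as returned by
#'   [read_residue_table()]. `labels` must have exactly one value column.
#' @param missing_policy `"drop_residue"` or `"fail"`.
#' @return An `epi_dataset`: a list with `keys` (tibble of residue keys),
#'   `features` (numeric matrix, possibly 0 columns), `scores` (numeric
#'   matrix), `labels` (integer 0/1 vector), and `exclusions` (report list
#'   with counts and the dropped keys).
#' @export
assemble_dataset <- function(features, scores, labels,
                             missing_policy = c("drop_residue", "fail")) {
  missing_policy <- match.arg(missing_policy)
  .check_keys(features, "features")
  .check_keys(scores, "scores")
  .check_keys(labels, "labels")
  label_col <- setdiff(names(labels), .key_cols)
  if (length(label_col) != 1) {
    abort("labels table must have exactly one value column")
  }

  merged <- dplyr::inner_join(features, scores, by = .key_cols)
  merged <- dplyr::inner_join(merged, labels, by = .key_cols)
  n_intersect <- nrow(merged)
  if (n_intersect == 0) abort("empty key intersection across feature/score/label tables")

  value_cols <- setdiff(names(merged), .key_cols)
  has_missing <- rowSums(is.na(merged[, value_cols, drop = FALSE])) > 0
  if (any(has_missing) && missing_policy == "fail") {
    abort(sprintf(
      "%d residue(s) have missing values (missing_policy = \"fail\")",
      sum(has_missing)
    ))
  }
  excluded <- merged[has_missing, .key_cols]
  merged <- merged[!has_missing, , drop = FALSE]
  if (nrow(merged) == 0) abort("no residues left after dropping rows with missing values")

  merged <- dplyr::arrange(merged, antigen_id, chain, position)

  feat_cols <- setdiff(names(features), .key_cols)
  score_cols <- setdiff(names(scores), .key_cols)
  new_epi_dataset(
    keys = tibble::as_tibble(merged[, .key_cols]),
    features = as.matrix(merged[, feat_cols, drop = FALSE]),
    scores = as.matrix(merged[, score_cols, drop = FALSE]),
    labels = as.integer(merged[[label_col]]),
    exclusions = list(
      n_key_intersection = n_intersect,
      n_dropped_missing = sum(has_missing),
      dropped_keys = tibble::as_tibble(excluded)
    )
  )
}

new_epi_dataset <- function(keys, features, scores, labels, exclusions = NULL) {
  stopifnot(nrow(keys) == nrow(features), nrow(keys) == nrow(scores),
            nrow(keys) == length(labels))
  structure(
    list(keys = keys, features = features, scores = scores,
         labels = as.integer(labels),
         exclusions = exclusions %||%
           list(n_key_intersection = nrow(keys), n_dropped_missing = 0L,
                dropped_keys = keys[0, ])),
    class = "epi_dataset"
  )
}

#' @export
print.epi_dataset <- function(x, ...) {
  cat(sprintf(
    "<epi_dataset> %d residues on %d antigen(s); %d feature column(s), %d score column(s)\n",
    nrow(x$keys), length(unique(x$keys$antigen_id)),
    ncol(x$features), ncol(x$scores)
  ))
  prev <- mean(x$labels)
  cat(sprintf("  epitope residues: %d (prevalence %.4f)\n", sum(x$labels), prev))
  if (x$exclusions$n_dropped_missing > 0) {
    cat(sprintf("  dropped for missing values: %d\n", x$exclusions$n_dropped_missing))
  }
  invisible(x)
}

#' @export
dim.epi_dataset <- function(x) {
  c(nrow(x$keys), ncol(x$features) + ncol(x$scores))
}

#' Subset an epi_dataset by row index and/or score columns
#'
#' @param dataset An `epi_dataset`.
#' @param rows Integer or logical row index (default all rows).
#' @param score_cols Character vector of score columns to keep (default all;
#'   `character(0)` drops the score block entirely, for feature-only models).
#' @return A new `epi_dataset`.
#' @export
dataset_subset <- function(dataset, rows = NULL, score_cols = NULL) {
  stopifnot(inherits(dataset, "epi_dataset"))
  rows <- rows %||% seq_len(nrow(dataset$keys))
  if (!is.null(score_cols)) {
    missing <- setdiff(score_cols, colnames(dataset$scores))
    if (length(missing) > 0) {
      abort(paste0("unknown score column(s): ", paste(missing, collapse = ", ")))
    }
  }
  cols <- score_cols %||% colnames(dataset$scores)
  new_epi_dataset(
    keys = dataset$keys[rows, , drop = FALSE],
    features = dataset$features[rows, , drop = FALSE],
    scores = dataset$scores[rows, cols, drop = FALSE],
    labels = dataset$labels[rows]
  )
}

#' Turn an epi_dataset back into a single residue-level tibble
#'
#' @param x An `epi_dataset`.
#' @param ... Unused.
#' @return Tibble with key columns, feature columns, score columns, and
#'   `label`.
#' @export
tidy.epi_dataset <- function(x, ...) {
  dplyr::bind_cols(
    x$keys,
    tibble::as_tibble(x$features),
    tibble::as_tibble(x$scores),
    tibble::tibble(label = x$labels)
  )
}

#' One-row summary of an epi_dataset
#'
#' @param x An `epi_dataset`.
#' @param ... Unused.
#' @return One-row tibble: residue count, antigen count, block widths,
#'   epitope count and prevalence, rows dropped at assembly.
#' @export
glance.epi_dataset <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$keys),
    n_antigens = length(unique(x$keys$antigen_id)),
    n_features = ncol(x$features),
    n_scores = ncol(x$scores),
    n_epitope = sum(x$labels),
    prevalence = mean(x$labels),
    n_dropped_missing = x$exclusions$n_dropped_missing
  )
}

#' Write per-residue predictions as TSV
#'
#' @param predictions Tibble as returned by [predict_meta()] (key columns plus
#'   `score`, `label_hat`, `threshold_used`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  needed <- c(.key_cols, "score", "label_hat", "threshold_used")
  missing <- setdiff(needed, names(predictions))
  if (length(missing) > 0) {
    abort(paste0("prediction table missing column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(predictions[, needed], path, progress = FALSE)
  invisible(path)
}
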