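#' Amino-acid propensity scale definition
#'
#' @param name Scale name.
#' @param per_aa_value Named numeric vector covering all 20 standard one-letter
#'   codes.
#' @param window Odd positive sliding-window width (default 7).
#' @return A `scale_definition` list.
#' @export
scale_definition <- function(name, per_aa_value, window = 7L) {
  missing <- setdiff(.standard_aa, names(per_aa_value))
  if (length(missing) > 0) {
    abort(paste0("scale '", name, "' missing amino acid(s): ",
                 paste(missing, collapse = ", ")))
  }
  .check_window(window)
  structure(
    list(name = name,
         per_aa_value = per_aa_value[.standard_aa],
         window = as.integer(window),
         aggregation = "mean"),
    class = "scale_definition"
  )
}

.check_window <- function(window) {
  if (length(window) != 1 || is.na(window) || window < 1 || window %% 2 != 1) {
    abort("window must be a single odd positive integer")
  }
  invisible(window)
}

# side-chain polarity classes partitioning the 20 standard amino acids
.polarity_class <- c(
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
  W = "nonpolar",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
  Q = "polar",
  D = "acidic_polar", E = "acidic_polar",
  K = "basic_polar", R = "basic_polar", H = "basic_polar"
)

.polarity_levels <- c("polar", "nonpolar", "acidic_polar", "basic_polar")

#' The shipped propensity-scale registry
#'
#' Loads the four sequence-propensity scales distributed with the package
#' (Parker hydrophilicity, Kyte-Doolittle hydropathy, Kolaskar-Tongaonkar
#' antigenicity, Karplus-Schulz flexibility) together with the four-way
#' side-chain polarity partition (polar, nonpolar, acidic polar, basic polar).
#'
#' @param windows Named integer vector of window widths per scale; scales not
#'   named keep the default of 7.
#' @return A `scale_registry` list with elements `scales` (named list of
#'   [scale_definition()]s) and `polarity_class` (named character vector).
#' @export
scale_registry <- function(windows = integer()) {
  scale_names <- c("parker_hydrophilicity", "kyte_doolittle_hydropathy",
                   "kolaskar_antigenicity", "karplus_schulz_flexibility")
  scales <- lapply(scale_names, function(nm) {
    path <- system.file("extdata", "scales", paste0(nm, ".tsv"),
                        package = "epistack", mustWork = TRUE)
    tbl <- readr::read_tsv(path, comment = "#", col_types = "cd",
                           progress = FALSE, show_col_types = FALSE)
    w <- if (nm %in% names(windows)) windows[[nm]] else 7L
    scale_definition(nm, setNames(tbl$value, tbl$aa), window = w)
  })
  names(scales) <- scale_names
  structure(list(scales = scales, polarity_class = .polarity_class),
            class = "scale_registry")
}

.split_seq <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    abort("sequence must be a single non-empty string")
  }
  strsplit(toupper(sequence), "")[[1]]
}

#' Sliding-window propensity profile of a sequence
#'
#' Element `i` is the mean scale value over the window centered at position
#' `i`; at the termini the window is truncated to the available positions, so
#' the output always has the same length as the input. Unknown residues
#' (`X`) contribute a scale value of 0.
#'
#' @param sequence Amino-acid string.
#' @param scale A [scale_definition()].
#' @param window Optional window override (odd positive integer).
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
windowed_scale <- function(sequence, scale, window = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  window <- window %||% scale$window
  .check_window(window)
  chars <- .split_seq(sequence)
  vals <- unname(scale$per_aa_value[chars])
  vals[is.na(vals)] <- 0
  n <- length(vals)
  half <- (window - 1) / 2
  # truncated-window mean via cumulative sums
  cs <- c(0, cumsum(vals))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Side-chain polarity indicator matrix
#'
#' One row per residue, four columns (`polar`, `nonpolar`, `acidic_polar`,
#' `basic_polar`); each row of a standard residue has exactly one 1. Unknown
#' codes yield an all-zero row.
#'
#' @param sequence Amino-acid string.
#' @return Binary matrix `nchar(sequence)` x 4.
#' @export
polarity_onehot <- function(sequence) {
  chars <- .split_seq(sequence)
  cls <- .polarity_class[chars]
  out <- matrix(0L, nrow = length(chars), ncol = 4,
                dimnames = list(NULL, .polarity_levels))
  known <- !is.na(cls)
  out[cbind(which(known), match(cls[known], .polarity_levels))] <- 1L
  out
}

#' Build the sequence-derived residue feature table
#'
#' For each antigen sequence, computes the four windowed propensity profiles
#' and the four polarity indicators, giving one row per residue with
#' positions numbered 1..length. The chain is taken from the trailing
#' `"_<chain>"` of the antigen id when present (e.g. `"1BZQ_A"`), else `"A"`.
#'
#' @param sequences Named character vector as returned by [read_fasta()].
#' @param registry A [scale_registry()].
#' @param windows Named integer vector of per-scale window overrides.
#' @return Residue feature tibble (key columns + 8 feature columns) suitable
#'   for [assemble_dataset()].
#' @export
build_feature_block <- function(sequences, registry = scale_registry(),
                                windows = integer()) {
  stopifnot(inherits(registry, "scale_registry"))
  if (length(sequences) == 0) abort("no sequences supplied")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("sequences must be named by antigen id")
  }
  unknown <- setdiff(names(windows), names(registry$scales))
  if (length(unknown) > 0) {
    abort(paste0("unknown scale name(s): ", paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(names(sequences), function(id) {
    seq <- sequences[[id]]
    chars <- .split_seq(seq)
    chain <- if (grepl("^.+_[^_]+$", id)) sub("^.*_", "", id) else "A"
    scale_cols <- purrr::map(registry$scales, function(sc) {
      w <- if (sc$name %in% names(windows)) windows[[sc$name]] else NULL
      windowed_scale(seq, sc, window = w)
    })
    dplyr::bind_cols(
      tibble::tibble(
        antigen_id = id, chain = chain,
        position = seq_along(chars), aa = chars
      ),
      tibble::as_tibble(scale_cols),
      tibble::as_tibble(polarity_onehot(seq))
    )
  })
}
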