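#' Nested downsampling by repeated halving
#'
#' Builds the downsampling series used throughout the saturation analysis:
#' level 1 draws half of the cells uniformly without replacement, and every
#' further level draws half of the *previous* level, so the subsets are
#' strictly nested. Odd sizes halve by floor (101,592 -> 50,796 -> 25,398 ->
#' 12,699 -> 6,349).
#'
#' @param cells Character vector of barcodes to sample from.
#' @param n_levels Number of halvings.
#' @param seed RNG seed; the whole series is reproducible from it.
#' @param parent_id Analysis id of the source matrix.
#' @return A `DownsampleSeries`: list with `subsets` (list of barcode
#'   vectors), `sizes`, `seed`, `scheme`, `parent_id`.
#' @export
nested_halving <- function(cells, n_levels, seed = 1L, parent_id = "full") {
  cells <- as.character(cells)
  n <- length(cells)
  stopifnot(n_levels >= 1)
  if (2^n_levels > n) {
    stop(sprintf("nested_halving: %d levels need at least %d cells, got %d",
                 n_levels, 2^n_levels, n))
  }
  set.seed(seed)
  subsets <- vector("list", n_levels)
  current <- cells
  for (i in seq_len(n_levels)) {
    current <- sample(current, floor(length(current) / 2))
    subsets[[i]] <- current
  }
  structure(list(subsets = subsets, sizes = lengths(subsets),
                 seed = as.integer(seed), scheme = "halving",
                 parent_id = parent_id),
            class = "DownsampleSeries")
}

#' Nested downsampling along an explicit fraction series
#'
#' Draws nested subsets of sizes `round(f * n)` for a descending series of
#' fractions (e.g. 0.9, 0.8, ..., 0.1), each drawn from the previous subset.
#'
#' @param cells Character vector of barcodes.
#' @param fractions Strictly descending fractions in `(0, 1]`.
#' @param seed RNG seed.
#' @param parent_id Analysis id of the source matrix.
#' @return A `DownsampleSeries`.
#' @export
fraction_series <- function(cells, fractions, seed = 1L, parent_id = "full") {
  cells <- as.character(cells)
  stopifnot(length(fractions) >= 1, all(fractions > 0), all(fractions <= 1))
  if (any(diff(fractions) >= 0)) {
    stop("fraction_series: fractions must be strictly descending")
  }
  sizes <- round(fractions * length(cells))
  if (any(sizes < 1)) stop("fraction_series: a fraction yields an empty subset")
  set.seed(seed)
  subsets <- vector("list", length(fractions))
  current <- cells
  for (i in seq_along(fractions)) {
    current <- if (sizes[i] == length(current)) current else sample(current, sizes[i])
    subsets[[i]] <- current
  }
  structure(list(subsets = subsets, sizes = as.integer(sizes),
                 seed = as.integer(seed), scheme = "fractions",
                 parent_id = parent_id),
            class = "DownsampleSeries")
}

#' @export
print.DownsampleSeries <- function(x, ...) {
  cat(sprintf("DownsampleSeries (%s, seed %d) from '%s': %s cells\n",
              x$scheme, x$seed, x$parent_id,
              paste(x$sizes, collapse = " > ")))
  invisible(x)
}

#' Library representation of a subset
#'
#' Uniform random downsampling should keep every library's share of cells
#' close to its share in the source; this table makes that check explicit.
#'
#' @param subset Character vector of barcodes (one downsampling level).
#' @param x The source `CountMatrix` (with library labels).
#' @return Data frame per library: `n_source`, `n_subset`, `source_frac`,
#'   `subset_frac`, and `ratio` = subset_frac / source_frac.
#' @export
library_representation <- function(subset, x) {
  libs <- x$library_labels
  src <- table(libs)
  in_sub <- barcodes(x) %in% subset
  sub <- table(factor(libs[in_sub], levels = names(src)))
  data.frame(library = names(src),
             n_source = as.integer(src),
             n_subset = as.integer(sub),
             source_frac = as.numeric(src / sum(src)),
             subset_frac = as.numeric(if (sum(sub) > 0) sub / sum(sub) else sub),
             ratio = as.numeric((sub / max(sum(sub), 1)) / (src / sum(src))),
             row.names = NULL, stringsAsFactors = FALSE)
}
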