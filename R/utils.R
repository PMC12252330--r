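#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here follow the
#' half-up convention usual in the germplasm literature (e.g. 92.3%).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 1) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Modal value with smallest-value tie-break; deterministic and order-free.
mode_smallest <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

# Stop unless `df` has all of `cols`.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Trait-matrix helpers: first column is the germplasm id, the rest traits.
matrix_traits <- function(m) setdiff(names(m), "germplasm_id")

as_numeric_matrix <- function(m) {
  out <- as.matrix(m[matrix_traits(m)])
  rownames(out) <- m$germplasm_id
  storage.mode(out) <- "double"
  out
}
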