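#' Trait codebooks
#'
#' A codebook declares, for every candidate trait, whether it is qualitative
#' (ordinal-coded, with an ordered set of level labels mapped to consecutive
#' integer codes starting at 0 -- binary traits are conventionally 0 = "no",
#' 1 = "yes") or quantitative (measured on a continuous scale with units).
#' The codebook drives validation, aggregation and the diversity indices.
#'
#' `as_codebook()` validates a data frame with columns `trait`, `kind`,
#' `levels` (a list column of data frames with `label` and `code`, or a
#' string of the form `"label:code;label:code"`), and optionally `units`.
#'
#' @param df data frame with one row per trait.
#' @return a `trait_codebook` tibble with columns `trait`, `kind`, `units`
#'   and list column `levels`.
#' @export
#' @examples
#' as_codebook(data.frame(
#'   trait = "Leaf texture", kind = "qualitative",
#'   levels = "Papery:0;Leathery:1"
#' ))
as_codebook <- function(df) {
  check_columns(df, c("trait", "kind"), "codebook")
  if (nrow(df) == 0) abort("codebook has no traits")
  if (anyDuplicated(df$trait)) {
    abort(sprintf("duplicate trait name(s): %s",
                  paste(unique(df$trait[duplicated(df$trait)]), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(df$kind), c("qualitative", "quantitative"))
  if (length(bad_kind) > 0) {
    abort(sprintf("unknown trait kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  cb <- tibble::as_tibble(df)
  if (!"units" %in% names(cb)) cb$units <- NA_character_
  if (!"levels" %in% names(cb)) cb$levels <- vector("list", nrow(cb))
  if (is.character(cb$levels)) cb$levels <- lapply(cb$levels, parse_levels)
  cb$levels <- purrr::map2(cb$levels, seq_len(nrow(cb)), function(lv, i) {
    if (cb$kind[i] == "quantitative") return(NULL)
    if (is.null(lv) || (is.data.frame(lv) && nrow(lv) == 0)) {
      abort(sprintf("qualitative trait '%s' declares no levels", cb$trait[i]))
    }
    lv <- tibble::as_tibble(lv)
    check_columns(lv, c("label", "code"), sprintf("levels of '%s'", cb$trait[i]))
    lv$code <- as.integer(lv$code)
    if (!identical(lv$code, seq_len(nrow(lv)) - 1L)) {
      abort(sprintf("trait '%s' has non-consecutive codes (must be 0..k-1 in order)",
                    cb$trait[i]))
    }
    lv
  })
  cb <- cb[c("trait", "kind", "units", "levels")]
  class(cb) <- c("trait_codebook", class(cb))
  cb
}

parse_levels <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  mat <- stringr::str_match(trimws(parts), "^(.*):(\\d+)$")
  if (anyNA(mat[, 1])) abort(sprintf("cannot parse level spec '%s'", s))
  tibble::tibble(label = mat[, 2], code = as.integer(mat[, 3]))
}

format_levels <- function(lv) {
  if (is.null(lv)) return(NA_character_)
  paste(sprintf("%s:%d", lv$label, lv$code), collapse = ";")
}

#' Number of declared levels per qualitative trait
#'
#' @param cb a `trait_codebook`.
#' @return named integer vector over qualitative traits.
#' @export
n_levels <- function(cb) {
  qual <- cb[cb$kind == "qualitative", ]
  stats::setNames(vapply(qual$levels, nrow, integer(1)), qual$trait)
}

#' Read or write a trait codebook
#'
#' Codebooks are stored either as UTF-8 tab-delimited text with columns
#' `trait`, `kind`, `levels` (`"label:code;..."`) and `units`, or as JSON
#' (an array of objects with the same fields, `levels` being an array of
#' `{label, code}` objects). The format is chosen by file extension
#' (`.json` for JSON, anything else is read as TSV).
#'
#' @param path file path.
#' @return `read_codebook()` returns a validated `trait_codebook`;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(recs) == 0 || NROW(recs) == 0) abort("no traits in codebook file")
    df <- tibble::as_tibble(recs)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (nrow(df) == 0) abort("no traits in codebook file")
  }
  as_codebook(df)
}

#' @rdname read_codebook
#' @param cb a `trait_codebook`.
#' @export
write_codebook <- function(cb, path) {
  out <- tibble::tibble(
    trait = cb$trait, kind = cb$kind,
    levels = vapply(cb$levels, format_levels, character(1)),
    units = cb$units
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
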