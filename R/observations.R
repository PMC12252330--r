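#' Validate a replicate-level observation table
#'
#' Observations are long-format leaf measurements: one row per germplasm x
#' replicate leaf x trait. Validation checks every trait against the
#' codebook (qualitative values must be declared integer codes), that every
#' (germplasm, trait) combination has at least one replicate and no missing
#' values, and -- when a register is supplied -- warns about germplasms
#' absent from it (rows are kept: the register may lag the field notebook).
#'
#' @param obs data frame with columns `germplasm_id`, `replicate_id`,
#'   `trait`, `value`.
#' @param cb a [as_codebook()] trait codebook.
#' @param register optional `germplasm_register` for id cross-checking.
#' @return the validated observation tibble, unchanged.
#' @export
validate_observations <- function(obs, cb, register = NULL) {
  check_columns(obs, c("germplasm_id", "replicate_id", "trait", "value"),
                "observation table")
  obs <- tibble::as_tibble(obs)
  unknown <- setdiff(unique(obs$trait), cb$trait)
  if (length(unknown) > 0) {
    abort(sprintf("trait(s) not in codebook: %s", paste(unknown, collapse = ", ")))
  }
  if (anyNA(obs$value)) abort("missing values in observation table")
  k <- n_levels(cb)
  for (tr in intersect(names(k), unique(obs$trait))) {
    v <- obs$value[obs$trait == tr]
    if (any(v != floor(v) | v < 0 | v > k[[tr]] - 1)) {
      abort(sprintf("qualitative trait '%s' has value(s) outside codes 0..%d",
                    tr, k[[tr]] - 1L))
    }
  }
  if (!is.null(register)) {
    stray <- setdiff(unique(obs$germplasm_id), register$id)
    if (length(stray) > 0) {
      warn(sprintf("germplasm(s) absent from register (rows kept): %s",
                   paste(stray, collapse = ", ")))
    }
  }
  obs
}

#' Aggregate replicate leaves to a germplasm-level trait matrix
#'
#' Quantitative traits are summarised by the replicate mean; qualitative
#' traits by the replicate mode, ties broken toward the smallest code so the
#' result is deterministic and independent of row order. The output is the
#' germplasm x trait matrix (wide tibble, `germplasm_id` first) on which all
#' downstream statistics operate; qualitative cells remain integer ordinal
#' codes.
#'
#' @inheritParams validate_observations
#' @return a wide tibble, one row per germplasm, one column per trait.
#' @export
aggregate_observations <- function(obs, cb) {
  obs <- validate_observations(obs, cb)
  kind <- stats::setNames(cb$kind, cb$trait)
  agg <- obs |>
    dplyr::group_by(.data$germplasm_id, .data$trait) |>
    dplyr::summarise(
      value = if (kind[[.data$trait[1]]] == "quantitative") {
        mean(.data$value)
      } else {
        mode_smallest(.data$value)
      },
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(agg, names_from = "trait", values_from = "value")
  if (anyNA(wide)) {
    holes <- names(wide)[colSums(is.na(wide)) > 0]
    abort(sprintf("germplasm(s) with no replicates for trait(s): %s",
                  paste(holes, collapse = ", ")))
  }
  # column order follows the codebook for reproducible downstream layouts
  wide[c("germplasm_id", intersect(cb$trait, names(wide)))]
}

#' Read or write observation tables and trait matrices
#'
#' All tables are UTF-8 tab-delimited text with a header row and `.` as the
#' decimal separator; write-then-read round-trips are exact.
#'
#' @param path file path.
#' @return readers return tibbles; writers return `path` invisibly.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    germplasm_id = "c", replicate_id = "i", trait = "c", value = "d"
  ), progress = FALSE)
}

#' @rdname read_observations
#' @param obs observation tibble.
#' @export
write_observations <- function(obs, path) {
  readr::write_tsv(obs, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_observations
#' @export
read_trait_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    germplasm_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_observations
#' @param m wide trait matrix tibble (`germplasm_id` plus trait columns).
#' @export
write_trait_matrix <- function(m, path) {
  readr::write_tsv(m, path, progress = FALSE)
  invisible(path)
}
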