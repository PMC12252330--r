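#' Germplasm registers
#'
#' The register lists every accession in the collection: its id, taxonomic
#' rank (`species` or `cultivar`), the infrageneric section for species, and
#' any known parents for cultivars (one or two; partial pedigrees are
#' common, full pedigrees rare). Parents referencing ids absent from the
#' register are kept but flagged external with a warning.
#'
#' @param df data frame with columns `id`, `rank`, and optionally `section`
#'   and `parents` (list column of character vectors, or `"p1;p2"` strings).
#' @return a `germplasm_register` tibble.
#' @export
as_register <- function(df) {
  check_columns(df, c("id", "rank"), "register")
  if (anyDuplicated(df$id)) {
    abort(sprintf("duplicate germplasm id(s): %s",
                  paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(df$rank), c("species", "cultivar"))
  if (length(bad) > 0) abort(sprintf("unknown rank(s): %s", paste(bad, collapse = ", ")))
  reg <- tibble::as_tibble(df)
  if (!"section" %in% names(reg)) reg$section <- NA_character_
  if (!"parents" %in% names(reg)) reg$parents <- vector("list", nrow(reg))
  if (is.character(reg$parents)) {
    reg$parents <- lapply(reg$parents, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  reg$parents <- lapply(reg$parents, function(p) if (is.null(p)) character(0) else p)
  sect_on_cultivar <- !is.na(reg$section) & reg$rank == "cultivar"
  if (any(sect_on_cultivar)) {
    abort(sprintf("sections are declared on species only; offending cultivar(s): %s",
                  paste(reg$id[sect_on_cultivar], collapse = ", ")))
  }
  external <- setdiff(unlist(reg$parents), reg$id)
  if (length(external) > 0) {
    warn(sprintf("parent id(s) not in register, treated as external: %s",
                 paste(external, collapse = ", ")))
  }
  reg <- reg[c("id", "rank", "section", "parents")]
  class(reg) <- c("germplasm_register", class(reg))
  reg
}

#' Read or write a germplasm register
#'
#' Tab-delimited text with columns `id`, `rank`, `section`, `parents`
#' (semicolon-separated parent ids, empty when unknown).
#'
#' @param path file path.
#' @return `read_register()` returns a `germplasm_register`;
#'   `write_register()` returns `path` invisibly.
#' @export
read_register <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  as_register(df)
}

#' @rdname read_register
#' @param reg a `germplasm_register`.
#' @export
write_register <- function(reg, path) {
  out <- tibble::tibble(
    id = reg$id, rank = reg$rank, section = reg$section,
    parents = vapply(reg$parents, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
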