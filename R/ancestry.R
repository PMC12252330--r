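#' Extract the pedigree set from a register
#'
#' Cultivars with at least one known parent form the pedigree set; a
#' cultivar with fewer than two known parents carries a partial pedigree
#' (full and partial pedigrees are analysed together).
#'
#' @param register a `germplasm_register`.
#' @return tibble `cultivar`, `parents` (list of ids), `n_parents`,
#'   `partial` (fewer than 2 known parents).
#' @export
pedigree_set <- function(register) {
  cult <- register[register$rank == "cultivar", ]
  known <- vapply(cult$parents, length, integer(1))
  ped <- tibble::tibble(
    cultivar = cult$id[known > 0],
    parents = cult$parents[known > 0],
    n_parents = known[known > 0]
  )
  if (any(ped$n_parents > 2)) abort("cultivars may have at most two parents")
  ped$partial <- ped$n_parents < 2
  ped
}

#' Ancestor-inclined distribution of pedigreed cultivars
#'
#' A pedigreed cultivar shows ancestor-inclined distribution when it falls
#' in the same cluster as at least one of its known parents. The
#' ancestor-inclined distribution probability is the percentage of
#' pedigreed cultivars for which this holds; it is coarser-partition
#' monotone (merging clusters can only create matches) and reaches 100 on a
#' single-cluster partition. Parents absent from the partition drop out of
#' the cultivar's check; a cultivar with no parent present is excluded from
#' the denominator with a warning.
#'
#' `ancestor_matches()` returns the per-cultivar outcomes;
#' `ancestor_inclined_probability()` summarises them.
#'
#' @param ped a [pedigree_set()] tibble.
#' @param partition tibble `germplasm_id`, `cluster`.
#' @return `ancestor_matches()`: tibble `cultivar`, `cluster`,
#'   `parent_clusters` (list), `n_parents_present`, `matched`.
#'   `ancestor_inclined_probability()`: one-row tibble `probability`
#'   (percent, one decimal), `n_matched`, `n` (denominator),
#'   `n_excluded`.
#' @export
ancestor_matches <- function(ped, partition) {
  if (nrow(ped) == 0) abort("empty pedigree set")
  cl <- stats::setNames(partition$cluster, partition$germplasm_id)
  missing_cult <- setdiff(ped$cultivar, names(cl))
  if (length(missing_cult) > 0) {
    abort(sprintf("pedigree cultivar(s) absent from partition: %s",
                  paste(missing_cult, collapse = ", ")))
  }
  tibble::tibble(
    cultivar = ped$cultivar,
    cluster = unname(cl[ped$cultivar]),
    parent_clusters = lapply(ped$parents, function(p) unname(cl[intersect(p, names(cl))])),
    n_parents_present = vapply(ped$parents, function(p) sum(p %in% names(cl)), integer(1)),
    matched = purrr::map2_lgl(cluster, parent_clusters, function(c0, pc) {
      length(pc) > 0 && c0 %in% pc
    })
  )
}

#' @rdname ancestor_matches
#' @export
ancestor_inclined_probability <- function(ped, partition) {
  mm <- ancestor_matches(ped, partition)
  absent <- mm$n_parents_present == 0
  if (any(absent)) {
    warn(sprintf("cultivar(s) with no parent in partition excluded from denominator: %s",
                 paste(mm$cultivar[absent], collapse = ", ")))
  }
  mm <- mm[!absent, ]
  tibble::tibble(
    probability = round_half_up(100 * sum(mm$matched) / nrow(mm), 1),
    n_matched = sum(mm$matched), n = nrow(mm), n_excluded = sum(absent)
  )
}

#' Breeding frequency of parental species
#'
#' Every pedigreed cultivar contributes two parental slots; known parents
#' occupy one slot each and the remainder are tracked as unknown so that
#' frequencies stay comparable across partial pedigrees. Frequency is the
#' percentage of all slots a parent occupies, ranked decreasing.
#'
#' @param ped a [pedigree_set()] tibble.
#' @return tibble `parent` (including `"(unknown)"` when slots are
#'   unfilled), `slots`, `frequency` (percent, one decimal), sorted by
#'   decreasing frequency with the unknown row last.
#' @export
breeding_frequency <- function(ped) {
  if (nrow(ped) == 0) abort("empty pedigree set")
  total_slots <- 2L * nrow(ped)
  known <- table(unlist(ped$parents))
  out <- tibble::tibble(
    parent = names(known), slots = as.integer(known)
  )
  out <- out[order(-out$slots, out$parent), ]
  unknown <- total_slots - sum(out$slots)
  if (unknown > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(parent = "(unknown)",
                                                slots = as.integer(unknown)))
  }
  out$frequency <- round_half_up(100 * out$slots / total_slots, 1)
  out
}

#' Distribution of taxonomic sections across clusters
#'
#' For every section, the percentage of its species falling in each cluster
#' (rows over clusters sum to 100). Species without a section are excluded
#' with a warning; cultivars carry no section and never enter.
#'
#' @param partition tibble `germplasm_id`, `cluster`.
#' @param register `germplasm_register` with sections on species.
#' @return tibble `section`, `cluster`, `n`, `pct` (percent of the
#'   section's species in that cluster, one decimal), completed with zero
#'   rows for absent combinations.
#' @export
section_distribution <- function(partition, register) {
  species <- register[register$rank == "species", ]
  no_sect <- is.na(species$section)
  if (any(no_sect)) {
    warn(sprintf("species without section excluded: %s",
                 paste(species$id[no_sect], collapse = ", ")))
    species <- species[!no_sect, ]
  }
  df <- dplyr::inner_join(
    tibble::tibble(germplasm_id = species$id, section = species$section),
    partition, by = "germplasm_id"
  )
  df |>
    dplyr::count(.data$section, .data$cluster, name = "n") |>
    tidyr::complete(section, cluster = unique(partition$cluster),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$section) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
}

#' Merge clusters of a partition
#'
#' Relabels clusters under a supplied mapping (e.g. consolidating subgroups
#' into a major group); membership counts are conserved.
#'
#' @param partition tibble `germplasm_id`, `cluster`.
#' @param mapping named character vector, `old label -> new label`; must
#'   cover every label present.
#' @return the relabelled partition tibble.
#' @export
#' @examples
#' p <- data.frame(germplasm_id = c("a", "b"), cluster = c("A1", "A2"))
#' merge_clusters(p, c(A1 = "A", A2 = "A"))
merge_clusters <- function(partition, mapping) {
  missing <- setdiff(unique(partition$cluster), names(mapping))
  if (length(missing) > 0) {
    abort(sprintf("mapping misses cluster label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dplyr::mutate(partition, cluster = unname(mapping[.data$cluster]))
}

#' Correlation between section order and cluster order
#'
#' Tests whether an assumed evolutionary ordering of taxonomic sections
#' agrees with an assumed ordering of phenetic clusters. Every species
#' belonging to both a coded section and a coded cluster contributes one
#' (section code, cluster code) pair; the statistic is the Pearson
#' correlation of the pairs with the exact t-transform p-value
#' (`t = r sqrt((n-2)/(1-r^2))`, two-sided), as a single unadjusted test.
#'
#' @param partition tibble `germplasm_id`, `cluster` (cluster labels after
#'   any merging).
#' @param register `germplasm_register`.
#' @param cluster_codes named numeric vector, cluster label -> ordinal code.
#' @param section_codes named numeric vector, section name -> ordinal code.
#' @return one-row tibble `r`, `r_squared`, `p_value`, `n`,
#'   `n_excluded` (species in uncoded sections or clusters).
#' @export
order_correlation <- function(partition, register, cluster_codes, section_codes) {
  if (length(cluster_codes) == 0 || length(section_codes) == 0) {
    abort("both code maps must be nonempty")
  }
  species <- register[register$rank == "species" & !is.na(register$section), ]
  df <- dplyr::inner_join(
    tibble::tibble(germplasm_id = species$id, section = species$section),
    partition, by = "germplasm_id"
  )
  coded <- df$section %in% names(section_codes) & df$cluster %in% names(cluster_codes)
  x <- unname(section_codes[df$section[coded]])
  y <- unname(cluster_codes[df$cluster[coded]])
  if (length(x) < 3) abort("fewer than 3 coded species pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant code vector")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value, n = length(x), n_excluded = sum(!coded)
  )
}
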