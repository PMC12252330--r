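#' Pairwise germplasm distances
#'
#' Euclidean distances between germplasm rows of a (normally standardized)
#' trait matrix; ordinal-coded qualitative and standardized quantitative
#' traits enter identically. A Gower option is available for users who
#' prefer range-scaled mixed-type dissimilarities, but Euclidean is the
#' default used throughout the pipeline.
#'
#' @param m trait matrix tibble.
#' @param method `"euclidean"` (default) or `"gower"`.
#' @return a `stats::dist` object labelled by germplasm id.
#' @export
trait_distances <- function(m, method = c("euclidean", "gower")) {
  method <- match.arg(method)
  x <- as_numeric_matrix(m)
  if (anyNA(x)) abort("trait matrix contains missing values")
  if (method == "euclidean") dist(x) else cluster::daisy(x, metric = "gower")
}

#' Ward.D2 hierarchical clustering of germplasms
#'
#' Agglomerative clustering minimizing the increase in total within-cluster
#' sum of squares at each merge (Ward's criterion on squared Euclidean
#' distances, Lance-Williams updated). Merge heights are reported on the
#' distance scale -- `sqrt(2 * increase in within-cluster sum of squares)` --
#' so a merge of two singletons sits at their Euclidean distance; heights
#' are monotone nondecreasing from leaves to root.
#'
#' @param d a `dist` of Euclidean distances (see [trait_distances()]).
#' @return a `germplasm_dendro` object (an `hclust` with germplasm labels).
#' @export
cluster_germplasm <- function(d) {
  if (attr(d, "Size") < 2) abort("clustering needs at least two germplasms")
  hc <- hclust(d, method = "ward.D2")
  class(hc) <- c("germplasm_dendro", "hclust")
  hc
}

#' @export
tidy.germplasm_dendro <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    node_a = x$merge[, 1], node_b = x$merge[, 2],
    height = x$height,
    size = cluster_sizes(x)
  )
}

cluster_sizes <- function(hc) {
  sizes <- numeric(length(hc$height))
  for (i in seq_along(sizes)) {
    sizes[i] <- sum(vapply(hc$merge[i, ], function(n) {
      if (n < 0) 1 else sizes[n]
    }, numeric(1)))
  }
  as.integer(sizes)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts by cluster count rather than height: printed dendrogram heights
#' depend on the data and on linkage-height conventions, whereas counts are
#' reproducible across software. Clusters are numbered by first occurrence
#' in the input row order.
#'
#' @param hc a [cluster_germplasm()] dendrogram.
#' @param k number of clusters, `1 <= k <= n`.
#' @param labels optional label per cluster number (e.g.
#'   `c("A", "B")`); defaults to `"C1" ... "Ck"`.
#' @return a partition tibble: `germplasm_id`, `cluster` (character).
#' @export
cut_dendrogram <- function(hc, k, labels = NULL) {
  n <- length(hc$labels)
  if (k < 1 || k > n) abort(sprintf("k must lie in 1..%d", n))
  cl <- cutree(hc, k = k)
  labels <- labels %||% paste0("C", seq_len(k))
  if (length(labels) != k) abort("need exactly k cluster labels")
  tibble::tibble(germplasm_id = names(cl), cluster = labels[cl])
}

#' Per-cluster germplasm and trait summaries
#'
#' For each cluster: member counts split by rank, the mean and sample sd of
#' every quantitative trait, and the modal level of every qualitative trait
#' (smallest-code tie-break). Singleton clusters have no sample sd; it is
#' reported as 0 with `sd_defined = FALSE`.
#'
#' @param partition tibble `germplasm_id`, `cluster` (see
#'   [cut_dendrogram()]).
#' @param m germplasm-level trait matrix (raw scale, so means are
#'   interpretable).
#' @param cb trait codebook.
#' @param register `germplasm_register` for rank counts.
#' @return tibble with one row per cluster x trait, columns `cluster`,
#'   `n`, `n_species`, `n_cultivars`, `trait`, `kind`, `mean`, `sd`,
#'   `sd_defined`, `mode`.
#' @export
summarize_groups <- function(partition, m, cb, register) {
  check_columns(partition, c("germplasm_id", "cluster"), "partition")
  stopifnot(all(m$germplasm_id %in% partition$germplasm_id))
  kind_of <- stats::setNames(cb$kind, cb$trait)
  rank_of <- stats::setNames(register$rank, register$id)
  long <- m |>
    tidyr::pivot_longer(-"germplasm_id", names_to = "trait", values_to = "value") |>
    dplyr::inner_join(partition, by = "germplasm_id")
  long |>
    dplyr::group_by(.data$cluster, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_species = sum(rank_of[.data$germplasm_id] == "species"),
      n_cultivars = sum(rank_of[.data$germplasm_id] == "cultivar"),
      kind = kind_of[[.data$trait[1]]],
      mean = if (kind_of[[.data$trait[1]]] == "quantitative") mean(.data$value) else NA_real_,
      sd = if (n > 1 && kind_of[[.data$trait[1]]] == "quantitative") sd(.data$value) else 0,
      sd_defined = dplyr::n() > 1,
      mode = if (kind_of[[.data$trait[1]]] == "qualitative") mode_smallest(.data$value) else NA_real_,
      .groups = "drop"
    )
}

#' Species composition of each cluster
#'
#' For each cluster, the number of members, the species/cultivar split, the
#' within-cluster species percentage (`pct_species`) and the cluster's
#' share of all species in the collection (`pct_of_species`). Percentages
#' are rounded half-up to one decimal, the convention of the germplasm
#' literature.
#'
#' @param partition tibble `germplasm_id`, `cluster`.
#' @param register `germplasm_register`.
#' @return tibble, one row per cluster.
#' @export
species_proportions <- function(partition, register) {
  rank <- stats::setNames(register$rank, register$id)
  total_species <- sum(rank[partition$germplasm_id] == "species")
  partition |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_species = sum(rank[.data$germplasm_id] == "species"),
      n_cultivars = n - n_species,
      pct_species = round_half_up(100 * n_species / n, 1),
      pct_of_species = round_half_up(100 * n_species / total_species, 1),
      .groups = "drop"
    )
}

#' Export a dendrogram as Newick text
#'
#' Converts the merge tree to a phylogram (`ape::as.phylo`) with merge
#' heights as node depths and writes standard Newick.
#'
#' @param hc a [cluster_germplasm()] dendrogram.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_newick <- function(hc, path) {
  class(hc) <- "hclust"
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
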