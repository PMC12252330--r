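#' Pipeline configuration
#'
#' Collects every tunable of the four-stage analysis. Defaults are the
#' standard gates of the leaf-trait screening framework: diversity
#' `D >= 0.50`, `H >= 0.80`, `E >= 0.60`; variation `CVbar <= 10%`,
#' `CV >= 15%`; PCA eigenvalue `lambda >= 0.90` and absolute loading
#' `>= 0.60`; correlation conflict `|r| > 0.80`; cuts at `k = 2` (major
#' groups) and `k = 5` (subgroups).
#'
#' @param thresholds a [screening_thresholds()] list.
#' @param lambda_min,load_min,r_max reduction gates.
#' @param prefer ordered character vector of traits protected during
#'   correlation pruning.
#' @param k integer vector of cluster counts to cut at.
#' @param distance `"euclidean"` or `"gower"`.
#' @param merge_map optional named vector merging the labels of the last
#'   cut (for coarse ancestry summaries).
#' @param cluster_codes,section_codes optional ordinal code maps for
#'   [order_correlation()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = screening_thresholds(),
                            lambda_min = 0.90, load_min = 0.60, r_max = 0.80,
                            prefer = character(),
                            k = c(2L, 5L),
                            distance = "euclidean",
                            merge_map = NULL,
                            cluster_codes = NULL, section_codes = NULL) {
  if (lambda_min < 0 || load_min < 0 || r_max < 0) abort("gates must be nonnegative")
  structure(list(
    thresholds = thresholds, lambda_min = lambda_min, load_min = load_min,
    r_max = r_max, prefer = prefer, k = as.integer(k), distance = distance,
    merge_map = merge_map, cluster_codes = cluster_codes,
    section_codes = section_codes
  ), class = "pipeline_config")
}

#' Run the full screening-reduction-clustering-ancestry pipeline
#'
#' Executes the stages in their canonical order: stage-1 screening by
#' diversity and variation gates, standardization, PCA with eigenvalue and
#' loading gates, correlation pruning, Euclidean + Ward.D2 clustering with
#' the requested k-cuts, and -- when the register carries pedigrees --
#' ancestor-inclined statistics on every cut. The trait count is strictly
#' nonincreasing across the three reduction stages. Outputs are pure
#' functions of the inputs and configuration; when `out_dir` is given,
#' every intermediate table is written there as TSV (plus the dendrogram as
#' Newick).
#'
#' @param obs replicate-level observation tibble.
#' @param cb trait codebook.
#' @param register `germplasm_register`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a `pipeline_run` list: `screen`, `matrix` (aggregated),
#'   `pca`, `pca_retained` (traits), `prune`, `final_traits`,
#'   `dendrogram`, `partitions` (list by k), `group_summaries`,
#'   `species_proportions`, `ancestry` (list by k, or NULL), `report`
#'   (per-stage trait counts tibble), `config`.
#' @export
run_pipeline <- function(obs, cb, register, config = pipeline_config(),
                         out_dir = NULL) {
  obs <- validate_observations(obs, cb, register)
  screen <- screen_traits(obs, cb, config$thresholds)
  kept1 <- retained_traits(screen)
  if (length(kept1) < 2) abort("fewer than two traits survive stage-1 screening")

  m <- aggregate_observations(obs, cb)
  m1 <- m[c("germplasm_id", kept1)]
  mz <- standardize_traits(m1)

  pca <- pca_retain(mz, config$lambda_min)
  kept2 <- low_contribution_filter(pca, config$load_min)
  if (length(kept2) < 2) abort("fewer than two traits survive the PCA loading gate")

  prune <- correlation_prune(mz, traits = kept2, r_max = config$r_max,
                             prefer = config$prefer)
  kept3 <- prune$retained

  d <- trait_distances(mz[c("germplasm_id", kept3)], method = config$distance)
  hc <- cluster_germplasm(d)
  partitions <- lapply(config$k, function(k) cut_dendrogram(hc, k))
  names(partitions) <- paste0("k", config$k)

  summaries <- lapply(partitions, summarize_groups, m = m1[c("germplasm_id", kept3)],
                      cb = cb, register = register)
  props <- lapply(partitions, species_proportions, register = register)

  ped <- pedigree_set(register)
  ancestry <- NULL
  if (nrow(ped) > 0) {
    ancestry <- lapply(partitions, function(p) ancestor_inclined_probability(ped, p))
  }

  report <- tibble::tibble(
    stage = c("candidates", "after_screen", "after_pca", "after_prune"),
    n_traits = c(nrow(cb), length(kept1), length(kept2), length(kept3))
  )
  stopifnot(!is.unsorted(rev(report$n_traits)))

  run <- list(
    screen = screen, matrix = m, pca = pca, pca_retained = kept2,
    prune = prune, final_traits = kept3, dendrogram = hc,
    partitions = partitions, group_summaries = summaries,
    species_proportions = props, ancestry = ancestry,
    report = report, config = config
  )
  class(run) <- "pipeline_run"
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Leaf-trait numerical taxonomy pipeline\n")
  cat(sprintf("  traits: %s\n",
              paste(sprintf("%s=%d", x$report$stage, x$report$n_traits),
                    collapse = " -> ")))
  cat(sprintf("  cuts: %s\n", paste(names(x$partitions), collapse = ", ")))
  if (!is.null(x$ancestry)) {
    for (k in names(x$ancestry)) {
      cat(sprintf("  ancestor-inclined probability (%s): %.1f%% (n=%d)\n",
                  k, x$ancestry[[k]]$probability, x$ancestry[[k]]$n))
    }
  }
  invisible(x)
}

#' @export
glance.pipeline_run <- function(x, ...) {
  tibble::tibble(
    n_germplasms = nrow(x$matrix),
    n_candidates = x$report$n_traits[1],
    n_after_screen = x$report$n_traits[2],
    n_after_pca = x$report$n_traits[3],
    n_final = x$report$n_traits[4],
    k_cuts = paste(sub("^k", "", names(x$partitions)), collapse = ",")
  )
}

write_pipeline_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$screen, file.path(dir, "screen.tsv"), progress = FALSE)
  write_trait_matrix(run$matrix, file.path(dir, "trait_matrix.tsv"))
  readr::write_tsv(tidy(run$pca), file.path(dir, "pca_loadings.tsv"), progress = FALSE)
  readr::write_tsv(run$prune$pairs, file.path(dir, "prune_pairs.tsv"), progress = FALSE)
  writeLines(run$final_traits, file.path(dir, "final_traits.txt"))
  readr::write_tsv(tidy(run$dendrogram), file.path(dir, "merges.tsv"), progress = FALSE)
  write_newick(run$dendrogram, file.path(dir, "dendrogram.nwk"))
  for (k in names(run$partitions)) {
    readr::write_tsv(run$partitions[[k]], file.path(dir, paste0("partition_", k, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(run$species_proportions[[k]],
                     file.path(dir, paste0("species_proportions_", k, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(run$report, file.path(dir, "report.tsv"), progress = FALSE)
  invisible(dir)
}
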