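# Small in-code fixtures shared across test files.

tiny_codebook <- function() {
  as_codebook(tibble::tibble(
    trait = c("Leaf texture", "Young leaf color", "Leaf length"),
    kind = c("qualitative", "qualitative", "quantitative"),
    levels = c("Papery:0;Leathery:1",
               "Green:0;Yellow-green:1;Brown-red:2;Purple-red:3",
               NA),
    units = c(NA, NA, "cm")
  ))
}

tiny_observations <- function() {
  grid <- expand.grid(germplasm_id = c("g1", "g2", "g3", "g4"),
                      replicate_id = 1:3, stringsAsFactors = FALSE)
  vals <- list(
    "Leaf texture" = c(0, 0, 1, 1),
    "Young leaf color" = c(0, 1, 2, 3),
    "Leaf length" = c(5, 6, 7, 8)
  )
  dplyr::bind_rows(lapply(names(vals), function(tr) {
    tibble::tibble(
      germplasm_id = grid$germplasm_id, replicate_id = grid$replicate_id,
      trait = tr,
      value = vals[[tr]][match(grid$germplasm_id, c("g1", "g2", "g3", "g4"))]
    )
  }))
}

# Register/partition pair matching the printed five-subgroup composition of
# the worked examples: sizes 22/10/21/7/13 with 6/2/11/3/12 species.
subgroup_fixture <- function() {
  comp <- tibble::tibble(
    cluster = c("A1", "A2", "A3", "B1", "B2"),
    n = c(22L, 10L, 21L, 7L, 13L),
    n_species = c(6L, 2L, 11L, 3L, 12L)
  )
  rows <- purrr::pmap_dfr(comp, function(cluster, n, n_species) {
    tibble::tibble(
      germplasm_id = sprintf("%s_m%02d", cluster, seq_len(n)),
      cluster = cluster,
      rank = rep(c("species", "cultivar"), c(n_species, n - n_species))
    )
  })
  register <- as_register(tibble::tibble(id = rows$germplasm_id, rank = rows$rank))
  list(partition = rows[c("germplasm_id", "cluster")], register = register)
}

# Exhaustive Ward oracle: at each step merge the pair of clusters whose
# union minimally increases the total within-cluster sum of squares.
# Heights on the distance scale, sqrt(2 * ESS increase). Independent of the
# Lance-Williams route used by the implementation.
ward_oracle <- function(x) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    sub <- x[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || inc < best$inc - 1e-12) {
          best <- list(i = i, j = j, inc = inc)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best$i]], clusters[[best$j]])),
      height = sqrt(2 * best$inc)
    )
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# Member sets per merge step of an hclust, for comparison with the oracle.
hclust_member_sets <- function(hc) {
  sets <- vector("list", length(hc$height))
  for (i in seq_along(sets)) {
    sets[[i]] <- sort(unlist(lapply(hc$merge[i, ], function(n) {
      if (n < 0) -n else sets[[n]]
    })))
  }
  sets
}

# Pair-enumeration oracle for Simpson diversity: fraction of unordered
# pairs of individuals carrying different levels.
simpson_oracle <- function(counts) {
  lv <- rep(seq_along(counts), counts)
  pairs <- utils::combn(length(lv), 2)
  mean(lv[pairs[1, ]] != lv[pairs[2, ]])
}

# All partitions of n into unordered positive parts (level-count vectors).
count_vectors <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in count_vectors(n - p, p)) out[[length(out) + 1]] <- c(p, rest)
  }
  out
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Drop trait columns with zero variance (the stage-1 screen would discard
# them; direct clustering tests bypass the screen).
drop_constant <- function(m) {
  keep <- names(which(vapply(m[-1], stats::sd, numeric(1)) > 0))
  m[c("germplasm_id", keep)]
}
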