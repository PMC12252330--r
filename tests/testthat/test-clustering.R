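test_that("euclidean distances satisfy metric identities", {
  m <- tibble::tibble(germplasm_id = c("a", "b", "c"),
                      x = c(0, 3, 0), y = c(0, 4, 0))
  d <- as.matrix(trait_distances(m))
  expect_equal(d["a", "b"], 5)        # 3-4-5 triangle
  expect_equal(d["a", "c"], 0)        # identical rows
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
})

test_that("ward clustering reports singleton merges at their euclidean distance", {
  m <- tibble::tibble(germplasm_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  hc <- cluster_germplasm(trait_distances(m))
  expect_equal(hc$height, 5)

  m3 <- tibble::tibble(germplasm_id = c("a", "b", "c"), x = c(0, 0.1, 10))
  hc3 <- cluster_germplasm(trait_distances(m3))
  first <- sort(hc3$labels[-hc3$merge[1, ]])
  expect_equal(first, c("a", "b"))  # nearest pair merges first
})

test_that("merge sequence equals the exhaustive minimal-ESS-increase oracle", {
  set.seed(19)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    m <- dplyr::bind_cols(tibble::tibble(germplasm_id = paste0("g", 1:n)),
                          tibble::as_tibble(as.data.frame(x)))
    hc <- cluster_germplasm(trait_distances(m))
    oracle <- ward_oracle(x)
    sets <- hclust_member_sets(hc)
    for (s in seq_len(n - 1)) {
      expect_equal(sets[[s]], oracle[[s]]$members)
      expect_equal(hc$height[s], oracle[[s]]$height, tolerance = 1e-8)
    }
    expect_false(is.unsorted(hc$height))  # Ward monotonicity
  }
})

test_that("clustering is invariant to row permutation up to cluster relabeling", {
  sim <- simulate_population(sim_config(n_species = 12, n_cultivars = 6,
                                        n_groups = 3, n_qualitative = 8,
                                        n_quantitative = 4, replicates = 3,
                                        seed = 23))
  m <- standardize_traits(drop_constant(aggregate_observations(sim$observations, sim$codebook)))
  p1 <- cut_dendrogram(cluster_germplasm(trait_distances(m)), 3)
  set.seed(1)
  mp <- m[sample.int(nrow(m)), ]
  p2 <- cut_dendrogram(cluster_germplasm(trait_distances(mp)), 3)
  joined <- dplyr::inner_join(p1, p2, by = "germplasm_id")
  expect_equal(adjusted_rand(joined$cluster.x, joined$cluster.y), 1)
})

test_that("cutting by k spans singletons to one cluster and respects topology", {
  set.seed(6)
  m <- dplyr::bind_cols(tibble::tibble(germplasm_id = paste0("g", 1:9)),
                        tibble::as_tibble(as.data.frame(matrix(rnorm(27), 9))))
  hc <- cluster_germplasm(trait_distances(m))
  expect_equal(dplyr::n_distinct(cut_dendrogram(hc, 9)$cluster), 9)
  expect_equal(dplyr::n_distinct(cut_dendrogram(hc, 1)$cluster), 1)
  expect_error(cut_dendrogram(hc, 0), "k must lie")
  expect_error(cut_dendrogram(hc, 10), "k must lie")
  # nested cuts: a k=2 cluster is a union of k=4 clusters
  p2 <- cut_dendrogram(hc, 2); p4 <- cut_dendrogram(hc, 4)
  tab <- table(p4$cluster, p2$cluster[match(p4$germplasm_id, p2$germplasm_id)])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("two separated synthetic blobs are recovered exactly at k = 2", {
  sim <- simulate_population(sim_config(
    n_species = 14, n_cultivars = 0, n_groups = 2, n_qualitative = 10,
    n_quantitative = 4, group_concentration = 1, group_separation = 0.8,
    species_jitter_cv = 1, within_cv = 1, level_flip_prob = 0,
    replicates = 4, seed = 31
  ))
  m <- standardize_traits(drop_constant(aggregate_observations(sim$observations, sim$codebook)))
  p <- cut_dendrogram(cluster_germplasm(trait_distances(m)), 2)
  truth <- sim$truth$group[match(p$germplasm_id, sim$truth$germplasm_id)]
  expect_equal(adjusted_rand(p$cluster, truth), 1)
})

test_that("average recovery degrades when group separation shrinks", {
  ari_at <- function(conc, sep, seed) {
    sim <- simulate_population(sim_config(
      n_species = 16, n_cultivars = 0, n_groups = 2, n_qualitative = 8,
      n_quantitative = 4, group_concentration = conc, group_separation = sep,
      species_jitter_cv = 8, within_cv = 5, level_flip_prob = 0.1,
      replicates = 3, seed = seed
    ))
    m <- aggregate_observations(sim$observations, sim$codebook)
    keep <- names(which(vapply(m[-1], sd, numeric(1)) > 0))
    m <- standardize_traits(m[c("germplasm_id", keep)])
    p <- cut_dendrogram(cluster_germplasm(trait_distances(m)), 2)
    truth <- sim$truth$group[match(p$germplasm_id, sim$truth$germplasm_id)]
    adjusted_rand(p$cluster, truth)
  }
  seeds <- 1:6
  high <- mean(vapply(seeds, function(s) ari_at(0.95, 0.8, s), numeric(1)))
  low <- mean(vapply(seeds, function(s) ari_at(0.15, 0.02, s), numeric(1)))
  expect_gt(high, low)
})

test_that("group summaries report counts, means and modal levels per cluster", {
  cb <- tiny_codebook()
  obs <- tiny_observations()
  m <- aggregate_observations(obs, cb)
  reg <- as_register(tibble::tibble(
    id = paste0("g", 1:4), rank = c("species", "species", "cultivar", "cultivar")
  ))
  one <- tibble::tibble(germplasm_id = paste0("g", 1:4), cluster = "all")
  gs <- summarize_groups(one, m, cb, reg)
  ll <- gs[gs$trait == "Leaf length", ]
  expect_equal(ll$mean, mean(c(5, 6, 7, 8)))   # whole-sample mean
  expect_equal(ll$n_species, 2); expect_equal(ll$n_cultivars, 2)

  solo <- tibble::tibble(germplasm_id = paste0("g", 1:4),
                         cluster = c("s", "r", "r", "r"))
  gsolo <- summarize_groups(solo, m, cb, reg)
  lone <- gsolo[gsolo$cluster == "s" & gsolo$trait == "Leaf length", ]
  expect_equal(lone$sd, 0)            # singleton: sd undefined, flagged
  expect_false(lone$sd_defined)
  tex <- gsolo[gsolo$cluster == "r" & gsolo$trait == "Leaf texture", ]
  expect_equal(tex$mode, 1)           # modal level of g2..g4 = 1
})

test_that("per-group means recover the generator's group means", {
  sim <- simulate_population(sim_config(
    n_species = 20, n_cultivars = 0, n_groups = 2, n_qualitative = 4,
    n_quantitative = 4, group_concentration = 1, group_separation = 0.6,
    species_jitter_cv = 2, within_cv = 2, level_flip_prob = 0,
    replicates = 10, seed = 37
  ))
  m <- aggregate_observations(sim$observations, sim$codebook)
  part <- tibble::tibble(germplasm_id = sim$truth$germplasm_id,
                         cluster = as.character(sim$truth$group))
  gs <- summarize_groups(part, m, sim$codebook, sim$register)
  # within each true group, germplasm values of a quantitative trait spread
  # only by the small jitter+noise, so group mean ~ every member's value
  quant <- gs[gs$kind == "quantitative", ]
  for (i in seq_len(nrow(quant))) {
    members <- part$germplasm_id[part$cluster == quant$cluster[i]]
    vals <- m[[quant$trait[i]]][match(members, m$germplasm_id)]
    expect_lt(abs(mean(vals) - quant$mean[i]), 1e-9)
    expect_lt(sd(vals) / mean(vals), 0.12)
  }
})

test_that("species proportions match hand counts and aggregate to the global share", {
  fx <- subgroup_fixture()
  sp <- species_proportions(fx$partition, fx$register)
  expect_equal(sp$pct_species[sp$cluster == "B2"], 92.3)
  expect_equal(sp$pct_species[sp$cluster == "A1"], 27.3)
  lone <- tibble::tibble(germplasm_id = fx$partition$germplasm_id[1:3],
                         cluster = "only")
  reg0 <- as_register(tibble::tibble(id = lone$germplasm_id, rank = "cultivar"))
  expect_equal(species_proportions(lone, reg0)$pct_species, 0)

  # size-weighted within-cluster fractions reproduce the global fraction
  global <- sum(sp$n_species) / sum(sp$n)
  expect_equal(sum(sp$n * sp$n_species / sp$n) / sum(sp$n), global)
  expect_equal(sum(sp$pct_of_species), 100, tolerance = 0.2)
})

test_that("newick export preserves leaves and heights", {
  set.seed(41)
  m <- dplyr::bind_cols(tibble::tibble(germplasm_id = paste0("tip", 1:6)),
                        tibble::as_tibble(as.data.frame(matrix(rnorm(18), 6))))
  hc <- cluster_germplasm(trait_distances(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("tip", 1:6))
  # root depth equals half the top merge height (as.phylo convention)
  expect_equal(max(ape::node.depth.edgelength(tree)), max(hc$height) / 2,
               tolerance = 1e-6)
})
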