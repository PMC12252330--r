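#' Configure a synthetic germplasm simulation
#'
#' The generator emulates the structure a leaf-macrostructure survey of a
#' woody germplasm repository produces: a set of species falling into a few
#' latent phenetic groups ("intraspecific uniformity, interspecific
#' distinctness"), a set of cultivars bred from those species whose traits
#' follow one donor parent with a tunable fidelity, and replicate leaves per
#' germplasm carrying measurement/plasticity noise. Defaults mirror a
#' collection of 34 species and 39 cultivars scored for 39 qualitative and
#' 11 quantitative candidate traits on 30 leaves each.
#'
#' @param n_species,n_cultivars accession counts.
#' @param n_groups latent phenetic groups among species.
#' @param n_qualitative,n_quantitative candidate trait counts.
#' @param qual_levels levels per qualitative trait (recycled).
#' @param group_concentration in `[0, 1]`: probability mass concentrated on
#'   a group's preferred level of each qualitative trait (0 = uniform,
#'   1 = deterministic). Controls group separation for qualitative traits.
#' @param group_separation relative spread of group means for quantitative
#'   traits (sd of the per-group multiplicative offset).
#' @param species_jitter_cv percent CV of species values around their group
#'   mean (keeps con-group species distinct but similar).
#' @param within_cv target within-germplasm replicate CV, percent.
#' @param level_flip_prob probability a qualitative replicate is mis-scored
#'   to a uniformly random level.
#' @param inheritance_fidelity probability a cultivar trait is copied from
#'   its donor parent rather than drawn from the pooled species distribution.
#' @param two_parent_prob probability a cultivar has two known parents.
#' @param replicates replicate leaves per germplasm.
#' @param seed integer seed governing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 34, n_cultivars = 39, n_groups = 5,
                       n_qualitative = 39, n_quantitative = 11,
                       qual_levels = c(2L, 3L, 4L, 5L),
                       group_concentration = 0.8,
                       group_separation = 0.25,
                       species_jitter_cv = 3,
                       within_cv = 8,
                       level_flip_prob = 0.05,
                       inheritance_fidelity = 0.9,
                       two_parent_prob = 0.8,
                       replicates = 30,
                       seed = 1L) {
  cfg <- list(
    n_species = n_species, n_cultivars = n_cultivars, n_groups = n_groups,
    n_qualitative = n_qualitative, n_quantitative = n_quantitative,
    qual_levels = as.integer(qual_levels),
    group_concentration = group_concentration,
    group_separation = group_separation,
    species_jitter_cv = species_jitter_cv,
    within_cv = within_cv, level_flip_prob = level_flip_prob,
    inheritance_fidelity = inheritance_fidelity,
    two_parent_prob = two_parent_prob,
    replicates = replicates, seed = as.integer(seed)
  )
  if (cfg$n_groups < 1) abort("need at least one group")
  if (cfg$n_species < cfg$n_groups) abort("need at least one species per group")
  if (cfg$n_species == 0 && cfg$n_cultivars > 0) {
    abort("cultivars require at least one species")
  }
  if (cfg$inheritance_fidelity < 0 || cfg$inheritance_fidelity > 1) {
    abort("inheritance_fidelity must lie in [0, 1]")
  }
  if (cfg$within_cv < 0 || cfg$species_jitter_cv < 0) abort("CV targets must be >= 0")
  if (cfg$group_concentration < 0 || cfg$group_concentration > 1) {
    abort("group_concentration must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic germplasm dataset with known truth
#'
#' Species are assigned round-robin to latent groups; each group owns a
#' preferred level per qualitative trait and a mean per quantitative trait.
#' Species draw trait values from their group's distributions. Each cultivar
#' picks one donor parent (uniformly among its 1-2 parents) and copies each
#' germplasm-level trait value from the donor with probability
#' `inheritance_fidelity`, otherwise drawing from the pooled species
#' distribution. Replicate leaves add multiplicative Gaussian noise at the
#' within-germplasm CV target for quantitative traits (draws clipped at a
#' small positive floor) and uniform level flips for qualitative traits.
#' Identical configuration implies identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `register`, `codebook`, `observations`
#'   (replicate-level tibble) and `truth` (tibble of germplasm, latent group,
#'   donor parent; plus the config as attribute `config`).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  q_names <- sprintf("qual_%02d", seq_len(cfg$n_qualitative))
  z_names <- sprintf("quant_%02d", seq_len(cfg$n_quantitative))
  ks <- rep_len(cfg$qual_levels, cfg$n_qualitative)

  cb <- as_codebook(tibble::tibble(
    trait = c(q_names, z_names),
    kind = rep(c("qualitative", "quantitative"),
               c(cfg$n_qualitative, cfg$n_quantitative)),
    levels = c(lapply(ks, function(k) {
      tibble::tibble(label = paste0("L", seq_len(k) - 1L), code = seq_len(k) - 1L)
    }), vector("list", cfg$n_quantitative)),
    units = rep(c(NA_character_, "cm"), c(cfg$n_qualitative, cfg$n_quantitative))
  ))

  sp_ids <- sprintf("SP%02d", seq_len(cfg$n_species))
  cv_ids <- if (cfg$n_cultivars > 0) sprintf("CV%02d", seq_len(cfg$n_cultivars)) else character(0)
  sp_group <- rep_len(seq_len(cfg$n_groups), cfg$n_species)

  # group-level generative parameters
  pref_level <- matrix(
    vapply(rep(ks, each = cfg$n_groups), function(k) sample.int(k, 1) - 1L, integer(1)),
    nrow = cfg$n_groups
  )  # groups x qualitative traits
  level_prob <- function(g, j) {
    k <- ks[j]
    p <- rep((1 - cfg$group_concentration) / k, k)
    p[pref_level[g, j] + 1L] <- p[pref_level[g, j] + 1L] + cfg$group_concentration
    p
  }
  base_mean <- runif(cfg$n_quantitative, 5, 50)
  group_mean <- outer(rep(1, cfg$n_groups), base_mean) *
    (1 + cfg$group_separation * matrix(rnorm(cfg$n_groups * cfg$n_quantitative),
                                       cfg$n_groups))
  group_mean <- pmax(group_mean, 0.05 * outer(rep(1, cfg$n_groups), base_mean))

  # germplasm-level latent values: species rows first
  qual_val <- matrix(0L, cfg$n_species + cfg$n_cultivars, cfg$n_qualitative)
  quant_val <- matrix(0, cfg$n_species + cfg$n_cultivars, cfg$n_quantitative)
  for (i in seq_len(cfg$n_species)) {
    g <- sp_group[i]
    for (j in seq_len(cfg$n_qualitative)) {
      qual_val[i, j] <- sample.int(ks[j], 1, prob = level_prob(g, j)) - 1L
    }
    quant_val[i, ] <- group_mean[g, ] *
      (1 + (cfg$species_jitter_cv / 100) * rnorm(cfg$n_quantitative))
  }

  # pooled species distributions for non-inherited cultivar draws
  pooled_draw_qual <- function(j) qual_val[sample.int(cfg$n_species, 1), j]
  pooled_mean <- colMeans(quant_val[seq_len(cfg$n_species), , drop = FALSE])
  pooled_sd <- apply(quant_val[seq_len(cfg$n_species), , drop = FALSE], 2, sd)

  parents <- vector("list", cfg$n_cultivars)
  donor <- integer(cfg$n_cultivars)
  for (c in seq_len(cfg$n_cultivars)) {
    np <- if (runif(1) < cfg$two_parent_prob && cfg$n_species >= 2) 2L else 1L
    par_idx <- sample.int(cfg$n_species, np)
    parents[[c]] <- sp_ids[par_idx]
    donor[c] <- par_idx[sample.int(np, 1)]
    row <- cfg$n_species + c
    for (j in seq_len(cfg$n_qualitative)) {
      qual_val[row, j] <- if (runif(1) < cfg$inheritance_fidelity) {
        qual_val[donor[c], j]
      } else pooled_draw_qual(j)
    }
    for (j in seq_len(cfg$n_quantitative)) {
      quant_val[row, j] <- if (runif(1) < cfg$inheritance_fidelity) {
        quant_val[donor[c], j]
      } else pooled_mean[j] + pooled_sd[j] * rnorm(1)
    }
  }
  quant_val <- pmax(quant_val, 1e-6)

  reg <- as_register(tibble::tibble(
    id = c(sp_ids, cv_ids),
    rank = rep(c("species", "cultivar"), c(cfg$n_species, cfg$n_cultivars)),
    section = c(paste0("Sect", sp_group), rep(NA_character_, cfg$n_cultivars)),
    parents = c(vector("list", cfg$n_species), parents)
  ))

  # replicate leaves
  ids <- c(sp_ids, cv_ids)
  n_g <- length(ids)
  R <- cfg$replicates
  qual_obs <- lapply(seq_len(cfg$n_qualitative), function(j) {
    base <- rep(qual_val[, j], each = R)
    flip <- runif(n_g * R) < cfg$level_flip_prob
    base[flip] <- sample.int(ks[j], sum(flip), replace = TRUE) - 1L
    base
  })
  quant_obs <- lapply(seq_len(cfg$n_quantitative), function(j) {
    base <- rep(quant_val[, j], each = R)
    pmax(base * (1 + (cfg$within_cv / 100) * rnorm(n_g * R)), 1e-6)
  })
  obs <- tibble::tibble(
    germplasm_id = rep(rep(ids, each = R), cfg$n_qualitative + cfg$n_quantitative),
    replicate_id = rep(rep(seq_len(R), n_g), cfg$n_qualitative + cfg$n_quantitative),
    trait = rep(c(q_names, z_names), each = n_g * R),
    value = c(unlist(qual_obs), unlist(quant_obs))
  )

  truth <- tibble::tibble(
    germplasm_id = ids,
    rank = rep(c("species", "cultivar"), c(cfg$n_species, cfg$n_cultivars)),
    group = c(sp_group, sp_group[donor]),
    donor = c(rep(NA_character_, cfg$n_species), sp_ids[donor])
  )
  attr(truth, "config") <- cfg

  list(register = reg, codebook = cb, observations = obs, truth = truth)
}

#' Perfectly uniform qualitative trait column
#'
#' A deterministic fixture for index tests: `n` observations spread exactly
#' evenly over `k` levels.
#'
#' @param n observation count; must be a multiple of `k`.
#' @param k level count.
#' @return integer vector of codes `0..k-1`, each occurring `n/k` times.
#' @export
#' @examples
#' table(generate_uniform_trait(8, 4))
generate_uniform_trait <- function(n, k) {
  if (k > n) abort("k must not exceed n")
  if (n %% k != 0) abort("k must divide n")
  rep(seq_len(k) - 1L, each = n %/% k)
}

#' Write the four simulation artifacts to a directory
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_register(sim$register, file.path(dir, "register.tsv"))
  write_codebook(sim$codebook, file.path(dir, "codebook.tsv"))
  write_observations(sim$observations, file.path(dir, "observations.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
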