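make_ped <- function(parents) {
  tibble::tibble(
    cultivar = paste0("c", seq_along(parents)),
    parents = lapply(parents, as.character),
    n_parents = vapply(parents, length, integer(1)),
    partial = vapply(parents, length, integer(1)) < 2
  )
}

test_that("ancestor-inclined probability counts co-clustered cultivars once", {
  part <- tibble::tibble(
    germplasm_id = c("p1", "p2", "c1", "c2", "c3", "c4"),
    cluster = c("A", "B", "A", "A", "B", "B")
  )
  ped <- make_ped(list("p1", c("p1", "p2"), "p2", "p2"))
  res <- ancestor_inclined_probability(ped, part)
  expect_equal(res$probability, 100)
  expect_equal(res$n, 4)

  # 9 of 10 matched -> 90.0%
  part10 <- tibble::tibble(
    germplasm_id = c("p", "q", paste0("c", 1:10)),
    cluster = c("A", "B", rep("A", 9), "B")
  )
  ped10 <- make_ped(rep(list("p"), 10))
  expect_equal(ancestor_inclined_probability(ped10, part10)$probability, 90)

  # a cultivar matching through either of two parents still counts once
  both <- make_ped(list(c("p1", "p2")))
  both$cultivar <- "c1"
  expect_equal(ancestor_inclined_probability(both, part)$n_matched, 1)
})

test_that("parents absent from the partition drop out; orphan cultivars leave the denominator", {
  part <- tibble::tibble(germplasm_id = c("p1", "c1", "c2"),
                         cluster = c("A", "A", "B"))
  ped <- make_ped(list(c("p1", "ghost"), "ghost"))
  ped$cultivar <- c("c1", "c2")
  expect_warning(res <- ancestor_inclined_probability(ped, part),
                 "no parent in partition")
  expect_equal(res$n, 1)          # c2 excluded
  expect_equal(res$n_excluded, 1)
  expect_equal(res$probability, 100)
  expect_error(ancestor_inclined_probability(ped[0, ], part), "empty")
})

test_that("probability is monotone under cluster merging and 100 on one cluster", {
  set.seed(27)
  for (i in 1:10) {
    n_par <- 6; n_c <- 12
    part <- tibble::tibble(
      germplasm_id = c(paste0("p", 1:n_par), paste0("c", 1:n_c)),
      cluster = sample(c("A1", "A2", "B1", "B2"), n_par + n_c, replace = TRUE)
    )
    ped <- make_ped(replicate(n_c, paste0("p", sample.int(n_par, sample(1:2, 1))),
                              simplify = FALSE))
    fine <- ancestor_inclined_probability(ped, part)$probability
    merged <- merge_clusters(part, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
    coarse <- ancestor_inclined_probability(ped, merged)$probability
    expect_gte(coarse, fine)
    one <- dplyr::mutate(part, cluster = "all")
    expect_equal(ancestor_inclined_probability(ped, one)$probability, 100)
  }
})

test_that("random assignment over c equal clusters matches the 1/c chance level", {
  set.seed(33)
  c_clusters <- 4
  hits <- replicate(600, {
    part <- tibble::tibble(
      germplasm_id = c("p", "c1"),
      cluster = c("K1", paste0("K", sample.int(c_clusters, 1)))
    )
    ancestor_inclined_probability(make_ped(list("p")), part)$probability
  })
  expect_lt(abs(mean(hits) - 100 / c_clusters), 5)  # MC tolerance
})

test_that("breeding frequency allocates two slots per cultivar with unknowns tracked", {
  ped <- make_ped(list(c("X", "Y"), c("X", "Z")))
  bf <- breeding_frequency(ped)
  expect_equal(bf$frequency[bf$parent == "X"], 50)
  expect_equal(bf$frequency[bf$parent == "Y"], 25)
  expect_equal(bf$frequency[bf$parent == "Z"], 25)
  expect_equal(sum(bf$frequency), 100)

  selfed <- make_ped(list(c("X", "X")))
  expect_equal(breeding_frequency(selfed)$frequency, 100)

  partial <- make_ped(list("X", c("Y", "Z"), "Y"))
  bfp <- breeding_frequency(partial)          # 6 slots, 2 unknown
  expect_equal(bfp$frequency[bfp$parent == "(unknown)"],
               round(100 * 2 / 6, 1))
  expect_equal(sum(bfp$frequency), 100, tolerance = 0.2)
  # a parent filling 7 of 20 slots sits at 35%
  twenty <- make_ped(c(replicate(3, c("T", "T"), simplify = FALSE),
                       list(c("T", "H")),
                       replicate(6, c("A", "B"), simplify = FALSE)))
  expect_equal(breeding_frequency(twenty)$frequency[1], 35)
})

test_that("section distribution rows sum to 100 and capture exclusivity and even splits", {
  reg <- as_register(tibble::tibble(
    id = paste0("s", 1:8), rank = "species",
    section = c("Doc", "Doc", "Yun", "Yun", "Mal", "Mal", "Mal", "Mal")
  ))
  part <- tibble::tibble(
    germplasm_id = paste0("s", 1:8),
    cluster = c("B1", "B1", "A3", "B2", "A1", "A1", "B1", "B2")
  )
  sd_tab <- section_distribution(part, reg)
  doc <- sd_tab[sd_tab$section == "Doc", ]
  expect_equal(doc$pct[doc$cluster == "B1"], 100)  # exclusive
  expect_true(all(doc$pct[doc$cluster != "B1"] == 0))
  yun <- sd_tab[sd_tab$section == "Yun", ]
  expect_setequal(yun$pct[yun$pct > 0], c(50, 50))  # even 1/1 split
  sums <- tapply(sd_tab$pct, sd_tab$section, sum)
  expect_true(all(abs(sums - 100) < 0.2))

  reg2 <- as_register(tibble::tibble(
    id = c("s1", "s2"), rank = "species", section = c("Doc", NA)
  ))
  part2 <- tibble::tibble(germplasm_id = c("s1", "s2"), cluster = "A")
  expect_warning(section_distribution(part2, reg2), "without section")
})

test_that("merging clusters relabels without changing membership", {
  p <- tibble::tibble(germplasm_id = paste0("g", 1:5),
                      cluster = c("A1", "A2", "A3", "B1", "B2"))
  ident <- merge_clusters(p, stats::setNames(unique(p$cluster), unique(p$cluster)))
  expect_equal(ident, p)
  merged <- merge_clusters(p, c(A1 = "A", A2 = "A", A3 = "A",
                                B1 = "B1", B2 = "B2"))
  expect_equal(dplyr::n_distinct(merged$cluster), 3)
  expect_equal(nrow(merged), nrow(p))  # counts conserved
  expect_error(merge_clusters(p, c(A1 = "A")), "misses")
})

test_that("order correlation reproduces closed-form r on coded species pairs", {
  reg <- as_register(tibble::tibble(
    id = paste0("s", 1:3), rank = "species", section = c("S1", "S2", "S3")
  ))
  codes_s <- c(S1 = 1, S2 = 2, S3 = 3)

  concord <- tibble::tibble(germplasm_id = paste0("s", 1:3),
                            cluster = c("C1", "C2", "C3"))
  res <- order_correlation(concord, reg, c(C1 = 1, C2 = 2, C3 = 3), codes_s)
  expect_equal(res$r, 1); expect_equal(res$r_squared, 1)

  res_rev <- order_correlation(concord, reg, c(C1 = 3, C2 = 2, C3 = 1), codes_s)
  expect_equal(res_rev$r, -1); expect_equal(res_rev$r_squared, 1)

  zig <- tibble::tibble(germplasm_id = paste0("s", 1:3),
                        cluster = c("C1", "C2", "C1"))
  res0 <- order_correlation(zig, reg, c(C1 = 1, C2 = 2), codes_s)
  expect_equal(res0$r, 0); expect_equal(res0$r_squared, 0)
  expect_equal(res0$n, 3)

  # species in uncoded sections are excluded and counted
  reg4 <- as_register(tibble::tibble(
    id = paste0("s", 1:4), rank = "species",
    section = c("S1", "S2", "S3", "Sx")
  ))
  zig4 <- tibble::tibble(germplasm_id = paste0("s", 1:4),
                         cluster = c("C1", "C2", "C1", "C2"))
  resx <- order_correlation(zig4, reg4, c(C1 = 1, C2 = 2), codes_s)
  expect_equal(resx$n, 3)
  expect_equal(resx$n_excluded, 1)

  expect_error(order_correlation(zig, reg, c(C1 = 1, C2 = 2), c(S1 = 1, S2 = 2)),
               "fewer than 3")
  same <- tibble::tibble(germplasm_id = paste0("s", 1:3), cluster = "C1")
  expect_error(order_correlation(same, reg, c(C1 = 1), codes_s), "constant")
})
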