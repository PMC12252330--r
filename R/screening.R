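#' Diversity indices for qualitative traits
#'
#' Stage-1 screening scores each qualitative trait across germplasms with
#' three indices of level diversity:
#' \describe{
#'   \item{Simpson's diversity}{`D = 1 - sum(ni (ni - 1)) / (n (n - 1))`,
#'     the unbiased probability that two distinct germplasms carry different
#'     levels of the trait.}
#'   \item{Shannon-Wiener information}{`H = -sum((ni/n) log(ni/n))` in nats.}
#'   \item{Evenness}{`E = H / log(k)` with `k` the number of declared
#'     levels; defined as 0 for the degenerate single-level trait.}
#' }
#' Here `n` is the number of germplasms and `ni` the count carrying level
#' `i`.
#'
#' @param level_counts non-negative integer vector of counts per level.
#' @return scalar index value.
#' @export
#' @examples
#' simpson_d(c(2, 2))      # 1 - 2/6
#' shannon_h(c(3, 1))
#' evenness_e(shannon_h(c(1, 1, 1, 1)), 4)
simpson_d <- function(level_counts) {
  n <- sum(level_counts)
  if (n < 2) abort("Simpson diversity needs at least two observations")
  1 - sum(level_counts * (level_counts - 1)) / (n * (n - 1))
}

#' @rdname simpson_d
#' @export
shannon_h <- function(level_counts) {
  n <- sum(level_counts)
  if (n < 1) abort("Shannon index needs at least one observation")
  p <- level_counts[level_counts > 0] / n
  -sum(p * log(p))
}

#' @rdname simpson_d
#' @param H Shannon-Wiener index in nats.
#' @param k number of declared levels.
#' @export
evenness_e <- function(H, k) {
  if (k < 1) abort("k must be at least 1")
  if (k == 1) {
    if (H > 1e-12) abort("H > 0 is inconsistent with a single level")
    return(0)
  }
  if (H > log(k) + 1e-9) abort("H exceeds log(k): inconsistent inputs")
  H / log(k)
}

#' Per-trait diversity table
#'
#' Computes `D`, `H` and `E` for every qualitative trait of a germplasm-level
#' trait matrix. `k` is the number of levels *declared* in the codebook;
#' when fewer levels are observed the gap is reported in the `k_observed`
#' column (absent levels lower `E`).
#'
#' @param m germplasm-level trait matrix (see [aggregate_observations()]).
#' @param cb trait codebook.
#' @return tibble with one row per qualitative trait: `trait`, `n`, `k`,
#'   `k_observed`, `counts` (list), `D`, `H`, `E`.
#' @export
trait_diversity <- function(m, cb) {
  k <- n_levels(cb)
  traits <- intersect(names(k), matrix_traits(m))
  purrr::map_dfr(traits, function(tr) {
    v <- m[[tr]]
    kk <- k[[tr]]
    cnt <- tabulate(v + 1L, nbins = kk)
    h <- shannon_h(cnt)
    tibble::tibble(
      trait = tr, n = length(v), k = kk,
      k_observed = sum(cnt > 0), counts = list(cnt),
      D = simpson_d(cnt), H = h, E = evenness_e(h, kk)
    )
  })
}

#' Coefficients of variation for quantitative traits
#'
#' Stage-1 screening of quantitative traits uses two coefficients:
#' \describe{
#'   \item{mean within-germplasm CV}{`CVbar = mean(Si / Xi) * 100`, the
#'     average over germplasms of the replicate-level coefficient of
#'     variation (sample sd `Si`, mean `Xi`) -- intraspecific uniformity.}
#'   \item{among-germplasm CV}{`CV = S' / X' * 100`, the coefficient of
#'     variation of the germplasm-level values -- interspecific
#'     distinctness.}
#' }
#' Both use the sample standard deviation (denominator `n - 1`) and are
#' invariant to positive rescaling of the trait.
#'
#' @param obs replicate-level observation tibble.
#' @param trait trait name.
#' @return percentage (scalar).
#' @export
#' @examples
#' obs <- data.frame(germplasm_id = c("a", "a", "b", "b"),
#'                   replicate_id = c(1, 2, 1, 2),
#'                   trait = "t", value = c(8, 12, 10, 10))
#' mean_within_cv(obs, "t")  # mean of {28.28%, 0%}
mean_within_cv <- function(obs, trait) {
  v <- obs[obs$trait == trait, ]
  if (nrow(v) == 0) abort(sprintf("no observations for trait '%s'", trait))
  per <- v |>
    dplyr::group_by(.data$germplasm_id) |>
    dplyr::summarise(n = dplyr::n(), s = sd(.data$value),
                     xbar = mean(.data$value), .groups = "drop")
  if (any(per$n < 2)) {
    abort(sprintf("trait '%s': germplasm(s) with fewer than 2 replicates", trait))
  }
  if (any(per$xbar == 0)) abort(sprintf("trait '%s': zero germplasm mean", trait))
  mean(per$s / per$xbar) * 100
}

#' @rdname mean_within_cv
#' @param m germplasm-level trait matrix.
#' @export
among_cv <- function(m, trait) {
  v <- m[[trait]]
  if (is.null(v)) abort(sprintf("trait '%s' not in matrix", trait))
  if (length(v) < 2) abort("among-germplasm CV needs at least two germplasms")
  if (mean(v) == 0) abort(sprintf("trait '%s': zero mean", trait))
  sd(v) / mean(v) * 100
}

#' Per-trait variation table
#'
#' Computes `CVbar` and `CV` for every quantitative trait. The
#' among-germplasm CV is taken over germplasm-level replicate means.
#'
#' @param obs replicate-level observation tibble.
#' @param cb trait codebook.
#' @return tibble with one row per quantitative trait: `trait`, `n`,
#'   `cv_within` (CVbar, %), `cv_among` (CV, %).
#' @export
trait_variation <- function(obs, cb) {
  traits <- intersect(cb$trait[cb$kind == "quantitative"], unique(obs$trait))
  purrr::map_dfr(traits, function(tr) {
    v <- obs[obs$trait == tr, ]
    means <- v |>
      dplyr::group_by(.data$germplasm_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    tibble::tibble(
      trait = tr, n = nrow(means),
      cv_within = mean_within_cv(obs, tr),
      cv_among = sd(means$value) / mean(means$value) * 100
    )
  })
}

#' Screening thresholds
#'
#' The retention gates of stage-1 screening. Defaults are the conventional
#' criteria: qualitative traits need `D >= 0.50`, `H >= 0.80` and
#' `E >= 0.60`; quantitative traits need `CVbar <= 10%` (intraspecific
#' uniformity) and `CV >= 15%` (interspecific distinctness). All
#' comparisons are inclusive.
#'
#' @param d_min,h_min,e_min qualitative gates.
#' @param cvbar_max,cv_min quantitative gates, percent.
#' @return a named list of thresholds.
#' @export
screening_thresholds <- function(d_min = 0.50, h_min = 0.80, e_min = 0.60,
                                 cvbar_max = 10, cv_min = 15) {
  th <- list(d_min = d_min, h_min = h_min, e_min = e_min,
             cvbar_max = cvbar_max, cv_min = cv_min)
  if (any(unlist(th) < 0)) abort("thresholds must be nonnegative")
  structure(th, class = "screening_thresholds")
}

#' Apply the screening gates
#'
#' `screen_qualitative()` flags each row of a [trait_diversity()] table as
#' retained when all three diversity gates pass (inclusively);
#' `screen_quantitative()` does the same for a [trait_variation()] table
#' under the CV gates. Both also record which gate(s) failed, so exclusions
#' are auditable.
#'
#' @param div a [trait_diversity()] tibble.
#' @param th a [screening_thresholds()] list.
#' @return the input tibble plus `retained` (logical) and `excluded_by`
#'   (comma-separated failed gates, `NA` when retained).
#' @export
screen_qualitative <- function(div, th = screening_thresholds()) {
  fails <- purrr::pmap_chr(div[c("D", "H", "E")], function(D, H, E) {
    f <- c(if (D < th$d_min) "D", if (H < th$h_min) "H", if (E < th$e_min) "E")
    if (length(f) == 0) NA_character_ else paste(f, collapse = ",")
  })
  dplyr::mutate(div, retained = is.na(fails), excluded_by = fails)
}

#' @rdname screen_qualitative
#' @param var a [trait_variation()] tibble.
#' @export
screen_quantitative <- function(var, th = screening_thresholds()) {
  fails <- purrr::pmap_chr(var[c("cv_within", "cv_among")], function(cv_within, cv_among) {
    f <- c(if (cv_within > th$cvbar_max) "CVbar", if (cv_among < th$cv_min) "CV")
    if (length(f) == 0) NA_character_ else paste(f, collapse = ",")
  })
  dplyr::mutate(var, retained = is.na(fails), excluded_by = fails)
}

#' Full stage-1 screen
#'
#' Convenience wrapper running [trait_diversity()] + [screen_qualitative()]
#' on the qualitative traits and [trait_variation()] +
#' [screen_quantitative()] on the quantitative traits of an observation
#' table, returning a single per-trait index table.
#'
#' @param obs replicate-level observations.
#' @param cb trait codebook.
#' @param th thresholds, see [screening_thresholds()].
#' @return a `trait_screen` tibble: `trait`, `kind`, `D`, `H`, `E`,
#'   `cv_within`, `cv_among`, `retained`, `excluded_by`.
#' @export
screen_traits <- function(obs, cb, th = screening_thresholds()) {
  m <- aggregate_observations(obs, cb)
  qual <- screen_qualitative(trait_diversity(m, cb), th)
  quant <- screen_quantitative(trait_variation(obs, cb), th)
  out <- dplyr::bind_rows(
    dplyr::mutate(qual[c("trait", "D", "H", "E", "retained", "excluded_by")],
                  kind = "qualitative"),
    dplyr::mutate(quant[c("trait", "cv_within", "cv_among", "retained", "excluded_by")],
                  kind = "quantitative")
  )
  out <- out[c("trait", "kind", "D", "H", "E", "cv_within", "cv_among",
               "retained", "excluded_by")]
  class(out) <- c("trait_screen", class(out))
  attr(out, "thresholds") <- th
  out
}

#' Retained trait names from a screen table
#'
#' @param screen a `trait_screen` (or any tibble with `trait`, `retained`).
#' @return character vector of retained traits.
#' @export
retained_traits <- function(screen) screen$trait[screen$retained]
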