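#' Standardize a trait matrix
#'
#' Centers and scales every trait column to mean 0 and sample standard
#' deviation 1 (z-scores, denominator `n - 1`), removing dimensional
#' differences before PCA and Euclidean distances. Constant columns cannot
#' be scaled and are an error naming the offenders.
#'
#' @param m trait matrix tibble (`germplasm_id` plus numeric trait columns).
#' @return tibble of the same shape with standardized trait columns.
#' @export
standardize_traits <- function(m) {
  traits <- matrix_traits(m)
  sds <- vapply(m[traits], sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("constant trait column(s): %s",
                  paste(traits[sds == 0], collapse = ", ")))
  }
  out <- m
  for (tr in traits) out[[tr]] <- (m[[tr]] - mean(m[[tr]])) / sds[[tr]]
  out
}

#' Correlation-matrix PCA with an eigenvalue retention gate
#'
#' Eigen-decomposes the trait correlation matrix. Components with
#' eigenvalue `lambda >= lambda_min` are retained; each component's variance
#' contribution is `lambda / p * 100` with `p` the number of traits, so the
#' eigenvalues sum to `p`. Loadings follow the component-matrix convention
#' of mainstream statistics software: eigenvector times `sqrt(lambda)`,
#' i.e. the correlation between trait and component, so a column's squared
#' loadings sum to its eigenvalue. The raw orthonormal eigenvectors are
#' kept alongside. Each eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive (a determinism convention; the
#' filter downstream uses absolute values, so the choice is cosmetic).
#'
#' @param m trait matrix tibble (standardization is immaterial: the
#'   correlation matrix is scale-free).
#' @param lambda_min eigenvalue retention threshold (default 0.90).
#' @return a `trait_pca` object: list with `eigenvalues`, `eigenvectors`
#'   (orthonormal, trait x component), `loadings` (trait-component
#'   correlations), `contribution`, `cumulative` (percent), `retained`
#'   (logical per component), `lambda_min`, `n`.
#' @export
pca_retain <- function(m, lambda_min = 0.90) {
  x <- as_numeric_matrix(m)
  if (ncol(x) < 2) abort("PCA needs at least two traits")
  if (nrow(x) < 3) abort("PCA needs at least three germplasms")
  R <- cor(x)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- eig$values
  if (any(lambda < -1e-10)) abort("correlation matrix has a negative eigenvalue")
  lambda <- pmax(lambda, 0)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(x), paste0("PC", seq_len(ncol(V))))
  p <- ncol(x)
  res <- list(
    eigenvalues = lambda,
    eigenvectors = V,
    loadings = structure(V %*% diag(sqrt(lambda), nrow = length(lambda)),
                         dimnames = dimnames(V)),
    contribution = lambda / p * 100,
    cumulative = cumsum(lambda / p * 100),
    retained = lambda >= lambda_min - 1e-9,
    lambda_min = lambda_min,
    n = nrow(x)
  )
  class(res) <- "trait_pca"
  res
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d traits, %d germplasms\n",
              nrow(x$loadings), x$n))
  cat(sprintf("%d / %d components retained (lambda >= %.2f), %.2f%% cumulative variance\n",
              sum(x$retained), length(x$eigenvalues), x$lambda_min,
              max(x$cumulative[x$retained], 0)))
  invisible(x)
}

#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$loadings), n_germplasms = x$n,
    n_components_retained = sum(x$retained),
    cumulative_contribution = if (any(x$retained)) max(x$cumulative[x$retained]) else 0,
    lambda_min = x$lambda_min
  )
}

#' Exclude low-contribution traits after PCA
#'
#' A trait is retained when the absolute value of its loading on at least
#' one retained component reaches `load_min`; traits never loading that
#' strongly carry little of the retained structure and are dropped.
#'
#' @param pca a [pca_retain()] result.
#' @param load_min absolute-loading significance threshold (default 0.60,
#'   applied inclusively with a 1e-9 tolerance).
#' @return character vector of retained trait names.
#' @export
low_contribution_filter <- function(pca, load_min = 0.60) {
  L <- pca$loadings[, pca$retained, drop = FALSE]
  if (ncol(L) == 0) return(character(0))
  keep <- apply(abs(L), 1, max) >= load_min - 1e-9
  rownames(pca$loadings)[keep]
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), both
#'   nonconstant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector")
  cor(x, y)
}

#' Prune highly correlated traits
#'
#' Builds the conflict graph whose edges are trait pairs with `|r| > r_max`
#' and removes traits until no edge remains. Traits on the `prefer` list
#' are protected (the analyst's observational-convenience choices); among
#' unprotected traits the vertex with the highest conflict degree is removed
#' first, ties broken alphabetically, so the result is deterministic. If two
#' protected traits conflict, the one listed earlier is kept and the clash
#' is reported.
#'
#' `correlation_prune()` is generic: give it a trait matrix (correlations
#' are computed with [pearson_r()]'s convention via `stats::cor`) or a
#' ready-made correlation matrix.
#'
#' @param x trait matrix tibble, or symmetric correlation matrix with trait
#'   dimnames.
#' @param traits optional subset of traits to consider (default: all).
#' @param r_max correlation threshold; pairs strictly above it conflict
#'   (default 0.80).
#' @param prefer ordered character vector of traits to keep when resolving
#'   conflicts.
#' @param ... passed between methods.
#' @return a `prune_report`: list with `pairs` (tibble of conflicting pairs
#'   and their r), `removed`, `retained`, `prefer`, `r_max`.
#' @export
correlation_prune <- function(x, ...) UseMethod("correlation_prune")

#' @rdname correlation_prune
#' @export
correlation_prune.data.frame <- function(x, traits = NULL, r_max = 0.80,
                                         prefer = character(), ...) {
  traits <- traits %||% matrix_traits(x)
  R <- cor(as_numeric_matrix(x[c("germplasm_id", traits)]))
  correlation_prune(R, traits = traits, r_max = r_max, prefer = prefer)
}

#' @rdname correlation_prune
#' @export
correlation_prune.matrix <- function(x, traits = NULL, r_max = 0.80,
                                     prefer = character(), ...) {
  traits <- traits %||% rownames(x)
  R <- x[traits, traits, drop = FALSE]
  idx <- which(upper.tri(R) & abs(R) > r_max, arr.ind = TRUE)
  pairs <- tibble::tibble(
    trait_a = traits[idx[, 1]], trait_b = traits[idx[, 2]],
    r = R[idx]
  )
  unknown_pref <- setdiff(prefer, traits)
  if (length(unknown_pref) > 0) {
    warn(sprintf("prefer list names absent trait(s): %s",
                 paste(unknown_pref, collapse = ", ")))
  }

  retained <- traits
  removed <- character(0)
  edges <- pairs[c("trait_a", "trait_b")]
  live_edges <- function() {
    edges[edges$trait_a %in% retained & edges$trait_b %in% retained, ]
  }
  repeat {
    e <- live_edges()
    if (nrow(e) == 0) break
    verts <- c(e$trait_a, e$trait_b)
    cand <- setdiff(unique(verts), prefer)
    if (length(cand) == 0) {
      # conflict entirely among protected traits: drop the later-preferred
      # endpoint of the first clash and report it
      clash <- e[1, ]
      later <- if (match(clash$trait_a, prefer) > match(clash$trait_b, prefer)) {
        clash$trait_a
      } else clash$trait_b
      warn(sprintf("preferred traits '%s' and '%s' conflict; keeping the earlier-listed",
                   clash$trait_a, clash$trait_b))
      drop <- later
    } else {
      deg <- table(factor(verts, levels = cand))
      drop <- sort(names(deg)[deg == max(deg)])[1]
    }
    removed <- c(removed, drop)
    retained <- setdiff(retained, drop)
  }

  res <- list(pairs = pairs, removed = removed, retained = retained,
              prefer = prefer, r_max = r_max)
  class(res) <- "prune_report"
  res
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("Correlation prune (|r| > %.2f): %d conflicting pair(s), %d trait(s) removed, %d retained\n",
              x$r_max, nrow(x$pairs), length(x$removed), length(x$retained)))
  if (length(x$removed) > 0) cat("removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.prune_report <- function(x, ...) x$pairs

#' @export
glance.prune_report <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), n_removed = length(x$removed),
                 n_retained = length(x$retained), r_max = x$r_max)
}
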