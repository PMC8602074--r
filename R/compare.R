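#' Two-group Kruskal–Wallis test
#'
#' Rank-based comparison of two samples with the standard tie correction,
#' with the H statistic referred to a chi-square distribution on one
#' degree of freedom. Moral-loading samples are heavily tied (many tweets
#' share simple fractions), so the tie correction matters. When every
#' pooled value is identical there is no rank separation and the test
#' degenerates to statistic 0, p-value 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list of class `kw_result` with `statistic`, `p_value` and
#'   `group_sizes`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
kruskal_wallis <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    res <- list(statistic = 0, p_value = 1,
                group_sizes = c(length(group_a), length(group_b)))
    class(res) <- "kw_result"
    return(res)
  }
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  kt <- stats::kruskal.test(pooled, g)
  res <- list(statistic = unname(kt$statistic),
              p_value = unname(kt$p.value),
              group_sizes = c(length(group_a), length(group_b)))
  class(res) <- "kw_result"
  res
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis: chi-squared =", format(x$statistic, digits = 6),
      ", p =", format(x$p_value, digits = 4),
      ", n =", paste(x$group_sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Per-dimension Kruskal–Wallis comparison of two loading tables
#'
#' For each of the five foundations, compares the loading values of all
#' moral tweets in corpus A against corpus B (zero loadings included; set
#' `labeled_only = TRUE` to restrict each dimension to tweets labeled with
#' it).
#'
#' @param loadings_a,loadings_b Labeled-tweet tables from
#'   [filter_moral_corpus()].
#' @param labeled_only Restrict dimension j's samples to tweets carrying
#'   label j (default `FALSE`).
#' @return Tibble with `dimension`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
kw_by_dimension <- function(loadings_a, loadings_b, labeled_only = FALSE) {
  cols <- c(CARE = "ml_care", FAIRNESS = "ml_fairness",
            INGROUP = "ml_ingroup", AUTHORITY = "ml_authority",
            PURITY = "ml_purity")
  pick <- function(df, f) {
    x <- df[[cols[[f]]]]
    if (labeled_only) {
      has <- vapply(split_labels(df$labels), function(s) f %in% s, NA)
      x <- x[has]
    }
    x
  }
  rows <- lapply(names(cols), function(f) {
    a <- pick(loadings_a, f); b <- pick(loadings_b, f)
    kw <- kruskal_wallis(a, b)
    tibble::tibble(dimension = f, statistic = kw$statistic,
                   p_value = kw$p_value, n_a = length(a), n_b = length(b))
  })
  dplyr::bind_rows(rows)
}

#' Principal component analysis of moral-loading vectors
#'
#' Centers (and optionally standardizes) the n x 5 matrix of per-tweet
#' loading vectors and decomposes it. With a foundation-disjoint lexicon
#' each row sums to 1, so the data live on a 4-dimensional simplex and
#' exactly four components carry variance; the covariance (unstandardized)
#' decomposition is the default since all five variables share the
#' \[0, 1\] scale.
#'
#' @param x Numeric matrix or data frame, n tweets x 5 foundations in
#'   [moral_foundations()] order; n >= 2.
#' @param standardize Scale columns to unit variance before decomposition
#'   (default `FALSE`; fails if a column is constant).
#' @param absolute_loadings Return absolute component loadings, the form
#'   used for contribution heatmaps (default `FALSE`).
#' @return A list of class `pca_moral` with `variance_explained`
#'   (fractions, non-increasing, zeroed below a 1e-12 variance floor),
#'   `loadings` (5 x c, unit-norm columns), `scores` (n x c),
#'   `n_nonzero` (number of components above the variance floor), and
#'   `center`.
#' @export
pca_moral <- function(x, standardize = FALSE, absolute_loadings = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 observations")
  if (ncol(x) != 5) stop("expected a 5-column loading matrix")
  if (standardize && any(apply(x, 2, stats::sd) == 0)) {
    stop("cannot standardize: a column has zero variance")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  vars <- p$sdev^2
  nonzero <- vars >= 1e-12
  vars[!nonzero] <- 0
  total <- sum(vars)
  ve <- if (total > 0) vars / total else vars
  loadings <- p$rotation
  if (absolute_loadings) loadings <- abs(loadings)
  structure(
    list(variance_explained = ve,
         loadings = loadings,
         scores = p$x,
         n_nonzero = sum(nonzero),
         center = p$center),
    class = "pca_moral"
  )
}

#' @export
print.pca_moral <- function(x, ...) {
  cat("<pca_moral> ", x$n_nonzero, " nonzero-variance components\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "),
      "\n")
  invisible(x)
}

# Extract the 5-column loading matrix from a labeled-tweet table.
loading_matrix <- function(labeled) {
  m <- as.matrix(labeled[, c("ml_care", "ml_fairness", "ml_ingroup",
                             "ml_authority", "ml_purity")])
  colnames(m) <- moral_foundations()
  m
}

#' Compare two scored corpora
#'
#' Runs the per-dimension Kruskal–Wallis tests and a per-corpus PCA of the
#' loading vectors — the two corpus-level comparisons used to contrast
#' moral expression across languages.
#'
#' @param loadings_a,loadings_b Labeled-tweet tables from
#'   [filter_moral_corpus()].
#' @param standardize Passed to [pca_moral()].
#' @return A list with `kruskal_wallis` (tibble), `pca_a`, `pca_b`.
#' @export
compare_corpora <- function(loadings_a, loadings_b, standardize = FALSE) {
  list(
    kruskal_wallis = kw_by_dimension(loadings_a, loadings_b),
    pca_a = pca_moral(loading_matrix(loadings_a), standardize = standardize),
    pca_b = pca_moral(loading_matrix(loadings_b), standardize = standardize)
  )
}
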