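#' Per-platform anti-vaccine category distributions
#'
#' Drops the positive categories and normalizes each platform's anti-vaccine
#' category counts by that platform's total number of anti-vaccine comments,
#' giving fixed-length frequency vectors (length 14 with the default
#' codebook) that are comparable across platforms.
#'
#' @param tab A `vax_contingency` (categories x platforms).
#' @param codebook The codebook defining polarity.
#' @return A numeric matrix (`vax_distributions`), anti categories x
#'   platforms; each column sums to 1.
#' @export
anti_category_distributions <- function(tab, codebook = default_codebook()) {
  anti <- intersect(rownames(tab), as.character(anti_ids(codebook)))
  m <- tab[anti, , drop = FALSE]
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort_data(paste0("Platform(s) with zero anti-vaccine comments: ",
                      paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  out <- sweep(m, 2, totals, "/")
  structure(out, class = c("vax_distributions", "matrix", "array"))
}

#' Cosine similarity of two non-negative frequency vectors
#'
#' `cos(x, y) = sum(x_i * y_i) / (sqrt(sum(x_i^2)) * sqrt(sum(y_i^2)))`.
#' For non-negative vectors the score lies in \[0, 1\]: 1 means identical
#' distributions (same direction), 0 means disjoint support. Results are
#' clamped to \[0, 1\] only against floating-point overshoot.
#'
#' @param x,y Numeric vectors of equal length with at least one nonzero
#'   entry each.
#' @return Cosine score in \[0, 1\].
#' @export
cosine_similarity <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort_param("Vectors must have equal length for cosine similarity.")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    abort_data("Cosine similarity is undefined for a zero vector.")
  }
  s <- sum(x * y) / (nx * ny)
  min(max(s, 0), 1)
}

#' Pairwise cosine similarity matrix of platform distributions
#'
#' @param dists A `vax_distributions` matrix (categories x platforms) or any
#'   numeric matrix whose columns are the platform vectors.
#' @return A symmetric `vax_similarity` matrix with unit diagonal, platforms
#'   in input column order.
#' @export
similarity_matrix <- function(dists) {
  p <- ncol(dists)
  if (p < 2) abort_param("At least 2 platforms are required.")
  platforms <- colnames(dists) %||% paste0("p", seq_len(p))
  s <- matrix(1, p, p, dimnames = list(platforms, platforms))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      s[i, j] <- s[j, i] <- cosine_similarity(dists[, i], dists[, j])
    }
  }
  structure(s, class = c("vax_similarity", "matrix", "array"))
}

#' Write a similarity matrix as CSV
#'
#' Platform names appear as both header row and first column.
#'
#' @param sim A `vax_similarity` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  df <- data.frame(platform = rownames(sim), unclass(sim),
                   check.names = FALSE)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Remove categories that force zero expected counts in pairwise tests
#'
#' A category is removed if and only if it has a zero count on two or more
#' platforms — the only configuration that produces an expected value of
#' exactly 0 in some pairwise platform subtable (a zero row total for that
#' pair). The removal applies to the omnibus table and, by construction, to
#' every pairwise subtable derived from it.
#'
#' @param tab A contingency matrix (categories x platforms, >= 2 platforms).
#' @return List with `table` (the reduced `vax_contingency`) and `removed`
#'   (integer ids of removed categories).
#' @export
prune_zero_expected <- function(tab) {
  if (ncol(tab) < 2) abort_param("At least 2 platforms are required.")
  zero_platforms <- rowSums(tab == 0)
  drop <- zero_platforms >= 2
  if (all(drop)) abort_data("All categories were removed by the zero-expected rule.")
  list(table = new_contingency(tab[!drop, , drop = FALSE]),
       removed = as.integer(rownames(tab)[drop]))
}

#' Chi-square test of homogeneity across platforms
#'
#' Pearson chi-square (no continuity correction) of whether the platforms
#' share one categorical distribution: expected counts are
#' `rowtotal * coltotal / n`, `df = (R - 1) * (C - 1)`, and the p-value
#' comes from the upper tail of the chi-square distribution. The table must
#' be pruned first so that all expected counts are positive (see
#' [prune_zero_expected()]).
#'
#' @param tab A contingency matrix (categories x platforms).
#' @return A `vax_homogeneity` list: `chi2`, `df`, `p`, `expected`,
#'   `removed` (filled by [run_pipeline()] when pruning was applied),
#'   `table_used`.
#' @export
chi_square_homogeneity <- function(tab) {
  m <- unclass(tab)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort_data("Homogeneity test needs at least 2 categories and 2 platforms.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort_data(paste0(
      "Zero expected count(s); remove sparse categories with ",
      "prune_zero_expected() before testing."))
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, expected = expected,
                 removed = integer(), table_used = tab),
            class = "vax_homogeneity")
}

#' @export
print.vax_homogeneity <- function(x, ...) {
  cat(sprintf("<vax_homogeneity> chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  if (length(x$removed)) {
    cat("  categories removed by zero-expected rule:",
        paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Post-hoc pairwise homogeneity tests with Bonferroni correction
#'
#' For each of the `m = C * (C - 1) / 2` platform pairs: the pair's
#' two-column subtable is pruned by the zero-row rule, tested with
#' [chi_square_homogeneity()], and the raw p-value is Bonferroni-adjusted
#' as `p_adjusted = min(1, m * p_raw)`. A pair whose subtable cannot be
#' tested is reported with `NA` statistics rather than aborting the batch.
#'
#' @param tab A contingency matrix (categories x platforms, >= 2 platforms);
#'   typically the omnibus-pruned anti-vaccine table.
#' @param alpha Significance level for the `significant` flag; default 0.05.
#' @return Tibble with one row per pair: `platform_a`, `platform_b`,
#'   `chi2`, `df`, `p_raw`, `p_adjusted`, `significant`.
#' @export
pairwise_posthoc <- function(tab, alpha = 0.05) {
  platforms <- colnames(tab)
  if (length(platforms) < 2) abort_param("At least 2 platforms are required.")
  pairs <- utils::combn(platforms, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    res <- tryCatch({
      sub <- tab[, c(a, b), drop = FALSE]
      pruned <- prune_zero_expected(sub)
      chi_square_homogeneity(pruned$table)
    }, error = function(e) NULL)
    if (is.null(res)) {
      tibble(platform_a = a, platform_b = b, chi2 = NA_real_,
             df = NA_integer_, p_raw = NA_real_)
    } else {
      tibble(platform_a = a, platform_b = b, chi2 = res$chi2,
             df = as.integer(res$df), p_raw = res$p)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "bonferroni", n = m)
  out$significant <- out$p_adjusted < alpha
  out
}
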