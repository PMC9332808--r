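#' Per-category and corpus term statistics
#'
#' Pools token counts over labeled token documents. For category `k` and
#' term `w`, `phi` is the count of `w` in `k` divided by the total number of
#' terms in `k`; `p` is the corpus-wide count of `w` divided by the total
#' number of terms. Empty categories are recorded with zero totals.
#'
#' @param docs A `vax_tokens` tibble from [preprocess_corpus()] (columns
#'   `comment_id`, `label`, list-column `tokens`). Every document must be
#'   labeled.
#' @return A `vax_term_stats` list: `counts` (tibble `category`, `term`,
#'   `n`, `phi`, `p`), `category_totals`, `term_totals`, `V`, `K`,
#'   `total_terms`.
#' @export
compute_term_stats <- function(docs) {
  if (anyNA(docs$label)) {
    abort_validation("All token documents must be labeled to compute term statistics.")
  }
  lens <- lengths(docs$tokens)
  if (sum(lens) == 0) abort_data("All token documents are empty; no terms to count.")
  long <- tibble(
    category = rep(as.integer(docs$label), lens),
    term = unlist(docs$tokens, use.names = FALSE))
  counts <- dplyr::count(long, category, term, name = "n")
  category_totals <- tapply(counts$n, counts$category, sum)
  cats_present <- sort(unique(as.integer(docs$label)))
  totals <- setNames(rep(0L, length(cats_present)), cats_present)
  totals[names(category_totals)] <- as.integer(category_totals)
  term_totals <- tapply(counts$n, counts$term, sum)
  total_terms <- sum(counts$n)
  counts$phi <- counts$n / as.numeric(totals[as.character(counts$category)])
  counts$p <- as.numeric(term_totals[counts$term]) / total_terms
  structure(
    list(counts = counts, category_totals = totals,
         term_totals = term_totals, V = length(term_totals),
         K = length(cats_present), total_terms = total_terms),
    class = "vax_term_stats")
}

#' Lambda-weighted term relevance
#'
#' Scores how relevant each term is to each category:
#' `r(w, k | lambda) = lambda * log(phi_kw) + (1 - lambda) * log(phi_kw / p_w)`
#' (natural logarithm). The first component is the within-category term
#' probability; the second is the term's lift — its within-category
#' probability relative to its corpus-wide probability — which down-weights
#' globally frequent terms. `lambda` balances the two; 0.5 weighs them
#' equally and is the default. Only (category, term) pairs with
#' `phi_kw > 0` are scored, so no `-Inf` entries arise; rankings are
#' invariant to the logarithm base.
#'
#' @param stats A `vax_term_stats`.
#' @param lambda Weight in \[0, 1\].
#' @return A `vax_relevance` tibble (`category`, `term`, `phi`, `p`,
#'   `relevance`), sorted within category by relevance descending with
#'   lexicographic term order as tie-break. The lambda used is stored in
#'   `attr(, "lambda")`.
#' @export
relevance_score <- function(stats, lambda = 0.5) {
  stopifnot(inherits(stats, "vax_term_stats"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    abort_param("lambda must be a single number in [0, 1].")
  }
  out <- stats$counts
  out$relevance <- lambda * log(out$phi) + (1 - lambda) * log(out$phi / out$p)
  out <- dplyr::arrange(out, category, dplyr::desc(relevance), term)
  out <- out[c("category", "term", "phi", "p", "relevance")]
  attr(out, "lambda") <- lambda
  class(out) <- c("vax_relevance", class(out))
  out
}

#' Top keywords per category by relevance
#'
#' @param table A `vax_relevance` tibble.
#' @param top_n Keywords per category; the default 6 matches the keyword
#'   lists typically reported per category.
#' @return Tibble with columns `category_id`, `rank`, `term`, `relevance`.
#'   Categories with fewer scored terms return what they have; categories
#'   with no tokens are absent.
#' @export
rank_keywords <- function(table, top_n = 6) {
  stopifnot(inherits(table, "vax_relevance"))
  if (!is.numeric(top_n) || top_n < 1) abort_param("top_n must be >= 1.")
  ranked <- dplyr::slice_head(dplyr::group_by(table, category), n = as.integer(top_n))
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number())
  ranked <- dplyr::ungroup(ranked)
  tibble(category_id = ranked$category, rank = ranked$rank,
         term = ranked$term, relevance = ranked$relevance)
}

#' Write ranked keywords to TSV
#'
#' Columns `category_id`, `rank`, `term`, `relevance`.
#'
#' @param keywords Output of [rank_keywords()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keywords <- function(keywords, path) {
  readr::write_tsv(keywords, path, progress = FALSE)
  invisible(path)
}
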