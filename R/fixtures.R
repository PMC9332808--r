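#' Published summary tables of the reference top-comment data set
#'
#' `reference_platform_summaries()` returns the published per-platform
#' summary of the reference 1,000-comment data set (250 top comments per
#' platform): total reactions and mean comment length in words.
#' `reference_category_counts()` returns the published marginal category
#' counts of the same data set (counts over the 15-category codebook,
#' summing to 1,000). Both are printed summary statistics usable as inputs
#' for fixture arithmetic and as generator defaults; the underlying raw
#' comments are not publicly deposited.
#'
#' @return `reference_platform_summaries()`: tibble with columns
#'   `platform`, `n_comments`, `sum_reactions`, `mean_length_words`.
#' @export
reference_platform_summaries <- function() {
  tibble(
    platform = canonical_platforms(),
    n_comments = rep(250L, 4),
    sum_reactions = c(39960L, 6918L, 34865L, 32449L),
    mean_length_words = c(30, 32, 12, 22))
}

#' @rdname reference_platform_summaries
#' @export
reference_category_counts <- function() {
  setNames(
    c(271L, 156L, 116L, 102L, 85L, 84L, 43L, 36L, 27L, 21L, 20L, 13L, 12L, 9L, 5L),
    0:14)
}

#' A deterministic corpus realizing the published summary tables
#'
#' Builds a synthetic labeled corpus whose marginal category counts equal
#' [reference_category_counts()] exactly and whose per-platform comment
#' counts, reaction sums, and mean word lengths equal
#' [reference_platform_summaries()] exactly. Labels are spread across the
#' four platforms by cycling, each comment's text has exactly the
#' platform's mean word count, and reactions split each platform's total
#' as evenly as integers allow. Useful for fixture arithmetic on the
#' published tables; it is a synthetic stand-in, not the unshared raw data.
#'
#' @return A `vax_corpus` of 1,000 labeled comments.
#' @export
reference_corpus <- function() {
  counts <- reference_category_counts()
  summaries <- reference_platform_summaries()
  labels <- rep(as.integer(names(counts)), counts)
  platforms <- rep_len(summaries$platform, length(labels))
  lens <- setNames(summaries$mean_length_words, summaries$platform)
  vocab <- default_filler_vocab(max(lens))
  texts <- vapply(platforms, function(p) {
    paste(vocab[seq_len(lens[[p]])], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  reactions <- integer(length(labels))
  for (i in seq_len(nrow(summaries))) {
    p <- summaries$platform[i]
    idx <- which(platforms == p)
    base <- summaries$sum_reactions[i] %/% length(idx)
    extra <- summaries$sum_reactions[i] %% length(idx)
    reactions[idx] <- base + as.integer(seq_along(idx) <= extra)
  }
  corpus(tibble(platform = platforms, text = texts,
                reactions = reactions, label = labels))
}
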