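#' Construct a comment corpus
#'
#' A corpus is a collection of social-media comments together with the
#' codebook used to label them. Each comment has a unique `id`, a `platform`,
#' the raw `text` (UTF-8, emojis preserved), a non-negative integer
#' `reactions` count (likes plus any platform-specific reaction buttons),
#' and an optional category `label` drawn from the codebook.
#'
#' @param comments Data frame with columns `platform`, `text`, `reactions`,
#'   and optionally `id` and `label`. Missing ids are auto-assigned
#'   sequentially ("c1", "c2", ...).
#' @param codebook A `vax_codebook`; defaults to [default_codebook()].
#' @return A `vax_corpus` object (list with elements `comments`, `codebook`).
#' @export
corpus <- function(comments, codebook = default_codebook()) {
  cm <- as_tibble(comments)
  required <- c("platform", "text", "reactions")
  missing_cols <- setdiff(required, names(cm))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Corpus table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"id" %in% names(cm) || all(is.na(cm$id))) {
    cm$id <- if (nrow(cm)) paste0("c", seq_len(nrow(cm))) else character()
  }
  cm$id <- as.character(cm$id)
  if (!"label" %in% names(cm)) cm$label <- NA_integer_
  cm$label <- suppressWarnings(as.integer(cm$label))
  cm$text <- as.character(cm$text)
  if (nrow(cm) > 0) cm$platform <- canonical_platform(cm$platform)

  reactions_num <- suppressWarnings(as.numeric(cm$reactions))
  bad <- which(is.na(reactions_num) | reactions_num < 0 |
                 reactions_num != floor(reactions_num))
  if (length(bad) > 0) {
    abort_validation(paste0(
      "Reactions must be non-negative integers; offending row(s): ",
      paste(head(bad, 10), collapse = ", ")))
  }
  cm$reactions <- as.integer(reactions_num)

  if (anyDuplicated(cm$id)) {
    abort_validation("Comment ids must be unique within a corpus.")
  }
  unknown <- which(!is.na(cm$label) & !cm$label %in% codebook$id)
  if (length(unknown) > 0) {
    abort_validation(paste0(
      "Label(s) not present in the codebook; offending row(s): ",
      paste(head(unknown, 10), collapse = ", ")))
  }
  cm <- cm[c("id", "platform", "text", "reactions", "label")]
  structure(list(comments = cm, codebook = codebook), class = "vax_corpus")
}

#' @export
print.vax_corpus <- function(x, ...) {
  cat("<vax_corpus> ", nrow(x$comments), " comments on ",
      length(unique(x$comments$platform)), " platform(s); ",
      sum(!is.na(x$comments$label)), " labeled\n", sep = "")
  print(x$comments, n = 5)
  invisible(x)
}

#' Number of comments in a corpus
#' @param x A `vax_corpus`.
#' @return Integer count.
#' @export
n_comments <- function(x) nrow(x$comments)

#' Read a comment corpus from CSV or JSONL
#'
#' CSV files are UTF-8, comma-separated, RFC-4180 quoted, with header
#' `id,platform,text,reactions,label` (`id` and `label` optional; empty
#' label means unlabeled). JSONL files carry one JSON object per line with
#' the same keys (`label` may be `null` or absent). Text is preserved
#' verbatim, including emojis and other non-ASCII content. An empty file
#' yields an empty corpus.
#'
#' @param path File path.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @param codebook Codebook used to validate labels.
#' @return A `vax_corpus`.
#' @export
read_corpus <- function(path, format = NULL, codebook = default_codebook()) {
  if (!file.exists(path)) abort_config(paste0("File not found: ", path))
  format <- format %||% infer_format(path, c(csv = "csv", jsonl = "jsonl", ndjson = "jsonl"))
  if (file.size(path) == 0) {
    return(corpus(tibble(platform = character(), text = character(),
                         reactions = integer()), codebook))
  }
  cm <- switch(format,
    csv = readr::read_csv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())),
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(lines, function(l) {
        obj <- jsonlite::fromJSON(l)
        tibble(id = as.character(obj$id %||% NA_character_),
               platform = as.character(obj$platform %||% NA_character_),
               text = as.character(obj$text %||% NA_character_),
               reactions = as.character(obj$reactions %||% NA_character_),
               label = as.character(obj$label %||% NA_character_))
      })
      dplyr::bind_rows(rows)
    },
    abort_config(paste0("Unsupported corpus format: ", format))
  )
  if (nrow(cm) > 0) {
    required <- c("platform", "text", "reactions")
    missing_cols <- setdiff(required, names(cm))
    if (length(missing_cols) > 0) {
      abort_schema(paste0("Corpus file is missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
    }
  }
  corpus(cm, codebook)
}

#' Write a comment corpus to CSV or JSONL
#'
#' @param x A `vax_corpus`.
#' @param path Output path.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = NULL) {
  format <- format %||% infer_format(path, c(csv = "csv", jsonl = "jsonl", ndjson = "jsonl"))
  cm <- x$comments
  switch(format,
    csv = readr::write_csv(cm, path, na = "", progress = FALSE),
    jsonl = {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      for (i in seq_len(nrow(cm))) {
        row <- list(id = cm$id[i], platform = cm$platform[i], text = cm$text[i],
                    reactions = cm$reactions[i],
                    label = if (is.na(cm$label[i])) NULL else cm$label[i])
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null"), con)
      }
    },
    abort_config(paste0("Unsupported corpus format: ", format))
  )
  invisible(path)
}

#' Select the most-reacted-to comments per platform
#'
#' Retains, for each platform, the `n_per_platform` comments with the most
#' reactions (the "top comments"). Ties at the cut are broken by stable input
#' order, making the selection deterministic. Platforms with fewer comments
#' than requested are kept whole, with a warning.
#'
#' @param x A `vax_corpus`.
#' @param n_per_platform Positive integer; 250 matches the common
#'   top-comment design for four platforms totalling 1,000 comments.
#' @return A `vax_corpus` containing only the selected comments, in their
#'   original relative order.
#' @export
select_top_by_reactions <- function(x, n_per_platform = 250) {
  stopifnot(inherits(x, "vax_corpus"))
  if (!is.numeric(n_per_platform) || n_per_platform < 1) {
    abort_param("n_per_platform must be a positive integer.")
  }
  cm <- x$comments
  keep <- logical(nrow(cm))
  for (p in platform_levels(cm$platform)) {
    idx <- which(cm$platform == p)
    if (length(idx) < n_per_platform) {
      warn(paste0("Platform '", p, "' has only ", length(idx),
                  " comments (< ", n_per_platform, "); keeping all."))
      keep[idx] <- TRUE
    } else {
      ord <- idx[order(-cm$reactions[idx], seq_along(idx))]
      keep[ord[seq_len(n_per_platform)]] <- TRUE
    }
  }
  out <- x
  out$comments <- cm[keep, ]
  out
}

#' Per-platform corpus summaries
#'
#' One row per platform: number of comments, exact integer sum of reactions,
#' and mean comment length in words. A comment's word count is its number of
#' whitespace-delimited tokens in the raw (unprocessed) text.
#'
#' @param x A non-empty `vax_corpus`.
#' @return Tibble with columns `platform`, `n_comments`, `sum_reactions`,
#'   `mean_length_words`, in platform first-appearance order.
#' @export
summarize_platforms <- function(x) {
  stopifnot(inherits(x, "vax_corpus"))
  cm <- x$comments
  if (nrow(cm) == 0) abort_data("Cannot summarize an empty corpus.")
  wc <- word_count(cm$text)
  out <- tibble(platform = cm$platform, n = 1L, reactions = cm$reactions, wc = wc)
  out <- dplyr::summarise(
    dplyr::group_by(out, platform = factor(platform, levels = platform_levels(cm$platform))),
    n_comments = sum(n),
    sum_reactions = sum(reactions),
    mean_length_words = sum(wc) / sum(n),
    .groups = "drop")
  out$platform <- as.character(out$platform)
  out
}

word_count <- function(text) {
  trimmed <- trimws(text)
  n <- stringr::str_count(trimmed, "\\S+")
  n[is.na(n)] <- 0L
  n
}

#' Tabulate category labels by platform
#'
#' Builds the category-by-platform contingency table of labeled comments.
#' Rows cover every codebook category (including zero-count ones), columns
#' are platforms in first-appearance order. All comments must be labeled.
#'
#' @param x A `vax_corpus` with all comments labeled.
#' @return A `vax_contingency` integer matrix (categories x platforms) with
#'   row names = category ids and column names = platforms.
#' @export
tabulate_categories <- function(x) {
  stopifnot(inherits(x, "vax_corpus"))
  cm <- x$comments
  unlabeled <- cm$id[is.na(cm$label)]
  if (length(unlabeled) > 0) {
    abort_validation(paste0(
      "All comments must be labeled before tabulation; unlabeled id(s): ",
      paste(head(unlabeled, 10), collapse = ", ")))
  }
  counts <- table(
    factor(cm$label, levels = x$codebook$id),
    factor(cm$platform, levels = platform_levels(cm$platform)))
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(rownames(counts), colnames(counts)))
  new_contingency(m)
}

new_contingency <- function(m) {
  storage.mode(m) <- "integer"
  structure(m, class = c("vax_contingency", class(m)))
}

#' @export
print.vax_contingency <- function(x, ...) {
  cat("<vax_contingency> ", nrow(x), " categories x ", ncol(x),
      " platforms, grand total ", sum(x), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Marginal category fractions of a contingency table
#'
#' @param tab A `vax_contingency`.
#' @return Named numeric vector: row totals divided by the grand total.
#' @export
category_fractions <- function(tab) {
  total <- sum(tab)
  if (total == 0) abort_data("Contingency table has grand total 0.")
  rowSums(tab) / total
}

#' Share of anti-vaccine comments
#'
#' The fraction of labeled comments falling in anti-polarity categories:
#' the sum of anti-category counts divided by the grand total (integer
#' arithmetic before the final division, so the anti and positive shares
#' add to exactly 1).
#'
#' @param tab A `vax_contingency` built by [tabulate_categories()].
#' @param codebook The codebook defining category polarity.
#' @return A fraction in \[0, 1\].
#' @export
anti_vaccine_share <- function(tab, codebook = default_codebook()) {
  total <- sum(tab)
  if (total == 0) abort_data("Contingency table has grand total 0.")
  anti <- intersect(rownames(tab), as.character(anti_ids(codebook)))
  sum(tab[anti, , drop = FALSE]) / total
}
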