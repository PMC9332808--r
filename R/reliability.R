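#' Construct an annotation matrix
#'
#' An items x coders grid of category labels, as produced by independent
#' double (or multiple) coding of a comment sample. Missing labels (`NA`)
#' are allowed; items need at least two non-missing labels to be pairable.
#'
#' @param labels A matrix (or data frame) of labels, rows = items,
#'   columns = coders. Values may be integers, characters, or factors.
#' @return A `vax_annotations` matrix.
#' @export
annotation_matrix <- function(labels) {
  m <- as.matrix(labels)
  if (ncol(m) < 2) abort_validation("At least 2 coders are required.")
  pairable <- rowSums(!is.na(m)) >= 2
  if (!any(pairable)) {
    abort_data("No item has >= 2 non-missing labels; nothing is pairable.")
  }
  structure(m, class = c("vax_annotations", class(m)))
}

#' Read annotations from a long-format CSV
#'
#' Expects columns `item_id`, `coder_id`, `label`; the long table is pivoted
#' to the items x coders grid.
#'
#' @param path CSV file path.
#' @return A `vax_annotations` matrix with item ids as row names and coder
#'   ids as column names.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("item_id", "coder_id", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Annotation file is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  items <- unique(df$item_id)
  coders <- unique(df$coder_id)
  m <- matrix(NA, nrow = length(items), ncol = length(coders),
              dimnames = list(as.character(items), as.character(coders)))
  m[cbind(match(df$item_id, items), match(df$coder_id, coders))] <- df$label
  annotation_matrix(m)
}

#' Build the coincidence matrix of pairable label values
#'
#' Standard construction for Krippendorff's alpha: every item with
#' `m >= 2` non-missing labels contributes, for each ordered pair of its
#' labels, a weight of `1/(m - 1)` to the corresponding cell. Items with
#' fewer than two labels are skipped and reported in the `skipped_items`
#' diagnostic. The resulting matrix is symmetric and its entries sum to the
#' total number of pairable values `n`.
#'
#' @param ann A `vax_annotations` matrix.
#' @return A list (`vax_coincidence`) with elements `o` (category x category
#'   matrix), `n_c` (per-category marginals), `n` (total pairable values),
#'   and `skipped_items`.
#' @export
build_coincidence <- function(ann) {
  if (!inherits(ann, "vax_annotations")) ann <- annotation_matrix(ann)
  values <- sort(unique(as.vector(ann[!is.na(ann)])))
  cats <- as.character(values)
  o <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  skipped <- integer()
  for (u in seq_len(nrow(ann))) {
    labs <- ann[u, ][!is.na(ann[u, ])]
    m <- length(labs)
    if (m < 2) {
      if (m > 0) skipped <- c(skipped, u)
      next
    }
    labs <- as.character(labs)
    w <- 1 / (m - 1)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) o[labs[i], labs[j]] <- o[labs[i], labs[j]] + w
      }
    }
  }
  n <- sum(o)
  if (n == 0) abort_data("No pairable items; cannot build a coincidence matrix.")
  structure(list(o = o, n_c = rowSums(o), n = n, skipped_items = skipped),
            class = "vax_coincidence")
}

#' Krippendorff's alpha for nominal data
#'
#' Chance-corrected interrater agreement, `alpha = 1 - D_o / D_e`, computed
#' from the coincidence matrix: observed disagreement
#' `D_o = sum of off-diagonal coincidences / n` and expected disagreement
#' `D_e = sum over c != k of n_c * n_k / (n * (n - 1))`. Labels are treated
#' as unordered categories (nominal metric). Alpha is 1 for perfect
#' agreement, 0 when agreement equals chance, and can be negative for
#' systematic disagreement.
#'
#' @param ann A `vax_annotations` matrix (or plain items x coders matrix).
#' @param metric Only `"nominal"` is supported.
#' @return A list (`vax_reliability`) with `alpha`, `D_o`, `D_e`,
#'   `n_items_used`, and the `coincidence` object.
#' @export
krippendorff_alpha <- function(ann, metric = "nominal") {
  metric <- match.arg(metric, "nominal")
  if (!inherits(ann, "vax_annotations")) ann <- annotation_matrix(ann)
  co <- build_coincidence(ann)
  o <- co$o
  n <- co$n
  n_c <- co$n_c
  D_o <- (sum(o) - sum(diag(o))) / n
  D_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n * (n - 1))
  if (D_e == 0) {
    abort_data(paste0(
      "Expected disagreement is 0 (all pairable values fall in one ",
      "category); alpha is undefined."))
  }
  alpha <- if (D_o == 0) 1 else 1 - D_o / D_e
  n_items_used <- sum(rowSums(!is.na(ann)) >= 2)
  structure(list(alpha = alpha, D_o = D_o, D_e = D_e,
                 n_items_used = n_items_used, coincidence = co),
            class = "vax_reliability")
}

#' @export
print.vax_reliability <- function(x, ...) {
  cat(sprintf(
    "<vax_reliability> Krippendorff's alpha (nominal) = %.3f  [D_o = %.4f, D_e = %.4f, items = %d]\n",
    x$alpha, x$D_o, x$D_e, x$n_items_used))
  invisible(x)
}

#' Raw percent agreement between two coders
#'
#' The fraction of items receiving identical labels from both coders; a
#' simple cross-check statistic alongside the chance-corrected alpha.
#' Requires exactly two coders and complete labels.
#'
#' @param ann A two-coder annotation matrix with no missing labels.
#' @return Fraction in \[0, 1\].
#' @export
percent_agreement <- function(ann) {
  if (!inherits(ann, "vax_annotations")) ann <- annotation_matrix(ann)
  if (ncol(ann) != 2) {
    abort(paste0("percent_agreement supports exactly 2 coders (got ",
                 ncol(ann), ")."), class = "vaxtalk_unsupported_error")
  }
  if (anyNA(ann)) abort_validation("percent_agreement requires complete labels.")
  mean(ann[, 1] == ann[, 2])
}
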