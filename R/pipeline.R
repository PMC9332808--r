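#' Configuration for an end-to-end analysis run
#'
#' Collects everything one run needs: a corpus (object, file path, or the
#' `"preset"` / `"null"` simulation profiles), optional paired annotations,
#' preprocessing settings, the relevance weight `lambda`, the keyword
#' cutoff `top_n`, the significance level, a seed, and an optional output
#' directory. Serializes to/from YAML so runs are reproducible from a
#' single file.
#'
#' @param corpus A `vax_corpus`, a file path, or one of `"preset"`
#'   (distinct-platform simulation) / `"null"` (homogeneous simulation).
#' @param annotations Optional `vax_annotations`, file path, or `"simulate"`
#'   to double-code a subsample of simulated ground truth.
#' @param preprocess A `vax_preprocess_config`.
#' @param lambda Relevance weight (default 0.5).
#' @param top_n Keywords per category (default 6).
#' @param alpha Significance level (default 0.05).
#' @param n_per_platform Comments per platform for simulated corpora.
#' @param seed Integer seed for all stochastic stages.
#' @param outdir Optional output directory for [write_bundle()].
#' @return A `vax_run_config` list.
#' @export
run_config <- function(corpus = "preset", annotations = "simulate",
                       preprocess = preprocess_config(), lambda = 0.5,
                       top_n = 6, alpha = 0.05, n_per_platform = 250,
                       seed = 1L, outdir = NULL) {
  structure(
    list(corpus = corpus, annotations = annotations, preprocess = preprocess,
         lambda = lambda, top_n = top_n, alpha = alpha,
         n_per_platform = n_per_platform, seed = as.integer(seed),
         outdir = outdir),
    class = "vax_run_config")
}

#' Run the full cross-platform discourse analysis
#'
#' Executes the stages in order: corpus acquisition (file, object, or
#' simulation), platform summaries, category tabulation and anti-vaccine
#' share, interrater reliability (when annotations are available),
#' preprocessing and keyword relevance, per-platform anti-vaccine
#' distributions with cosine similarity, and chi-square homogeneity with
#' zero-expected-cell pruning and Bonferroni post-hoc pairwise tests.
#' Stages whose preconditions fail (e.g. an unlabeled corpus) are recorded
#' as skipped with a diagnostic instead of aborting the run.
#'
#' @param config A `vax_run_config`.
#' @return A `vax_report_bundle` list with elements `summaries`, `table`,
#'   `fractions`, `anti_share`, `reliability`, `keywords`, `distributions`,
#'   `similarity`, `homogeneity`, `pairwise`, `skipped`, and `meta`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "vax_run_config"))
  skipped <- list()
  truth <- NULL

  corp <- config$corpus
  if (is.character(corp) && corp %in% c("preset", "null")) {
    sim_cfg <- if (corp == "preset") {
      preset_platform_profiles(seed = config$seed,
                               n_per_platform = config$n_per_platform)
    } else {
      synthetic_config(seed = config$seed,
                       n_per_platform = config$n_per_platform)
    }
    sim <- generate_corpus(sim_cfg)
    corp <- sim$corpus
    truth <- sim$truth
  } else if (is.character(corp)) {
    corp <- read_corpus(corp)
  }
  stopifnot(inherits(corp, "vax_corpus"))

  bundle <- list(summaries = summarize_platforms(corp))
  labeled <- !anyNA(corp$comments$label) && nrow(corp$comments) > 0

  if (labeled) {
    bundle$table <- tabulate_categories(corp)
    bundle$fractions <- category_fractions(bundle$table)
    bundle$anti_share <- anti_vaccine_share(bundle$table, corp$codebook)
  } else {
    skipped$tabulation <- "corpus has unlabeled comments; category stages skipped"
  }

  ann <- config$annotations
  if (is.character(ann) && identical(ann, "simulate") && !is.null(truth)) {
    ann <- generate_annotations(truth, truth$config)
  } else if (is.character(ann) && file.exists(ann)) {
    ann <- read_annotations(ann)
  }
  if (inherits(ann, "vax_annotations")) {
    bundle$reliability <- krippendorff_alpha(ann)
  } else {
    skipped$reliability <- "no annotations supplied; reliability skipped"
  }

  if (labeled) {
    docs <- preprocess_corpus(corp, config$preprocess)
    stats <- compute_term_stats(docs)
    rel <- relevance_score(stats, lambda = config$lambda)
    bundle$keywords <- rank_keywords(rel, top_n = config$top_n)
  } else {
    skipped$keywords <- "corpus has unlabeled comments; keyword stage skipped"
  }

  if (labeled) {
    dists <- tryCatch(anti_category_distributions(bundle$table, corp$codebook),
                      error = function(e) {
                        skipped$similarity <<- conditionMessage(e)
                        NULL
                      })
    if (!is.null(dists)) {
      bundle$distributions <- dists
      bundle$similarity <- similarity_matrix(dists)
      anti <- intersect(rownames(bundle$table),
                        as.character(anti_ids(corp$codebook)))
      anti_tab <- new_contingency(bundle$table[anti, , drop = FALSE])
      pruned <- prune_zero_expected(anti_tab)
      hom <- chi_square_homogeneity(pruned$table)
      hom$removed <- pruned$removed
      bundle$homogeneity <- hom
      bundle$pairwise <- pairwise_posthoc(pruned$table, alpha = config$alpha)
    }
  } else {
    skipped$similarity <- "corpus has unlabeled comments; comparison stages skipped"
  }

  bundle$skipped <- skipped
  bundle$meta <- list(
    package_version = as.character(utils::packageVersion("vaxtalk")),
    seed = config$seed, lambda = config$lambda, top_n = config$top_n,
    alpha = config$alpha, n_comments = n_comments(corp))
  structure(bundle, class = "vax_report_bundle")
}

#' Render a report bundle as Markdown
#'
#' Mirrors the usual result layout of a cross-platform content analysis:
#' a per-platform summary table, the category count table with fractions
#' and the anti-vaccine share, the reliability estimate, per-category
#' keywords, the cosine similarity matrix, and the homogeneity test battery
#' with pruning decisions disclosed. Skipped stages are rendered with an
#' explicit notice, never dropped silently.
#'
#' @param bundle A `vax_report_bundle`.
#' @return Character vector of Markdown lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "vax_report_bundle"))
  out <- c("# Cross-platform vaccine discourse report", "")

  out <- c(out, "## Platform summaries", "",
           "| Platform | Comments | Sum of reactions | Mean length (words) |",
           "|---|---|---|---|")
  s <- bundle$summaries
  out <- c(out, sprintf("| %s | %d | %d | %.3g |", s$platform, s$n_comments,
                        s$sum_reactions, s$mean_length_words), "")

  if (!is.null(bundle$table)) {
    out <- c(out, "## Categories", "",
             "| Category | Count | Fraction |", "|---|---|---|",
             sprintf("| %s | %d | %.3f |", rownames(bundle$table),
                     rowSums(bundle$table), bundle$fractions),
             "",
             sprintf("Anti-vaccine share: %.1f%%", 100 * bundle$anti_share), "")
  } else {
    out <- c(out, "## Categories", "", paste0("_Skipped: ", bundle$skipped$tabulation, "_"), "")
  }

  out <- c(out, "## Interrater reliability", "")
  if (!is.null(bundle$reliability)) {
    out <- c(out, sprintf("Krippendorff's alpha (nominal): %.3f over %d double-coded items.",
                          bundle$reliability$alpha, bundle$reliability$n_items_used), "")
  } else {
    out <- c(out, paste0("_Skipped: ", bundle$skipped$reliability, "_"), "")
  }

  out <- c(out, "## Keywords by category", "")
  if (!is.null(bundle$keywords)) {
    kw <- bundle$keywords
    for (cat_id in unique(kw$category_id)) {
      terms <- kw$term[kw$category_id == cat_id]
      out <- c(out, sprintf("- category %s: %s", cat_id, paste(terms, collapse = ", ")))
    }
    out <- c(out, "")
  } else {
    out <- c(out, paste0("_Skipped: ", bundle$skipped$keywords, "_"), "")
  }

  out <- c(out, "## Platform similarity and homogeneity", "")
  if (!is.null(bundle$similarity)) {
    sim <- bundle$similarity
    out <- c(out,
             paste0("| | ", paste(colnames(sim), collapse = " | "), " |"),
             paste0("|", strrep("---|", ncol(sim) + 1)))
    for (i in seq_len(nrow(sim))) {
      out <- c(out, paste0("| ", rownames(sim)[i], " | ",
                           paste(sprintf("%.3f", sim[i, ]), collapse = " | "), " |"))
    }
    hom <- bundle$homogeneity
    out <- c(out, "",
             sprintf("Omnibus chi-square: chi2 = %.4g, df = %d, p = %.3g.",
                     hom$chi2, hom$df, hom$p))
    out <- c(out, if (length(hom$removed)) {
      sprintf("Categories removed by the zero-expected-cell rule: %s.",
              paste(hom$removed, collapse = ", "))
    } else {
      "No categories removed by the zero-expected-cell rule."
    })
    pw <- bundle$pairwise
    out <- c(out, "",
             "| Pair | chi2 | df | p (raw) | p (Bonferroni) | Significant |",
             "|---|---|---|---|---|---|",
             sprintf("| %s vs %s | %.4g | %d | %.3g | %.3g | %s |",
                     pw$platform_a, pw$platform_b, pw$chi2, pw$df,
                     pw$p_raw, pw$p_adjusted, ifelse(pw$significant, "yes", "no")),
             "")
  } else {
    out <- c(out, paste0("_Skipped: ", bundle$skipped$similarity, "_"), "")
  }
  out
}

#' Write a report bundle's machine-readable files
#'
#' Writes the keyword TSV, similarity CSV, homogeneity JSON (omnibus plus
#' pairwise results), and the Markdown report to `outdir`. All files are
#' UTF-8; machine files carry full numeric precision.
#'
#' @param bundle A `vax_report_bundle`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$keywords)) {
    write_keywords(bundle$keywords, file.path(outdir, "keywords.tsv"))
  }
  if (!is.null(bundle$similarity)) {
    write_similarity_csv(bundle$similarity, file.path(outdir, "similarity.csv"))
  }
  if (!is.null(bundle$homogeneity)) {
    hom <- bundle$homogeneity
    payload <- list(
      omnibus = list(chi2 = hom$chi2, df = hom$df, p = hom$p,
                     removed = hom$removed),
      pairwise = bundle$pairwise)
    jsonlite::write_json(payload, file.path(outdir, "homogeneity.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(render_report(bundle), file.path(outdir, "report.md"),
             useBytes = TRUE)
  invisible(outdir)
}
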