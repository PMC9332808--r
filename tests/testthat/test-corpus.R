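test_that("CSV corpora parse with labels, auto ids, and verbatim text", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("platform,text,reactions,label",
               "facebook,\"I love vaccines \U0001F489\",10,0",
               "twitter,never ever,3,1",
               "twitter,\"freedom, always\",2,1",
               "tiktok,zażółć gęślą jaźń,1,3"), path, useBytes = FALSE)
  corp <- read_corpus(path)
  expect_equal(n_comments(corp), 4)
  expect_equal(corp$comments$id, paste0("c", 1:4))
  expect_equal(sum(corp$comments$label %in% anti_ids(corp$codebook)), 3)
  expect_match(corp$comments$text[1], "\U0001F489")
  expect_equal(corp$comments$text[4], "zażółć gęślą jaźń")
})

test_that("an empty file yields an empty corpus without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_equal(n_comments(read_corpus(path)), 0)
})

test_that("schema and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("platform,text", "facebook,hi"), path)
  expect_error(read_corpus(path), class = "vaxtalk_schema_error",
               regexp = "reactions")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("platform,text,reactions", "facebook,hi,-2"), path2)
  expect_error(read_corpus(path2), class = "vaxtalk_validation_error")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("platform,text,reactions,label", "facebook,hi,2,99"), path3)
  expect_error(read_corpus(path3), class = "vaxtalk_validation_error",
               regexp = "1")
  expect_error(
    corpus(tibble::tibble(id = c("x", "x"), platform = "facebook",
                          text = "t", reactions = 1L)),
    class = "vaxtalk_validation_error")
})

test_that("write/read round-trips corpus content field-for-field", {
  corp <- toy_corpus()
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_corpus(corp, path)
    back <- read_corpus(path)
    expect_equal(back$comments, corp$comments, info = fmt)
  }
})

test_that("JSONL round-trip preserves unlabeled comments and emojis", {
  corp <- corpus(tibble::tibble(
    platform = c("facebook", "tiktok"),
    text = c("emoji \U0001F600 stays", "plain"),
    reactions = c(1L, 0L), label = c(NA_integer_, 2L)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(back$comments, corp$comments)
})

test_that("top-by-reactions selection keeps the most reacted comments", {
  cm <- tibble::tibble(
    id = paste0("c", 1:5), platform = "facebook",
    text = "t", reactions = c(10L, 7L, 7L, 3L, 1L), label = NA_integer_)
  corp <- corpus(cm)
  top <- select_top_by_reactions(corp, 3)
  expect_setequal(top$comments$reactions, c(10L, 7L, 7L))
  # n larger than the platform keeps everything, with a warning
  expect_warning(all5 <- select_top_by_reactions(corp, 10))
  expect_equal(n_comments(all5), 5)
})

test_that("ties at the cut resolve by stable input order", {
  cm <- tibble::tibble(
    id = c("first", "tie1", "tie2"), platform = "twitter",
    text = "t", reactions = c(5L, 4L, 4L), label = NA_integer_)
  top <- select_top_by_reactions(corpus(cm), 2)
  expect_equal(top$comments$id, c("first", "tie1"))
})

test_that("top selection is idempotent", {
  sim <- generate_corpus(synthetic_config(seed = 3, n_per_platform = 40))
  once <- select_top_by_reactions(sim$corpus, 20)
  twice <- select_top_by_reactions(once, 20)
  expect_equal(twice$comments, once$comments)
})

test_that("platform summaries compute word counts and reaction sums", {
  corp <- corpus(tibble::tibble(
    platform = "facebook",
    text = c("one two three four", "a b c d e f"),
    reactions = c(1L, 2L)))
  s <- summarize_platforms(corp)
  expect_equal(s$mean_length_words, 5)
  expect_equal(s$sum_reactions, 3L)
  one <- summarize_platforms(corpus(tibble::tibble(
    platform = "tiktok", text = "just three words", reactions = 0L)))
  expect_equal(one$mean_length_words, 3)
})

test_that("the reference fixture reproduces the published summary table", {
  s <- summarize_platforms(reference_corpus())
  expect_equal(s, reference_platform_summaries())
  # and survives a write/read round trip unchanged
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(reference_corpus(), path)
  expect_equal(summarize_platforms(read_corpus(path)),
               reference_platform_summaries())
})

test_that("tabulation counts labels per platform and demands full labeling", {
  corp <- corpus(tibble::tibble(
    platform = "facebook", text = "t", reactions = 0L,
    label = c(0L, 0L, 1L)))
  tab <- tabulate_categories(corp)
  expect_equal(unname(tab["0", "facebook"]), 2L)
  expect_equal(unname(tab["1", "facebook"]), 1L)
  fr <- category_fractions(tab)
  expect_equal(unname(fr[c("0", "1")]), c(2 / 3, 1 / 3))
  bad <- corpus(tibble::tibble(
    id = "naughty", platform = "facebook", text = "t",
    reactions = 0L, label = NA_integer_))
  expect_error(tabulate_categories(bad), class = "vaxtalk_validation_error",
               regexp = "naughty")
})

test_that("tabulation conserves mass and fractions sum to one", {
  for (seed in 1:3) {
    sim <- generate_corpus(synthetic_config(seed = seed, n_per_platform = 60))
    tab <- tabulate_categories(sim$corpus)
    expect_equal(sum(tab), n_comments(sim$corpus))
    expect_equal(sum(category_fractions(tab)), 1, tolerance = 1e-12)
  }
})

test_that("anti-vaccine share behaves at its extremes and complements exactly", {
  all_pos <- corpus(tibble::tibble(platform = "facebook", text = "t",
                                   reactions = 0L, label = c(0L, 0L)))
  expect_equal(anti_vaccine_share(tabulate_categories(all_pos)), 0)
  all_anti <- corpus(tibble::tibble(platform = "facebook", text = "t",
                                    reactions = 0L, label = c(3L, 7L)))
  expect_equal(anti_vaccine_share(tabulate_categories(all_anti)), 1)
  tab <- tabulate_categories(toy_corpus())
  pos_share <- sum(tab["0", ]) / sum(tab)
  expect_identical(anti_vaccine_share(tab) + pos_share, 1)
})

test_that("codebooks validate and round-trip through JSON and YAML", {
  cb <- default_codebook()
  expect_equal(length(anti_ids(cb)), 14)
  expect_equal(positive_ids(cb), 0L)
  for (fmt in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_codebook(cb, path)
    back <- read_codebook(path)
    expect_equal(as.data.frame(back), as.data.frame(cb), info = fmt)
  }
  expect_error(codebook(data.frame(id = c(1, 1), description = "d",
                                   polarity = "anti")),
               class = "vaxtalk_validation_error")
})
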