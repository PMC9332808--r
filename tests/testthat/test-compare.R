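test_that("anti-vaccine distributions exclude the positive category and normalize", {
  cm <- tibble::tibble(
    platform = rep(c("facebook", "twitter"), each = 4),
    text = "t", reactions = 0L,
    label = c(1L, 1L, 2L, 2L, 0L, 1L, 3L, 3L))
  tab <- tabulate_categories(corpus(cm))
  d <- anti_category_distributions(tab)
  expect_equal(nrow(d), 14)
  expect_equal(unname(colSums(d)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(d["1", "facebook"]), 0.5)
  expect_equal(unname(d["2", "facebook"]), 0.5)
  expect_false("0" %in% rownames(d))
  # a platform with zero anti comments is an error naming the platform
  only_pos <- tabulate_categories(corpus(tibble::tibble(
    platform = c("facebook", "twitter"), text = "t", reactions = 0L,
    label = c(1L, 0L))))
  expect_error(anti_category_distributions(only_pos),
               class = "vaxtalk_data_error", regexp = "twitter")
})

test_that("equal platform spreads of the published counts give the marginal vector", {
  counts <- reference_category_counts()
  tab <- matrix(rep(counts, 4), ncol = 4,
                dimnames = list(names(counts), canonical_platforms()))
  d <- anti_category_distributions(vaxtalk:::new_contingency(tab))
  expect_equal(unname(d["1", ]), rep(156 / 729, 4), tolerance = 1e-12)
  expect_equal(unname(d[, "facebook"]), unname(counts[-1] / 729),
               tolerance = 1e-12)
})

test_that("cosine similarity matches its defining identities", {
  x <- c(0.2, 0.3, 0.5)
  expect_equal(cosine_similarity(x, x), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5,
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), class = "vaxtalk_data_error")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)),
               class = "vaxtalk_parameter_error")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  two <- cbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  expect_equal(unclass(similarity_matrix(two)),
               matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  withr::local_seed(41)
  four <- matrix(runif(14 * 4), 14, 4,
                 dimnames = list(NULL, canonical_platforms()))
  s <- similarity_matrix(four)
  expect_equal(dim(s), c(4L, 4L))
  expect_equal(unclass(s), t(unclass(s)))
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_equal(length(unique(signif(s[upper.tri(s)], 12))), 6)
})

test_that("cosine is scale invariant: raw counts equal normalized frequencies", {
  withr::local_seed(42)
  for (i in 1:50) {
    x <- rpois(14, 5) + 1
    y <- rpois(14, 5) + 1
    expect_equal(cosine_similarity(x, y),
                 cosine_similarity(x / sum(x), y / sum(y)), tolerance = 1e-12)
    expect_equal(cosine_similarity(10 * x, y), cosine_similarity(x, y),
                 tolerance = 1e-12)
  }
})

test_that("zero-expected pruning removes exactly the right categories", {
  tab <- rbind(`1` = c(0L, 0L, 8L, 13L),
               `2` = c(0L, 5L, 8L, 13L),
               `3` = c(4L, 5L, 8L, 13L))
  colnames(tab) <- canonical_platforms()
  pruned <- prune_zero_expected(tab)
  expect_equal(pruned$removed, 1L)
  expect_equal(rownames(pruned$table), c("2", "3"))
  # no zero cells anywhere: identity
  dense <- tab[c("3", "3"), ]
  rownames(dense) <- c("3", "4")
  expect_equal(prune_zero_expected(dense)$removed, integer())
  # all categories removed: insufficient data
  sparse <- rbind(`1` = c(0L, 0L, 1L, 1L))
  colnames(sparse) <- canonical_platforms()
  expect_error(prune_zero_expected(sparse), class = "vaxtalk_data_error")
})

test_that("chi-square homogeneity matches the closed form and its edge cases", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2,
                dimnames = list(c("1", "2"), c("facebook", "twitter")))
  res <- chi_square_homogeneity(tab)
  expect_equal(res$chi2, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(res$chi2, 6.6667, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p, 0.0098, tolerance = 1e-2)

  ident <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
                  dimnames = list(c("1", "2", "3"), c("a", "b")))
  res0 <- chi_square_homogeneity(ident)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  expect_equal(chi_square_homogeneity(2 * tab)$chi2, 2 * res$chi2,
               tolerance = 1e-12)
  expect_equal(chi_square_homogeneity(2 * tab)$df, res$df)

  with_zero <- matrix(c(0, 5, 0, 7), 2, 2,
                      dimnames = list(c("1", "2"), c("a", "b")))
  expect_error(chi_square_homogeneity(with_zero),
               class = "vaxtalk_data_error", regexp = "prune")
})

test_that("post-hoc pairwise tests cover all pairs with Bonferroni adjustment", {
  withr::local_seed(43)
  sim <- generate_corpus(preset_platform_profiles(seed = 5))
  tab <- tabulate_categories(sim$corpus)
  anti <- tab[as.character(1:14), , drop = FALSE]
  pruned <- prune_zero_expected(anti)
  pw <- pairwise_posthoc(pruned$table, alpha = 0.05)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_adjusted >= pw$p_raw, na.rm = TRUE))
  ok <- !is.na(pw$p_raw)
  expect_equal(pw$p_adjusted[ok], pmin(1, 6 * pw$p_raw[ok]), tolerance = 1e-12)
  expect_equal(pw$significant[ok], pw$p_adjusted[ok] < 0.05)

  # identical columns: p = 1, never significant
  same <- matrix(c(5L, 9L, 5L, 9L), 2, 2,
                 dimnames = list(c("1", "2"), c("a", "b")))
  pw2 <- pairwise_posthoc(same)
  expect_equal(pw2$p_raw, 1, tolerance = 1e-12)
  expect_equal(pw2$p_adjusted, 1)
  expect_false(pw2$significant)
})
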