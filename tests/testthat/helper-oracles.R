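# Brute-force Krippendorff alpha oracle: enumerates every ordered pairable
# pair directly, without building a coincidence matrix. Returns NA when no
# item is pairable or when expected disagreement is zero.
brute_alpha <- function(m) {
  units <- apply(m, 1, function(r) r[!is.na(r)], simplify = FALSE)
  units <- units[lengths(units) >= 2]
  if (length(units) == 0) return(NA_real_)
  n <- sum(lengths(units))
  disagree_w <- 0
  for (u in units) {
    mu <- length(u)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j && u[i] != u[j]) disagree_w <- disagree_w + 1 / (mu - 1)
      }
    }
  }
  D_o <- disagree_w / n
  pooled <- unlist(units, use.names = FALSE)
  disagree_e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && pooled[i] != pooled[j]) disagree_e <- disagree_e + 1
    }
  }
  D_e <- disagree_e / (n * (n - 1))
  if (D_e == 0) return(NA_real_)
  if (D_o == 0) 1 else 1 - D_o / D_e
}

# Large-sample expectation of alpha under the coder-copy model: coder 1
# draws the true label from pi over C categories; coder 2 copies it with
# probability q, otherwise draws uniformly from the other C - 1 categories.
# Observed disagreement is 1 - q; expected disagreement is 1 - sum(q_c^2)
# with q_c the pooled label marginal over both coders (the n/(n-1) finite-
# sample factor vanishes for the item counts used in tests).
expected_alpha_copy_model <- function(q, pi) {
  C <- length(pi)
  r <- q * pi + (1 - q) * (1 - pi) / (C - 1)   # coder 2 marginal
  qc <- (pi + r) / 2
  if (q == 1) return(1)
  1 - (1 - q) / (1 - sum(qc^2))
}

# Small random annotation grid with optional missingness, for property tests.
random_grid <- function(n_items, n_coders, n_cats, p_missing = 0) {
  m <- matrix(sample(letters[seq_len(n_cats)], n_items * n_coders, replace = TRUE),
              nrow = n_items)
  if (p_missing > 0) m[runif(length(m)) < p_missing] <- NA
  m
}

# A tiny labeled corpus used across tests.
toy_corpus <- function() {
  corpus(tibble::tibble(
    id = c("a", "b", "c", "d"),
    platform = c("facebook", "facebook", "twitter", "twitter"),
    text = c("Vaccines are safe and effective",
             "I will never get vaccinated",
             "freedom of choice matters",
             "trust the data"),
    reactions = c(10L, 5L, 3L, 1L),
    label = c(0L, 1L, 1L, 4L)))
}
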