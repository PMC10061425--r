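test_that("concentration vector prefers metadata, falls back to totals", {
  ct <- count_table(matrix(c(40L, 60L, 100L, 200L), 2, 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))),
                    unassigned = c(0, 0))
  md <- metadata(data.frame(md_conc = c(2.0, 4.0), kit = c("A", "B"),
                            row.names = c("s1", "s2")),
                 kinds = c(md_conc = "numeric", kit = "categorical"))
  expect_equal(unname(concentration_vector(ct, md, "md_conc")), c(2, 4))
  # fallback: column sums (100, 300) plus unassigned (0, 0)
  expect_equal(unname(concentration_vector(ct)), c(100, 300))
  expect_error(concentration_vector(ct, md, "kit"), "not numeric")
  expect_error(concentration_vector(ct, md, "absent"), "not found")
})

test_that("frequency score hits the analytic edge cases", {
  conc <- c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512)
  # perfect inverse law: the contaminant model fits exactly
  expect_equal(frequency_score(0.5 / conc, conc), 0)
  # constant frequency: the non-contaminant model fits exactly
  expect_equal(frequency_score(rep(0.01, 10), conc), 1)
  # fewer usable samples than min_samples -> undefined
  expect_true(is.na(frequency_score(c(0.1, 0.2), c(1, 2), min_samples = 5)))
  # zero-frequency and zero-concentration samples are excluded
  f <- c(rep(0.01, 10), 0); cc <- c(conc, 5)
  expect_equal(frequency_score(f, cc), 1)
  expect_equal(frequency_score(c(rep(0.01, 10), 0.5), c(conc, 0)), 1)
})

test_that("noisy inverse-law observations score as contaminants", {
  withr::with_seed(42, {
    lc <- runif(30, 0, 2)
    lf <- -lc + rnorm(30, sd = 0.1)
  })
  p <- frequency_score(10^lf, 10^lc)
  expect_lt(p, 0.05)
  expect_equal(p, oracle_freq_score(10^lf, 10^lc), tolerance = 1e-9)
})

test_that("frequency score equals the constrained least-squares oracle", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      n <- sample(5:40, 1)
      conc <- 10^runif(n, -1, 2)
      slope <- runif(1, -1.5, 0.5)
      freqs <- 10^(slope * log10(conc) + rnorm(n, sd = runif(1, 0.05, 0.6)))
      freqs[runif(n) < 0.15] <- 0  # dropouts
    })
    expect_equal(frequency_score(freqs, conc),
                 oracle_freq_score(freqs, conc), tolerance = 1e-9)
  }
})

test_that("prevalence score is the exact one-sided hypergeometric tail", {
  # 3/3 controls vs 0/5 samples: C(3,3)C(5,0)/C(8,3) = 1/56
  expect_equal(prevalence_score(3, 3, 0, 5), 1 / 56, tolerance = 1e-12)
  expect_equal(prevalence_score(0, 3, 5, 5), 1)   # opposite direction
  expect_equal(prevalence_score(3, 3, 5, 5), 1)   # present everywhere
  expect_true(is.na(prevalence_score(0, 0, 1, 2)))
})

test_that("prevalence score matches exhaustive enumeration up to n=12", {
  for (n_c in 1:11) for (n_s in 1:(12 - n_c))
    for (k_c in 0:n_c) for (k_s in 0:n_s)
      expect_equal(prevalence_score(k_c, n_c, k_s, n_s),
                   oracle_hyper(k_c, n_c, k_s, n_s), tolerance = 1e-12,
                   label = sprintf("k_c=%d n_c=%d k_s=%d n_s=%d",
                                   k_c, n_c, k_s, n_s))
})

test_that("more presence in controls never weakens the evidence", {
  for (n_c in c(3, 6)) for (n_s in c(4, 6)) for (k_s in 0:n_s) {
    p <- vapply(0:n_c, function(k_c) prevalence_score(k_c, n_c, k_s, n_s),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("Fisher combination behaves at the anchors", {
  expect_equal(combine_scores(1, 1), 1)
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(combine_scores(0.05, 0.05), oracle_chisq4_sf(x),
               tolerance = 1e-12)
  expect_equal(combine_scores(0.05, 0.05), 0.0175, tolerance = 2e-3)
  expect_true(is.na(combine_scores(NA, 0.5)))
  expect_true(is.na(combine_scores(0.5, NA)))
})

test_that("score_all keeps undefined-score records and validates inputs", {
  st <- small_study()
  # an observation present in only 2 biological samples: p_freq undefined
  m <- st$table$counts
  rare <- which(rowSums(m[, 1:12] > 0) >= 2)[1]
  m[rare, ] <- 0L
  m[rare, 1:2] <- 1L
  tbl <- count_table(m, unassigned = st$table$unassigned)
  sc <- score_all(tbl, st$metadata, st$controls, conc_field = "dna_conc",
                  min_samples = 5)
  row <- sc[sc$observation_id == rownames(m)[rare], ]
  expect_equal(nrow(row), 1L)
  expect_true(is.na(row$p_freq))
  expect_false(isTRUE(row$flagged))
  expect_error(score_all(tbl, st$metadata, controls = NULL,
                         method = "prevalence"), "control")
  expect_error(score_all(tbl, st$metadata, st$controls,
                         control_group = "nope"), "unknown control group")
})

test_that("flagging is governed by the requested method", {
  st <- small_study()
  for (method in c("frequency", "prevalence", "combined")) {
    sc <- score_all(st$table, st$metadata, st$controls,
                    conc_field = "dna_conc", method = method)
    expect_equal(nrow(sc), nrow(st$table$counts))
    governing <- switch(method, frequency = sc$p_freq,
                        prevalence = sc$p_prev, combined = sc$p_combined)
    expect_equal(sc$score, governing)
    expect_true(all(!sc$flagged | !is.na(sc$score)))
    expect_true(all(stats::na.omit(sc$score) >= 0 &
                      stats::na.omit(sc$score) <= 1))
  }
})
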