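# shared fixtures and independent oracles

# strip transform tags so matrices compare against bare oracle output
bare <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

make_table <- function(counts, unassigned = NULL) {
  count_table(counts, unassigned = unassigned)
}

# deterministic random count table
rand_table <- function(n_obs, n_smp, seed, lambda = 20, zero_frac = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_obs * n_smp, lambda), n_obs, n_smp)
    m[runif(length(m)) < zero_frac] <- 0L
    # keep every sample non-empty
    for (j in seq_len(n_smp)) if (sum(m[, j]) == 0) m[1, j] <- 1L
    dimnames(m) <- list(sprintf("o%02d", seq_len(n_obs)),
                        sprintf("s%02d", seq_len(n_smp)))
    count_table(m)
  })
}

write_tsv_fixture <- function(lines, path = withr::local_tempfile(
                                fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# 6-node fixture tree: root > Bacteria > Proteo > Ralstonia > 2 species
fixture_tax <- function() {
  taxonomy_db(data.frame(
    id = c("1", "2", "1224", "48736", "305", "1597"),
    parent = c("1", "1", "2", "1224", "48736", "48736"),
    rank = c("no rank", "superkingdom", "phylum", "genus", "species",
             "species"),
    name = c("root", "Bacteria", "Proteobacteria", "Ralstonia",
             "Ralstonia pickettii", "Ralstonia insidiosa"),
    stringsAsFactors = FALSE))
}

# memoized default-parameter synthetic study (seed 7)
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study()
    cache
  }
})

small_study <- function(seed = 5)
  generate_study(n_bio = 12, n_ctrl = 4, n_obs = 16, n_contam = 4,
                 seed = seed, depth_mean = 5000)

# --- independent oracles ----------------------------------------------------

# clr by direct evaluation of ln(x / geometric mean), per sample
oracle_clr <- function(counts, pseudo) {
  x <- counts * 1.0
  x[x == 0] <- pseudo
  apply(x, 2L, function(col) log(col / exp(mean(log(col)))))
}

# F CDF through the incomplete beta relation (independent of stats::pf)
oracle_f_cdf <- function(q, d1, d2) {
  pbeta(d1 * q / (d1 * q + d2), d1 / 2, d2 / 2)
}

# frequency score by explicit residual sums + beta-based F CDF
oracle_freq_score <- function(freqs, conc, min_samples = 5) {
  use <- !is.na(freqs) & !is.na(conc) & freqs > 0 & conc > 0
  n <- sum(use)
  if (n < min_samples) return(NA_real_)
  y0 <- log10(freqs[use])
  y1 <- log10(freqs[use]) + log10(conc[use])
  ss0 <- sum((y0 - sum(y0) / n)^2)
  ss1 <- sum((y1 - sum(y1) / n)^2)
  if (ss1 == 0 && ss0 == 0) return(0.5)
  if (ss1 == 0) return(0)
  if (ss0 == 0) return(1)
  oracle_f_cdf(ss1 / ss0, n - 1, n - 1)
}

# one-sided hypergeometric tail by direct enumeration with choose()
oracle_hyper <- function(k_c, n_c, k_s, n_s) {
  present <- k_c + k_s
  total <- n_c + n_s
  js <- max(0, present - n_s):min(n_c, present)
  probs <- choose(present, js) * choose(total - present, n_c - js) /
    choose(total, n_c)
  sum(probs[js >= k_c])
}

# rho via the covariance identity 2*cov/(var+var)
oracle_rho_cov <- function(a) {
  n <- nrow(a)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(a), rownames(a))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- 2 * cov(a[i, ], a[j, ]) / (var(a[i, ]) + var(a[j, ]))
    out[i, j] <- out[j, i] <- r
  }
  out
}

# chi-square(4) upper tail in closed form: (1 + x/2) * exp(-x/2)
oracle_chisq4_sf <- function(x) (1 + x / 2) * exp(-x / 2)
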