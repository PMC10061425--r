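#' Per-sample DNA concentration, with total-count fallback
#'
#' Returns the metadata concentration field when one is named; otherwise the
#' per-sample total counts (column sum + unassigned) stand in as an indirect
#' concentration proxy. Samples with missing or non-positive values are not
#' removed here — the frequency fit excludes them downstream.
#'
#' @param table a [count_table]
#' @param metadata optional `sample_metadata`
#' @param conc_field name of a numeric metadata field, or `NULL` for the
#'   total-count fallback
#' @return named numeric vector over the table's samples
#' @export
concentration_vector <- function(table, metadata = NULL, conc_field = NULL) {
  if (!is.null(conc_field)) {
    if (is.null(metadata) || !conc_field %in% colnames(metadata))
      kstop("concentration_vector", "metadata field not found: ", conc_field)
    if (metadata_kinds(metadata)[[conc_field]] != "numeric")
      kstop("concentration_vector", "field '", conc_field, "' is not numeric")
    stats::setNames(as.numeric(metadata[[conc_field]]), rownames(metadata))
  } else {
    kmsg("concentration_vector: no concentration field, using total counts")
    sample_totals(table)
  }
}

#' Frequency-based contamination score
#'
#' Contaminants contribute a roughly fixed number of reads per sample, so
#' their relative frequency varies inversely with DNA concentration, while
#' genuine community members hold a frequency independent of concentration.
#' Both hypotheses are fit as intercept-only models in log10 space — slope 0
#' for "not contaminant" (`y0 = log10 freq`) and slope -1 for "contaminant"
#' (`y1 = log10 freq + log10 conc`) — and compared through the ratio of
#' their residual sums of squares via the F distribution with
#' `(n - 1, n - 1)` degrees of freedom. A low score means the contaminant
#' model fits better.
#'
#' @param freqs per-sample relative frequencies of one observation
#' @param conc per-sample concentrations (same order)
#' @param min_samples minimum number of usable samples (freq > 0 and
#'   conc > 0); below it the score is undefined (`NA`) rather than
#'   unreliable
#' @return score in \[0, 1\], or `NA` when fewer than `min_samples` usable
#'   samples exist
#' @export
frequency_score <- function(freqs, conc, min_samples = 5) {
  stopifnot(length(freqs) == length(conc))
  use <- !is.na(freqs) & !is.na(conc) & freqs > 0 & conc > 0
  n <- sum(use)
  if (n < min_samples) return(NA_real_)
  y0 <- log10(freqs[use])
  y1 <- y0 + log10(conc[use])
  ss_non <- sum((y0 - mean(y0))^2)
  ss_cont <- sum((y1 - mean(y1))^2)
  if (ss_cont == 0 && ss_non == 0) return(0.5)
  if (ss_cont == 0) return(0)
  if (ss_non == 0) return(1)
  stats::pf(ss_cont / ss_non, n - 1, n - 1)
}

#' Prevalence-based contamination score
#'
#' One-sided exact (hypergeometric) test on the 2x2 presence/absence table,
#' with the alternative that the observation is more prevalent in control
#' samples than in biological samples. A low score means control-enriched,
#' i.e. contaminant-like.
#'
#' @param k_c number of control samples where the observation is present
#' @param n_c number of control samples
#' @param k_s number of biological samples where the observation is present
#' @param n_s number of biological samples
#' @return score in (0, 1\], or `NA` when either sample set is empty
#' @export
prevalence_score <- function(k_c, n_c, k_s, n_s) {
  if (n_c < 1 || n_s < 1) return(NA_real_)
  stopifnot(k_c >= 0, k_c <= n_c, k_s >= 0, k_s <= n_s)
  present <- k_c + k_s
  stats::phyper(k_c - 1, m = present, n = (n_c + n_s) - present, k = n_c,
                lower.tail = FALSE)
}

#' Combine frequency and prevalence scores (Fisher's method)
#'
#' `X = -2 (ln p_freq + ln p_prev)` referred to the upper tail of a
#' chi-square distribution with 4 degrees of freedom. Undefined inputs
#' propagate to an undefined combined score.
#'
#' @param p_freq frequency score
#' @param p_prev prevalence score
#' @return combined score, or `NA` if either input is `NA`
#' @export
combine_scores <- function(p_freq, p_prev) {
  if (is.na(p_freq) || is.na(p_prev)) return(NA_real_)
  if (p_freq == 0 || p_prev == 0) return(0)
  x <- -2 * (log(p_freq) + log(p_prev))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Score every observation of a table for contamination evidence
#'
#' Computes frequency, prevalence and combined scores per observation.
#' The frequency model is fitted on the non-control samples only (controls
#' carry contaminant-dominated compositions that would distort the inverse
#' frequency-concentration relationship); the prevalence test compares the
#' designated control group (or the union of all groups) against the
#' remaining samples. Presence means count strictly greater than
#' `presence_threshold`.
#'
#' @param table a [count_table] (optionally rank-decomposed)
#' @param metadata optional `sample_metadata`
#' @param controls optional `control_groups`; required for the prevalence
#'   and combined methods
#' @param conc_field numeric metadata field holding DNA concentration;
#'   `NULL` falls back to total counts (see [concentration_vector()])
#' @param method governing score: `"combined"` (default), `"frequency"` or
#'   `"prevalence"`
#' @param threshold observations whose governing score falls strictly below
#'   this are flagged (default 0.1)
#' @param min_samples minimum usable samples for the frequency fit
#' @param control_group name of the group to use; `NULL` takes the union
#' @param presence_threshold minimum count for presence (default 0: any
#'   positive count)
#' @param include_unassigned include unassigned counts in the frequency
#'   denominator
#' @return data.frame with one row per observation: `observation_id`,
#'   `rank`, `p_freq`, `p_prev`, `p_combined`, `score` (the governing
#'   score), `n_samples_used`, `flagged`, `method`
#' @export
score_all <- function(table, metadata = NULL, controls = NULL,
                      conc_field = NULL,
                      method = c("combined", "frequency", "prevalence"),
                      threshold = 0.1, min_samples = 5, control_group = NULL,
                      presence_threshold = 0, include_unassigned = TRUE) {
  method <- match.arg(method)
  smp <- sample_ids(table)
  ctrl <- character(0)
  if (!is.null(controls)) {
    ctrl <- if (!is.null(control_group)) {
      if (!control_group %in% names(controls))
        kstop("score_all", "unknown control group: ", control_group)
      controls[[control_group]]
    } else unique(unlist(controls))
  }
  if (method %in% c("prevalence", "combined") && length(ctrl) == 0L)
    kstop("score_all", "method '", method,
          "' requires at least one control group")
  is_ctrl <- smp %in% ctrl
  need_freq <- method %in% c("frequency", "combined")
  need_prev <- method %in% c("prevalence", "combined")

  totals <- if (include_unassigned) sample_totals(table)
            else colSums(table$counts)
  conc <- concentration_vector(table, metadata, conc_field)[smp]
  bio <- !is_ctrl & totals > 0
  freq_bio <- sweep(table$counts[, bio, drop = FALSE], 2L, totals[bio], "/")
  conc_bio <- conc[bio]

  present <- table$counts > presence_threshold
  n_c <- sum(is_ctrl); n_s <- sum(!is_ctrl)
  obs <- observation_ids(table)

  p_freq <- rep(NA_real_, length(obs))
  p_prev <- rep(NA_real_, length(obs))
  n_used <- integer(length(obs))
  for (i in seq_along(obs)) {
    if (need_freq) {
      f <- freq_bio[i, ]
      usable <- sum(!is.na(f) & f > 0 & !is.na(conc_bio) & conc_bio > 0)
      n_used[i] <- usable
      p_freq[i] <- frequency_score(f, conc_bio, min_samples = min_samples)
    }
    if (need_prev)
      p_prev[i] <- prevalence_score(sum(present[i, is_ctrl]), n_c,
                                    sum(present[i, !is_ctrl]), n_s)
  }
  p_comb <- if (method == "combined")
    mapply(combine_scores, p_freq, p_prev) else rep(NA_real_, length(obs))
  score <- switch(method, frequency = p_freq, prevalence = p_prev,
                  combined = p_comb)
  flagged <- !is.na(score) & score < threshold
  kmsg(sprintf("score_all: %d/%d observations flagged (method=%s, threshold=%g)",
               sum(flagged), length(obs), method, threshold))
  data.frame(observation_id = obs,
             rank = attr(table, "rank") %||% NA_character_,
             p_freq = p_freq, p_prev = p_prev, p_combined = p_comb,
             score = score, n_samples_used = n_used, flagged = flagged,
             method = method, stringsAsFactors = FALSE, row.names = NULL)
}
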