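#' Abundance matrix constructor
#'
#' A real-valued observations x samples matrix tagged with the transform
#' that produced it (`counts`, `norm`, `log`, `clr`) and the pseudo-count
#' used for zero replacement, if any.
#'
#' @param values numeric matrix with dimnames
#' @param transform transform tag
#' @param pseudo pseudo-count used, or `NA`
#' @export
abundance_matrix <- function(values,
                             transform = c("counts", "norm", "log", "clr"),
                             pseudo = NA_real_) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(values))
  structure(values, class = c("abundance_matrix", class(values)),
            transform = transform, pseudo_count = pseudo)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix (%s): %d observations x %d samples\n",
              attr(x, "transform"), nrow(x), ncol(x)))
  invisible(x)
}

#' Filter observations and samples of a count table
#'
#' Observation filters run first (total count, prevalence), then sample
#' filters (total count), each applied once. The unassigned counts are not
#' touched by observation filters; removed samples drop their unassigned
#' entry along with their column.
#'
#' @param table a [count_table]
#' @param min_total_count observations with total count below this are removed
#' @param min_prevalence observations present (count > 0) in fewer than
#'   `min_prevalence * n_samples` samples are removed; fraction in \[0, 1\]
#' @param min_sample_total samples whose total (column sum + unassigned)
#'   falls below this are removed
#' @return the filtered [count_table]
#' @export
filter_table <- function(table, min_total_count = 0, min_prevalence = 0,
                         min_sample_total = 0) {
  stopifnot(min_total_count >= 0, min_prevalence >= 0, min_prevalence <= 1,
            min_sample_total >= 0)
  m <- table$counts
  keep_obs <- rowSums(m) >= min_total_count &
    rowSums(m > 0) >= min_prevalence * ncol(m)
  if (!any(keep_obs))
    kstop("filter_table", "all observations removed by filtering")
  kmsg(sprintf("filter_table: removed %d/%d observations",
               sum(!keep_obs), nrow(m)))
  m <- m[keep_obs, , drop = FALSE]
  keep_smp <- colSums(m) + as.numeric(table$unassigned) >= min_sample_total
  if (!any(keep_smp))
    kstop("filter_table", "all samples removed by filtering")
  kmsg(sprintf("filter_table: removed %d/%d samples",
               sum(!keep_smp), ncol(m)))
  count_table(m[, keep_smp, drop = FALSE],
              unassigned = table$unassigned[keep_smp])
}

#' Relative-abundance normalisation
#'
#' Divides each sample's counts by its total. With
#' `include_unassigned = TRUE` (default) the denominator is the column sum
#' plus the unassigned count, so columns sum to at most 1 and the shortfall
#' is the unassigned fraction; otherwise columns sum to exactly 1.
#'
#' @param table a [count_table]
#' @param include_unassigned include unassigned counts in the denominator
#' @return an [abundance_matrix] tagged `"norm"`
#' @export
normalize_relative <- function(table, include_unassigned = TRUE) {
  denom <- if (include_unassigned) sample_totals(table)
           else colSums(table$counts)
  if (any(denom <= 0))
    kstop("normalize_relative", "zero-total sample(s): ",
          paste(sample_ids(table)[denom <= 0], collapse = ", "))
  abundance_matrix(sweep(table$counts, 2L, denom, "/"), "norm")
}

#' Replace zeros with a pseudo-count
#'
#' @param m numeric matrix or [count_table]
#' @param pseudo positive replacement value for zero cells
#' @return numeric matrix with zeros replaced; other cells unchanged
#' @export
replace_zeros <- function(m, pseudo) {
  if (inherits(m, "count_table")) m <- m$counts
  if (!is.numeric(pseudo) || length(pseudo) != 1L || pseudo <= 0)
    kstop("replace_zeros", "pseudo-count must be a single positive number")
  m <- m * 1.0
  m[m == 0] <- pseudo
  m
}

#' Centered log-ratio transform
#'
#' Treats each sample (column) as one composition: zeros are replaced by
#' `pseudo`, then `clr(o, s) = ln x\[o, s\] - mean_o(ln x\[., s\])`. Each
#' sample's clr values sum to zero (within 1e-9). Natural log is used; the
#' display-oriented [log_transform()] uses log10.
#'
#' @param table a [count_table] or numeric matrix of counts
#' @param pseudo positive pseudo-count for zero replacement (default 0.5,
#'   the conventional half count)
#' @return an [abundance_matrix] tagged `"clr"`
#' @export
clr_transform <- function(table, pseudo = 0.5) {
  x <- replace_zeros(table, pseudo)
  lx <- log(x)
  out <- sweep(lx, 2L, colMeans(lx), "-")
  abundance_matrix(out, "clr", pseudo = pseudo)
}

#' Element-wise log10 transform
#'
#' @param m numeric matrix, [abundance_matrix] or [count_table]
#' @param pseudo positive pseudo-count; required when zeros are present
#' @return an [abundance_matrix] tagged `"log"`
#' @export
log_transform <- function(m, pseudo = NULL) {
  if (inherits(m, "count_table")) m <- m$counts
  if (any(m < 0)) kstop("log_transform", "negative values cannot be log-transformed")
  if (any(m == 0)) {
    if (is.null(pseudo)) kstop("log_transform", "zeros present: pseudo-count required")
    m <- replace_zeros(m, pseudo)
  }
  abundance_matrix(log10(unclass(m) * 1.0), "log",
                   pseudo = pseudo %||% NA_real_)
}

#' Select the most abundant observations
#'
#' The `n` observations with the largest total counts; ties are broken
#' lexicographically by observation id. If the table has fewer than `n`
#' observations, all are returned.
#'
#' @param table a [count_table]
#' @param n number of observations to select
#' @return character vector of observation ids, most abundant first
#' @export
select_top_observations <- function(table, n) {
  stopifnot(n >= 1)
  totals <- rowSums(table$counts)
  ids <- observation_ids(table)
  ord <- order(-totals, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}
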