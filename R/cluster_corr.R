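#' Symmetric proportionality (rho) between top observations
#'
#' Proportionality is the association measure of choice for compositional
#' data: for clr-transformed observation vectors `a_i`, `a_j` across
#' samples, `rho_ij = 1 - var(a_i - a_j) / (var(a_i) + var(a_j))`
#' (sample variance, n - 1 denominator), which is algebraically
#' `2 cov(a_i, a_j) / (var(a_i) + var(a_j))` and lies in \[-1, 1\].
#' The clr transform is applied to the **full** table before subsetting to
#' `top_ids`, so the compositional reference (the per-sample geometric mean)
#' is not distorted by the selection.
#'
#' @param table a [count_table] with at least 3 samples
#' @param top_ids observation ids to correlate (at least 2), e.g. from
#'   [select_top_observations()]
#' @param pseudo pseudo-count for zero replacement in the clr step
#' @return a `correlation_matrix`: symmetric numeric matrix with unit
#'   diagonal over `top_ids`
#' @export
rho_matrix <- function(table, top_ids, pseudo = 0.5) {
  if (length(top_ids) < 2L)
    kstop("rho_matrix", "need at least 2 observations")
  if (ncol(table$counts) < 3L)
    kstop("rho_matrix", "need at least 3 samples for a stable variance")
  missing_ids <- setdiff(top_ids, observation_ids(table))
  if (length(missing_ids))
    kstop("rho_matrix", "unknown observation id(s): ",
          paste(missing_ids, collapse = ", "))
  a <- unclass(clr_transform(table, pseudo = pseudo))[top_ids, , drop = FALSE]
  n <- length(top_ids)
  v <- apply(a, 1L, stats::var)
  rho <- diag(1, n)
  dimnames(rho) <- list(top_ids, top_ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- v[i] + v[j]
    r <- if (denom == 0) 1 else 1 - stats::var(a[i, ] - a[j, ]) / denom
    rho[i, j] <- rho[j, i] <- r
  }
  structure(rho, class = c("correlation_matrix", class(rho)))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (rho): %d x %d, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

metric_dist <- function(items, metric) {
  switch(metric,
    euclidean = stats::dist(items, method = "euclidean"),
    braycurtis = {
      if (any(items < 0))
        kstop("hierarchical_cluster",
              "braycurtis requires non-negative values")
      vegan::vegdist(items, method = "bray")
    },
    correlation = stats::as.dist(1 - stats::cor(t(items))),
    kstop("hierarchical_cluster", "unknown metric: ", metric))
}

#' Agglomerative clustering of one axis of a matrix
#'
#' Standard hierarchical clustering over pairwise distances of the rows
#' (observations) or columns (samples). Items are sorted lexicographically
#' by id before the distance computation, so equal-height merge candidates
#' resolve to the lexicographically smallest pair and repeated runs are
#' byte-identical. The reported leaf order comes from a traversal of the
#' merge tree that places the smaller subtree first (ties: subtree with the
#' lexicographically smallest leaf first).
#'
#' @param m numeric matrix (observations x samples), e.g. an
#'   [abundance_matrix]
#' @param axis `"observations"` (rows) or `"samples"` (columns)
#' @param metric `"euclidean"`, `"braycurtis"` (non-negative data only) or
#'   `"correlation"`
#' @param method `"complete"`, `"average"`, `"single"` or `"ward"`
#'   (ward requires euclidean)
#' @return a `clustering_result`: list with `axis`, `metric`, `method`,
#'   `merges` (data.frame `a`, `b`, `height`; `a`/`b` are leaf ids or
#'   `"#k"` references to merge k) and `leaf_order`
#' @export
hierarchical_cluster <- function(m, axis = c("observations", "samples"),
                                 metric = c("euclidean", "braycurtis",
                                            "correlation"),
                                 method = c("complete", "average", "single",
                                            "ward")) {
  axis <- match.arg(axis); metric <- match.arg(metric)
  method <- match.arg(method)
  if (method == "ward" && metric != "euclidean")
    kstop("hierarchical_cluster", "ward linkage requires the euclidean metric")
  items <- if (axis == "samples") t(unclass(m)) else unclass(m)
  if (nrow(items) < 2L)
    kstop("hierarchical_cluster", "need at least 2 items on the ", axis,
          " axis")
  items <- items[order(rownames(items)), , drop = FALSE]
  ids <- rownames(items)
  d <- metric_dist(items, metric)
  hc <- stats::hclust(d, method = if (method == "ward") "ward.D2" else method)
  ordered <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    ordered[[i]] <- join_ordered(
      ordered_leaves(hc, hc$merge[i, 1L], ids, ordered),
      ordered_leaves(hc, hc$merge[i, 2L], ids, ordered))
  }
  leaf_order <- if (nrow(hc$merge) > 0L) ordered[[nrow(hc$merge)]] else ids
  merges <- data.frame(
    a = vapply(hc$merge[, 1L], function(k) if (k < 0) ids[-k]
               else paste0("#", k), character(1)),
    b = vapply(hc$merge[, 2L], function(k) if (k < 0) ids[-k]
               else paste0("#", k), character(1)),
    height = hc$height, stringsAsFactors = FALSE)
  structure(list(axis = axis, metric = metric, method = method,
                 merges = merges, leaf_order = leaf_order),
            class = "clustering_result")
}

ordered_leaves <- function(hc, k, ids, ordered) {
  if (k < 0) ids[-k] else ordered[[k]]
}

# smaller subtree first; equal sizes -> lexicographically smallest leaf first
join_ordered <- function(la, lb) {
  if (length(la) < length(lb)) c(la, lb)
  else if (length(lb) < length(la)) c(lb, la)
  else if (min(la) <= min(lb)) c(la, lb) else c(lb, la)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %s axis, %s/%s, %d leaves\n",
              x$axis, x$metric, x$method, length(x$leaf_order)))
  invisible(x)
}

#' Run a grid of clusterings
#'
#' One clustering per axis x metric x method combination; invalid
#' combinations (ward with a non-euclidean metric, braycurtis on
#' negative-valued data) are skipped with a warning.
#'
#' @param m numeric matrix (observations x samples)
#' @param metrics distance metrics to combine
#' @param methods linkage methods to combine
#' @param axes axes to cluster
#' @return named list of `clustering_result`s, keyed
#'   `"axis|metric|method"`
#' @export
cluster_grid <- function(m, metrics = c("euclidean", "braycurtis"),
                         methods = c("complete", "average"),
                         axes = c("observations", "samples")) {
  stopifnot(length(metrics) > 0, length(methods) > 0)
  out <- list()
  attempted <- 0L
  for (axis in axes) for (metric in metrics) for (method in methods) {
    attempted <- attempted + 1L
    key <- paste(axis, metric, method, sep = "|")
    res <- tryCatch(hierarchical_cluster(m, axis, metric, method),
                    error = function(e) {
                      kwarn("cluster_grid: skipping ", key, ": ",
                            conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) out[[key]] <- res
  }
  if (attempted > 0L && length(out) == 0L)
    kstop("cluster_grid", "all metric/method combinations were invalid")
  out
}
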