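#' Assemble all contamination evidence into one bundle
#'
#' Runs the full pipeline — filtering, taxonomic decomposition per rank,
#' transforms, contamination scores, reference/control/biome annotation,
#' clustering and proportionality correlation — and collects every result in
#' a serializable structure. The bundle, not the HTML rendering, is the
#' canonical machine-readable output. Inputs beyond the table are optional
#' and the bundle degrades gracefully: without a taxonomy a single
#' pseudo-rank `"default"` is used; without controls no contamination scores
#' are computed (unless `config$method = "frequency"` is forced).
#'
#' @param table a [count_table]
#' @param metadata optional `sample_metadata`
#' @param controls optional `control_groups`
#' @param tax optional [taxonomy_db]
#' @param refsets list of `reference_set`s
#' @param biome_summary optional `biome_summary`
#' @param config named list overriding the defaults: `ranks`, `input_kind`,
#'   `lineage_separator`, `min_total_count`, `min_prevalence`,
#'   `min_sample_total`, `pseudo_count` (0.5), `include_unassigned` (TRUE),
#'   `method`, `threshold` (0.1), `min_samples` (5), `conc_field`,
#'   `control_group`, `presence_threshold` (0), `top_n` (50), `metrics`,
#'   `methods`, `seed`
#' @return an `evidence_bundle`
#' @export
assemble_evidence <- function(table, metadata = NULL, controls = NULL,
                              tax = NULL, refsets = list(),
                              biome_summary = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  t0 <- proc.time()[["elapsed"]]
  stage_log <- function(stage, t_start)
    kmsg(sprintf("%s: %.2fs", stage, proc.time()[["elapsed"]] - t_start))

  ts <- proc.time()[["elapsed"]]
  table <- with_stage("filter", filter_table(
    table, cfg$min_total_count, cfg$min_prevalence, cfg$min_sample_total))
  stage_log("filter", ts)

  # default to the ranks actually present in the taxonomy, in ladder order
  ranks <- if (is.null(tax)) "default"
           else (cfg$ranks %||% intersect(tax$ranks, unique(tax$rank)))
  if (!is.null(tax) && length(ranks) == 0L)
    kstop("decompose", "taxonomy carries no rank from the configured ladder")
  if (!is.null(tax)) {
    bad <- setdiff(ranks, tax$ranks)
    if (length(bad))
      kstop("decompose", "rank(s) not in taxonomy: ",
            paste(bad, collapse = ", "))
  }
  lin <- if (!is.null(tax))
    with_stage("resolve", resolve_observations(
      table, tax, input_kind = cfg$input_kind,
      lineage_separator = cfg$lineage_separator)) else NULL

  method <- cfg$method
  if (is.null(method)) method <- if (!is.null(controls)) "combined" else "none"
  if (method %in% c("prevalence", "combined") && is.null(controls))
    kstop("scores", "method '", method, "' requires control groups")

  rank_sections <- lapply(ranks, function(r) {
    ts <- proc.time()[["elapsed"]]
    rt <- if (r == "default") table
          else with_stage("decompose", decompose_counts(table, lin, r))
    rlin <- if (is.null(tax)) NULL
            else with_stage("resolve",
                            resolve_observations(rt, tax, input_kind = "ids"))
    norm <- with_stage("transforms",
                       normalize_relative(rt, cfg$include_unassigned))
    clr <- with_stage("transforms", clr_transform(rt, cfg$pseudo_count))
    scores <- if (method == "none") NULL else
      with_stage("scores", score_all(
        rt, metadata, controls, conc_field = cfg$conc_field, method = method,
        threshold = cfg$threshold, min_samples = cfg$min_samples,
        control_group = cfg$control_group,
        presence_threshold = cfg$presence_threshold,
        include_unassigned = cfg$include_unassigned))
    annot <- with_stage("annotation", annotation_table(
      rt, lin = rlin, refsets = refsets, controls = controls,
      biome_summary = biome_summary))
    grid <- with_stage("clustering", {
      g1 <- if (nrow(rt$counts) >= 2L || ncol(rt$counts) >= 2L)
        cluster_grid(unclass(clr), setdiff(cfg$metrics, "braycurtis"),
                     cfg$methods) else list()
      g2 <- if ("braycurtis" %in% cfg$metrics)
        cluster_grid(unclass(norm), "braycurtis", cfg$methods) else list()
      c(g1, g2)
    })
    top_ids <- select_top_observations(rt, cfg$top_n)
    corr <- if (length(top_ids) >= 2L && ncol(rt$counts) >= 3L)
      with_stage("correlation", rho_matrix(rt, top_ids, cfg$pseudo_count))
      else NULL
    obs_df <- observation_summary(rt, rlin, scores)
    stage_log(paste0("rank ", r), ts)
    list(rank = r, counts = rt, observations = obs_df,
         transforms = list(norm = norm, clr = clr),
         scores = scores, annotation = annot,
         clusterings = grid, correlation = corr)
  })
  names(rank_sections) <- ranks

  md_sec <- if (is.null(metadata)) NULL else {
    kinds <- metadata_kinds(metadata)
    fields <- as.data.frame(metadata)
    attr(fields, "kinds") <- NULL
    class(fields) <- "data.frame"
    list(fields = fields, kinds = kinds,
         color_class = ifelse(kinds == "numeric", "sequential", "distinct"))
  }
  bundle <- structure(list(
    version = as.character(utils::packageVersion("kitomeR")),
    summary = list(
      n_observations = nrow(table$counts), n_samples = ncol(table$counts),
      total_counts = sum(as.numeric(table$counts)),
      total_unassigned = sum(as.numeric(table$unassigned)),
      sample_ids = sample_ids(table)),
    metadata = md_sec,
    controls = if (is.null(controls)) NULL else unclass(controls),
    ranks = rank_sections,
    provenance = list(parameters = cfg[order(names(cfg))],
                      seed = cfg$seed,
                      n_reference_sets = length(refsets),
                      reference_sets = vapply(refsets, `[[`, "", "name"),
                      has_taxonomy = !is.null(tax),
                      has_biome_summary = !is.null(biome_summary))),
    class = "evidence_bundle")
  stage_log("assemble_evidence total", t0)
  bundle
}

default_config <- function() {
  list(ranks = NULL, input_kind = "ids", lineage_separator = ";",
       min_total_count = 0, min_prevalence = 0, min_sample_total = 0,
       pseudo_count = 0.5, include_unassigned = TRUE, method = NULL,
       threshold = 0.1, min_samples = 5, conc_field = NULL,
       control_group = NULL, presence_threshold = 0, top_n = 50,
       metrics = c("euclidean", "braycurtis"),
       methods = c("complete", "average"), seed = 1L)
}

observation_summary <- function(rt, rlin, scores) {
  obs <- observation_ids(rt)
  nm <- attr(rt, "taxon_names")
  df <- data.frame(
    observation_id = obs,
    name = if (!is.null(nm)) unname(nm[obs]) else obs,
    total = unname(rowSums(rt$counts)),
    prevalence = unname(rowMeans(rt$counts > 0)),
    mean_rel_abundance = unname(rowMeans(
      sweep(rt$counts, 2L, pmax(sample_totals(rt), 1), "/"))),
    stringsAsFactors = FALSE)
  if (!is.null(scores))
    df <- cbind(df, scores[match(obs, scores$observation_id),
                           c("p_freq", "p_prev", "p_combined", "score",
                             "flagged"), drop = FALSE])
  rownames(df) <- NULL
  df
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("evidence_bundle v%s: %d observations x %d samples, ranks: %s\n",
              x$version, x$summary$n_observations, x$summary$n_samples,
              paste(names(x$ranks), collapse = ", ")))
  invisible(x)
}

# --- lossless JSON serialisation -------------------------------------------

enc_vec <- function(v) list(kind = typeof(v), values = as.list(unname(v)))

dec_vec <- function(e) {
  cast <- switch(e$kind, character = as.character, integer = as.integer,
                 double = as.double, logical = as.logical, identity)
  vapply(e$values, function(x) if (is.null(x)) cast(NA) else cast(x),
         cast(NA))
}

enc_matrix <- function(m) {
  list(kind = typeof(m), rows = as.list(rownames(m)),
       cols = as.list(colnames(m)),
       data = lapply(seq_len(nrow(m)), function(i) as.list(unname(m[i, ]))))
}

dec_matrix <- function(e) {
  rows <- unlist(e$rows); cols <- unlist(e$cols)
  vals <- unlist(lapply(e$data, function(r)
    vapply(r, function(x) if (is.null(x)) NA_real_ else as.double(x),
           double(1))))
  m <- matrix(vals, nrow = length(rows), byrow = TRUE,
              dimnames = list(rows, cols))
  if (e$kind == "integer") storage.mode(m) <- "integer"
  m
}

enc_df <- function(df) {
  list(rows = as.list(rownames(df)), cols = as.list(colnames(df)),
       columns = lapply(df, enc_vec))
}

dec_df <- function(e, default_rownames = FALSE) {
  cols <- unlist(e$cols)
  out <- as.data.frame(lapply(e$columns, dec_vec), check.names = FALSE,
                       stringsAsFactors = FALSE, optional = TRUE)
  if (length(cols) == 0L)
    out <- data.frame(row.names = unlist(e$rows))
  else {
    colnames(out) <- cols
    if (!default_rownames) rownames(out) <- unlist(e$rows)
  }
  out
}

enc_bundle <- function(b) {
  enc_table <- function(ct)
    list(counts = enc_matrix(ct$counts), unassigned = enc_vec(ct$unassigned),
         rank = attr(ct, "rank"),
         taxon_names = if (is.null(attr(ct, "taxon_names"))) NULL
                       else enc_vec(attr(ct, "taxon_names")))
  enc_abund <- function(am)
    list(transform = attr(am, "transform"),
         pseudo_count = attr(am, "pseudo_count"), values = enc_matrix(am))
  enc_clust <- function(cl)
    list(axis = cl$axis, metric = cl$metric, method = cl$method,
         merges = enc_df(cl$merges), leaf_order = as.list(cl$leaf_order))
  list(
    version = b$version,
    summary = list(n_observations = b$summary$n_observations,
                   n_samples = b$summary$n_samples,
                   total_counts = b$summary$total_counts,
                   total_unassigned = b$summary$total_unassigned,
                   sample_ids = as.list(b$summary$sample_ids)),
    metadata = if (is.null(b$metadata)) NULL else list(
      fields = enc_df(b$metadata$fields),
      kinds = enc_vec(b$metadata$kinds),
      color_class = enc_vec(b$metadata$color_class)),
    controls = if (is.null(b$controls)) NULL
               else lapply(b$controls, as.list),
    ranks = lapply(b$ranks, function(rs) list(
      rank = rs$rank,
      counts = enc_table(rs$counts),
      observations = enc_df(rs$observations),
      transforms = lapply(rs$transforms, enc_abund),
      scores = if (is.null(rs$scores)) NULL else enc_df(rs$scores),
      annotation = list(raw = enc_df(rs$annotation$raw),
                        normalized = enc_df(rs$annotation$normalized)),
      clusterings = lapply(rs$clusterings, enc_clust),
      correlation = if (is.null(rs$correlation)) NULL
                    else enc_matrix(unclass(rs$correlation)))),
    provenance = b$provenance)
}

dec_bundle <- function(e) {
  dec_table <- function(x) {
    ct <- count_table(dec_matrix(x$counts), unassigned = dec_vec(x$unassigned))
    if (!is.null(x$rank)) attr(ct, "rank") <- x$rank
    if (!is.null(x$taxon_names)) {
      tn <- dec_vec(x$taxon_names)
      names(tn) <- rownames(ct$counts)
      attr(ct, "taxon_names") <- tn
    }
    ct
  }
  dec_abund <- function(x)
    abundance_matrix(dec_matrix(x$values), x$transform,
                     pseudo = if (is.null(x$pseudo_count)) NA_real_
                              else as.double(x$pseudo_count))
  dec_clust <- function(x)
    structure(list(axis = x$axis, metric = x$metric, method = x$method,
                   merges = dec_df(x$merges, default_rownames = TRUE),
                   leaf_order = unlist(x$leaf_order)),
              class = "clustering_result")
  dec_prov <- function(p) {
    p$parameters <- lapply(p$parameters, function(v)
      if (is.list(v)) unlist(v) else v)
    p$reference_sets <- if (length(p$reference_sets))
      unlist(p$reference_sets) else character(0)
    names(p$reference_sets) <- NULL
    p
  }
  structure(list(
    version = e$version,
    summary = list(n_observations = as.integer(e$summary$n_observations),
                   n_samples = as.integer(e$summary$n_samples),
                   total_counts = as.double(e$summary$total_counts),
                   total_unassigned = as.double(e$summary$total_unassigned),
                   sample_ids = unlist(e$summary$sample_ids)),
    metadata = if (is.null(e$metadata)) NULL else {
      kinds <- dec_vec(e$metadata$kinds)
      fields <- dec_df(e$metadata$fields)
      names(kinds) <- colnames(fields)
      cc <- dec_vec(e$metadata$color_class)
      names(cc) <- colnames(fields)
      list(fields = fields, kinds = kinds, color_class = cc)
    },
    controls = if (is.null(e$controls)) NULL
               else lapply(e$controls, function(g) unlist(g)),
    ranks = lapply(e$ranks, function(rs) list(
      rank = rs$rank,
      counts = dec_table(rs$counts),
      observations = dec_df(rs$observations, default_rownames = TRUE),
      transforms = lapply(rs$transforms, dec_abund),
      scores = if (is.null(rs$scores)) NULL
               else dec_df(rs$scores, default_rownames = TRUE),
      annotation = list(raw = dec_df(rs$annotation$raw),
                        normalized = dec_df(rs$annotation$normalized)),
      clusterings = lapply(rs$clusterings, dec_clust),
      correlation = if (is.null(rs$correlation)) NULL
                    else structure(dec_matrix(rs$correlation),
                                   class = c("correlation_matrix", "matrix",
                                             "array")))),
    provenance = dec_prov(e$provenance)),
    class = "evidence_bundle")
}

bundle_json <- function(bundle) {
  jsonlite::toJSON(enc_bundle(bundle), auto_unbox = TRUE, digits = I(17),
                   null = "null", na = "null", pretty = FALSE)
}

#' Serialise an evidence bundle to JSON (and back)
#'
#' The write/read cycle is lossless: `read_bundle(write_bundle(b))` equals
#' `b`, and the bytes written are a deterministic function of the bundle (no
#' timestamps), so identical inputs and seed give byte-identical files.
#'
#' @param bundle an `evidence_bundle`
#' @param path output JSON file
#' @export
write_bundle <- function(bundle, path) {
  writeLines(bundle_json(bundle), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) kstop("read_bundle", "file not found: ", path)
  dec_bundle(jsonlite::read_json(path, simplifyVector = FALSE))
}
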