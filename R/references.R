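#' Load a reference set of taxa
#'
#' Reference sets link taxa (curated contaminants, human-related organisms,
#' or any custom group) to the literature sources reporting them. The file
#' is YAML: either a flat mapping `taxon: [source, ...]`, or entries of the
#' form `taxon: {id: ..., rank: ..., sources: [...]}`; an optional top-level
#' `name`/`entries` pair names the set. Duplicate sources per taxon are
#' deduplicated. When a [taxonomy_db] is supplied, entry names are resolved
#' to taxon ids (exact then case-insensitive match, ranked nodes preferred);
#' unresolvable entries are kept name-only with a warning.
#'
#' @param path YAML file
#' @param tax optional [taxonomy_db] for name resolution
#' @param name set name; defaults to the file's `name` field or basename
#' @return a `reference_set`: list with `name` and `entries`, each entry a
#'   list with `name`, `id` (possibly `NA`), `rank` (possibly `NA`) and
#'   `sources` (character)
#' @export
load_reference_set <- function(path, tax = NULL, name = NULL) {
  if (!file.exists(path)) kstop("load_reference_set", "file not found: ", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) kstop("load_reference_set",
                                          "malformed file: ",
                                          conditionMessage(e)))
  if (is.list(y) && !is.null(y$entries)) {
    set_name <- name %||% y$name %||% basename(path)
    y <- y$entries
  } else set_name <- name %||% sub("\\.[^.]+$", "", basename(path))
  if (!is.list(y) || length(y) == 0L)
    kstop("load_reference_set", "empty reference set: ", path)
  entries <- lapply(names(y), function(taxon) {
    v <- y[[taxon]]
    if (is.list(v) && !is.null(v$sources))
      list(name = taxon, id = as.character(v$id %||% NA_character_),
           rank = as.character(v$rank %||% NA_character_),
           sources = unique(as.character(v$sources)))
    else
      list(name = taxon, id = NA_character_, rank = NA_character_,
           sources = unique(as.character(v)))
  })
  if (!is.null(tax)) {
    by_name <- split(names(tax$name), tolower(tax$name))
    entries <- lapply(entries, function(e) {
      if (!is.na(e$id) && e$id %in% names(tax$parent)) return(e)
      ids <- by_name[[tolower(e$name)]] %||% character(0)
      if (length(ids) > 1L) ids <- ids[tax$rank[ids] %in% tax$ranks]
      if (length(ids) == 1L) e$id <- ids
      else kwarn("load_reference_set: entry '", e$name,
                 "' not resolvable in the taxonomy; kept name-only")
      e
    })
  }
  structure(list(name = set_name, entries = entries),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s': %d entries, %d distinct sources\n",
              x$name, length(x$entries),
              length(unique(unlist(lapply(x$entries, `[[`, "sources"))))))
  invisible(x)
}

#' Match observations against a reference set
#'
#' An observation hits a reference entry when the entry's taxon equals the
#' observation's own node or lies anywhere on its lineage — a species
#' observation inherits its genus-level contaminant annotation. Id matches
#' are preferred; name matches (case-insensitive) are the fallback. The hit
#' count is the number of distinct sources over all matched entries.
#'
#' @param lin a `lineage_map` from [resolve_observations()]
#' @param refset a `reference_set`
#' @return named integer vector of hit counts per observation
#' @export
match_references <- function(lin, refset) {
  vapply(names(lin$lineages), function(obs) {
    l <- lin$lineages[[obs]]
    if (nrow(l) == 0L) return(0L)
    lineage_names <- tolower(l$name)
    sources <- character(0)
    for (e in refset$entries) {
      hit <- (!is.na(e$id) && e$id %in% l$id) ||
        (tolower(e$name) %in% lineage_names)
      if (hit) sources <- union(sources, e$sources)
    }
    length(sources)
  }, integer(1))
}

#' Aggregate per-study contaminant reports at a rank
#'
#' Lifts each source's reported taxa to the requested rank and counts, per
#' rank-level taxon, how many sources report it — a source contributes at
#' most once per taxon even when it reports several of its children.
#'
#' @param study_lists named list, `source label -> character vector` of
#'   taxon ids (or names resolvable in `tax`)
#' @param tax a [taxonomy_db]
#' @param rank target rank
#' @return named integer vector, taxon id at `rank` -> number of sources
#' @export
aggregate_reference_report <- function(study_lists, tax, rank) {
  if (!rank %in% tax$ranks)
    kstop("aggregate_reference_report", "unknown rank: ", rank)
  by_name <- split(names(tax$name), tolower(tax$name))
  resolve <- function(t) {
    if (t %in% names(tax$parent)) return(t)
    ids <- by_name[[tolower(t)]] %||% character(0)
    if (length(ids) > 1L) ids <- ids[tax$rank[ids] %in% tax$ranks]
    if (length(ids) == 1L) ids else NA_character_
  }
  lift <- function(id) {
    path <- taxon_path(tax, id)
    at <- path[tax$rank[path] == rank]
    if (length(at)) at[length(at)] else NA_character_
  }
  counts <- new.env(parent = emptyenv())
  for (src in names(study_lists)) {
    ids <- vapply(study_lists[[src]], resolve, character(1))
    lifted <- unique(stats::na.omit(vapply(ids[!is.na(ids)], lift,
                                           character(1))))
    for (t in lifted)
      assign(t, (if (exists(t, envir = counts)) get(t, envir = counts)
                 else 0L) + 1L, envir = counts)
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) out <- stats::setNames(integer(0), character(0))
  out[order(names(out))]
}

#' Per-group control prevalence of each observation
#'
#' Fraction of the group's control samples where the observation is present
#' (count > 0).
#'
#' @param table a [count_table]
#' @param controls a `control_groups`
#' @return matrix observations x groups of fractions in \[0, 1\]
#' @export
control_prevalence <- function(table, controls) {
  present <- table$counts > 0
  out <- vapply(controls, function(g) {
    rowMeans(present[, sample_ids(table) %in% g, drop = FALSE])
  }, numeric(nrow(table$counts)))
  out <- matrix(out, nrow = nrow(table$counts),
                dimnames = list(observation_ids(table), names(controls)))
  out
}

#' Build a biome-occurrence summary from study profiles
#'
#' For each study the `top_n` most abundant taxa (ties broken
#' lexicographically by taxon id) are linked to every prefix level of the
#' study's biome lineage, each taxon counting once per study. The result
#' maps each taxon to how often it occurred among the top taxa of studies of
#' each biome, at every level of the biome hierarchy.
#'
#' @param study_profiles named list, `study -> named numeric` (taxon ->
#'   abundance)
#' @param study_biomes named list, `study -> biome lineage`: character
#'   vector of up to 5 levels, or a single `":"`-separated string
#' @param top_n number of taxa retained per study (default 10)
#' @return a `biome_summary`: list with `counts` (data.frame `taxon`,
#'   `biome`, `level`, `count`) and `totals` (named integer, studies per
#'   taxon)
#' @export
build_biome_summary <- function(study_profiles, study_biomes, top_n = 10) {
  stopifnot(top_n >= 1)
  acc <- new.env(parent = emptyenv())
  totals <- new.env(parent = emptyenv())
  bump <- function(env, key, by = 1L)
    assign(key, (if (exists(key, envir = env)) get(key, envir = env)
                 else 0L) + by, envir = env)
  for (study in names(study_profiles)) {
    prof <- study_profiles[[study]]
    if (length(prof) == 0L) {
      kwarn("build_biome_summary: study '", study, "' has an empty profile")
      next
    }
    lineage <- study_biomes[[study]]
    if (length(lineage) == 1L && grepl(":", lineage, fixed = TRUE))
      lineage <- strsplit(lineage, ":", fixed = TRUE)[[1L]]
    lineage <- lineage[seq_len(min(length(lineage), 5L))]
    sel <- names(prof)[order(-prof, names(prof))]
    sel <- sel[seq_len(min(top_n, length(sel)))]
    for (taxon in sel) {
      bump(totals, taxon)
      for (k in seq_along(lineage))
        bump(acc, paste(taxon, k, paste(lineage[seq_len(k)], collapse = ":"),
                        sep = "\r"))
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  counts <- data.frame(
    taxon = vapply(parts, `[[`, "", 1L),
    level = as.integer(vapply(parts, `[[`, "", 2L)),
    biome = vapply(parts, `[[`, "", 3L),
    count = vapply(keys, function(k) get(k, envir = acc), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- counts[order(counts$taxon, counts$level, counts$biome), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  tot <- unlist(as.list(totals))
  if (is.null(tot)) tot <- stats::setNames(integer(0), character(0))
  structure(list(counts = counts, totals = tot[order(names(tot))]),
            class = "biome_summary")
}

#' @export
print.biome_summary <- function(x, ...) {
  cat(sprintf("biome_summary: %d taxa, %d (taxon, biome, level) counts\n",
              length(x$totals), nrow(x$counts)))
  invisible(x)
}

#' Query biome occurrences for one taxon
#'
#' @param summary a `biome_summary`
#' @param taxon taxon id
#' @param level biome level, 1 to 5
#' @return data.frame `biome`, `count`, `fraction` (count over the taxon's
#'   total studies), sorted by count descending; empty for unknown taxa
#' @export
lookup_biomes <- function(summary, taxon, level) {
  stopifnot(level >= 1, level <= 5)
  rows <- summary$counts[summary$counts$taxon == taxon &
                           summary$counts$level == level, , drop = FALSE]
  if (nrow(rows) == 0L)
    return(data.frame(biome = character(0), count = integer(0),
                      fraction = numeric(0)))
  total <- summary$totals[[taxon]]
  out <- data.frame(biome = rows$biome, count = rows$count,
                    fraction = rows$count / total, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$biome), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a biome summary to TSV (and back)
#'
#' Columns: `taxon`, `biome`, `level`, `count`. Totals per taxon are the sum
#' of its level-1 counts and are rebuilt on read.
#'
#' @param summary a `biome_summary`
#' @param path TSV file
#' @export
write_biome_summary <- function(summary, path) {
  utils::write.table(summary$counts[c("taxon", "biome", "level", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biome_summary
#' @export
read_biome_summary <- function(path) {
  if (!file.exists(path)) kstop("read_biome_summary", "file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          colClasses = c("character", "character", "integer",
                                         "integer"))
  df <- df[c("taxon", "level", "biome", "count")]
  df <- df[order(df$taxon, df$level, df$biome), , drop = FALSE]
  rownames(df) <- NULL
  lvl1 <- df[df$level == 1L, , drop = FALSE]
  tot <- vapply(split(lvl1$count, lvl1$taxon), sum, integer(1))
  structure(list(counts = df, totals = tot[order(names(tot))]),
            class = "biome_summary")
}

#' Assemble normalized annotation tracks for a set of observations
#'
#' One column ("track") per reference set (distinct-source hit counts), per
#' control group (prevalence fraction) and, when a biome summary is given,
#' the number of studies where the observation's taxon occurred among the
#' top taxa. Each track is also normalized to \[0, 1\] by dividing by its
#' maximum (an all-zero track stays zero), so heterogeneous tracks share one
#' color scale in the report.
#'
#' @param table a [count_table]
#' @param lin optional `lineage_map` (required for reference matching)
#' @param refsets list of `reference_set`s
#' @param controls optional `control_groups`
#' @param biome_summary optional `biome_summary`
#' @return list with data.frames `raw` and `normalized` (rows =
#'   observations, columns = tracks)
#' @export
annotation_table <- function(table, lin = NULL, refsets = list(),
                             controls = NULL, biome_summary = NULL) {
  obs <- observation_ids(table)
  tracks <- list()
  if (!is.null(lin))
    for (rs in refsets)
      tracks[[rs$name]] <- as.numeric(match_references(lin, rs)[obs])
  if (!is.null(controls)) {
    cp <- control_prevalence(table, controls)
    for (g in colnames(cp)) tracks[[paste0("control:", g)]] <- cp[, g]
  }
  if (!is.null(biome_summary)) {
    key <- function(o) {
      if (o %in% names(biome_summary$totals)) return(o)
      if (!is.null(lin)) {
        l <- lin$lineages[[o]]
        if (!is.null(l) && nrow(l) > 0L) {
          leaf_name <- l$name[nrow(l)]
          if (leaf_name %in% names(biome_summary$totals)) return(leaf_name)
        }
      }
      NA_character_
    }
    tracks[["biomes"]] <- vapply(obs, function(o) {
      k <- key(o)
      if (is.na(k)) 0 else as.numeric(biome_summary$totals[[k]])
    }, numeric(1))
  }
  raw <- as.data.frame(tracks, check.names = FALSE, optional = TRUE)
  if (ncol(raw) == 0L) raw <- data.frame(row.names = obs)
  else rownames(raw) <- obs
  normalized <- raw
  for (j in seq_along(normalized)) {
    mx <- max(normalized[[j]])
    if (mx > 0) normalized[[j]] <- normalized[[j]] / mx
  }
  list(raw = raw, normalized = normalized)
}
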