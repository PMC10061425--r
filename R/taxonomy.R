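#' Default rank ladder (root to leaf)
#' @export
DEFAULT_RANKS <- c("superkingdom", "phylum", "class", "order",
                   "family", "genus", "species")

# rank-prefix map shared by the GTDB / GreenGenes lineage dialects
PREFIX_RANKS <- c(d = "superkingdom", k = "superkingdom", p = "phylum",
                  c = "class", o = "order", f = "family", g = "genus",
                  s = "species")

#' Construct a taxonomy database
#'
#' A rooted tree of taxa. The root is the unique node whose parent is itself
#' (or empty/NA). Ranks outside `ranks` are normalised to `"no rank"`.
#' Parent links must be acyclic and every node must reach the root.
#'
#' @param nodes data.frame with columns `id`, `parent`, `rank`, `name`
#' @param ranks ordered rank vector used for decomposition and tie-breaking
#' @return an object of class `taxonomy_db` with named lookup vectors
#'   `parent`, `rank`, `name`, the `root` id and the `ranks` ladder.
#' @export
taxonomy_db <- function(nodes, ranks = DEFAULT_RANKS) {
  stopifnot(all(c("id", "parent", "rank", "name") %in% colnames(nodes)))
  nodes <- as.data.frame(lapply(nodes[c("id", "parent", "rank", "name")],
                                as.character), stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) kstop("taxonomy_db", "empty taxonomy dump")
  if (anyDuplicated(nodes$id))
    kstop("taxonomy_db", "duplicate taxon id: ",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  is_root <- nodes$parent == nodes$id | is.na(nodes$parent) |
    !nzchar(nodes$parent)
  if (sum(is_root) != 1L)
    kstop("taxonomy_db", "expected exactly one root, found ", sum(is_root))
  root <- nodes$id[is_root]
  orphan <- !is_root & !(nodes$parent %in% nodes$id)
  if (any(orphan))
    kstop("taxonomy_db", "orphan node(s): ",
          paste(nodes$id[orphan], collapse = ", "))
  rank <- ifelse(nodes$rank %in% ranks, nodes$rank, "no rank")
  parent <- stats::setNames(nodes$parent, nodes$id)
  parent[root] <- root
  # cycle check: every chain must hit the root within n steps
  n <- nrow(nodes)
  for (id in nodes$id) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      if (cur == root) break
      cur <- parent[[cur]]
      if (step > n) kstop("taxonomy_db", "cycle detected at node ", id)
    }
    if (cur != root) kstop("taxonomy_db", "cycle detected at node ", id)
  }
  structure(list(parent = parent,
                 rank = stats::setNames(rank, nodes$id),
                 name = stats::setNames(nodes$name, nodes$id),
                 root = root, ranks = ranks),
            class = "taxonomy_db")
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("taxonomy_db: %d nodes, root '%s', ranks: %s\n",
              length(x$parent), x$root, paste(x$ranks, collapse = " > ")))
  invisible(x)
}

#' Load a taxonomy dump
#'
#' Normalises several taxonomy dump dialects into the one internal tree
#' model:
#' * `generic-tsv` — one TSV with header columns `id`, `parent`, `rank`,
#'   `name`;
#' * `ncbi` — `nodes.dmp` + `names.dmp` pair (`\t|\t`-separated, scientific
#'   names kept);
#' * `ott` — OpenTree `taxonomy.tsv` (`\t|\t`-separated, columns uid,
#'   parent_uid, name, rank);
#' * `gtdb`, `greengenes` — per-leaf lineage strings with `x__` rank
#'   prefixes (`accession<TAB>d__...;p__...;...`);
#' * `silva` — `tax_slv`-style rows (`lineage path<TAB>id<TAB>rank`).
#'
#' @param dump_paths character vector of dump files; `ncbi` expects
#'   `c(nodes = ..., names = ...)` (or two paths in that order)
#' @param dialect taxonomy dialect
#' @param ranks rank ladder for [taxonomy_db()]
#' @return a [taxonomy_db]
#' @export
load_taxonomy <- function(dump_paths,
                          dialect = c("generic-tsv", "ncbi", "gtdb", "silva",
                                      "greengenes", "ott"),
                          ranks = DEFAULT_RANKS) {
  dialect <- match.arg(dialect)
  for (p in dump_paths)
    if (!file.exists(p)) kstop("load_taxonomy", "file not found: ", p)
  nodes <- switch(dialect,
    "generic-tsv" = parse_generic_tsv(dump_paths[[1L]]),
    "ncbi"        = parse_ncbi(dump_paths),
    "ott"         = parse_ott(dump_paths[[1L]]),
    "gtdb"        = parse_prefixed_lineages(dump_paths[[1L]]),
    "greengenes"  = parse_prefixed_lineages(dump_paths[[1L]]),
    "silva"       = parse_silva(dump_paths[[1L]]))
  taxonomy_db(nodes, ranks = ranks)
}

parse_generic_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "#")
  need <- c("id", "parent", "rank", "name")
  if (!all(need %in% colnames(df)))
    kstop("load_taxonomy", "generic-tsv needs header columns: ",
          paste(need, collapse = ", "))
  df[need]
}

parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  parts
}

parse_ncbi <- function(paths) {
  if (!is.null(names(paths)) && all(c("nodes", "names") %in% names(paths))) {
    nodes_p <- paths[["nodes"]]; names_p <- paths[["names"]]
  } else {
    if (length(paths) < 2L)
      kstop("load_taxonomy", "ncbi dialect needs nodes.dmp and names.dmp")
    nodes_p <- paths[[1L]]; names_p <- paths[[2L]]
  }
  nd <- parse_dmp(nodes_p)
  nm <- parse_dmp(names_p)
  sci <- Filter(function(x) length(x) >= 4 && trimws(x[4]) == "scientific name", nm)
  name_map <- stats::setNames(vapply(sci, function(x) trimws(x[2]), ""),
                              vapply(sci, function(x) trimws(x[1]), ""))
  ids <- vapply(nd, function(x) trimws(x[1]), "")
  data.frame(id = ids,
             parent = vapply(nd, function(x) trimws(x[2]), ""),
             rank = vapply(nd, function(x) trimws(x[3]), ""),
             name = ifelse(is.na(name_map[ids]), ids, name_map[ids]),
             stringsAsFactors = FALSE)
}

parse_ott <- function(path) {
  rows <- parse_dmp(path)
  hdr <- trimws(rows[[1L]])
  iu <- match("uid", hdr); ip <- match("parent_uid", hdr)
  inm <- match("name", hdr); ir <- match("rank", hdr)
  if (anyNA(c(iu, ip, inm, ir)))
    kstop("load_taxonomy", "ott dump needs uid, parent_uid, name, rank columns")
  rows <- rows[-1L]
  data.frame(id = vapply(rows, function(x) trimws(x[iu]), ""),
             parent = vapply(rows, function(x) trimws(x[ip]), ""),
             rank = vapply(rows, function(x) trimws(x[ir]), ""),
             name = vapply(rows, function(x) trimws(x[inm]), ""),
             stringsAsFactors = FALSE)
}

# GTDB / GreenGenes style: leaf id <TAB> d__A;p__B;...;s__Z
parse_prefixed_lineages <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nodes <- list(list(id = "root", parent = "root", rank = "no rank",
                     name = "root"))
  seen <- new.env(parent = emptyenv()); assign("root", TRUE, envir = seen)
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) next
    leaf <- trimws(f[1L])
    toks <- trimws(strsplit(f[2L], ";", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(sub("^[a-z]__", "", toks))]
    parent <- "root"
    for (tok in toks) {
      pr <- sub("^([a-z])__.*$", "\\1", tok)
      nm <- sub("^[a-z]__", "", tok)
      rk <- if (pr %in% names(PREFIX_RANKS)) PREFIX_RANKS[[pr]] else "no rank"
      if (!exists(tok, envir = seen)) {
        nodes[[length(nodes) + 1L]] <- list(id = tok, parent = parent,
                                            rank = rk, name = nm)
        assign(tok, TRUE, envir = seen)
      }
      parent <- tok
    }
    if (!exists(leaf, envir = seen)) {
      nodes[[length(nodes) + 1L]] <- list(id = leaf, parent = parent,
                                          rank = "no rank", name = leaf)
      assign(leaf, TRUE, envir = seen)
    }
  }
  do.call(rbind, lapply(nodes, as.data.frame, stringsAsFactors = FALSE))
}

# SILVA tax_slv style: "Bacteria;Proteobacteria;...;"<TAB>taxid<TAB>rank
parse_silva <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  path_id <- new.env(parent = emptyenv())
  nodes <- list(list(id = "root", parent = "root", rank = "no rank",
                     name = "root"))
  recs <- lapply(lines, function(line) strsplit(line, "\t", fixed = TRUE)[[1L]])
  for (f in recs) {
    lineage <- sub(";$", "", trimws(f[1L]))
    assign(lineage, trimws(f[2L]), envir = path_id)
  }
  for (f in recs) {
    lineage <- sub(";$", "", trimws(f[1L]))
    id <- trimws(f[2L])
    rk <- if (length(f) >= 3L) trimws(f[3L]) else "no rank"
    toks <- strsplit(lineage, ";", fixed = TRUE)[[1L]]
    parent_path <- paste(toks[-length(toks)], collapse = ";")
    parent <- if (nzchar(parent_path) &&
                  exists(parent_path, envir = path_id))
      get(parent_path, envir = path_id) else "root"
    nodes[[length(nodes) + 1L]] <- list(id = id, parent = parent, rank = rk,
                                        name = toks[length(toks)])
  }
  do.call(rbind, lapply(nodes, as.data.frame, stringsAsFactors = FALSE))
}

# --- lineage resolution -----------------------------------------------------

taxon_path <- function(tax, id) {
  out <- character(0)
  cur <- id
  while (TRUE) {
    out <- c(cur, out)
    if (cur == tax$root) break
    cur <- tax$parent[[cur]]
  }
  out
}

#' Resolve observation labels against a taxonomy
#'
#' Matches observation ids directly against taxon ids (`"ids"`), by name —
#' exact first, then case-insensitive (`"names"`) — or leaf-first over the
#' tokens of a lineage string (`"lineage-strings"`). A name shared by
#' several taxa is resolved to the unique node carrying a rank from the
#' taxonomy's rank ladder; if that is still ambiguous the observation is
#' flagged unresolved (and kept). Resolution statistics are reported via
#' `message()` when `options(kitomeR.verbose = TRUE)`.
#'
#' @param table a [count_table]
#' @param tax a [taxonomy_db]
#' @param input_kind how observation ids should be interpreted
#' @param lineage_separator separator for `"lineage-strings"`
#' @return a `lineage_map`: list with `lineages` (named list of data.frames
#'   with columns `rank`, `id`, `name`, ordered root to leaf; zero rows when
#'   unresolved), `ranks`, and `unresolved` (character vector of ids).
#' @export
resolve_observations <- function(table, tax,
                                 input_kind = c("ids", "names",
                                                "lineage-strings"),
                                 lineage_separator = ";") {
  input_kind <- match.arg(input_kind)
  obs <- observation_ids(table)
  by_name <- split(names(tax$name), tax$name)
  by_lname <- split(names(tax$name), tolower(tax$name))

  match_name <- function(label) {
    ids <- by_name[[label]] %||% by_lname[[tolower(label)]] %||% character(0)
    if (length(ids) == 1L) return(ids)
    if (length(ids) > 1L) {
      ranked <- ids[tax$rank[ids] %in% tax$ranks]
      if (length(ranked) == 1L) return(ranked)
    }
    NA_character_
  }
  resolve_one <- function(label) {
    switch(input_kind,
      "ids" = if (label %in% names(tax$parent)) label else NA_character_,
      "names" = match_name(label),
      "lineage-strings" = {
        toks <- trimws(strsplit(label, lineage_separator, fixed = TRUE)[[1L]])
        toks <- rev(toks[nzchar(toks)])
        hit <- NA_character_
        for (tok in toks) {
          hit <- match_name(sub("^[a-z]__", "", tok))
          if (!is.na(hit)) break
        }
        hit
      })
  }
  lineages <- lapply(obs, function(label) {
    node <- resolve_one(label)
    if (is.na(node))
      return(data.frame(rank = character(0), id = character(0),
                        name = character(0), stringsAsFactors = FALSE))
    ids <- taxon_path(tax, node)
    data.frame(rank = unname(tax$rank[ids]), id = ids,
               name = unname(tax$name[ids]), stringsAsFactors = FALSE)
  })
  names(lineages) <- obs
  unresolved <- obs[vapply(lineages, nrow, 0L) == 0L]
  for (r in tax$ranks) {
    n_at <- sum(vapply(lineages, function(l) r %in% l$rank, logical(1)))
    kmsg(sprintf("resolve_observations: %d/%d observations have a %s ancestor",
                 n_at, length(obs), r))
  }
  kmsg(sprintf("resolve_observations: %d/%d resolved",
               length(obs) - length(unresolved), length(obs)))
  structure(list(lineages = lineages, ranks = tax$ranks,
                 unresolved = unresolved),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat(sprintf("lineage_map: %d observations (%d unresolved)\n",
              length(x$lineages), length(x$unresolved)))
  invisible(x)
}

# ancestor taxon id at `rank` for one observation, or NA
ancestor_at <- function(lin, obs, rank) {
  l <- lin$lineages[[obs]]
  if (is.null(l) || nrow(l) == 0L) return(NA_character_)
  hit <- which(l$rank == rank)
  if (length(hit) == 0L) NA_character_ else l$id[hit[length(hit)]]
}

#' Decompose a count table to a taxonomic rank
#'
#' Sums each observation's counts into its ancestor at the requested rank.
#' Observations with no ancestor at that rank (unresolved, or annotated above
#' it) are collected under the reserved `"(unannotated)"` observation, so
#' per-sample totals — including the unassigned count — are conserved
#' exactly.
#'
#' @param table a [count_table]
#' @param lin a `lineage_map` from [resolve_observations()]
#' @param rank target rank, one of `lin$ranks`
#' @return a [count_table] whose observation ids are taxon ids at `rank`
#'   (plus possibly `"(unannotated)"`), with attribute `taxon_names` for
#'   display.
#' @export
decompose_counts <- function(table, lin, rank) {
  if (!rank %in% lin$ranks)
    kstop("decompose_counts", "unknown rank: ", rank)
  obs <- observation_ids(table)
  group <- vapply(obs, function(o) {
    a <- ancestor_at(lin, o, rank)
    if (is.na(a)) UNANNOTATED_ID else a
  }, character(1))
  agg <- rowsum(table$counts, group = group, reorder = TRUE)
  out <- count_table(agg, unassigned = table$unassigned)
  nm <- rownames(agg)
  # display names from any lineage row carrying the id
  all_rows <- do.call(rbind, lin$lineages[vapply(lin$lineages, nrow, 0L) > 0])
  if (!is.null(all_rows)) {
    nm_map <- all_rows$name[match(nm, all_rows$id)]
    disp <- ifelse(is.na(nm_map), nm, nm_map)
  } else disp <- nm
  attr(out, "taxon_names") <- stats::setNames(disp, nm)
  attr(out, "rank") <- rank
  out
}
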