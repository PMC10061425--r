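#' Construct a count table
#'
#' The central container of the package: a matrix of raw integer counts with
#' observations (taxa, OTUs, ASVs, features) in rows and samples in columns,
#' plus an optional per-sample count of unassigned/unclassified units. The
#' per-sample total is the column sum plus the unassigned count, so
#' normalisation can account for the mass the quantification step could not
#' place.
#'
#' @param counts numeric matrix (observations x samples) of non-negative
#'   integers, with unique non-empty dimnames. Whole-valued doubles are cast
#'   to integer; fractional values are an error (raw-counts contract).
#' @param unassigned optional numeric vector of per-sample unassigned counts,
#'   recycled-length-checked against `ncol(counts)`. Defaults to all zero.
#' @return an object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `unassigned` (named integer vector).
#' @examples
#' m <- matrix(c(3L, 0L, 4L, 2L), 2, 2,
#'             dimnames = list(c("obsA", "obsB"), c("s1", "s2")))
#' ct <- count_table(m, unassigned = c(1, 0))
#' sample_totals(ct)
#' @export
count_table <- function(counts, unassigned = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    kstop("count_table", "empty table: need at least 1 observation and 1 sample")
  obs <- rownames(counts); smp <- colnames(counts)
  if (is.null(obs) || is.null(smp) || any(!nzchar(obs)) || any(!nzchar(smp)))
    kstop("count_table", "observation and sample ids must be non-empty")
  if (anyDuplicated(obs))
    kstop("count_table", "duplicate observation id: ",
          paste(unique(obs[duplicated(obs)]), collapse = ", "))
  if (anyDuplicated(smp))
    kstop("count_table", "duplicate sample id: ",
          paste(unique(smp[duplicated(smp)]), collapse = ", "))
  counts <- check_integral(counts, "count_table")
  if (is.null(unassigned)) unassigned <- rep(0L, ncol(counts))
  if (length(unassigned) != ncol(counts))
    kstop("count_table", "unassigned length (", length(unassigned),
          ") does not match number of samples (", ncol(counts), ")")
  unassigned <- check_integral(unassigned, "count_table")
  names(unassigned) <- smp
  structure(list(counts = counts, unassigned = unassigned),
            class = "count_table")
}

check_integral <- function(x, stage) {
  if (!is.numeric(x)) kstop(stage, "non-numeric counts")
  if (anyNA(x)) kstop(stage, "missing or non-numeric count cells")
  if (any(x < 0)) kstop(stage, "negative counts are not allowed")
  if (any(abs(x - round(x)) > 1e-8))
    kstop(stage, "non-integer counts: raw counts required")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d observations x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts: %.0f (+ %.0f unassigned)\n",
              sum(as.numeric(x$counts)), sum(as.numeric(x$unassigned))))
  invisible(x)
}

#' @rdname count_table
#' @param table a `count_table`
#' @export
observation_ids <- function(table) rownames(table$counts)

#' @rdname count_table
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Per-sample totals (assigned + unassigned)
#'
#' @param table a `count_table`
#' @return named numeric vector of per-sample totals, including the
#'   unassigned count. This quantity is conserved by rank decomposition and
#'   by read/write round-trips.
#' @export
sample_totals <- function(table) {
  colSums(table$counts) + as.numeric(table$unassigned)
}

#' Read a count table from TSV or BIOM
#'
#' TSV files must carry a header row; by default rows are observations and
#' columns are samples, and `transpose = TRUE` flips that interpretation.
#' BIOM input supports the JSON (1.0) and HDF5 (2.x) serialisations via the
#' biomformat package. A row whose id matches `unassigned_label`
#' (case-insensitively) is removed from the observations and stored as the
#' per-sample unassigned count.
#'
#' @param path input file
#' @param format one of "auto", "tsv", "biom"; "auto" decides by file
#'   extension (`.biom` is BIOM, everything else TSV)
#' @param transpose flip the TSV row/column interpretation
#'   (rows = samples). Ignored for BIOM, which is always observations x
#'   samples.
#' @param unassigned_label reserved observation id holding unassigned counts;
#'   `NULL` disables the special handling
#' @return a [count_table]
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom"),
                             transpose = FALSE,
                             unassigned_label = "unassigned") {
  format <- match.arg(format)
  if (!file.exists(path)) kstop("read_count_table", "file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  m <- if (format == "biom") read_matrix_biom(path) else read_matrix_tsv(path)
  if (format == "tsv" && isTRUE(transpose)) m <- t(m)
  unassigned <- NULL
  if (!is.null(unassigned_label)) {
    hit <- tolower(rownames(m)) == tolower(unassigned_label)
    if (sum(hit) > 1L)
      kstop("read_count_table", "duplicate observation id: ", unassigned_label)
    if (any(hit)) {
      unassigned <- m[hit, , drop = TRUE]
      m <- m[!hit, , drop = FALSE]
      if (nrow(m) == 0L)
        kstop("read_count_table", "table contains only the unassigned row")
    }
  }
  count_table(m, unassigned = unassigned)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) kstop("read_count_table", "TSV needs an id column and at least one sample column")
  ids <- df[[1L]]
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(vals)) kstop("read_count_table", "non-numeric count cell in ", path)
  vals
}

read_matrix_biom <- function(path) {
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  m
}

#' Write a count table to TSV or BIOM
#'
#' The inverse of [read_count_table()]: a write/read cycle reproduces the
#' table exactly (ids, counts, unassigned). A non-zero unassigned vector is
#' exported as an extra observation row labelled `unassigned_label`.
#'
#' @param table a [count_table]
#' @param path output file
#' @param format "tsv" or "biom"
#' @param unassigned_label label for the exported unassigned row
#' @return `path`, invisibly
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom"),
                              unassigned_label = "unassigned") {
  format <- match.arg(format)
  m <- table$counts
  if (any(table$unassigned > 0)) {
    if (tolower(unassigned_label) %in% tolower(rownames(m)))
      kstop("write_count_table", "observation id collides with unassigned label")
    m <- rbind(m, matrix(table$unassigned, nrow = 1,
                         dimnames = list(unassigned_label, colnames(m))))
  }
  if (format == "tsv") {
    df <- data.frame(observation = rownames(m), m, check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) kstop("write_count_table", "cannot write ", path)
  } else {
    b <- biomformat::make_biom(m)
    tryCatch(biomformat::write_biom(b, path),
             error = function(e) kstop("write_count_table", "cannot write ",
                                       path, ": ", conditionMessage(e)))
  }
  invisible(path)
}

#' Read sample metadata aligned to a count table
#'
#' Tabular metadata with the sample id in the first column. A field is typed
#' numeric when every non-missing value parses as a number, otherwise
#' categorical. Rows for samples absent from the table are dropped with a
#' warning; samples in the table without a metadata row get missing values.
#' The result rows follow the table's sample order.
#'
#' @param path metadata TSV
#' @param table a [count_table] to align against
#' @param na_tokens values treated as missing
#' @return a `sample_metadata`: a data.frame (rownames = sample ids in table
#'   order) with attribute `kinds`, a named character vector mapping each
#'   field to "numeric" or "categorical".
#' @export
read_metadata <- function(path, table, na_tokens = DEFAULT_NA_TOKENS) {
  if (!file.exists(path)) kstop("read_metadata", "file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    kstop("read_metadata", "duplicate sample id rows: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- ids %in% sample_ids(table)
  if (!any(keep))
    kstop("read_metadata", "no overlap between metadata and table sample ids")
  if (any(!keep))
    kwarn("read_metadata: dropping ", sum(!keep),
          " metadata sample(s) absent from the count table")
  df <- df[keep, , drop = FALSE]
  ids <- ids[keep]
  fields <- df[-1L]
  fields[] <- lapply(fields, function(v) {
    v[v %in% na_tokens] <- NA_character_
    v
  })
  kinds <- vapply(fields, function(v) {
    vv <- v[!is.na(v)]
    if (length(vv) > 0 && !anyNA(suppressWarnings(as.numeric(vv))))
      "numeric" else "categorical"
  }, character(1))
  fields[kinds == "numeric"] <- lapply(fields[kinds == "numeric"], as.numeric)
  # align to table order, missing samples become NA rows
  idx <- match(sample_ids(table), ids)
  out <- fields[idx, , drop = FALSE]
  rownames(out) <- sample_ids(table)
  metadata(out, kinds)
}

#' @rdname read_metadata
#' @param fields data.frame of per-sample fields (rownames = sample ids)
#' @param kinds named character vector ("numeric"/"categorical") per field
#' @export
metadata <- function(fields, kinds) {
  stopifnot(is.data.frame(fields), length(kinds) == ncol(fields))
  names(kinds) <- colnames(fields)
  structure(fields, kinds = kinds, class = c("sample_metadata", "data.frame"))
}

#' @export
print.sample_metadata <- function(x, ...) {
  k <- attr(x, "kinds")
  cat(sprintf("sample_metadata: %d samples, %d fields (%d numeric, %d categorical)\n",
              nrow(x), ncol(x), sum(k == "numeric"), sum(k == "categorical")))
  invisible(x)
}

metadata_kinds <- function(md) attr(md, "kinds")

#' Read groups of control samples
#'
#' Each file lists one sample id per line; `#` starts a comment. Ids not
#' present in the count table are dropped with a warning; a group left empty
#' is an error. Groups may overlap.
#'
#' @param paths named character vector or named list, `group name = path`
#' @param table a [count_table]
#' @return a named list of character vectors of sample ids
#'   (class `control_groups`)
#' @export
read_control_groups <- function(paths, table) {
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    kstop("read_control_groups", "control files must be named (group = path)")
  groups <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]; gname <- names(paths)[i]
    if (!file.exists(p)) kstop("read_control_groups", "file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    known <- lines %in% sample_ids(table)
    if (any(!known))
      kwarn("read_control_groups: group '", gname, "': dropping ",
            sum(!known), " id(s) not in the count table")
    ids <- unique(lines[known])
    if (length(ids) == 0L)
      kstop("read_control_groups", "group '", gname,
            "' has no samples matching the count table")
    ids
  })
  names(groups) <- names(paths)
  structure(groups, class = "control_groups")
}

#' @rdname read_control_groups
#' @param groups named list of character vectors of sample ids
#' @export
control_groups <- function(groups, table) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  groups <- lapply(groups, function(g) {
    g <- unique(as.character(g))
    bad <- setdiff(g, sample_ids(table))
    if (length(bad)) kstop("control_groups", "unknown sample id(s): ",
                           paste(bad, collapse = ", "))
    if (length(g) == 0L) kstop("control_groups", "empty control group")
    g
  })
  structure(groups, class = "control_groups")
}
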