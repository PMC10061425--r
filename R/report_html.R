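#' @importFrom grDevices colorRamp rgb
NULL

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

PAL_DISTINCT <- c("#4e79a7", "#f28e2b", "#e15759", "#76b7b2", "#59a14f",
                  "#edc948", "#b07aa1", "#ff9da7", "#9c755f", "#bab0ac",
                  "#1b9e77", "#7570b3")

ramp_hex <- function(v, colors) {
  f <- grDevices::colorRamp(colors)
  v <- pmin(pmax(v, 0), 1)
  cc <- f(v)
  grDevices::rgb(cc[, 1], cc[, 2], cc[, 3], maxColorValue = 255)
}

# diverging scale for clr / rho values, symmetric around 0
col_diverging <- function(v, lim = max(abs(v), 1e-9)) {
  ramp_hex((v / lim + 1) / 2, c("#2166ac", "#f7f7f7", "#b2182b"))
}

col_sequential <- function(v) ramp_hex(v, c("#f7fbff", "#08306b"))

svg_open <- function(w, h)
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
          w, h, w, h)

svg_rects <- function(x, y, w, h, fill, title = NULL) {
  t <- if (is.null(title)) "" else
    sprintf("<title>%s</title>", html_escape(title))
  paste0(sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s">',
                 x, y, w, h, fill), t, "</rect>", collapse = "")
}

svg_text <- function(x, y, s, size = 9, anchor = "start", rotate = NULL) {
  tr <- if (is.null(rotate)) "" else
    sprintf(' transform="rotate(%d %.1f %.1f)"', rotate, x, y)
  sprintf('<text x="%.1f" y="%.1f" font-size="%d" font-family="sans-serif" text-anchor="%s"%s>%s</text>',
          x, y, size, anchor, tr, html_escape(s))
}

# horizontal bar chart of named totals
svg_barplot <- function(values, width = 640, bar_h = 14, title = "") {
  n <- length(values)
  lab_w <- 160
  h <- n * (bar_h + 3) + 24
  mx <- max(values, 1)
  parts <- c(svg_open(width, h),
             svg_text(4, 14, title, size = 11))
  for (i in seq_len(n)) {
    y <- 20 + (i - 1) * (bar_h + 3)
    bw <- (width - lab_w - 60) * values[i] / mx
    parts <- c(parts,
               svg_text(lab_w - 4, y + bar_h - 3, names(values)[i],
                        anchor = "end"),
               svg_rects(lab_w, y, max(bw, 0.5), bar_h, PAL_DISTINCT[1],
                         title = sprintf("%s: %g", names(values)[i],
                                         values[i])),
               svg_text(lab_w + bw + 4, y + bar_h - 3,
                        format(values[i], big.mark = ",")))
  }
  paste0(c(parts, "</svg>"), collapse = "")
}

# per-sample stacked relative-abundance bars
svg_stacked_bars <- function(norm, sample_order, top_ids, height = 260) {
  ns <- length(sample_order)
  bw <- max(4, min(18, floor(860 / max(ns, 1))))
  width <- ns * (bw + 1) + 180
  cols <- stats::setNames(PAL_DISTINCT[(seq_along(top_ids) - 1) %%
                                         length(PAL_DISTINCT) + 1], top_ids)
  parts <- svg_open(width, height + 80)
  for (s in seq_len(ns)) {
    smp <- sample_order[s]
    x <- (s - 1) * (bw + 1)
    y <- height
    for (o in top_ids) {
      v <- norm[o, smp]
      hh <- v * height
      if (hh > 0.05) {
        parts <- c(parts, svg_rects(x, y - hh, bw, hh, cols[[o]],
                                    title = sprintf("%s / %s: %.3f",
                                                    smp, o, v)))
        y <- y - hh
      }
    }
    if (bw >= 8)
      parts <- c(parts, svg_text(x + bw / 2, height + 10, smp, size = 7,
                                 anchor = "end", rotate = -60))
  }
  lx <- ns * (bw + 1) + 10
  for (i in seq_along(top_ids)) {
    parts <- c(parts,
               svg_rects(lx, (i - 1) * 14, 10, 10, cols[[top_ids[i]]]),
               svg_text(lx + 14, (i - 1) * 14 + 9, top_ids[i], size = 8))
  }
  paste0(c(parts, "</svg>"), collapse = "")
}

# heatmap: rows = samples, columns = observations; per-sample metadata
# color columns on the right, per-observation annotation tracks below
svg_heatmap <- function(values, obs_order, smp_order, meta_colors = NULL,
                        annot = NULL, cell = NULL) {
  no <- length(obs_order); ns <- length(smp_order)
  cw <- cell %||% max(3, min(14, floor(800 / max(no, 1))))
  ch <- max(3, min(12, floor(420 / max(ns, 1))))
  lab_w <- 90
  n_meta <- if (is.null(meta_colors)) 0L else ncol(meta_colors)
  annot_h <- if (is.null(annot) || ncol(annot) == 0) 0 else
    ncol(annot) * (ch + 1) + 4
  width <- lab_w + no * cw + n_meta * (cw + 1) + 160
  height <- ns * ch + annot_h + 90
  lim <- max(abs(values), 1e-9)
  parts <- svg_open(width, height)
  for (i in seq_len(ns)) {
    smp <- smp_order[i]
    fills <- col_diverging(values[obs_order, smp], lim)
    parts <- c(parts,
               svg_text(lab_w - 4, (i - 1) * ch + ch - 1, smp,
                        size = 7, anchor = "end"),
               svg_rects((seq_len(no) - 1) * cw + lab_w,
                         rep((i - 1) * ch, no), cw, ch, fills))
    if (n_meta > 0)
      parts <- c(parts,
                 svg_rects(lab_w + no * cw + 6 + (seq_len(n_meta) - 1) *
                             (cw + 1),
                           rep((i - 1) * ch, n_meta), cw, ch,
                           meta_colors[smp, ]))
  }
  if (n_meta > 0)
    for (j in seq_len(n_meta))
      parts <- c(parts,
                 svg_text(lab_w + no * cw + 6 + (j - 1) * (cw + 1) + cw / 2,
                          ns * ch + 10, colnames(meta_colors)[j], size = 7,
                          anchor = "end", rotate = -60))
  ya <- ns * ch + (if (n_meta > 0) 24 else 4)
  if (!is.null(annot) && ncol(annot) > 0)
    for (j in seq_len(ncol(annot))) {
      v <- annot[obs_order, j]
      parts <- c(parts,
                 svg_text(lab_w - 4, ya + (j - 1) * (ch + 1) + ch - 1,
                          colnames(annot)[j], size = 8, anchor = "end"),
                 svg_rects((seq_len(no) - 1) * cw + lab_w,
                           rep(ya + (j - 1) * (ch + 1), no), cw, ch,
                           col_sequential(v)))
    }
  yl <- ya + (if (is.null(annot)) 0 else ncol(annot) * (ch + 1)) + 12
  if (cw >= 6)
    for (i in seq_len(no))
      parts <- c(parts, svg_text(lab_w + (i - 1) * cw + cw / 2, yl,
                                 obs_order[i], size = 7, anchor = "end",
                                 rotate = -60))
  paste0(c(parts, "</svg>"), collapse = "")
}

svg_corr_matrix <- function(rho) {
  ids <- rownames(rho)
  n <- length(ids)
  cw <- max(4, min(14, floor(560 / max(n, 1))))
  lab <- 110
  width <- lab + n * cw + 20
  height <- lab + n * cw + 20
  parts <- svg_open(width, height)
  for (i in seq_len(n)) {
    fills <- col_diverging(rho[i, ], 1)
    parts <- c(parts,
               svg_text(lab - 4, lab + (i - 1) * cw + cw - 1, ids[i],
                        size = 7, anchor = "end"),
               svg_rects(lab + (seq_len(n) - 1) * cw,
                         rep(lab + (i - 1) * cw, n), cw, cw, fills,
                         title = NULL))
  }
  if (cw >= 6)
    for (j in seq_len(n))
      parts <- c(parts, svg_text(lab + (j - 1) * cw + cw / 2, lab - 4,
                                 ids[j], size = 7, anchor = "end",
                                 rotate = -70))
  paste0(c(parts, "</svg>"), collapse = "")
}

html_table <- function(df, max_rows = 100) {
  df <- utils::head(df, max_rows)
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "",
                              formatC(v, digits = 4, format = "g"))
    else ifelse(is.na(v), "", as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  rows <- apply(cells, 1L, function(r)
    paste0("<tr><td>", paste(html_escape(r), collapse = "</td><td>"),
           "</td></tr>"))
  paste0("<table><thead><tr><th>",
         paste(html_escape(colnames(df)), collapse = "</th><th>"),
         "</th></tr></thead><tbody>", paste(rows, collapse = ""),
         "</tbody></table>")
}

metadata_color_matrix <- function(md, max_fields = 3) {
  if (is.null(md)) return(NULL)
  fields <- utils::head(colnames(md$fields), max_fields)
  if (length(fields) == 0) return(NULL)
  out <- sapply(fields, function(f) {
    v <- md$fields[[f]]
    if (md$kinds[[f]] == "numeric") {
      rng <- range(v, na.rm = TRUE)
      sc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
      sc[is.na(sc)] <- 0
      col_sequential(sc)
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      idx <- match(v, lev)
      cols <- PAL_DISTINCT[(idx - 1) %% length(PAL_DISTINCT) + 1]
      cols[is.na(idx)] <- "#dddddd"
      cols
    }
  })
  out <- matrix(out, nrow = nrow(md$fields),
                dimnames = list(rownames(md$fields), fields))
  out
}

REPORT_CSS <- "
body { font-family: sans-serif; margin: 0; background: #fafafa; }
nav { background: #263238; padding: 0 12px; }
nav a { display: inline-block; color: #eceff1; text-decoration: none;
        padding: 10px 14px; font-size: 14px; }
nav a:hover { background: #37474f; }
section { padding: 12px 18px; border-bottom: 2px solid #e0e0e0; }
h2 { font-size: 16px; color: #263238; }
h3 { font-size: 13px; color: #455a64; }
table { border-collapse: collapse; font-size: 11px; }
th, td { border: 1px solid #ccc; padding: 2px 6px; text-align: left; }
th { background: #eceff1; position: sticky; top: 0; }
.tablewrap { max-height: 420px; overflow: auto; background: #fff; }
.flagged { color: #b71c1c; font-weight: bold; }
"

BUNDLE_MARK_OPEN <- '<script id="evidence-bundle" type="application/json">'

#' Render a self-contained offline HTML report
#'
#' One HTML file, no external scripts, styles, images or fonts: every asset
#' is inlined and all charts are static inline SVG. The report has the four
#' panels — Overview (per-observation evidence table and top-abundance bar
#' plot), Samples (stacked relative-abundance bars, grouped by the first
#' categorical metadata field), Heatmap (clr values in clustered order with
#' metadata and annotation side bars, one per rank), Correlation (rho
#' matrix) — and embeds the full evidence bundle as JSON, recoverable with
#' [extract_bundle()].
#'
#' @param bundle an `evidence_bundle`
#' @param out_path output HTML file
#' @return `out_path`, invisibly
#' @export
render_report <- function(bundle, out_path) {
  json <- gsub("</", "<\\/", bundle_json(bundle), fixed = TRUE)
  first <- bundle$ranks[[1L]]
  md_cols <- metadata_color_matrix(bundle$metadata)

  overview <- c(sprintf("<h2>Overview</h2><p>%d observations x %d samples; %s total counts (+%s unassigned). Ranks: %s.</p>",
                        bundle$summary$n_observations,
                        bundle$summary$n_samples,
                        format(bundle$summary$total_counts, big.mark = ","),
                        format(bundle$summary$total_unassigned,
                               big.mark = ","),
                        html_escape(paste(names(bundle$ranks),
                                          collapse = ", "))))
  for (rs in bundle$ranks) {
    totals <- stats::setNames(rs$observations$total,
                              rs$observations$observation_id)
    top20 <- sort(totals, decreasing = TRUE)
    top20 <- top20[seq_len(min(20, length(top20)))]
    obs_tab <- rs$observations
    if (ncol(rs$annotation$raw) > 0)
      obs_tab <- cbind(obs_tab, rs$annotation$raw[
        match(obs_tab$observation_id, rownames(rs$annotation$raw)), ,
        drop = FALSE])
    overview <- c(overview,
                  sprintf("<h3>Rank: %s</h3>", html_escape(rs$rank)),
                  svg_barplot(top20, title = "Top observations by total count"),
                  '<div class="tablewrap">', html_table(obs_tab, 200),
                  "</div>")
  }

  norm <- first$transforms$norm
  smp_order <- colnames(norm)
  if (!is.null(bundle$metadata)) {
    kinds <- bundle$metadata$kinds
    catf <- names(kinds)[kinds == "categorical"]
    tot <- colSums(first$counts$counts)
    if (length(catf)) {
      g <- as.character(bundle$metadata$fields[[catf[1]]])
      smp_order <- smp_order[order(g, -tot)]
    } else smp_order <- smp_order[order(-tot)]
  }
  top10 <- utils::head(first$observations$observation_id[
    order(-first$observations$total, first$observations$observation_id)], 10)
  samples <- c("<h2>Samples</h2>",
               "<p>Stacked relative abundance of the top observations per sample.</p>",
               svg_stacked_bars(unclass(norm), smp_order, top10))

  heat <- "<h2>Heatmap</h2>"
  for (rs in bundle$ranks) {
    clr <- unclass(rs$transforms$clr)
    obs_cl <- rs$clusterings[["observations|euclidean|complete"]] %||%
      Find(function(x) x$axis == "observations", rs$clusterings)
    smp_cl <- rs$clusterings[["samples|euclidean|complete"]] %||%
      Find(function(x) x$axis == "samples", rs$clusterings)
    obs_ord <- if (!is.null(obs_cl)) obs_cl$leaf_order else rownames(clr)
    smp_ord <- if (!is.null(smp_cl)) smp_cl$leaf_order else colnames(clr)
    show <- utils::head(rs$observations$observation_id[
      order(-rs$observations$total, rs$observations$observation_id)], 60)
    obs_ord <- obs_ord[obs_ord %in% show]
    annot <- rs$annotation$normalized
    annot_m <- if (ncol(annot) > 0)
      as.matrix(annot[rownames(clr), , drop = FALSE]) else NULL
    heat <- c(heat,
              sprintf("<h3>Rank: %s (clr; rows clustered %s)</h3>",
                      html_escape(rs$rank),
                      if (is.null(smp_cl)) "no"
                      else paste(smp_cl$metric, smp_cl$method, sep = "/")),
              svg_heatmap(clr, obs_ord, smp_ord,
                          meta_colors = md_cols, annot = annot_m))
  }

  corr <- "<h2>Correlation</h2><p>Symmetric proportionality (rho) between top observations; red positive, blue negative.</p>"
  for (rs in bundle$ranks)
    if (!is.null(rs$correlation))
      corr <- c(corr, sprintf("<h3>Rank: %s</h3>", html_escape(rs$rank)),
                svg_corr_matrix(unclass(rs$correlation)))

  nav <- paste0('<nav><a href="#overview">Overview</a>',
                '<a href="#samples">Samples</a>',
                '<a href="#heatmap">Heatmap</a>',
                '<a href="#correlation">Correlation</a></nav>')
  html <- c("<!DOCTYPE html>",
            '<html lang="en"><head><meta charset="utf-8">',
            "<title>Contamination evidence report</title>",
            "<style>", REPORT_CSS, "</style></head><body>", nav,
            '<section id="overview">', overview, "</section>",
            '<section id="samples">', samples, "</section>",
            '<section id="heatmap">', heat, "</section>",
            '<section id="correlation">', corr, "</section>",
            BUNDLE_MARK_OPEN, json, "</script>",
            "</body></html>")
  ok <- tryCatch({
    con <- file(out_path, open = "wb")
    on.exit(close(con))
    writeLines(html, con, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) kstop("render_report", "cannot write ", out_path)
  kmsg(sprintf("render_report: wrote %s (%.2f MB)", out_path,
               file.size(out_path) / 1e6))
  invisible(out_path)
}

#' Recover the evidence bundle embedded in a rendered report
#'
#' @param html_path a report written by [render_report()]
#' @return the embedded `evidence_bundle`
#' @export
extract_bundle <- function(html_path) {
  if (!file.exists(html_path)) kstop("extract_bundle", "file not found: ",
                                     html_path)
  lines <- readLines(html_path, warn = FALSE)
  start <- which(lines == BUNDLE_MARK_OPEN)
  if (length(start) != 1L)
    kstop("extract_bundle", "no embedded bundle found in ", html_path)
  end <- start + which(lines[(start + 1L):length(lines)] == "</script>")[1L]
  json <- paste(lines[(start + 1L):(end - 1L)], collapse = "\n")
  json <- gsub("<\\/", "</", json, fixed = TRUE)
  dec_bundle(jsonlite::parse_json(json, simplifyVector = FALSE))
}
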