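small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- small_study()
      cache <<- assemble_evidence(st$table, st$metadata, st$controls,
                                  st$taxonomy)
    }
    cache
  }
})

test_that("a table-only run degrades to one pseudo-rank without scores", {
  ct <- rand_table(6, 5, seed = 21)
  b <- assemble_evidence(ct)
  expect_s3_class(b, "evidence_bundle")
  expect_equal(names(b$ranks), "default")
  expect_null(b$ranks$default$scores)
  expect_gt(length(b$ranks$default$clusterings), 0L)
  expect_s3_class(b$ranks$default$correlation, "correlation_matrix")
  expect_null(b$metadata)
})

test_that("a full synthetic study populates every rank section", {
  b <- small_bundle()
  expect_setequal(names(b$ranks), c("genus", "species"))
  for (rs in b$ranks) {
    expect_false(is.null(rs$scores))
    expect_true(all(c("p_freq", "p_prev", "p_combined") %in%
                      colnames(rs$scores)))
    expect_true("control:negative_controls" %in%
                  colnames(rs$annotation$raw))
    expect_identical(attr(rs$transforms$clr, "transform"), "clr")
    expect_gt(length(rs$clusterings), 0L)
    # every id referenced by the matrices exists in the observation table
    expect_setequal(rownames(rs$transforms$clr), rs$observations$observation_id)
    expect_true(all(rownames(rs$correlation) %in%
                      rs$observations$observation_id))
  }
  expect_equal(b$metadata$color_class[["dna_conc"]], "sequential")
  expect_equal(b$metadata$color_class[["sample_type"]], "distinct")
})

test_that("unknown ranks fail with a stage-labelled error", {
  st <- small_study()
  expect_error(
    assemble_evidence(st$table, tax = st$taxonomy,
                      config = list(ranks = "phylum")),
    "\\[decompose\\]")
})

test_that("bundles serialize losslessly and deterministically", {
  b <- small_bundle()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_bundle(b, p1)
  back <- read_bundle(p1)
  expect_equal(back, b, tolerance = 0)
  write_bundle(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the same inputs produce byte-identical bundles end to end", {
  st1 <- small_study(seed = 31)
  st2 <- small_study(seed = 31)
  b1 <- assemble_evidence(st1$table, st1$metadata, st1$controls, st1$taxonomy)
  b2 <- assemble_evidence(st2$table, st2$metadata, st2$controls, st2$taxonomy)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bundle(b1, p1); write_bundle(b2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the report is one offline HTML file with all four panels", {
  b <- small_bundle()
  html <- withr::local_tempfile(fileext = ".html")
  render_report(b, html)
  lines <- readLines(html)
  expect_equal(lines[1], "<!DOCTYPE html>")
  for (panel in c("overview", "samples", "heatmap", "correlation"))
    expect_true(any(grepl(sprintf('<section id="%s">', panel), lines,
                          fixed = TRUE)), label = panel)
  # offline contract: no remote script/style/image/font references
  expect_false(any(grepl('src="http|href="http|url\\(http|@import|<link',
                         lines)))
  expect_false(any(grepl("<script src", lines, fixed = TRUE)))
})

test_that("the embedded bundle is recoverable from the report", {
  b <- small_bundle()
  html <- withr::local_tempfile(fileext = ".html")
  render_report(b, html)
  expect_equal(extract_bundle(html), b, tolerance = 0)
})

test_that("the CLI runs the full pipeline from files", {
  st <- small_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  out_html <- file.path(dir, "report.html")
  out_bundle <- file.path(dir, "bundle.json")
  code <- run_cli(c("-i", paths[["counts"]],
                    "-m", paths[["metadata"]],
                    "--controls", paste0("negative_controls:",
                                         paths[["controls"]]),
                    "-t", paths[["taxonomy"]],
                    "--tax-dialect", "generic-tsv",
                    "--concentration-field", "dna_conc",
                    "-o", out_html, "--bundle", out_bundle))
  expect_equal(code, 0L)
  expect_true(file.exists(out_html))
  b <- read_bundle(out_bundle)
  expect_setequal(names(b$ranks), c("genus", "species"))
  expect_false(is.null(b$ranks$species$scores))
})

test_that("CLI failures exit non-zero with a stage-labelled message", {
  expect_message(code <- run_cli(c("-i", "does-not-exist.tsv", "-o", "x.html")),
                 "does-not-exist")
  expect_equal(code, 1L)
  st <- small_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_message(
    code2 <- run_cli(c("-i", paths[["counts"]], "--method", "prevalence",
                       "-o", file.path(dir, "r.html"))),
    "control")
  expect_equal(code2, 1L)
  expect_message(code3 <- run_cli(c("--frobnicate")), "unknown flag")
  expect_equal(code3, 1L)
  expect_message(code4 <- run_cli(c("-i", paths[["counts"]])), "output")
  expect_equal(code4, 1L)
})

test_that("config files are overridden by flags", {
  st <- small_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  cfgp <- file.path(dir, "cfg.yml")
  writeLines(c("top_n: 5", "threshold: 0.2", "ranks: species"), cfgp)
  outb <- file.path(dir, "b.json")
  code <- run_cli(c("-i", paths[["counts"]],
                    "-t", paths[["taxonomy"]],
                    "-c", cfgp, "--top-n", "4", "--bundle", outb))
  expect_equal(code, 0L)
  b <- read_bundle(outb)
  expect_equal(names(b$ranks), "species")                 # from config
  expect_equal(b$provenance$parameters$top_n, 4L)         # flag wins
  expect_equal(b$provenance$parameters$threshold, 0.2)    # from config
  expect_lte(nrow(b$ranks$species$correlation), 4L)
})
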