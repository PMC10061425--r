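contam_fixture <- function()
  load_reference_set(system.file("extdata", "common_contaminants.yml",
                                 package = "kitomeR"))

test_that("the bundled contaminant fixture loads with its source counts", {
  rs <- contam_fixture()
  expect_s3_class(rs, "reference_set")
  expect_equal(rs$name, "contaminants")
  counts <- vapply(rs$entries, function(e) length(e$sources), integer(1))
  names(counts) <- vapply(rs$entries, `[[`, "", "name")
  expect_equal(unname(counts["Ralstonia"]), 12L)
  expect_equal(unname(counts["Pseudomonas"]), 13L)
  expect_equal(unname(counts["Cutibacterium acnes"]), 4L)
})

test_that("reference files deduplicate sources and tolerate name-only entries", {
  p <- write_tsv_fixture(c("Ralstonia:", "  - S1", "  - S2", "  - S1",
                           "Unknownus:", "  - S3"))
  rs <- load_reference_set(p)
  expect_equal(rs$entries[[1]]$sources, c("S1", "S2"))
  expect_warning(load_reference_set(p, tax = fixture_tax()),
                 "not resolvable")
  empty <- write_tsv_fixture("{}")
  expect_error(load_reference_set(empty), "empty")
})

test_that("observations inherit reference hits from their lineage", {
  tax <- fixture_tax()
  ct <- count_table(matrix(1L, 2, 1,
                           dimnames = list(c("305", "ghost"), "s1")))
  lin <- resolve_observations(ct, tax, "ids")
  rs <- structure(list(name = "contam", entries = list(
    list(name = "Ralstonia", id = NA_character_, rank = "genus",
         sources = paste0("S", 1:12)))), class = "reference_set")
  hits <- match_references(lin, rs)
  expect_equal(unname(hits[["305"]]), 12L)   # species inherits genus entry
  expect_equal(unname(hits[["ghost"]]), 0L)  # unresolved observation
  # two matched entries with disjoint sources count their union
  rs2 <- structure(list(name = "x", entries = list(
    list(name = "Ralstonia", id = NA, rank = NA, sources = "S1"),
    list(name = "Ralstonia pickettii", id = NA, rank = NA,
         sources = "S2"))), class = "reference_set")
  expect_equal(unname(match_references(lin, rs2)[["305"]]), 2L)
})

test_that("per-source aggregation counts each source once per rank taxon", {
  tax <- fixture_tax()
  # one source reporting two species of the same genus counts once
  agg <- aggregate_reference_report(list(S = c("305", "1597")), tax, "genus")
  expect_equal(unname(agg[["48736"]]), 1L)
  # two sources reporting the genus count twice
  agg2 <- aggregate_reference_report(list(A = "48736", B = "Ralstonia"),
                                     tax, "genus")
  expect_equal(unname(agg2[["48736"]]), 2L)
})

test_that("aggregation matches a brute-force set-membership oracle", {
  withr::with_seed(99, {
    genera <- sprintf("g%02d", 1:6)
    species <- sprintf("sp%02d", 1:30)
    parent <- sample(genera, 30, replace = TRUE)
    nodes <- rbind(
      data.frame(id = "r", parent = "r", rank = "no rank", name = "root"),
      data.frame(id = genera, parent = "r", rank = "genus", name = genera),
      data.frame(id = species, parent = parent, rank = "species",
                 name = species))
    tax <- taxonomy_db(nodes, ranks = c("genus", "species"))
    lists <- lapply(1:8, function(i) sample(species, sample(1:10, 1)))
    names(lists) <- paste0("src", 1:8)
  })
  agg <- aggregate_reference_report(lists, tax, "genus")
  g_of <- setNames(parent, species)
  for (g in genera) {
    brute <- sum(vapply(lists, function(tt) any(g_of[tt] == g), logical(1)))
    got <- if (g %in% names(agg)) agg[[g]] else 0L
    expect_equal(got, brute, label = g)
  }
})

test_that("control prevalence is the within-group presence fraction", {
  m <- matrix(0L, 2, 8, dimnames = list(c("a", "b"), paste0("c", 1:8)))
  m[1, 1:4] <- 1L
  m[2, ] <- 1L
  ct <- count_table(m)
  cg <- control_groups(list(blanks = paste0("c", 1:8)), ct)
  cp <- control_prevalence(ct, cg)
  expect_equal(unname(cp[, "blanks"]), c(0.5, 1))
  cg2 <- control_groups(list(sub = paste0("c", 5:8)), ct)
  expect_equal(unname(control_prevalence(ct, cg2)["a", ]), 0)
})

test_that("biome summaries count top taxa once per study with prefix levels", {
  profiles <- list(st1 = c(T1 = 10, T2 = 5), st2 = c(T1 = 8, T3 = 2))
  biomes <- list(st1 = "Environmental:Aquatic", st2 = "Environmental:Aquatic")
  bs <- build_biome_summary(profiles, biomes, top_n = 10)
  t1 <- lookup_biomes(bs, "T1", 1)
  expect_equal(t1$count, 2L)
  expect_equal(t1$biome, "Environmental")
  expect_equal(lookup_biomes(bs, "T1", 2)$count, 2L)
  expect_equal(lookup_biomes(bs, "T2", 1)$count, 1L)
  # taxon below the top_n cut is not counted
  prof <- list(st = setNames(11:1, paste0("x", sprintf("%02d", 1:11))))
  bs2 <- build_biome_summary(prof, list(st = "A:B"), top_n = 10)
  expect_false("x11" %in% names(bs2$totals))
  expect_true(all(bs2$counts$count == 1L))
})

test_that("biome fractions and level monotonicity behave", {
  profiles <- c(lapply(1:8, function(i) c(Prevotella = 5, Other = 1)),
                list(c(Prevotella = 2)))
  names(profiles) <- paste0("s", 1:9)
  biomes <- c(rep(list(c("Host-associated", "Human", "Digestive", "Oral",
                         "Saliva")), 8),
              list(c("Environmental", "Aquatic")))
  names(biomes) <- names(profiles)
  bs <- build_biome_summary(profiles, biomes, top_n = 10)
  l1 <- lookup_biomes(bs, "Prevotella", 1)
  expect_equal(l1$fraction, c(8 / 9, 1 / 9), tolerance = 1e-12)
  expect_equal(nrow(lookup_biomes(bs, "nobody", 1)), 0L)
  l5 <- lookup_biomes(bs, "Prevotella", 5)
  expect_true(all(l5$count <= max(l1$count)))
  # total increments = sum over studies of min(top_n, profile size)
  expect_equal(sum(bs$counts$count[bs$counts$level == 1]),
               sum(vapply(profiles, function(p) min(10, length(p)), 1)))
})

test_that("biome summaries round-trip through TSV", {
  profiles <- list(a = c(T1 = 3, T2 = 1), b = c(T1 = 2))
  bs <- build_biome_summary(profiles, list(a = "E:Aq", b = "H:Gut"), 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_biome_summary(bs, path)
  back <- read_biome_summary(path)
  expect_equal(back$counts, bs$counts)
  expect_equal(back$totals, bs$totals)
})

test_that("annotation tracks normalize per track and scale-invariantly", {
  tax <- fixture_tax()
  m <- matrix(c(5L, 1L, 0L, 2L), 2, 2,
              dimnames = list(c("305", "1597"), c("s1", "s2")))
  ct <- count_table(m)
  lin <- resolve_observations(ct, tax, "ids")
  rs <- structure(list(name = "contam", entries = list(
    list(name = "Ralstonia pickettii", id = NA, rank = NA,
         sources = c("S1", "S2")))), class = "reference_set")
  cg <- control_groups(list(blanks = "s2"), ct)
  at <- annotation_table(ct, lin, list(rs), cg)
  expect_equal(at$raw[["contam"]], c(2, 0))
  expect_equal(at$normalized[["contam"]], c(1, 0))
  expect_equal(at$raw[["control:blanks"]], c(0, 1))
  # scaling all hit counts leaves the normalized track unchanged
  rs10 <- rs
  rs10$entries[[1]]$sources <- paste0("S", 1:20)
  at10 <- annotation_table(ct, lin, list(rs10), cg)
  expect_equal(at10$normalized[["contam"]], at$normalized[["contam"]])
})
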