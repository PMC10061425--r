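test_that("generic-tsv dumps load into a rooted tree", {
  p <- write_tsv_fixture(c("id\tparent\trank\tname",
                           "r\tr\tno rank\troot",
                           "g1\tr\tgenus\tGenusOne",
                           "s1\tg1\tspecies\tSp one",
                           "s2\tg1\tspecies\tSp two"))
  tax <- load_taxonomy(p, "generic-tsv")
  expect_equal(length(tax$parent), 4L)
  expect_equal(tax$root, "r")
  expect_equal(unname(tax$rank[["g1"]]), "genus")
})

test_that("broken dumps are rejected", {
  orphan <- write_tsv_fixture(c("id\tparent\trank\tname",
                                "r\tr\tno rank\troot",
                                "x\tmissing\tgenus\tX"))
  expect_error(load_taxonomy(orphan, "generic-tsv"), "orphan")
  cycle <- write_tsv_fixture(c("id\tparent\trank\tname",
                               "r\tr\tno rank\troot",
                               "a\tb\tgenus\tA",
                               "b\ta\tgenus\tB"))
  expect_error(load_taxonomy(cycle, "generic-tsv"), "cycle")
  empty <- write_tsv_fixture("id\tparent\trank\tname")
  expect_error(load_taxonomy(empty, "generic-tsv"), "empty")
  two_roots <- write_tsv_fixture(c("id\tparent\trank\tname",
                                   "r1\tr1\tno rank\troot",
                                   "r2\tr2\tno rank\troot2"))
  expect_error(load_taxonomy(two_roots, "generic-tsv"), "one root")
})

test_that("the NCBI dmp adapter builds the same tree as generic-tsv", {
  nodes <- write_tsv_fixture(c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "1224\t|\t2\t|\tphylum\t|",
    "48736\t|\t1224\t|\tgenus\t|",
    "305\t|\t48736\t|\tspecies\t|",
    "1597\t|\t48736\t|\tspecies\t|"))
  names_d <- write_tsv_fixture(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "1\t|\tall\t|\t\t|\tsynonym\t|",
    "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "1224\t|\tProteobacteria\t|\t\t|\tscientific name\t|",
    "48736\t|\tRalstonia\t|\t\t|\tscientific name\t|",
    "305\t|\tRalstonia pickettii\t|\t\t|\tscientific name\t|",
    "1597\t|\tRalstonia insidiosa\t|\t\t|\tscientific name\t|"))
  tax <- load_taxonomy(c(nodes = nodes, names = names_d), "ncbi")
  ref <- fixture_tax()
  expect_equal(sort(names(tax$parent)), sort(names(ref$parent)))
  expect_equal(tax$parent[names(ref$parent)], ref$parent)
  expect_equal(tax$rank[names(ref$rank)], ref$rank)
  expect_equal(tax$name[names(ref$name)], ref$name)
})

test_that("prefixed-lineage dumps (GTDB/GreenGenes style) build a tree", {
  p <- write_tsv_fixture(c(
    "otu1\tk__Bacteria; p__Proteobacteria; g__Ralstonia; s__pickettii",
    "otu2\tk__Bacteria; p__Proteobacteria; g__Ralstonia; s__insidiosa"))
  tax <- load_taxonomy(p, "greengenes")
  expect_equal(unname(tax$rank[["g__Ralstonia"]]), "genus")
  expect_equal(unname(tax$parent[["otu1"]]), "s__pickettii")
  expect_equal(unname(tax$parent[["g__Ralstonia"]]), "p__Proteobacteria")
})

test_that("observation labels resolve by id, name and lineage string", {
  tax <- fixture_tax()
  m <- matrix(1L, 3, 3,
              dimnames = list(c("48736", "Ralstonia insidiosa",
                                "Bacteria|Proteobacteria|Ralstonia"),
                              c("s1", "s2", "s3")))
  ct <- count_table(m)
  by_id <- resolve_observations(ct, tax, "ids")
  expect_equal(by_id$lineages[["48736"]]$id, c("1", "2", "1224", "48736"))
  expect_equal(length(by_id$unresolved), 2L)

  by_name <- resolve_observations(ct, tax, "names")
  expect_equal(tail(by_name$lineages[["Ralstonia insidiosa"]]$id, 1), "1597")

  by_lin <- resolve_observations(ct, tax, "lineage-strings",
                                 lineage_separator = "|")
  l <- by_lin$lineages[["Bacteria|Proteobacteria|Ralstonia"]]
  expect_equal(tail(l$id, 1), "48736")  # leaf-first match
})

test_that("homonym names prefer the ranked node, else stay unresolved", {
  tax <- taxonomy_db(data.frame(
    id = c("r", "g", "x", "y"),
    parent = c("r", "r", "g", "g"),
    rank = c("no rank", "genus", "no rank", "no rank"),
    name = c("root", "Shared", "Shared", "Other"),
    stringsAsFactors = FALSE))
  ct <- count_table(matrix(1L, 2, 1,
                           dimnames = list(c("Shared", "Missing"), "s1")))
  lin <- resolve_observations(ct, tax, "names")
  expect_equal(tail(lin$lineages[["Shared"]]$id, 1), "g")
  expect_true("Missing" %in% lin$unresolved)
})

test_that("rank decomposition sums children and conserves totals", {
  tax <- fixture_tax()
  m <- matrix(c(3L, 0L, 4L, 2L, 5L, 5L), 3, 2, byrow = TRUE,
              dimnames = list(c("305", "1597", "ghost"), c("s1", "s2")))
  ct <- count_table(m, unassigned = c(1, 2))
  lin <- resolve_observations(ct, tax, "ids")
  gen <- decompose_counts(ct, lin, "genus")
  expect_equal(unname(gen$counts["48736", ]), c(3 + 4, 0 + 2))
  expect_equal(unname(gen$counts["(unannotated)", ]), c(5, 5))
  expect_equal(sample_totals(gen), sample_totals(ct))
})

test_that("decomposition at the observations' own rank is the identity", {
  tax <- fixture_tax()
  m <- matrix(c(3L, 1L, 4L, 2L), 2, 2,
              dimnames = list(c("305", "1597"), c("s1", "s2")))
  ct <- count_table(m)
  lin <- resolve_observations(ct, tax, "ids")
  sp <- decompose_counts(ct, lin, "species")
  expect_equal(sp$counts[sort(rownames(m)), ], m[sort(rownames(m)), ])
  # idempotence: decomposing the decomposed table again changes nothing
  lin2 <- resolve_observations(sp, tax, "ids")
  sp2 <- decompose_counts(sp, lin2, "species")
  expect_identical(sp$counts, sp2$counts)
})

test_that("conservation and nesting hold on the synthetic taxonomy", {
  st <- small_study()
  lin <- resolve_observations(st$table, st$taxonomy, "ids")
  for (r in st$taxonomy$ranks) {
    dec <- decompose_counts(st$table, lin, r)
    expect_equal(sample_totals(dec), sample_totals(st$table))
  }
  gen <- decompose_counts(st$table, lin, "genus")
  # genus counts dominate each member species, per sample
  for (o in observation_ids(st$table)) {
    g <- ancestor <- lin$lineages[[o]]
    gid <- g$id[g$rank == "genus"]
    expect_true(all(gen$counts[gid, ] >= st$table$counts[o, ]))
  }
})
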