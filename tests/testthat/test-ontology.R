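test_that("parse_obo builds the chain DAG with the expected structure", {
  fx <- chain_fixture()
  expect_s3_class(fx$dag, "ontology_dag")
  expect_length(fx$dag$terms, 3L)
  expect_identical(unname(fx$dag$roots["BP"]), fx$r)
  expect_identical(names(fx$dag$parents[[fx$b]]), fx$a)
  expect_identical(unname(fx$dag$parents[[fx$b]]), "is_a")
})

test_that("parse_obo keeps both is_a and part_of parents with their types", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: p1",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000003", "name: p2",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000004", "name: c",
               "namespace: biological_process", "is_a: GO:0000002",
               "relationship: part_of GO:0000003"), obo)
  dag <- parse_obo(obo)
  pv <- dag$parents[["GO:0000004"]]
  expect_setequal(names(pv), c("GO:0000002", "GO:0000003"))
  expect_identical(unname(pv[["GO:0000002"]]), "is_a")
  expect_identical(unname(pv[["GO:0000003"]]), "part_of")
})

test_that("unrecognized relationship types are dropped with a warning", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: a",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000003", "name: b",
               "namespace: biological_process", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000004", "name: c",
               "namespace: biological_process", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000005", "name: d",
               "namespace: biological_process", "is_a: GO:0000004",
               "relationship: regulates GO:0000003"), obo)
  expect_warning(dag <- parse_obo(obo), "regulates")
  expect_length(dag$terms, 5L)  # term count unchanged
  # 5 stanza edges declared, 4 retained
  expect_identical(sum(vapply(dag$parents, length, 1L)), 4L)
})

test_that("malformed stanzas and cyclic relations are rejected", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
               "name: root", "namespace: biological_process",
               "this line has no colon-separated key"), obo)
  expect_error(parse_obo(obo), "line 7")
  obo2 <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: a",
               "namespace: biological_process", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "name: b",
               "namespace: biological_process", "is_a: GO:0000001"), obo2)
  expect_error(parse_obo(obo2), "cycle")
})

test_that("obsolete terms are retained but flagged, alt_ids resolve", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "alt_id: GO:0009999", "",
               "[Term]", "id: GO:0000002", "name: gone",
               "namespace: biological_process", "is_obsolete: true"), obo)
  dag <- suppressWarnings(parse_obo(obo))
  expect_true(dag$obsolete[["GO:0000002"]])
  expect_true("GO:0000002" %in% dag$terms)
  expect_identical(unname(dag$alt_id[["GO:0009999"]]), "GO:0000001")
})

test_that("parse_gaf propagates annotations along the chain", {
  fx <- chain_fixture()
  expect_setequal(fx$annot$propagated[["P1"]], c(fx$b, fx$a, fx$r))
  expect_setequal(fx$annot$propagated[["P2"]], c(fx$a, fx$r))
  expect_identical(fx$annot$propagated[["P3"]], fx$r)
  expect_identical(unname(fx$annot$corpus_size["BP"]), 3L)
})

test_that("parse_gaf applies set semantics, skips NOT rows, counts corpus", {
  fx <- chain_fixture()
  gaf <- tempfile()
  writeLines(c("!gaf-version: 2.2",
               gaf_row("P1", fx$b, "IDA"),
               gaf_row("P1", fx$b, "IDA"),          # duplicate
               gaf_row("P2", fx$a, "IDA", "NOT"),    # excluded
               gaf_row("P3", fx$r, "IEA")), gaf)
  annot <- parse_gaf(gaf, fx$dag)
  expect_identical(nrow(annot$direct), 2L)
  expect_false("P2" %in% names(annot$propagated))
  expect_identical(unname(annot$corpus_size["BP"]), 2L)
})

test_that("parse_gaf rejects unusable files and warns on unknown terms", {
  fx <- chain_fixture()
  gaf <- tempfile()
  writeLines(c("!gaf-version: 2.2", "! nothing here"), gaf)
  expect_error(parse_gaf(gaf, fx$dag), "no usable")
  expect_error(parse_gaf(tempfile(), fx$dag), "not found")
  gaf2 <- tempfile()
  writeLines(c(gaf_row("P1", "GO:9999999", "IDA"),
               gaf_row("P2", fx$a, "IDA")), gaf2)
  expect_warning(annot <- parse_gaf(gaf2, fx$dag), "unknown term")
  expect_identical(nrow(annot$direct), 1L)
})

test_that("information content matches hand counts on the chain corpus", {
  fx <- chain_fixture()
  ic <- compute_ic(fx$dag, fx$annot, "BP")
  expect_equal(unname(ic$ic[fx$r]), 0, tolerance = 1e-12)
  expect_equal(unname(ic$ic[fx$a]), -log(2 / 3), tolerance = 1e-12)
  expect_equal(unname(ic$ic[fx$b]), -log(1 / 3), tolerance = 1e-12)
  # direct-count convention differs: a annotates only P2 directly
  icd <- compute_ic(fx$dag, fx$annot, "BP", counts = "direct")
  expect_equal(unname(icd$ic[fx$a]), -log(1 / 3), tolerance = 1e-12)
  expect_error(compute_ic(fx$dag, fx$annot, "CC"), "no proteins")
})

test_that("max-IC common ancestor follows IC and breaks ties predictably", {
  fx <- chain_fixture()
  ic <- compute_ic(fx$dag, fx$annot, "BP")
  expect_identical(max_ic_common_ancestor(fx$dag, ic, fx$b, fx$a), fx$a)
  expect_identical(max_ic_common_ancestor(fx$dag, ic, fx$b, fx$b), fx$b)
  # siblings under the root share only the root
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: s1",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000003", "name: s2",
               "namespace: biological_process", "is_a: GO:0000001"), obo)
  dag2 <- parse_obo(obo)
  gaf <- tempfile()
  writeLines(c(gaf_row("Q1", "GO:0000002", "IDA"),
               gaf_row("Q2", "GO:0000003", "IDA")), gaf)
  ic2 <- compute_ic(dag2, parse_gaf(gaf, dag2), "BP")
  expect_identical(max_ic_common_ancestor(dag2, ic2, "GO:0000002", "GO:0000003"),
                   "GO:0000001")
})

test_that("transitive reduction removes shortcuts and preserves reachability", {
  # chain with an added shortcut b -> r
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: r",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: a",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000003", "name: b",
               "namespace: biological_process", "is_a: GO:0000002",
               "is_a: GO:0000001"), obo)
  dag <- parse_obo(obo)
  red <- transitive_reduction(dag)
  expect_identical(names(red$parents[["GO:0000003"]]), "GO:0000002")
  # chains and trees are already reduced
  fx <- chain_fixture()
  red2 <- transitive_reduction(fx$dag)
  expect_identical(red2$parents[fx$dag$terms], fx$dag$parents[fx$dag$terms])
  # cycle in a hand-built slice is detected
  bad <- structure(list(terms = c("x", "y"),
                        name = c(x = "x", y = "y"),
                        aspect = c(x = "BP", y = "BP"),
                        obsolete = c(x = FALSE, y = FALSE),
                        parents = list(x = c(y = "is_a"), y = c(x = "is_a"))),
                   class = "ontology_dag")
  expect_error(transitive_reduction(bad), "cycle")
})

test_that("transitive reduction preserves the reachability matrix on random DAGs", {
  for (seed in 1:15) {
    dag <- random_dag(sample(8:20, 1L), seed = 300 + seed)
    red <- transitive_reduction(dag)
    expect_identical(oracle_reachability(red), oracle_reachability(dag))
    # no removed edge can be re-added without creating redundancy:
    # reduced edge set is a subset of the original
    for (id in dag$terms)
      expect_true(all(names(red$parents[[id]]) %in% names(dag$parents[[id]])))
  }
})

test_that("IC never decreases from parent to child under propagation", {
  bench <- make_cocomplex_benchmark(6L, c(4L, 6L), 0.7, seed = 9L)
  for (aspect in c("BP", "MF", "CC")) {
    ic <- compute_ic(bench$dag, bench$annot, aspect)
    for (id in names(ic$ic)) {
      for (p in names(bench$dag$parents[[id]])) {
        if (p %in% names(ic$ic))
          expect_gte(ic$ic[[id]], ic$ic[[p]] - 1e-12)
      }
    }
  }
})

test_that("propagation closure equals DFS reachability plus direct terms", {
  bench <- make_cocomplex_benchmark(4L, c(4L, 5L), 0.6, seed = 17L)
  annot <- bench$annot
  proteins <- names(annot$propagated)
  set.seed(1)
  for (p in sample(proteins, min(25L, length(proteins)))) {
    direct <- unique(annot$direct$term[annot$direct$protein == p])
    expected <- direct
    for (t in direct) expected <- union(expected, oracle_ancestors(bench$dag, t))
    expect_setequal(annot$propagated[[p]], expected)
  }
})
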