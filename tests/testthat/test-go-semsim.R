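# Two-branch fixture: root with branch heads x, y; x has children x1, x2;
# y has child y1; d hangs under both x2 and y1 (multi-parent term).
two_branch_fixture <- function() {
  obo <- tempfile(fileext = ".obo")
  term <- function(id, name, ...) c("", "[Term]", paste0("id: ", id),
                                    paste0("name: ", name),
                                    "namespace: biological_process", ...)
  writeLines(c("format-version: 1.2",
               term("GO:0000001", "root"),
               term("GO:0000002", "x", "is_a: GO:0000001"),
               term("GO:0000003", "y", "is_a: GO:0000001"),
               term("GO:0000004", "x1", "is_a: GO:0000002"),
               term("GO:0000005", "x2", "is_a: GO:0000002"),
               term("GO:0000006", "y1", "is_a: GO:0000003"),
               term("GO:0000007", "d", "is_a: GO:0000005",
                    "is_a: GO:0000006")), obo)
  dag <- parse_obo(obo)
  gaf <- tempfile()
  writeLines(c(gaf_row("p1", "GO:0000004", "IDA"),
               gaf_row("p2", "GO:0000005", "IDA"),
               gaf_row("p3", "GO:0000006", "IDA"),
               gaf_row("p4", "GO:0000007", "IDA"),
               gaf_row("p5", "GO:0000002", "IDA"),
               gaf_row("p6", "GO:0000003", "IDA")), gaf)
  list(dag = dag, annot = parse_gaf(gaf, dag))
}

test_that("ICA matches hand counts and the propagated-count IC", {
  fx <- chain_fixture()
  ica <- tcss_ica(fx$dag, fx$annot, "BP")
  expect_equal(unname(ica[fx$r]), 0, tolerance = 1e-12)
  expect_equal(unname(ica[fx$a]), -log(2 / 3), tolerance = 1e-12)
  expect_equal(unname(ica[fx$b]), -log(1 / 3), tolerance = 1e-12)
  ic <- compute_ic(fx$dag, fx$annot, "BP")
  expect_equal(ica[sort(names(ica))], ic$ic[sort(names(ic$ic))],
               tolerance = 1e-12)
  # literal immediate-children reading under-counts deep descendants:
  # the chain has no depth-2 gap, so construct one via the two-branch DAG
  fx2 <- two_branch_fixture()
  lit <- tcss_ica(fx2$dag, fx2$annot, "BP", descendants = "children")
  full <- tcss_ica(fx2$dag, fx2$annot, "BP")
  expect_true(lit[["GO:0000001"]] > full[["GO:0000001"]])
})

test_that("a threshold above max ICA yields one whole-aspect subgraph", {
  fx <- chain_fixture()
  part <- tcss_partition(fx$dag, fx$annot, "BP", ic_threshold = 10)
  expect_length(part$subgraphs, 1L)
  expect_setequal(part$subgraphs[[1L]]$terms, c(fx$r, fx$a, fx$b))
  expect_equal(unname(part$ics[[1L]][fx$a]),
               -log(2 / 3) / -log(1 / 3), tolerance = 1e-12)
  expect_equal(max(part$ics[[1L]]), 1, tolerance = 1e-12)
})

test_that("the two-branch DAG splits into two subgraphs with duplication", {
  fx <- two_branch_fixture()
  part <- tcss_partition(fx$dag, fx$annot, "BP", ic_threshold = 0.2,
                         merge_tolerance = 0.05)
  expect_length(part$subgraphs, 2L)
  roots <- vapply(part$subgraphs, `[[`, "", "root")
  expect_setequal(roots, c("GO:0000002", "GO:0000003"))
  # the multi-parent term d belongs to both subgraphs after duplication
  expect_length(part$membership[["GO:0000007"]], 2L)
  # terms below the cut (here only the root) form the meta-graph with roots
  expect_setequal(part$meta_terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
})

test_that("TCSS protein similarity reproduces hand values on the chain", {
  fx <- chain_fixture()
  part <- tcss_partition(fx$dag, fx$annot, "BP", ic_threshold = 0)
  expect_equal(tcss_protein_sim(part, fx$annot, "P1", "P2"),
               log(2 / 3) / log(1 / 3), tolerance = 1e-12)
  expect_equal(tcss_protein_sim(part, fx$annot, "P3", "P1"), 0,
               tolerance = 1e-12)
  # self-similarity of the protein holding the max-ICA term is exactly 1
  expect_equal(tcss_protein_sim(part, fx$annot, "P1", "P1"), 1,
               tolerance = 1e-12)
  # unannotated protein yields the missing sentinel, not 0
  expect_true(is.na(tcss_protein_sim(part, fx$annot, "P1", "Pnone")))
})

test_that("TCSS similarity never decreases for deeper common ancestors", {
  # path r <- a <- b <- c, single subgraph: ICS increases down the chain
  obo <- tempfile(fileext = ".obo")
  term <- function(id, name, ...) c("", "[Term]", paste0("id: ", id),
                                    paste0("name: ", name),
                                    "namespace: biological_process", ...)
  writeLines(c("format-version: 1.2",
               term("GO:0000001", "r"),
               term("GO:0000002", "a", "is_a: GO:0000001"),
               term("GO:0000003", "b", "is_a: GO:0000002"),
               term("GO:0000004", "c", "is_a: GO:0000003")), obo)
  dag <- parse_obo(obo)
  gaf <- tempfile()
  writeLines(c(gaf_row("q1", "GO:0000001", "IDA"),
               gaf_row("q2", "GO:0000002", "IDA"),
               gaf_row("q3", "GO:0000003", "IDA"),
               gaf_row("q4", "GO:0000004", "IDA")), gaf)
  annot <- parse_gaf(gaf, dag)
  part <- tcss_partition(dag, annot, "BP", ic_threshold = 0)
  s_r <- tcss_protein_sim(part, annot, "q4", "q1")
  s_a <- tcss_protein_sim(part, annot, "q4", "q2")
  s_b <- tcss_protein_sim(part, annot, "q4", "q3")
  expect_lte(s_r, s_a)
  expect_lte(s_a, s_b)
})

test_that("inverse annotation frequency matches direct hand counts", {
  fx <- chain_fixture()
  expect_equal(intelligo_iaf(fx$annot, "BP", fx$b), log(3), tolerance = 1e-12)
  # 4-protein corpus where a term annotates 2 directly
  gaf <- tempfile()
  writeLines(c(gaf_row("q1", fx$b, "IDA"), gaf_row("q2", fx$b, "IEA"),
               gaf_row("q3", fx$a, "IDA"), gaf_row("q4", fx$r, "IDA")), gaf)
  annot <- parse_gaf(gaf, fx$dag)
  expect_equal(intelligo_iaf(annot, "BP", fx$b), log(2), tolerance = 1e-12)
  # a term annotating every protein carries no information
  gaf2 <- tempfile()
  writeLines(c(gaf_row("q1", fx$b, "IDA"), gaf_row("q2", fx$b, "IDA")), gaf2)
  annot2 <- parse_gaf(gaf2, fx$dag)
  expect_equal(intelligo_iaf(annot2, "BP", fx$b), 0, tolerance = 1e-12)
  expect_error(intelligo_iaf(fx$annot, "BP", "GO:0000001x"), "no protein")
})

test_that("IntelliGO cosine behaves on degenerate and collinear vectors", {
  fx <- two_branch_fixture()
  expect_equal(intelligo_protein_sim(fx$dag, fx$annot, "p1", "p1", "BP"), 1,
               tolerance = 1e-12)
  # identical single term under different evidence codes is still collinear
  gaf <- tempfile()
  writeLines(c(gaf_row("w1", "GO:0000004", "IDA"),
               gaf_row("w2", "GO:0000004", "IEA"),
               gaf_row("w3", "GO:0000002", "IDA"),
               gaf_row("w4", "GO:0000003", "IDA")), gaf)
  annot <- parse_gaf(gaf, fx$dag)
  expect_equal(intelligo_protein_sim(fx$dag, annot, "w1", "w2", "BP"), 1,
               tolerance = 1e-12)
  # terms whose only common ancestor is the depth-0 root are orthogonal
  expect_equal(intelligo_protein_sim(fx$dag, annot, "w3", "w4", "BP"), 0,
               tolerance = 1e-12)
  # unannotated protein -> missing sentinel
  expect_true(is.na(intelligo_protein_sim(fx$dag, annot, "w1", "zz", "BP")))
})

test_that("IntelliGO is invariant to a global rescaling of EC weights", {
  fx <- two_branch_fixture()
  w1 <- default_ec_weights()
  w2 <- w1
  w2$weights <- w1$weights * 0.5
  w2$default_weight <- w1$default_weight * 0.5
  for (pair in list(c("p1", "p2"), c("p1", "p4"), c("p2", "p3"))) {
    expect_equal(
      intelligo_protein_sim(fx$dag, fx$annot, pair[1], pair[2], "BP",
                            ec_weights = w1),
      intelligo_protein_sim(fx$dag, fx$annot, pair[1], pair[2], "BP",
                            ec_weights = w2),
      tolerance = 1e-12)
  }
})

test_that("Wang contributions propagate with the max rule", {
  fx <- chain_fixture()
  wc <- wang_contributions(fx$dag, fx$b)
  expect_equal(wc$s_values[[fx$b]], 1, tolerance = 1e-12)
  expect_equal(wc$s_values[[fx$a]], 0.8, tolerance = 1e-12)
  expect_equal(wc$s_values[[fx$r]], 0.64, tolerance = 1e-12)
  expect_equal(wc$sv, 2.44, tolerance = 1e-12)
  # anchor at the root has a bare table
  wr <- wang_contributions(fx$dag, fx$r)
  expect_identical(names(wr$s_values), fx$r)
  expect_equal(wr$sv, 1, tolerance = 1e-12)
  # diamond: path weights 0.8*0.8 vs 0.6 (part_of), max wins
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: r",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: m",
               "namespace: biological_process", "is_a: GO:0000001", "",
               "[Term]", "id: GO:0000003", "name: t",
               "namespace: biological_process", "is_a: GO:0000002",
               "relationship: part_of GO:0000001"), obo)
  dagd <- parse_obo(obo)
  wd <- wang_contributions(dagd, "GO:0000003")
  expect_equal(wd$s_values[["GO:0000001"]], 0.64, tolerance = 1e-12)
})

test_that("Wang term and protein similarities match hand computation", {
  fx <- chain_fixture()
  expect_equal(wang_term_sim(fx$dag, fx$b, fx$b), 1, tolerance = 1e-12)
  expect_equal(wang_term_sim(fx$dag, fx$b, fx$a), 3.24 / 4.24,
               tolerance = 1e-12)
  expect_equal(wang_term_sim(fx$dag, fx$b, fx$r), 1.64 / 3.44,
               tolerance = 1e-12)
  expect_equal(wang_protein_sim(fx$dag, fx$annot, "P1", "P2", "BP"),
               3.24 / 4.24, tolerance = 1e-12)
  expect_equal(wang_protein_sim(fx$dag, fx$annot, "P3", "P1", "BP"),
               1.64 / 3.44, tolerance = 1e-12)
  expect_true(is.na(wang_protein_sim(fx$dag, fx$annot, "P1", "Pnone", "BP")))
  # sharing any term pins the max at 1
  fx2 <- two_branch_fixture()
  gaf <- tempfile()
  writeLines(c(gaf_row("u1", "GO:0000004", "IDA"),
               gaf_row("u1", "GO:0000006", "IDA"),
               gaf_row("u2", "GO:0000004", "IEA")), gaf)
  annot <- parse_gaf(gaf, fx2$dag)
  expect_equal(wang_protein_sim(fx2$dag, annot, "u1", "u2", "BP"), 1,
               tolerance = 1e-12)
})

test_that("the three protein similarities are symmetric and bounded on toys", {
  bench <- make_cocomplex_benchmark(5L, c(4L, 6L), 0.7, seed = 23L)
  part <- tcss_partition(bench$dag, bench$annot, "BP")
  ic <- compute_ic(bench$dag, bench$annot, "BP")
  proteins <- names(bench$annot$propagated)
  set.seed(4)
  for (k in 1:25) {
    p <- sample(proteins, 2L)
    w1 <- wang_protein_sim(bench$dag, bench$annot, p[1], p[2], "BP")
    w2 <- wang_protein_sim(bench$dag, bench$annot, p[2], p[1], "BP")
    t1 <- tcss_protein_sim(part, bench$annot, p[1], p[2])
    t2 <- tcss_protein_sim(part, bench$annot, p[2], p[1])
    i1 <- intelligo_protein_sim(bench$dag, bench$annot, p[1], p[2], "BP",
                                ic = ic)
    i2 <- intelligo_protein_sim(bench$dag, bench$annot, p[2], p[1], "BP",
                                ic = ic)
    for (v in list(c(w1, w2), c(t1, t2), c(i1, i2))) {
      expect_equal(v[1], v[2], tolerance = 1e-9)
      expect_true(is.na(v[1]) || (v[1] >= 0 && v[1] <= 1))
    }
  }
})

test_that("Wang agrees with exhaustive path enumeration on random DAGs", {
  for (seed in 1:10) {
    dag <- random_dag(sample(6:15, 1L), seed = 700 + seed)
    terms <- dag$terms
    set.seed(seed)
    for (k in 1:5) {
      mn <- sample(terms, 2L, replace = TRUE)
      expect_equal(wang_term_sim(dag, mn[1], mn[2]),
                   oracle_wang_term_sim(dag, mn[1], mn[2]),
                   tolerance = 1e-12)
    }
  }
})
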