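test_that("parse_newick reads labels, lengths and supports and round-trips", {
  cases <- c("(A,B);",
             "((A:1,B:1)90:1,C:2);",
             "(((A:0.5,B:0.25)75:1,C:2)60:0.1,D:3.5);")
  for (nwk in cases) {
    tr <- parse_newick(nwk)
    rt <- parse_newick(paste0(write_newick(tr)))
    expect_identical(sort(rt$tip.label), sort(tr$tip.label))
    expect_equal(rt$Nnode, tr$Nnode)
    if (!is.null(tr$edge.length)) {
      expect_equal(sort(rt$edge.length), sort(tr$edge.length), tolerance = 1e-10)
    }
    expect_identical(rt$node.label, tr$node.label)
  }
  two <- parse_newick("(A,B);")
  expect_equal(ape::Ntip(two), 2L)
  expect_equal(two$Nnode, 1L)
  sup <- parse_newick("((A:1,B:1)90:1,C:2);")
  expect_equal(node_supports(sup)[2], 90)
  expect_equal(patristic_distances(sup)["A", "C"], 4)
})

test_that("parse_newick rejects malformed input with informative errors", {
  expect_error(parse_newick("((A,B;"), "unbalanced")
  expect_error(parse_newick("(A,B)"), ";")
  expect_error(parse_newick("(A,A);"), "duplicate")
  expect_error(parse_newick("(A:-1,B:1);"), "negative")
  expect_error(parse_newick(""), "empty")
})

test_that("fractional supports are rescaled to percent with a warning", {
  expect_warning(tr <- parse_newick("((A,B)0.9,C);"), "rescal")
  expect_equal(node_supports(tr)[2], 90)
})

test_that("patristic distances match hand values and the path-sum oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  for (seed in 1:10) {
    rt <- simulate_yule(6, 1, seed = seed)
    expect_equal(patristic_distances(rt), oracle_patristic(rt), tolerance = 1e-10)
  }
})

test_that("patristic distances satisfy the four-point condition on additive trees", {
  for (seed in 11:15) {
    tr <- simulate_yule(7, 1, seed = seed)
    D <- patristic_distances(tr)
    labs <- rownames(D)
    for (q in utils::combn(labs, 4, simplify = FALSE)) {
      s <- c(D[q[1], q[2]] + D[q[3], q[4]],
             D[q[1], q[3]] + D[q[2], q[4]],
             D[q[1], q[4]] + D[q[2], q[3]])
      s <- sort(s)
      expect_lte(s[3] - s[2], 1e-8 * max(1, s[3]))
    }
  }
  expect_error(patristic_distances(simulate_pda(c("A", "B", "C"))), "branch length")
})

test_that("collapse_low_support contracts strictly sub-threshold nodes only", {
  tr <- parse_newick("(((A:1,B:1)65:1,C:2)80:1,D:3);")
  ct <- collapse_low_support(tr, 70)
  expect_equal(ct$Nnode, tr$Nnode - 1L)
  expect_setequal(ct$tip.label, tr$tip.label)
  # leaf depths preserved by redistributing the contracted edge
  expect_equal(patristic_distances(ct)["A", "D"], patristic_distances(tr)["A", "D"])
  at <- parse_newick("(((A:1,B:1)70:1,C:2)80:1,D:3);")
  expect_equal(collapse_low_support(at, 70)$Nnode, at$Nnode)
  hi <- parse_newick("(((A:1,B:1)95:1,C:2)99:1,D:3);")
  expect_identical(write_newick(collapse_low_support(hi, 70)), write_newick(hi))
  # no supports at all: identity
  ns <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(write_newick(collapse_low_support(ns, 70)), write_newick(ns))
})

test_that("collapse_low_support keeps the leaf set on random trees", {
  set.seed(31)
  for (i in 1:10) {
    tr <- simulate_yule(10, 1)
    tr$node.label <- c("", sprintf("%d", sample(0:100, tr$Nnode - 1L, replace = TRUE)))
    ct <- collapse_low_support(tr, 70)
    expect_setequal(ct$tip.label, tr$tip.label)
    expect_lte(ct$Nnode, tr$Nnode)
  }
})

test_that("terminal single-host clades collapse to one representative leaf", {
  p <- parse_newick("(((p1:1,p2:1):1,p3:1):1,(p4:1,p5:1):1);")
  L <- links_matrix(paste0("p", 1:5), c("X", "X", "X", "Y", "Z"))
  out <- collapse_terminal_host_clades(p, L)
  expect_setequal(out$tree$tip.label, c("p1", "p4", "p5"))
  expect_equal(unname(out$links["p1", "X"]), 1L)
  # the set of distinct (clade, host) associations is preserved
  expect_setequal(colnames(out$links)[colSums(out$links) > 0],
                  colnames(L)[colSums(L) > 0])
  # cherry on two different hosts stays
  q <- parse_newick("((p1:1,p2:1):1,p3:1);")
  L2 <- links_matrix(paste0("p", 1:3), c("X", "Y", "Z"))
  out2 <- collapse_terminal_host_clades(q, L2)
  expect_setequal(out2$tree$tip.label, paste0("p", 1:3))
  # idempotent
  again <- collapse_terminal_host_clades(out$tree, out$links)
  expect_identical(write_newick(again$tree), write_newick(out$tree))
  expect_error(collapse_terminal_host_clades(p, L[1:3, , drop = FALSE]), "missing")
})

test_that("link tables read, deduplicate and validate", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "p1\tH1", "p2\tH1", "p3\tH2"), tf)
  A <- read_links(tf)
  expect_equal(sum(A), 3L)
  expect_setequal(rownames(A), paste0("p", 1:3))
  writeLines(c("p1\tH1", "p1\tH1", "p2\tH2"), tf)
  expect_warning(A2 <- read_links(tf), "duplicated")
  expect_equal(sum(A2), 2L)
  writeLines(c("p1\tH1", "p2"), tf)
  expect_error(read_links(tf), "line 2")
  writeLines(character(0), tf)
  expect_error(read_links(tf), "empty")
  writeLines(c("parasite\thost", "p1\tH1"), tf)
  expect_equal(sum(read_links(tf)), 1L)
  # round trip through the writer
  write_links(A, tf)
  expect_identical(read_links(tf), A)
})
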