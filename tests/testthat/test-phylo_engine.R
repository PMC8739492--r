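test_that("the Jukes-Cantor correction matches the closed form and its domain", {
  expect_identical(jc_distance(0), 0)
  expect_equal(jc_distance(0.3), -0.75 * log(1 - 4 / 3 * 0.3), tolerance = 1e-12)
  expect_equal(jc_distance(0.3), 0.3831192, tolerance = 1e-6)
  expect_error(jc_distance(0.75), "saturation")
  expect_error(jc_distance(0.76), "saturation")
  # protein form uses the 20-letter alphabet limit
  expect_equal(jc_distance(0.5, k = 20), -(19 / 20) * log(1 - 20 / 19 * 0.5),
               tolerance = 1e-12)
  expect_error(jc_distance(0.95, k = 20), "saturation")

  # strictly increasing and >= p on its domain
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("alphabet detection picks the nucleotide or amino-acid correction", {
  nt <- alignment(c(a = "ACGTACGT", b = "ACGTACGA"))
  aa <- alignment(c(a = "MKLVWYEH", b = "MKLVWYEA"))
  p <- 1 / 8
  expect_equal(jc_dist_matrix(nt)[1, 2], jc_distance(p, k = 4))
  expect_equal(jc_dist_matrix(aa)[1, 2], jc_distance(p, k = 20))
  # gap columns are pairwise-deleted
  g <- alignment(c(a = "AC-TACGT", b = "ACGTACGA"))
  expect_equal(jc_dist_matrix(g)[1, 2], jc_distance(1 / 7, k = 4))
})

test_that("neighbour joining solves the three-taxon case in closed form", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- nj_tree(D)
  # three-point formulas: x_a = (dab + dac - dbc) / 2, etc.
  len <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])], tree$tip.label)
  expect_equal(unname(len["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["c"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("neighbour joining is exact on additive matrices from random trees", {
  set.seed(31)
  for (n in c(4, 6, 8)) {
    for (rep in 1:10) {
      tr <- ape::rtree(n)
      tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
      D <- ape::cophenetic.phylo(tr)
      est <- nj_tree(D)
      expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
      # branch lengths solve the additive system
      expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  }
})

test_that("bootstrap supports are seeded, bounded and saturate on uniform signal", {
  # repeated copies of one perfectly informative column (plus constant
  # columns keeping every pairwise p inside the correction's domain)
  seqs <- c(a = paste0(strrep("A", 30), strrep("G", 70)),
            b = paste0(strrep("A", 29), "C", strrep("G", 70)),
            c = paste0(strrep("T", 30), strrep("G", 70)),
            d = paste0(strrep("T", 30), strrep("G", 70)),
            e = paste0(strrep("T", 30), strrep("G", 50), strrep("C", 20)))
  aln <- alignment(seqs)
  tree <- bootstrap_support(aln, reps = 100, seed = 5)
  sup <- attr(tree, "bipartition_support")
  expect_true(all(sup >= 0 & sup <= 100))
  ab <- sup[["a|b"]]             # the {a,b} vs {c,d,e} split is in every replicate
  expect_identical(ab, 100)

  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  aln2 <- simulate_alignment(tr, 200, seed = 9)
  t1 <- bootstrap_support(aln2, reps = 50, seed = 11)
  t2 <- bootstrap_support(aln2, reps = 50, seed = 11)
  expect_identical(attr(t1, "bipartition_support"), attr(t2, "bipartition_support"))
  t3 <- bootstrap_support(aln2, reps = 50, seed = 12)
  expect_false(identical(attr(t1, "bipartition_support"),
                         attr(t3, "bipartition_support")))

  expect_error(bootstrap_support(alignment(c(a = "A", b = "C", c = "G")),
                                 reps = 10, seed = 1), "2 columns")
  expect_error(bootstrap_support(aln2, reps = 10), "seed")
})

test_that("queries simulated from a labelled subtree classify into that clade", {
  set.seed(17)
  # a reference tree with two well-separated clades of carrier proteins
  nwk <- "((P1:0.05,(P2:0.05,Q:0.05):0.05):0.4,(A1:0.05,A2:0.05,A3:0.05):0.4);"
  tr <- ape::read.tree(text = nwk)
  aln <- simulate_alignment(tr, 300, seed = 23, k = 20)
  rows <- apply(aln, 1, paste, collapse = "")
  labels <- c(P1 = "PCP", P2 = "PCP", A1 = "ACP", A2 = "ACP", A3 = "ACP")
  refs <- alignment(rows[names(labels)])
  res <- classify_clade(c(Q = rows[["Q"]]), refs, labels, reps = 100, seed = 3)
  expect_identical(res$label, "PCP")
  expect_true(res$support > 50)
})

test_that("a query identical to a reference joins it with full support", {
  set.seed(19)
  tr <- ape::read.tree(text = "((A1:0.1,A2:0.1):0.5,(P1:0.1,P2:0.1):0.5);")
  aln <- simulate_alignment(tr, 200, seed = 29, k = 20)
  rows <- apply(aln, 1, paste, collapse = "")
  labels <- c(A1 = "ACP", A2 = "ACP", P1 = "PCP", P2 = "PCP")
  res <- classify_clade(c(Q = rows[["A1"]]), alignment(rows), labels,
                        reps = 100, seed = 7)
  expect_identical(res$label, "ACP")
  expect_identical(res$support, 100)
})

test_that("a star-like equidistant query stays unclassified with diagnostics", {
  refs <- alignment(c(A1 = "AAAAAACCGGGG", A2 = "AAAAAATTGGGG",
                      P1 = "CCCCCCCCGGGG", P2 = "CCCCCCTTGGGG"))
  labels <- c(A1 = "ACP", A2 = "ACP", P1 = "PCP", P2 = "PCP")
  query <- c(Q = "AAACCCAAGGGG")   # equally far from both clades
  res <- classify_clade(query, refs, labels, reps = 50, seed = 13)
  expect_identical(res$label, "unclassified")
  expect_match(res$diagnostics, "tie|no single-label")
})

test_that("misaligned queries are rejected", {
  refs <- alignment(c(A1 = "AAAA", P1 = "TTTT", A2 = "AAAT"))
  expect_error(classify_clade(c(Q = "AA"), refs,
                              c(A1 = "ACP", P1 = "PCP", A2 = "ACP")),
               "pre-aligned")
})
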