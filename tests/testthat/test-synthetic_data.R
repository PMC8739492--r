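test_that("generators are pure functions of (cfg, seed)", {
  a1 <- simulate_architecture(sim_config(3))
  a2 <- simulate_architecture(sim_config(3))
  expect_identical(a1, a2)
  a3 <- simulate_architecture(sim_config(4))
  expect_false(identical(a1, a3))

  p1 <- simulate_proteins(sim_config(3, n_per_motif = 2, n_decoys = 3))
  p2 <- simulate_proteins(sim_config(3, n_per_motif = 2, n_decoys = 3))
  expect_identical(p1, p2)

  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  expect_identical(simulate_alignment(tr, 100, seed = 6),
                   simulate_alignment(tr, 100, seed = 6))
  expect_false(identical(simulate_alignment(tr, 100, seed = 6),
                         simulate_alignment(tr, 100, seed = 7)))
})

test_that("an all-zero-probability draw gives pure ketone elongations", {
  cfg <- sim_config(1, n_elongations = c(3, 3), p_nrps = 0, p_kr = 0,
                    p_cmt = 0, p_trans_er = 0, p_hcs = 0, p_llm = 0)
  sim <- simulate_architecture(cfg)
  expect_identical(sim$truth$E, 3L)
  expect_identical(nrow(sim$truth$hydroxyls), 0L)
  expect_identical(nrow(sim$truth$olefins), 0L)
  expect_true(is.na(sim$truth$ring_to))        # linear product
  st <- suppressWarnings(assemble(sim$arch))
  expect_null(st$ring)
})

test_that("degenerate elongation ranges are rejected", {
  expect_error(simulate_architecture(sim_config(1, n_elongations = c(5, 2))),
               "degenerate")
  expect_error(sim_config(1, p_kr = 1.5), "probabilities")
})

test_that("assembly engine output equals the naive-interpreter truth on 500 draws", {
  for (s in 1:500) {
    sim <- simulate_architecture(sim_config(s))
    st <- suppressWarnings(assemble(sim$arch))
    expect_identical(structure_summary(st), naive_summary(sim$truth),
                     info = paste("seed", s))
  }
})

test_that("embedded motifs are recovered and decoys are clean by construction", {
  prot <- simulate_proteins(sim_config(5, n_per_motif = 4, n_decoys = 10))
  motifs <- pal_motifs()
  kr_rows <- prot[!is.na(prot$motif_id) & prot$motif_id == "kr_b_type", ]
  for (i in seq_len(nrow(kr_rows))) {
    expect_identical(classify_kr(kr_rows$seq[i])$kr_type, "B")
  }
  decoys <- prot[is.na(prot$motif_id), ]
  for (i in seq_len(nrow(decoys))) {
    expect_identical(nrow(scan_motifs(decoys$seq[i], motifs)), 0L)
  }
})

test_that("zero-length branches copy the root sequence to every tip", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln <- simulate_alignment(tr, 50, seed = 2)
  rows <- apply(aln, 1, paste, collapse = "")
  expect_identical(length(unique(rows)), 1L)
  expect_error(simulate_alignment(tr, 0, seed = 2), ">= 1")
})

test_that("corrected distances converge to path lengths on long alignments", {
  tr <- ape::read.tree(text = "((a:0.25,b:0.15):0.1,(c:0.2,d:0.3):0.05);")
  aln <- simulate_alignment(tr, 10000, seed = 8)
  D <- jc_dist_matrix(aln)
  path <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  off <- upper.tri(D)
  expect_true(all(abs(D[off] - path[off]) / path[off] < 0.1))
})
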