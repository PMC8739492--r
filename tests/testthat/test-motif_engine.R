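# independent reference scanner: translate the motif syntax to a regex and
# find overlapping matches with the regex engine
regex_scan <- function(seq, pattern) {
  rx <- gsub("x", "X", pattern)
  rx <- gsub("\\(([A-Z/]+)\\)", "[\\1]", rx)
  rx <- gsub("/", "", rx)
  rx <- gsub("X", ".", rx)
  m <- gregexpr(paste0("(?=(", rx, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

test_that("scan_motifs finds exactly the matching windows", {
  hits <- scan_motifs("AAGLDSAA", list(list(motif_id = "acp_beta", pattern = "GXDS")))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 2L)
  expect_identical(hits$matched, "GLDS")

  expect_identical(nrow(scan_motifs("AAAA",
                                    list(list(motif_id = "m", pattern = "GXDS")))), 0L)
})

test_that("illegal residues are reported with their positions", {
  expect_error(scan_motifs("AC1DE"), "position\\(s\\) 3")
  expect_error(scan_motifs(""), "empty")
})

test_that("scan_motifs agrees with a regex-engine oracle on random sequences", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motifs <- pal_motifs()
  for (i in 1:200) {
    seq <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    for (m in motifs) {
      got <- scan_motifs(seq, list(m))$start
      expect_identical(got, regex_scan(seq, m$pattern),
                       info = paste(m$motif_id, seq))
    }
  }
})

test_that("KR typing follows LDD / tryptophan / neither with stated stereochemistry", {
  b <- classify_kr("AAAALDDAAAA")
  expect_identical(b$kr_type, "B")
  expect_identical(b$predicted_config, "D")

  a <- classify_kr("AAAAWAAAA")
  expect_identical(a$kr_type, "A")
  expect_identical(a$predicted_config, "L")

  c3 <- classify_kr("AAAAGAAAA")
  expect_identical(c3$kr_type, "C")
  expect_identical(c3$predicted_config, "none")

  # LDD takes precedence over an active-site tryptophan
  both <- classify_kr("AAWALDDAA")
  expect_identical(both$kr_type, "B")

  expect_error(classify_kr(""), "empty")
})

test_that("condensation domains classify by length with degenerate HHXXDDG matching", {
  set.seed(5)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("H", "D", "G"))
  bg <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
  short <- paste0(bg(60), "HHAADDG", bg(66))   # 133 residues
  res <- classify_condensation(short)
  expect_identical(res$classification, "truncated")
  expect_true(res$catalytic_his)

  long <- paste0(bg(200), "HHAADDG", bg(243))  # ~450 residues
  res <- classify_condensation(long)
  expect_identical(res$classification, "canonical")
  expect_true(res$catalytic_his)

  none <- classify_condensation(bg(300))
  expect_identical(none$classification, "canonical")
  expect_false(none$catalytic_his)

  # up to two mismatches tolerated, but never at the catalytic histidine
  expect_true(classify_condensation(paste0(bg(50), "AHAADDA", bg(50)))$catalytic_his)
  expect_false(classify_condensation(paste0(bg(50), "HAAADDG", bg(50)))$catalytic_his)
})

test_that("AT specificity needs the serine, phenylalanine confers malonate selection", {
  expect_identical(classify_at("AAASAAFAA"), "malonate_specific")
  expect_identical(classify_at("AAASAAAAA"), "relaxed")
  expect_identical(classify_at("AAAAAAAAA"), "inactive")
  # window restriction excludes an out-of-window phenylalanine
  expect_identical(classify_at("FAAASAAAA", phe_window = c(3, 8)), "relaxed")
})

test_that("carrier attachment-site motif accepts both L- and I-terminated forms", {
  ile <- classify_carrier_motif("AAADAGVDSIAAA")
  expect_true(ile$attachment_site_present)
  expect_identical(ile$terminal_residue, "I")

  leu <- classify_carrier_motif("AAEAGADSLAAA")
  expect_true(leu$attachment_site_present)
  expect_identical(leu$terminal_residue, "L")

  none <- classify_carrier_motif("AAAAAAAA")
  expect_false(none$attachment_site_present)
  expect_identical(none$terminal_residue, "other")
})

test_that("classification is deterministic", {
  seq <- "MKTLDDAWVSEAGADSLHHAADDG"
  expect_identical(classify_kr(seq), classify_kr(seq))
  expect_identical(scan_motifs(seq), scan_motifs(seq))
})
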