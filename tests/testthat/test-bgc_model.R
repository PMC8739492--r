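test_that("the pal BGC 4 fixture parses with 25 genes in order and round-trips", {
  arch <- parse_architecture(pal_bgc_path(4), is_file = TRUE)
  expect_s3_class(arch, "bgc_architecture")
  expect_length(arch$genes, 25)
  expect_identical(arch$genes[[1]]$gene_id, "palA")
  expect_null(arch$modules)

  # serialize -> parse identity
  json <- serialize_architecture(arch)
  expect_identical(parse_architecture(json), arch)
})

test_that("malformed and empty fixtures raise informative parse errors", {
  expect_error(parse_architecture("{not json"), "malformed")
  expect_error(parse_architecture('{"bgc_id":"x","genes":[]}'), "empty gene list")
  expect_error(
    parse_architecture('{"bgc_id":"x","genes":[{"gene_id":"gA","domains":[]}]}'),
    "gA")
})

test_that("unknown domain codes map to OTHER with a warning record", {
  arch <- parse_architecture(
    '{"bgc_id":"x","genes":[{"gene_id":"g1","domains":[{"kind":"KS"},{"kind":"WEIRD"},{"kind":"ACP"}]}]}')
  expect_identical(arch$genes[[1]]$domains[[2]]$kind, "OTHER")
  expect_identical(arch$genes[[1]]$domains[[2]]$label, "WEIRD")
  expect_match(arch$parse_warnings, "WEIRD")
})

test_that("segmentation of pal BGC 4 yields 14 core modules, 11 elongating", {
  arch <- pal_arch(4)
  counts <- module_counts(arch)
  expect_identical(unname(counts["modules"]), 14L)
  expect_identical(unname(counts["elongation"]), 11L)
  roles <- vapply(arch$modules, `[[`, character(1), "role")
  expect_identical(roles[1], "loading")
  expect_identical(roles[2], "nrps")
  expect_identical(roles[14], "termination")
  # the starter-dock rule places KS1 and its carrier inside module 1
  m1_kinds <- vapply(arch$modules[[1]]$domains, `[[`, character(1), "kind")
  expect_identical(m1_kinds, c("ACP", "ACP_beta", "ACP", "KS", "PCP"))
  # elongation ordinals are 1..E in order
  ords <- vapply(arch$modules[roles == "pks_elongation"], `[[`, integer(1),
                 "elongation_ordinal")
  expect_identical(ords, 1:11)
})

test_that("a single KS boundary splits a carriers-then-KS stream into two modules", {
  arch <- segment_modules(bgc_architecture("t", list(gene_record("g", list(
    domain("ACP"), domain("KS"), domain("KR", kr_type = "A"), domain("ACP"))))))
  expect_length(arch$modules, 2)
  expect_identical(arch$modules[[1]]$role, "loading")
  expect_identical(arch$modules[[2]]$role, "pks_elongation")
})

test_that("a core stream without KS domains is rejected", {
  expect_error(segment_modules(bgc_architecture("t", list(gene_record("g", list(
    domain("ACP"), domain("C"), domain("A")))))), "no elongation machinery")
})

test_that("segmentation conserves domains and matches a boundary-scan oracle", {
  for (s in 1:50) {
    sim <- simulate_architecture(sim_config(s, n_elongations = c(2, 9)))
    arch <- sim$arch
    core <- unlist(lapply(arch$genes, function(g) {
      if (g$trans_acting) return(character(0))
      vapply(g$domains, `[[`, character(1), "kind")
    }))
    # independent linear scan: one module per boundary domain, plus the
    # pre-boundary loading chunk (generator prefixes are plain carriers, so
    # the starter-dock absorption never applies here)
    oracle_modules <- sum(core %in% c("KS", "C", "C_trunc")) +
      as.integer(!core[1] %in% c("KS", "C", "C_trunc"))
    oracle_elong <- sum(core == "KS")
    counts <- module_counts(arch)
    expect_identical(unname(counts["modules"]), oracle_modules)
    expect_identical(unname(counts["elongation"]), oracle_elong)
    # conservation: modules cover every core domain exactly once
    expect_identical(sum(lengths(lapply(arch$modules, `[[`, "domains"))),
                     length(core))
  }
})

test_that("validation flags the DH-without-KR module of pal BGC 4 without raising", {
  report <- validate_architecture(pal_arch(4))
  flagged <- report[report$severity == "flag", ]
  expect_true(3 %in% flagged$module)
  expect_match(flagged$message[flagged$module == 3], "permissive")
  expect_false(any(report$severity == "violation"))
})

test_that("a fully canonical module set validates cleanly; two KS domains do not", {
  clean <- toy_arch(list(list(domain("KS"), domain("KR", kr_type = "A"))))
  expect_identical(nrow(validate_architecture(clean)), 0L)

  broken <- segment_modules(bgc_architecture("t", list(gene_record("g", list(
    domain("ACP"), domain("KS"), domain("KS"), domain("ACP"),
    domain("C_trunc"))))))
  # force both KS into one module to breach the invariant
  broken$modules <- list(
    list(index = 1L, role = "loading", domains = list(domain("ACP")),
         elongation_ordinal = NA_integer_, trans_annotations = character(0)),
    list(index = 2L, role = "pks_elongation",
         domains = list(domain("KS"), domain("KS"), domain("ACP")),
         elongation_ordinal = 1L, trans_annotations = character(0)),
    list(index = 3L, role = "termination", domains = list(domain("C_trunc")),
         elongation_ordinal = NA_integer_, trans_annotations = character(0)))
  report <- validate_architecture(broken)
  expect_true(any(report$severity == "violation" & grepl("2 KS", report$message)))
})

test_that("parse/serialize round-trips hold over simulated architectures", {
  for (s in 1:25) {
    arch <- simulate_architecture(sim_config(s))$arch
    arch["modules"] <- list(NULL)   # modules are computed, never stored
    rt <- parse_architecture(serialize_architecture(arch))
    expect_identical(rt, arch)
  }
})
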