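# Shared fixture loaders (memoised; tests run against the installed package).

.fixture_cache <- new.env(parent = emptyenv())

pal_arch <- function(i) {
  key <- paste0("bgc", i)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- pal_bgc(i)
  }
  .fixture_cache[[key]]
}

pal_struct <- function(letter) {
  key <- paste0("pal", letter)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- palmerolide_structure(letter)
  }
  .fixture_cache[[key]]
}

# a minimal canonical synthetic architecture: loading + NRPS(gly) +
# elongations given as domain-kind shorthand + termination
toy_arch <- function(elongations, starter = "acetate", nrps = TRUE,
                     site_annotations = list(), trans_genes = list(),
                     tailoring = list()) {
  doms <- list(domain("ACP"))
  if (nrps) doms <- c(doms, list(domain("C"), domain("A", substrate = "glycine"),
                                 domain("ACP")))
  for (spec in elongations) {
    doms <- c(doms, spec, list(domain("ACP")))
  }
  doms <- c(doms, list(domain("C_trunc")))
  genes <- c(list(gene_record("g1", doms)), trans_genes)
  segment_modules(bgc_architecture("toy", genes, starter_monomer = starter,
                                   site_annotations = site_annotations,
                                   tailoring = tailoring))
}

# summarise an assembled structure the same way naive_product() reports,
# for dual-route comparison
structure_summary <- function(st) {
  list(E = st$E,
       polyketide = st$polyketide_carbon_count,
       backbone = st$backbone_carbon_count,
       total = st$total_carbon_count,
       hydroxyls = hydroxyl_positions(st)$position,
       stereo = hydroxyl_positions(st)$stereo,
       ketones = st$table$position[st$table$ketone],
       olefins = olefin_positions(st)$delta,
       geometry = olefin_positions(st)$geometry,
       methyls = st$table$position[st$table$methyl],
       branches = st$table$position[st$table$branch],
       ring = if (is.null(st$ring)) NA_integer_ else st$ring[["to"]])
}

naive_summary <- function(truth) {
  ord <- order(truth$hydroxyls$position)
  oord <- order(truth$olefins$position)
  list(E = truth$E,
       polyketide = truth$polyketide_carbons,
       backbone = truth$backbone_carbons,
       total = truth$total_carbons,
       hydroxyls = truth$hydroxyls$position[ord],
       stereo = truth$hydroxyls$stereo[ord],
       ketones = truth$ketones,
       olefins = truth$olefins$position[oord],
       geometry = truth$olefins$geometry[oord],
       methyls = truth$methyls,
       branches = sort(truth$branches$position),
       ring = truth$ring_to)
}
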