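# Linear SMILES emission for assembled structures.  Stereo is emitted only
# for backbone positions carrying an L/D hydroxyl label (L -> @, D -> @@; an
# arbitrary but fixed mapping, since conversion of the biosynthetic L/D labels
# to CIP descriptors is out of scope).  Olefin geometry is not encoded.

.starter_smiles <- list(
  "3-methylcrotonic_acid" = "C=C(C)C",      # after the acyl carbonyl
  "3-methyl-3-butenoic_acid" = "CC(=C)C",
  "acetate" = "C")

#' Emit a SMILES string for an assembled structure
#'
#' The backbone is walked from C1 (the ester carbonyl) toward the starter;
#' the macrolactone is closed with a ring bond to the nucleophile oxygen;
#' substituent methyls, beta-branches (exo-methylene or internal-olefin
#' form), decorations (carbamate, sulfate, glycosyl stand-in) and the
#' amide-linked starter are appended in place.
#'
#' @param struct A `pal_structure`.
#' @return A SMILES string.
#' @export
to_smiles <- function(struct) {
  stopifnot(inherits(struct, "pal_structure"))
  tab <- struct$table
  n <- nrow(tab)
  ring_to <- if (!is.null(struct$ring)) struct$ring[["to"]] else NA_integer_
  out <- character(0)
  for (i in seq_len(n)) {
    tok <- ""
    if (i > 1 && tab$olefin[i - 1L]) tok <- "="
    atom <- "C"
    if (tab$hydroxyl[i] && !is.na(tab$stereo[i])) {
      atom <- if (tab$stereo[i] == "L") "[C@H]" else "[C@@H]"
    }
    tok <- paste0(tok, atom)
    if (i == 1L) {
      if (!is.na(ring_to)) tok <- paste0(tok, "1(=O)") else tok <- paste0(tok, "(O)(=O)")
    }
    if (!is.na(ring_to) && i == ring_to) {
      tok <- paste0(tok, "(O1)")
    } else if (tab$hydroxyl[i]) {
      deco <- tab$decoration[i]
      sub <- switch(if (is.na(deco)) "free" else deco,
                    free = "(O)",
                    carbamate = "(OC(N)=O)",
                    sulfate = "(OS(=O)(=O)O)",
                    glycosyl = "(OC9OCC(O)C(O)C9O)",
                    lactone = "(O)",
                    "(O)")
      tok <- paste0(tok, sub)
    }
    if (tab$ketone[i]) tok <- paste0(tok, "(=O)")
    if (tab$methyl[i]) tok <- paste0(tok, "(C)")
    if (tab$branch[i]) {
      tok <- paste0(tok, if (tab$branch_internal_olefin[i]) "(C)" else "(=C)")
    }
    out <- c(out, tok)
  }
  if (length(struct$amino_acids)) out <- c(out, "N")
  if (!is.null(struct$starter)) {
    # starter acyl: amide-linked after the amino-acid step, otherwise joined
    # directly to the last polyketide carbon (its carbonyl carbon is the
    # unnumbered beta-carbon of the first elongation)
    ext <- character(0)
    if (struct$tail_extension > 0) {
      for (k in seq_len(struct$tail_extension)) ext <- c(ext, "CC")
      if (struct$tail_methyls > 0) {
        ext <- c(ext, strrep("(C)", struct$tail_methyls))
      }
    }
    out <- c(out, "C(=O)", ext, .starter_smiles[[struct$starter$monomer_id]])
  }
  paste(out, collapse = "")
}

#' Expected heavy-atom composition of a structure's SMILES
#'
#' Recounts carbons and nitrogens from the feature table (including
#' decoration atoms) so that [to_smiles()] output can be checked
#' independently of the emitter.
#'
#' @param struct A `pal_structure`.
#' @return Named integer vector with `C` and `N`.
#' @export
expected_formula <- function(struct) {
  tab <- struct$table
  deco <- tab$decoration[!is.na(tab$decoration)]
  c(C = struct$total_carbon_count +
      sum(deco == "carbamate") + 5L * sum(deco == "glycosyl"),
    N = length(struct$amino_acids) + sum(deco == "carbamate"))
}
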