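# Backbone numbering.  C1 is the carbonyl carbon laid down by the final
# elongation (the ester carbonyl); numbers increase toward the starter.  Each
# elongation e of E contributes carbons alpha(e) = 2*(E-e)+2 and
# alpha(e)-1 = 2*(E-e)+1; the beta-carbon whose oxidation state module e sets,
# beta(e) = 2*(E-e)+3, was contributed by the upstream unit (or by the amino
# acid for e = 1).  Amino-acid backbone carbons are numbered after C(2E) in
# chain order; starter carbons sit beyond the amide nitrogen and are excluded
# from the numbered backbone.  Olefins are named by their lower carbon
# (Delta-n = bond between Cn and Cn+1).

#' Compute the elongation-to-backbone-carbon position map
#'
#' @param E Number of elongation cycles (>= 1).
#' @param amino_acid_carbons Backbone carbons contributed by amino-acid
#'   residues inserted between starter and polyketide (2 for glycine).
#' @return A `position_map`: data frame with columns `e`, `alpha`, `beta`
#'   plus attributes `E`, `backbone_carbons`, `polyketide_carbons`.
#' @export
compute_position_map <- function(E, amino_acid_carbons = 0L) {
  E <- as.integer(E)
  if (is.na(E) || E < 1) stop("E must be >= 1", call. = FALSE)
  e <- seq_len(E)
  map <- data.frame(e = e, alpha = 2L * (E - e) + 2L, beta = 2L * (E - e) + 3L)
  structure(map, class = c("position_map", "data.frame"),
            E = E,
            polyketide_carbons = 2L * E,
            backbone_carbons = 2L * E + as.integer(amino_acid_carbons))
}

#' @export
print.position_map <- function(x, ...) {
  cat("<position_map> E =", attr(x, "E"),
      "| polyketide carbons:", attr(x, "polyketide_carbons"),
      "| backbone carbons:", attr(x, "backbone_carbons"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
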