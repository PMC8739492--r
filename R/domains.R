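# Core domain-type vocabulary and constructors for BGC architectures.

#' Recognised domain codes
#'
#' The closed enumeration of catalytic and carrier domain kinds used in
#' architecture fixtures.  Unknown codes encountered by [parse_architecture()]
#' are mapped to `"OTHER"` (with a warning record), never dropped.
#'
#' @return Character vector of domain codes.
#' @export
domain_kinds <- function() {
  c("KS", "AT", "KR", "DH", "DHt", "ER", "cMT", "ECH",
    "ACP", "ACP_beta", "PCP", "CARRIER_UNRESOLVED",
    "C", "C_trunc", "A", "LLM", "HCS", "CT", "GTF", "LO", "TE", "OTHER")
}

.carrier_kinds <- c("ACP", "ACP_beta", "PCP", "CARRIER_UNRESOLVED")

# domains that change the chemistry of an elongation unit; used by the
# loading-module absorption rule and by capability extraction
.processing_kinds <- c("KR", "DH", "DHt", "ER", "cMT", "ECH", "LLM")

#' Create a single domain annotation
#'
#' @param kind Domain code, one of [domain_kinds()].
#' @param kr_type For `kind = "KR"`: `"A"`, `"B"`, `"C"` or `"unknown"`.
#' @param active Logical; catalytically competent (default `TRUE`).  For the
#'   truncated termination condensation domain this encodes retention of the
#'   catalytic histidine.
#' @param substrate Adenylation substrate (amino-acid name) for `kind = "A"`.
#' @param shift Logical; olefin-shifting dehydratase behaviour (double bond
#'   repositioned from the alpha,beta- to the beta,gamma-position).
#' @param sequence Optional amino-acid sequence for motif scanning.
#' @param label Free-text label retained for `OTHER` domains.
#' @return A `domain_annotation` list.
#' @export
domain <- function(kind, kr_type = NULL, active = TRUE, substrate = NULL,
                   shift = FALSE, sequence = NULL, label = NULL) {
  kind <- as.character(kind)
  if (!kind %in% domain_kinds()) {
    stop("unknown domain kind: ", kind, call. = FALSE)
  }
  if (!is.null(kr_type)) {
    if (kind != "KR") stop("kr_type is only meaningful for KR domains", call. = FALSE)
    kr_type <- match.arg(kr_type, c("A", "B", "C", "unknown"))
  } else if (kind == "KR") {
    kr_type <- "unknown"
  }
  structure(list(kind = kind, kr_type = kr_type, active = isTRUE(active),
                 substrate = substrate, shift = isTRUE(shift),
                 sequence = sequence, label = label),
            class = "domain_annotation")
}

#' Create a gene record
#'
#' @param gene_id Gene name (e.g. `"palA"`).
#' @param domains List of [domain()] annotations, in gene order.
#' @param trans_acting Logical; gene acts in trans (excluded from the core
#'   module stream).
#' @return A `gene_record` list.
#' @export
gene_record <- function(gene_id, domains, trans_acting = FALSE) {
  if (length(domains) == 0) stop("gene ", gene_id, " has no domains", call. = FALSE)
  stopifnot(all(vapply(domains, inherits, logical(1), "domain_annotation")))
  structure(list(gene_id = as.character(gene_id), domains = domains,
                 trans_acting = isTRUE(trans_acting)),
            class = "gene_record")
}

#' Create a (possibly unsegmented) BGC architecture
#'
#' @param bgc_id Cluster identifier.
#' @param genes Ordered list of [gene_record()]s.
#' @param starter_monomer Starter-unit identifier from [monomer_library()], or
#'   `NULL` for clusters lacking a loading module.
#' @param tailoring List of tailoring records, each
#'   `list(enzyme =, target =)` where `target` is a backbone carbon number or
#'   `"default"`.
#' @param site_annotations List of `list(module =, type =)` records attaching
#'   trans-acting sites of action (`"trans_ER"`, `"hcs_site"`, `"llm_site"`)
#'   to core module indices.
#' @return A `bgc_architecture` with an empty `modules` field; see
#'   [segment_modules()].
#' @export
bgc_architecture <- function(bgc_id, genes, starter_monomer = NULL,
                             tailoring = list(), site_annotations = list()) {
  if (length(genes) == 0) stop("architecture has no genes", call. = FALSE)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids", call. = FALSE)
  structure(list(bgc_id = as.character(bgc_id), genes = genes,
                 modules = NULL, starter_monomer = starter_monomer,
                 tailoring = tailoring, site_annotations = site_annotations,
                 parse_warnings = character(0)),
            class = "bgc_architecture")
}

#' Starter-unit monomer library
#'
#' Carbon accounting for the recognised starter units.  `backbone_carbons` is
#' the contribution to the numbered product backbone; by the numbering
#' convention used here starter carbons sit beyond the amide nitrogen and are
#' excluded, so it is 0 for the acyl starters.
#'
#' @return Named list of monomer specifications.
#' @export
monomer_library <- function() {
  list(
    "3-methylcrotonic_acid" = list(
      monomer_id = "3-methylcrotonic_acid", carbon_count = 5L,
      backbone_carbons = 0L, heteroatoms = c(O = 1L),
      terminal_olefin = FALSE, beta_branch_in_starter = TRUE),
    "3-methyl-3-butenoic_acid" = list(
      monomer_id = "3-methyl-3-butenoic_acid", carbon_count = 5L,
      backbone_carbons = 0L, heteroatoms = c(O = 1L),
      terminal_olefin = TRUE, beta_branch_in_starter = TRUE),
    "acetate" = list(
      monomer_id = "acetate", carbon_count = 2L,
      backbone_carbons = 0L, heteroatoms = c(O = 1L),
      terminal_olefin = FALSE, beta_branch_in_starter = FALSE)
  )
}

#' @export
print.domain_annotation <- function(x, ...) {
  extras <- c(
    if (x$kind == "KR") paste0("type=", x$kr_type),
    if (!x$active) "inactive",
    if (x$shift) "shift",
    if (!is.null(x$substrate)) paste0("substrate=", x$substrate),
    if (!is.null(x$label)) paste0("label=", x$label))
  cat(x$kind, if (length(extras)) paste0("[", paste(extras, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.bgc_architecture <- function(x, ...) {
  cat("<bgc_architecture> ", x$bgc_id, "\n", sep = "")
  cat("  genes: ", length(x$genes), " (",
      sum(vapply(x$genes, function(g) !g$trans_acting, logical(1))),
      " core, ",
      sum(vapply(x$genes, function(g) g$trans_acting, logical(1))),
      " trans-acting)\n", sep = "")
  cat("  starter: ", if (is.null(x$starter_monomer)) "none" else x$starter_monomer,
      "\n", sep = "")
  if (is.null(x$modules)) {
    cat("  modules: <not segmented; run segment_modules()>\n")
  } else {
    roles <- vapply(x$modules, `[[`, character(1), "role")
    cat("  modules: ", length(x$modules), " (",
        sum(roles == "pks_elongation"), " elongation)\n", sep = "")
  }
  invisible(x)
}

# internal: flat ordered list of domains across the non-trans-acting genes,
# carrying gene ids and ordinals
core_domain_stream <- function(arch) {
  out <- list()
  for (g in arch$genes) {
    if (g$trans_acting) next
    for (i in seq_along(g$domains)) {
      d <- g$domains[[i]]
      d$gene_id <- g$gene_id
      d$ordinal <- i - 1L
      out[[length(out) + 1L]] <- d
    }
  }
  out
}
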