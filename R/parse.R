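# Architecture fixture format: JSON with top-level bgc_id, genes array,
# starter_monomer, tailoring and site_annotations.  Module boundaries are never
# stored; they are recomputed by segment_modules().

#' Parse a BGC architecture fixture
#'
#' Reads the JSON architecture format.  Gene and domain order is preserved;
#' unknown domain codes are mapped to `OTHER` and recorded in
#' `$parse_warnings`.  The `modules` field is left empty until
#' [segment_modules()] is called.
#'
#' @param text JSON string, or a file path when `is_file = TRUE`.
#' @param is_file Treat `text` as a path.
#' @return A [bgc_architecture()].
#' @export
parse_architecture <- function(text, is_file = FALSE) {
  raw <- tryCatch(
    jsonlite::fromJSON(if (is_file) text else I(text), simplifyVector = FALSE),
    error = function(e) stop("malformed architecture fixture: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(raw$bgc_id)) stop("fixture lacks bgc_id", call. = FALSE)
  if (length(raw$genes) == 0) {
    stop("architecture ", raw$bgc_id, " has an empty gene list", call. = FALSE)
  }
  warnings <- character(0)
  genes <- lapply(raw$genes, function(g) {
    if (is.null(g$gene_id)) stop("gene without gene_id in ", raw$bgc_id, call. = FALSE)
    if (length(g$domains) == 0) {
      stop("gene ", g$gene_id, " has no domains", call. = FALSE)
    }
    domains <- lapply(g$domains, function(d) {
      kind <- d$kind
      if (is.null(kind)) stop("domain without kind in gene ", g$gene_id, call. = FALSE)
      if (!kind %in% domain_kinds()) {
        warnings <<- c(warnings, paste0("gene ", g$gene_id, ": unknown domain code '",
                                        kind, "' mapped to OTHER"))
        d$label <- if (is.null(d$label)) kind else d$label
        kind <- "OTHER"
      }
      domain(kind,
             kr_type = d$kr_type,
             active = if (is.null(d$active)) TRUE else d$active,
             substrate = d$substrate,
             shift = isTRUE(d$shift),
             sequence = d$sequence,
             label = d$label)
    })
    gene_record(g$gene_id, domains, trans_acting = isTRUE(g$trans_acting))
  })
  arch <- bgc_architecture(
    bgc_id = raw$bgc_id, genes = genes,
    starter_monomer = raw$starter_monomer,
    tailoring = lapply(raw$tailoring, function(t)
      list(enzyme = t$enzyme, target = t$target)),
    site_annotations = lapply(raw$site_annotations, function(s)
      list(module = as.integer(s$module), type = s$type)))
  arch$parse_warnings <- warnings
  arch
}

#' Serialise an architecture back to fixture JSON
#'
#' Inverse of [parse_architecture()]: `parse_architecture(serialize_architecture(a))`
#' reproduces `a` (computed modules are not stored).
#'
#' @param arch A [bgc_architecture()].
#' @param path Optional file to write to.
#' @return JSON string, invisibly when `path` is given.
#' @export
serialize_architecture <- function(arch, path = NULL) {
  stopifnot(inherits(arch, "bgc_architecture"))
  genes <- lapply(arch$genes, function(g) {
    list(gene_id = g$gene_id,
         trans_acting = g$trans_acting,
         domains = lapply(g$domains, function(d) {
           out <- list(kind = d$kind)
           if (d$kind == "KR") out$kr_type <- d$kr_type
           if (!d$active) out$active <- FALSE
           if (d$shift) out$shift <- TRUE
           if (!is.null(d$substrate)) out$substrate <- d$substrate
           if (!is.null(d$sequence)) out$sequence <- d$sequence
           if (!is.null(d$label)) out$label <- d$label
           out
         }))
  })
  obj <- list(bgc_id = arch$bgc_id,
              starter_monomer = arch$starter_monomer,
              genes = genes,
              tailoring = arch$tailoring,
              site_annotations = arch$site_annotations)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  as.character(json)
}

#' Read a shipped or on-disk architecture fixture
#'
#' @param path Path to a fixture JSON file.
#' @param segment Also run [segment_modules()].
#' @return A [bgc_architecture()].
#' @export
read_architecture <- function(path, segment = TRUE) {
  arch <- parse_architecture(path, is_file = TRUE)
  if (segment) arch <- segment_modules(arch) else arch
}

#' Path to a shipped pal BGC fixture
#'
#' @param bgc Cluster number 1-5.
#' @return File path under the installed package.
#' @export
pal_bgc_path <- function(bgc) {
  stopifnot(bgc %in% 1:5)
  system.file("extdata", "bgc", paste0("pal_bgc_", bgc, ".json"),
              package = "palcolin", mustWork = TRUE)
}

#' Load a shipped pal BGC architecture, segmented
#'
#' @inheritParams pal_bgc_path
#' @return A segmented [bgc_architecture()].
#' @export
pal_bgc <- function(bgc) read_architecture(pal_bgc_path(bgc))
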