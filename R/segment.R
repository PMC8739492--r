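# Module segmentation: cut the concatenated core-gene domain stream into
# loading / NRPS / elongation / termination modules.

#' Segment a flat domain stream into biosynthetic modules
#'
#' A new module starts at each KS and at each full condensation (C) domain in
#' the concatenated domain stream of the non-trans-acting genes; a trailing
#' truncated condensation domain (`C_trunc`) opens the termination module.
#' Domains before the first boundary form the loading module.
#'
#' One refinement reflects starter loading in beta-branch primed clusters:
#' when the pre-boundary prefix contains a beta-branch accepting carrier
#' (`ACP_beta`, the starter dock) and the first KS chunk is chemically silent
#' (KS plus carriers only), that KS receives the starter unit rather than
#' extending the chain, and is absorbed into the loading module.  This places
#' KS1 and its trailing carrier protein inside module 1 of the pal clusters.
#'
#' @param arch A parsed [bgc_architecture()].
#' @return The architecture with `$modules` populated: each module has
#'   `index` (1-based), `role` (`loading`, `nrps`, `pks_elongation`,
#'   `termination`), `domains`, `elongation_ordinal` (for elongation modules)
#'   and `trans_annotations` (from the fixture's `site_annotations`).
#' @export
segment_modules <- function(arch) {
  stopifnot(inherits(arch, "bgc_architecture"))
  stream <- core_domain_stream(arch)
  kinds <- vapply(stream, `[[`, character(1), "kind")
  if (!any(kinds == "KS")) stop("no elongation machinery: core genes contain no KS domain",
                                call. = FALSE)
  boundary <- kinds %in% c("KS", "C", "C_trunc")
  starts <- which(boundary)
  # chunks: [prefix][chunk at each boundary]
  chunk_of <- cumsum(boundary)              # 0 = prefix
  chunks <- split(stream, chunk_of)
  prefix <- if ("0" %in% names(chunks)) chunks[["0"]] else list()
  chunks <- chunks[names(chunks) != "0"]
  chunk_kind <- kinds[starts]

  # starter-dock absorption of the first KS chunk
  absorb <- FALSE
  if (length(chunks) >= 1 && chunk_kind[1] == "KS" && length(prefix) > 0) {
    prefix_kinds <- vapply(prefix, `[[`, character(1), "kind")
    first_kinds <- vapply(chunks[[1]], `[[`, character(1), "kind")
    silent <- all(first_kinds %in% c("KS", .carrier_kinds))
    if (all(prefix_kinds %in% .carrier_kinds) && "ACP_beta" %in% prefix_kinds && silent) {
      absorb <- TRUE
    }
  }

  modules <- list()
  add_module <- function(domains, role) {
    modules[[length(modules) + 1L]] <<- list(
      index = length(modules) + 1L, role = role, domains = domains,
      elongation_ordinal = NA_integer_, trans_annotations = character(0))
  }
  if (absorb) {
    add_module(c(prefix, chunks[[1]]), "loading")
    chunks <- chunks[-1]
    chunk_kind <- chunk_kind[-1]
  } else if (length(prefix) > 0) {
    add_module(prefix, "loading")
  }
  for (i in seq_along(chunks)) {
    role <- switch(chunk_kind[i],
                   KS = "pks_elongation",
                   C = "nrps",
                   C_trunc = "termination")
    add_module(chunks[[i]], role)
  }

  # elongation ordinals
  e <- 0L
  for (i in seq_along(modules)) {
    if (modules[[i]]$role == "pks_elongation") {
      e <- e + 1L
      modules[[i]]$elongation_ordinal <- e
    }
  }
  # attach site-of-action annotations by module index
  for (s in arch$site_annotations) {
    m <- s$module
    if (m >= 1 && m <= length(modules)) {
      modules[[m]]$trans_annotations <- c(modules[[m]]$trans_annotations, s$type)
    }
  }
  arch$modules <- modules
  arch
}

#' Count core modules and elongation modules
#'
#' @param arch Segmented architecture.
#' @return Named integer vector with `modules` and `elongation`.
#' @export
module_counts <- function(arch) {
  stopifnot(!is.null(arch$modules))
  roles <- vapply(arch$modules, `[[`, character(1), "role")
  c(modules = length(roles), elongation = sum(roles == "pks_elongation"))
}

#' Rule-based validation of a segmented architecture
#'
#' Report-only checks: structural invariant breaches (e.g. an elongation
#' module with two KS domains, an NRPS module without C and A domains) and
#' chemistry flags that require a documented permissive rule (a DH without an
#' accompanying KR, which yields an olefin only under the permissive rule).
#'
#' @param arch Segmented architecture.
#' @return Data frame with columns `module`, `severity`
#'   (`"violation"`/`"flag"`) and `message`; zero rows when fully canonical.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "bgc_architecture"), !is.null(arch$modules))
  rows <- list()
  note <- function(module, severity, message) {
    rows[[length(rows) + 1L]] <<- data.frame(module = module, severity = severity,
                                             message = message)
  }
  for (m in arch$modules) {
    kinds <- vapply(m$domains, `[[`, character(1), "kind")
    if (m$role == "pks_elongation") {
      if (sum(kinds == "KS") != 1) {
        note(m$index, "violation",
             sprintf("elongation module has %d KS domains (expected 1)",
                     sum(kinds == "KS")))
      }
      has_kr <- any(kinds == "KR" &
                      vapply(m$domains, function(d) d$kind == "KR" && d$active &&
                               !identical(d$kr_type, "C"), logical(1)))
      has_dh <- any(vapply(m$domains, function(d) d$kind == "DH" && d$active,
                           logical(1)))
      if (has_dh && !has_kr) {
        note(m$index, "flag", "DH without KR: needs permissive olefin rule")
      }
      if (!any(kinds %in% .carrier_kinds)) {
        note(m$index, "flag", "elongation module lacks a carrier protein")
      }
    }
    if (m$role == "nrps" && !(any(kinds == "C") && any(kinds == "A"))) {
      note(m$index, "violation", "NRPS module must contain C and A domains")
    }
    if (m$role == "termination" && !any(kinds %in% c("C_trunc", "TE"))) {
      note(m$index, "violation", "termination module lacks a release domain")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(module = integer(0), severity = character(0),
                      message = character(0)))
  }
  do.call(rbind, rows)
}
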