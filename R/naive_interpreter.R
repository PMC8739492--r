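# Intentionally naive rule-by-rule interpreter used as ground truth for the
# synthetic-architecture generator.  It re-derives the product summary with
# straight-line code and shares no helpers with the assembly engine (no
# position map, no module-chemistry summary); equivalence of the two routes
# is asserted over hundreds of simulated architectures in the test suite.

#' Naive ground-truth product summary for an architecture
#'
#' @param arch Segmented [bgc_architecture()].
#' @param permissive_dh Allow KR-less DH domains to dehydrate.
#' @return A plain list summarising the product: `E`, carbon counts, and
#'   sorted position/state tables for hydroxyls, ketones, olefins, methyls
#'   and branches, plus the auto-selected ring nucleophile (`NA` if linear).
#' @export
naive_product <- function(arch, permissive_dh = TRUE) {
  roles <- sapply(arch$modules, function(m) m$role)
  nrps_at <- which(roles == "nrps")
  aa_n <- 2L * length(nrps_at)

  # collect elongation modules downstream of the (first) NRPS module
  elong <- list()
  for (i in seq_along(arch$modules)) {
    if (roles[i] != "pks_elongation") next
    if (length(nrps_at) && i < min(nrps_at)) next   # starter-side extension
    elong[[length(elong) + 1L]] <- arch$modules[[i]]
  }
  E <- length(elong)
  backbone <- 2L * E + aa_n

  hydroxyls <- data.frame(position = integer(0), stereo = character(0))
  ketones <- integer(0)
  olefins <- data.frame(position = integer(0), geometry = character(0))
  methyls <- integer(0)
  branches <- data.frame(position = integer(0), internal = logical(0))
  n_branch_methyl <- 0L

  for (e in seq_len(E)) {
    m <- elong[[e]]
    # positions counted from the thioester end by walking the finished chain
    a_pos <- 2L * E - 2L * e + 2L
    b_pos <- a_pos + 1L
    kinds <- sapply(m$domains, function(d) d$kind)
    kr_type <- ""
    for (d in m$domains) {
      if (d$kind == "KR" && d$active && d$kr_type %in% c("A", "B")) kr_type <- d$kr_type
    }
    has_dh <- FALSE
    has_shift <- FALSE
    for (d in m$domains) {
      if (d$kind == "DH" && d$active) has_dh <- TRUE
      if (d$kind %in% c("DH", "DHt") && d$shift) has_shift <- TRUE
    }
    er <- "trans_ER" %in% m$trans_annotations
    hcs <- "hcs_site" %in% m$trans_annotations

    if (hcs) {
      # ketone consumed by the branch
      if (b_pos <= backbone) {
        internal <- "ECH" %in% kinds
        branches <- rbind(branches,
                          data.frame(position = b_pos, internal = internal))
        n_branch_methyl <- n_branch_methyl + 1L
        if (internal && b_pos - 1L >= 1L) {
          olefins <- rbind(olefins, data.frame(position = b_pos - 1L,
                                               geometry = NA_character_))
        }
      }
    } else if (er) {
      # fully reduced
    } else if (kr_type != "" && has_dh) {
      geom <- if (kr_type == "A") "cis" else "trans"
      bond_at <- if (has_shift) b_pos else a_pos
      if (bond_at + 1L <= backbone) {
        olefins <- rbind(olefins, data.frame(position = bond_at, geometry = geom))
      }
    } else if (kr_type != "") {
      if (b_pos <= backbone) {
        hydroxyls <- rbind(hydroxyls, data.frame(
          position = b_pos, stereo = if (kr_type == "A") "L" else "D"))
      }
    } else if (has_dh && permissive_dh) {
      bond_at <- if (has_shift) b_pos else a_pos
      if (bond_at + 1L <= backbone) {
        olefins <- rbind(olefins, data.frame(position = bond_at, geometry = "trans"))
      }
    } else {
      if (b_pos <= backbone) ketones <- c(ketones, b_pos)
    }
    if ("cMT" %in% kinds) methyls <- c(methyls, a_pos)
    if ("LLM" %in% kinds) {
      hydroxyls <- rbind(hydroxyls, data.frame(position = a_pos,
                                               stereo = NA_character_))
    }
  }

  oh_pos <- sort(hydroxyls$position)
  ring_to <- NA_integer_
  eligible <- oh_pos[oh_pos + 1L >= 12L]
  if (length(eligible)) ring_to <- max(eligible)

  lib <- monomer_library()
  starter_c <- if (is.null(arch$starter_monomer)) 0L else {
    lib[[arch$starter_monomer]]$carbon_count
  }
  tails <- 0L
  tail_methyls <- 0L
  for (i in seq_along(arch$modules)) {
    if (roles[i] == "pks_elongation" && length(nrps_at) && i < min(nrps_at)) {
      tails <- tails + 1L
      if (any(sapply(arch$modules[[i]]$domains, function(d) d$kind) == "cMT")) {
        tail_methyls <- tail_methyls + 1L
      }
    }
  }
  total <- starter_c + 2L * E + aa_n + length(methyls) + n_branch_methyl +
    2L * tails + tail_methyls

  ord <- order(hydroxyls$position)
  oord <- order(olefins$position)
  list(E = E,
       polyketide_carbons = 2L * E,
       backbone_carbons = backbone,
       total_carbons = total,
       hydroxyls = hydroxyls[ord, , drop = FALSE],
       ketones = sort(ketones),
       olefins = olefins[oord, , drop = FALSE],
       methyls = sort(methyls),
       branches = branches,
       ring_to = ring_to)
}
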