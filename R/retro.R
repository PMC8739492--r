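# Retrobiosynthesis: invert the forward assembly rules to predict the module
# architecture a structure requires, and score the congruence of a prediction
# against a candidate cluster.

# human-readable domain sets for requirement tokens
.token_label <- c(elongate = "KS", "reduce:A" = "KR(A)", "reduce:B" = "KR(B)",
                  "reduce:any" = "KR", dehydrate = "DH", shift = "DH(shift)",
                  methylate = "cMT", hydroxylate = "LLM/hydroxylase",
                  er_site = "trans-ER", hcs_site = "HCS site", ech = "ECH",
                  free = "(unconstrained)")

#' Predict a module architecture from a structure feature table
#'
#' Walks the backbone from the starter end in elongation pairs and inverts
#' the forward assembly rules: each beta-state implies a required domain set
#' (with documented degeneracies expressed as alternatives, e.g. a trans
#' olefin from either a B-type KR plus DH or a permissive KR-less DH); a
#' beta-branch implies the HCS cassette; glycine-derived backbone carbons
#' imply an NRPS glycine module; a carbamate implies a carbamoyl transferase.
#'
#' @param struct A `pal_structure` (assembled or read via
#'   [read_feature_table()]).
#' @return A `retro_prediction`: predicted elongation count `E`, per-module
#'   requirement alternatives, cluster-level requirements and provenance
#'   notes.
#' @export
retro_predict <- function(struct) {
  stopifnot(inherits(struct, "pal_structure"))
  tab <- struct$table
  backbone_n <- nrow(tab)
  pk <- sum(tab$source == "polyketide")
  if (pk %% 2L != 0L) {
    stop("structure error: odd polyketide backbone carbon count (", pk, ")",
         call. = FALSE)
  }
  # internal consistency: an olefin needs both its carbons
  if (any(tab$olefin & tab$position >= backbone_n)) {
    stop("structure error: olefin at the terminal backbone position", call. = FALSE)
  }
  E <- as.integer(ceiling(pk / 2))
  aa_carbons <- backbone_n - pk
  pmap <- compute_position_map(E, aa_carbons)
  notes <- character(0)

  modules <- vector("list", E)
  for (e in seq_len(E)) {
    alpha <- pmap$alpha[e]
    beta <- pmap$beta[e]
    alts <- NULL
    if (beta > backbone_n) {
      # the unit's beta-carbon lies on the starter side; its processing state
      # is unrecoverable from the numbered backbone (documented degeneracy)
      alts <- list("free")
      notes <- c(notes, sprintf("unit %d: beta-state unconstrained (starter-side)", e))
    } else if (tab$branch[beta]) {
      base <- c("elongate", "hcs_site")
      alts <- list(if (tab$branch_internal_olefin[beta]) c(base, "ech") else base)
    } else if (tab$hydroxyl[beta]) {
      alts <- switch(ifelse(is.na(tab$stereo[beta]), "any", tab$stereo[beta]),
                     L = list(c("elongate", "reduce:A")),
                     D = list(c("elongate", "reduce:B")),
                     any = list(c("elongate", "reduce:any")))
    } else if (tab$olefin[beta]) {
      # beta,gamma-olefin: shifted dehydration
      geo <- tab$geometry[beta]
      red <- switch(ifelse(is.na(geo), "any", geo),
                    cis = "reduce:A", trans = "reduce:B", any = "reduce:any")
      alts <- list(c("elongate", red, "dehydrate", "shift"),
                   c("elongate", "dehydrate", "shift"))
    } else if (tab$olefin[alpha]) {
      geo <- tab$geometry[alpha]
      if (identical(geo, "cis")) {
        alts <- list(c("elongate", "reduce:A", "dehydrate"))
      } else {
        red <- if (identical(geo, "trans")) "reduce:B" else "reduce:any"
        alts <- list(c("elongate", red, "dehydrate"),
                     c("elongate", "dehydrate"))
      }
    } else if (tab$ketone[beta]) {
      alts <- list("elongate")
    } else {
      alts <- list(c("elongate", "reduce:any", "dehydrate", "er_site"))
    }
    if (!identical(alts[[1]], "free")) {
      if (tab$methyl[alpha]) alts <- lapply(alts, c, "methylate")
      if (tab$hydroxyl[alpha]) alts <- lapply(alts, c, "hydroxylate")
    }
    modules[[e]] <- list(e = e, alternatives = alts)
  }

  cluster <- character(0)
  if (!is.null(struct$starter)) {
    cluster <- c(cluster, "loading", paste0("starter:", struct$starter$monomer_id))
  }
  if (length(struct$amino_acids)) cluster <- c(cluster, "nrps_glycine")
  if (any(tab$branch)) cluster <- c(cluster, "hcs_cassette")
  deco <- tab$decoration[!is.na(tab$decoration)]
  if (any(deco == "carbamate")) cluster <- c(cluster, "ct")
  if (any(deco == "sulfate")) {
    cluster <- c(cluster, "sulfotransferase")
    notes <- c(notes, "sulfation attributed to genome-encoded (non-cluster) sulfatases")
  }
  if (any(deco == "glycosyl")) cluster <- c(cluster, "gtf")
  # chain release (cyclising or linear) always needs the termination domain
  cluster <- c(cluster, "termination")
  if (struct$tail_extension > 0) {
    cluster <- c(cluster, paste0("tail_extension:", struct$tail_extension))
  }

  structure(list(E = E, modules = modules, cluster = cluster, notes = notes),
            class = "retro_prediction")
}

#' @export
print.retro_prediction <- function(x, ...) {
  cat("<retro_prediction> E =", x$E, "elongation modules\n")
  for (m in x$modules) {
    alts <- vapply(m$alternatives, function(a)
      paste(ifelse(a %in% names(.token_label), .token_label[a], a), collapse = "+"),
      character(1))
    cat(sprintf("  e%-2d  %s\n", m$e, paste(alts, collapse = "  |  ")))
  }
  cat("  cluster:", paste(x$cluster, collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# capability tokens of an architecture's backbone elongation modules plus
# cluster-level capabilities
arch_capabilities <- function(arch) {
  stopifnot(!is.null(arch$modules))
  roles <- vapply(arch$modules, `[[`, character(1), "role")
  nrps_idx <- which(roles == "nrps")
  first_nrps <- if (length(nrps_idx)) min(nrps_idx) else -Inf
  elong_idx <- which(roles == "pks_elongation")
  backbone_idx <- elong_idx[elong_idx > first_nrps]
  tail_idx <- setdiff(elong_idx, backbone_idx)
  mods <- lapply(arch$modules[backbone_idx], function(m) {
    chem <- module_chemistry(m)
    caps <- "elongate"
    if (!is.null(chem$kr_type) && chem$kr_type %in% c("A", "B")) {
      caps <- c(caps, paste0("reduce:", chem$kr_type))
    }
    if (chem$dh) caps <- c(caps, "dehydrate")
    if (chem$shift) caps <- c(caps, "shift")
    if (chem$cmt) caps <- c(caps, "methylate")
    if (chem$llm) caps <- c(caps, "hydroxylate")
    if (chem$ech) caps <- c(caps, "ech")
    if (chem$trans_er) caps <- c(caps, "er_site")
    if (chem$hcs_site) caps <- c(caps, "hcs_site")
    caps
  })
  trans_kinds <- unlist(lapply(arch$genes, function(g) {
    if (!g$trans_acting) return(character(0))
    vapply(g$domains, `[[`, character(1), "kind")
  }))
  cassette <- detect_hcs_cassette(arch)
  cluster <- character(0)
  if (any(roles == "loading")) cluster <- c(cluster, "loading")
  if (!is.null(arch$starter_monomer)) {
    cluster <- c(cluster, paste0("starter:", arch$starter_monomer))
  }
  if (length(nrps_idx)) cluster <- c(cluster, "nrps_glycine")
  if (any(roles == "termination")) cluster <- c(cluster, "termination")
  if (cassette$hcs && cassette$free_ks) cluster <- c(cluster, "hcs_cassette")
  if (any(trans_kinds == "CT")) cluster <- c(cluster, "ct")
  if (any(trans_kinds == "GTF")) cluster <- c(cluster, "gtf")
  if (length(tail_idx)) {
    cluster <- c(cluster, paste0("tail_extension:", length(tail_idx)))
  }
  list(modules = mods, cluster = cluster)
}

# match one requirement alternative against a capability set; wildcard
# "reduce:any" consumes any reduce:* capability, "free" consumes everything
match_alternative <- function(req, caps) {
  if (identical(req, "free")) {
    return(list(matched = caps, missing = character(0), extra = character(0)))
  }
  matched <- character(0)
  remaining <- caps
  missing <- character(0)
  for (tok in req) {
    hit <- if (tok == "reduce:any") {
      grep("^reduce:", remaining, value = TRUE)[1]
    } else if (tok %in% remaining) tok else NA_character_
    if (!is.na(hit)) {
      matched <- c(matched, hit)
      remaining <- remaining[-match(hit, remaining)]
    } else {
      missing <- c(missing, tok)
    }
  }
  list(matched = matched, missing = missing, extra = remaining)
}

#' Score the congruence of a retro prediction against an architecture
#'
#' Feature assertions are compared per elongation position (requirement
#' alternatives against module capabilities) and at cluster level; the score
#' is the Jaccard-style fraction `matched / (matched + missing + extra)`.
#' The numeric statistic is this package's construction — the congruence is
#' otherwise a qualitative notion — and is labelled as such in output.
#'
#' @param pred A [retro_predict()] result.
#' @param arch A segmented [bgc_architecture()].
#' @return A `congruence_report` with `score`, and `matched` / `missing` /
#'   `extra` assertion tables.
#' @export
congruence_score <- function(pred, arch) {
  stopifnot(inherits(pred, "retro_prediction"))
  caps <- arch_capabilities(arch)
  matched <- character(0)
  missing <- character(0)
  extra <- character(0)
  n_arch <- length(caps$modules)
  for (e in seq_len(max(pred$E, n_arch))) {
    tag <- function(tok) if (length(tok)) paste0("e", e, ":", tok) else character(0)
    if (e <= pred$E && e <= n_arch) {
      cands <- lapply(pred$modules[[e]]$alternatives, match_alternative,
                      caps = caps$modules[[e]])
      cost <- vapply(cands, function(x) length(x$missing) + length(x$extra),
                     numeric(1))
      best <- cands[[which.min(cost)]]
      matched <- c(matched, tag(best$matched))
      missing <- c(missing, tag(best$missing))
      extra <- c(extra, tag(best$extra))
    } else if (e <= pred$E) {
      missing <- c(missing, tag(pred$modules[[e]]$alternatives[[1]]))
    } else {
      extra <- c(extra, tag(caps$modules[[e]]))
    }
  }
  for (tok in pred$cluster) {
    if (tok == "sulfotransferase") {
      matched <- c(matched, paste0("cluster:", tok, " (genome-encoded)"))
    } else if (tok %in% caps$cluster) {
      matched <- c(matched, paste0("cluster:", tok))
    } else {
      missing <- c(missing, paste0("cluster:", tok))
    }
  }
  has_free <- any(vapply(pred$modules, function(m)
    identical(m$alternatives[[1]], "free"), logical(1)))
  for (tok in setdiff(caps$cluster, pred$cluster)) {
    if (tok == "hcs_cassette" && has_free) {
      # a starter-side unit whose beta-state is unrecoverable may be the
      # cassette's site of action (documented degeneracy)
      matched <- c(matched, "cluster:hcs_cassette (starter-side site)")
    } else {
      extra <- c(extra, paste0("cluster:", tok))
    }
  }
  score <- length(matched) / (length(matched) + length(missing) + length(extra))
  structure(list(score = score, matched = matched, missing = missing,
                 extra = extra, bgc_id = arch$bgc_id),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("<congruence_report> vs %s: score %.3f (package-defined Jaccard-style statistic)\n",
              x$bgc_id, x$score))
  cat(sprintf("  matched %d | missing %d | extra %d\n",
              length(x$matched), length(x$missing), length(x$extra)))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  if (length(x$extra)) cat("  extra:  ", paste(x$extra, collapse = ", "), "\n")
  invisible(x)
}
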