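# Forward co-linear assembly: starter capture, amino-acid step, one
# two-carbon extension per elongation module, HCS-cassette beta-branching,
# macrolactonising release and trans-acting tailoring.

#' Initialise an open chain state
#'
#' @param starter Starter monomer id from [monomer_library()], or `NULL` for
#'   clusters without a loading module (free amino-terminus product).
#' @param amino_acids Character vector of amino-acid residues incorporated by
#'   NRPS modules, in order (currently `"glycine"`, contributing two backbone
#'   carbons and one nitrogen).
#' @return A `chain_state` with zero units, `open = TRUE`.
#' @export
initialize_chain <- function(starter = NULL, amino_acids = character(0)) {
  spec <- NULL
  if (!is.null(starter)) {
    lib <- monomer_library()
    if (!starter %in% names(lib)) {
      stop("unknown starter monomer: ", starter, call. = FALSE)
    }
    spec <- lib[[starter]]
  }
  aa <- lapply(amino_acids, function(a) {
    if (!identical(a, "glycine")) {
      stop("unsupported amino acid: ", a, call. = FALSE)
    }
    list(name = "glycine", backbone_carbons = 2L, nitrogens = 1L)
  })
  structure(list(starter = spec, amino_acids = aa, units = list(),
                 tail_extensions = list(), open = TRUE,
                 warnings = character(0)),
            class = "chain_state")
}

# internal: summarise the catalytic content of an elongation module
module_chemistry <- function(module) {
  kinds <- vapply(module$domains, `[[`, character(1), "kind")
  kr <- NULL
  for (d in module$domains) {
    if (d$kind == "KR" && d$active) { kr <- d; break }
  }
  list(
    kr_type = if (!is.null(kr) && kr$kr_type != "C") kr$kr_type else NULL,
    dh = any(vapply(module$domains,
                    function(d) d$kind == "DH" && d$active, logical(1))),
    shift = any(vapply(module$domains,
                       function(d) d$kind %in% c("DH", "DHt") && d$shift,
                       logical(1))),
    cmt = any(kinds == "cMT"),
    llm = any(kinds == "LLM"),
    ech = any(kinds == "ECH"),
    trans_er = "trans_ER" %in% module$trans_annotations,
    hcs_site = "hcs_site" %in% module$trans_annotations
  )
}

#' Apply one elongation module to an open chain
#'
#' Adds one two-carbon unit whose beta-state follows the module's domain set:
#' KS alone gives a ketone; an active A-type KR gives an L-configured
#' (B-type: D-configured) beta-hydroxyl; KR plus DH gives an olefin whose
#' geometry is cis for A-type and trans for B-type KRs; a trans-acting ER
#' annotation reduces the unit to saturation; a DH without KR yields an olefin
#' only under `permissive_dh` (else a ketone with a warning); cMT adds an
#' alpha-methyl, LLM an alpha-hydroxyl; a shift-flagged dehydratase
#' repositions the double bond from the alpha,beta- to the beta,gamma-bond; an
#' in-module ECH or an `hcs_site` annotation marks the unit as the
#' beta-branching substrate.
#'
#' @param chain Open `chain_state`.
#' @param module A `pks_elongation` module from a segmented architecture.
#' @param permissive_dh Allow a KR-less DH to dehydrate (default `TRUE`).
#' @param geometry_override Optional `"cis"`/`"trans"` forcing the olefin
#'   geometry of this unit (used for geometry-variant analogues).
#' @return Updated `chain_state`.
#' @export
apply_elongation <- function(chain, module, permissive_dh = TRUE,
                             geometry_override = NULL) {
  stopifnot(inherits(chain, "chain_state"))
  if (!chain$open) stop("chain is closed", call. = FALSE)
  if (!identical(module$role, "pks_elongation")) {
    stop("module ", module$index, " is not an elongation module", call. = FALSE)
  }
  kinds <- vapply(module$domains, `[[`, character(1), "kind")
  if (sum(kinds == "KS") != 1) {
    stop("elongation module ", module$index, " must contain exactly one KS",
         call. = FALSE)
  }
  chem <- module_chemistry(module)
  warn <- character(0)
  geometry <- NA_character_
  if (chem$trans_er) {
    beta_state <- "saturated"
  } else if (!is.null(chem$kr_type) && chem$dh) {
    beta_state <- "olefin"
    geometry <- switch(chem$kr_type, A = "cis", B = "trans", {
      warn <- c(warn, sprintf("module %d: untyped KR with DH, defaulting to trans olefin",
                              module$index))
      "trans"
    })
  } else if (!is.null(chem$kr_type)) {
    beta_state <- switch(chem$kr_type,
                         A = "hydroxyl_L", B = "hydroxyl_D", {
                           warn <- c(warn, sprintf("module %d: untyped KR, defaulting to L-hydroxyl",
                                                   module$index))
                           "hydroxyl_L"
                         })
  } else if (chem$dh) {
    if (permissive_dh) {
      beta_state <- "olefin"
      geometry <- "trans"
    } else {
      beta_state <- "ketone"
      warn <- c(warn, sprintf("module %d: DH without KR treated as inactive",
                              module$index))
    }
  } else {
    beta_state <- "ketone"
  }
  if (beta_state == "olefin" && chem$shift) beta_state <- "olefin_shifted"
  if (beta_state %in% c("olefin", "olefin_shifted") && !is.null(geometry_override)) {
    geometry <- match.arg(geometry_override, c("cis", "trans"))
  }
  unit <- list(e = length(chain$units) + 1L,
               origin_module = module$index,
               beta_state = beta_state, geometry = geometry,
               alpha_methyl = chem$cmt, alpha_hydroxyl = chem$llm,
               hcs_site = chem$hcs_site, inline_ech = chem$ech,
               branch = NULL)
  chain$units[[length(chain$units) + 1L]] <- unit
  chain$warnings <- c(chain$warnings, warn)
  chain
}

#' Install an HCS-cassette beta-branch on a ketone unit
#'
#' The hydroxymethylglutaryl-CoA synthase (HCS) cassette — a trans-acting
#' carrier protein, HCS, free KS and ECH set — installs a methyl branch at the
#' beta-carbon of a ketone-state unit.  With an in-line ECH present on the
#' accepting module the exocyclic methylene is isomerised to the internal
#' olefin adjacent to the branch; otherwise the exo-methylene is retained.
#'
#' @param chain Open `chain_state`.
#' @param cassette `list(acp =, hcs =, free_ks =, n_ech =)` describing the
#'   trans-acting cassette (see [detect_hcs_cassette()]).
#' @param site_unit Elongation ordinal of the accepting unit.
#' @return Updated `chain_state`.
#' @export
apply_beta_branch <- function(chain, cassette, site_unit) {
  stopifnot(inherits(chain, "chain_state"))
  if (!chain$open) stop("chain is closed", call. = FALSE)
  if (!isTRUE(cassette$hcs) || !isTRUE(cassette$free_ks)) {
    stop("incomplete HCS cassette: requires an HCS and a free KS", call. = FALSE)
  }
  if (site_unit < 1 || site_unit > length(chain$units)) {
    stop("no such elongation unit: ", site_unit, call. = FALSE)
  }
  unit <- chain$units[[site_unit]]
  if (!identical(unit$beta_state, "ketone") || !isTRUE(unit$hcs_site)) {
    stop("beta-branch substrate error: unit ", site_unit,
         " is not an hcs-flagged ketone (state: ", unit$beta_state, ")",
         call. = FALSE)
  }
  unit$branch <- list(methyl = TRUE, internal_olefin = isTRUE(unit$inline_ech))
  unit$beta_state <- "saturated"  # ketone consumed by branch formation
  chain$units[[site_unit]] <- unit
  chain
}

#' Close the chain and build the product feature table
#'
#' Chain release by the truncated condensation domain forms an ester between
#' C1 and an internal hydroxyl (macrolactonisation).  With
#' `nucleophile = "auto"` the hydroxyl-bearing backbone position giving the
#' largest ring of at least 12 atoms is selected; if no hydroxyl qualifies, a
#' linear (free-acid) structure is returned with a warning.
#'
#' @param chain `chain_state` with at least one unit.
#' @param term_module The `termination` module (truncated condensation domain
#'   with its catalytic histidine).
#' @param nucleophile `"auto"` or an explicit backbone carbon number.
#' @param bgc_id Identifier copied onto the structure.
#' @return A `pal_structure`: the per-position feature table plus counts,
#'   ring closure, starter and warning records.
#' @export
terminate_and_cyclize <- function(chain, term_module, nucleophile = "auto",
                                  bgc_id = NA_character_) {
  stopifnot(inherits(chain, "chain_state"))
  if (!chain$open) stop("chain already closed", call. = FALSE)
  if (length(chain$units) == 0) stop("chain has no elongation units", call. = FALSE)
  if (!identical(term_module$role, "termination")) {
    stop("termination module required", call. = FALSE)
  }
  td <- NULL
  for (d in term_module$domains) if (d$kind %in% c("C_trunc", "C")) { td <- d; break }
  if (is.null(td)) stop("termination module lacks a condensation domain", call. = FALSE)
  his <- if (!is.null(td$sequence)) {
    classify_condensation(td$sequence)$catalytic_his
  } else {
    td$active
  }
  if (!isTRUE(his)) {
    stop("termination error: condensation domain lacks the catalytic histidine",
         call. = FALSE)
  }

  E <- length(chain$units)
  aa_carbons <- sum(vapply(chain$amino_acids, `[[`, integer(1), "backbone_carbons"))
  backbone_n <- 2L * E + aa_carbons
  pmap <- compute_position_map(E, aa_carbons)
  warnings <- chain$warnings
  notes <- character(0)

  tab <- data.frame(
    position = seq_len(backbone_n),
    source = c(rep("polyketide", 2L * E), rep("glycine", aa_carbons)),
    hydroxyl = FALSE, stereo = NA_character_, ketone = FALSE,
    olefin = FALSE, geometry = NA_character_,
    methyl = FALSE, methyl_carbon = NA_integer_,
    branch = FALSE, branch_carbon = NA_integer_, branch_internal_olefin = FALSE,
    decoration = NA_character_, stringsAsFactors = FALSE)

  units_df <- data.frame(e = integer(0), origin_module = integer(0),
                         beta_state = character(0), alpha = integer(0),
                         beta = integer(0), olefin_position = integer(0))
  default_ct <- NA_integer_
  alpha_oh <- integer(0)
  for (u in chain$units) {
    alpha <- pmap$alpha[pmap$e == u$e]
    beta <- pmap$beta[pmap$e == u$e]
    olefin_pos <- NA_integer_
    on_backbone <- beta <= backbone_n
    st <- u$beta_state
    if (st == "ketone" && on_backbone) {
      tab$ketone[beta] <- TRUE
    } else if (st %in% c("hydroxyl_L", "hydroxyl_D") && on_backbone) {
      tab$hydroxyl[beta] <- TRUE
      tab$stereo[beta] <- if (st == "hydroxyl_L") "L" else "D"
      tab$decoration[beta] <- "free"
    } else if (st == "olefin") {
      if (beta <= backbone_n) {
        tab$olefin[alpha] <- TRUE
        tab$geometry[alpha] <- u$geometry
        olefin_pos <- alpha
      } else {
        notes <- c(notes, sprintf(
          "unit %d: alpha,beta-olefin extends onto the starter side", u$e))
      }
    } else if (st == "olefin_shifted") {
      if (beta + 1L <= backbone_n) {
        tab$olefin[beta] <- TRUE
        tab$geometry[beta] <- u$geometry
        olefin_pos <- beta
      } else {
        notes <- c(notes, sprintf(
          "unit %d: shifted olefin falls beyond the numbered backbone", u$e))
      }
    } else if (!on_backbone && st != "saturated") {
      notes <- c(notes, sprintf(
        "unit %d: beta-position C%d lies on the starter side of the backbone",
        u$e, beta))
    }
    if (u$alpha_methyl) tab$methyl[alpha] <- TRUE
    if (u$alpha_hydroxyl) {
      tab$hydroxyl[alpha] <- TRUE
      tab$decoration[alpha] <- "free"
      alpha_oh <- c(alpha_oh, alpha)
      if (on_backbone && tab$hydroxyl[beta]) default_ct <- beta
    }
    if (!is.null(u$branch) && on_backbone) {
      tab$branch[beta] <- TRUE
      if (isTRUE(u$branch$internal_olefin) && beta - 1L >= 1L) {
        tab$olefin[beta - 1L] <- TRUE
        tab$branch_internal_olefin[beta] <- TRUE
      }
    }
    units_df <- rbind(units_df, data.frame(
      e = u$e, origin_module = u$origin_module, beta_state = st,
      alpha = alpha, beta = beta, olefin_position = olefin_pos))
  }

  # methyl carbon numbering: substituent methyls (beta-branch and SAM-derived
  # alpha-methyls) are numbered after the backbone, by increasing host carbon
  hosts <- sort(c(which(tab$methyl), which(tab$branch)))
  next_c <- backbone_n
  for (h in hosts) {
    next_c <- next_c + 1L
    if (tab$branch[h]) tab$branch_carbon[h] <- next_c else tab$methyl_carbon[h] <- next_c
  }

  # ring closure
  ring <- NULL
  candidates <- which(tab$hydroxyl)
  if (identical(nucleophile, "auto")) {
    eligible <- candidates[candidates + 1L >= 12L]  # ring atoms = n carbons + ester O
    if (length(eligible)) {
      ring <- c(from = 1L, to = max(eligible))
    } else {
      warnings <- c(warnings, "no eligible hydroxyl for macrolactonization; linear product")
      warning("no eligible hydroxyl for macrolactonization; returning linear structure",
              call. = FALSE)
    }
  } else {
    nucleophile <- as.integer(nucleophile)
    if (!nucleophile %in% candidates) {
      stop("nucleophile position C", nucleophile, " lacks a hydroxyl", call. = FALSE)
    }
    ring <- c(from = 1L, to = nucleophile)
  }
  if (!is.null(ring)) tab$decoration[ring["to"]] <- "lactone"

  n_tail <- length(chain$tail_extensions)
  tail_methyls <- sum(vapply(chain$tail_extensions, function(x) x$methyls, integer(1)))
  n_methyl <- sum(tab$methyl)
  n_branch <- sum(tab$branch)
  starter_carbons <- if (is.null(chain$starter)) 0L else chain$starter$carbon_count
  total <- starter_carbons + 2L * E + aa_carbons + n_methyl + n_branch +
    2L * n_tail + tail_methyls

  structure(list(
    bgc_id = bgc_id,
    E = E,
    polyketide_carbon_count = 2L * E,
    backbone_carbon_count = backbone_n,
    total_carbon_count = total,
    starter = chain$starter,
    amino_acids = chain$amino_acids,
    tail_extension = n_tail,
    tail_methyls = tail_methyls,
    terminal_olefin = !is.null(chain$starter) && isTRUE(chain$starter$terminal_olefin),
    table = tab,
    units = units_df,
    alpha_hydroxyls = alpha_oh,
    ring = ring,
    default_ct_target = default_ct,
    hydrolyzed = FALSE,
    warnings = warnings,
    notes = notes), class = "pal_structure")
}

#' Detect the trans-acting HCS cassette of a cluster
#'
#' @param arch Architecture with trans-acting genes flagged.
#' @return `list(acp, hcs, free_ks, n_ech)` summarising the cassette content
#'   found among the trans-acting genes.
#' @export
detect_hcs_cassette <- function(arch) {
  kinds <- unlist(lapply(arch$genes, function(g) {
    if (!g$trans_acting) return(character(0))
    vapply(g$domains, `[[`, character(1), "kind")
  }))
  list(acp = any(kinds %in% .carrier_kinds),
       hcs = any(kinds == "HCS"),
       free_ks = any(kinds == "KS"),
       n_ech = sum(kinds == "ECH"))
}

#' Apply trans-acting tailoring enzymes to a finalised structure
#'
#' Carbamoyl transfer (`CT`) installs a carbamate, sulfotransferase a sulfate
#' and glycosyl transferase (`GTF`) a glycosyl group, each on an existing free
#' hydroxyl; a trans-acting `hydroxylase` adds a hydroxyl at a stated
#' position.  A target of `"default"` resolves to the beta-hydroxyl of the
#' LLM-containing module when it lies on the numbered backbone, otherwise to
#' the highest-numbered backbone hydroxyl.  Targets are consumed: decorating
#' the same hydroxyl twice is a tailoring error.
#'
#' @param struct A `pal_structure`.
#' @param tailoring List of `list(enzyme =, target =)` records.
#' @return Updated `pal_structure`.
#' @export
apply_tailoring <- function(struct, tailoring) {
  stopifnot(inherits(struct, "pal_structure"))
  tab <- struct$table
  resolve <- function(target) {
    if (identical(target, "default")) {
      if (!is.na(struct$default_ct_target)) return(struct$default_ct_target)
      free <- which(tab$hydroxyl & !is.na(tab$decoration) & tab$decoration == "free")
      if (!length(free)) stop("tailoring error: no free hydroxyl for default target",
                              call. = FALSE)
      return(max(free))
    }
    as.integer(target)
  }
  for (t in tailoring) {
    enz <- t$enzyme
    if (identical(enz, "hydroxylase")) {
      pos <- as.integer(t$target)
      if (is.na(pos) || pos < 1 || pos > nrow(tab)) {
        stop("tailoring error: hydroxylase target off the backbone", call. = FALSE)
      }
      tab$hydroxyl[pos] <- TRUE
      if (is.na(tab$decoration[pos])) tab$decoration[pos] <- "free"
      next
    }
    deco <- switch(enz,
                   CT = "carbamate",
                   sulfotransferase = "sulfate",
                   GTF = "glycosyl",
                   stop("unknown tailoring enzyme: ", enz, call. = FALSE))
    pos <- resolve(t$target)
    if (pos < 1 || pos > nrow(tab) || !tab$hydroxyl[pos]) {
      stop("tailoring error: position C", pos, " lacks a hydroxyl", call. = FALSE)
    }
    if (!identical(tab$decoration[pos], "free")) {
      stop("tailoring error: hydroxyl at C", pos, " already consumed (",
           tab$decoration[pos], ")", call. = FALSE)
    }
    tab$decoration[pos] <- deco
  }
  struct$table <- tab
  struct
}

#' Assemble the predicted product of a segmented architecture
#'
#' Composition of [initialize_chain()], per-module [apply_elongation()],
#' [apply_beta_branch()] at HCS-flagged sites, [terminate_and_cyclize()] and
#' [apply_tailoring()].  Elongation modules occurring before an NRPS module
#' extend the starter unit (their carbons sit beyond the amide nitrogen and
#' are recorded as a tail extension, not numbered backbone).
#'
#' @param arch Segmented [bgc_architecture()].
#' @param permissive_dh Allow KR-less DH domains to dehydrate.
#' @param nucleophile Macrolactonisation nucleophile (see
#'   [terminate_and_cyclize()]).
#' @param geometry_override Named list mapping core module index to a forced
#'   olefin geometry (`"cis"`/`"trans"`).
#' @param tailoring Replacement tailoring list; default the architecture's.
#' @param run_tailoring Apply the tailoring step.
#' @return A `pal_structure`.
#' @export
assemble <- function(arch, permissive_dh = TRUE, nucleophile = "auto",
                     geometry_override = NULL, tailoring = NULL,
                     run_tailoring = TRUE) {
  stopifnot(inherits(arch, "bgc_architecture"))
  if (is.null(arch$modules)) {
    stop("architecture must be segmented first (segment_modules)", call. = FALSE)
  }
  roles <- vapply(arch$modules, `[[`, character(1), "role")
  nrps_idx <- which(roles == "nrps")
  amino_acids <- unlist(lapply(arch$modules[nrps_idx], function(m) {
    sub <- NULL
    for (d in m$domains) if (d$kind == "A") sub <- d$substrate
    if (is.null(sub)) "glycine" else sub
  }))
  chain <- initialize_chain(arch$starter_monomer,
                            if (is.null(amino_acids)) character(0) else amino_acids)

  elong_idx <- which(roles == "pks_elongation")
  first_nrps <- if (length(nrps_idx)) min(nrps_idx) else -Inf
  step <- function(expr, module_index) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("module %d: %s", module_index, conditionMessage(e)), call. = FALSE)
    })
  }
  for (i in elong_idx) {
    m <- arch$modules[[i]]
    if (i < first_nrps) {
      # starter-side extension (e.g. the extra KS+cMT module of pal BGCs 1/3)
      chem <- module_chemistry(m)
      chain$tail_extensions[[length(chain$tail_extensions) + 1L]] <-
        list(module = m$index, methyls = as.integer(chem$cmt))
      next
    }
    ov <- NULL
    if (!is.null(geometry_override)) {
      ov <- geometry_override[[as.character(m$index)]]
    }
    chain <- step(apply_elongation(chain, m, permissive_dh = permissive_dh,
                                   geometry_override = ov), m$index)
  }

  hcs_units <- which(vapply(chain$units, function(u) isTRUE(u$hcs_site), logical(1)))
  if (length(hcs_units)) {
    cassette <- detect_hcs_cassette(arch)
    for (e in hcs_units) {
      chain <- step(apply_beta_branch(chain, cassette, e),
                    chain$units[[e]]$origin_module)
    }
  }

  term_idx <- which(roles == "termination")
  if (!length(term_idx)) stop("architecture has no termination module", call. = FALSE)
  struct <- terminate_and_cyclize(chain, arch$modules[[term_idx[1]]],
                                  nucleophile = nucleophile, bgc_id = arch$bgc_id)
  if (run_tailoring) {
    tl <- if (is.null(tailoring)) arch$tailoring else tailoring
    if (length(tl)) struct <- apply_tailoring(struct, tl)
  }
  struct
}

#' Post-assembly amide hydrolysis (speculative variant mechanism)
#'
#' Cleaves the glycine amide of a finalised structure, removing the
#' amino-acid carbons and any starter from the product; backbone numbering of
#' the polyketide positions is unchanged.
#'
#' @param struct A `pal_structure` containing an amino-acid step.
#' @return Updated `pal_structure` with `hydrolyzed = TRUE`.
#' @export
hydrolyze_amide <- function(struct) {
  stopifnot(inherits(struct, "pal_structure"))
  if (length(struct$amino_acids) == 0) {
    stop("structure has no amide to hydrolyse", call. = FALSE)
  }
  keep <- struct$table$source == "polyketide"
  struct$table <- struct$table[keep, , drop = FALSE]
  struct$backbone_carbon_count <- sum(keep)
  aa_c <- sum(vapply(struct$amino_acids, `[[`, integer(1), "backbone_carbons"))
  starter_c <- if (is.null(struct$starter)) 0L else struct$starter$carbon_count
  struct$total_carbon_count <- struct$total_carbon_count - aa_c - starter_c -
    2L * struct$tail_extension - struct$tail_methyls
  struct$amino_acids <- list()
  struct$starter <- NULL
  struct$tail_extension <- 0L
  struct$tail_methyls <- 0L
  struct$terminal_olefin <- FALSE
  struct$hydrolyzed <- TRUE
  struct
}

#' Summary accessors for assembled structures
#'
#' `olefin_positions()` returns the Delta indices (lower-carbon convention)
#' with geometry; `hydroxyl_positions()` the hydroxyl-bearing carbons with
#' stereo labels and decorations.
#'
#' @param struct A `pal_structure`.
#' @return A data frame.
#' @export
olefin_positions <- function(struct) {
  tab <- struct$table
  idx <- which(tab$olefin)
  data.frame(delta = tab$position[idx], geometry = tab$geometry[idx])
}

#' @rdname olefin_positions
#' @export
hydroxyl_positions <- function(struct) {
  tab <- struct$table
  idx <- which(tab$hydroxyl)
  data.frame(position = tab$position[idx], stereo = tab$stereo[idx],
             decoration = tab$decoration[idx])
}

#' @export
print.pal_structure <- function(x, ...) {
  cat("<pal_structure>", if (!is.na(x$bgc_id)) x$bgc_id, "\n")
  cat("  elongation cycles (E):      ", x$E, "\n")
  cat("  polyketide backbone carbons:", x$polyketide_carbon_count, "\n")
  cat("  total backbone carbons:     ", x$backbone_carbon_count,
      if (length(x$amino_acids)) sprintf(" (incl. %d amino-acid carbons)",
                                         sum(vapply(x$amino_acids, `[[`, integer(1),
                                                    "backbone_carbons"))), "\n", sep = "")
  cat("  total carbons (scaffold):   ", x$total_carbon_count, "\n")
  cat("  starter: ",
      if (is.null(x$starter)) "none" else x$starter$monomer_id,
      if (x$terminal_olefin) " (terminal olefin)",
      if (x$tail_extension > 0) sprintf(" (+%d tail extension)", x$tail_extension),
      "\n", sep = "")
  ole <- olefin_positions(x)
  if (nrow(ole)) {
    cat("  olefins: ",
        paste(sprintf("Δ%d(%s)", ole$delta,
                      ifelse(is.na(ole$geometry), "?", ole$geometry)),
              collapse = " "), "\n", sep = "")
  }
  oh <- hydroxyl_positions(x)
  if (nrow(oh)) {
    cat("  hydroxyls:",
        paste(sprintf("C%d[%s%s]", oh$position,
                      ifelse(is.na(oh$stereo), "-", oh$stereo),
                      ifelse(is.na(oh$decoration) | oh$decoration == "free", "",
                             paste0(",", oh$decoration))),
              collapse = " "), "\n")
  }
  br <- which(x$table$branch)
  if (length(br)) {
    cat("  beta-branch methyl at:",
        paste(sprintf("C%d%s", br,
                      ifelse(x$table$branch_internal_olefin[br],
                             " (internal olefin)", " (exo-methylene)")),
              collapse = " "), "\n")
  }
  if (!is.null(x$ring)) {
    cat("  ring: ester(C", x$ring["from"], ", C", x$ring["to"], ")\n", sep = "")
  } else {
    cat("  ring: linear\n")
  }
  if (x$hydrolyzed) cat("  note: amide hydrolysed (speculative)\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pal_structure <- function(object, ...) {
  print(object)
  cat("\nPer-position feature table:\n")
  print(object$table, row.names = FALSE)
  invisible(object)
}
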