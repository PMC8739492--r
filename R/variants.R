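# Comparison of multi-copy cluster architectures and assignment of candidate
# analogues via the three diversity mechanisms: trans-acting site-of-action
# variants, starter-unit promiscuity, and core-module differences.

# canonical per-module signature string used for diffing
module_signature <- function(m) {
  doms <- vapply(m$domains, function(d) {
    paste0(d$kind,
           if (d$kind == "KR") paste0("(", d$kr_type, ")"),
           if (d$shift) "*",
           if (!d$active) "!")
  }, character(1))
  paste0(m$role, ":", paste(doms, collapse = "+"),
         if (length(m$trans_annotations)) {
           paste0("{", paste(sort(m$trans_annotations), collapse = ","), "}")
         })
}

lcs_table <- function(a, b) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- if (a[i] == b[j]) L[i, j] + 1L else max(L[i, j + 1], L[i + 1, j])
    }
  }
  L
}

#' Module-level diff between two segmented architectures
#'
#' Computes a minimal module-level edit script via longest common subsequence
#' over module domain signatures; unmatched modules between common anchors
#' are paired as modifications (with domain-level differences) where
#' possible, the remainder reported as insertions/deletions.  The diff is
#' verified by patching: applying it to `a`'s module signatures must
#' reproduce `b`'s.
#'
#' @param a,b Segmented [bgc_architecture()]s.
#' @return An `architecture_diff` with `module_ops` (data frame of `keep` /
#'   `modify` / `delete` / `insert` operations), `starter_diff` and
#'   `trans_diff`.
#' @export
diff_architectures <- function(a, b) {
  stopifnot(!is.null(a$modules), !is.null(b$modules))
  sa <- vapply(a$modules, module_signature, character(1))
  sb <- vapply(b$modules, module_signature, character(1))
  L <- lcs_table(sa, sb)
  ops <- list()
  i <- length(sa); j <- length(sb)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && sa[i] == sb[j]) {
      ops[[length(ops) + 1L]] <- data.frame(op = "keep", a_index = i, b_index = j,
                                            signature = sa[i])
      i <- i - 1; j <- j - 1
    } else if (j > 0 && (i == 0 || L[i + 1, j] >= L[i, j + 1])) {
      ops[[length(ops) + 1L]] <- data.frame(op = "insert", a_index = NA_integer_,
                                            b_index = j, signature = sb[j])
      j <- j - 1
    } else {
      ops[[length(ops) + 1L]] <- data.frame(op = "delete", a_index = i,
                                            b_index = NA_integer_, signature = sa[i])
      i <- i - 1
    }
  }
  module_ops <- do.call(rbind, rev(ops))
  # pair adjacent delete/insert runs as modifications
  if (!is.null(module_ops) && nrow(module_ops)) {
    rle_op <- rle(module_ops$op)
    ends <- cumsum(rle_op$lengths)
    starts <- ends - rle_op$lengths + 1L
    for (r in seq_along(rle_op$values)) {
      if (r < length(rle_op$values) && rle_op$values[r] == "delete" &&
          rle_op$values[r + 1] == "insert") {
        k <- min(rle_op$lengths[r], rle_op$lengths[r + 1])
        for (t in seq_len(k)) {
          di <- starts[r] + t - 1L
          ii <- starts[r + 1] + t - 1L
          module_ops$op[di] <- "modify"
          module_ops$b_index[di] <- module_ops$b_index[ii]
          module_ops$signature[di] <- paste(module_ops$signature[di], "->",
                                            module_ops$signature[ii])
          module_ops$op[ii] <- "drop"
        }
      }
    }
    module_ops <- module_ops[module_ops$op != "drop", , drop = FALSE]
    rownames(module_ops) <- NULL
  }
  trans_kinds <- function(x) sort(unlist(lapply(x$genes, function(g) {
    if (!g$trans_acting) return(character(0))
    vapply(g$domains, `[[`, character(1), "kind")
  })))
  out <- structure(list(
    a = a$bgc_id, b = b$bgc_id,
    module_ops = module_ops,
    changed = module_ops[module_ops$op != "keep", , drop = FALSE],
    starter_diff = if (!identical(a$starter_monomer, b$starter_monomer)) {
      c(a = if (is.null(a$starter_monomer)) "none" else a$starter_monomer,
        b = if (is.null(b$starter_monomer)) "none" else b$starter_monomer)
    },
    trans_diff = list(only_a = setdiff(trans_kinds(a), trans_kinds(b)),
                      only_b = setdiff(trans_kinds(b), trans_kinds(a)))),
    class = "architecture_diff")
  # patch verification: replay the edit script over a's signatures
  patched <- character(0)
  for (r in seq_len(nrow(module_ops))) {
    op <- module_ops$op[r]
    if (op == "keep") patched <- c(patched, sa[module_ops$a_index[r]])
    if (op == "modify") patched <- c(patched, sb[module_ops$b_index[r]])
    if (op == "insert") patched <- c(patched, sb[module_ops$b_index[r]])
  }
  stopifnot(identical(patched, sb))
  out
}

#' @export
print.architecture_diff <- function(x, ...) {
  cat("<architecture_diff>", x$a, "vs", x$b, "\n")
  ch <- x$changed
  if (!nrow(ch) && is.null(x$starter_diff)) {
    cat("  identical module structure\n")
  } else {
    for (r in seq_len(nrow(ch))) {
      cat(sprintf("  %s  %s\n", ch$op[r], ch$signature[r]))
    }
    if (!is.null(x$starter_diff)) {
      cat("  starter:", x$starter_diff["a"], "->", x$starter_diff["b"], "\n")
    }
  }
  invisible(x)
}

#' Read analogue definitions from YAML
#'
#' @param path YAML file; default the shipped palmerolide A-H definitions.
#' @return List of definitions (`name`, `mechanisms`, `assertions`,
#'   `speculative`).
#' @export
read_analogue_definitions <- function(path = system.file(
  "extdata", "analogues.yaml", package = "palcolin", mustWork = TRUE)) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(d) {
    if (is.null(d$name) || is.null(d$assertions)) {
      stop("analogue definition error: each entry needs a name and assertions",
           call. = FALSE)
    }
    d$mechanisms <- as.character(unlist(d$mechanisms))
    d$speculative <- isTRUE(d$speculative)
    d
  })
}

# check one feature assertion against an assembled structure
check_assertion <- function(struct, a) {
  tab <- struct$table
  at <- function(pos) pos >= 1 && pos <= nrow(tab)
  switch(a$type,
    backbone_carbons = struct$backbone_carbon_count == a$value,
    polyketide_carbons = struct$polyketide_carbon_count == a$value,
    starter = {
      id <- if (is.null(struct$starter)) "none" else struct$starter$monomer_id
      identical(id, a$value)
    },
    tail_extension = struct$tail_extension == a$value,
    terminal_olefin = identical(struct$terminal_olefin, isTRUE(a$value)),
    hydrolyzed = identical(struct$hydrolyzed, isTRUE(a$value)),
    decoration = at(a$position) && identical(tab$decoration[a$position], a$decoration),
    hydroxyl = at(a$position) && tab$hydroxyl[a$position] &&
      (is.null(a$stereo) || identical(tab$stereo[a$position], a$stereo)),
    olefin = at(a$position) && tab$olefin[a$position] &&
      (is.null(a$geometry) || identical(tab$geometry[a$position], a$geometry)),
    branch = at(a$position) && tab$branch[a$position],
    ring = !is.null(struct$ring) && struct$ring[["to"]] == a$to,
    stop("unknown analogue assertion vocabulary: ", a$type, call. = FALSE))
}

# apply the trans-site post-assembly swaps to a structure
apply_trans_site_swaps <- function(struct, ct_swap, hydroxylase_swap) {
  tab <- struct$table
  if (hydroxylase_swap) {
    if (!length(struct$alpha_hydroxyls)) return(NULL)
    from <- struct$alpha_hydroxyls[1]
    to <- from - 2L
    if (to < 1) return(NULL)
    tab$hydroxyl[from] <- FALSE
    tab$decoration[from] <- NA_character_
    tab$hydroxyl[to] <- TRUE
    tab$decoration[to] <- "free"
    # olefin repositioning away from the new hydroxylation site
    if (tab$olefin[to]) {
      tab$olefin[to] <- FALSE
      g <- tab$geometry[to]
      tab$geometry[to] <- NA_character_
      if (to + 1L < nrow(tab)) {
        tab$olefin[to + 1L] <- TRUE
        tab$geometry[to + 1L] <- g
      }
    }
    struct$alpha_hydroxyls <- c(to, struct$alpha_hydroxyls[-1])
  }
  struct$table <- tab
  ct_target <- struct$default_ct_target
  if (is.na(ct_target)) return(NULL)
  if (ct_swap) {
    free_beta <- which(tab$hydroxyl & !is.na(tab$stereo) &
                         !is.na(tab$decoration) & tab$decoration == "free")
    free_beta <- setdiff(free_beta, ct_target)
    if (!length(free_beta)) return(NULL)
    struct <- apply_tailoring(struct, list(
      list(enzyme = "CT", target = min(free_beta)),
      list(enzyme = "sulfotransferase", target = ct_target)))
  } else {
    struct <- apply_tailoring(struct, list(list(enzyme = "CT", target = ct_target)))
  }
  struct
}

# enumerate variant structures of one architecture within the mechanism budget
enumerate_variants <- function(arch, variant_budget) {
  shift_mods <- vapply(arch$modules, function(m) {
    chem <- module_chemistry(m)
    identical(m$role, "pks_elongation") && chem$shift && chem$dh &&
      !is.null(chem$kr_type)
  }, logical(1))
  geom_module <- if (any(shift_mods)) which(shift_mods)[1] else NA_integer_
  has_starter <- !is.null(arch$starter_monomer)
  out <- list()
  for (ct_swap in c(FALSE, TRUE)) {
    for (hcx_swap in c(FALSE, TRUE)) {
      for (starter_swap in if (has_starter) c(FALSE, TRUE) else FALSE) {
        for (geom in if (!is.na(geom_module)) c(FALSE, TRUE) else FALSE) {
          for (hydro in if (!has_starter) c(FALSE, TRUE) else FALSE) {
            classes <- c(if (ct_swap || hcx_swap) "trans_site",
                         if (starter_swap) "starter",
                         if (geom) "core_geometry",
                         if (hydro) "amide_hydrolysis")
            if (length(classes) > variant_budget) next
            v_arch <- arch
            if (starter_swap) v_arch$starter_monomer <- "3-methyl-3-butenoic_acid"
            ov <- if (geom) setNames(list("cis"), as.character(geom_module))
            struct <- tryCatch(
              suppressWarnings(assemble(v_arch, geometry_override = ov,
                                        run_tailoring = FALSE)),
              error = function(e) NULL)
            if (is.null(struct)) next
            has_ct <- any(vapply(arch$tailoring, function(t)
              identical(t$enzyme, "CT"), logical(1)))
            if (has_ct) {
              struct <- tryCatch(
                apply_trans_site_swaps(struct, ct_swap, hcx_swap),
                error = function(e) NULL)
            } else if (ct_swap || hcx_swap) {
              struct <- NULL
            }
            if (is.null(struct)) next
            if (hydro) {
              struct <- tryCatch(hydrolyze_amide(struct), error = function(e) NULL)
              if (is.null(struct)) next
            }
            out[[length(out) + 1L]] <- list(classes = classes, struct = struct)
          }
        }
      }
    }
  }
  out
}

#' Assign candidate analogues to a set of cluster architectures
#'
#' For each architecture, enumerates the allowed variant applications
#' (starter swap to the terminal-olefin isomer, carbamoyl-transfer target
#' swap with sulfation of the freed hydroxyl, hydroxylase site swap with
#' olefin repositioning, olefin-geometry override, and — for starter-less
#' clusters only — post-assembly amide hydrolysis), assembles each variant,
#' and reports the analogues whose required feature assertions are fully
#' satisfied by some variant using no more mechanism classes than
#' `variant_budget` and only mechanisms the definition allows.
#'
#' @param archs List of segmented [bgc_architecture()]s.
#' @param defs Analogue definitions ([read_analogue_definitions()]).
#' @param variant_budget Maximum number of diversity-mechanism classes per
#'   candidate (default 2).
#' @return Named list mapping `bgc_id` to a character vector of analogue
#'   names; attribute `"speculative"` lists assignments flagged speculative.
#' @export
assign_analogues <- function(archs, defs = read_analogue_definitions(),
                             variant_budget = 2) {
  spec_notes <- character(0)
  out <- list()
  for (arch in archs) {
    variants <- enumerate_variants(arch, variant_budget)
    hits <- character(0)
    for (d in defs) {
      ok <- FALSE
      for (v in variants) {
        if (!all(v$classes %in% d$mechanisms)) next
        if (all(vapply(d$assertions, function(a) check_assertion(v$struct, a),
                       logical(1)))) {
          ok <- TRUE
          break
        }
      }
      if (ok) {
        hits <- c(hits, d$name)
        if (d$speculative) {
          spec_notes <- c(spec_notes, paste0(arch$bgc_id, " -> ", d$name,
                                             " (speculative)"))
        }
      }
    }
    out[[arch$bgc_id]] <- hits
  }
  attr(out, "speculative") <- spec_notes
  out
}
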