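# Seeded generators for synthetic test inputs: random valid architectures
# (with ground truth computed by the independent naive interpreter), motif
# labelled protein sets, and alignments evolved under the Jukes-Cantor model.
#
# All generators are pure functions of (cfg, seed): each derives its own RNG
# stream from the seed (so adding a generator never perturbs existing
# fixtures) and restores the caller's RNG state on exit.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(expr)
}

#' Default simulation configuration
#'
#' @param seed Integer seed (mandatory; there is no wall-clock seeding).
#' @param ... Overrides for the defaults: `n_elongations` (range),
#'   probabilities `p_nrps`, `p_kr`, `p_dh_given_kr`, `p_cmt`, `p_trans_er`,
#'   `p_hcs`, `p_llm`, `p_shift_given_dh`, `p_inline_ech_given_hcs`,
#'   `kr_type_probs`, plus `protein_length`, `n_per_motif`, `n_decoys`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_elongations = c(3L, 8L),
              p_nrps = 0.5, p_kr = 0.7, p_dh_given_kr = 0.5,
              p_cmt = 0.2, p_trans_er = 0.1, p_hcs = 0.1, p_llm = 0.1,
              p_shift_given_dh = 0.1, p_inline_ech_given_hcs = 0.5,
              kr_type_probs = c(A = 0.45, B = 0.45, C = 0.10),
              protein_length = 200L, n_per_motif = 5L, n_decoys = 20L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- modifyList(cfg, over)
  probs <- unlist(cfg[grep("^p_", names(cfg))])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a random valid architecture with known ground truth
#'
#' Draws from the structural grammar (loading module, optional NRPS glycine
#' module, E elongation modules, truncated-condensation termination, plus a
#' trans-acting HCS cassette when any module is branch-flagged), splits the
#' domain stream across a random number of genes, and computes the
#' ground-truth product with the naive rule-by-rule interpreter
#' ([naive_product()]), which is kept independent of the assembly engine.
#'
#' @param cfg A [sim_config()].
#' @return List with `arch` (segmented [bgc_architecture()]) and `truth`
#'   (the naive interpreter's product summary).
#' @export
simulate_architecture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lo <- cfg$n_elongations[1]; hi <- cfg$n_elongations[2]
  if (lo > hi || lo < 1) stop("degenerate n_elongations range", call. = FALSE)
  with_seed(cfg$seed, {
    E <- if (lo == hi) as.integer(lo) else sample(lo:hi, 1)
    has_nrps <- runif(1) < cfg$p_nrps
    stream <- list(domain("ACP"))
    if (has_nrps) {
      stream <- c(stream, list(domain("C"), domain("A", substrate = "glycine"),
                               domain("ACP")))
    }
    hcs_modules <- integer(0)
    trans_er_modules <- integer(0)
    module_offset <- 1L + as.integer(has_nrps)   # loading (+ nrps) precede
    for (e in seq_len(E)) {
      doms <- list(domain("KS"))
      idx <- module_offset + e
      if (runif(1) < cfg$p_hcs) {
        if (runif(1) < cfg$p_inline_ech_given_hcs) doms <- c(doms, list(domain("ECH")))
        hcs_modules <- c(hcs_modules, idx)
      } else {
        kr <- NULL
        if (runif(1) < cfg$p_kr) {
          type <- sample(names(cfg$kr_type_probs), 1, prob = cfg$kr_type_probs)
          kr <- domain("KR", kr_type = type)
        }
        dh <- !is.null(kr) && kr$kr_type %in% c("A", "B") &&
          runif(1) < cfg$p_dh_given_kr
        trans_er <- dh && runif(1) < cfg$p_trans_er
        if (dh) {
          shift <- !trans_er && runif(1) < cfg$p_shift_given_dh
          doms <- c(doms, list(domain("DH", shift = shift)))
        }
        if (!is.null(kr)) doms <- c(doms, list(kr))
        if (trans_er) trans_er_modules <- c(trans_er_modules, idx)
        if (runif(1) < cfg$p_cmt) doms <- c(doms, list(domain("cMT")))
        if (runif(1) < cfg$p_llm) doms <- c(doms, list(domain("LLM")))
      }
      doms <- c(doms, list(domain("ACP")))
      stream <- c(stream, doms)
    }
    stream <- c(stream, list(domain("C_trunc")))

    # split the stream across 1-4 core genes
    n_genes <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(length(stream) - 1), n_genes - 1))
    bounds <- c(0, cuts, length(stream))
    genes <- lapply(seq_len(n_genes), function(i) {
      gene_record(paste0("synG", i), stream[(bounds[i] + 1):bounds[i + 1]])
    })
    if (length(hcs_modules)) {
      genes <- c(genes, list(gene_record(
        "synHCS", list(domain("ACP"), domain("HCS"), domain("KS"),
                       domain("ECH"), domain("ECH")), trans_acting = TRUE)))
    }
    starter <- sample(names(monomer_library()), 1)
    site_ann <- c(
      lapply(hcs_modules, function(m) list(module = m, type = "hcs_site")),
      lapply(trans_er_modules, function(m) list(module = m, type = "trans_ER")))
    arch <- bgc_architecture(paste0("syn_", cfg$seed), genes,
                             starter_monomer = starter,
                             site_annotations = site_ann)
    arch <- segment_modules(arch)
    list(arch = arch, truth = naive_product(arch))
  })
}

.motif_alphabet_sample <- function(n) sample(.AA20, n, replace = TRUE)

# draw a concrete instance of a motif pattern
motif_instance <- function(pattern) {
  sets <- compile_motif(pattern)
  paste(vapply(sets, function(s) {
    if (identical(s, "any")) sample(.AA20, 1) else sample(s, 1)
  }, character(1)), collapse = "")
}

#' Simulate motif-labelled protein sequences
#'
#' For each built-in motif, generates `n_per_motif` sequences with one
#' embedded instance at a known offset (backgrounds rejected until they
#' contain no spurious match of that motif), plus `n_decoys` decoy sequences
#' verified free of every built-in motif.
#'
#' @param cfg A [sim_config()].
#' @param motifs Motif definitions (default [pal_motifs()]).
#' @return Data frame with columns `id`, `seq`, `motif_id` (`NA` for
#'   decoys) and `offset` (0-based embedding offset, `NA` for decoys).
#' @export
simulate_proteins <- function(cfg, motifs = pal_motifs()) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$protein_length
  with_seed(cfg$seed + 1000003L, {
    rows <- list()
    for (m in motifs) {
      k <- nchar(gsub("\\(.*?\\)", ".", m$pattern))
      inst_len <- length(compile_motif(m$pattern))
      if (inst_len > L) stop("motif ", m$motif_id, " longer than sequence", call. = FALSE)
      for (i in seq_len(cfg$n_per_motif)) {
        repeat {
          offset <- sample.int(L - inst_len + 1L, 1) - 1L
          inst <- motif_instance(m$pattern)
          bg <- paste(.motif_alphabet_sample(L), collapse = "")
          seq <- paste0(substr(bg, 1, offset), inst,
                        substr(bg, offset + inst_len + 1L, L))
          hits <- scan_motifs(seq, list(m))
          if (nrow(hits) == 1 && hits$start == offset) break
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(m$motif_id, "_", i), seq = seq,
          motif_id = m$motif_id, offset = offset)
      }
    }
    for (i in seq_len(cfg$n_decoys)) {
      repeat {
        seq <- paste(.motif_alphabet_sample(L), collapse = "")
        if (nrow(scan_motifs(seq, motifs)) == 0) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("decoy_", i), seq = seq,
        motif_id = NA_character_, offset = NA_integer_)
    }
    do.call(rbind, rows)
  })
}

#' Simulate an alignment under the Jukes-Cantor process along a tree
#'
#' Sites are i.i.d.; along each edge of length `t` a site substitutes with
#' probability `((k-1)/k) * (1 - exp(-t * k/(k-1)))` to a uniformly chosen
#' different state (the equal-rates process whose pairwise distances the
#' [jc_distance()] correction recovers).
#'
#' @param tree An `ape::phylo` with non-negative branch lengths.
#' @param length Number of columns (>= 1).
#' @param seed Integer seed.
#' @param k Alphabet size: 4 (ACGT) or 20 (amino acids).
#' @return An [alignment()] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, length, seed, k = 4) {
  if (length < 1) stop("alignment length must be >= 1", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths", call. = FALSE)
  }
  states <- if (k == 4) c("A", "C", "G", "T") else .AA20
  lim <- (k - 1) / k
  with_seed(seed + 2000003L, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(states, length, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[i, 1]; child <- ord$edge[i, 2]
      t_len <- ord$edge.length[i]
      p_sub <- lim * (1 - exp(-t_len / lim))
      s <- seqs[[parent]]
      mut <- runif(length) < p_sub
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(cur) {
          sample(states[states != cur], 1)
        }, character(1))
      }
      seqs[[child]] <- s
    }
    alignment(setNames(
      vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1)),
      tree$tip.label))
  })
}
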