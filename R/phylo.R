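# Jukes-Cantor distances, neighbour-joining trees (via ape), bootstrap
# bipartition support, and clade-membership classification of carrier
# proteins.

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differing sites into the expected
#' number of substitutions per site under the equal-rates model:
#' `d = -((k-1)/k) * log(1 - (k/(k-1)) * p)` for alphabet size `k`
#' (4 for nucleotides; 20 for the amino-acid generalisation).
#'
#' @param p Proportion of differing sites in `[0, (k-1)/k)`.
#' @param k Alphabet size (default 4).
#' @return Corrected distance (`d >= p`).
#' @export
jc_distance <- function(p, k = 4) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  lim <- (k - 1) / k
  if (any(p >= lim)) {
    stop(sprintf("saturation: p >= %.4g is outside the Jukes-Cantor domain (k = %d)",
                 lim, k), call. = FALSE)
  }
  -lim * log(1 - p / lim)
}

#' Build an alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gap character `"-"`).
#' @return An `alignment` object (matrix of residues, taxa as rows).
#' @export
alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows need unique taxon labels", call. = FALSE)
  }
  n <- nchar(seqs)
  if (length(unique(n)) != 1) stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(mat, class = c("alignment", class(mat)))
}

# detect nucleotide vs amino-acid alphabet
alignment_k <- function(aln) {
  res <- setdiff(unique(as.vector(aln)), c("-", "N", "X", "?"))
  if (all(res %in% c("A", "C", "G", "T", "U"))) 4L else 20L
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise deletion of gap/ambiguous columns; the alphabet size for the
#' correction is chosen by alphabet detection (ACGT(U) -> 4, otherwise the
#' 20-letter amino-acid form), overridable via `k`.
#'
#' @param aln An [alignment()] (or named character vector).
#' @param k Alphabet size override.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
jc_dist_matrix <- function(aln, k = NULL) {
  if (!inherits(aln, "alignment")) aln <- alignment(aln)
  if (is.null(k)) k <- alignment_k(aln)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  skip <- c("-", "N", "X", "?")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !(aln[i, ] %in% skip) & !(aln[j, ] %in% skip)
      if (!any(ok)) stop("no comparable sites between ", rownames(aln)[i],
                         " and ", rownames(aln)[j], call. = FALSE)
      p <- mean(aln[i, ok] != aln[j, ok])
      D[i, j] <- D[j, i] <- jc_distance(p, k = k)
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbour joining (delegated to `ape::nj`); on
#' additive matrices the generating topology and branch lengths are
#' recovered.  Negative branch lengths are clamped to zero with a warning.
#'
#' @param D Symmetric distance matrix (>= 3 taxa).
#' @return An `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  tree <- ape::nj(as.dist(D))
  if (any(tree$edge.length < 0)) {
    warning("negative neighbour-joining branch length(s) clamped to 0",
            call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# internal: one NJ tree from an alignment
build_nj <- function(aln, k = NULL) nj_tree(jc_dist_matrix(aln, k = k))

# bipartitions (as sorted tip-label sets of the smaller side) of an unrooted tree
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- list()
  ntip <- length(labs)
  for (p in parts) {
    if (length(p) <= 1 || length(p) >= ntip - 1) next  # trivial
    side <- sort(labs[p])
    other <- sort(setdiff(labs, side))
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = "|") < paste(other, collapse = "|"))) side else other
    out[[paste(key, collapse = "|")]] <- key
  }
  out
}

#' Bootstrap bipartition support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance-plus-NJ tree for each replicate, and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition.  Seeded: the same seed gives identical supports.
#'
#' @param aln An [alignment()].
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed (required).
#' @param k Alphabet size override.
#' @return The full-data tree with `$node.label` holding supports in
#'   `[0, 100]` and an attribute `"bipartition_support"` (named vector).
#' @export
bootstrap_support <- function(aln, reps = 100, seed, k = NULL) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!inherits(aln, "alignment")) aln <- alignment(aln)
  if (ncol(aln) < 2) stop("alignment must have at least 2 columns", call. = FALSE)
  main <- build_nj(aln, k = k)
  main_parts <- tree_bipartitions(main)
  counts <- setNames(numeric(length(main_parts)), names(main_parts))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    rep_aln <- aln[, cols, drop = FALSE]
    class(rep_aln) <- class(aln)
    rep_tree <- tryCatch(suppressWarnings(build_nj(rep_aln, k = k)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rep_parts <- names(tree_bipartitions(rep_tree))
    hit <- names(counts) %in% rep_parts
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / reps
  # map supports onto internal nodes
  node_lab <- rep(NA_character_, main$Nnode)
  parts <- ape::prop.part(main)
  labs <- attr(parts, "labels")
  ntip <- length(labs)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) <= 1 || length(p) >= ntip - 1) { node_lab[i] <- ""; next }
    side <- sort(labs[p])
    other <- sort(setdiff(labs, side))
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = "|") < paste(other, collapse = "|"))) side else other
    node_lab[i] <- format(support[[paste(key, collapse = "|")]])
  }
  main$node.label <- node_lab
  attr(main, "bipartition_support") <- support
  main
}

#' Classify a query sequence into a labelled reference clade
#'
#' Joins the (pre-aligned) query to the reference alignment, builds the
#' Jukes-Cantor + neighbour-joining tree, and assigns the label of the
#' reference clade whose members form the query's smallest enclosing group
#' (the smallest non-trivial bipartition side containing the query whose
#' other members carry a single label).  Support is the bootstrap percentage
#' of that defining bipartition.  Returns `"unclassified"` when no labelled
#' group encloses the query or minimal enclosing groups tie across labels.
#'
#' @param query Named length-1 character vector (aligned to the reference
#'   columns; same length, no realignment is performed).
#' @param references An [alignment()] of reference sequences.
#' @param labels Named character vector of clade labels (e.g. `"ACP"`,
#'   `"PCP"`) for every reference taxon.
#' @param reps,seed Bootstrap settings (see [bootstrap_support()]).
#' @return List with `label`, `support`, and `diagnostics`.
#' @export
classify_clade <- function(query, references, labels, reps = 100, seed = 1) {
  if (!inherits(references, "alignment")) references <- alignment(references)
  qname <- names(query)
  if (is.null(qname)) qname <- "query"
  if (nchar(query[[1]]) != ncol(references)) {
    stop("query must be pre-aligned to the reference alignment length",
         call. = FALSE)
  }
  if (!all(rownames(references) %in% names(labels))) {
    stop("every reference taxon needs a clade label", call. = FALSE)
  }
  seqs <- c(setNames(apply(references, 1, paste, collapse = ""), rownames(references)),
            setNames(query[[1]], qname))
  aln <- alignment(seqs)
  # an identical reference is conclusive: the zero-length join holds in every
  # column resample, so report it directly instead of leaving the zero-branch
  # tie resolution to the tree builder
  identical_ref <- rownames(references)[apply(references, 1, paste, collapse = "") ==
                                          query[[1]]]
  if (length(identical_ref)) {
    return(list(label = unname(labels[identical_ref[1]]), support = 100,
                diagnostics = paste("query identical to reference",
                                    identical_ref[1])))
  }
  boot <- bootstrap_support(aln, reps = reps, seed = seed)
  parts <- tree_bipartitions(boot)
  support <- attr(boot, "bipartition_support")
  all_taxa <- rownames(aln)
  enclosing <- list()
  for (key in names(parts)) {
    side <- parts[[key]]
    grp <- if (qname %in% side) side else setdiff(all_taxa, side)
    members <- setdiff(grp, qname)
    if (!length(members) || length(members) == length(all_taxa) - 1) next
    grp_labels <- unique(labels[members])
    if (length(grp_labels) == 1) {
      enclosing[[length(enclosing) + 1L]] <- list(
        size = length(grp), label = grp_labels, support = support[[key]])
    }
  }
  if (!length(enclosing)) {
    return(list(label = "unclassified", support = NA_real_,
                diagnostics = "no single-label group encloses the query"))
  }
  sizes <- vapply(enclosing, `[[`, numeric(1), "size")
  minimal <- enclosing[sizes == min(sizes)]
  labs <- unique(vapply(minimal, `[[`, character(1), "label"))
  if (length(labs) > 1) {
    return(list(label = "unclassified", support = NA_real_,
                diagnostics = paste("minimal enclosing groups tie across labels:",
                                    paste(labs, collapse = " vs "))))
  }
  sup <- max(vapply(minimal, `[[`, numeric(1), "support"))
  list(label = labs, support = sup, diagnostics = sprintf(
    "smallest enclosing single-label group of size %d", min(sizes)))
}
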