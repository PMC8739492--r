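# Readers and writers for the pipeline's table formats.  Column order and
# line endings are fixed so identical inputs give byte-identical outputs.

#' Write a structure feature table to TSV
#'
#' Structure-level fields (counts, starter, ring closure, ...) are stored as
#' `#key<TAB>value` pragma lines ahead of the per-position table, so the file
#' round-trips through [read_feature_table()].
#'
#' @param struct A `pal_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(struct, path) {
  stopifnot(inherits(struct, "pal_structure"))
  con <- file(path, open = "wb")   # fixed line endings across platforms
  on.exit(close(con))
  pragma <- c(
    bgc_id = if (is.na(struct$bgc_id)) "NA" else struct$bgc_id,
    E = struct$E,
    starter = if (is.null(struct$starter)) "none" else struct$starter$monomer_id,
    n_glycine = length(struct$amino_acids),
    tail_extension = struct$tail_extension,
    tail_methyls = struct$tail_methyls,
    terminal_olefin = struct$terminal_olefin,
    ring_to = if (is.null(struct$ring)) "NA" else struct$ring[["to"]],
    hydrolyzed = struct$hydrolyzed,
    alpha_hydroxyls = paste(struct$alpha_hydroxyls, collapse = ","))
  writeLines(paste0("#", names(pragma), "\t", unname(pragma)), con, sep = "\n")
  cols <- c("position", "source", "hydroxyl", "stereo", "ketone", "olefin",
            "geometry", "methyl", "methyl_carbon", "branch", "branch_carbon",
            "branch_internal_olefin", "decoration")
  tab <- struct$table[, cols]
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  lines <- apply(tab, 1, function(r) paste(ifelse(is.na(r), "NA", trimws(r)),
                                           collapse = "\t"))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a structure feature table written by [write_feature_table()]
#'
#' @param path TSV file with pragma header.
#' @return A `pal_structure` (without the per-unit provenance of a live
#'   assembly; sufficient for [retro_predict()]).
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  pragma_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", pragma_lines), "\t")
  pragma <- setNames(vapply(kv, `[[`, character(1), 2),
                     vapply(kv, `[[`, character(1), 1))
  body <- lines[!grepl("^#", lines)]
  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE)
  for (col in c("hydroxyl", "ketone", "olefin", "methyl", "branch",
                "branch_internal_olefin")) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  for (col in c("stereo", "geometry", "decoration", "source")) {
    tab[[col]] <- as.character(tab[[col]])
  }
  starter <- if (pragma[["starter"]] == "none") NULL else {
    monomer_library()[[pragma[["starter"]]]]
  }
  n_gly <- as.integer(pragma[["n_glycine"]])
  ring <- if (pragma[["ring_to"]] == "NA") NULL else {
    c(from = 1L, to = as.integer(pragma[["ring_to"]]))
  }
  aoh <- pragma[["alpha_hydroxyls"]]
  aoh <- if (nzchar(aoh)) as.integer(strsplit(aoh, ",")[[1]]) else integer(0)
  E <- as.integer(pragma[["E"]])
  tail_ext <- as.integer(pragma[["tail_extension"]])
  tail_met <- as.integer(pragma[["tail_methyls"]])
  structure(list(
    bgc_id = pragma[["bgc_id"]],
    E = E,
    polyketide_carbon_count = sum(tab$source == "polyketide"),
    backbone_carbon_count = nrow(tab),
    total_carbon_count = (if (is.null(starter)) 0L else starter$carbon_count) +
      nrow(tab) + sum(tab$methyl) + sum(tab$branch) + 2L * tail_ext + tail_met,
    starter = starter,
    amino_acids = rep(list(list(name = "glycine", backbone_carbons = 2L,
                                nitrogens = 1L)), n_gly),
    tail_extension = tail_ext,
    tail_methyls = tail_met,
    terminal_olefin = as.logical(pragma[["terminal_olefin"]]),
    table = tab,
    units = NULL,
    alpha_hydroxyls = aoh,
    ring = ring,
    default_ct_target = if (length(aoh) && (aoh[1] + 1L) <= nrow(tab) &&
                            tab$hydroxyl[aoh[1] + 1L]) aoh[1] + 1L else NA_integer_,
    hydrolyzed = as.logical(pragma[["hydrolyzed"]]),
    warnings = character(0),
    notes = character(0)), class = "pal_structure")
}

#' Path to a shipped palmerolide feature-table fixture
#'
#' @param analogue Letter `"A"` to `"H"`.
#' @return File path.
#' @export
palmerolide_path <- function(analogue) {
  analogue <- toupper(analogue)
  stopifnot(analogue %in% LETTERS[1:8])
  system.file("extdata", "structures",
              paste0("palmerolide_", analogue, ".tsv"),
              package = "palcolin", mustWork = TRUE)
}

#' Load a shipped palmerolide structure feature table
#'
#' @inheritParams palmerolide_path
#' @return A `pal_structure`.
#' @export
palmerolide_structure <- function(analogue) read_feature_table(palmerolide_path(analogue))

#' Read / write FASTA (via Biostrings)
#'
#' Thin wrappers returning and accepting named character vectors.
#'
#' @param path FASTA file.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA input", call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA output", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
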