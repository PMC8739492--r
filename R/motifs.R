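# Active-site motif scanning and motif-based domain classification.
#
# Motif pattern syntax: uppercase residue letters match themselves, "X" (or
# "x") matches any residue, "(D/E)" matches any of the bracketed alternatives,
# "[LI]" style sets are also accepted.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Built-in motif definitions
#'
#' The active-site motifs used throughout: `GXDS` (beta-branch accepting
#' carrier), `(D/E)xGxDSL` with terminal L or I (phosphopantetheine arm
#' attachment), `LDD` (B-type ketoreductase), `HHXXDDG` (condensation catalytic
#' core), and `GGNGSGKST` (ABC-transporter nucleotide binding).
#'
#' @return Named list of motif definitions (`motif_id`, `pattern`,
#'   `min_region`, `max_region`).
#' @export
pal_motifs <- function() {
  mk <- function(id, pattern) list(motif_id = id, pattern = pattern,
                                   min_region = NA_integer_, max_region = NA_integer_)
  list(
    acp_beta   = mk("acp_beta", "GXDS"),
    ppant      = mk("ppant", "(D/E)XGXDS(L/I)"),
    kr_b_type  = mk("kr_b_type", "LDD"),
    c_catalytic = mk("c_catalytic", "HHXXDDG"),
    abc_nbd    = mk("abc_nbd", "GGNGSGKST")
  )
}

# compile motif pattern to a list of per-position allowed-residue sets
compile_motif <- function(pattern) {
  if (!nzchar(pattern)) stop("empty motif pattern", call. = FALSE)
  sets <- list()
  i <- 1L
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) {
      close <- if (ch == "(") ")" else "]"
      j <- i + 1L
      alt <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        if (chars[j] != "/") alt <- c(alt, toupper(chars[j]))
        j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced bracket in motif pattern", call. = FALSE)
      sets[[length(sets) + 1L]] <- alt
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- if (toupper(ch) == "X") "any" else toupper(ch)
      i <- i + 1L
    }
  }
  sets
}

check_sequence <- function(seq) {
  if (length(seq) != 1 || !nzchar(seq)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c(.AA20, "X"))
  if (length(bad)) {
    stop("illegal residue(s) at position(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(chars[bad]), collapse = ""), call. = FALSE)
  }
  chars
}

#' Scan a protein sequence for motif occurrences
#'
#' Returns all and only the matching windows (overlaps allowed), sorted by
#' start offset.  An `X` in the subject sequence matches any pattern position.
#'
#' @param seq Amino-acid string (20-letter alphabet plus `X`).
#' @param motifs A single motif definition or a list of them (see
#'   [pal_motifs()]); a bare pattern string is also accepted.
#' @return Data frame with columns `motif_id`, `start` (0-based), `matched`.
#' @export
scan_motifs <- function(seq, motifs = pal_motifs()) {
  chars <- check_sequence(seq)
  if (is.character(motifs)) motifs <- list(list(motif_id = motifs, pattern = motifs))
  if (!is.null(motifs$pattern)) motifs <- list(motifs)
  hits <- list()
  for (m in motifs) {
    sets <- compile_motif(m$pattern)
    k <- length(sets)
    if (k > length(chars)) next
    lo <- if (!is.null(m$min_region) && !is.na(m$min_region)) m$min_region + 1L else 1L
    hi <- if (!is.null(m$max_region) && !is.na(m$max_region)) {
      min(m$max_region + 1L, length(chars) - k + 1L)
    } else length(chars) - k + 1L
    starts <- seq_len(length(chars) - k + 1L)
    ok <- starts >= lo & starts <= hi
    for (p in seq_len(k)) {
      allowed <- sets[[p]]
      if (identical(allowed, "any")) next
      res <- chars[starts + p - 1L]
      ok <- ok & (res %in% allowed | res == "X")
    }
    for (s in starts[ok]) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = m$motif_id, start = s - 1L,
        matched = paste(chars[s:(s + k - 1L)], collapse = ""))
    }
  }
  if (!length(hits)) {
    return(data.frame(motif_id = character(0), start = integer(0),
                      matched = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_id), , drop = FALSE]
}

#' Classify a ketoreductase domain from its sequence
#'
#' B-type ketoreductases are identified by the `LDD` motif and give
#' D-configured beta-hydroxy groups; A-type lack `LDD` but carry an
#' active-site tryptophan and give L-configured hydroxy groups; domains with
#' neither are C-type and lack reductase activity.  `LDD` takes precedence
#' when both signals are present.
#'
#' @param seq Amino-acid string of the KR region.
#' @param ldd_window,trp_window Optional `c(min, max)` 0-based windows
#'   restricting where the LDD motif / the key tryptophan is looked for;
#'   default is the whole sequence.
#' @return List with `kr_type` (`"A"`, `"B"` or `"C"`), `predicted_config`
#'   (`"L"`, `"D"` or `"none"`) and `evidence` (hit data frame).
#' @export
classify_kr <- function(seq, ldd_window = NULL, trp_window = NULL) {
  chars <- check_sequence(seq)
  mot <- list(motif_id = "kr_b_type", pattern = "LDD",
              min_region = if (!is.null(ldd_window)) ldd_window[1] else NA,
              max_region = if (!is.null(ldd_window)) ldd_window[2] else NA)
  ldd <- scan_motifs(seq, list(mot))
  if (nrow(ldd) > 0) {
    return(list(kr_type = "B", predicted_config = "D", evidence = ldd))
  }
  w_pos <- which(chars == "W") - 1L
  if (!is.null(trp_window)) {
    w_pos <- w_pos[w_pos >= trp_window[1] & w_pos <= trp_window[2]]
  }
  if (length(w_pos) > 0) {
    ev <- data.frame(motif_id = "kr_a_trp", start = w_pos, matched = "W")
    return(list(kr_type = "A", predicted_config = "L", evidence = ev))
  }
  list(kr_type = "C", predicted_config = "none",
       evidence = data.frame(motif_id = character(0), start = integer(0),
                             matched = character(0)))
}

#' Classify a condensation domain as canonical or truncated
#'
#' A canonical condensation domain is roughly 450 residues; truncated
#' termination-type domains (which catalyse macrolactonising release) are far
#' shorter.  The catalytic histidine is sought in a degenerate `HHXXDDG`
#' match: the second-position histidine must be present, and up to
#' `max_mismatch` of the remaining fixed positions may deviate.
#'
#' @param seq Amino-acid string of the C-domain region.
#' @param length_threshold Residue count below which the domain is called
#'   truncated (default 250).
#' @param max_mismatch Mismatches tolerated outside the catalytic position.
#' @return List with `classification` (`"canonical"`/`"truncated"`) and
#'   `catalytic_his` (logical).
#' @export
classify_condensation <- function(seq, length_threshold = 250, max_mismatch = 2) {
  chars <- check_sequence(seq)
  n <- length(chars)
  template <- c("H", "H", NA, NA, "D", "D", "G")   # NA = wildcard
  his <- FALSE
  if (n >= 7) {
    for (s in seq_len(n - 6L)) {
      win <- chars[s:(s + 6L)]
      if (win[2] != "H") next
      fixed <- c(1L, 5L, 6L, 7L)
      mism <- sum(win[fixed] != template[fixed] & win[fixed] != "X")
      if (mism <= max_mismatch) {
        his <- TRUE
        break
      }
    }
  }
  list(classification = if (n < length_threshold) "truncated" else "canonical",
       catalytic_his = his)
}

#' Classify an acyltransferase domain's substrate behaviour
#'
#' Requires the catalytic active-site serine; without it the domain is called
#' inactive.  With the serine, an active-site phenylalanine in the specificity
#' window confers specificity for malonate selection; otherwise the domain is
#' called relaxed (no definitive specificity for malonyl-CoA, compatible with
#' unusual starters).
#'
#' @param seq Amino-acid string of the AT region.
#' @param ser_window,phe_window Optional 0-based `c(min, max)` windows.
#' @return One of `"malonate_specific"`, `"relaxed"`, `"inactive"`.
#' @export
classify_at <- function(seq, ser_window = NULL, phe_window = NULL) {
  chars <- check_sequence(seq)
  in_window <- function(res, window) {
    pos <- which(chars == res) - 1L
    if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
    length(pos) > 0
  }
  if (!in_window("S", ser_window)) return("inactive")
  if (in_window("F", phe_window)) "malonate_specific" else "relaxed"
}

#' Detect the phosphopantetheine attachment-site motif on a carrier protein
#'
#' Matches `(D/E)xGxDS(L/I)`; both the canonical leucine-terminated form and
#' the isoleucine variant seen in hybrid PKS-NRPS carrier proteins count as
#' present, and the terminal residue is reported.
#'
#' @param seq Amino-acid string of the carrier-protein region.
#' @return List with `attachment_site_present` (logical) and
#'   `terminal_residue` (`"L"`, `"I"` or `"other"`).
#' @export
classify_carrier_motif <- function(seq) {
  hits <- scan_motifs(seq, pal_motifs()["ppant"])
  if (nrow(hits) == 0) {
    return(list(attachment_site_present = FALSE, terminal_residue = "other"))
  }
  term <- substr(hits$matched[1], 7, 7)
  list(attachment_site_present = TRUE,
       terminal_residue = if (term %in% c("L", "I")) term else "other")
}
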