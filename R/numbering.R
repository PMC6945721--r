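#' IMGT unique numbering of a V-REGION
#'
#' Places a translated V-REGION onto the IMGT unique numbering scheme:
#' FR1-IMGT positions 1-26, CDR1-IMGT 27-38, FR2-IMGT 39-55, CDR2-IMGT
#' 56-65 and FR3-IMGT 66-104, with the four anchors 1st-CYS 23,
#' CONSERVED-TRP 41, hydrophobic 89 and 2nd-CYS 104. Gaps are inserted
#' inside the CDR intervals only (IMGT convention: CDR residues fill the
#' interval from both ends, gaps in the middle), so the framework lengths
#' are fixed and the placement search reduces to choosing the CDR1 and
#' CDR2 occupancies. Among all length-consistent placements the one
#' matching the most anchors is selected (ties prefer full coverage up to
#' position 104, then balanced CDR loops).
#'
#' @param aa character, translated V-REGION (at most ~120 residues;
#'   residues beyond position 104, e.g. the germline CDR3 stub, remain
#'   unnumbered).
#' @return A \linkS4class{VNumbering}; \code{ok(slot)} is FALSE when no
#'   placement satisfying the monotonic region constraints exists.
#' @export
numberVRegion <- function(aa) {
  aa <- toupper(as.character(aa))
  res <- strsplit(aa, "")[[1]]
  L <- length(res)
  fail <- new("VNumbering", positions = rep(NA_integer_, L),
              anchors = c(c23 = FALSE, w41 = FALSE, h89 = FALSE,
                          c104 = FALSE), ok = FALSE)
  if (L > 120L || L < 82L) return(fail)
  # enumerate CDR1 length l1 (0..12) and CDR2 length l2 (0..10) such that
  # 26 + l1 + 17 + l2 + 39 = 82 + l1 + l2 <= L
  cand <- expand.grid(l1 = 0:12, l2 = 0:10)
  cand <- cand[82L + cand$l1 + cand$l2 <= L, , drop = FALSE]
  if (!nrow(cand)) return(fail)
  i41 <- 26L + cand$l1 + 3L
  i89 <- 26L + cand$l1 + 17L + cand$l2 + 24L
  i104 <- 82L + cand$l1 + cand$l2
  a23 <- res[23] == "C"
  a41 <- res[i41] == "W"
  a89 <- res[i89] %in% .hydrophobic
  a104 <- res[i104] == "C"
  score <- a23 + a41 + a89 + a104
  full <- i104 == L
  ord <- order(-score, -full, abs(cand$l1 - cand$l2), cand$l1)
  best <- ord[1]
  l1 <- cand$l1[best]; l2 <- cand$l2[best]
  pos <- rep(NA_integer_, L)
  pos[1:26] <- 1:26
  if (l1 > 0) {
    lead <- ceiling(l1 / 2); trail <- l1 - lead
    pos[26L + seq_len(lead)] <- 26L + seq_len(lead)
    if (trail > 0) pos[26L + lead + seq_len(trail)] <- 38L - trail + seq_len(trail)
  }
  o <- 26L + l1
  pos[o + 1:17] <- 39:55
  o <- o + 17L
  if (l2 > 0) {
    lead <- ceiling(l2 / 2); trail <- l2 - lead
    pos[o + seq_len(lead)] <- 55L + seq_len(lead)
    if (trail > 0) pos[o + lead + seq_len(trail)] <- 65L - trail + seq_len(trail)
  }
  o <- o + l2
  pos[o + 1:39] <- 66:104
  new("VNumbering", positions = as.integer(pos),
      anchors = c(c23 = a23, w41 = a41[best], h89 = a89[best],
                  c104 = a104[best]),
      ok = TRUE)
}

#' IMGT region boundaries used by the numbering
#' @return named list of IMGT position ranges
#' @export
imgtRegions <- function() {
  list(FR1 = c(1L, 26L), CDR1 = c(27L, 38L), FR2 = c(39L, 55L),
       CDR2 = c(56L, 65L), FR3 = c(66L, 104L))
}

#' Classify gene functionality from its defect list
#'
#' IMGT-style functionality: a gene is a pseudogene (P) when its coding
#' region is broken (STOP_CODON, FRAMESHIFT or DEGENERATE); otherwise an
#' open reading frame (ORF) when the coding frame is intact but the gene
#' carries a non-canonical recombination signal, a missing conserved
#' anchor or a missing splice site; otherwise functional (F). The
#' classification is a pure, idempotent function of the defect list.
#'
#' @param defects character vector of defect labels (see
#'   \code{DEFECT_LEVELS}).
#' @return "F", "ORF" or "P".
#' @export
classifyFunctionality <- function(defects) {
  if (any(defects %in% c("STOP_CODON", "FRAMESHIFT", "DEGENERATE"))) return("P")
  if (any(defects %in% c("NONCANONICAL_RS", "MISSING_ANCHOR",
                         "MISSING_SPLICE"))) return("ORF")
  "F"
}
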