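#' Recombination-signal detection
#'
#' The recombination signal (RS) flanking rearranging V, D and J genes is a
#' conserved heptamer (consensus CACAGTG) and nonamer (consensus
#' ACAAAAACC) separated by a spacer of 12 or 23 nt. Motifs are stored and
#' scored gene-centric: the heptamer is always the gene-proximal element
#' read 5'->3' pointing away from the coding segment, so a 5' RS (J genes,
#' D 5' side) appears reverse-complemented on the locus forward strand.
#'
#' @name rs-detection
NULL

# generating/reference base frequencies of the canonical RS elements; the
# first three heptamer positions (cac) and the nonamer poly-A tract are the
# strongly conserved features.
.rsRefFreqs <- function(element = c("HEPTAMER", "NONAMER")) {
  element <- match.arg(element)
  if (element == "HEPTAMER") {
    f <- cbind(
      c(.01, .97, .01, .01),   # C
      c(.97, .01, .01, .01),   # A
      c(.01, .97, .01, .01),   # C
      c(.70, .10, .10, .10),   # A
      c(.08, .04, .80, .08),   # G
      c(.05, .05, .05, .85),   # T
      c(.10, .10, .70, .10))   # G
  } else {
    f <- cbind(
      c(.75, .09, .08, .08),   # A
      c(.08, .75, .09, .08),   # C
      c(.84, .06, .05, .05),   # A
      c(.90, .04, .03, .03),   # A
      c(.90, .04, .03, .03),   # A
      c(.90, .04, .03, .03),   # A
      c(.84, .06, .05, .05),   # A
      c(.10, .70, .10, .10),   # C
      c(.15, .60, .15, .10))   # C
  }
  rownames(f) <- DNA_BASES
  f
}

#' Reference log-odds matrices for RS scanning
#'
#' @param element "HEPTAMER" or "NONAMER"
#' @return 5 x L log2-odds matrix against a uniform background; the fifth
#'   row scores non-ACGT characters.
#' @export
rsReferencePWM <- function(element = c("HEPTAMER", "NONAMER")) {
  f <- .rsRefFreqs(match.arg(element))
  lo <- log2(f / 0.25)
  rbind(lo, OTHER = rep(min(lo) - 1, ncol(lo)))
}

#' Canonicality of an RS motif
#'
#' A motif is flagged canonical when its heptamer starts with the crucial
#' first three nucleotides CAC and its nonamer shows the conserved poly-A
#' tract (at least 4 A among positions 3-7). Only the heptamer condition
#' participates in F vs ORF functionality classification.
#'
#' @param heptamer,nonamer motif strings
#' @return logical
#' @export
rsIsCanonical <- function(heptamer, nonamer) {
  polyA <- vapply(strsplit(substr(nonamer, 3, 7), ""), function(x)
    sum(x == "A"), numeric(1))
  substr(heptamer, 1, 3) == "CAC" & polyA >= 4
}

# score one PWM at every offset of an integer-coded sequence (vectorised)
.pwmScan <- function(si, lo) {
  L <- length(si); w <- ncol(lo)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) sc <- sc + lo[si[k:(k + n - 1L)], k]
  sc
}

#' Detect recombination signals in a sequence
#'
#' Scans every window of \code{dna} for a heptamer-spacer-nonamer motif and
#' scores it by the summed log-odds of the heptamer and nonamer position
#' weight matrices (the spacer is not scored). For \code{side = "5p"} the
#' scan runs on the reverse complement so that reported motifs are always
#' gene-centric; \code{start}/\code{end} are positions on the input strand.
#'
#' @param dna character or DNAString.
#' @param side "3p" (RS downstream of a gene: heptamer first on the input
#'   strand) or "5p" (RS upstream: motif reverse-complemented on the input
#'   strand).
#' @param spacer_len 12 or 23.
#' @param pwm optional list(heptamer=, nonamer=) of log-odds matrices as
#'   returned by [rsReferencePWM()].
#' @param min_score report only hits scoring at least this many bits.
#' @return data.frame with columns start, end (1-based closed span of the
#'   whole motif on the input strand), heptamer, spacer, nonamer, score,
#'   canonical, sorted by decreasing score.
#' @export
detectRS <- function(dna, side = c("3p", "5p"), spacer_len,
                     pwm = NULL, min_score = 0) {
  side <- match.arg(side)
  if (!spacer_len %in% c(12L, 23L))
    stop("spacer_len must be 12 or 23")
  dna <- as.character(dna)
  L <- nchar(dna)
  w <- 7L + spacer_len + 9L
  if (L < w) stop("sequence shorter than one RS window")
  if (is.null(pwm))
    pwm <- list(heptamer = rsReferencePWM("HEPTAMER"),
                nonamer = rsReferencePWM("NONAMER"))
  scanSeq <- if (side == "5p") .rc(dna) else dna
  si <- .seq2int(scanSeq)
  sh <- .pwmScan(si, pwm$heptamer)
  sn <- .pwmScan(si, pwm$nonamer)
  n <- L - w + 1L
  idx <- seq_len(n)
  score <- sh[idx] + sn[idx + 7L + spacer_len]
  keep <- which(score >= min_score)
  if (!length(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      heptamer = character(0), spacer = character(0),
                      nonamer = character(0), score = numeric(0),
                      canonical = logical(0)))
  }
  hept <- substring(scanSeq, keep, keep + 6L)
  spac <- substring(scanSeq, keep + 7L, keep + 6L + spacer_len)
  nona <- substring(scanSeq, keep + 7L + spacer_len, keep + w - 1L)
  if (side == "5p") {
    start <- L - (keep + w - 1L) + 1L
  } else {
    start <- keep
  }
  out <- data.frame(start = start, end = start + w - 1L,
                    heptamer = hept, spacer = spac, nonamer = nona,
                    score = score[keep],
                    canonical = rsIsCanonical(hept, nona))
  out[order(-out$score, out$start), , drop = FALSE]
}
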