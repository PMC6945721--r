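#' Collect aligned recombination-signal elements from a germline set
#'
#' Pulls the fixed-width heptamers or nonamers of the genes of one type.
#' Following the convention of profiling only potentially functional
#' genes, the default keeps functionality F; ORF genes can be included.
#'
#' @param gset a \linkS4class{GermlineSet}.
#' @param gene_type "V", "D" or "J".
#' @param element "HEPTAMER" or "NONAMER".
#' @param side for D genes, which RS to take ("5p" or "3p"); V genes use
#'   their 3' RS and J genes their 5' RS automatically.
#' @param include_orf also keep ORF genes.
#' @return character vector of motif strings (possibly empty, with a
#'   warning).
#' @export
collectRS <- function(gset, gene_type, element = c("HEPTAMER", "NONAMER"),
                      side = NULL, include_orf = FALSE) {
  element <- match.arg(element)
  keep <- geneType(gset) == gene_type &
    functionality(gset) %in% c("F", if (include_orf) "ORF")
  if (!any(keep)) {
    warning("no ", gene_type, " genes selected for RS collection")
    return(character(0))
  }
  if (is.null(side)) side <- switch(gene_type, V = "3p", J = "5p", D = "5p")
  col <- paste0(if (side == "3p") "rs3" else "rs5", "_",
                tolower(element))
  out <- S4Vectors::mcols(gset@genes)[[col]][keep]
  names(out) <- geneNames(gset)[keep]
  out[!is.na(out)]
}

#' Build a position weight matrix from an aligned motif set
#'
#' Frequencies are \code{(count + pseudocount) / (n + 4 * pseudocount)}
#' per column; the information content is 2 minus the Shannon entropy of
#' the column, in bits. The default pseudocount of 0 reports raw relative
#' frequencies, as in a sequence-logo display.
#'
#' @param x character vector or DNAStringSet of equal-length sequences.
#' @param element label stored in the result (e.g. "V-HEPTAMER").
#' @param pseudocount nonnegative smoothing constant added per base.
#' @return An \linkS4class{RSProfile}.
#' @export
buildPWM <- function(x, element = "RS", pseudocount = 0) {
  x <- toupper(as.character(x))
  if (!length(x)) stop("buildPWM needs at least one sequence")
  if (length(unique(nchar(x))) != 1L)
    stop("buildPWM: ragged sequence lengths")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(x))
  counts <- matrix(0L, 4, nchar(x[1]), dimnames = list(DNA_BASES, NULL))
  common <- intersect(rownames(cm), DNA_BASES)
  counts[common, ] <- cm[common, , drop = FALSE]
  n <- length(x)
  freqs <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  # renormalise in case of non-ACGT characters in the input
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  ent <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  new("RSProfile", element = element, counts = counts, freqs = freqs,
      info = pmin(pmax(2 - ent, 0), 2), nseq = as.integer(n))
}

#' Export sequence-logo heights for a PWM
#'
#' Writes (and returns) a tidy per-position table with base heights equal
#' to frequency times information content, the quantity a logo renderer
#' stacks. Frequencies are recoverable as height / sum(height per column)
#' wherever the column information is non-zero.
#'
#' @param pwm an \linkS4class{RSProfile}.
#' @param path optional output TSV path.
#' @return data.frame with columns position, base, freq, height.
#' @export
exportLogoData <- function(pwm, path = NULL) {
  L <- ncol(pwm@freqs)
  out <- data.frame(
    position = rep(seq_len(L), each = 4L),
    base = rep(DNA_BASES, L),
    freq = as.vector(pwm@freqs),
    height = as.vector(sweep(pwm@freqs, 2, pwm@info, "*")))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
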