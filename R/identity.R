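#' Percent nucleotide identity between two sequences
#'
#' Global end-gap-free ("overlap") alignment with match +1, mismatch 0,
#' gap opening -5 and gap extension -1; identity is the number of matches
#' divided by the number of aligned columns excluding terminal gaps,
#' reported as a percentage to one decimal.
#'
#' @param a,b nucleotide strings (character or DNAString).
#' @return numeric percent identity in (0, 100].
#' @export
pairwiseIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("empty sequence in pairwiseIdentity")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncols <- length(pa)
  if (!ncols) return(0)
  matches <- sum(pa == sa & pa != "-")
  round(100 * matches / ncols, 1)
}

#' Partition V genes into subgroups by nucleotide identity
#'
#' Single-linkage clustering of V-REGION sequences: two genes belong to the
#' same subgroup when they are connected by a chain of pairwise identities
#' strictly greater than \code{threshold} percent. Subgroup numbering is
#' intrinsic (by the 5'-most member in locus coordinate order when
#' \code{starts} is given, else by the lexicographically smallest member
#' name), so the partition and the labels are invariant under input
#' permutation. Members of multimember subgroups are numbered 5'->3' along
#' the locus.
#'
#' @param seqs named character vector or DNAStringSet of V-REGION
#'   sequences.
#' @param threshold percent identity cut-off (default 75: "more than 75\%"
#'   joins a subgroup).
#' @param starts optional numeric vector of locus start coordinates used
#'   for ordering; defaults to alphabetical member names.
#' @param prefix optional gene-name prefix (e.g. "TRGV"); when given, the
#'   returned data.frame carries IMGT-style names
#'   \code{<prefix><subgroup>-<member>} (no member suffix for
#'   single-member subgroups).
#' @return data.frame with columns name, subgroup (integer), member
#'   (integer) and, when \code{prefix} is given, gene_name.
#' @export
assignSubgroups <- function(seqs, threshold = 75, starts = NULL,
                            prefix = NULL) {
  nm <- names(seqs)
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (!n) stop("assignSubgroups needs at least one sequence")
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  if (n == 1L) {
    cl <- 1L
  } else {
    idm <- matrix(100, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- pairwiseIdentity(seqs[i], seqs[j])
    }
    h <- hclust(as.dist(100 - idm), method = "single")
    cl <- cutree(h, h = 100 - threshold - 1e-7)
  }
  ord <- if (is.null(starts)) order(nm) else order(starts)
  first <- vapply(split(seq_len(n), cl), function(ix)
    min(match(ix, ord)), numeric(1))
  relabel <- rank(first)
  sub <- as.integer(relabel[as.character(cl)])
  member <- integer(n)
  for (s in unique(sub)) {
    ix <- which(sub == s)
    member[ix[order(match(ix, ord))]] <- seq_along(ix)
  }
  out <- data.frame(name = nm, subgroup = sub, member = member,
                    stringsAsFactors = FALSE)
  if (!is.null(prefix)) {
    multi <- table(sub)
    out$gene_name <- ifelse(multi[as.character(sub)] > 1L,
                            paste0(prefix, sub, "-", member),
                            paste0(prefix, sub))
  }
  out[order(match(seq_len(n), ord)), , drop = FALSE]
}
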