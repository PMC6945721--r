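#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString DNAStringSet
#'   QualityScaledDNAStringSet
#' @importFrom stats median quantile rbinom rgeom rpois runif sd setNames
#'   hclust cutree as.dist
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# positive-strand character reverse complement
.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence -> integer code A=1 C=2 G=3 T=4, anything else 5
.seq2int <- function(x) {
  m <- match(strsplit(toupper(x), "")[[1]], DNA_BASES)
  m[is.na(m)] <- 5L
  m
}

# translate an nt string in frame 1, truncating a trailing partial codon
.tx <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), if.fuzzy.codon = "X")))
}

.hydrophobic <- c("A", "V", "L", "I", "F", "M", "W", "Y", "C")

# standard codon table for back-translation (no stop codons)
.codons <- local({
  cod <- Biostrings::GENETIC_CODE
  split(names(cod), cod)[setdiff(unique(cod), "*")]
})

.randCodon <- function(aa) {
  vapply(aa, function(a) {
    cs <- .codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

.randSeq <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# first index where x is TRUE, 0L if none (vectorised over rows of a matrix)
.firstTrue <- function(m) {
  m2 <- cbind(m, TRUE)
  idx <- max.col(m2, ties.method = "first")
  ifelse(idx > ncol(m), 0L, idx)
}

# row-wise cumulative sums via triangular matrix product (BLAS-backed)
.rowCumsum <- function(m) {
  if (ncol(m) == 0L) return(m)
  tri <- upper.tri(diag(ncol(m)), diag = TRUE)
  m %*% (tri * 1)
}

# split a character vector of equal-length strings into an n x L matrix
.charMatrix <- function(x, width = NULL) {
  if (length(x) == 0L) return(matrix(character(0), 0, 0))
  if (is.null(width)) width <- max(nchar(x))
  pad <- width - nchar(x)
  if (any(pad > 0)) {
    x <- paste0(x, strrep("-", pmax(pad, 0L)))
  }
  matrix(unlist(strsplit(x, ""), use.names = FALSE), nrow = length(x),
         ncol = width, byrow = TRUE)
}

.pasteRows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
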