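#' GermlineSet: annotated germline genes of a T cell receptor locus
#'
#' Container for the germline V, D, J and C genes of one TR locus. Gene
#' coordinates live in a \linkS4class{GRanges} (1-based, closed intervals on
#' the forward strand of the locus sequence; reverse-strand genes carry
#' strand \code{"-"}); per-gene metadata columns hold the IMGT-style
#' classification: gene type, subgroup, functionality (F/ORF/P), the defect
#' list driving functionality, the flanking recombination signals, anchor
#' codon offsets and, for C genes, exon structure.
#'
#' @slot genes GRanges of gene bodies with the metadata columns described
#'   above.
#' @slot locusSeq DNAString, the locus sequence the coordinates refer to.
#' @slot locusId character, one of TRA, TRB, TRG, TRD, TRA/TRD.
#' @export
setClass("GermlineSet",
  representation(genes = "GRanges", locusSeq = "DNAString",
                 locusId = "character"))

GENE_MCOLS <- c("name", "gene_type", "subgroup", "functionality", "defects",
  "nt", "score", "unit",
  "rs3_heptamer", "rs3_spacer", "rs3_nonamer", "rs3_score", "rs3_canonical",
  "rs5_heptamer", "rs5_spacer", "rs5_nonamer", "rs5_score", "rs5_canonical",
  "anchor104", "anchor118", "exon_starts", "exon_ends")

DEFECT_LEVELS <- c("STOP_CODON", "FRAMESHIFT", "NONCANONICAL_RS",
                   "MISSING_ANCHOR", "MISSING_SPLICE", "DEGENERATE")

setValidity("GermlineSet", function(object) {
  g <- object@genes
  mc <- S4Vectors::mcols(g)
  miss <- setdiff(GENE_MCOLS, colnames(mc))
  if (length(miss))
    return(paste("missing gene metadata columns:", paste(miss, collapse = ", ")))
  if (length(g)) {
    if (!all(mc$gene_type %in% c("V", "D", "J", "C")))
      return("gene_type must be one of V, D, J, C")
    if (!all(mc$functionality %in% c("F", "ORF", "P")))
      return("functionality must be one of F, ORF, P")
    if (any(GenomicRanges::end(g) > length(object@locusSeq)))
      return("gene coordinates exceed locus length")
    bad <- unlist(lapply(mc$defects, function(d) setdiff(d, DEFECT_LEVELS)))
    if (length(bad))
      return(paste("unknown defect:", paste(unique(bad), collapse = ", ")))
    # V: 3' RS only; J: 5' RS only; D: both
    isV <- mc$gene_type == "V"; isJ <- mc$gene_type == "J"
    isD <- mc$gene_type == "D"
    if (any(isV & (is.na(mc$rs3_heptamer) | !is.na(mc$rs5_heptamer))))
      return("V genes must carry exactly one RS, at the 3' end")
    if (any(isJ & (is.na(mc$rs5_heptamer) | !is.na(mc$rs3_heptamer))))
      return("J genes must carry exactly one RS, at the 5' end")
    if (any(isD & (is.na(mc$rs5_heptamer) | is.na(mc$rs3_heptamer))))
      return("D genes must carry both a 5' and a 3' RS")
    # functionality must be the pure function of the defect list
    expect <- vapply(mc$defects, classifyFunctionality, character(1))
    if (!all(expect == mc$functionality))
      return("functionality inconsistent with defect list")
  }
  TRUE
})

#' Construct a GermlineSet from a per-gene data.frame
#'
#' @param genes data.frame with columns \code{name}, \code{gene_type},
#'   \code{start}, \code{end}, \code{strand} plus any of the optional
#'   metadata columns (subgroup, defects (list column), nt, score, unit,
#'   rs3_*/rs5_* recombination-signal fields, anchor104, anchor118,
#'   exon_starts/exon_ends (list columns)). Missing optional columns are
#'   filled with NA. Functionality is derived from the defect list.
#' @param locusSeq DNAString or character locus sequence.
#' @param locusId locus identifier (TRA, TRB, TRG, TRD or TRA/TRD).
#' @return A \linkS4class{GermlineSet}.
#' @export
GermlineSet <- function(genes, locusSeq, locusId) {
  if (is.character(locusSeq)) locusSeq <- Biostrings::DNAString(locusSeq)
  n <- nrow(genes)
  if (is.null(genes$defects)) genes$defects <- replicate(n, character(0), FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(locusId, n),
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  df <- S4Vectors::DataFrame(
    name = as.character(genes$name),
    gene_type = as.character(genes$gene_type),
    subgroup = if (is.null(genes$subgroup)) rep(NA_character_, n) else as.character(genes$subgroup),
    functionality = vapply(genes$defects, classifyFunctionality, character(1)),
    defects = IRanges::CharacterList(genes$defects),
    nt = if (is.null(genes$nt)) rep(NA_character_, n) else as.character(genes$nt),
    score = if (is.null(genes$score)) rep(NA_real_, n) else as.numeric(genes$score),
    unit = if (is.null(genes$unit)) rep(NA_integer_, n) else as.integer(genes$unit),
    anchor104 = if (is.null(genes$anchor104)) rep(NA_integer_, n) else as.integer(genes$anchor104),
    anchor118 = if (is.null(genes$anchor118)) rep(NA_integer_, n) else as.integer(genes$anchor118),
    exon_starts = if (is.null(genes$exon_starts))
      IRanges::IntegerList(replicate(n, integer(0), FALSE)) else IRanges::IntegerList(genes$exon_starts),
    exon_ends = if (is.null(genes$exon_ends))
      IRanges::IntegerList(replicate(n, integer(0), FALSE)) else IRanges::IntegerList(genes$exon_ends))
  for (side in c("rs3", "rs5")) {
    for (f in c("heptamer", "spacer", "nonamer")) {
      col <- paste0(side, "_", f)
      df[[col]] <- if (is.null(genes[[col]])) rep(NA_character_, n) else as.character(genes[[col]])
    }
    col <- paste0(side, "_score")
    df[[col]] <- if (is.null(genes[[col]])) rep(NA_real_, n) else as.numeric(genes[[col]])
    col <- paste0(side, "_canonical")
    df[[col]] <- if (is.null(genes[[col]])) rep(NA, n) else as.logical(genes[[col]])
  }
  S4Vectors::mcols(gr) <- df[, GENE_MCOLS]
  new("GermlineSet", genes = gr, locusSeq = locusSeq, locusId = locusId)
}

#' RSProfile: position weight matrix of a recombination-signal element
#'
#' Per-position nucleotide counts, relative frequencies and information
#' content (bits) for an aligned set of RS heptamers or nonamers.
#'
#' @slot element label such as V-HEPTAMER or J-NONAMER.
#' @slot counts 4 x L integer matrix (rows A, C, G, T).
#' @slot freqs 4 x L matrix of relative frequencies; columns sum to 1.
#' @slot info numeric length-L vector, 2 minus the Shannon entropy per
#'   column, in bits.
#' @slot nseq number of sequences the matrix was built from.
#' @export
setClass("RSProfile",
  representation(element = "character", counts = "matrix", freqs = "matrix",
                 info = "numeric", nseq = "integer"))

setValidity("RSProfile", function(object) {
  f <- object@freqs
  if (!identical(rownames(f), DNA_BASES)) return("freqs rows must be A,C,G,T")
  if (ncol(f) && any(abs(colSums(f) - 1) > 1e-9))
    return("freqs columns must sum to 1")
  if (any(object@info < -1e-9 | object@info > 2 + 1e-9))
    return("information content must lie in [0, 2] bits")
  TRUE
})

#' VNumbering: IMGT unique numbering of a V-REGION translation
#'
#' Maps each residue of a translated V-REGION to its IMGT position
#' (1..104), records which of the four anchors (1st-CYS 23, CONSERVED-TRP
#' 41, hydrophobic 89, 2nd-CYS 104) are present, and whether a consistent
#' placement was found at all.
#'
#' @slot positions integer vector, IMGT position per residue (NA for
#'   residues beyond position 104).
#' @slot anchors named logical: c23, w41, h89, c104.
#' @slot ok logical, FALSE when no placement satisfying the region
#'   constraints exists.
#' @export
setClass("VNumbering",
  representation(positions = "integer", anchors = "logical", ok = "logical"))

#' GeneProfile: position-specific scoring profile for gene discovery
#'
#' Log-odds profile over the positions of an aligned germline gene set,
#' used to score candidate gene segments during locus scanning.
#'
#' @slot logodds 4 x L log2-odds matrix against a uniform background.
#' @slot consensus DNAString majority-rule consensus of the training set.
#' @slot threshold acceptance score: mean minus 3 SD of the training
#'   sequences' self-scores.
#' @slot relic lower "relic" score bound above which heavily degenerate
#'   pseudogene candidates are still reported (with a DEGENERATE defect).
#' @export
setClass("GeneProfile",
  representation(logodds = "matrix", consensus = "DNAString",
                 threshold = "numeric", relic = "numeric"))

## ---- accessors -----------------------------------------------------------

#' @describeIn GermlineSet number of genes
#' @param x,object a GermlineSet
#' @export
setMethod("length", "GermlineSet", function(x) length(x@genes))

#' Accessors for GermlineSet
#'
#' @param x a \linkS4class{GermlineSet}
#' @return \code{geneNames}, \code{geneType}, \code{functionality} return
#'   character vectors; \code{geneDefects} a CharacterList; \code{geneSeqs}
#'   a DNAStringSet of gene-centric (coding-strand) sequences;
#'   \code{geneRanges} the underlying GRanges; \code{unitIndex} the cassette
#'   or cluster index per gene; \code{locusId} and \code{locusSeq} the locus
#'   identifier and sequence.
#' @name germline-accessors
NULL

#' @rdname germline-accessors
#' @export
geneNames <- function(x) S4Vectors::mcols(x@genes)$name
#' @rdname germline-accessors
#' @export
geneType <- function(x) S4Vectors::mcols(x@genes)$gene_type
#' @rdname germline-accessors
#' @export
functionality <- function(x) S4Vectors::mcols(x@genes)$functionality
#' @rdname germline-accessors
#' @export
geneDefects <- function(x) S4Vectors::mcols(x@genes)$defects
#' @rdname germline-accessors
#' @export
geneRanges <- function(x) x@genes
#' @rdname germline-accessors
#' @export
unitIndex <- function(x) S4Vectors::mcols(x@genes)$unit
#' @rdname germline-accessors
#' @export
locusId <- function(x) x@locusId
#' @rdname germline-accessors
#' @export
locusSeq <- function(x) x@locusSeq
#' @rdname germline-accessors
#' @export
geneSeqs <- function(x) {
  s <- Biostrings::DNAStringSet(S4Vectors::mcols(x@genes)$nt)
  names(s) <- geneNames(x)
  s
}

#' @describeIn GermlineSet subset genes
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "GermlineSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, genes = x@genes[i])
})

setMethod("show", "GermlineSet", function(object) {
  tab <- table(factor(geneType(object), c("V", "D", "J", "C")))
  cat("GermlineSet:", object@locusId, "locus,",
      length(object@locusSeq), "nt\n")
  cat(sprintf("  %d genes (%d V, %d D, %d J, %d C)\n", length(object),
              tab[["V"]], tab[["D"]], tab[["J"]], tab[["C"]]))
  ft <- table(factor(functionality(object), c("F", "ORF", "P")))
  cat(sprintf("  functionality: %d F, %d ORF, %d P\n",
              ft[["F"]], ft[["ORF"]], ft[["P"]]))
})

setMethod("show", "RSProfile", function(object) {
  cat("RSProfile:", object@element, "-", ncol(object@freqs), "positions,",
      object@nseq, "sequences\n")
  cat("  information content (bits):",
      paste(sprintf("%.2f", object@info), collapse = " "), "\n")
})

setMethod("show", "VNumbering", function(object) {
  if (!object@ok) {
    cat("VNumbering: no consistent placement\n")
  } else {
    cat("VNumbering:", length(object@positions), "residues; anchors",
        paste(names(object@anchors)[object@anchors], collapse = ","), "\n")
  }
})

#' Per-type, per-functionality gene count summary
#'
#' Tabulates gene counts by type and functionality class, in the style of a
#' locus-description summary table, exposing both the per-class tallies and
#' the raw totals.
#'
#' @param gset a \linkS4class{GermlineSet}
#' @return data.frame with columns gene_type, functionality and n, plus a
#'   \code{"total"} attribute with the overall gene count.
#' @export
countsByFunctionality <- function(gset) {
  tab <- as.data.frame(table(
    gene_type = factor(geneType(gset), c("V", "D", "J", "C")),
    functionality = factor(functionality(gset), c("F", "ORF", "P"))),
    stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  attr(tab, "total") <- length(gset)
  tab
}
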