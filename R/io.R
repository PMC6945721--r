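#' Read a FASTA file with validation
#'
#' Wraps Biostrings' FASTA reader with the checks the pipeline relies on:
#' record order is preserved, sequences are upper-cased, U is mapped to T
#' in nucleotide mode, and empty files, duplicate identifiers and
#' non-IUPAC characters raise errors naming the offending record.
#'
#' @param path FASTA file.
#' @param alphabet "dna" or "aa".
#' @return DNAStringSet (dna) or AAStringSet (aa), named by record id.
#' @export
readFasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  ids <- names(x)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1])
  s <- toupper(as.character(x))
  if (alphabet == "dna") {
    s <- chartr("U", "T", s)
    legal <- paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
    bad <- grepl(sprintf("[^%s.-]", legal), s)
    if (any(bad))
      stop("illegal nucleotide character in record: ", ids[bad][1])
    out <- Biostrings::DNAStringSet(s)
  } else {
    bad <- grepl("[^A-Z*.-]", s)
    if (any(bad))
      stop("illegal amino-acid character in record: ", ids[bad][1])
    out <- Biostrings::AAStringSet(s)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x XStringSet or named character vector.
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Sanger phred+33)
#'
#' @param path FASTQ file (optionally gzipped).
#' @return QualityScaledDNAStringSet.
#' @export
readFastq <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write a FASTQ file (Sanger phred+33)
#'
#' @param x QualityScaledDNAStringSet.
#' @param path output file.
#' @export
writeFastq <- function(x, path) {
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

AIRR_REQUIRED <- c("sequence_id", "v_call", "j_call", "junction",
                   "junction_aa", "productive", "locus")

#' Write rearrangements as an AIRR Rearrangement TSV
#'
#' Emits the community-standard tab-separated rearrangement table.
#' Ambiguous gene calls must already be comma-joined in locus order in a
#' single field. Logical \code{productive} is serialised as T/F.
#'
#' @param x data.frame of rearrangements; must contain the mandatory AIRR
#'   fields sequence_id, v_call, j_call, junction, junction_aa, productive
#'   and locus.
#' @param path output TSV.
#' @export
writeAirr <- function(x, path) {
  miss <- setdiff(AIRR_REQUIRED, colnames(x))
  if (length(miss))
    stop("missing mandatory AIRR field(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)
  if (is.logical(x$productive))
    x$productive <- ifelse(is.na(x$productive), "", ifelse(x$productive, "T", "F"))
  first <- intersect(c("sequence_id", "locus", "v_call", "d_call", "j_call",
                       "junction", "junction_aa", "cdr3", "productive"),
                     colnames(x))
  x <- x[, c(first, setdiff(colnames(x), first)), drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR Rearrangement TSV
#'
#' @param path TSV written by [writeAirr()] (or any AIRR rearrangement
#'   file containing the mandatory fields).
#' @return data.frame with \code{productive} decoded to logical.
#' @export
readAirr <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(AIRR_REQUIRED, colnames(x))
  if (length(miss))
    stop("missing mandatory AIRR field(s): ", paste(miss, collapse = ", "))
  x$productive <- ifelse(x$productive == "", NA, x$productive %in% c("T", "TRUE", "true"))
  for (col in intersect(c("v_cassette", "j_cassette"), colnames(x)))
    x[[col]] <- suppressWarnings(as.integer(x[[col]]))
  x
}

#' Write a locus map as GFF3
#'
#' One feature per gene plus one per recombination signal, 1-based
#' inclusive coordinates, strand reflecting transcriptional orientation.
#' C-gene exons are emitted as child exon features.
#'
#' @param gset a \linkS4class{GermlineSet}.
#' @param path output GFF3.
#' @export
writeGff3 <- function(gset, path) {
  g <- gset@genes
  if (any(GenomicRanges::end(g) > length(gset@locusSeq)) ||
      any(GenomicRanges::start(g) < 1L))
    stop("gene coordinates outside the locus sequence")
  if (!length(g)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(g)
  feats <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(g),
    ranges = IRanges::ranges(g), strand = GenomicRanges::strand(g),
    type = "gene",
    ID = mc$name, Name = mc$name, gene_type = mc$gene_type,
    functionality = mc$functionality,
    defects = vapply(mc$defects, paste, character(1), collapse = ","))
  add <- list()
  for (side in c("rs3", "rs5")) {
    has <- !is.na(mc[[paste0(side, "_heptamer")]])
    if (!any(has)) next
    hept <- mc[[paste0(side, "_heptamer")]][has]
    spac <- mc[[paste0(side, "_spacer")]][has]
    nona <- mc[[paste0(side, "_nonamer")]][has]
    w <- nchar(hept) + nchar(spac) + nchar(nona)
    fwd <- as.character(GenomicRanges::strand(g)[has]) != "-"
    threePrime <- (side == "rs3") == fwd  # RS right of the gene on + strand
    st <- ifelse(threePrime, GenomicRanges::end(g)[has] + 1L,
                 GenomicRanges::start(g)[has] - w)
    add[[side]] <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(g)[has],
      ranges = IRanges::IRanges(st, width = w),
      strand = GenomicRanges::strand(g)[has],
      type = "recombination_signal",
      ID = paste0(mc$name[has], "_", side),
      Name = paste0(mc$name[has], "_", side),
      gene_type = NA_character_, functionality = NA_character_,
      defects = NA_character_)
  }
  es <- mc$exon_starts; ee <- mc$exon_ends
  nex <- lengths(es)
  if (any(nex > 0)) {
    ix <- rep(seq_along(g), nex)
    add$exons <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(g)[ix],
      ranges = IRanges::IRanges(unlist(es), unlist(ee)),
      strand = GenomicRanges::strand(g)[ix],
      type = "exon",
      ID = paste0(mc$name[ix], "_EX", unlist(lapply(nex[nex > 0], seq_len))),
      Name = NA_character_, gene_type = NA_character_,
      functionality = NA_character_, defects = NA_character_)
  }
  out <- suppressWarnings(c(feats, do.call(c, unname(add))))
  if (any(GenomicRanges::start(out) < 1L) ||
      any(GenomicRanges::end(out) > length(gset@locusSeq)))
    stop("feature coordinates outside the locus sequence")
  rtracklayer::export.gff3(out, path)
  invisible(path)
}

#' Run configuration
#'
#' Validated bundle of the pipeline's tunable parameters: the locus, the
#' RS spacer policy (12/23 rule), the subgroup identity threshold, quality
#' trimming settings and the RNG seed.
#'
#' @param locus_id one of TRA, TRB, TRG, TRD, TRA/TRD.
#' @param spacer_policy named list of spacer lengths (nt) per RS: v_3p,
#'   j_5p, d_5p, d_3p. The defaults (V 23, J 12, D 5' 12 / 3' 23) let the
#'   12/23 rule permit both direct V-J and V-D-J joins.
#' @param identity_threshold percent identity for subgroup assignment.
#' @param trim_quality phred cut-off of the sliding-window trimmer.
#' @param trim_window window width (nt).
#' @param rng_seed integer seed.
#' @param output_dir output directory.
#' @return a validated list of class \code{tr_config}.
#' @export
runConfig <- function(locus_id = "TRG",
                      spacer_policy = list(v_3p = 23L, j_5p = 12L,
                                           d_5p = 12L, d_3p = 23L),
                      identity_threshold = 75, trim_quality = 30,
                      trim_window = 4L, rng_seed = 1L,
                      output_dir = ".") {
  if (!locus_id %in% c("TRA", "TRB", "TRG", "TRD", "TRA/TRD"))
    stop("unknown locus_id: ", locus_id)
  if (!all(unlist(spacer_policy) %in% c(12L, 23L)))
    stop("spacer lengths must be 12 or 23")
  if (identity_threshold <= 0 || identity_threshold > 100)
    stop("identity_threshold must be in (0, 100]")
  if (trim_quality < 0) stop("trim_quality must be >= 0")
  structure(list(locus_id = locus_id, spacer_policy = spacer_policy,
                 identity_threshold = identity_threshold,
                 trim_quality = trim_quality, trim_window = trim_window,
                 rng_seed = as.integer(rng_seed), output_dir = output_dir),
            class = "tr_config")
}

#' @rdname runConfig
#' @param path JSON file.
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spacer_policy <- as.list(x$spacer_policy)
  do.call(runConfig, x)
}

#' @rdname runConfig
#' @param config a \code{tr_config}.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Germline FASTA with pipeline metadata
#'
#' The repertoire pipeline needs, besides each germline sequence, its gene
#' type, anchor codon offset (2nd-CYS 104 for V, J-PHE/J-TRP 118 for J)
#' and cassette/cluster index. These travel in the FASTA header as
#' \code{>name type=V anchor=292 unit=1}.
#'
#' @param gset a \linkS4class{GermlineSet}.
#' @param path output FASTA.
#' @export
writeGermlineFasta <- function(gset, path) {
  mc <- S4Vectors::mcols(gset@genes)
  anchor <- ifelse(mc$gene_type == "V", mc$anchor104,
                   ifelse(mc$gene_type == "J", mc$anchor118, NA))
  exlen <- vapply(seq_along(mc$exon_starts), function(i) {
    w <- mc$exon_ends[[i]] - mc$exon_starts[[i]] + 1L
    if (length(w)) paste(w, collapse = ",") else ""
  }, character(1))
  hdr <- paste0(mc$name, " type=", mc$gene_type,
                ifelse(is.na(anchor), "", paste0(" anchor=", anchor)),
                ifelse(is.na(mc$unit), "", paste0(" unit=", mc$unit)),
                ifelse(exlen == "", "", paste0(" exons=", exlen)),
                " functionality=", mc$functionality)
  x <- Biostrings::DNAStringSet(mc$nt)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeGermlineFasta
#' @return \code{readGermlineFasta}: a germline reference table
#'   (data.frame with name, gene_type, seq, anchor, unit, functionality)
#'   usable by [assignGenes()].
#' @export
readGermlineFasta <- function(path) {
  x <- readFasta(path, "dna")
  hdr <- names(x)
  getField <- function(f) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]+", f), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(sprintf("%s=", f), hdr)] <- sub(sprintf("%s=", f), "",
      regmatches(hdr, regexpr(sprintf("%s=[^ ]+", f), hdr)))
    out
  }
  data.frame(name = sub(" .*", "", hdr),
             gene_type = getField("type"),
             seq = as.character(x),
             anchor = suppressWarnings(as.integer(getField("anchor"))),
             unit = suppressWarnings(as.integer(getField("unit"))),
             exon_lens = getField("exons"),
             functionality = getField("functionality"),
             stringsAsFactors = FALSE)
}
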