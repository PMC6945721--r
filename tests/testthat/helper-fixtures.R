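# shared fixtures: all synthetic, built in code at test time

# a default 5-cassette TRG locus with its training germline lists
# (profiles are trained on the potentially functional genes, as curated
# germline directories contain)
tinyTRG <- function(seed = 7, blueprint = locusBlueprint("TRG")) {
  sl <- buildSyntheticLocus(blueprint, seed = seed)
  mc <- S4Vectors::mcols(sl$truth@genes)
  firstC <- which(mc$gene_type == "C")[1]
  ok <- mc$functionality %in% c("F", "ORF")
  germ <- list(
    V = mc$nt[mc$gene_type == "V" & ok],
    J = mc$nt[mc$gene_type == "J" & ok],
    C = substring(as.character(sl$truth@locusSeq),
                  mc$exon_starts[[firstC]], mc$exon_ends[[firstC]]))
  list(sl = sl, truth = sl$truth, mc = mc, germ = germ)
}

# identity of a recovered gene: exact span, type, strand, functionality
geneKey <- function(gset) {
  paste(GenomicRanges::start(gset@genes), GenomicRanges::end(gset@genes),
        S4Vectors::mcols(gset@genes)$gene_type,
        as.character(GenomicRanges::strand(gset@genes)),
        S4Vectors::mcols(gset@genes)$functionality)
}

coordKey <- function(gset) {
  paste(GenomicRanges::start(gset@genes), GenomicRanges::end(gset@genes),
        S4Vectors::mcols(gset@genes)$gene_type,
        as.character(GenomicRanges::strand(gset@genes)))
}

# QualityScaledDNAStringSet from plain strings and a quality string/values
qreads <- function(seqs, quals) {
  if (is.numeric(quals))
    quals <- vapply(list(quals), function(q)
      rawToChar(as.raw(q + 33L)), character(1))
  if (length(quals) == 1L && length(seqs) > 1L)
    quals <- rep(quals, length(seqs))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- if (is.null(names(seqs))) paste0("r", seq_along(seqs))
              else names(seqs)
  x
}

# mean per-column Kullback-Leibler divergence between a PWM and the
# generating frequencies
meanKL <- function(pwm, gen) {
  f <- pwm@freqs
  mean(vapply(seq_len(ncol(f)), function(j) {
    p <- gen[, j]; q <- f[, j]
    sum(p * log(p / q))
  }, numeric(1)))
}
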