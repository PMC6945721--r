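#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' and cuts it at the start of the first window
#' whose mean phred quality drops below \code{qmin}; reads shorter than
#' \code{min_len} after trimming are dropped.
#'
#' @param reads QualityScaledDNAStringSet (phred+33).
#' @param window window width (nt).
#' @param qmin phred cut-off (default 30).
#' @param min_len minimum kept length.
#' @return trimmed QualityScaledDNAStringSet (dropped reads removed;
#'   names preserved).
#' @export
slidingWindowTrim <- function(reads, window = 4L, qmin = 30, min_len = 50L) {
  n <- length(reads)
  if (!n) return(reads)
  lens <- Biostrings::width(reads)
  qlens <- Biostrings::width(Biostrings::quality(reads))
  if (!all(lens == qlens))
    stop("sequence/quality length mismatch in record ",
         names(reads)[which(lens != qlens)[1]])
  qints <- as(Biostrings::quality(reads), "IntegerList")
  keepLen <- integer(n)
  for (L in unique(lens)) {
    ix <- which(lens == L)
    if (L < window) { keepLen[ix] <- 0L; next }
    qm <- matrix(unlist(qints[ix], use.names = FALSE), nrow = length(ix),
                 ncol = L, byrow = TRUE)
    cs <- .rowCumsum(qm)
    nw <- L - window + 1L
    wsum <- cs[, window:L, drop = FALSE] -
      cbind(0, cs[, seq_len(nw - 1L), drop = FALSE])
    fail <- wsum / window < qmin
    first <- .firstTrue(fail)
    keepLen[ix] <- ifelse(first == 0L, L, first - 1L)
  }
  keep <- keepLen >= min_len
  if (!any(keep)) {
    out <- reads[0]
    return(out)
  }
  sq <- substr(as.character(reads)[keep], 1L, keepLen[keep])
  qu <- substr(as.character(Biostrings::quality(reads))[keep], 1L,
               keepLen[keep])
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(sq), Biostrings::PhredQuality(qu))
  names(out) <- names(reads)[keep]
  out
}

#' Merge read pairs by overlap
#'
#' Finds, for each pair, the best arrangement of R1 and the reverse
#' complement of R2 with an overlap of at least \code{min_overlap} nt and
#' at most \code{max_mm} mismatches (score: overlap matches minus 5 per
#' mismatch). Overlap disagreements are resolved toward the
#' higher-quality base; overlap qualities take the per-base maximum.
#'
#' @param r1,r2 QualityScaledDNAStringSet mates (r2 is the reverse mate).
#' @param min_overlap minimum admissible overlap.
#' @param max_mm maximum mismatches within the overlap.
#' @return list with \code{merged} (QualityScaledDNAStringSet of merged
#'   sequences) and \code{merged_flag} (logical per input pair).
#' @export
mergePairs <- function(r1, r2, min_overlap = 20L, max_mm = 5L) {
  n <- length(r1)
  stopifnot(length(r2) == n)
  s1 <- as.character(r1)
  s2 <- .rc(as.character(r2))
  q1c <- as.character(Biostrings::quality(r1))
  q2c <- vapply(strsplit(as.character(Biostrings::quality(r2)), ""),
                function(z) paste(rev(z), collapse = ""), character(1))
  L1 <- nchar(s1); L2 <- nchar(s2)
  bestT <- rep(NA_integer_, n); bestScore <- rep(-Inf, n)
  grpKey <- paste(L1, L2)
  for (key in unique(grpKey)) {
    ix <- which(grpKey == key)
    l1 <- L1[ix[1]]; l2 <- L2[ix[1]]
    M1 <- .charMatrix(s1[ix], l1); M2 <- .charMatrix(s2[ix], l2)
    for (T in max(l1, l2):(l1 + l2 - min_overlap)) {
      o2 <- T - l2
      ov <- l1 - o2
      if (ov < min_overlap) break
      c1 <- (o2 + 1L):l1; c2 <- seq_len(ov)
      k <- min(20L, ov)
      cheap <- rowSums(M1[, c1[seq_len(k)], drop = FALSE] !=
                         M2[, c2[seq_len(k)], drop = FALSE])
      cand <- which(cheap <= 2L)
      if (!length(cand)) next
      mm <- rowSums(M1[cand, c1, drop = FALSE] != M2[cand, c2, drop = FALSE])
      ok <- mm <= max_mm
      sc <- (ov - mm) - 5 * mm
      upd <- ok & sc > bestScore[ix[cand]]
      bestScore[ix[cand][upd]] <- sc[upd]
      bestT[ix[cand][upd]] <- T
    }
  }
  flag <- !is.na(bestT)
  if (!any(flag)) {
    return(list(merged = Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character(0)),
      Biostrings::PhredQuality(character(0))), merged_flag = flag))
  }
  mseq <- character(n); mqual <- character(n)
  sel <- which(flag)
  for (T in unique(bestT[sel])) {
    ix <- sel[bestT[sel] == T]
    for (key in unique(grpKey[ix])) {
      jj <- ix[grpKey[ix] == key]
      l1 <- L1[jj[1]]; l2 <- L2[jj[1]]
      o2 <- T - l2; ov <- l1 - o2
      A1 <- .charMatrix(s1[jj], l1); A2 <- .charMatrix(s2[jj], l2)
      Q1 <- .charMatrix(q1c[jj], l1); Q2 <- .charMatrix(q2c[jj], l2)
      c1 <- (o2 + 1L):l1; c2 <- seq_len(ov)
      useR2 <- (A1[, c1, drop = FALSE] != A2[, c2, drop = FALSE]) &
        (Q2[, c2, drop = FALSE] > Q1[, c1, drop = FALSE])
      ovB <- A1[, c1, drop = FALSE]; ovB[useR2] <- A2[, c2, drop = FALSE][useR2]
      ovQ <- pmax(Q1[, c1, drop = FALSE], Q2[, c2, drop = FALSE])
      pre <- if (o2 > 0) A1[, seq_len(o2), drop = FALSE] else NULL
      post <- if (l2 > ov) A2[, (ov + 1L):l2, drop = FALSE] else NULL
      preQ <- if (o2 > 0) Q1[, seq_len(o2), drop = FALSE] else NULL
      postQ <- if (l2 > ov) Q2[, (ov + 1L):l2, drop = FALSE] else NULL
      mseq[jj] <- .pasteRows(cbind(pre, ovB, post))
      mqual[jj] <- .pasteRows(cbind(preQ, ovQ, postQ))
    }
  }
  merged <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(mseq[flag]),
    Biostrings::PhredQuality(mqual[flag]))
  names(merged) <- names(r1)[flag]
  list(merged = merged, merged_flag = flag)
}

#' Build a gene-assignment reference from a germline set
#'
#' Extracts the rearrangement-eligible genes (functionality F or ORF with
#' intact junction anchors) in locus order, as needed by
#' [assignGenes()].
#'
#' @param x a \linkS4class{GermlineSet} or a data.frame from
#'   [readGermlineFasta()].
#' @return list with data.frames \code{v} (name, seq, anchor, unit),
#'   \code{j} (idem) and \code{d} (name, seq).
#' @export
referenceTable <- function(x) {
  if (is(x, "GermlineSet")) {
    x <- x[order(GenomicRanges::start(x@genes))]
    mc <- S4Vectors::mcols(x@genes)
    df <- data.frame(name = mc$name, gene_type = mc$gene_type, seq = mc$nt,
      anchor = ifelse(mc$gene_type == "V", mc$anchor104,
                      ifelse(mc$gene_type == "J", mc$anchor118, NA)),
      unit = mc$unit, functionality = mc$functionality,
      stringsAsFactors = FALSE)
  } else df <- x
  elig <- df$functionality %in% c("F", "ORF") | is.na(df$functionality)
  v <- df[df$gene_type == "V" & elig & !is.na(df$anchor), , drop = FALSE]
  j <- df[df$gene_type == "J" & elig & !is.na(df$anchor), , drop = FALSE]
  d <- df[df$gene_type == "D" & (df$functionality %in% "F" | is.na(df$functionality)), , drop = FALSE]
  list(v = v[, c("name", "seq", "anchor", "unit")],
       j = j[, c("name", "seq", "anchor", "unit")],
       d = d[, c("name", "seq"), drop = FALSE])
}

# seed-and-extend ungapped scoring of one gene over a read set.
# anchored = "left" (V genes: gene 5' end present in the read) or "right"
# (J genes: gene 3' end present). Returns per-read score (+1 match /
# -1 mismatch over the best-scoring extension), aligned length, identity
# and the read position of gene position 1.
.scoreGene <- function(reads, gene, anchored, min_len, probe_len = 16L,
                       bound = NULL) {
  n <- length(reads)
  res <- list(score = rep(NA_real_, n), len = rep(NA_integer_, n),
              ident = rep(NA_real_, n), offset = rep(NA_integer_, n))
  Lg <- nchar(gene)
  probe_len <- min(probe_len, Lg)
  probe <- if (anchored == "left") substr(gene, 1L, probe_len)
           else substr(gene, Lg - probe_len + 1L, Lg)
  m <- Biostrings::vmatchPattern(probe, Biostrings::DNAStringSet(reads),
                                 max.mismatch = 2L)
  st <- Biostrings::startIndex(m)
  first <- vapply(st, function(z) if (length(z)) z[[1]] else NA_integer_,
                  integer(1))
  hit <- which(!is.na(first))
  if (!length(hit)) return(res)
  # offset: read position of gene position 1 (may be <= 0 for right anchor)
  off <- if (anchored == "left") first[hit]
         else first[hit] - (Lg - probe_len)
  gch <- strsplit(gene, "")[[1]]
  rl <- nchar(reads)
  for (o in unique(off)) {
    ix <- hit[off == o]
    gpos <- seq_len(Lg)
    rpos <- gpos + o - 1L
    ok <- rpos >= 1L
    gpos <- gpos[ok]; rpos <- rpos[ok]
    W <- max(rpos)
    M <- .charMatrix(substr(reads[ix], 1L, W), W)
    eq <- M[, rpos, drop = FALSE] ==
      matrix(gch[gpos], nrow = length(ix), ncol = length(gpos), byrow = TRUE)
    pm <- ifelse(eq, 1, -1)
    if (!is.null(bound)) {
      # read positions already claimed by the V alignment are neutral:
      # a chance match there must not break a genuine ambiguity tie
      claimed <- outer(bound[ix], rpos, ">=")
      pm[claimed] <- 0
    }
    if (anchored == "right") pm <- pm[, rev(seq_len(ncol(pm))), drop = FALSE]
    cum <- .rowCumsum(pm)
    k <- ncol(cum)
    if (k < min_len) next
    span <- min_len:k
    sub <- cum[, span, drop = FALSE]
    bi <- max.col(sub, ties.method = "last")
    bscore <- sub[cbind(seq_along(ix), bi)]
    blen <- span[bi]
    res$score[ix] <- bscore
    res$len[ix] <- blen
    res$ident[ix] <- ((bscore + blen) / 2) / blen
    res$offset[ix] <- o
  }
  res
}

#' Assign V and J germline genes to rearranged sequences
#'
#' Seed-and-extend ungapped alignment of each eligible germline gene
#' against each read: a short anchor probe (the gene's 5' end for V, 3'
#' end for J) locates the diagonal, which is then scored +1/-1 over its
#' best extension. The best-scoring V (of the read's 5' part) and J (3'
#' part) are called; all genes within \code{tie_margin} match-equivalents
#' of the top score form the ambiguity set, reported in locus order.
#' Assignment floors: V needs >= \code{v_min_len} aligned nt at >=
#' \code{v_min_ident} identity; J needs >= \code{j_min_len} aligned nt.
#' Reads failing either floor are unassigned.
#'
#' @param seqs character vector or DNAStringSet of merged reads.
#' @param ref reference list from [referenceTable()].
#' @param tie_margin score margin for the ambiguity set (1 = one
#'   match-equivalent).
#' @param v_min_len,v_min_ident,j_min_len assignment floors.
#' @return data.frame per read: v_call, j_call (comma-joined ambiguity
#'   sets), v_best, j_best, v_identity, p104, p118 (read positions of the
#'   2nd-CYS and J-PHE/TRP codon starts), v_unit, j_unit, unassigned.
#' @export
assignGenes <- function(seqs, ref, tie_margin = 1, v_min_len = 50L,
                        v_min_ident = 0.6, j_min_len = 14L) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  nV <- nrow(ref$v); nJ <- nrow(ref$j)
  vS <- matrix(NA_real_, n, nV); vO <- matrix(NA_integer_, n, nV)
  vI <- matrix(NA_real_, n, nV); vL <- matrix(NA_integer_, n, nV)
  for (g in seq_len(nV)) {
    r <- .scoreGene(seqs, ref$v$seq[g], "left", v_min_len)
    vS[, g] <- r$score; vO[, g] <- r$offset; vI[, g] <- r$ident
    vL[, g] <- r$len
  }
  vS[!is.na(vI) & vI < v_min_ident] <- NA
  # read positions covered by the best V alignment are off limits for J
  # extension (junction partitioning)
  vbestIdx <- rep(NA_integer_, n)
  okV <- which(apply(!is.na(vS), 1, any))
  if (length(okV))
    vbestIdx[okV] <- apply(vS[okV, , drop = FALSE], 1, which.max)
  bound <- ifelse(is.na(vbestIdx), 0L,
                  vO[cbind(seq_len(n), vbestIdx)] +
                    vL[cbind(seq_len(n), vbestIdx)] - 1L)
  bound[is.na(bound)] <- 0L
  jS <- matrix(NA_real_, n, nJ); jO <- matrix(NA_integer_, n, nJ)
  for (g in seq_len(nJ)) {
    r <- .scoreGene(seqs, ref$j$seq[g], "right", j_min_len, bound = bound)
    jS[, g] <- r$score; jO[, g] <- r$offset
  }
  pickCalls <- function(S, namesv) {
    best <- suppressWarnings(apply(S, 1, max, na.rm = TRUE))
    best[!is.finite(best)] <- NA
    bi <- rep(NA_integer_, n)
    call <- rep(NA_character_, n)
    okRow <- which(!is.na(best))
    if (length(okRow)) {
      inSet <- !is.na(S[okRow, , drop = FALSE]) &
        S[okRow, , drop = FALSE] > best[okRow] - tie_margin
      call[okRow] <- apply(inSet, 1, function(z) paste(namesv[z], collapse = ","))
      bi[okRow] <- apply(S[okRow, , drop = FALSE], 1, which.max)
    }
    list(best = bi, call = call)
  }
  pv <- pickCalls(vS, ref$v$name)
  pj <- pickCalls(jS, ref$j$name)
  p104 <- ifelse(is.na(pv$best), NA_integer_,
                 vO[cbind(seq_len(n), pv$best)] + ref$v$anchor[pv$best] - 1L)
  p118 <- ifelse(is.na(pj$best), NA_integer_,
                 jO[cbind(seq_len(n), pj$best)] + ref$j$anchor[pj$best] - 1L)
  data.frame(
    v_call = pv$call, j_call = pj$call,
    v_best = ref$v$name[pv$best], j_best = ref$j$name[pj$best],
    v_identity = ifelse(is.na(pv$best), NA_real_,
                        vI[cbind(seq_len(n), pv$best)]),
    p104 = p104, p118 = p118,
    v_unit = ref$v$unit[pv$best], j_unit = ref$j$unit[pj$best],
    unassigned = is.na(pv$call) | is.na(pj$call),
    stringsAsFactors = FALSE)
}

# best-effort D labelling: longest exact contiguous D substring (>= 5 nt)
# inside the junction
.labelD <- function(junctions, dref, min_match = 5L) {
  out <- rep(NA_character_, length(junctions))
  if (is.null(dref) || !nrow(dref)) return(out)
  js <- Biostrings::DNAStringSet(ifelse(is.na(junctions) | junctions == "",
                                        "N", junctions))
  cand <- seq_along(junctions)
  lens <- sort(unique(unlist(lapply(nchar(dref$seq), function(L)
    seq(L, min_match)))), decreasing = TRUE)
  for (l in lens) {
    if (!length(cand)) break
    for (g in seq_len(nrow(dref))) {
      Ld <- nchar(dref$seq[g])
      if (l > Ld) next
      for (s in seq_len(Ld - l + 1L)) {
        pat <- substr(dref$seq[g], s, s + l - 1L)
        hits <- Biostrings::vcountPattern(pat, js[cand]) > 0
        if (any(hits)) {
          out[cand[hits]] <- dref$name[g]
          cand <- cand[!hits]
          if (!length(cand)) break
        }
      }
      if (!length(cand)) break
    }
  }
  out
}

#' Extract junctions and productivity
#'
#' The junction spans the 2nd-CYS codon 104 through the J-PHE/J-TRP codon
#' 118, both inclusive; the CDR3 is the junction minus the two anchor
#' codons. A rearrangement is productive when the junction length is a
#' multiple of 3, its translation is stop-free, and both anchors (C at
#' 104, F/W at 118) are present.
#'
#' @param seqs merged read sequences (character).
#' @param assign data.frame from [assignGenes()].
#' @return data.frame with junction, junction_aa, cdr3, productive.
#' @export
extractJunction <- function(seqs, assign) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  ok <- !assign$unassigned & !is.na(assign$p104) & !is.na(assign$p118) &
    assign$p104 >= 1L & assign$p118 + 2L <= lens & assign$p104 < assign$p118
  junction <- rep(NA_character_, n)
  junction[ok] <- substr(seqs[ok], assign$p104[ok], assign$p118[ok] + 2L)
  jlen <- nchar(junction)
  inframe <- ok & jlen %% 3L == 0L & jlen >= 6L
  aa <- rep(NA_character_, n)
  if (any(inframe)) {
    aa[inframe] <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(junction[inframe]), if.fuzzy.codon = "X")))
  }
  productive <- inframe & !is.na(aa) & !grepl("\\*", aa) &
    substr(aa, 1, 1) == "C" &
    substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
  cdr3 <- ifelse(is.na(junction), NA_character_,
                 substr(junction, 4L, jlen - 3L))
  data.frame(junction = junction, junction_aa = aa, cdr3 = cdr3,
             productive = ifelse(ok, productive, NA), stringsAsFactors = FALSE)
}

#' Run the expressed-repertoire pipeline on paired reads
#'
#' Quality-trims both mates, merges pairs, assigns V/J (and best-effort
#' D) genes and extracts junctions, returning an AIRR-style rearrangement
#' data.frame.
#'
#' @param r1,r2 QualityScaledDNAStringSet mates.
#' @param ref reference list from [referenceTable()].
#' @param locus locus label for the output.
#' @param sample_id per-pair sample labels (default: read-name prefix
#'   before the first underscore).
#' @param trim_quality,trim_window,min_len trimming parameters (set
#'   \code{trim_quality = 0} to skip).
#' @param min_overlap,max_mm merging parameters.
#' @param ... passed to [assignGenes()].
#' @return AIRR rearrangement data.frame (one row per merged, assigned or
#'   not, read pair).
#' @export
runRepertoire <- function(r1, r2, ref, locus = "TRG", sample_id = NULL,
                          trim_quality = 30, trim_window = 4L,
                          min_len = 50L, min_overlap = 20L, max_mm = 5L,
                          ...) {
  stem <- function(x) sub("/[12]$", "", names(x))
  if (trim_quality > 0) {
    t1 <- slidingWindowTrim(r1, trim_window, trim_quality, min_len)
    t2 <- slidingWindowTrim(r2, trim_window, trim_quality, min_len)
    common <- intersect(stem(t1), stem(t2))
    t1 <- t1[match(common, stem(t1))]
    t2 <- t2[match(common, stem(t2))]
  } else { t1 <- r1; t2 <- r2 }
  mg <- mergePairs(t1, t2, min_overlap, max_mm)
  seqs <- as.character(mg$merged)
  ids <- names(mg$merged)
  if (!length(seqs)) {
    return(data.frame(sequence_id = character(0), locus = character(0),
      v_call = character(0), d_call = character(0), j_call = character(0),
      junction = character(0), junction_aa = character(0),
      cdr3 = character(0), productive = logical(0),
      v_cassette = integer(0), j_cassette = integer(0),
      sample_id = character(0), sequence = character(0),
      stringsAsFactors = FALSE))
  }
  asg <- assignGenes(seqs, ref, ...)
  jx <- extractJunction(seqs, asg)
  d_call <- .labelD(jx$junction, ref$d)
  if (is.null(sample_id)) sample_id <- sub("_.*", "", ids)
  data.frame(sequence_id = ids, locus = locus,
             v_call = asg$v_call, d_call = d_call, j_call = asg$j_call,
             junction = jx$junction, junction_aa = jx$junction_aa,
             cdr3 = jx$cdr3, productive = jx$productive,
             v_cassette = asg$v_unit, j_cassette = asg$j_unit,
             sample_id = sample_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Per-sample gene usage with cross-sample summary
#'
#' Computes, per sample, the frequency of each gene (or subgroup) among
#' assigned rearrangements of one locus. Ambiguous calls contribute 1/k
#' to each member of the ambiguity set (or, with
#' \code{combine_ambiguous}, the comma-joined set is kept as its own
#' category). Frequencies sum to 1 per sample. The cross-sample summary
#' reports median and quartiles (linear interpolation) and flags values
#' beyond 1.5 IQR from the quartiles as outliers.
#'
#' @param df AIRR rearrangement data.frame (needs v_call/j_call,
#'   sample_id).
#' @param which "v" or "j".
#' @param by "gene" or "subgroup" (subgroup = gene name minus its member
#'   suffix).
#' @param combine_ambiguous keep ambiguity sets as combined categories.
#' @return list with \code{per_sample} (genes x samples frequency
#'   matrix) and \code{summary} (data.frame gene, median, q1, q3,
#'   n_outliers), frequencies in percent.
#' @export
usageStats <- function(df, which = c("v", "j"), by = c("gene", "subgroup"),
                       combine_ambiguous = FALSE) {
  which <- match.arg(which); by <- match.arg(by)
  calls <- df[[paste0(which, "_call")]]
  keep <- !is.na(calls) & calls != ""
  calls <- calls[keep]; samp <- as.character(df$sample_id)[keep]
  if (!length(calls)) stop("no assigned rearrangements")
  if (combine_ambiguous) {
    genes <- calls; w <- rep(1, length(calls)); sam <- samp
  } else {
    parts <- strsplit(calls, ",", fixed = TRUE)
    k <- lengths(parts)
    genes <- unlist(parts)
    w <- rep(1 / k, k)
    sam <- rep(samp, k)
  }
  if (by == "subgroup") genes <- sub("-[0-9]+$", "", genes)
  agg <- tapply(w, list(gene = genes, sample = sam), sum, default = 0)
  freq <- sweep(agg, 2, colSums(agg), "/") * 100
  summ <- t(apply(freq, 1, function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
    iqr <- q[3] - q[1]
    c(median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
      n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr))
  }))
  list(per_sample = freq,
       summary = data.frame(gene = rownames(freq), summ,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' V x J pairing matrix with cassette summary
#'
#' Fractionally counts every V/J pairing (ambiguity sets split 1/k per
#' axis), ordered by chromosomal gene order from the locus map. For
#' cassette loci the pairings are classified intra- vs inter-cassette via
#' the map's unit indices; for nested TRA/TRD output each pairing is also
#' labelled by the J gene's locus. Calls absent from the map are counted
#' under "unmapped".
#'
#' @param df AIRR rearrangement data.frame.
#' @param gset locus map \linkS4class{GermlineSet} (or [referenceTable()]
#'   list).
#' @return list: \code{matrix} (V x J fractional counts),
#'   \code{intra_fraction} (fraction of unit-attributable pairings with
#'   matching cassette), \code{by_j_locus} (pair counts by the J gene's
#'   locus prefix).
#' @export
pairingMatrix <- function(df, gset) {
  ref <- if (is(gset, "GermlineSet")) referenceTable(gset) else gset
  keep <- !is.na(df$v_call) & !is.na(df$j_call)
  vparts <- strsplit(df$v_call[keep], ",", fixed = TRUE)
  jparts <- strsplit(df$j_call[keep], ",", fixed = TRUE)
  kv <- lengths(vparts); kj <- lengths(jparts)
  idx <- rep(seq_along(vparts), kv * kj)
  vg <- unlist(lapply(seq_along(vparts), function(i)
    rep(vparts[[i]], each = kj[i])))
  jg <- unlist(lapply(seq_along(jparts), function(i)
    rep(jparts[[i]], times = kv[i])))
  w <- 1 / (kv * kj)[idx]
  vlev <- c(ref$v$name, "unmapped"); jlev <- c(ref$j$name, "unmapped")
  vg[!vg %in% ref$v$name] <- "unmapped"
  jg[!jg %in% ref$j$name] <- "unmapped"
  m <- tapply(w, list(factor(vg, vlev), factor(jg, jlev)), sum, default = 0)
  vu <- ref$v$unit[match(vg, ref$v$name)]
  ju <- ref$j$unit[match(jg, ref$j$name)]
  att <- !is.na(vu) & !is.na(ju)
  intra <- if (any(att)) sum(w[att & vu == ju], na.rm = TRUE) / sum(w[att])
           else NA_real_
  jloc <- sub("J.*", "", jg)
  byloc <- tapply(w, jloc, sum)
  list(matrix = m, intra_fraction = intra, by_j_locus = byloc)
}
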