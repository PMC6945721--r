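#' Train a position-specific gene-discovery profile
#'
#' Builds a log-odds profile over the positions of an (implicitly aligned,
#' equal-length) germline gene set; candidate segments in a locus scan are
#' scored against it. Sequences deviating from the modal length (e.g.
#' frameshifted pseudogenes in a mixed training set) are dropped. The
#' acceptance threshold is the mean of the training sequences' self-scores
#' minus three standard deviations; a lower "relic" bound (20\% of the
#' mean self-score) still admits heavily degenerate pseudogene candidates,
#' which are then flagged DEGENERATE.
#'
#' @param seqs DNAStringSet or character vector of germline genes.
#' @param pseudocount smoothing added per base and position.
#' @return A \linkS4class{GeneProfile}.
#' @export
trainGeneProfile <- function(seqs, pseudocount = 0.5) {
  s <- toupper(as.character(seqs))
  if (!length(s)) stop("no training sequences")
  lens <- nchar(s)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  s <- s[lens == modal]
  n <- length(s)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(s))
  counts <- matrix(0, 4, modal, dimnames = list(DNA_BASES, NULL))
  common <- intersect(rownames(cm), DNA_BASES)
  counts[common, ] <- cm[common, , drop = FALSE]
  freqs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(freqs / 0.25)
  lo <- rbind(lo, OTHER = rep(min(lo) - 1, modal))
  cons <- DNA_BASES[apply(counts, 2, which.max)]
  self <- vapply(s, function(x) {
    si <- .seq2int(x)
    sum(lo[cbind(si, seq_len(modal))])
  }, numeric(1), USE.NAMES = FALSE)
  thr <- if (n > 1 && sd(self) > 0) mean(self) - 3 * sd(self) else mean(self) - 3
  new("GeneProfile", logodds = lo,
      consensus = Biostrings::DNAString(paste(cons, collapse = "")),
      threshold = thr, relic = min(0.2 * mean(self), thr))
}

# score the subject of a consensus-anchored alignment position by position
.profileScoreAln <- function(aln, lo) {
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  j <- 0L; sc <- 0
  # indels must earn their keep: twice the worst substitution score
  gapPen <- 2 * (min(lo) - 1)
  for (k in seq_along(pa)) {
    if (pa[k] == "-") { sc <- sc + gapPen; next }  # subject insertion
    j <- j + 1L
    sc <- sc + if (sa[k] == "-") gapPen else lo[.seq2int(sa[k]), j]
  }
  sc
}

# best ungapped score allowing at most one indel, gene anchored at its
# left end (position 1 aligns to profile column 1); g is the integer-coded
# candidate region of length L-1, L or L+1
.indel1Score <- function(g, lo) {
  L <- ncol(lo)
  n <- length(g)
  if (n == L) return(sum(lo[cbind(g, seq_len(L))]))
  if (n == L - 1L) {          # one deletion in the gene
    pre <- lo[cbind(g, seq_len(n))]
    post <- lo[cbind(g, seq_len(n) + 1L)]
    cpost <- rev(cumsum(rev(post)))
    return(max(cumsum(c(0, pre[-n]))[seq_len(n)] + cpost,
               sum(pre)))
  }
  if (n == L + 1L) {          # one insertion in the gene
    pre <- c(lo[cbind(g[seq_len(L)], seq_len(L))], 0)
    post <- c(0, lo[cbind(g[2:n], seq_len(L))])
    cpre <- cumsum(c(0, pre))[seq_len(n)]          # consume gene 1..j
    cpost <- rev(cumsum(rev(post)))                # consume gene j+2..n
    return(max(cpre + c(cpost[-1], 0)))
  }
  stop("candidate length must be within 1 of the profile length")
}

# quick gate before full alignment: best of the no-indel and 1-indel
# ungapped placements of the profile over a candidate region
.prescreen <- function(si, lo, from, to, anchored) {
  L <- ncol(lo)
  if (anchored == "right") {
    lo <- lo[, rev(seq_len(L)), drop = FALSE]
    slice <- function(a, b) rev(si[max(1L, a):min(length(si), b)])
    g0 <- slice(to - L + 1L, to)
    gD <- slice(to - L + 2L, to)
    gI <- slice(to - L, to)
  } else {
    slice <- function(a, b) si[max(1L, a):min(length(si), b)]
    g0 <- slice(from, from + L - 1L)
    gD <- slice(from, from + L - 2L)
    gI <- slice(from, from + L)
  }
  sc <- -Inf
  if (length(g0) == L) sc <- max(sc, .indel1Score(g0, lo))
  if (length(gD) == L - 1L) sc <- max(sc, .indel1Score(gD, lo))
  if (length(gI) == L + 1L) sc <- max(sc, .indel1Score(gI, lo))
  sc
}

.alnParams <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 2,
         mismatch = -1, baseOnly = FALSE),
       gapOpening = 6, gapExtension = 2)
}

.emptyGeneDf <- function() {
  data.frame(name = character(0), gene_type = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

# drop candidates overlapping a better-scoring one on the same strand
.dedupCandidates <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  ir <- IRanges::IRanges(df$start, df$end)
  ov <- IRanges::findOverlaps(ir, minoverlap = 10L)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  for (k in seq_along(ov)) {
    q <- S4Vectors::queryHits(ov)[k]; s <- S4Vectors::subjectHits(ov)[k]
    if (keep[q] && df$strand[q] == df$strand[s]) keep[s] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Scan a locus for V genes
#'
#' A V candidate is a segment scoring above the profile threshold that is
#' immediately followed (3', coding strand) by a recombination signal with
#' the configured V spacer. Both strands are scanned. Each candidate is
#' aligned to the profile consensus (to expose indels), translated,
#' IMGT-numbered, and annotated with its defect list: STOP_CODON,
#' FRAMESHIFT (net indel not a multiple of 3), MISSING_ANCHOR (any of
#' C23/W41/hydrophobic-89/C104 absent), NONCANONICAL_RS (heptamer not
#' starting CAC) and DEGENERATE (score between the relic bound and the
#' threshold).
#'
#' @param locus DNAString or character locus sequence.
#' @param profile \linkS4class{GeneProfile} trained on germline V genes.
#' @param spacer_len V-RS spacer (default 23).
#' @param rs_min minimum RS log-odds score to seed a candidate.
#' @param pwm optional RS PWM pair for [detectRS()].
#' @return data.frame of candidate V rows (GermlineSet schema).
#' @export
scanVGenes <- function(locus, profile, spacer_len = 23L, rs_min = -5,
                       pwm = NULL) {
  locus <- as.character(locus)
  Lc <- nchar(locus)
  L <- ncol(profile@logodds)
  ap <- .alnParams()
  out <- list()
  gate <- min(profile@relic, profile@threshold) - 12
  for (strand in c("+", "-")) {
    seqc <- if (strand == "+") locus else .rc(locus)
    si <- .seq2int(seqc)
    hits <- detectRS(seqc, "3p", spacer_len, pwm = pwm, min_score = rs_min)
    for (h in seq_len(nrow(hits))) {
      p <- hits$start[h]
      if (p - 1L < 30L) next
      if (.prescreen(si, profile@logodds, NA, p - 1L, "right") < gate) next
      ws <- max(1L, p - L - 8L)
      window <- substr(seqc, ws, p - 1L)
      aln <- Biostrings::pairwiseAlignment(profile@consensus, window,
        type = "global-local", substitutionMatrix = ap$mat,
        gapOpening = ap$gapOpening, gapExtension = ap$gapExtension)
      gs <- ws + Biostrings::start(Biostrings::subject(aln)) - 1L
      ge <- ws + Biostrings::end(Biostrings::subject(aln)) - 1L
      sc <- .profileScoreAln(aln, profile@logodds)
      # prefer the exact RS-abutting, indel-free placement when it scores
      # at least as well (guards against spurious alignment indels)
      if (p - L >= 1L) {
        sc0 <- sum(profile@logodds[cbind(si[(p - L):(p - 1L)], seq_len(L))])
        if (sc0 >= sc) { gs <- p - L; ge <- p - 1L; sc <- sc0 }
      }
      gene_nt <- substr(seqc, gs, ge)
      if (sc < profile@relic) next
      defects <- character(0)
      degen <- sc < profile@threshold
      net <- (ge - gs + 1L) - L
      anchor104 <- NA_integer_
      if (net %% 3L != 0L) {
        defects <- c(defects, "FRAMESHIFT")
      } else if (!degen) {
        aa <- .tx(gene_nt)
        if (grepl("\\*", aa)) {
          defects <- c(defects, "STOP_CODON")
        } else {
          nb <- numberVRegion(aa)
          if (!nb@ok || !all(nb@anchors)) defects <- c(defects, "MISSING_ANCHOR")
          if (nb@ok) {
            i104 <- which(nb@positions == 104L)
            if (length(i104)) anchor104 <- (i104 - 1L) * 3L + 1L
          }
        }
      }
      if (degen) defects <- c(defects, "DEGENERATE")
      if (substr(hits$heptamer[h], 1, 3) != "CAC")
        defects <- c(defects, "NONCANONICAL_RS")
      if (strand == "+") { fs <- gs; fe <- ge } else {
        fs <- Lc - ge + 1L; fe <- Lc - gs + 1L
      }
      out[[length(out) + 1L]] <- c(
        list(name = NA_character_, gene_type = "V", start = fs, end = fe,
             strand = strand, subgroup = NA_character_,
             defects = list(defects), nt = gene_nt, score = sc,
             unit = NA_integer_, anchor104 = anchor104,
             anchor118 = NA_integer_),
        .rsFields("rs3", hits$heptamer[h], hits$spacer[h], hits$nonamer[h]))
    }
  }
  if (!length(out)) return(.emptyGeneDf())
  .dedupCandidates(.rowsToDf(out))
}

#' Scan a locus for J genes
#'
#' A J candidate is a segment immediately preceded (5') by a
#' recombination signal with the configured J spacer, containing an
#' FGXG-compatible reading frame (the J-PHE/J-TRP 118 anchor) and ending
#' at a GT splice-donor site. Defects are recorded as for V genes;
#' a missing GT donor yields MISSING_SPLICE, a missing FGXG motif
#' MISSING_ANCHOR.
#'
#' @inheritParams scanVGenes
#' @param spacer_len J-RS spacer (default 12).
#' @return data.frame of candidate J rows.
#' @export
scanJGenes <- function(locus, profile, spacer_len = 12L, rs_min = -5,
                       pwm = NULL) {
  locus <- as.character(locus)
  Lc <- nchar(locus)
  L <- ncol(profile@logodds)
  ap <- .alnParams()
  out <- list()
  gate <- min(profile@relic, profile@threshold) - 12
  for (strand in c("+", "-")) {
    seqc <- if (strand == "+") locus else .rc(locus)
    si <- .seq2int(seqc)
    hits <- detectRS(seqc, "5p", spacer_len, pwm = pwm, min_score = rs_min)
    for (h in seq_len(nrow(hits))) {
      gstart <- hits$end[h] + 1L
      if (gstart + 20L > nchar(seqc)) next
      if (.prescreen(si, profile@logodds, gstart, NA, "left") < gate) next
      window <- substr(seqc, gstart, min(nchar(seqc), gstart + L + 7L))
      aln <- Biostrings::pairwiseAlignment(profile@consensus, window,
        type = "global-local", substitutionMatrix = ap$mat,
        gapOpening = ap$gapOpening, gapExtension = ap$gapExtension)
      gs <- gstart + Biostrings::start(Biostrings::subject(aln)) - 1L
      ge <- gstart + Biostrings::end(Biostrings::subject(aln)) - 1L
      sc <- .profileScoreAln(aln, profile@logodds)
      # placement choice includes the GT donor evidence: the J 3' end is
      # pinned by its splice site, so an RS-abutting end followed by GT
      # outranks an indel-bearing alignment of similar profile score
      donor <- function(e) 8 * (substr(seqc, e + 1L, e + 2L) == "GT")
      pen <- 2 * (min(profile@logodds) - 1)
      best <- sc + donor(ge)
      for (len in c(L - 1L, L, L + 1L)) {
        e <- gstart + len - 1L
        if (e > nchar(seqc)) next
        s <- .indel1Score(si[gstart:e], profile@logodds) +
          (len != L) * pen
        if (s + donor(e) > best) {
          gs <- gstart; ge <- e; sc <- s; best <- s + donor(e)
        }
      }
      gene_nt <- substr(seqc, gs, ge)
      if (sc < profile@relic) next
      defects <- character(0)
      if (sc < profile@threshold) defects <- c(defects, "DEGENERATE")
      if (substr(seqc, ge + 1L, ge + 2L) != "GT")
        defects <- c(defects, "MISSING_SPLICE")
      anchor118 <- NA_integer_
      for (f in 1:3) {
        aa <- .tx(substr(gene_nt, f, nchar(gene_nt)))
        m <- regexpr("FG.G", aa)
        if (m > 0) { anchor118 <- (m - 1L) * 3L + f; break }
      }
      if (is.na(anchor118)) defects <- c(defects, "MISSING_ANCHOR")
      net <- (ge - gs + 1L) - L
      if (net %% 3L != 0L) {
        defects <- c(defects, "FRAMESHIFT")
      } else if (!is.na(anchor118)) {
        f0 <- (anchor118 - 1L) %% 3L + 1L
        if (grepl("\\*", .tx(substr(gene_nt, f0, nchar(gene_nt)))))
          defects <- c(defects, "STOP_CODON")
      }
      if (substr(hits$heptamer[h], 1, 3) != "CAC")
        defects <- c(defects, "NONCANONICAL_RS")
      if (strand == "+") { fs <- gs; fe <- ge } else {
        fs <- Lc - ge + 1L; fe <- Lc - gs + 1L
      }
      out[[length(out) + 1L]] <- c(
        list(name = NA_character_, gene_type = "J", start = fs, end = fe,
             strand = strand, subgroup = NA_character_,
             defects = list(defects), nt = gene_nt, score = sc,
             unit = NA_integer_, anchor104 = NA_integer_,
             anchor118 = anchor118),
        .rsFields("rs5", hits$heptamer[h], hits$spacer[h], hits$nonamer[h]))
    }
  }
  if (!length(out)) return(.emptyGeneDf())
  .dedupCandidates(.rowsToDf(out))
}

#' Scan a locus for D genes
#'
#' A D candidate is a short (8-25 nt) segment flanked by a 5'
#' recombination signal and a 3' recombination signal whose spacer
#' lengths satisfy the configured 12/23 pairing. Both signals are stored
#' with the gene. Segments with only one flanking RS are not reported.
#'
#' @inheritParams scanVGenes
#' @param spacer5,spacer3 spacer lengths of the 5' and 3' RS (defaults
#'   12 and 23).
#' @param min_len,max_len D segment length bounds.
#' @return data.frame of candidate D rows.
#' @export
scanDGenes <- function(locus, spacer5 = 12L, spacer3 = 23L, rs_min = 5,
                       min_len = 8L, max_len = 25L, pwm = NULL) {
  locus <- as.character(locus)
  Lc <- nchar(locus)
  out <- list()
  for (strand in c("+", "-")) {
    seqc <- if (strand == "+") locus else .rc(locus)
    h5 <- detectRS(seqc, "5p", spacer5, pwm = pwm, min_score = rs_min)
    h3 <- detectRS(seqc, "3p", spacer3, pwm = pwm, min_score = rs_min)
    for (i in seq_len(nrow(h5))) for (j in seq_len(nrow(h3))) {
      gs <- h5$end[i] + 1L; ge <- h3$start[j] - 1L
      w <- ge - gs + 1L
      if (w < min_len || w > max_len) next
      defects <- character(0)
      if (substr(h5$heptamer[i], 1, 3) != "CAC" ||
          substr(h3$heptamer[j], 1, 3) != "CAC")
        defects <- c(defects, "NONCANONICAL_RS")
      if (strand == "+") { fs <- gs; fe <- ge } else {
        fs <- Lc - ge + 1L; fe <- Lc - gs + 1L
      }
      out[[length(out) + 1L]] <- c(
        list(name = NA_character_, gene_type = "D", start = fs, end = fe,
             strand = strand, subgroup = NA_character_,
             defects = list(defects), nt = substr(seqc, gs, ge),
             score = h5$score[i] + h3$score[j], unit = NA_integer_,
             anchor104 = NA_integer_, anchor118 = NA_integer_),
        .rsFields("rs5", h5$heptamer[i], h5$spacer[i], h5$nonamer[i]),
        .rsFields("rs3", h3$heptamer[j], h3$spacer[j], h3$nonamer[j]))
    }
  }
  if (!length(out)) return(.emptyGeneDf())
  .dedupCandidates(.rowsToDf(out))
}

#' Scan a locus for C genes by exon similarity
#'
#' Locates each reference exon by approximate matching (substitutions and
#' indels allowed), groups consecutive exon hits into genes, and checks
#' canonical GT/AG intron boundaries. A net exon-length shift that is not
#' a multiple of 3 is a FRAMESHIFT; an in-frame stop in the concatenated
#' exons is a STOP_CODON; a missing GT/AG boundary is MISSING_SPLICE.
#'
#' @param locus DNAString or character.
#' @param c_refs reference exon sets: a character vector of exon
#'   sequences (one C gene), or a named list of such vectors.
#' @param max_mismatch_frac tolerated per-exon edit fraction.
#' @param max_intron maximum intron length when grouping exon hits.
#' @return data.frame of candidate C rows with exon structure.
#' @export
scanCGenes <- function(locus, c_refs, max_mismatch_frac = 0.15,
                       max_intron = 2000L) {
  locus <- as.character(locus)
  Lc <- nchar(locus)
  if (!is.list(c_refs)) c_refs <- list(C = c_refs)
  out <- list()
  for (strand in c("+", "-")) {
    seqc <- if (strand == "+") locus else .rc(locus)
    sub <- Biostrings::DNAString(seqc)
    for (rname in names(c_refs)) {
      exons <- toupper(as.character(c_refs[[rname]]))
      hits <- list()
      for (e in seq_along(exons)) {
        w <- nchar(exons[e])
        mm <- max(2L, floor(max_mismatch_frac * w))
        # substitution-only hits keep exact exon widths; indel matching
        # additionally finds frameshifted copies elsewhere in the locus
        m1 <- Biostrings::matchPattern(exons[e], sub, max.mismatch = mm)
        m2 <- Biostrings::matchPattern(exons[e], sub, max.mismatch = mm,
                                       with.indels = TRUE)
        r1 <- IRanges::IRanges(Biostrings::start(m1), Biostrings::end(m1))
        r2 <- IRanges::IRanges(Biostrings::start(m2), Biostrings::end(m2))
        novel <- which(!IRanges::overlapsAny(r2, r1))
        if (length(novel)) {
          # edit-distance matching can trim mismatching terminal bases;
          # re-anchor indel hits by aligning the reference exon locally
          ap <- .alnParams()
          ref <- Biostrings::DNAString(exons[e])
          for (k in seq_along(novel)) {
            hs <- IRanges::start(r2)[novel[k]]; he <- IRanges::end(r2)[novel[k]]
            ws <- max(1L, hs - 6L); we <- min(nchar(seqc), he + 6L)
            aln <- Biostrings::pairwiseAlignment(ref,
              Biostrings::DNAString(substr(seqc, ws, we)),
              type = "global-local", substitutionMatrix = ap$mat,
              gapOpening = ap$gapOpening, gapExtension = ap$gapExtension)
            IRanges::start(r2)[novel[k]] <-
              ws + Biostrings::start(Biostrings::subject(aln)) - 1L
            IRanges::end(r2)[novel[k]] <-
              ws + Biostrings::end(Biostrings::subject(aln)) - 1L
          }
        }
        m <- c(r1, r2[novel])
        if (length(m))
          hits[[length(hits) + 1L]] <- data.frame(
            exon = e, start = Biostrings::start(m), end = Biostrings::end(m))
      }
      if (!length(hits)) next
      hits <- do.call(rbind, hits)
      hits <- hits[order(hits$start), , drop = FALSE]
      # group into genes: exon indices must increase within a group
      grp <- integer(nrow(hits)); cur <- 0L; lastExon <- Inf; lastEnd <- -Inf
      for (i in seq_len(nrow(hits))) {
        if (hits$exon[i] <= lastExon || hits$start[i] - lastEnd > max_intron)
          cur <- cur + 1L
        grp[i] <- cur; lastExon <- hits$exon[i]; lastEnd <- hits$end[i]
      }
      for (g in unique(grp)) {
        hg <- hits[grp == g, , drop = FALSE]
        if (nrow(hg) != length(exons)) next
        defects <- character(0)
        for (i in seq_len(nrow(hg) - 1L)) {
          if (substr(seqc, hg$end[i] + 1L, hg$end[i] + 2L) != "GT" ||
              substr(seqc, hg$start[i + 1L] - 2L, hg$start[i + 1L] - 1L) != "AG") {
            defects <- c(defects, "MISSING_SPLICE"); break
          }
        }
        cnt <- paste(substring(seqc, hg$start, hg$end), collapse = "")
        net <- nchar(cnt) - sum(nchar(exons))
        if (net %% 3L != 0L) {
          defects <- c(defects, "FRAMESHIFT")
        } else if (grepl("\\*", .tx(cnt))) {
          defects <- c(defects, "STOP_CODON")
        }
        if (strand == "+") {
          fs <- hg$start[1]; fe <- hg$end[nrow(hg)]
          es <- hg$start; ee <- hg$end
        } else {
          fs <- Lc - hg$end[nrow(hg)] + 1L; fe <- Lc - hg$start[1] + 1L
          es <- rev(Lc - hg$end + 1L); ee <- rev(Lc - hg$start + 1L)
        }
        out[[length(out) + 1L]] <- list(
          name = NA_character_, gene_type = "C", start = fs, end = fe,
          strand = strand, subgroup = NA_character_,
          defects = list(unique(defects)), nt = cnt, score = NA_real_,
          unit = NA_integer_, anchor104 = NA_integer_,
          anchor118 = NA_integer_,
          exon_starts = list(as.integer(es)), exon_ends = list(as.integer(ee)))
      }
    }
  }
  if (!length(out)) return(.emptyGeneDf())
  df <- .rowsToDf(out)
  df$score[is.na(df$score)] <- 0
  .dedupCandidates(df)
}

#' Assemble the ordered locus map
#'
#' Sorts genes by locus coordinate and assigns structural units: for TRG,
#' cassette indices (a cassette is a V-J-(J)-C unit; the index advances
#' after each C gene, so a trailing unit without C is an incomplete
#' cassette); for TRB/TRD-style loci, D-J-C cluster indices (a new
#' cluster opens at each D gene, or at a J following a closed cluster);
#' V genes outside cassette loci carry no unit. Genes that cannot be
#' attributed to a unit trigger a warning and keep unit NA.
#'
#' @param gset a \linkS4class{GermlineSet} (units are recomputed).
#' @return the GermlineSet with genes sorted and \code{unit} filled.
#' @export
buildLocusMap <- function(gset) {
  g <- gset@genes
  if (!length(g)) return(gset)
  ord <- order(GenomicRanges::start(g))
  g <- g[ord]
  mc <- S4Vectors::mcols(g)
  unit <- rep(NA_integer_, length(g))
  if (gset@locusId == "TRG") {
    cur <- 1L
    for (i in seq_along(g)) {
      unit[i] <- cur
      if (mc$gene_type[i] == "C") cur <- cur + 1L
    }
  } else {
    cur <- 0L; open <- FALSE
    for (i in seq_along(g)) {
      t <- mc$gene_type[i]
      if (t == "V") next
      if (t == "D") { cur <- cur + 1L; open <- TRUE }
      if (t == "J" && !open) { cur <- cur + 1L; open <- TRUE }
      if (cur == 0L) {
        warning("gene ", mc$name[i], " not attributable to a unit")
        next
      }
      unit[i] <- cur
      if (t == "C") open <- FALSE
    }
  }
  mc$unit <- unit
  S4Vectors::mcols(g) <- mc
  initialize(gset, genes = g)
}

#' Name genes from subgroups and locus structure
#'
#' V genes are clustered into subgroups ([assignSubgroups()]) and named
#' \code{<locus>V<subgroup>(-<member>)}; DEGENERATE relic V genes stay
#' outside numeric subgroups and receive letter names (\code{<locus>VA},
#' \code{VB}, ...). J and C (and D) genes are named by their cassette or
#' cluster: \code{J<unit>-<index>}, \code{C<unit>}, \code{D<unit>}.
#'
#' @param gset a \linkS4class{GermlineSet} with units assigned.
#' @param identity_threshold subgroup percent-identity cut-off.
#' @return the GermlineSet with \code{name} and \code{subgroup} filled.
#' @export
nameGenes <- function(gset, identity_threshold = 75) {
  mc <- S4Vectors::mcols(gset@genes)
  pre <- sub("/.*", "", gset@locusId)
  isV <- mc$gene_type == "V"
  degen <- isV & vapply(mc$defects, function(d) "DEGENERATE" %in% d, logical(1))
  core <- which(isV & !degen)
  if (length(core)) {
    sg <- assignSubgroups(setNames(mc$nt[core], seq_along(core)),
                          threshold = identity_threshold,
                          starts = GenomicRanges::start(gset@genes)[core],
                          prefix = paste0(pre, "V"))
    ord <- as.integer(sg$name)
    mc$name[core[ord]] <- sg$gene_name
    mc$subgroup[core[ord]] <- paste0(pre, "V", sg$subgroup)
  }
  if (any(degen)) {
    dd <- which(degen)[order(GenomicRanges::start(gset@genes)[degen])]
    mc$name[dd] <- paste0(pre, "V", LETTERS[seq_along(dd)])
  }
  for (t in c("J", "C", "D")) {
    ix <- which(mc$gene_type == t)
    if (!length(ix)) next
    ix <- ix[order(GenomicRanges::start(gset@genes)[ix])]
    un <- mc$unit[ix]
    if (t == "J") {
      idx <- stats::ave(seq_along(ix), un, FUN = seq_along)
      mc$name[ix] <- paste0(pre, "J", ifelse(is.na(un), "x", un), "-", idx)
    } else {
      mc$name[ix] <- paste0(pre, t, ifelse(is.na(un), "", un))
    }
  }
  g <- gset@genes
  S4Vectors::mcols(g) <- mc
  initialize(gset, genes = g)
}

#' Annotate a TR locus end to end
#'
#' Runs the full germline discovery pipeline on a locus sequence: V and J
#' scanning against profiles trained from the provided germline
#' directory, D scanning (TRB/TRD-containing loci), C location by exon
#' similarity, locus-map assembly and subgroup-based naming.
#'
#' @param locus DNAString or character locus sequence.
#' @param germline list with elements \code{V} and \code{J} (DNAStringSet
#'   or character training sets) and optionally \code{C} (reference exon
#'   set(s) for [scanCGenes()]).
#' @param config a [runConfig()].
#' @return A \linkS4class{GermlineSet} of the discovered locus map.
#' @export
annotateLocus <- function(locus, germline, config = runConfig()) {
  locus <- as.character(locus)
  sp <- config$spacer_policy
  vdf <- scanVGenes(locus, trainGeneProfile(germline$V),
                    spacer_len = sp$v_3p)
  jdf <- scanJGenes(locus, trainGeneProfile(germline$J),
                    spacer_len = sp$j_5p)
  parts <- list(vdf, jdf)
  if (config$locus_id %in% c("TRB", "TRD", "TRA/TRD")) {
    parts <- c(parts, list(scanDGenes(locus, spacer5 = sp$d_5p,
                                      spacer3 = sp$d_3p)))
  }
  if (!is.null(germline$C)) {
    parts <- c(parts, list(scanCGenes(locus, germline$C)))
  }
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  df <- do.call(rbind, lapply(parts, .padGeneDf))
  gset <- GermlineSet(df, locus, config$locus_id)
  gset <- buildLocusMap(gset)
  nameGenes(gset, config$identity_threshold)
}

.padGeneDf <- function(df) {
  tmpl <- c("name", "gene_type", "start", "end", "strand", "subgroup",
            "nt", "score", "unit", "anchor104", "anchor118",
            paste0(rep(c("rs3", "rs5"), each = 5),
                   c("_heptamer", "_spacer", "_nonamer", "_score", "_canonical")))
  for (cn in tmpl) {
    if (is.null(df[[cn]])) {
      df[[cn]] <- if (cn %in% c("start", "end", "unit", "anchor104", "anchor118"))
        NA_integer_ else if (cn %in% c("score") || grepl("_score$", cn))
        NA_real_ else if (grepl("_canonical$", cn)) NA else NA_character_
    }
  }
  if (is.null(df$defects)) df$defects <- I(replicate(nrow(df), character(0), FALSE))
  if (is.null(df$exon_starts)) {
    df$exon_starts <- I(replicate(nrow(df), integer(0), FALSE))
    df$exon_ends <- I(replicate(nrow(df), integer(0), FALSE))
  }
  df[, c(tmpl, "defects", "exon_starts", "exon_ends")]
}
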