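#' Synthetic V(D)J locus and repertoire simulation
#'
#' The simulator builds ground-truth TR loci (cassette-organized TRG,
#' D-J-C-cluster TRB, nested TRA/TRD) with planted genes, recombination
#' signals and defects, and generates 5'RACE-style rearranged amplicons
#' with exonucleolytic trimming, TdT N-insertions and per-base sequencing
#' error, so that annotation and repertoire recovery can be tested against
#' known truth.
#'
#' @name vdj-simulation
NULL

.aaPool <- setdiff(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                     "P", "Q", "R", "S", "T", "V", "Y"), NULL)

#' Sample recombination-signal elements from the generating motif model
#'
#' Draws heptamers or nonamers position-independently from the reference
#' base frequencies (the generating distribution the RS profile module is
#' expected to recover). With \code{force_canonical} the crucial first
#' three heptamer nucleotides are pinned to CAC.
#'
#' @param n number of motifs.
#' @param element "HEPTAMER" or "NONAMER".
#' @param force_canonical pin heptamer positions 1-3 to C,A,C.
#' @return character vector of motifs.
#' @export
sampleRS <- function(n, element = c("HEPTAMER", "NONAMER"),
                     force_canonical = FALSE) {
  element <- match.arg(element)
  f <- .rsRefFreqs(element)
  m <- vapply(seq_len(ncol(f)), function(j)
    sample(DNA_BASES, n, replace = TRUE, prob = f[, j]), character(n))
  m <- matrix(m, nrow = n)
  if (force_canonical && element == "HEPTAMER") {
    m[, 1] <- "C"; m[, 2] <- "A"; m[, 3] <- "C"
  }
  .pasteRows(m)
}

#' @rdname sampleRS
#' @return \code{rsGeneratorFreqs}: the generating 4 x L frequency matrix.
#' @export
rsGeneratorFreqs <- function(element = c("HEPTAMER", "NONAMER")) {
  .rsRefFreqs(match.arg(element))
}

.rsScore <- function(hept, nona) {
  loH <- rsReferencePWM("HEPTAMER"); loN <- rsReferencePWM("NONAMER")
  vapply(seq_along(hept), function(i) {
    sum(loH[cbind(.seq2int(hept[i]), 1:7)]) +
      sum(loN[cbind(.seq2int(nona[i]), 1:9)])
  }, numeric(1))
}

# ---- gene factories -------------------------------------------------------

.makeVGene <- function(cdr1 = 8L, cdr2 = 8L) {
  fr1 <- sample(.aaPool, 26, replace = TRUE); fr1[23] <- "C"
  c1 <- sample(.aaPool, cdr1, replace = TRUE)
  fr2 <- sample(.aaPool, 17, replace = TRUE)
  fr2[1:4] <- c("I", "H", "W", "Y")               # IHWY at IMGT 39-42
  c2 <- sample(.aaPool, cdr2, replace = TRUE)
  fr3 <- sample(.aaPool, 39, replace = TRUE)
  fr3[24] <- "V"; fr3[39] <- "C"                  # hydrophobic 89, 2nd-CYS 104
  tail <- sample(setdiff(.aaPool, "G"), 2, replace = TRUE)
  aa <- c(fr1, c1, fr2, c2, fr3, tail)
  protected <- c(23L, 26L + cdr1 + 1:4, 26L + cdr1 + 17L + cdr2 + c(24L, 39L))
  list(nt = paste(.randCodon(aa), collapse = ""), aa = paste(aa, collapse = ""),
       l1 = cdr1, l2 = cdr2,
       anchor104 = (26L + cdr1 + 17L + cdr2 + 39L - 1L) * 3L + 1L,
       protected = protected, naa = length(aa))
}

# derive a same-subgroup member: re-draw ~5% of unprotected residues
.deriveMember <- function(base, aa_rate = 0.05) {
  aa <- strsplit(base$aa, "")[[1]]
  nt <- base$nt
  free <- setdiff(seq_along(aa), base$protected)
  k <- max(1L, round(aa_rate * length(aa)))
  hit <- sample(free, k)
  for (i in hit) {
    newaa <- sample(setdiff(.aaPool, aa[i]), 1)
    substr(nt, (i - 1L) * 3L + 1L, i * 3L) <- .randCodon(newaa)
    aa[i] <- newaa
  }
  out <- base
  out$nt <- nt; out$aa <- paste(aa, collapse = "")
  out
}

.makeJGene <- function() {
  # in frame from its first base, so an untrimmed germline V-J join is
  # productive; the J-PHE (118) codon starts at nt 16
  pre <- sample(.aaPool, 5, replace = TRUE)
  x <- sample(.aaPool, 1)
  post <- sample(.aaPool, 7, replace = TRUE)
  aa <- c(pre, "F", "G", x, "G", post)
  list(nt = paste(.randCodon(aa), collapse = ""),
       anchor118 = 5L * 3L + 1L)
}

# derive a related J paralog: re-draw a fraction of the residues outside
# the F-G-X-G anchor motif
.deriveJ <- function(proto, aa_rate = 0.25) {
  nt <- proto$nt
  naa <- nchar(nt) %/% 3L
  free <- setdiff(seq_len(naa), c(6L, 7L, 9L))
  k <- max(1L, round(aa_rate * naa))
  for (i in sample(free, k)) {
    s <- (i - 1L) * 3L + 1L
    cur <- .tx(substr(nt, s, s + 2L))
    substr(nt, s, s + 2L) <- .randCodon(sample(setdiff(.aaPool, cur), 1))
  }
  out <- proto
  out$nt <- nt
  out
}

# derive a related C paralog: re-draw a fraction of codons per exon
.deriveC <- function(proto, aa_rate = 0.05) {
  exons <- proto$exons
  for (e in seq_along(exons)) {
    nc <- nchar(exons[e]) %/% 3L
    k <- max(1L, round(aa_rate * nc))
    for (i in sample(nc, k)) {
      s <- (i - 1L) * 3L + 1L
      cur <- .tx(substr(exons[e], s, s + 2L))
      substr(exons[e], s, s + 2L) <- .randCodon(sample(setdiff(.aaPool, cur), 1))
    }
  }
  list(exons = exons)
}

.makeDGene <- function(len = 13L) {
  list(nt = .randSeq(len, bases = c("G", "G", "G", "A", "C", "T")))
}

.makeCGene <- function(exon_lens = c(90L, 60L, 60L)) {
  exons <- vapply(exon_lens / 3L, function(k)
    paste(.randCodon(sample(.aaPool, k, replace = TRUE)), collapse = ""),
    character(1))
  list(exons = exons)
}

# ---- defect planting ------------------------------------------------------

.plantVDefect <- function(v, defect) {
  if (defect == "STOP_CODON") {
    off <- 26L + v$l1 + 17L + v$l2
    for (i in off + c(5L, 15L)) {   # two stops in the V-REGION
      substr(v$nt, (i - 1L) * 3L + 1L, i * 3L) <- "TAA"
    }
  } else if (defect == "FRAMESHIFT") {
    mid <- floor(nchar(v$nt) / 2)
    v$nt <- paste0(substr(v$nt, 1, mid), substr(v$nt, mid + 2, nchar(v$nt)))
    v$anchor104 <- NA_integer_
  } else if (defect == "MISSING_ANCHOR") {
    substr(v$nt, 67, 69) <- "CGT"   # 1st-CYS 23 -> Arg
  } else if (defect == "DEGENERATE") {
    v$nt <- .mutateNt(v$nt, 0.22)
    v$anchor104 <- NA_integer_
  }
  v$defect <- defect
  v
}

.plantJDefect <- function(j, defect) {
  if (defect == "FRAMESHIFT") {
    j$nt <- paste0(substr(j$nt, 1, 9), substr(j$nt, 11, nchar(j$nt)))
    j$anchor118 <- NA_integer_
  } else if (defect == "STOP_CODON") {
    substr(j$nt, 4, 6) <- "TAA"     # stop upstream of the FGXG anchor
  }
  j$defect <- defect
  j
}

.mutateNt <- function(nt, rate) {
  if (rate <= 0) return(nt)
  ch <- strsplit(nt, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- DNA_BASES[(match(ch[hit], DNA_BASES) - 1L +
                            sample(3L, length(hit), TRUE)) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

# ---- blueprints -----------------------------------------------------------

#' Blueprint of a synthetic TR locus
#'
#' Describes the organization the locus builder plants. For TRG the locus
#' is a series of V-J-(J)-C cassettes; for TRB a V-gene region followed by
#' D-J-C clusters (optionally with a 3'-inverted V after the last C); for
#' "TRA/TRD" a V region, an embedded TRD D-J-C cluster with an inverted
#' TRDV after its C, then the TRAJ cluster and TRAC. Defect plans are
#' data.frames (gene index, defect label) applied to the planted genes.
#'
#' @param locus "TRG", "TRB" or "TRA/TRD".
#' @param cassettes number of TRG cassettes.
#' @param v_per_cassette integer vector, V genes per cassette (TRG).
#' @param j_per_cassette J genes per cassette (TRG).
#' @param subgroup_sizes sizes of the V subgroups; must sum to the total V
#'   count. Members of one subgroup stay above the subgroup identity
#'   threshold, different subgroups fall well below it.
#' @param v_defects,j_defects,c_defects optional data.frames with columns
#'   \code{idx} (gene index in locus order) and \code{defect}; defaults
#'   plant a realistic mixture for TRG (stop-codon, frameshift and
#'   missing-anchor V genes; frameshift/stop/non-canonical-RS J genes; one
#'   frameshift C gene) and no defects otherwise.
#' @param incomplete_cassette append a trailing V without J/C (TRG).
#' @param clusters,j_per_cluster,n_v TRB layout: number of D-J-C clusters,
#'   J genes per cluster, V genes upstream.
#' @param invert_last_v add a 3'-inverted V downstream of the last C (TRB
#'   and TRA/TRD).
#' @param n_trav,n_trdv,n_traj,trd_j TRA/TRD layout sizes.
#' @param mutation_rate per-base substitution rate applied to the finished
#'   locus (0 = clean truth).
#' @param intergenic min/max intergenic spacer length.
#' @return blueprint list (class \code{tr_blueprint}).
#' @export
locusBlueprint <- function(locus = c("TRG", "TRB", "TRA/TRD"),
                           cassettes = 5L,
                           v_per_cassette = c(3L, 3L, 2L, 2L, 2L),
                           j_per_cassette = 2L,
                           subgroup_sizes = c(4L, 4L, 1L, 1L, 1L, 1L),
                           v_defects = NULL, j_defects = NULL,
                           c_defects = NULL,
                           incomplete_cassette = FALSE,
                           clusters = 2L, j_per_cluster = 6L, n_v = 6L,
                           invert_last_v = FALSE,
                           n_trav = 4L, n_trdv = 2L, n_traj = 5L,
                           trd_j = 3L,
                           mutation_rate = 0,
                           intergenic = c(150L, 350L)) {
  locus <- match.arg(locus)
  if (locus == "TRG") {
    if (length(v_per_cassette) != cassettes)
      stop("v_per_cassette must have one entry per cassette")
    nv <- sum(v_per_cassette) + as.integer(incomplete_cassette)
    if (sum(subgroup_sizes) != nv)
      stop("subgroup_sizes must sum to the V gene count (", nv, ")")
    if (is.null(v_defects) && identical(subgroup_sizes, c(4L, 4L, 1L, 1L, 1L, 1L))) {
      # mirror a realistic cassette locus: second 4-member subgroup mostly
      # defective, one ORF single-member subgroup
      v_defects <- data.frame(
        subgroup = c(2L, 2L, 2L, 6L), member = c(1L, 2L, 3L, 1L),
        defect = c("STOP_CODON", "FRAMESHIFT", "MISSING_ANCHOR",
                   "NONCANONICAL_RS"))
    }
    if (is.null(j_defects)) {
      j_defects <- data.frame(idx = c(1L, 3L, 5L),
                              defect = c("FRAMESHIFT", "STOP_CODON",
                                         "NONCANONICAL_RS"))
    }
    if (is.null(c_defects)) {
      c_defects <- data.frame(idx = min(5L, cassettes),
                              defect = "FRAMESHIFT")
    }
  }
  structure(list(locus = locus, cassettes = cassettes,
                 v_per_cassette = v_per_cassette,
                 j_per_cassette = j_per_cassette,
                 subgroup_sizes = subgroup_sizes,
                 v_defects = v_defects, j_defects = j_defects,
                 c_defects = c_defects,
                 incomplete_cassette = incomplete_cassette,
                 clusters = clusters, j_per_cluster = j_per_cluster,
                 n_v = n_v, invert_last_v = invert_last_v,
                 n_trav = n_trav, n_trdv = n_trdv, n_traj = n_traj,
                 trd_j = trd_j,
                 mutation_rate = mutation_rate, intergenic = intergenic),
            class = "tr_blueprint")
}

# assemble helper: a growing piece list with a cursor
.newAsm <- function() new.env(parent = emptyenv())

.asmInit <- function() {
  a <- .newAsm(); a$pieces <- character(0); a$cursor <- 0L; a$genes <- list()
  a
}
.asmAdd <- function(a, s) {
  a$pieces[[length(a$pieces) + 1L]] <- s
  start <- a$cursor + 1L
  a$cursor <- a$cursor + nchar(s)
  start
}
.asmGap <- function(a, rng) .asmAdd(a, .randSeq(sample(rng[1]:rng[2], 1)))

.rsFields <- function(side, hept, spacer, nona) {
  out <- list(hept, spacer, nona, .rsScore(hept, nona),
              rsIsCanonical(hept, nona))
  names(out) <- paste0(side, c("_heptamer", "_spacer", "_nonamer",
                               "_score", "_canonical"))
  out
}

.newRS <- function(spacer_len, canonical = TRUE, heptamer = NULL) {
  hept <- if (is.null(heptamer)) sampleRS(1, "HEPTAMER", force_canonical = canonical)
          else heptamer
  list(hept = hept, spacer = .randSeq(spacer_len),
       nona = sampleRS(1, "NONAMER"))
}

# plant one V gene (body + 3' RS) into the assembly, return truth row
.plantV <- function(a, v, name, subgroup, unit, strand = "+") {
  canonical_rs <- !identical(v$defect, "NONCANONICAL_RS")
  rs <- .newRS(23L, canonical = TRUE,
               heptamer = if (canonical_rs) NULL else "TACAGTG")
  defects <- character(0)
  if (!is.null(v$defect) && v$defect != "NONE") {
    defects <- if (v$defect == "STOP_CODON") "STOP_CODON" else v$defect
  }
  block <- paste0(v$nt, rs$hept, rs$spacer, rs$nona)
  if (strand == "-") block <- .rc(block)
  bs <- .asmAdd(a, block)
  w <- nchar(v$nt)
  if (strand == "+") { gs <- bs; ge <- bs + w - 1L }
  else { ge <- bs + nchar(block) - 1L; gs <- ge - w + 1L }
  c(list(name = name, gene_type = "V", start = gs, end = ge, strand = strand,
         subgroup = subgroup, defects = list(defects), nt = v$nt,
         unit = unit, anchor104 = v$anchor104, anchor118 = NA_integer_),
    .rsFields("rs3", rs$hept, rs$spacer, rs$nona))
}

.plantJ <- function(a, j, name, unit, strand = "+") {
  canonical_rs <- !identical(j$defect, "NONCANONICAL_RS")
  rs <- .newRS(12L, heptamer = if (canonical_rs) NULL else "TACAGTG")
  defects <- character(0)
  if (!is.null(j$defect) && j$defect != "NONE") defects <- j$defect
  rsStr <- paste0(rs$hept, rs$spacer, rs$nona)
  block <- paste0(.rc(rsStr), j$nt, "GT")
  if (strand == "-") block <- .rc(block)
  bs <- .asmAdd(a, block)
  w <- nchar(j$nt)
  if (strand == "+") { gs <- bs + 28L; ge <- gs + w - 1L }
  else { ge <- bs + nchar(block) - 1L - 28L; gs <- ge - w + 1L }
  c(list(name = name, gene_type = "J", start = gs, end = ge, strand = strand,
         subgroup = NA_character_, defects = list(defects), nt = j$nt,
         unit = unit, anchor104 = NA_integer_, anchor118 = j$anchor118),
    .rsFields("rs5", rs$hept, rs$spacer, rs$nona))
}

.plantD <- function(a, d, name, unit, strand = "+") {
  rs5 <- .newRS(12L); rs3 <- .newRS(23L)
  rs5Str <- paste0(rs5$hept, rs5$spacer, rs5$nona)
  block <- paste0(.rc(rs5Str), d$nt, rs3$hept, rs3$spacer, rs3$nona)
  if (strand == "-") block <- .rc(block)
  bs <- .asmAdd(a, block)
  w <- nchar(d$nt)
  gs <- bs + 28L; ge <- gs + w - 1L
  c(list(name = name, gene_type = "D", start = gs, end = ge, strand = strand,
         subgroup = NA_character_, defects = list(character(0)), nt = d$nt,
         unit = unit, anchor104 = NA_integer_, anchor118 = NA_integer_),
    .rsFields("rs5", rs5$hept, rs5$spacer, rs5$nona),
    .rsFields("rs3", rs3$hept, rs3$spacer, rs3$nona))
}

.plantC <- function(a, cg, name, unit, defect = NULL, strand = "+") {
  exons <- cg$exons
  defects <- character(0)
  if (!is.null(defect) && defect == "FRAMESHIFT") {
    exons[1] <- paste0(substr(exons[1], 1, 40),
                       substr(exons[1], 42, nchar(exons[1])))
    defects <- "FRAMESHIFT"
  }
  introns <- vapply(seq_len(length(exons) - 1L), function(i)
    paste0("GT", .randSeq(sample(60:90, 1)), "AG"), character(1))
  block <- exons[1]
  for (i in seq_along(introns)) block <- paste0(block, introns[i], exons[i + 1])
  bs <- .asmAdd(a, block)
  ew <- nchar(exons); iw <- nchar(introns)
  es <- bs + c(0L, cumsum(ew[-length(ew)] + iw))
  ee <- es + ew - 1L
  c(list(name = name, gene_type = "C", start = bs, end = bs + nchar(block) - 1L,
         strand = strand, subgroup = NA_character_, defects = list(defects),
         nt = paste(exons, collapse = ""), unit = unit,
         anchor104 = NA_integer_, anchor118 = NA_integer_,
         exon_starts = list(as.integer(es)), exon_ends = list(as.integer(ee))))
}

.rowsToDf <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])
    if (cn %in% c("defects", "exon_starts", "exon_ends")) {
      lapply(vals, function(v) if (is.list(v)) v[[1]] else
        if (all(is.na(v))) if (cn == "defects") character(0) else integer(0) else v)
    } else unlist(vals)
  })
  names(out) <- cols
  if (is.null(out$defects))
    out$defects <- replicate(length(rows), character(0), FALSE)
  for (cn in c("exon_starts", "exon_ends")) {
    if (is.null(out[[cn]]))
      out[[cn]] <- replicate(length(rows), integer(0), FALSE)
  }
  plain <- setdiff(names(out), c("defects", "exon_starts", "exon_ends"))
  as.data.frame(
    c(out[plain],
      list(defects = I(out$defects),
           exon_starts = I(out$exon_starts), exon_ends = I(out$exon_ends))),
    stringsAsFactors = FALSE)
}

#' Build a synthetic ground-truth locus
#'
#' Assembles a locus sequence according to a blueprint: genes with their
#' recombination signals (canonical unless a defect says otherwise),
#' configured spacers and random intergenic sequence, planting the defects
#' the blueprint requests. Deterministic for a given seed.
#'
#' @param blueprint a [locusBlueprint()].
#' @param seed integer RNG seed.
#' @return list with elements \code{truth} (a \linkS4class{GermlineSet}
#'   carrying the exact planted coordinates, defects, functionality, RS
#'   and anchors) and \code{locus} (DNAString; also inside the truth
#'   object).
#' @export
buildSyntheticLocus <- function(blueprint, seed = 1L) {
  stopifnot(inherits(blueprint, "tr_blueprint"))
  withr::with_seed(as.integer(seed), .buildLocusImpl(blueprint))
}

.buildLocusImpl <- function(bp) {
  a <- .asmInit()
  rows <- list()
  ig <- bp$intergenic
  if (bp$locus == "TRG") {
    nv <- sum(bp$v_per_cassette) + as.integer(bp$incomplete_cassette)
    sizes <- bp$subgroup_sizes
    # interleave subgroup members across the locus
    slots <- data.frame(subgroup = unlist(lapply(seq_len(max(sizes)),
      function(m) which(sizes >= m))), stringsAsFactors = FALSE)
    slots$member <- unlist(lapply(seq_len(max(sizes)),
      function(m) rep(m, sum(sizes >= m))))
    anc <- .makeVGene()
    bases <- replicate(length(sizes), .deriveMember(anc, 0.30), simplify = FALSE)
    vname <- ifelse(sizes[slots$subgroup] > 1L,
                    paste0("TRGV", slots$subgroup, "-", slots$member),
                    paste0("TRGV", slots$subgroup))
    vdef <- rep("NONE", nv)
    if (!is.null(bp$v_defects)) {
      for (r in seq_len(nrow(bp$v_defects))) {
        hit <- which(slots$subgroup == bp$v_defects$subgroup[r] &
                     slots$member == bp$v_defects$member[r])
        vdef[hit] <- bp$v_defects$defect[r]
      }
    }
    vgenes <- lapply(seq_len(nv), function(i) {
      v <- if (slots$member[i] == 1L) bases[[slots$subgroup[i]]]
           else .deriveMember(bases[[slots$subgroup[i]]])
      if (vdef[i] != "NONE") v <- .plantVDefect(v, vdef[i]) else v$defect <- "NONE"
      v
    })
    jproto <- .makeJGene()
    cproto <- .makeCGene()
    jdef <- rep("NONE", bp$cassettes * bp$j_per_cassette)
    if (!is.null(bp$j_defects)) jdef[bp$j_defects$idx] <- bp$j_defects$defect
    cdef <- rep("NONE", bp$cassettes)
    if (!is.null(bp$c_defects)) cdef[bp$c_defects$idx] <- bp$c_defects$defect
    vi <- 0L; ji <- 0L
    for (k in seq_len(bp$cassettes)) {
      .asmGap(a, ig)
      for (m in seq_len(bp$v_per_cassette[k])) {
        vi <- vi + 1L
        rows[[length(rows) + 1L]] <- .plantV(a, vgenes[[vi]], vname[vi],
          paste0("TRGV", slots$subgroup[vi]), unit = k)
        .asmGap(a, ig)
      }
      for (jj in seq_len(bp$j_per_cassette)) {
        ji <- ji + 1L
        j <- .deriveJ(jproto)
        if (jdef[ji] != "NONE") j <- .plantJDefect(j, jdef[ji]) else j$defect <- "NONE"
        if (identical(j$defect, "NONCANONICAL_RS")) j$defect <- "NONCANONICAL_RS"
        rows[[length(rows) + 1L]] <- .plantJ(a, j, paste0("TRGJ", k, "-", jj),
                                             unit = k)
        .asmGap(a, ig)
      }
      cgk <- .deriveC(cproto)
      rows[[length(rows) + 1L]] <- .plantC(a, cgk, paste0("TRGC", k), unit = k,
        defect = if (cdef[k] != "NONE") cdef[k])
    }
    if (bp$incomplete_cassette) {
      .asmGap(a, ig)
      vi <- vi + 1L
      rows[[length(rows) + 1L]] <- .plantV(a, vgenes[[vi]], vname[vi],
        paste0("TRGV", slots$subgroup[vi]), unit = bp$cassettes + 1L)
    }
    .asmGap(a, ig)
  } else if (bp$locus == "TRB") {
    sizes <- bp$subgroup_sizes
    if (sum(sizes) != bp$n_v) sizes <- rep(1L, bp$n_v)
    anc <- .makeVGene()
    bases <- replicate(length(sizes), .deriveMember(anc, 0.30), simplify = FALSE)
    jproto <- .makeJGene()
    cproto <- .makeCGene(c(90L, 60L, 45L, 45L))
    vi <- 0L
    for (s in seq_along(sizes)) for (m in seq_len(sizes[s])) {
      vi <- vi + 1L
      .asmGap(a, ig)
      v <- if (m == 1L) bases[[s]] else .deriveMember(bases[[s]])
      v$defect <- "NONE"
      nm <- if (sizes[s] > 1L) paste0("TRBV", s, "-", m) else paste0("TRBV", s)
      rows[[length(rows) + 1L]] <- .plantV(a, v, nm, paste0("TRBV", s), NA_integer_)
    }
    for (cl in seq_len(bp$clusters)) {
      .asmGap(a, ig)
      rows[[length(rows) + 1L]] <- .plantD(a, .makeDGene(),
                                           paste0("TRBD", cl), cl)
      for (jj in seq_len(bp$j_per_cluster)) {
        .asmGap(a, ig)
        j <- .deriveJ(jproto); j$defect <- "NONE"
        rows[[length(rows) + 1L]] <- .plantJ(a, j, paste0("TRBJ", cl, "-", jj), cl)
      }
      .asmGap(a, ig)
      rows[[length(rows) + 1L]] <- .plantC(a, .deriveC(cproto),
                                           paste0("TRBC", cl), cl)
    }
    if (bp$invert_last_v) {
      .asmGap(a, ig)
      v <- .deriveMember(anc, 0.30); v$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantV(a, v, "TRBV30", "TRBV30",
                                           NA_integer_, strand = "-")
    }
    .asmGap(a, ig)
  } else {  # TRA/TRD
    anc <- .makeVGene()
    jproto <- .makeJGene()
    cproto <- .makeCGene(c(90L, 60L, 45L, 45L))
    for (i in seq_len(bp$n_trav)) {
      .asmGap(a, ig)
      v <- .deriveMember(anc, 0.30); v$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantV(a, v, paste0("TRAV", i),
                                           paste0("TRAV", i), NA_integer_)
    }
    for (i in seq_len(bp$n_trdv)) {
      .asmGap(a, ig)
      v <- .deriveMember(anc, 0.30); v$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantV(a, v, paste0("TRDV", i),
                                           paste0("TRDV", i), NA_integer_)
    }
    .asmGap(a, ig)
    rows[[length(rows) + 1L]] <- .plantD(a, .makeDGene(), "TRDD1", 1L)
    for (jj in seq_len(bp$trd_j)) {
      .asmGap(a, ig)
      j <- .deriveJ(jproto); j$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantJ(a, j, paste0("TRDJ", jj), 1L)
    }
    .asmGap(a, ig)
    rows[[length(rows) + 1L]] <- .plantC(a, .deriveC(cproto), "TRDC", 1L)
    if (bp$invert_last_v) {
      .asmGap(a, ig)
      v <- .deriveMember(anc, 0.30); v$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantV(a, v, "TRDV3", "TRDV3",
                                           NA_integer_, strand = "-")
    }
    for (jj in seq_len(bp$n_traj)) {
      .asmGap(a, ig)
      j <- .deriveJ(jproto); j$defect <- "NONE"
      rows[[length(rows) + 1L]] <- .plantJ(a, j, paste0("TRAJ", jj), 2L)
    }
    .asmGap(a, ig)
    rows[[length(rows) + 1L]] <- .plantC(a, .deriveC(cproto), "TRAC", 2L)
    .asmGap(a, ig)
  }
  locus <- paste(a$pieces, collapse = "")
  if (bp$mutation_rate > 0) locus <- .mutateNt(locus, bp$mutation_rate)
  df <- .rowsToDf(rows)
  truth <- GermlineSet(df, locus, bp$locus)
  list(truth = truth, locus = Biostrings::DNAString(locus))
}

# ---- repertoire simulation ------------------------------------------------

#' Repertoire simulation configuration
#'
#' @param v_usage,j_usage named probability vectors over eligible (F/ORF,
#'   anchor-bearing) germline gene names; must sum to 1.
#' @param cassette_bias probability that the J partner is drawn uniformly
#'   from the V gene's own cassette instead of from \code{j_usage}
#'   (0 = independent V/J draws).
#' @param p_trim geometric success probability of the exonucleolytic trim
#'   length at the V 3' and J 5' ends (mean (1-p)/p nt).
#' @param max_trim hard cap on each trim (keeps the junction anchors).
#' @param lambda_n Poisson mean of TdT N-insertion lengths.
#' @param include_d insert a (trimmed) D segment between N regions.
#' @param error per-base substitution error rate of sequencing.
#' @param read_len paired-end read length.
#' @param n_reads rearrangements per sample.
#' @param n_samples number of samples (libraries).
#' @param seed integer RNG seed.
#' @param adapter synthetic 5' template-switch adapter so reads cover the
#'   full junction.
#' @param c_stub_len length of the constant-region 5' stub mimicking the
#'   C primer site.
#' @return config list (class \code{sim_config}).
#' @export
simConfig <- function(v_usage = NULL, j_usage = NULL, cassette_bias = 0,
                      p_trim = 0.4, max_trim = 6L, lambda_n = 2,
                      include_d = FALSE, error = 0, read_len = 300L,
                      n_reads = 1000L, n_samples = 1L, seed = 1L,
                      adapter = "AAGCAGTGGTATCAACGCAGAGT",
                      c_stub_len = 30L) {
  stopifnot(error >= 0, error <= 0.1, p_trim > 0, p_trim <= 1,
            cassette_bias >= 0, cassette_bias <= 1, lambda_n >= 0)
  structure(list(v_usage = v_usage, j_usage = j_usage,
                 cassette_bias = cassette_bias, p_trim = p_trim,
                 max_trim = as.integer(max_trim), lambda_n = lambda_n,
                 include_d = include_d, error = error,
                 read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 adapter = adapter, c_stub_len = as.integer(c_stub_len)),
            class = "sim_config")
}

#' Default usage distribution for a synthetic germline set
#'
#' Emulates the strongly biased usage seen in cassette loci: if a
#' 4-member all-functional V subgroup exists it receives 95\% of the V
#' usage (split evenly), the remaining eligible V genes share the rest;
#' J genes that are second in their cassette share 80\% of the J usage.
#'
#' @param gset a \linkS4class{GermlineSet} (typically simulator truth).
#' @return list(v = named numeric, j = named numeric).
#' @export
defaultUsage <- function(gset) {
  mc <- S4Vectors::mcols(gset@genes)
  eligV <- mc$gene_type == "V" & mc$functionality %in% c("F", "ORF") &
    !is.na(mc$anchor104)
  eligJ <- mc$gene_type == "J" & mc$functionality %in% c("F", "ORF") &
    !is.na(mc$anchor118)
  vn <- mc$name[eligV]
  vsub <- mc$subgroup[eligV]
  tab <- table(mc$subgroup[mc$gene_type == "V"])
  big <- names(tab)[tab == 4L]
  big <- big[vapply(big, function(s) sum(vsub == s) == 4L, logical(1))]
  v <- setNames(rep(0, length(vn)), vn)
  if (length(big)) {
    inBig <- vsub == big[1]
    v[inBig] <- 0.95 / sum(inBig)
    if (any(!inBig)) v[!inBig] <- 0.05 / sum(!inBig)
    else v <- v / sum(v)
  } else v[] <- 1 / length(v)
  jn <- mc$name[eligJ]
  second <- grepl("-2$", jn)
  j <- setNames(rep(0, length(jn)), jn)
  if (any(second) && any(!second)) {
    j[second] <- 0.8 / sum(second); j[!second] <- 0.2 / sum(!second)
  } else j[] <- 1 / length(j)
  list(v = v, j = j)
}

#' Simulate rearranged 5'RACE amplicons
#'
#' Draws V (and optionally D) and J genes according to the configured
#' usage, applies geometric exonucleolytic trimming at the coding ends,
#' inserts Poisson-length TdT N regions, and assembles each amplicon as
#' adapter + trimmed V + N (+ trimmed D + N) + trimmed J + constant-region
#' stub. Only functional/ORF genes with intact junction anchors are
#' eligible. Every generating choice is recorded in the truth table; the
#' amplicon is exactly reconstructible from it.
#'
#' @param gset germline \linkS4class{GermlineSet} (e.g. simulator truth).
#' @param config a [simConfig()]; NULL usage fields fall back to
#'   [defaultUsage()].
#' @return list(amplicons = DNAStringSet, truth = data.frame).
#' @export
simulateRepertoire <- function(gset, config = simConfig()) {
  withr::with_seed(config$seed, .simRepImpl(gset, config))
}

.simRepImpl <- function(gset, cfg) {
  mc <- S4Vectors::mcols(gset@genes)
  usage <- defaultUsage(gset)
  vu <- if (is.null(cfg$v_usage)) usage$v else cfg$v_usage
  ju <- if (is.null(cfg$j_usage)) usage$j else cfg$j_usage
  if (!all(names(vu) %in% mc$name) || !all(names(ju) %in% mc$name))
    stop("usage references unknown gene(s)")
  if (abs(sum(vu) - 1) > 1e-6 || abs(sum(ju) - 1) > 1e-6)
    stop("usage probabilities must sum to 1")
  vtab <- data.frame(name = names(vu),
    seq = mc$nt[match(names(vu), mc$name)],
    anchor = mc$anchor104[match(names(vu), mc$name)],
    unit = mc$unit[match(names(vu), mc$name)])
  jtab <- data.frame(name = names(ju),
    seq = mc$nt[match(names(ju), mc$name)],
    anchor = mc$anchor118[match(names(ju), mc$name)],
    unit = mc$unit[match(names(ju), mc$name)])
  if (any(is.na(vtab$anchor)) || any(is.na(jtab$anchor)))
    stop("usage includes genes without junction anchors")
  okFun <- mc$functionality[match(c(vtab$name, jtab$name), mc$name)]
  if (any(!okFun %in% c("F", "ORF")))
    stop("only F/ORF genes are eligible for rearrangement")
  dtab <- NULL
  if (cfg$include_d) {
    isD <- mc$gene_type == "D" & mc$functionality == "F"
    if (!any(isD)) stop("include_d requested but no functional D gene")
    dtab <- data.frame(name = mc$name[isD], seq = mc$nt[isD])
  }
  cseq <- mc$nt[mc$gene_type == "C"]
  cstub <- if (length(cseq)) substr(cseq[1], 1, cfg$c_stub_len) else ""
  n <- cfg$n_reads * cfg$n_samples
  sample_id <- rep(seq_len(cfg$n_samples), each = cfg$n_reads)
  vi <- sample(nrow(vtab), n, replace = TRUE, prob = vu)
  ji <- sample(nrow(jtab), n, replace = TRUE, prob = ju)
  if (cfg$cassette_bias > 0) {
    useBias <- runif(n) < cfg$cassette_bias
    for (u in unique(vtab$unit)) {
      inU <- which(jtab$unit == u)
      if (!length(inU)) next
      hit <- which(useBias & vtab$unit[vi] == u)
      if (length(hit))
        ji[hit] <- inU[sample.int(length(inU), length(hit), replace = TRUE)]
    }
  }
  vlen <- nchar(vtab$seq)[vi]
  vslack <- vlen - (vtab$anchor[vi] + 2L)
  tv <- pmin(rgeom(n, cfg$p_trim), cfg$max_trim, vslack)
  jslack <- jtab$anchor[ji] - 1L
  tj <- pmin(rgeom(n, cfg$p_trim), cfg$max_trim, jslack)
  n1len <- rpois(n, cfg$lambda_n)
  n1 <- vapply(n1len, .randSeq, character(1))
  n1[n1len == 0] <- ""
  if (!is.null(dtab)) {
    di <- sample(nrow(dtab), n, replace = TRUE)
    dlen <- nchar(dtab$seq)[di]
    cap <- pmax(floor((dlen - 5L) / 2), 0L)
    td5 <- pmin(rgeom(n, cfg$p_trim), cap)
    td3 <- pmin(rgeom(n, cfg$p_trim), cap)
    dpart <- substr(dtab$seq[di], td5 + 1L, dlen - td3)
    n2len <- rpois(n, cfg$lambda_n)
    n2 <- vapply(n2len, .randSeq, character(1))
    n2[n2len == 0] <- ""
  } else {
    di <- rep(NA_integer_, n); td5 <- td3 <- rep(NA_integer_, n)
    dpart <- rep("", n); n2 <- rep("", n)
  }
  vpart <- substr(vtab$seq[vi], 1L, vlen - tv)
  jpart <- substr(jtab$seq[ji], tj + 1L, nchar(jtab$seq)[ji])
  amp <- paste0(cfg$adapter, vpart, n1, dpart, n2, jpart, cstub)
  adl <- nchar(cfg$adapter)
  a104 <- adl + vtab$anchor[vi]
  f118 <- adl + nchar(vpart) + nchar(n1) + nchar(dpart) + nchar(n2) +
    (jtab$anchor[ji] - tj)
  junction <- substr(amp, a104, f118 + 2L)
  ids <- paste0("S", sample_id, "_R", sequence(rep(cfg$n_reads, cfg$n_samples)))
  truth <- data.frame(sequence_id = ids, sample_id = sample_id,
    v_name = vtab$name[vi],
    d_name = if (is.null(dtab)) NA_character_ else dtab$name[di],
    j_name = jtab$name[ji],
    v_trim = tv, j_trim = tj, d5_trim = td5, d3_trim = td3,
    n1 = n1, n2 = n2,
    v_unit = vtab$unit[vi], j_unit = jtab$unit[ji],
    junction = junction, amplicon = amp, stringsAsFactors = FALSE)
  amps <- Biostrings::DNAStringSet(amp)
  names(amps) <- ids
  list(amplicons = amps, truth = truth)
}

#' Emit paired-end reads from amplicons
#'
#' R1 reads the amplicon forward from its 5' end, R2 is the reverse
#' complement of its 3' end (2 x read_len). Per-base qualities are drawn
#' from a two-point mixture of Q40 and rare Q2 "dropout" bases, weighted
#' so the mean error probability equals \code{error}; substitution errors
#' occur per base with the probability its quality encodes, so qualities
#' and errors are mutually consistent (and Q30 sliding-window trimming
#' behaves as on real instrument data: most reads survive full length).
#' Deterministic for a given seed; \code{error = 0} emits error-free
#' all-Q40 reads.
#'
#' @param amplicons DNAStringSet (or named character).
#' @param read_len read length.
#' @param error mean per-base substitution rate, in [0, 0.1].
#' @param seed integer RNG seed.
#' @return list(r1, r2) of QualityScaledDNAStringSet.
#' @export
emitReads <- function(amplicons, read_len = 300L, error = 0, seed = 1L) {
  stopifnot(error >= 0, error <= 0.1)
  if (read_len < 30L) stop("read_len below the overlap floor")
  withr::with_seed(as.integer(seed), {
    amp <- as.character(amplicons)
    L <- nchar(amp)
    r1 <- substr(amp, 1L, pmin(read_len, L))
    r2 <- .rc(substr(amp, pmax(1L, L - read_len + 1L), L))
    out1 <- .addErrors(r1, error)
    out2 <- .addErrors(r2, error)
    mk <- function(o, suffix) {
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(o$seq),
        Biostrings::PhredQuality(o$qual))
      names(x) <- paste0(names(amplicons), suffix)
      x
    }
    list(r1 = mk(out1, "/1"), r2 = mk(out2, "/2"))
  })
}

.addErrors <- function(reads, error) {
  lens <- nchar(reads)
  total <- sum(lens)
  if (error <= 1e-4) {
    q <- rep(40L, total)
    err <- logical(total)
  } else {
    w <- (error - 1e-4) / (10^-0.2 - 1e-4)
    q <- ifelse(runif(total) < w, 2L, 40L)
    err <- runif(total) < 10^(-q / 10)
  }
  big <- paste(reads, collapse = "")
  ends <- cumsum(lens); starts <- ends - lens + 1L
  if (any(err)) {
    ch <- strsplit(big, "")[[1]]
    ch[err] <- DNA_BASES[(match(ch[err], DNA_BASES) - 1L +
                            sample(3L, sum(err), TRUE)) %% 4L + 1L]
    big <- paste(ch, collapse = "")
  }
  qbig <- rawToChar(as.raw(q + 33L))
  list(seq = substring(big, starts, ends),
       qual = substring(qbig, starts, ends))
}
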