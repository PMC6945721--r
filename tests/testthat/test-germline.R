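test_that("pairwise identity follows the end-gap-free definition", {
  expect_equal(pairwiseIdentity("ACGTACGTAC", "ACGTACGTAC"), 100.0)
  expect_equal(pairwiseIdentity("ACGTACGTAC", "ACGTACGTAA"), 90.0)
  expect_error(pairwiseIdentity("", "ACGT"), "empty")
  # terminal overhangs are excluded from the denominator
  expect_equal(pairwiseIdentity("ACGTACGTAC", "GGGACGTACGTAC"), 100.0)
})

test_that("subgroup assignment clusters by the >75% identity rule", {
  base <- strrep("ACGTACGTGC", 10)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(1, by = floor(length(ch) / k), length.out = k)
    ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  s80 <- mut(base, 20)   # 80% identity to base
  s70 <- mut(base, 30)   # 70% identity to base
  sg <- assignSubgroups(c(a = base, b = s80), 75)
  expect_equal(sg$subgroup[1], sg$subgroup[2])
  sg2 <- assignSubgroups(c(a = base, b = s70), 75)
  expect_false(sg2$subgroup[1] == sg2$subgroup[2])
})

test_that("subgroup partition is invariant under permutation and thresholds", {
  fx <- tinyTRG(seed = 5)
  vseqs <- setNames(fx$mc$nt[fx$mc$gene_type == "V"],
                    fx$mc$name[fx$mc$gene_type == "V"])
  vseqs <- vseqs[nchar(vseqs) == 300]
  starts <- GenomicRanges::start(fx$truth@genes)[fx$mc$gene_type == "V"]
  starts <- starts[seq_along(vseqs)]
  ref <- assignSubgroups(vseqs, 75, starts = starts)
  part <- split(ref$name, ref$subgroup)
  withr::with_seed(41, {
    for (i in 1:3) {
      p <- sample(seq_along(vseqs))
      alt <- assignSubgroups(vseqs[p], 75, starts = starts[p])
      expect_equal(split(alt$name, alt$subgroup)[names(part)], part)
    }
  })
  # threshold extremes
  one <- assignSubgroups(vseqs, 1e-9)
  expect_equal(length(unique(one$subgroup)), 1L)
  singles <- assignSubgroups(vseqs, 100)
  expect_equal(length(unique(singles$subgroup)), length(vseqs))
})

test_that("the simulated TRG V set recovers its planted subgroup structure", {
  fx <- tinyTRG(seed = 9)
  isV <- fx$mc$gene_type == "V"
  vseqs <- setNames(fx$mc$nt[isV], fx$mc$name[isV])
  keep <- nchar(vseqs) == 300   # drop the frameshifted member
  sg <- assignSubgroups(vseqs[keep], 75,
                        starts = GenomicRanges::start(fx$truth@genes)[isV][keep])
  got <- split(sg$name, sg$subgroup)
  planted <- split(fx$mc$name[isV][keep], fx$mc$subgroup[isV][keep])
  expect_equal(length(got), length(planted))
  expect_setequal(lapply(unname(got), sort), lapply(unname(planted), sort))
})

test_that("closed-loop annotation recovers every planted TRG gene exactly", {
  fx <- tinyTRG(seed = 12)
  ann <- annotateLocus(fx$sl$locus, fx$germ, runConfig("TRG"))
  expect_equal(length(ann), length(fx$truth))
  expect_setequal(geneKey(ann), geneKey(fx$truth))
  # cassette units and IMGT-style names reproduce the planted layout
  am <- S4Vectors::mcols(ann@genes)
  ord <- match(coordKey(fx$truth), coordKey(ann))
  expect_equal(am$unit[ord], fx$mc$unit)
  expect_equal(am$name[ord], fx$mc$name)
})

test_that("planted defects are detected with their specific labels", {
  fx <- tinyTRG(seed = 12)
  ann <- annotateLocus(fx$sl$locus, fx$germ, runConfig("TRG"))
  am <- S4Vectors::mcols(ann@genes)
  ord <- match(coordKey(fx$truth), coordKey(ann))
  truthDef <- vapply(fx$mc$defects, paste, character(1), collapse = ",")
  getDef <- function(name) unlist(am$defects[ord[which(fx$mc$name == name)]])
  # the stop-codon V (two planted stops) is P with STOP_CODON only
  stopV <- fx$mc$name[vapply(fx$mc$defects, identical, logical(1), "STOP_CODON") &
                        fx$mc$gene_type == "V"]
  expect_equal(getDef(stopV[1]), "STOP_CODON")
  fsV <- fx$mc$name[truthDef == "FRAMESHIFT" & fx$mc$gene_type == "V"]
  expect_true("FRAMESHIFT" %in% getDef(fsV[1]))
  orfV <- fx$mc$name[truthDef == "NONCANONICAL_RS" & fx$mc$gene_type == "V"]
  expect_equal(getDef(orfV[1]), "NONCANONICAL_RS")
  maV <- fx$mc$name[truthDef == "MISSING_ANCHOR"]
  expect_equal(getDef(maV[1]), "MISSING_ANCHOR")
})

test_that("annotation is strand-symmetric under reverse complement", {
  fx <- tinyTRG(seed = 4)
  L <- length(fx$sl$locus)
  rcLocus <- Biostrings::reverseComplement(fx$sl$locus)
  ann <- annotateLocus(fx$sl$locus, fx$germ, runConfig("TRG"))
  annRC <- annotateLocus(rcLocus, fx$germ, runConfig("TRG"))
  expect_equal(length(ann), length(annRC))
  # mirrored coordinates, flipped strand, same classification
  mirror <- paste(L - GenomicRanges::end(annRC@genes) + 1L,
                  L - GenomicRanges::start(annRC@genes) + 1L,
                  S4Vectors::mcols(annRC@genes)$gene_type,
                  c("+" = "-", "-" = "+")[as.character(
                    GenomicRanges::strand(annRC@genes))],
                  S4Vectors::mcols(annRC@genes)$functionality)
  expect_setequal(mirror, geneKey(ann))
})

test_that("degenerate relic V genes are reported as lettered pseudogenes", {
  bp <- locusBlueprint("TRG",
    v_defects = data.frame(subgroup = c(2L, 2L), member = c(1L, 2L),
                           defect = c("DEGENERATE", "STOP_CODON")))
  fx <- tinyTRG(seed = 18, blueprint = bp)
  ann <- annotateLocus(fx$sl$locus, fx$germ, runConfig("TRG"))
  am <- S4Vectors::mcols(ann@genes)
  degTruth <- which(vapply(fx$mc$defects, identical, logical(1), "DEGENERATE"))
  ti <- GenomicRanges::start(fx$truth@genes)[degTruth]
  hit <- which(abs(GenomicRanges::start(ann@genes) - ti) < 50 &
                 am$gene_type == "V")
  expect_length(hit, 1L)
  expect_equal(am$functionality[hit], "P")
  expect_true("DEGENERATE" %in% unlist(am$defects[hit]))
  expect_match(am$name[hit], "^TRGV[A-Z]$")  # outside numeric subgroups
})

test_that("TRB scanning finds D genes with both signals and cluster structure", {
  bp <- locusBlueprint("TRB", n_v = 6, subgroup_sizes = c(2L, 1L, 1L, 1L, 1L),
                       clusters = 2, j_per_cluster = 6, invert_last_v = TRUE)
  sl <- buildSyntheticLocus(bp, seed = 3)
  mc <- S4Vectors::mcols(sl$truth@genes)
  firstC <- which(mc$gene_type == "C")[1]
  germ <- list(V = mc$nt[mc$gene_type == "V"], J = mc$nt[mc$gene_type == "J"],
    C = substring(as.character(sl$truth@locusSeq),
                  mc$exon_starts[[firstC]], mc$exon_ends[[firstC]]))
  ann <- annotateLocus(sl$locus, germ, runConfig("TRB"))
  am <- S4Vectors::mcols(ann@genes)
  expect_setequal(coordKey(ann), coordKey(sl$truth))
  dIdx <- which(am$gene_type == "D")
  expect_length(dIdx, 2L)
  expect_false(any(is.na(am$rs5_heptamer[dIdx])))
  expect_false(any(is.na(am$rs3_heptamer[dIdx])))
  expect_equal(sort(am$unit[dIdx]), c(1L, 2L))
  # each cluster: 1 D, 6 J, 1 C
  tab <- table(am$gene_type[!is.na(am$unit)], am$unit[!is.na(am$unit)])
  expect_equal(unname(tab["D", ]), c(1, 1))
  expect_equal(unname(tab["J", ]), c(6, 6))
  expect_equal(unname(tab["C", ]), c(1, 1))
  # the 3'-inverted V is on the minus strand
  inv <- which(GenomicRanges::start(ann@genes) ==
                 GenomicRanges::start(sl$truth@genes)[mc$name == "TRBV30"])
  expect_equal(as.character(GenomicRanges::strand(ann@genes))[inv], "-")
  # C genes comprise 4 exons here
  expect_true(all(lengths(am$exon_starts[am$gene_type == "C"]) == 4L))
})

test_that("segments flanked by a single RS are not called D genes", {
  withr::with_seed(44, {
    bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  })
  rs3 <- paste0("CACAGTG", strrep("T", 23), "ACAAAAACC")
  dna <- paste0(substr(bg, 1, 200), rs3, substr(bg, 240, 400))
  d <- scanDGenes(dna)
  expect_equal(nrow(d), 0L)
})

test_that("locus map handles an empty gene set and incomplete cassettes", {
  empty <- GermlineSet(
    data.frame(name = character(0), gene_type = character(0),
               start = integer(0), end = integer(0), strand = character(0)),
    strrep("A", 100), "TRG")
  expect_equal(length(buildLocusMap(empty)), 0L)
  bp <- locusBlueprint("TRG", incomplete_cassette = TRUE,
                       subgroup_sizes = c(4L, 4L, 1L, 1L, 1L, 2L))
  sl <- buildSyntheticLocus(bp, seed = 6)
  mc <- S4Vectors::mcols(sl$truth@genes)
  lastV <- which.max(GenomicRanges::start(sl$truth@genes))
  expect_equal(mc$gene_type[lastV], "V")
  expect_equal(mc$unit[lastV], 6L)  # trailing unit without J/C
})
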