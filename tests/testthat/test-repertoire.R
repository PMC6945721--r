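test_that("sliding-window trimming matches a brute-force window scan", {
  bruteTrim <- function(q, w, qmin) {
    for (i in seq_len(length(q) - w + 1L)) {
      if (mean(q[i:(i + w - 1L)]) < qmin) return(i - 1L)
    }
    length(q)
  }
  # stated examples
  allQ40 <- qreads("ACGTACGTAC", rep(40L, 10))
  expect_equal(as.character(slidingWindowTrim(allQ40, min_len = 5)[[1]]),
               "ACGTACGTAC")
  allQ2 <- qreads(strrep("ACGT", 25), rep(2L, 100))
  expect_length(slidingWindowTrim(allQ2), 0L)
  q <- c(rep(40L, 50), rep(2L, 50))
  r <- qreads(strrep("AC", 50), q)
  out <- slidingWindowTrim(r, window = 4L, qmin = 30, min_len = 1)
  expect_equal(Biostrings::width(out), bruteTrim(q, 4L, 30))
  # property: random qualities equal the brute-force rule
  withr::with_seed(61, {
    for (i in 1:40) {
      L <- sample(20:120, 1)
      q <- sample(2:40, L, replace = TRUE)
      r <- qreads(paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), q)
      keep <- bruteTrim(q, 4L, 30)
      out <- slidingWindowTrim(r, 4L, 30, min_len = 0)
      got <- if (length(out)) Biostrings::width(out) else 0L
      expect_equal(got, keep)
    }
  })
})

test_that("pair merging finds exact overlaps and resolves by quality", {
  withr::with_seed(62, {
    amp <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
  })
  r1 <- qreads(substr(amp, 1, 60), rep(40L, 60))
  r2 <- qreads(TRkit:::.rc(substr(amp, 31, 90)), rep(40L, 60))
  mg <- mergePairs(r1, r2, min_overlap = 20)
  expect_true(mg$merged_flag)
  expect_equal(as.character(mg$merged[[1]]), amp)   # 30-nt overlap, len 90
  # a disagreement resolves toward the higher-quality base
  s1 <- substr(amp, 1, 60)
  substr(s1, 45, 45) <- if (substr(amp, 45, 45) == "A") "G" else "A"
  q1 <- rep(40L, 60); q1[45] <- 10L
  mg2 <- mergePairs(qreads(s1, q1),
                    qreads(TRkit:::.rc(substr(amp, 31, 90)), rep(40L, 60)),
                    min_overlap = 20)
  expect_equal(substr(as.character(mg2$merged[[1]]), 45, 45),
               substr(amp, 45, 45))
  # and symmetrically when R1 has the better base
  mg3 <- mergePairs(qreads(s1, rep(40L, 60)),
                    qreads(TRkit:::.rc(substr(amp, 31, 90)), rep(10L, 60)),
                    min_overlap = 20)
  expect_equal(substr(as.character(mg3$merged[[1]]), 45, 45),
               substr(s1, 45, 45))
  # no admissible overlap -> unmerged flag
  other <- qreads(paste(rep("T", 60), collapse = ""), rep(40L, 60))
  mg4 <- mergePairs(r1, other, min_overlap = 20, max_mm = 2)
  expect_false(mg4$merged_flag)
})

test_that("simulated fragment pairs merge back to their amplicons", {
  fx <- tinyTRG(seed = 8)
  sim <- simulateRepertoire(fx$truth, simConfig(n_reads = 300, seed = 71))
  rd <- emitReads(sim$amplicons, read_len = 300, error = 0, seed = 72)
  mg <- mergePairs(rd$r1, rd$r2)
  expect_gte(mean(mg$merged_flag), 0.99)
  expect_equal(unname(as.character(mg$merged)),
               unname(sim$truth$amplicon[mg$merged_flag]))
})

test_that("error-free rearrangements are assigned their generating genes", {
  fx <- tinyTRG(seed = 8)
  ref <- referenceTable(fx$truth)
  sim <- simulateRepertoire(fx$truth, simConfig(n_reads = 400, seed = 73))
  asg <- assignGenes(sim$truth$amplicon, ref)
  expect_false(any(asg$unassigned))
  expect_equal(asg$v_best, sim$truth$v_name)
  expect_equal(asg$j_best, sim$truth$j_name)
})

test_that("a J pair differing by one trimmed 5' nt yields an ambiguity set", {
  j <- withr::with_seed(74, TRkit:::.makeJGene())
  j2 <- j$nt
  substr(j2, 1, 1) <- if (substr(j$nt, 1, 1) == "A") "C" else "A"
  v <- withr::with_seed(75, TRkit:::.makeVGene())
  ref <- list(
    v = data.frame(name = "TRGV1", seq = v$nt, anchor = v$anchor104, unit = 1L),
    j = data.frame(name = c("TRGJ2-2", "TRGJ3-2"), seq = c(j$nt, j2),
                   anchor = j$anchor118, unit = c(2L, 3L)),
    d = data.frame(name = character(0), seq = character(0)))
  # the distinguishing nucleotide is deleted in the rearrangement
  readTrim <- paste0(v$nt, substr(j$nt, 2, nchar(j$nt)))
  asg <- assignGenes(readTrim, ref)
  expect_equal(asg$v_call, "TRGV1")
  expect_equal(asg$j_call, "TRGJ2-2,TRGJ3-2")
  # with the nucleotide present only the true gene is called
  readFull <- paste0(v$nt, j$nt)
  expect_equal(assignGenes(readFull, ref)$j_call, "TRGJ2-2")
})

test_that("reads from an unrelated locus stay unassigned", {
  fx <- tinyTRG(seed = 8)
  ref <- referenceTable(fx$truth)
  withr::with_seed(76, {
    junk <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = ""),
      character(1))
  })
  asg <- assignGenes(junk, ref)
  expect_true(all(asg$unassigned))
})

test_that("junctions span codon 104 through 118 with productivity rules", {
  fx <- tinyTRG(seed = 8)
  ref <- referenceTable(fx$truth)
  # zero trimming, zero N: junction equals the germline join between anchors
  cfg <- simConfig(n_reads = 50, p_trim = 1, lambda_n = 0, seed = 77,
                   v_usage = setNames(1, ref$v$name[1]),
                   j_usage = setNames(1, ref$j$name[1]))
  sim <- simulateRepertoire(fx$truth, cfg)
  expect_equal(length(unique(sim$truth$junction)), 1L)
  vseq <- ref$v$seq[1]; jseq <- ref$j$seq[1]
  germJoin <- paste0(substr(vseq, ref$v$anchor[1], nchar(vseq)),
                     substr(jseq, 1, ref$j$anchor[1] + 2))
  expect_equal(sim$truth$junction[1], germJoin)
  asg <- assignGenes(sim$truth$amplicon, ref)
  jx <- extractJunction(sim$truth$amplicon, asg)
  expect_equal(unique(jx$junction), germJoin)
  expect_true(all(jx$productive))       # germline join is in frame here
  aa <- unique(jx$junction_aa)
  expect_match(aa, "^C")
  expect_match(aa, "[FW]$")
  expect_equal(unique(jx$cdr3),
               substr(germJoin, 4, nchar(germJoin) - 3))
  # out-of-frame junction length is unproductive
  cfg2 <- simConfig(n_reads = 300, lambda_n = 2, seed = 78)
  sim2 <- simulateRepertoire(fx$truth, cfg2)
  asg2 <- assignGenes(sim2$truth$amplicon, ref)
  jx2 <- extractJunction(sim2$truth$amplicon, asg2)
  inframe <- nchar(jx2$junction) %% 3 == 0
  expect_true(all(!jx2$productive[!inframe]))
  expect_equal(jx2$junction, sim2$truth$junction)
})

test_that("usage statistics split ambiguity fractionally and sum to one", {
  df <- data.frame(
    v_call = c("V1", "V1", "V2", "V1,V2"),
    j_call = "J1",
    sample_id = c("S1", "S1", "S1", "S1"), stringsAsFactors = FALSE)
  us <- usageStats(df, "v")
  expect_equal(sum(us$per_sample[, "S1"]), 100)
  expect_equal(us$per_sample["V1", "S1"], (2 + 0.5) / 4 * 100)
  expect_equal(us$per_sample["V2", "S1"], (1 + 0.5) / 4 * 100)
  # combined-category mode keeps the ambiguity set as its own label
  usc <- usageStats(df, "v", combine_ambiguous = TRUE)
  expect_true("V1,V2" %in% rownames(usc$per_sample))
  expect_equal(usc$per_sample["V1,V2", "S1"], 25)
  # single gene, one sample
  one <- usageStats(data.frame(v_call = "V9", j_call = "J1",
                               sample_id = "S1"), "v")
  expect_equal(unname(one$per_sample["V9", "S1"]), 100)
})

test_that("cross-sample medians use linear-interpolation quartiles", {
  df <- data.frame(
    v_call = c(rep("V1", 1 + 2 + 3), rep("V2", 9 + 8 + 7)),
    j_call = "J1",
    sample_id = c(rep("S1", 1), rep("S2", 2), rep("S3", 3),
                  rep("S1", 9), rep("S2", 8), rep("S3", 7)),
    stringsAsFactors = FALSE)
  us <- usageStats(df, "v")
  expect_equal(us$summary$median[us$summary$gene == "V1"], 20)
  expect_equal(unname(us$per_sample["V1", ]), c(10, 20, 30))
})

test_that("pairing matrices classify intra- vs inter-cassette joins", {
  ref <- list(
    v = data.frame(name = c("TRGV1", "TRGV2"), seq = "A", anchor = 1L,
                   unit = c(1L, 2L)),
    j = data.frame(name = c("TRGJ1-1", "TRGJ2-1"), seq = "A", anchor = 1L,
                   unit = c(1L, 2L)),
    d = data.frame(name = character(0), seq = character(0)))
  allIntra <- data.frame(v_call = "TRGV2", j_call = "TRGJ2-1",
                         sample_id = "S1")[rep(1, 5), ]
  pm <- pairingMatrix(allIntra, ref)
  expect_equal(pm$intra_fraction, 1.0)
  expect_equal(unname(pm$matrix["TRGV2", "TRGJ2-1"]), 5)
  mixed <- data.frame(v_call = c("TRGV1", "TRGV1", "TRGV2", "TRGVX"),
                      j_call = c("TRGJ1-1", "TRGJ2-1", "TRGJ2-1", "TRGJ1-1"),
                      sample_id = "S1")
  pm2 <- pairingMatrix(mixed, ref)
  expect_equal(pm2$intra_fraction, 2 / 3)      # unmapped V excluded
  expect_equal(unname(pm2$matrix["unmapped", "TRGJ1-1"]), 1)
  # fractional ambiguity conserves the total count
  amb <- data.frame(v_call = "TRGV1,TRGV2", j_call = "TRGJ1-1,TRGJ2-1",
                    sample_id = "S1")
  pm3 <- pairingMatrix(amb, ref)
  expect_equal(sum(pm3$matrix), 1)
})

test_that("simulated cassette bias is recovered from the pipeline", {
  fx <- tinyTRG(seed = 13)
  ref <- referenceTable(fx$truth)
  cfg <- simConfig(n_reads = 4000, cassette_bias = 0.8, seed = 79)
  sim <- simulateRepertoire(fx$truth, cfg)
  rd <- emitReads(sim$amplicons, 300, 0, 80)
  airr <- runRepertoire(rd$r1, rd$r2, ref, locus = "TRG")
  pm <- pairingMatrix(airr, fx$truth)
  truthIntra <- mean(sim$truth$v_unit == sim$truth$j_unit)
  se <- sqrt(truthIntra * (1 - truthIntra) / nrow(airr))
  expect_lt(abs(pm$intra_fraction - truthIntra), 3 * se + 1e-3)
})

test_that("cross-locus TRA/TRD rearrangements are labelled by the J locus", {
  bp <- locusBlueprint("TRA/TRD", invert_last_v = TRUE)
  sl <- buildSyntheticLocus(bp, seed = 14)
  tr <- sl$truth
  cfg <- simConfig(n_reads = 300, seed = 81,
    v_usage = setNames(c(0.5, 0.5), c("TRDV1", "TRDV3")),
    j_usage = setNames(c(0.9, 0.1), c("TRDJ1", "TRAJ2")))
  sim <- simulateRepertoire(tr, cfg)
  rd <- emitReads(sim$amplicons, 300, 0, 82)
  airr <- runRepertoire(rd$r1, rd$r2, referenceTable(tr), locus = "TRA/TRD")
  pm <- pairingMatrix(airr, tr)
  expect_setequal(names(pm$by_j_locus), c("TRA", "TRD"))
  frac <- pm$by_j_locus / sum(pm$by_j_locus)
  expect_lt(abs(frac[["TRD"]] - 0.9), 0.06)
  # the rare cross-locus join is representable as its own cell
  expect_gt(sum(pm$matrix[, grepl("^TRAJ", colnames(pm$matrix))]), 0)
})
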