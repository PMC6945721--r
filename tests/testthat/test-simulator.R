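test_that("locus building is bitwise deterministic per seed", {
  bp <- locusBlueprint("TRG")
  a <- buildSyntheticLocus(bp, seed = 91)
  b <- buildSyntheticLocus(bp, seed = 91)
  expect_identical(as.character(a$locus), as.character(b$locus))
  expect_identical(S4Vectors::mcols(a$truth@genes),
                   S4Vectors::mcols(b$truth@genes))
  c <- buildSyntheticLocus(bp, seed = 92)
  expect_false(identical(as.character(a$locus), as.character(c$locus)))
})

test_that("planted gene sequences and signals are embedded verbatim", {
  fx <- tinyTRG(seed = 93)
  loc <- as.character(fx$sl$locus)
  st <- GenomicRanges::start(fx$truth@genes)
  en <- GenomicRanges::end(fx$truth@genes)
  for (i in seq_along(fx$truth)) {
    span <- substr(loc, st[i], en[i])
    if (as.character(GenomicRanges::strand(fx$truth@genes))[i] == "-")
      span <- TRkit:::.rc(span)
    if (fx$mc$gene_type[i] == "C") {
      exns <- substring(loc, fx$mc$exon_starts[[i]], fx$mc$exon_ends[[i]])
      expect_equal(paste(exns, collapse = ""), fx$mc$nt[i])
    } else {
      expect_equal(span, fx$mc$nt[i])
    }
  }
  # V genes abut their 3' RS heptamer; J genes their 5' RS
  isV <- which(fx$mc$gene_type == "V" &
                 as.character(GenomicRanges::strand(fx$truth@genes)) == "+")
  for (i in isV)
    expect_equal(substr(loc, en[i] + 1L, en[i] + 7L), fx$mc$rs3_heptamer[i])
  isJ <- which(fx$mc$gene_type == "J" &
                 as.character(GenomicRanges::strand(fx$truth@genes)) == "+")
  for (i in isJ)
    expect_equal(substr(loc, st[i] - 7L, st[i] - 1L),
                 TRkit:::.rc(fx$mc$rs5_heptamer[i]))
})

test_that("a defect-free blueprint yields only functional genes", {
  bp <- locusBlueprint("TRG",
                       v_defects = data.frame(subgroup = integer(0),
                                              member = integer(0),
                                              defect = character(0)),
                       j_defects = data.frame(idx = integer(0),
                                              defect = character(0)),
                       c_defects = data.frame(idx = integer(0),
                                              defect = character(0)))
  fx <- tinyTRG(seed = 94, blueprint = bp)
  expect_true(all(functionality(fx$truth) == "F"))
  ann <- annotateLocus(fx$sl$locus, fx$germ, runConfig("TRG"))
  expect_true(all(functionality(ann) == "F"))
  expect_setequal(geneKey(ann), geneKey(fx$truth))
})

test_that("amplicons are exactly reconstructible from the truth record", {
  bp <- locusBlueprint("TRB", n_v = 4, subgroup_sizes = rep(1L, 4))
  sl <- buildSyntheticLocus(bp, seed = 95)
  mc <- S4Vectors::mcols(sl$truth@genes)
  cfg <- simConfig(n_reads = 200, include_d = TRUE, seed = 96)
  sim <- simulateRepertoire(sl$truth, cfg)
  tt <- sim$truth
  adapter <- cfg$adapter
  cstub <- substr(mc$nt[mc$gene_type == "C"][1], 1, cfg$c_stub_len)
  rebuilt <- vapply(seq_len(nrow(tt)), function(i) {
    v <- mc$nt[mc$name == tt$v_name[i]]
    j <- mc$nt[mc$name == tt$j_name[i]]
    d <- mc$nt[mc$name == tt$d_name[i]]
    paste0(adapter,
           substr(v, 1, nchar(v) - tt$v_trim[i]), tt$n1[i],
           substr(d, tt$d5_trim[i] + 1, nchar(d) - tt$d3_trim[i]), tt$n2[i],
           substr(j, tt$j_trim[i] + 1, nchar(j)), cstub)
  }, character(1))
  expect_equal(rebuilt, tt$amplicon)
  expect_equal(unname(as.character(sim$amplicons)), tt$amplicon)
  # junctions carry the planted D core when trims allow
  dseq <- mc$nt[mc$gene_type == "D"]
  core <- vapply(seq_len(nrow(tt)), function(i) {
    d <- mc$nt[mc$name == tt$d_name[i]]
    substr(d, tt$d5_trim[i] + 1, nchar(d) - tt$d3_trim[i])
  }, character(1))
  expect_true(all(mapply(grepl, core, tt$junction, fixed = TRUE)))
})

test_that("empirical usage converges to the configured distribution", {
  fx <- tinyTRG(seed = 97)
  usage <- defaultUsage(fx$truth)
  big4 <- names(usage$v)[usage$v > 0.2]
  expect_length(big4, 4L)
  expect_equal(sum(usage$v[big4]), 0.95)
  sim <- simulateRepertoire(fx$truth,
                            simConfig(n_reads = 50000, seed = 98))
  emp <- table(sim$truth$v_name)[names(usage$v)] / 50000
  se <- sqrt(usage$v * (1 - usage$v) / 50000)
  expect_true(all(abs(emp - usage$v) <= 3 * se + 1e-9))
  # subgroup-level check at the stated 95% share
  subEmp <- sum(emp[big4])
  expect_lt(abs(subEmp - 0.95), 3 * sqrt(0.95 * 0.05 / 50000))
})

test_that("trim and N-insertion models follow their distributions", {
  fx <- tinyTRG(seed = 97)
  cfg <- simConfig(n_reads = 20000, p_trim = 0.4, max_trim = 6L,
                   lambda_n = 2, seed = 99)
  sim <- simulateRepertoire(fx$truth, cfg)
  tt <- sim$truth
  # geometric trims, censored at the cap
  expect_true(all(tt$v_trim <= 6L))
  expect_gt(mean(tt$v_trim == 0L), 0.35)  # P(geom=0)=0.4, minus censoring
  expect_lt(abs(mean(nchar(tt$n1)) - 2), 3 * sqrt(2 / 20000) + 0.02)
  # zero-trim zero-N configuration gives identical germline junctions
  cfg0 <- simConfig(n_reads = 20, p_trim = 1, lambda_n = 0, seed = 100,
                    v_usage = setNames(1, tt$v_name[1]),
                    j_usage = setNames(1, tt$j_name[1]))
  sim0 <- simulateRepertoire(fx$truth, cfg0)
  expect_equal(length(unique(sim0$truth$junction)), 1L)
  expect_true(all(sim0$truth$v_trim == 0 & sim0$truth$j_trim == 0))
})

test_that("read emission is deterministic with quality-consistent errors", {
  fx <- tinyTRG(seed = 97)
  sim <- simulateRepertoire(fx$truth, simConfig(n_reads = 500, seed = 101))
  r1 <- emitReads(sim$amplicons, 300, 0.01, seed = 102)
  r2 <- emitReads(sim$amplicons, 300, 0.01, seed = 102)
  expect_identical(as.character(r1$r1), as.character(r2$r1))
  expect_identical(as.character(Biostrings::quality(r1$r2)),
                   as.character(Biostrings::quality(r2$r2)))
  # observed substitution rate within 3 SE of the configured rate
  truth1 <- substr(sim$truth$amplicon, 1, 300)
  obs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, as.character(r1$r1), truth1)
  n <- sum(nchar(truth1))
  rate <- sum(obs) / n
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  # error-free mode reconstructs amplicons exactly through merging
  r0 <- emitReads(sim$amplicons, 300, 0, seed = 103)
  mg <- mergePairs(r0$r1, r0$r2)
  expect_equal(unname(as.character(mg$merged)),
               unname(sim$truth$amplicon[mg$merged_flag]))
})

test_that("configuration errors are caught", {
  fx <- tinyTRG(seed = 97)
  expect_error(simulateRepertoire(fx$truth,
    simConfig(v_usage = c(NOSUCH = 1), j_usage = setNames(1, "TRGJ1-2"))),
    "unknown gene")
  expect_error(simConfig(error = 0.5), "error")
  expect_error(emitReads(Biostrings::DNAStringSet("ACGT"), read_len = 10),
               "overlap floor")
  # usage must not include pseudogenes
  mc <- S4Vectors::mcols(fx$truth@genes)
  pseudoV <- mc$name[mc$gene_type == "V" & mc$functionality == "P"][1]
  fn <- mc$name[mc$gene_type == "V" & mc$functionality == "F"][1]
  expect_error(simulateRepertoire(fx$truth, simConfig(
    v_usage = setNames(c(0.5, 0.5), c(pseudoV, fn)),
    j_usage = setNames(1, mc$name[mc$gene_type == "J" &
                                    mc$functionality == "F"][1]))),
    "anchors|eligible")
})
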