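test_that("distances follow the p and JC69 definitions with pairwise deletion", {
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 7), "CCC")
  d <- vRegionDistances(c(a = a, b = b), "p")
  expect_equal(unname(d["a", "b"]), 0.3)
  expect_equal(diag(d), c(a = 0, b = 0))
  dj <- vRegionDistances(c(a = a, b = b), "JC69")
  expect_equal(unname(dj["a", "b"]), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(round(unname(dj["a", "b"]), 5), 0.38312)
  # gap/N columns are deleted pairwise
  d2 <- vRegionDistances(c(a = "AC-TA", b = "ACNTT"), "p")
  expect_equal(unname(d2["a", "b"]), 0.25)
  expect_error(vRegionDistances(c(a = "---", b = "AAA")), "no comparable")
  expect_error(vRegionDistances(c(a = strrep("A", 8), b = strrep("C", 8)),
                                "JC69"), "undefined")
  expect_error(vRegionDistances(c(a = "ACGT", b = "AC")), "equal length")
})

test_that("three taxa resolve to the closed-form star with exact lengths", {
  D <- matrix(c(0, 3, 2, 3, 0, 2, 2, 2, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  expect_equal(ape::Ntip(tr), 3L)
  la <- (3 + 2 - 2) / 2; lb <- 3 - la; lc <- (2 + 2 - 3) / 2
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[c("a", "b", "c")], c(a = la, b = lb, c = lc))
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
})

test_that("additive matrices are recovered exactly, matching the four-point truth", {
  withr::with_seed(111, {
    for (n in 5:8) {
      tree <- ape::rtree(n)
      tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.4)
      D <- ape::cophenetic.phylo(tree)
      got <- njTree(D)
      expect_true(ape::dist.topo(ape::unroot(tree), got) == 0)
      # path distances reproduce the input matrix
      co <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
      expect_equal(co, D, tolerance = 1e-8)
      # cross-check against the reference NJ implementation
      expect_true(ape::dist.topo(got, ape::nj(D)) == 0)
      # taxon-order invariance of the unrooted topology
      p <- sample(n)
      expect_true(ape::dist.topo(njTree(D[p, p]), got) == 0)
    }
  })
})

test_that("negative branch estimates are clamped and flagged", {
  D <- matrix(c(0, 4, 1, 4, 0, 1, 1, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- njTree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(attr(tr, "clamped"), 1L)
})

test_that("bootstrap supports separate well-resolved clusters at 100%", {
  aln <- c(a = paste0(strrep("ACGT", 10), "AAAA"),
           b = paste0(strrep("ACGT", 10), "AAAT"),
           c = paste0(strrep("TGCA", 10), "CCCC"),
           d = paste0(strrep("TGCA", 10), "CCCG"))
  tr <- bootstrapSupport(aln, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))   # the a,b | c,d bipartition
  tr2 <- bootstrapSupport(aln, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  # Newick round trip keeps supports as internal node labels
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, names(aln))
  expect_true("100" %in% back$node.label)
})

test_that("simulated V subgroups form monophyletic clades at low divergence", {
  fx <- tinyTRG(seed = 115)
  isV <- fx$mc$gene_type == "V" & nchar(fx$mc$nt) == 300
  aln <- setNames(fx$mc$nt[isV], fx$mc$name[isV])
  tr <- njTree(vRegionDistances(aln, "p"))
  for (sub in unique(fx$mc$subgroup[isV])) {
    members <- fx$mc$name[isV][fx$mc$subgroup[isV] == sub]
    if (length(members) >= 2)
      expect_true(ape::is.monophyletic(tr, members),
                  label = paste("monophyly of", sub))
  }
})
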