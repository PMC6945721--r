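#' Pairwise distances between aligned V-REGION sequences
#'
#' p-distance (mismatches over compared sites) or Jukes-Cantor (JC69)
#' distance with pairwise deletion: for each pair, only columns where
#' both sequences carry an unambiguous A/C/G/T are compared.
#'
#' @param aln equal-length aligned sequences (character, DNAStringSet or
#'   named vector).
#' @param model "p" or "JC69" (\eqn{d = -3/4 \log(1 - 4p/3)}).
#' @return symmetric distance matrix with taxa dimnames.
#' @export
vRegionDistances <- function(aln, model = c("p", "JC69")) {
  model <- match.arg(model)
  nm <- names(aln)
  s <- toupper(as.character(aln))
  if (length(unique(nchar(s))) != 1L)
    stop("sequences must be aligned to equal length")
  if (is.null(nm)) nm <- paste0("t", seq_along(s))
  n <- length(s)
  M <- .charMatrix(s, nchar(s[1]))
  valid <- matrix(M %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- valid[i, ] & valid[j, ]
    if (!any(comp))
      stop("no comparable sites between ", nm[i], " and ", nm[j])
    p <- sum(M[i, comp] != M[j, comp]) / sum(comp)
    if (model == "JC69") {
      if (p >= 0.75)
        stop("JC69 undefined at p >= 0.75 for pair ", nm[i], "/", nm[j])
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q matrix are broken toward the pair containing the lowest original
#' taxon index (then the lowest partner index), making the result
#' deterministic. Negative branch-length estimates are clamped to zero
#' and counted in the \code{"clamped"} attribute.
#'
#' @param d symmetric distance matrix (taxa in dimnames) or dist object.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("neighbor-joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.10g", x)
  }
  # active clusters: newick fragment + smallest original taxon index
  nwk <- labels
  rep_ix <- seq_len(n0)
  D <- d
  while (length(nwk) > 3L) {
    n <- length(nwk)
    r <- rowSums(D)
    bestQ <- Inf; bi <- bj <- 0L
    ord <- order(rep_ix)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      i <- ord[a]; j <- ord[b]
      q <- (n - 2) * D[i, j] - r[i] - r[j]
      if (q < bestQ - 1e-12) { bestQ <- q; bi <- i; bj <- j }
    }
    li <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    lj <- D[bi, bj] - li
    newD <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[bi], fmt(li), nwk[bj], fmt(lj))
    keep <- setdiff(seq_len(n), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
                c(newD[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], merged)
    rep_ix <- c(rep_ix[keep], min(rep_ix[c(bi, bj)]))
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement \code{n_reps} times,
#' rebuilds the NJ tree for each replicate, and reports for every
#' internal edge of the full-data tree the percentage of replicate trees
#' containing the same bipartition, stored as internal node labels.
#'
#' @param aln aligned sequences (as for [vRegionDistances()]).
#' @param n_reps number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param model distance model passed to [vRegionDistances()].
#' @return the full-data \code{phylo} tree with \code{node.label} set to
#'   the support percentages (root label empty).
#' @export
bootstrapSupport <- function(aln, n_reps = 100L, seed = 1L,
                             model = c("p", "JC69")) {
  model <- match.arg(model)
  nm <- names(aln)
  s <- toupper(as.character(aln))
  if (is.null(nm)) nm <- paste0("t", seq_along(s))
  names(s) <- nm
  full <- njTree(vRegionDistances(s, model))
  L <- nchar(s[1])
  M <- .charMatrix(s, L)
  boots <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- .pasteRows(M[, cols, drop = FALSE])
      names(rs) <- nm
      njTree(vRegionDistances(rs, model))
    })
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  pct <- round(100 * counts / n_reps)
  lab <- as.character(pct)
  lab[is.na(lab)] <- ""
  full$node.label <- lab
  attr(full, "n_reps") <- n_reps
  full
}

#' Write a tree in Newick format
#'
#' @param tree ape phylo (supports travel as internal node labels).
#' @param path output file.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
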