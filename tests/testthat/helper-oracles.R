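# Independent brute-force implementations used as oracles. These
# deliberately take different routes from the package code: descendant
# sets come from phangorn::Descendants / ape::nodepath rather than the
# package's own postorder accumulation, and every metric is written as a
# direct transcription of its defining formula.

oracleBray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracleShannon <- function(x) {
  q <- x[x > 0] / sum(x)
  -sum(q * log(q))
}

oraclePielou <- function(x) {
  S <- sum(x > 0)
  if (S < 2) return(NA_real_)
  oracleShannon(x) / log(S)
}

# Faith's whole-tree PD: union of all edges on root-to-tip paths of the
# observed tips.
oraclePD <- function(x, tree) {
  tips <- names(x)[x > 0]
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  for (tp in tips) {
    nodes <- ape::nodepath(tree, from = root,
                           to = match(tp, tree$tip.label))
    for (i in seq_len(length(nodes) - 1)) {
      e <- which(tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1])
      edges <- union(edges, e)
    }
  }
  sum(tree$edge.length[edges])
}

# UniFrac via explicit per-branch descendant sets (phangorn::Descendants).
oracleUnifrac <- function(xa, xb, tree, weighted, normalized) {
  pa <- xa / sum(xa)
  pb <- xb / sum(xb)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  num <- 0; unionLen <- 0; sharedLen <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tipIdx <- desc[[e]]
    labs <- tree$tip.label[tipIdx]
    qa <- sum(pa[labs]); qb <- sum(pb[labs])
    l <- tree$edge.length[e]
    if (weighted) {
      num <- num + l * abs(qa - qb)
    } else {
      inA <- qa > 0; inB <- qb > 0
      if (inA || inB) unionLen <- unionLen + l
      if (inA && inB) sharedLen <- sharedLen + l
    }
  }
  if (!weighted) return(if (unionLen > 0) (unionLen - sharedLen) / unionLen else 0)
  if (!normalized) return(num)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depth) <- tree$tip.label
  den <- sum(depth[names(pa)] * (pa + pb))
  if (den > 0) num / den else 0
}

# One-way PERMANOVA from the defining sums of squares.
oraclePermanova <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  k <- nlevels(groups)
  ssTotal <- sum(d[lower.tri(d)]^2) / n
  ssWithin <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ssWithin <- ssWithin + sum(dg[lower.tri(dg)]^2) / length(idx)
  }
  ssBetween <- ssTotal - ssWithin
  list(pseudoF = (ssBetween / (k - 1)) / (ssWithin / (n - k)),
       r2 = ssBetween / ssTotal)
}

# small random fixtures -------------------------------------------------

randomSmallTree <- function(ntips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntips, tip.label = paste0("t", seq_len(ntips)))
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
    tr
  })
}

randomSmallCounts <- function(ntips, nsamples, seed, maxCount = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(ntips * nsamples, 5), ntips, nsamples,
                dimnames = list(paste0("t", seq_len(ntips)),
                                paste0("s", seq_len(nsamples))))
    # guarantee positive depths and taxon totals
    m[1, ] <- m[1, ] + 1L
    m[, 1] <- m[, 1] + 1L
    storage.mode(m) <- "integer"
    m
  })
}
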