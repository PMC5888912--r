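ACGT <- c("A", "C", "G", "T")

randomSites <- function(n, freq = c(.3, .2, .2, .3)) {
  sample(ACGT, n, replace = TRUE, prob = freq)
}

apeTn93 <- function(a, b) {
  bin <- ape::as.DNAbin(matrix(c(a, b), nrow = 2, byrow = TRUE,
                               dimnames = list(c("x", "y"), NULL)))
  as.numeric(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
}

test_that("TN93 distance is zero for identical sequences and matches the
          published closed form", {
  set.seed(101)
  s <- randomSites(300)
  expect_identical(as.numeric(tn93Distance(s, s)), 0)

  # 300-nt pair differing by exactly 15 A<->G transitions, against an
  # independent evaluation of the TN93 formula (ape::dist.dna)
  a <- randomSites(300)
  ag <- which(a == "A")[1:15]
  b <- a
  b[ag] <- "G"
  expect_lt(abs(tn93Distance(a, b) - apeTn93(a, b)), 1e-12)

  # random divergent pairs
  for (i in 1:20) {
    a <- randomSites(500)
    b <- a
    idx <- sample(500, 60)
    b[idx] <- sample(ACGT, 60, replace = TRUE)
    expect_lt(abs(tn93Distance(a, b) - apeTn93(a, b)), 1e-12)
  }
})

test_that("pairwise deletion: gap columns do not change the distance", {
  set.seed(102)
  a <- randomSites(400)
  b <- a
  idx <- sample(400, 50)
  b[idx] <- sample(ACGT, 50, replace = TRUE)
  d0 <- as.numeric(tn93Distance(a, b))
  a2 <- c(a, rep("-", 30))
  b2 <- c(b, randomSites(30))
  expect_equal(as.numeric(tn93Distance(a2, b2)), d0, tolerance = 1e-15)
  # ambiguity codes are excluded the same way
  a3 <- a; a3[1:5] <- "N"
  b3 <- b; b3[1:5] <- "A"
  expect_equal(as.numeric(tn93Distance(a3, b3)),
               as.numeric(tn93Distance(a[-(1:5)], b[-(1:5)])),
               tolerance = 1e-15)
})

test_that("TN93 reduces to the Kimura two-parameter distance under equal
          frequencies", {
  # construct sequences with exactly balanced base composition
  set.seed(103)
  for (i in 1:10) {
    n <- 400L
    a <- rep(ACGT, each = n / 4L)
    b <- a
    # symmetric substitution pattern preserving equal pair frequencies:
    # swap A<->G in one block and C<->T in another, transversions balanced
    b[1:20] <- "G"; b[(n / 4 + 1):(n / 4 + 20)] <- "T"
    b[(n / 2 + 1):(n / 2 + 20)] <- "A"; b[(3 * n / 4 + 1):(3 * n / 4 + 20)] <- "C"
    bin <- ape::as.DNAbin(matrix(c(a, b), nrow = 2, byrow = TRUE,
                                 dimnames = list(c("x", "y"), NULL)))
    k80 <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_lt(abs(tn93Distance(a, b) - k80), 1e-9)
  }
})

test_that("saturated and sparse pairs are capped and flagged invalid", {
  # maximally divergent: transversion proportion beyond the TN93 domain
  a <- rep(c("A", "G"), 100)
  b <- rep(c("C", "T"), 100)
  d <- tn93Distance(a, b)
  expect_identical(as.numeric(d), 5)
  expect_false(attr(d, "valid"))

  # fewer than 20 comparable sites
  a2 <- c(randomSites(10), rep("-", 30))
  b2 <- c(randomSites(10), randomSites(30))
  b2[31:40] <- "-"
  d2 <- tn93Distance(a2, b2)
  expect_false(attr(d2, "valid"))

  # njTree refuses invalid pairs, naming them
  m <- rbind(x = a, y = b, z = a)
  dm <- tn93Matrix(m)
  expect_error(njTree(dm), "x/y")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- njTree(d)
  el <- setNames(phy$edge.length,
                 phy$tip.label[phy$edge[, 2]])
  expect_equal(el[["a"]], (5 + 9 - 8) / 2)
  expect_equal(el[["b"]], (5 + 8 - 9) / 2)
  expect_equal(el[["c"]], (9 + 8 - 5) / 2)
})

test_that("NJ recovers random additive trees exactly and is order
          invariant", {
  set.seed(104)
  for (i in 1:20) {
    tr <- ape::rtree(sample(8:16, 1L))
    D <- ape::cophenetic.phylo(tr)
    phy <- njTree(D)
    expect_identical(as.numeric(phangorn::RF.dist(ape::unroot(tr), phy)), 0)
    Dhat <- ape::cophenetic.phylo(phy)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dhat - D)), 1e-9)
    # taxon order invariance
    perm <- sample(nrow(D))
    phy2 <- njTree(D[perm, perm])
    expect_identical(as.numeric(phangorn::RF.dist(phy, phy2)), 0)
  }
})

test_that("negative NJ branch lengths are clamped with the deficit moved to
          the sibling", {
  # a non-additive matrix known to produce a negative NJ branch
  set.seed(105)
  repeat {
    n <- 6L
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 1)
    D <- D + t(D)
    raw <- ape::nj(as.dist(D))
    if (any(raw$edge.length < 0)) break
  }
  phy <- njTree(D)
  expect_true(all(phy$edge.length >= 0))
  # topology untouched; each clamped edge's deficit went to its sibling
  expect_identical(as.numeric(phangorn::RF.dist(phy, raw)), 0)
  changed <- which(abs(phy$edge.length - raw$edge.length) > 1e-14)
  for (i in changed) {
    if (raw$edge.length[i] < 0) {
      expect_identical(phy$edge.length[i], 0)
    } else {
      # a sibling that absorbed a deficit
      expect_gt(phy$edge.length[i], raw$edge.length[i])
    }
  }
})

test_that("bootstrap supports saturate on clear signal and are
          deterministic", {
  spn <- ape::read.tree(text = paste0(
    "(((A|1:0.1,B|1:0.1):0.1,(C|1:0.1,D|1:0.1):0.1):0.05,",
    "((E|1:0.1,F|1:0.1):0.1,(G|1:0.1,H|1:0.1):0.1):0.05);"))
  ca <- simulateSequences(spn, nCodons = 1000L, seed = 7L)
  sites <- selectCodonPositions(ca, "Inc3rd")
  cfg <- pipelineConfig(rngSeed = 3L, nBootstrap = 100L)
  gt <- bootstrapSupport(sites, cfg)
  sup <- supportValues(gt)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 100))

  gt2 <- bootstrapSupport(sites, cfg)
  expect_identical(supportValues(gt), supportValues(gt2))
  expect_identical(writeNewick(gt), writeNewick(gt2))

  # single replicate: supports are 0 or 100
  g1 <- bootstrapSupport(sites, pipelineConfig(rngSeed = 4L,
                                               nBootstrap = 1L))
  s1 <- supportValues(g1)
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon relabeling", {
  spn <- ape::read.tree(text = paste0(
    "(((A|1:0.1,B|1:0.1):0.1,C|1:0.2):0.05,(D|1:0.15,E|1:0.15):0.1);"))
  ca <- simulateSequences(spn, nCodons = 400L, seed = 17L)
  sites <- selectCodonPositions(ca, "Inc3rd")
  cfg <- pipelineConfig(rngSeed = 5L, nBootstrap = 50L)
  gt <- bootstrapSupport(sites, cfg)

  perm <- c("D|1", "A|1", "C|1", "E|1", "B|1")
  sites2 <- sites[perm, ]
  attr(sites2, "codonIndex") <- attr(sites, "codonIndex")
  gt2 <- bootstrapSupport(sites2, cfg)

  keyed <- function(g) {
    phy <- treeOf(g)
    nt <- length(phy$tip.label)
    tipsBelow <- function(v) {
      if (v <= nt) return(phy$tip.label[v])
      unlist(lapply(phy$edge[phy$edge[, 1] == v, 2], tipsBelow))
    }
    out <- list()
    for (v in nt + seq_len(phy$Nnode)) {
      out[[paste(sort(tipsBelow(v)), collapse = "|")]] <- supportValues(g)[v]
    }
    out
  }
  k1 <- keyed(gt); k2 <- keyed(gt2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0L)
  for (s in shared) expect_equal(k1[[s]], k2[[s]])
})
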