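twoSpecies <- function() {
  sp <- ape::read.tree(text = "(A,B);")
  sp$edge.length <- rep(1, nrow(sp$edge))
  SpeciesTree(sp, list(a = "A", b = "B"))
}

threeSpecies <- function() {
  sp <- ape::read.tree(text = "((A,B),C);")
  sp$edge.length <- rep(1, nrow(sp$edge))
  SpeciesTree(sp, list(a = "A", b = "B", c = "C"))
}

test_that("congruent gene trees reconcile with zero cost", {
  st <- speciesTreeFixture()
  phy <- treeOf(st)
  phy$tip.label <- paste0(phy$tip.label, "|g1")
  rr <- lcaReconcile(GeneTree(phy), st)
  expect_identical(nDuplications(rr), 0L)
  expect_identical(nLosses(rr), 0L)
  expect_identical(dlCost(rr), 0)
  expect_true(all(rr@events[rr@events != "leaf"] == "speciation"))
})

test_that("the four-leaf duplication instance matches exhaustive history
          enumeration", {
  st <- twoSpecies()
  gt <- parseNewick("((A|1,B|1),(A|2,B|2));")
  rr <- lcaReconcile(gt, st)
  expect_identical(rr@D, 1L)
  expect_identical(rr@L, 0L)
  # duplication at the root, mapped to the species root
  root <- length(treeOf(gt)$tip.label) + 1L
  expect_identical(rr@events[root], "duplication")
  # brute-force check over all event histories
  expect_identical(dlCost(rr),
                   oracleHistoryMinCost(treeOf(gt), speciesMap(gt),
                                        treeOf(st)))
})

test_that("a family absent from one subclade accrues a loss on its stem", {
  st <- speciesTreeFixture()
  # protostome and chordate genes, no ambulacrarian genes, rooted between
  # protostomes and chordates
  gt <- parseNewick(paste0(
    "((Drosophila_melanogaster|g1,Caenorhabditis_elegans|g1),",
    "((Branchiostoma_floridae|g1,Oikopleura_dioica|g1),Homo_sapiens|g1));"))
  rr <- lcaReconcile(gt, st)
  # the Ambulacraria stem branch is the edge above mrca(hemichordates,
  # echinoderms)
  ambu <- mrca(st, c("Saccoglossus_kowalevskii",
                     "Strongylocentrotus_purpuratus"))
  expect_gte(rr@branchLosses[[as.character(ambu)]], 1L)
})

test_that("non-binary gene trees are rejected with guidance", {
  st <- threeSpecies()
  gt <- parseNewick("(A|1,B|1,C|1);")
  expect_error(lcaReconcile(gt, st), "resolvePolytomies")
  expect_error(lcaReconcile(parseNewick("(A|1,(B|1,X|1));"), st),
               "absent")
})

test_that("reconciliation cost equals the brute-force history minimum on
          random instances", {
  set.seed(61)
  for (i in 1:60) {
    st <- randomSpeciesTree(sample(2:5, 1L))
    gtPhy <- randomGeneTreePhylo(sample(3:7, 1L), treeOf(st)$tip.label)
    gt <- GeneTree(gtPhy)
    rr <- lcaReconcile(gt, st)
    expect_identical(dlCost(rr),
                     oracleHistoryMinCost(gtPhy, speciesMap(gt),
                                          treeOf(st)))
  }
})

test_that("duplication totals are invariant to relabeling genes within a
          species", {
  set.seed(62)
  for (i in 1:20) {
    st <- randomSpeciesTree(4)
    gtPhy <- randomGeneTreePhylo(6, treeOf(st)$tip.label)
    gt <- GeneTree(gtPhy)
    rr <- lcaReconcile(gt, st)
    # permute gene numbering within each species
    phy2 <- gtPhy
    sp <- sub("\\|.*", "", phy2$tip.label)
    for (s in unique(sp)) {
      idx <- which(sp == s)
      phy2$tip.label[idx] <- paste0(s, "|h", sample(seq_along(idx)))
    }
    rr2 <- lcaReconcile(GeneTree(phy2), st)
    expect_identical(rr2@D, rr@D)
    expect_identical(rr2@L, rr@L)
  }
})

test_that("equal weights make the reported cost exactly D + L", {
  set.seed(63)
  for (i in 1:10) {
    st <- randomSpeciesTree(4)
    gt <- GeneTree(randomGeneTreePhylo(6, treeOf(st)$tip.label))
    rr <- lcaReconcile(gt, st)
    expect_identical(dlCost(rr), as.numeric(rr@D + rr@L))
    # and the weighted cost scales accordingly
    rr2 <- lcaReconcile(gt, st, pipelineConfig(dupCost = 2, lossCost = 3))
    expect_identical(dlCost(rr2), 2 * rr@D + 3 * rr@L)
  }
})

test_that("DL rooting recovers the congruent optimum and is deterministic", {
  st <- speciesTreeFixture()
  phy <- treeOf(st)
  phy$tip.label <- paste0(phy$tip.label, "|g1")
  un <- GeneTree(ape::unroot(phy), unrooted = TRUE)
  r1 <- rootByDL(un, st)
  rr <- lcaReconcile(r1, st)
  expect_identical(rr@D, 0L)
  expect_identical(rr@L, 0L)
  r2 <- rootByDL(un, st)
  expect_identical(writeNewick(r1), writeNewick(r2))
})

test_that("DL rooting attains the all-rootings brute-force minimum", {
  set.seed(64)
  for (i in 1:40) {
    st <- randomSpeciesTree(sample(2:4, 1L))
    gtPhy <- ape::unroot(randomGeneTreePhylo(sample(4:6, 1L),
                                             treeOf(st)$tip.label))
    gt <- GeneTree(gtPhy, unrooted = TRUE)
    rooted <- rootByDL(gt, st)
    got <- dlCost(lcaReconcile(rooted, st))
    want <- oracleAllRootingsMinCost(gtPhy, speciesMap(gt), treeOf(st))
    expect_identical(got, want)
  }
})

test_that("polytomy resolution produces lexicographic caterpillars with
          rearrangeable edges", {
  gt <- parseNewick("((A|1,B|1),C|1);")
  expect_identical(writeNewick(resolvePolytomies(gt)), writeNewick(gt))

  tri <- parseNewick("(C|1,A|1,B|1);")
  res <- resolvePolytomies(tri)
  phy <- treeOf(res)
  expect_true(ape::is.binary(phy))
  # one introduced edge with support 0
  expect_identical(sum(!is.na(supportValues(res)) &
                         supportValues(res) == 0), 1L)
  # lexicographic: A and B group first
  expect_false(is.na(cladeSupport(res, c("A|1", "B|1"))))

  set.seed(65)
  for (i in 1:10) {
    k <- sample(4:8, 1L)
    tips <- paste0(LETTERS[1:k], "|1")
    nwk <- paste0("(", paste(sample(tips), collapse = ","), ");")
    big <- resolvePolytomies(parseNewick(nwk))
    expect_setequal(treeOf(big)$tip.label, tips)
    expect_true(ape::is.binary(treeOf(big)))
  }
})

test_that("trees with only strong supports pass through rearrangement
          unchanged", {
  st <- twoSpecies()
  gt <- parseNewick("((A|1,B|1)95,(B|2,A|2)80);")
  out <- rearrangeWeakNodes(gt, st)
  expect_identical(writeNewick(out), writeNewick(gt))
  expect_error(rearrangeWeakNodes(parseNewick("((A|1,B|1),(B|2,A|2));"),
                                  st),
               "no support values")
})

test_that("rearrangement strictly lowers cost when a weak grouping
          conflicts with the species tree", {
  st <- threeSpecies()
  # (a1,c1) weakly grouped against b1: cost 4 as rooted; regrouping
  # ((a1,b1),c1) is congruent with the species tree (cost 0)
  gt <- parseNewick("((A|1,C|1)40,B|1)90;")
  inCost <- dlCost(lcaReconcile(gt, st))
  out <- rearrangeWeakNodes(gt, st)
  outCost <- dlCost(lcaReconcile(out, st))
  expect_lt(outCost, inCost)
  expect_identical(outCost, 0)
  # the species-congruent grouping (A,B) now exists as a clade
  expect_true(paste(sort(c("A|1", "B|1")), collapse = "|") %in%
                rootedCladeSet(treeOf(out)))
})

test_that("rearrangement attains the exhaustive optimum and never alters
          strong edges", {
  set.seed(66)
  for (i in 1:30) {
    st <- randomSpeciesTree(sample(3:5, 1L))
    gtPhy <- randomGeneTreePhylo(sample(6:9, 1L), treeOf(st)$tip.label)
    ntip <- length(gtPhy$tip.label)
    n <- ntip + gtPhy$Nnode
    support <- rep(NA_real_, n)
    internal <- setdiff((ntip + 1L):n, ntip + 1L)
    support[internal] <- 90
    # one weak region: a random internal node, possibly with its internal
    # parent, weakened
    v <- sample(internal, 1L)
    support[v] <- 30
    par <- integer(n); par[gtPhy$edge[, 2]] <- gtPhy$edge[, 1]
    if (par[v] %in% internal && runif(1) < 0.5) support[par[v]] <- 40
    gt <- GeneTree(gtPhy, support = support)
    out <- rearrangeWeakNodes(gt, st)
    outCost <- dlCost(lcaReconcile(out, st))

    # independent exhaustive oracle over resolutions of the weak region
    weak <- which(!is.na(support) & support < 70)
    S <- unique(c(weak, par[weak]))
    top <- S[which.min(vapply(S, function(x) {
      d <- 0L; w <- x
      while (par[w] != 0L) { w <- par[w]; d <- d + 1L }
      d
    }, integer(1L)))]
    kidsOf <- function(u) gtPhy$edge[gtPhy$edge[, 1] == u, 2]
    boundary <- integer(0L)
    for (u in S) {
      if (!(u %in% weak) && u != top) next
      for (k in kidsOf(u)) if (!(k %in% weak)) boundary <- c(boundary, k)
    }
    frags <- vapply(boundary, function(b) cladeFragment(gtPhy, b),
                    character(1L))
    topFrag <- cladeFragment(gtPhy, top)
    fullFrag <- cladeFragment(gtPhy, ntip + 1L)
    costs <- vapply(oracleAllRootedTrees(frags), function(fr) {
      nwk <- paste0(sub(topFrag, fr, fullFrag, fixed = TRUE), ";")
      cand <- GeneTree(ape::read.tree(text = nwk))
      dlCost(lcaReconcile(cand, st))
    }, numeric(1L))
    expect_identical(outCost, min(costs))

    # strong clades survive: every strongly supported clade of the input
    # is a clade of the output
    strongClades <- rootedCladeSet(gtPhy)
    inSets <- vapply(which(!is.na(support) & support >= 70), function(v2) {
      tipsBelow <- function(u) {
        if (u <= ntip) return(gtPhy$tip.label[u])
        unlist(lapply(kidsOf(u), tipsBelow))
      }
      paste(sort(tipsBelow(v2)), collapse = "|")
    }, character(1L))
    outSets <- rootedCladeSet(treeOf(out))
    outSets <- c(outSets, paste(sort(treeOf(out)$tip.label), collapse = "|"))
    expect_true(all(inSets %in% outSets))

    # rearrangement never exceeds the input cost
    expect_lte(outCost, dlCost(lcaReconcile(gt, st)))
  }
})

test_that("edges created by rearrangement are flagged and unsupported", {
  st <- threeSpecies()
  gt <- parseNewick("((A|1,C|1)40,B|1)90;")
  out <- rearrangeWeakNodes(gt, st)
  expect_true(any(out@rearranged))
  expect_true(all(is.na(out@support[out@rearranged])))
})
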