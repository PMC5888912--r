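test_that("key-node support reads the separating edge and detects
          paraphyly", {
  # perfectly separated: outgroup clade vs ingroup clade
  gt <- parseNewick("((X|o1,X|o2),((A|1,B|1),A|2)98);")
  expect_identical(keyNodeSupport(gt, "X", c("A", "B")), 98)

  # ingroup paraphyletic with respect to the outgroup
  gt2 <- parseNewick("((A|1,X|o1)90,(A|2,B|1)80);")
  expect_identical(keyNodeSupport(gt2, "X", c("A", "B")), 0)

  expect_error(keyNodeSupport(gt, character(0), "A"), "non-empty")
  expect_error(keyNodeSupport(gt, "Z", "A"), "at least one gene")
})

test_that("key-node support agrees with a brute-force clade scan", {
  set.seed(71)
  for (i in 1:50) {
    species <- c("O1", "O2", LETTERS[1:4])
    gtPhy <- randomGeneTreePhylo(sample(5:9, 1L), species)
    sup <- sample(0:100, gtPhy$Nnode, replace = TRUE)
    gtPhy$node.label <- as.character(sup)
    gt <- parseNewick(ape::write.tree(gtPhy))
    sp <- speciesMap(gt)[treeOf(gt)$tip.label]
    outGenes <- treeOf(gt)$tip.label[sp %in% c("O1", "O2")]
    inGenes <- setdiff(treeOf(gt)$tip.label, outGenes)
    if (!length(outGenes) || !length(inGenes)) next

    got <- keyNodeSupport(gt, c("O1", "O2"), LETTERS[1:4])

    # brute force: scan every clade; the smallest containing all ingroup
    # genes and no outgroup genes
    phy <- treeOf(gt)
    ntip <- length(phy$tip.label)
    tipsBelow <- function(v) {
      if (v <= ntip) return(phy$tip.label[v])
      unlist(lapply(phy$edge[phy$edge[, 1] == v, 2], tipsBelow))
    }
    bestSize <- Inf; want <- 0
    for (v in seq_len(ntip + phy$Nnode)) {
      tl <- tipsBelow(v)
      if (all(inGenes %in% tl) && !any(outGenes %in% tl) &&
          length(tl) < bestSize) {
        bestSize <- length(tl)
        s <- supportValues(gt)[v]
        want <- if (is.na(s)) 0 else s
      }
    }
    expect_identical(got, want)
  }
})

test_that("orthogroup acceptance is inclusive at the threshold and
          monotone", {
  cfg <- pipelineConfig()
  expect_true(acceptOrthogroup(70, cfg))
  expect_false(acceptOrthogroup(69, cfg))
  expect_true(acceptOrthogroup(100, cfg))
  expect_error(acceptOrthogroup(101, cfg))
  sups <- sort(runif(20, 0, 100))
  acc <- vapply(sups, acceptOrthogroup, logical(1L), config = cfg)
  expect_true(all(diff(acc) >= 0))
})

test_that("ortholog counting tallies per species and zero-fills", {
  st <- speciesTreeFixture()
  genes <- c(paste0("Homo_sapiens|g", 1:4), "Gallus_gallus|g1")
  og <- Orthogroup("fam", genes, 85, defaultSpeciesMap(genes))
  cnt <- countOrthologs(og, st)
  expect_identical(cnt[["Homo_sapiens"]], 4L)
  expect_identical(cnt[["Gallus_gallus"]], 1L)
  expect_identical(cnt[["Ciona_savignyi"]], 0L)
  expect_identical(sum(cnt), length(genes))

  bad <- Orthogroup("f2", "Nessie|g1", 90, c(`Nessie|g1` = "Nessie"))
  expect_error(countOrthologs(bad, st), "absent")
})

test_that("published count table reproduces the printed totals and lineage
          averages exactly", {
  counts <- muscleOrthologTable()
  expect_identical(dim(counts), c(13L, 16L))
  totals <- rowSums(counts)
  expect_identical(totals[["Homo_sapiens"]], 58)
  expect_identical(totals[["Ciona_intestinalis"]], 24)
  expect_identical(totals[["Branchiostoma_belcheri"]], 45)

  census <- censusFromCounts(t(counts))
  st <- speciesTreeFixture()
  agg <- lineageAggregate(census, st, deuterostomeLineages())
  avg <- agg$lineageAverages
  expect_identical(avg[["hemichordata"]], 16.5)
  expect_identical(avg[["echinodermata"]], 16.0)
  expect_identical(avg[["ambulacraria"]], 16.2)
  expect_identical(avg[["cephalochordata"]], 37.0)
  expect_identical(avg[["urochordata"]], 31.0)
  expect_identical(avg[["vertebrata"]], 55.0)
  expect_identical(avg[["chordata"]], 38.5)
})

test_that("duplication placement conserves the duplication total", {
  st <- speciesTreeFixture()
  # the engineered 4-leaf duplication instance on two species
  gt <- parseNewick("((Gallus_gallus|a,Homo_sapiens|a),(Gallus_gallus|b,Homo_sapiens|b));")
  rr <- lcaReconcile(gt, st)
  pd <- placeDuplications(rr, st)
  vertStem <- mrca(st, c("Gallus_gallus", "Homo_sapiens"))
  expect_identical(pd[[as.character(vertStem)]], 1L)
  expect_identical(sum(pd), rr@D)

  # conservation on random reconciliations
  set.seed(72)
  for (i in 1:50) {
    sp <- randomSpeciesTree(sample(3:5, 1L))
    rr2 <- lcaReconcile(GeneTree(randomGeneTreePhylo(sample(4:8, 1L),
                                                     treeOf(sp)$tip.label)),
                        sp)
    expect_identical(sum(placeDuplications(rr2, sp)), rr2@D)
  }

  # D = 0 gives all-zero branch counts
  phy <- treeOf(st)
  phy$tip.label <- paste0(phy$tip.label, "|g1")
  rr0 <- lcaReconcile(GeneTree(phy), st)
  expect_true(all(placeDuplications(rr0, st) == 0L))
})

test_that("lineage aggregation splits peripheral from ancestral branches", {
  st <- speciesTreeFixture()
  # one duplication on the Homo terminal branch, one on the vertebrate stem
  gtTerm <- parseNewick("((Gallus_gallus|a,(Homo_sapiens|a,Homo_sapiens|b)),Ciona_savignyi|a);")
  rrTerm <- lcaReconcile(gtTerm, st)
  ogTerm <- Orthogroup("ft", treeOf(gtTerm)$tip.label, 90,
                       speciesMap(gtTerm))
  gtStem <- parseNewick("((Gallus_gallus|a,Homo_sapiens|a),(Gallus_gallus|b,Homo_sapiens|b));")
  rrStem <- lcaReconcile(gtStem, st)
  ogStem <- Orthogroup("fs", treeOf(gtStem)$tip.label, 90,
                       speciesMap(gtStem))
  census <- buildCensus(list(ogTerm, ogStem), list(rrTerm, rrStem), st)
  agg <- lineageAggregate(census, st)
  expect_identical(agg$dupPeripheral[["vertebrata"]], 1)   # Homo terminal
  expect_identical(agg$dupStem[["vertebrata"]], 1)         # vertebrate stem
  expect_identical(agg$nFamilies, 2L)
  expect_equal(agg$dupPerFamily[["vertebrata"]], 1)

  # single-species lineage average equals that species' total
  cnts <- matrix(c(3L, 5L), 1L, 2L,
                 dimnames = list("f", c("Homo_sapiens", "Gallus_gallus")))
  agg2 <- lineageAggregate(censusFromCounts(cnts), st,
                           list(homo = "Homo_sapiens",
                                gallus = "Gallus_gallus"))
  expect_identical(agg2$lineageAverages[["homo"]], 3)
  expect_error(lineageAggregate(censusFromCounts(cnts), st,
                                list(homo = "Homo_sapiens")),
               "missing")
})

test_that("census conservation: species counts sum to orthogroup size", {
  set.seed(73)
  st <- speciesTreeFixture()
  species <- treeOf(st)$tip.label
  for (i in 1:10) {
    genes <- paste0(sample(species, sample(3:12, 1L), replace = TRUE),
                    "|g", 1:100)[1:sample(3:12, 1L)]
    genes <- unique(genes)
    og <- Orthogroup(paste0("f", i), genes, 75, defaultSpeciesMap(genes))
    expect_identical(sum(countOrthologs(og, st)), length(genes))
  }
})
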