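# DHS atlas clustering, signature trees, combination enrichment and
# transcription classification.

gr1 <- function(starts, ends, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

test_that("single-linkage clustering forms overlap components", {
  # identical interval in every cell type: one ubiquitous cluster
  atlas <- list(a = gr1(100, 400), b = gr1(100, 400), c = gr1(100, 400))
  cl <- cluster_dhs(atlas)
  expect_length(cl, 1)
  expect_equal(cl$specificity, "ubiquitous")
  expect_equal(cl$k, 3L)

  # non-overlapping intervals: each cell-type-specific
  atlas2 <- list(a = gr1(100, 200), b = gr1(300, 400), c = gr1(500, 600))
  cl2 <- cluster_dhs(atlas2)
  expect_length(cl2, 3)
  expect_true(all(cl2$specificity == "cell_type_specific"))

  # chain: a-b overlap, b-c overlap, a-c none -> one cluster of all three
  atlas3 <- list(a = gr1(100, 250), b = gr1(200, 350), c = gr1(300, 450))
  cl3 <- cluster_dhs(atlas3)
  expect_length(cl3, 1)
  expect_equal(cl3$members, "a,b,c")
  expect_equal(GenomicRanges::start(cl3), 100)
  expect_equal(GenomicRanges::end(cl3), 450)

  # book-ended (touching) intervals do not link
  atlas4 <- list(a = gr1(100, 200), b = gr1(201, 300))
  expect_length(cluster_dhs(atlas4), 2)
})

test_that("cluster territory conserves the input union", {
  set.seed(21)
  atlas <- lapply(setNames(1:5, paste0("ct", 1:5)), function(i) {
    s <- sort(sample.int(50000, 30)) * 10
    GenomicRanges::reduce(gr1(s, s + sample(50:400, 30, TRUE)))
  })
  cl <- cluster_dhs(atlas)
  union <- GenomicRanges::reduce(suppressWarnings(
    do.call(c, unname(atlas))))
  expect_equal(sum(GenomicRanges::width(cl)),
               sum(GenomicRanges::width(union)))
  # specificity histogram sums to the cluster count
  expect_equal(sum(table(cl$k)), length(cl))
})

test_that("identical cell types are zero-distance sibling leaves", {
  atlas <- list(x1 = gr1(c(100, 900), c(300, 1100)),
                x2 = gr1(c(100, 900), c(300, 1100)),
                far = gr1(5000, 5300),
                far2 = gr1(c(5000, 7000), c(5300, 7300)))
  tree <- build_tree(cluster_dhs(atlas))
  d <- as.matrix(tree$dist)
  expect_equal(d["x1", "x2"], 0)
  # x1 and x2 merge first: cophenetic distance 0
  cd <- ape::cophenetic.phylo(tree$phylo)
  expect_equal(cd["x1", "x2"], 0)
  expect_gt(min(cd["x1", c("far", "far2")]), 0)
})

test_that("a clade-structured atlas recovers its topology with outgroup", {
  # two clades sharing archetypes: {a1,a2} and {g1,g2}; the g clade is
  # the outgroup
  mk <- function(idx) gr1(idx * 1000, idx * 1000 + 200)
  atlas <- list(a1 = mk(c(1, 2, 3, 7)), a2 = mk(c(1, 2, 3, 8)),
                g1 = mk(c(4, 5, 6, 9)), g2 = mk(c(4, 5, 6, 10)))
  tree <- build_tree(cluster_dhs(atlas), outgroup = c("g1", "g2"))
  phy <- tree$phylo
  expect_true(ape::is.monophyletic(phy, c("a1", "a2")))
  expect_true(ape::is.monophyletic(phy, c("g1", "g2")))
  # permuting cluster columns leaves distances unchanged
  m <- tree$matrix
  d2 <- stats::dist(m[, sample(ncol(m))])
  expect_equal(as.matrix(d2)[rownames(as.matrix(tree$dist)),
                             colnames(as.matrix(tree$dist))],
               as.matrix(tree$dist))
})

test_that("newick serialisation round-trips the topology", {
  atlas <- list(a = gr1(c(100, 500), c(200, 600)),
                b = gr1(c(100, 900), c(200, 1000)),
                c = gr1(2000, 2100))
  tree <- build_tree(cluster_dhs(atlas))
  nwk <- write_dhs_tree(tree)
  reread <- ape::read.tree(text = nwk)
  expect_setequal(reread$tip.label, c("a", "b", "c"))
  expect_equal(as.numeric(suppressWarnings(
    ape::dist.topo(ape::unroot(reread), ape::unroot(tree$phylo)))), 0)
  f <- tempfile(fileext = ".nwk")
  write_dhs_tree(tree, f)
  expect_equal(ape::read.tree(f)$tip.label, reread$tip.label)
})

test_that("combination enrichment splits series by focal membership", {
  set.seed(41)
  terr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200000))
  # focal-containing pairs and focal-absent pairs at k = 1 and 2
  atlas <- list(
    mel = gr1(seq(1000, 40000, 1000), seq(1000, 40000, 1000) + 150),
    oth = gr1(seq(1000, 20000, 1000) + 50,
              seq(1000, 20000, 1000) + 200),
    lone = gr1(seq(100000, 140000, 1000), seq(100000, 140000, 1000) + 150))
  cl <- cluster_dhs(atlas)
  v <- data.frame(chrom = "chr1", pos = sample.int(200000, 400))
  comb <- combination_enrichment(cl, "mel", v, terr, n_samplings = 100,
                                 seed = 6)
  expect_true(all(comb$k <= 3))
  expect_setequal(unique(comb$focal), c("containing", "absent"))
  # the k = 2 containing series is the mel+oth overlap clusters
  expect_equal(comb$n_clusters[comb$k == 2 & comb$focal == "containing"],
               20L)
})

test_that("variants avoiding all DHSs deplete every ungated series", {
  set.seed(51)
  terr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  atlas <- list(mel = gr1(seq(1000, 50000, 500), seq(1000, 50000, 500) + 300))
  cl <- cluster_dhs(atlas)
  # variants strictly outside all clusters
  pos <- sample(60000:100000, 300)
  comb <- combination_enrichment(cl, "mel",
                                 data.frame(chrom = "chr1", pos = pos),
                                 terr, n_samplings = 300, seed = 7,
                                 min_overlap = 0)
  ok <- !comb$gated & comb$focal == "containing"
  expect_true(all(comb$log2_enrichment[ok] < 0 | comb$observed[ok] == 0))
})

test_that("transcription flags honour the inclusive mapQ 30 threshold", {
  cl <- gr1(c(100, 1000, 2000), c(300, 1200, 2200))
  rna <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(150, 1050, 2050), width = 50),
    mapq = c(30, 29.99, 60))
  tx <- transcribed_dhs(cl, rna)
  expect_equal(tx, c(TRUE, FALSE, TRUE))
  expect_equal(transcribed_dhs(cl, rna[0]), rep(FALSE, 3))
})

test_that("the Fisher comparison matches the hypergeometric oracle", {
  r <- compare_transcription(rep(c(TRUE, FALSE), c(10, 0)),
                             rep(c(TRUE, FALSE), c(0, 10)))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(round(r$p_value, 10), 1.082e-05, tolerance = 1e-3)
  even <- compare_transcription(rep(c(TRUE, FALSE), c(5, 5)),
                                rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(even$p_value, 1)
})
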