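# Landmark partitioning, chromatin-state masks, constraint tiling,
# regression and transcript-distance profiles.

test_that("the landmark hierarchy claims bases in priority order", {
  gm <- toy_genes()
  genome <- c(chr1 = 100000L)
  part <- partition_by_landmark(gm, genome)
  # disjoint and, with unassigned, tiling the genome exactly
  cats <- unclass(part)
  total <- sum(vapply(cats, function(g) {
    sum(GenomicRanges::width(g))
  }, numeric(1)))
  expect_equal(total, 100000)
  all_gr <- suppressWarnings(do.call(c, unname(cats)))
  expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(all_gr))),
               100000)

  # an interval overlapping both coding and intron is coding
  targets <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1480, 1600, 5500, 50000),
                             c(1520, 1700, 5600, 50100)))
  lab <- partition_by_landmark(gm, genome, targets = targets)
  expect_equal(as.character(lab),
               c("coding", "intron", "tss_proximal", "tss_distal"))
})

test_that("the TSS-proximal window is inclusive at 5000 bp", {
  gm <- toy_genes()
  genome <- c(chr1 = 100000L)
  part <- partition_by_landmark(gm, genome)
  # gA TSS at 1001; intergenic bases 1..1000 are within 5000
  expect_true(positions_in_mask("chr1", 1000, part$tss_proximal))
  # gB TSS at 26000: 26000 + 5000 = 31000 proximal, 31001 distal
  expect_true(positions_in_mask("chr1", 31000, part$tss_proximal))
  expect_true(positions_in_mask("chr1", 31001, part$tss_distal))
})

test_that("partition matches brute-force per-base labels on random fixtures", {
  set.seed(300)
  for (rep in 1:20) {
    L <- 30000L
    g_start <- sample(2000:8000, 1)
    g_len <- sample(3000:8000, 1)
    strand <- sample(c("+", "-"), 1)
    cds <- IRanges::IRanges(g_start + 500, g_start + 1500)
    u5 <- IRanges::IRanges(g_start, g_start + 499)
    u3 <- IRanges::IRanges(g_start + g_len - 300, g_start + g_len - 1)
    gm <- gene_models(
      GenomicRanges::GRanges("chr1",
                             IRanges::IRanges(g_start,
                                              g_start + g_len - 1),
                             strand = strand, gene_id = "g"),
      GenomicRanges::GRanges("chr1", c(u5, cds, u3),
                             strand = strand,
                             gene_id = c("g", "g", "g"),
                             type = c("utr5", "cds", "utr3")),
      GenomicRanges::GRanges("chr1",
                             IRanges::IRanges(
                               if (strand == "+") g_start else
                                 g_start + g_len - 1,
                               width = 1),
                             strand = strand, gene_id = "g"))
    part <- partition_by_landmark(gm, c(chr1 = L))

    # independent per-base labelling
    lab <- rep("tss_distal", L)
    tss <- if (strand == "+") g_start else g_start + g_len - 1
    prox <- max(1, tss - 5000):min(L, tss + 5000)
    lab[prox] <- "tss_proximal"
    lab[g_start:(g_start + g_len - 1)] <- "intron"
    lab[IRanges::start(u3):IRanges::end(u3)] <- "utr3"
    lab[IRanges::start(u5):IRanges::end(u5)] <- "utr5"
    lab[IRanges::start(cds):IRanges::end(cds)] <- "coding"
    for (cat in c("coding", "utr5", "utr3", "intron", "tss_proximal",
                  "tss_distal")) {
      expect_equal(sum(GenomicRanges::width(part[[cat]])),
                   sum(lab == cat), label = paste(rep, cat))
    }
  }
})

test_that("repeat states are dropped and the rest conserved", {
  states <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 101, 201, 301), c(100, 200, 300, 400)),
    state = c(13L, 14L, 15L, 2L))
  masks <- chromatin_state_mask(states)
  expect_equal(names(masks), c("state2", "state13"))
  expect_equal(sum(vapply(masks, function(m) {
    sum(GenomicRanges::width(m))
  }, numeric(1))), 200)
  only14 <- chromatin_state_mask(states[states$state == 14L])
  expect_length(only14, 0)
})

test_that("non-genic tiles are masked, binned and remainder-packed", {
  # one gene at 100001..120000 with its TSS; 10 kb flank masks
  gm <- gene_models(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 120000),
                           strand = "+", gene_id = "g"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 101000),
                           strand = "+", gene_id = "g", type = "cds"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 100001),
                           strand = "+", gene_id = "g"))
  genome <- c(chr1 = 1000000L)
  constrained <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 999000, by = 1000), width = 50))
  bins <- nongenic_constraint_bins(gm, constrained, genome)
  gr <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start, bins$end))
  masked <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90001, 130000))
  expect_false(any(IRanges::overlapsAny(gr, masked)))
  expect_true(all(bins$constrained_fraction > 0))
  # tiles sorted ascending by constraint within the bin order
  expect_true(!is.unsorted(bins$constrained_fraction))

  # remainder rule: 13 surviving tiles -> 9 bins of 1 and a last bin of 4
  toy <- nongenic_constraint_bins(
    gm, constrained, c(chr1 = 780000L))
  n <- nrow(toy)
  size <- n %/% 10
  expect_equal(as.vector(table(toy$bin)),
               c(rep(size, 9), n - 9 * size))
})

test_that("regression recovers a planted transcribed-fraction slope", {
  set.seed(19)
  n <- 60
  d <- data.frame(constraint = runif(n), gc = runif(n, 0.3, 0.6),
                  transcribed = runif(n))
  d$response <- 50 - 12 * d$transcribed + rnorm(n, sd = 1)
  fit <- regress_mutation_rate(d)
  co <- fit$coefficients
  b <- co[co$term == "transcribed", ]
  expect_lt(abs(b$estimate - (-12)), 3 * b$std.error + 0.5)
  expect_lt(fit$spearman_transcribed, -0.8)

  # constant response: all slopes zero (perfect fit warns harmlessly)
  d0 <- d; d0$response <- 5
  co0 <- suppressWarnings(regress_mutation_rate(d0)$coefficients)
  expect_true(all(abs(co0$estimate) < 1e-9))

  # perfectly anti-correlated covariate
  d1 <- d; d1$response <- -d1$transcribed
  expect_equal(suppressWarnings(
    regress_mutation_rate(d1)$spearman_transcribed), -1)
})

test_that("transcript distance profiles honour strand and bins", {
  gm <- toy_genes()
  # gA: TSS 1001 (+); gB: TSS 26000 (-)
  v <- data.frame(chrom = "chr1", pos = c(1002, 25999, 20500))
  prof <- transcript_distance_profile(v, gm)
  # 1002 is TSS+1 -> bin 0; 25999 is 1 bp along gB -> bin 0;
  # 20500 is 5500 bp along gB -> bin 1
  expect_equal(prof$count[prof$bin == 0], 2L)
  expect_equal(prof$count[prof$bin == 1], 1L)
  # territory in bin 0: gA contributes 4000 bp, gB the full 5000 bp bin
  expect_equal(prof$territory[prof$bin == 0], 9000)

  # uniformly planted variants give a flat profile within Poisson noise
  set.seed(4)
  one_gene <- gene_models(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000),
                           strand = "+", gene_id = "g"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100),
                           strand = "+", gene_id = "g", type = "cds"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1001),
                           strand = "+", gene_id = "g"))
  u <- data.frame(chrom = "chr1",
                  pos = sample(1001:5000, 400, replace = TRUE))
  pr <- transcript_distance_profile(u, one_gene, bin_width = 1000)
  rates <- pr$rate_per_mb[pr$bin %in% 0:3]
  expect_lt(max(abs(rates - mean(rates))) / mean(rates), 0.5)
})

test_that("per-state rates are count over territory", {
  masks <- list(stateA = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 1000000)),
    stateB = GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(2000001, 2500000)))
  v <- data.frame(chrom = "chr1", pos = c(seq(1, 999959, length.out = 42),
                                          2100000))
  r <- per_state_rate(v, masks)
  expect_equal(r$rate_per_mb[r$state == "stateA"], 42)
  expect_equal(r$rate_per_mb[r$state == "stateB"], 2)
  empty <- per_state_rate(v[0, ], masks)
  expect_equal(empty$count, c(0L, 0L))
  expect_equal(empty$territory_mb, c(1, 0.5))
})
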