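# Synthetic tumor/normal generator: determinism, composition, allele
# fractions, UV spectrum, annotation structure and the validation fixtures.

small_cfg <- function(...) {
  sim_config(genome_length = 100000, n_chroms = 2, seed = 7, ...)
}

test_that("reference simulation is deterministic and respects composition", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  expect_equal(length(r1), 2L)
  expect_equal(names(r1), c("chr1", "chr2"))

  big <- sim_config(genome_length = 1e6, n_chroms = 1, seed = 3)
  ref <- simulate_reference(big)
  gc <- sum(Biostrings::letterFrequency(ref[[1]], c("G", "C")))
  p <- big$base_comp[["G"]] + big$base_comp[["C"]]
  sd <- sqrt(1e6 * p * (1 - p))
  expect_lt(abs(gc - 1e6 * p), 5 * sd)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(genome_length = 0), "positive")
  expect_error(sim_config(purity = c(t = 1.2)), "purity")
  expect_error(sim_config(somatic_rate = -1), "non-negative")
  expect_error(sim_config(
    genome_length = 2e6, n_chroms = 2,
    cnv_spec = data.frame(chrom = "chr1", start = c(1, 50), end = c(100, 90),
                          cn = 3, sample = "tissue")), "disjoint")
})

test_that("truth sets are reproducible and structurally consistent", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  t1 <- simulate_truth(cfg, ref)
  t2 <- simulate_truth(cfg, ref)
  expect_identical(t1, t2)
  # somatic positions disjoint from germline, alt always differs from ref
  expect_length(intersect(paste0(t1$somatic$chrom, ":", t1$somatic$pos),
                          paste0(t1$germline$chrom, ":", t1$germline$pos)),
                0)
  expect_true(all(t1$somatic$alt != t1$somatic$ref))
  rc <- strsplit(as.character(ref[["chr1"]]), "")[[1]]
  s1 <- t1$somatic[t1$somatic$chrom == "chr1", ]
  expect_equal(rc[s1$pos], s1$ref)
})

test_that("planted somatic density per Mb matches the Poisson expectation", {
  cfg <- sim_config(genome_length = 2e6, n_chroms = 3, seed = 21)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  # per-sample load: shared + sample-specific
  for (s in names(cfg$purity)) {
    n <- sum(truth$somatic$origin %in% c("shared", s))
    lambda <- 6 * cfg$somatic_rate
    expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  }
})

test_that("uv_fraction 1 collapses every somatic SSNV to the C>T class", {
  cfg <- sim_config(genome_length = 200000, n_chroms = 1, uv_fraction = 1,
                    seed = 5)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  key <- paste0(truth$somatic$ref, ">", truth$somatic$alt)
  expect_true(all(key %in% c("C>T", "G>A")))
})

test_that("per-read pileups track purity: pure tumor 0.5, 42% normal 0.29", {
  for (case in list(list(purity = 1.0, expect = 0.5),
                    list(purity = 0.58, expect = 0.29))) {
    cfg <- sim_config(genome_length = 50000, n_chroms = 1,
                      purity = c(tumor = case$purity),
                      mean_depth = c(normal = 48, tumor = 1000),
                      somatic_rate = 200, seed = 13)
    ref <- simulate_reference(cfg)
    truth <- simulate_truth(cfg, ref)
    som <- truth$somatic[truth$somatic$chrom == "chr1", ]
    piles <- simulate_pileups(ref, truth, cfg, "tumor", "chr1",
                              positions = som$pos)
    fracs <- vapply(seq_len(nrow(som)), function(i) {
      r <- piles[[i]]$reads
      mean(r$base == som$alt[i])
    }, numeric(1))
    n_tot <- sum(vapply(piles, function(p) nrow(p$reads), numeric(1)))
    sd3 <- 3 * sqrt(case$expect * (1 - case$expect) / n_tot)
    expect_lt(abs(mean(fracs) - case$expect), sd3 + 0.005)
  }
})

test_that("base error rate follows the Phred model at hom-ref sites", {
  cfg <- sim_config(genome_length = 20000, n_chroms = 1,
                    purity = c(tumor = 1),
                    base_q_model = c("20" = 1), mean_depth = c(normal = 50,
                                                               tumor = 50),
                    germline_het_rate = 0, somatic_rate = 0, seed = 2)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  piles <- simulate_pileups(ref, truth, cfg, "tumor", "chr1",
                            positions = seq(1, 20000, by = 10))
  nonref <- vapply(seq_along(piles), function(i) {
    sum(piles[[i]]$reads$base != piles[[i]]$ref)
  }, numeric(1))
  depth <- vapply(piles, function(p) nrow(p$reads), numeric(1))
  rate <- sum(nonref) / sum(depth)
  sd3 <- 3 * sqrt(0.01 * 0.99 / sum(depth))
  expect_lt(abs(rate - 0.01), sd3)
})

test_that("compact count matrices agree with the scoring layout", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  pm <- simulate_pileup_matrix(ref, truth, cfg, "tissue", "chr1")
  expect_identical(dim(pm$counts),
                   c(cfg$genome_length, 4L * length(pm$quals)))
  expect_identical(as.integer(rowSums(pm$counts)), pm$depth)
  # identical seed => identical evidence
  pm2 <- simulate_pileup_matrix(ref, truth, cfg, "tissue", "chr1")
  expect_identical(pm, pm2)
  # somatic alt fraction converges to purity/2 in diploid territory
  vs <- pm$variant_sites
  som <- vs[vs$origin_type == "somatic", ]
  p_exp <- cfg$purity[["tissue"]] / 2
  n_reads <- sum(som$depth)
  expect_lt(abs(sum(som$alt_count) / n_reads - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / n_reads))
})

test_that("copy number scales depth and allele fractions in CNV segments", {
  cnv <- data.frame(chrom = "chr1", start = 1L, end = 50000L, cn = 4L,
                    sample = "tumor")
  cfg <- sim_config(genome_length = 100000, n_chroms = 1,
                    purity = c(tumor = 1), cnv_spec = cnv,
                    mean_depth = c(normal = 30, tumor = 30), seed = 9)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  pm <- simulate_pileup_matrix(ref, truth, cfg, "tumor", "chr1")
  inside <- mean(pm$depth[1:50000] + pm$n_low[1:50000])
  outside <- mean(pm$depth[50001:100000] + pm$n_low[50001:100000])
  expect_equal(inside / outside, 2, tolerance = 0.05)
  som <- pm$variant_sites[pm$variant_sites$origin_type == "somatic", ]
  in_cnv <- som$pos <= 50000
  if (any(in_cnv)) {
    # one mutated copy out of four
    expect_lt(abs(mean(som$alt_count[in_cnv] / som$depth[in_cnv]) - 0.25),
              0.12)
  }
})

test_that("annotation landscapes have the promised structure", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 1, seed = 31)
  ref <- simulate_reference(cfg)
  ann <- simulate_annotations(ref, cfg)

  # chromatin states partition the chromosome
  expect_equal(sum(GenomicRanges::width(ann$states)), 1e6)
  expect_true(all(GenomicRanges::start(ann$states)[-1] ==
                    head(GenomicRanges::end(ann$states), -1) + 1))

  # exon sub-features nest within genes
  within <- GenomicRanges::findOverlaps(ann$genes$exons, ann$genes$genes,
                                        type = "within",
                                        ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(within))),
               length(ann$genes$exons))

  # per-type DHS interval sets are non-overlapping
  for (ct in names(ann$dhs)) {
    expect_true(all(GenomicRanges::countOverlaps(ann$dhs[[ct]],
                                                 ann$dhs[[ct]]) == 1L))
  }
})

test_that("DHS sharing structure is controllable", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 1, seed = 17)
  ref <- simulate_reference(cfg)
  # everything ubiquitous: all cell-type sets identical
  ann_u <- simulate_annotations(ref, cfg,
                                ann_config(dhs_ubiq_frac = 1,
                                           dhs_specific_frac = 0))
  first <- ann_u$dhs[[1]]
  for (ct in names(ann_u$dhs)) {
    expect_identical(GenomicRanges::ranges(ann_u$dhs[[ct]]),
                     GenomicRanges::ranges(first))
  }
  # exactly k focal-specific archetypes on request
  ann_k <- simulate_annotations(ref, cfg,
                                ann_config(dhs_focal_specific = 7))
  others <- GenomicRanges::reduce(suppressWarnings(do.call(
    c, unname(ann_k$dhs[setdiff(names(ann_k$dhs), "melano")]))))
  only_mel <- sum(!IRanges::overlapsAny(ann_k$dhs[["melano"]], others))
  expect_equal(only_mel, 7L)
})

test_that("validation fixtures encode the Sanger outcomes", {
  tis <- make_validation_fixture("tissue")
  expect_equal(nrow(tis$variants), 73L)
  expect_equal(sum(tis$variants$sanger_concordant), 43L)
  expect_equal(sum(!tis$variants$sanger_concordant), 30L)
  cc <- make_validation_fixture("cell_culture")
  expect_equal(nrow(cc$variants), 78L)
  expect_equal(sum(cc$variants$sanger_concordant), 75L)
  expect_equal(sum(!cc$variants$sanger_concordant), 3L)
  # every variant has evidence at its site
  keys <- paste0(tis$variants$chrom, ":", tis$variants$pos)
  expect_true(all(keys %in% names(tis$normal_evidence)))
  expect_true(all(keys %in% names(tis$tumor_evidence)))
})
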