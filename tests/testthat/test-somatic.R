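# Somatic SSNV detection rules, the three-filter validation cascade,
# callset comparison and somatic indel calling.

mk_tumor <- function(pos, var_gt, mpv = 50, ref = "A", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, var_genotype = var_gt,
             mpv = mpv, stringsAsFactors = FALSE)
}
mk_normal <- function(pos, gt, mpg = 40, ratio = 0.7, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, genotype = gt, mpg = mpg,
             ratio = ratio, stringsAsFactors = FALSE)
}

test_that("somatic subtraction keeps novel alleles and drops LOH", {
  tumor <- mk_tumor(c(100, 200, 300), c("AG", "AA", "AG"))
  normal <- mk_normal(c(100, 200, 300), c("AA", "AG", "AG"))
  out <- detect_ssnv(tumor, normal)
  # 100: novel G; 200: tumor AA subset of normal AG (LOH) dropped;
  # 300: same genotype, nothing novel
  expect_equal(out$pos, 100)
  expect_equal(out$somatic_allele, "G")
})

test_that("known variants and indel-proximal sites are subtracted", {
  tumor <- mk_tumor(c(100, 200, 300, 400), rep("AG", 4))
  normal <- mk_normal(c(100, 200, 300, 400), rep("AA", 4))
  known <- data.frame(chrom = "chr1", pos = 200)
  indels <- data.frame(chrom = "chr1", pos = c(110, 311))
  out <- detect_ssnv(tumor, normal, known, indels)
  # 100 is 10 bp from the indel at 110 (inclusive window) -> removed;
  # 200 is known; 300 is 11 bp from 311 -> kept; 400 untouched
  expect_equal(out$pos, c(300, 400))
})

test_that("uncallable sites in either sample are not somatic", {
  tumor <- mk_tumor(c(100, 200, 300), rep("AG", 3),
                    mpv = c(9.99, 10, 50))
  normal <- mk_normal(c(100, 200, 300), rep("AA", 3),
                      mpg = c(40, 40, 9), ratio = c(0.7, 0.7, 0.7))
  out <- detect_ssnv(tumor, normal)
  expect_equal(out$pos, 200)
  expect_error(detect_ssnv(mk_tumor(c(200, 100), c("AG", "AG")),
                           mk_normal(c(100, 200), c("AA", "AA"))),
               "sorted")
})

test_that("the filter cascade reproduces the tissue validation outcomes", {
  fx <- make_validation_fixture("tissue")
  res <- apply_validation_filters(fx$variants, fx$normal_evidence,
                                  fx$tumor_evidence, fx$indels)
  conc <- fx$variants$sanger_concordant
  expect_equal(sum(!res$pass & !conc), 29L)   # 29 of 30 discordant removed
  expect_equal(sum(!res$pass & conc), 0L)     # 0 of 43 concordant removed
  s <- validation_summary(res)
  expect_equal(s$post_filter_concordance_pct, 100 * 43 / 44,
               tolerance = 1e-12)
})

test_that("the filter cascade reproduces the cell-culture outcomes", {
  fx <- make_validation_fixture("cell_culture")
  res <- apply_validation_filters(fx$variants, fx$normal_evidence,
                                  fx$tumor_evidence, fx$indels)
  conc <- fx$variants$sanger_concordant
  expect_equal(sum(!res$pass & !conc), 2L)
  expect_equal(sum(!res$pass & conc), 0L)
  expect_equal(validation_summary(res)$post_filter_concordance_pct,
               100 * 75 / 76, tolerance = 1e-12)
})

test_that("strand bias requires >= 2 one-strand somatic reads", {
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A",
                  somatic_allele = "G", stringsAsFactors = FALSE)
  ev <- data.frame(normal_alt_mapq1 = c(0, 0, 0),
                   tumor_alt_plus = c(5, 1, 3),
                   tumor_alt_minus = c(0, 0, 2))
  res <- apply_validation_filters(v, ev)
  expect_equal(res$flag_strand_bias, c(TRUE, FALSE, FALSE))
})

test_that("filters are idempotent and flag evidence as specified", {
  fx <- make_validation_fixture("tissue")
  r1 <- apply_validation_filters(fx$variants, fx$normal_evidence,
                                 fx$tumor_evidence, fx$indels)
  r2 <- apply_validation_filters(
    as.data.frame(r1)[names(fx$variants)], fx$normal_evidence,
    fx$tumor_evidence, fx$indels)
  expect_equal(r1$pass, r2$pass)
  expect_equal(r1$flag_normal_lookup, r2$flag_normal_lookup)
  # missing evidence is an error naming the site
  expect_error(apply_validation_filters(fx$variants,
                                        fx$normal_evidence[-1],
                                        fx$tumor_evidence, fx$indels),
               "chrT:1500")
})

test_that("callset comparison restricts to common territory", {
  a <- data.frame(chrom = "chr1", pos = c(1, 2, 3))
  b <- data.frame(chrom = "chr1", pos = c(2, 3, 4))
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  cmp <- compare_callsets(a, b, full)
  expect_equal(cmp$shared, 2L)
  expect_equal(cmp$union, 4L)
  expect_equal(cmp$shared_frac, 0.5)
  # symmetry under label swap
  cmp_rev <- compare_callsets(b, a, full)
  expect_equal(cmp_rev$shared_frac, cmp$shared_frac)
  expect_equal(cmp_rev$a_only, cmp$b_only)
  # disjoint masks give an explicit empty comparison
  empty_mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
  cmp0 <- compare_callsets(a, b, empty_mask)
  expect_equal(cmp0$union, 0L)
  expect_true(is.na(cmp0$shared_frac))
  # identical callsets are 100% shared
  expect_equal(compare_callsets(a, a, full)$shared_frac, 1)
})

test_that("somatic indels require tumor support differing from normal", {
  tumor <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                      size = c(1L, -1L, 2L, 1L, -2L),
                      score = c(30, 30, 30, 9, 30))
  normal <- data.frame(chrom = "chr1", pos = c(20, 30),
                       size = c(-1L, 1L), score = c(30, 30))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 45))
  res <- detect_somatic_indels(tumor, normal, mask)
  # 10: somatic; 20: matches normal; 30: differs from normal (size) ->
  # somatic; 40: below score; 50: outside the non-CNV mask
  expect_equal(res$somatic$pos, c(10, 30))
  expect_equal(as.vector(res$size_histogram), c(1L, 1L))
  # CNV exclusion of an otherwise somatic call
  res_all <- detect_somatic_indels(tumor, normal, NULL)
  expect_true(50 %in% res_all$somatic$pos)
})

test_that("simulated somatic recall and precision are high in a pure tumor", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 2, seed = 27,
                    purity = c(culture = 1.0),
                    mean_depth = c(normal = 48, tumor = 30),
                    cnv_spec = data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer(), cn = integer(),
                                          sample = character()))
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  found <- list(); truth_keys <- character()
  for (chrom in c("chr1", "chr2")) {
    pm_n <- simulate_pileup_matrix(ref, truth, cfg, "normal", chrom)
    pm_t <- simulate_pileup_matrix(ref, truth, cfg, "culture", chrom)
    cn <- score_sites(pm_n$counts, pm_n$ref, pm_n$quals)
    ct <- score_sites(pm_t$counts, pm_t$ref, pm_t$quals)
    idx <- which(!is.na(ct$mpv) & ct$mpv >= 10)
    tumor_calls <- data.frame(chrom = chrom, pos = idx,
                              ref = pm_t$ref[idx],
                              var_genotype = ct$var_genotype[idx],
                              mpv = ct$mpv[idx], stringsAsFactors = FALSE)
    normal_calls <- data.frame(chrom = chrom, pos = idx,
                               genotype = cn$genotype[idx],
                               mpg = cn$mpg[idx], ratio = cn$ratio[idx],
                               stringsAsFactors = FALSE)
    known <- truth$germline[truth$germline$known &
                              truth$germline$chrom == chrom,
                            c("chrom", "pos")]
    found[[chrom]] <- detect_ssnv(tumor_calls, normal_calls, known,
                                  truth$indels[truth$indels$chrom == chrom,
                                               c("chrom", "pos")])
  }
  calls <- do.call(rbind, found)
  call_keys <- paste0(calls$chrom, ":", calls$pos)
  tr <- truth$somatic
  truth_keys <- paste0(tr$chrom, ":", tr$pos)
  recall <- mean(truth_keys %in% call_keys)
  precision <- mean(call_keys %in% truth_keys)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.99)
})
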