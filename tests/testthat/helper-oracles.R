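# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: straight loops over reads and genotypes
# with probabilities multiplied on the natural scale.

ORACLE_GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT",
                      "GG", "GT", "TT")

# brute-force flat-prior posterior over the ten diploid genotypes
oracle_posteriors <- function(base, baseq) {
  lik <- numeric(length(ORACLE_GENOTYPES))
  for (g in seq_along(ORACLE_GENOTYPES)) {
    a1 <- substr(ORACLE_GENOTYPES[g], 1, 1)
    a2 <- substr(ORACLE_GENOTYPES[g], 2, 2)
    p <- 1
    for (i in seq_along(base)) {
      e <- 10^(-baseq[i] / 10)
      p1 <- if (base[i] == a1) 1 - e else e / 3
      p2 <- if (base[i] == a2) 1 - e else e / 3
      p <- p * (0.5 * p1 + 0.5 * p2)
    }
    lik[g] <- p
  }
  stats::setNames(lik / sum(lik), ORACLE_GENOTYPES)
}

oracle_mpg_score <- function(post) {
  s <- sort(post, decreasing = TRUE)
  log(s[[1]] / s[[2]])
}

oracle_mpv_score <- function(post, ref) {
  rr <- paste0(ref, ref)
  log(sum(post[names(post) != rr]) / post[[rr]])
}

# random read stack at one site
random_stack <- function(max_depth = 50, quals = c(20, 25, 30, 35, 40)) {
  n <- sample.int(max_depth, 1)
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  frac <- sample(c(0, 0.1, 0.3, 0.5, 1), 1)
  base <- ifelse(runif(n) < frac, alt, ref)
  flip <- runif(n) < 0.02
  base[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
  list(ref = ref, base = base,
       baseq = sample(quals, n, replace = TRUE),
       mapq = rep(60, n),
       strand = sample(c("+", "-"), n, replace = TRUE))
}

stack_to_site <- function(st, chrom = "chr1", pos = 100) {
  site_evidence(chrom, pos, st$ref, base = st$base, baseq = st$baseq,
                mapq = st$mapq, strand = st$strand)
}

# read stack -> count matrix row in score_sites() layout
stack_to_counts <- function(st, quals) {
  m <- matrix(0L, 1, 4L * length(quals))
  for (i in seq_along(st$base)) {
    j <- match(st$baseq[i], quals)
    b <- match(st$base[i], c("A", "C", "G", "T"))
    m[1, (j - 1L) * 4L + b] <- m[1, (j - 1L) * 4L + b] + 1L
  }
  m
}

# tiles with prescribed log2 ratios on one chromosome (5 kb grid)
mk_tiles <- function(log2r, chrom = "chr1") {
  n <- length(log2r)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 5000L + 1L,
             end = seq_len(n) * 5000L, normal_depth = 30,
             tumor_depth = 30 * 2^ifelse(is.na(log2r), 0, log2r),
             mappable_fraction = ifelse(is.na(log2r), 0.5, 1),
             log2_ratio = log2r, stringsAsFactors = FALSE)
}

# independent run-length encoding of thresholded tiles
oracle_segments <- function(log2r, amp = 0.25, del = -0.25) {
  lab <- ifelse(is.na(log2r), "na",
                ifelse(log2r >= amp, "amp",
                       ifelse(log2r <= del, "del", "neutral")))
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("amp", "del") & r$lengths >= 2
  data.frame(first = starts[keep], last = ends[keep],
             direction = r$values[keep])
}

# small deterministic gene-model fixture: two genes on chr1 (one per
# strand) with explicit cds/utr sub-features
toy_genes <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 20001), c(5000, 26000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1001, 1101, 3001, 4501, 20001, 23001, 25801),
                     c(1100, 1500, 3400, 5000, 20400, 23500, 26000)),
    strand = c("+", "+", "+", "+", "-", "-", "-"),
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB"),
    type = c("utr5", "cds", "cds", "utr3", "utr3", "cds", "utr5"))
  tss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 26000), c(1001, 26000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  gene_models(genes, exons, tss)
}
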