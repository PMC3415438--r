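# Bayesian per-site genotype (MPG) and variant (MPV) scoring.
#
# Model: diploid genotype g = {a1, a2} over {A,C,G,T} (10 unordered pairs).
# Per-read likelihood of observed base b with Phred quality Q:
#   P(b | g) = 0.5 * P(b | a1) + 0.5 * P(b | a2)
#   P(b | a) = 1 - e  if b == a,  e / 3 otherwise,  e = 10^(-Q/10)
# Flat prior over the 10 genotypes. The MPG score is the natural-log
# posterior odds of the best genotype versus the second best; the MPV score
# is the natural-log odds of any non-reference genotype versus homozygous
# reference. Natural-log units make the quoted callability thresholds
# jointly satisfiable: a concordant read contributes ln(2) = 0.69 to a
# hom-ref MPG score, so score/depth reaches the 0.5 coverage-ratio
# criterion, and score >= 10 corresponds to roughly 15 concordant reads.

BASES <- c("A", "C", "G", "T")

#' The ten diploid genotypes in lexicographic order
#'
#' Lexicographic order fixes tie-breaking: when two genotypes are equally
#' probable the earlier one is reported and the score is 0 (uncallable).
#'
#' @return Character vector of the 10 unordered diploid genotypes.
#' @export
genotypes <- function() {
  c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
}

# 10 x 2 allele matrix matching genotypes()
gt_allele_matrix <- function() {
  gts <- genotypes()
  cbind(substr(gts, 1, 1), substr(gts, 2, 2))
}

# Score clamp applied when posterior mass underflows (natural-log odds)
MPG_SCORE_CAP <- 255

#' Construct per-site read evidence
#'
#' A pileup column for one sample: the observed base, Phred base quality,
#' Phred mapping quality and strand of every read covering a position.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref Reference base at the position.
#' @param base Character vector of observed bases (`A`,`C`,`G`,`T`,`N`).
#' @param baseq Numeric vector of Phred base qualities.
#' @param mapq Numeric vector of Phred mapping qualities.
#' @param strand Character vector of read strands (`+`/`-`).
#' @return A `site_evidence` object.
#' @export
site_evidence <- function(chrom, pos, ref, base = character(),
                          baseq = numeric(), mapq = numeric(),
                          strand = character()) {
  n <- length(base)
  stopifnot(length(baseq) == n, length(mapq) == n, length(strand) == n)
  if (n && !all(base %in% c(BASES, "N"))) {
    stop("observed bases must be one of A, C, G, T, N")
  }
  if (n && (any(baseq < 0) || any(mapq < 0))) stop("qualities must be >= 0")
  structure(
    list(chrom = chrom, pos = as.integer(pos), ref = ref,
         reads = data.frame(base = base, baseq = as.numeric(baseq),
                            mapq = as.numeric(mapq), strand = strand,
                            stringsAsFactors = FALSE)),
    class = "site_evidence")
}

#' @export
print.site_evidence <- function(x, ...) {
  cat(sprintf("<site_evidence> %s:%d ref=%s depth=%d\n",
              x$chrom, x$pos, x$ref, nrow(x$reads)))
  invisible(x)
}

#' Filter read evidence on mapping and base quality
#'
#' Retains reads with mapping quality at or above `min_mapq` and base quality
#' at or above `min_baseq` (both inclusive); `N` bases are always dropped.
#' Defaults are the calling thresholds used throughout: mapQ >= 30,
#' baseQ >= 20.
#'
#' @param site A [site_evidence()] object.
#' @param min_mapq Minimum mapping quality retained (inclusive).
#' @param min_baseq Minimum base quality retained (inclusive).
#' @return A `site_evidence` object containing only retained reads.
#' @export
filter_evidence <- function(site, min_mapq = 30, min_baseq = 20) {
  stopifnot(inherits(site, "site_evidence"))
  r <- site$reads
  keep <- r$mapq >= min_mapq & r$baseq >= min_baseq & r$base != "N"
  site$reads <- r[keep, , drop = FALSE]
  rownames(site$reads) <- NULL
  site
}

# log-likelihood matrix: rows index (quality tier, base) pairs laid out
# base-fastest (tier j, base b) -> row (j-1)*4 + b; columns the 10 genotypes.
geno_loglik_matrix <- function(quals) {
  al <- gt_allele_matrix()
  nq <- length(quals)
  L <- matrix(NA_real_, nrow = 4L * nq, ncol = 10L)
  for (j in seq_len(nq)) {
    e <- 10^(-quals[j] / 10)
    for (b in 1:4) {
      pb <- ifelse(BASES[b] == al[, 1], 1 - e, e / 3) / 2 +
            ifelse(BASES[b] == al[, 2], 1 - e, e / 3) / 2
      L[(j - 1L) * 4L + b, ] <- log(pb)
    }
  }
  L
}

# per-site genotype log-likelihoods from a read data.frame (assumed filtered)
site_logliks <- function(reads) {
  quals <- sort(unique(reads$baseq))
  counts <- table(factor(match(reads$baseq, quals), levels = seq_along(quals)),
                  factor(match(reads$base, BASES), levels = 1:4))
  cvec <- as.vector(t(counts))  # base-fastest within tier
  drop(cvec %*% geno_loglik_matrix(quals))
}

#' Posterior distribution over the ten diploid genotypes
#'
#' Computes the flat-prior posterior over the 10 diploid genotypes from
#' already-filtered evidence. With zero retained reads there is no
#' information and `NULL` (the no-call sentinel) is returned.
#'
#' @param site A filtered [site_evidence()] object.
#' @return Named numeric vector of 10 posterior probabilities summing to 1,
#'   or `NULL` when no reads remain.
#' @export
genotype_posteriors <- function(site) {
  stopifnot(inherits(site, "site_evidence"))
  if (nrow(site$reads) == 0L) return(NULL)
  ll <- site_logliks(site$reads)
  post <- exp(ll - max(ll))
  setNames(post / sum(post), genotypes())
}

# top-two log-likelihood gap and argmax (lexicographic tie-break = first max)
top_two <- function(ll) {
  i1 <- which.max(ll)
  ll2 <- ll
  ll2[i1] <- -Inf
  i2 <- which.max(ll2)
  list(best = i1, second = i2, gap = ll[i1] - ll[i2])
}

#' Call the most probable genotype (MPG)
#'
#' Applies the quality filters, computes genotype posteriors, and scores the
#' best genotype as the natural-log posterior odds over the runner-up. The
#' coverage ratio is the MPG score divided by the retained (base Q20) depth.
#'
#' @param site A [site_evidence()] object (raw; filtering is applied here).
#' @param min_mapq,min_baseq Quality filters, see [filter_evidence()].
#' @return A `genotype_call`: list with `chrom`, `pos`, `ref`, `genotype`,
#'   `mpg_score`, `q20_depth`, `coverage_ratio`, `posterior`. With no
#'   retained reads, `genotype` is `NA` (no-call).
#' @export
call_mpg <- function(site, min_mapq = 30, min_baseq = 20) {
  fs <- filter_evidence(site, min_mapq, min_baseq)
  out <- list(chrom = site$chrom, pos = site$pos, ref = site$ref,
              genotype = NA_character_, mpg_score = NA_real_,
              q20_depth = nrow(fs$reads), coverage_ratio = NA_real_,
              posterior = NULL)
  class(out) <- "genotype_call"
  if (nrow(fs$reads) == 0L) return(out)
  ll <- site_logliks(fs$reads)
  tt <- top_two(ll)
  post <- exp(ll - max(ll)); post <- post / sum(post)
  out$genotype <- genotypes()[tt$best]
  out$mpg_score <- min(tt$gap, MPG_SCORE_CAP)
  out$coverage_ratio <- out$mpg_score / out$q20_depth
  out$posterior <- setNames(post, genotypes())
  out
}

#' Call the most probable variant (MPV)
#'
#' Scores the evidence that the sample genotype differs from homozygous
#' reference: the natural-log odds of the aggregate non-reference posterior
#' versus the homozygous-reference genotype, clamped to a finite cap when
#' either mass underflows. The best variant genotype is the most probable
#' of the nine non-reference genotypes.
#'
#' @inheritParams call_mpg
#' @return A `variant_call`: list with `chrom`, `pos`, `ref`,
#'   `best_variant_genotype`, `mpv_score`, `q20_depth`. `NA` fields denote
#'   a no-call (zero retained reads).
#' @export
call_mpv <- function(site, min_mapq = 30, min_baseq = 20) {
  fs <- filter_evidence(site, min_mapq, min_baseq)
  out <- list(chrom = site$chrom, pos = site$pos, ref = site$ref,
              best_variant_genotype = NA_character_, mpv_score = NA_real_,
              q20_depth = nrow(fs$reads))
  class(out) <- "variant_call"
  if (nrow(fs$reads) == 0L) return(out)
  if (!site$ref %in% BASES) stop("reference base must be A, C, G or T")
  ll <- site_logliks(fs$reads)
  rr <- match(paste0(site$ref, site$ref), genotypes())
  others <- ll[-rr]
  m <- max(others)
  lse_alt <- m + log(sum(exp(others - m)))
  out$mpv_score <- max(min(lse_alt - ll[rr], MPG_SCORE_CAP),
                       -MPG_SCORE_CAP)
  best_alt <- which(ll == max(others) & seq_along(ll) != rr)[1L]
  out$best_variant_genotype <- genotypes()[best_alt]
  out
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s:%d %s MPG=%.2f depth=%d ratio=%.3f\n",
              x$chrom, x$pos,
              ifelse(is.na(x$genotype), "no-call", x$genotype),
              x$mpg_score, x$q20_depth, x$coverage_ratio))
  invisible(x)
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("<variant_call> %s:%d ref=%s best=%s MPV=%.2f depth=%d\n",
              x$chrom, x$pos, x$ref,
              ifelse(is.na(x$best_variant_genotype), "no-call",
                     x$best_variant_genotype),
              x$mpv_score, x$q20_depth))
  invisible(x)
}

#' Genotype-call callability
#'
#' A genotype call is callable when the MPG score is at least 10 and the
#' score-to-depth coverage ratio is at least 0.5 (both inclusive).
#'
#' @param call A `genotype_call`.
#' @param min_score Minimum MPG score (inclusive).
#' @param min_ratio Minimum coverage ratio (inclusive).
#' @return Logical flag.
#' @export
is_callable_mpg <- function(call, min_score = 10, min_ratio = 0.5) {
  if (is.na(call$mpg_score)) return(FALSE)
  call$mpg_score >= min_score && call$coverage_ratio >= min_ratio
}

#' Variant-call callability
#'
#' A variant call is callable when the MPV score is at least 10 (inclusive);
#' there is no coverage-ratio criterion for MPV.
#'
#' @param call A `variant_call`.
#' @param min_score Minimum MPV score (inclusive).
#' @return Logical flag.
#' @export
is_callable_mpv <- function(call, min_score = 10) {
  if (is.na(call$mpv_score)) return(FALSE)
  call$mpv_score >= min_score
}

#' Vectorised MPG/MPV scoring of a pileup count matrix
#'
#' Genome-scale scoring engine. Evidence is a per-site matrix of retained
#' read counts grouped by (quality tier, base); because the per-read
#' likelihood depends only on the observed base and its quality, the site
#' log-likelihood of every genotype is an exact linear function of these
#' counts and all sites are scored with one matrix product.
#'
#' @param counts Integer matrix, one row per site, `4 * length(quals)`
#'   columns laid out base-fastest within quality tier (tier 1 A,C,G,T,
#'   tier 2 A,C,G,T, ...).
#' @param ref Character vector of reference bases, one per site.
#' @param quals Numeric vector of the Phred base-quality tiers matching the
#'   column layout of `counts`.
#' @return A data.frame with one row per site: `genotype`, `mpg`, `depth`,
#'   `ratio`, `mpv`, `var_genotype`. Zero-depth sites are no-calls (`NA`).
#' @export
score_sites <- function(counts, ref, quals) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L * length(quals),
            nrow(counts) == length(ref))
  n <- nrow(counts)
  L <- geno_loglik_matrix(quals)
  ll <- counts %*% L                     # n x 10
  gts <- genotypes()

  # top-two per row with lexicographic tie-break (first maximal column)
  best <- max.col(ll, ties.method = "first")
  ll_best <- ll[cbind(seq_len(n), best)]
  ll2 <- ll
  ll2[cbind(seq_len(n), best)] <- -Inf
  second <- max.col(ll2, ties.method = "first")
  ll_second <- ll2[cbind(seq_len(n), second)]

  depth <- as.integer(rowSums(counts))
  mpg <- pmin(ll_best - ll_second, MPG_SCORE_CAP)
  mpg[depth == 0L] <- NA_real_

  # homozygous-reference column per site
  rr <- match(paste0(ref, ref), gts)
  ll_rr <- ll[cbind(seq_len(n), rr)]
  llo <- ll
  llo[cbind(seq_len(n), rr)] <- -Inf
  m <- llo[cbind(seq_len(n), max.col(llo, ties.method = "first"))]
  lse_alt <- m + log(rowSums(exp(llo - m)))
  mpv <- pmax(pmin(lse_alt - ll_rr, MPG_SCORE_CAP),
              -MPG_SCORE_CAP)
  mpv[depth == 0L] <- NA_real_
  var_best <- max.col(llo, ties.method = "first")

  nocall <- depth == 0L
  genotype <- gts[best]; genotype[nocall] <- NA_character_
  var_genotype <- gts[var_best]; var_genotype[nocall] <- NA_character_
  ratio <- mpg / depth; ratio[nocall] <- NA_real_
  structure(list(genotype = genotype, mpg = mpg, depth = depth,
                 ratio = ratio, mpv = mpv, var_genotype = var_genotype),
            class = "data.frame", row.names = c(NA, -n))
}

# alleles of a genotype string, e.g. "AG" -> c("A","G")
gt_alleles <- function(gt) {
  if (is.na(gt)) return(character())
  c(substr(gt, 1, 1), substr(gt, 2, 2))
}
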