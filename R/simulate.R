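# Synthetic tumor/normal generator.
#
# Emulates the statistical structure of a melanoma tumor/normal whole-genome
# study at desk scale: diploid germline heterozygous sites, two tumor samples
# (a pure cell culture and a normal-contaminated tissue) sharing most of a
# UV-biased somatic mutation load, copy-number segments, indels, Phred-driven
# sequencing error, and a configurable annotation landscape (gene models,
# chromatin states, per-cell-type DHS sets, constrained regions, mappability,
# RNA read intervals).
#
# Evidence is generated per site (pileup columns), not per aligned read pair:
# every downstream method consumes per-site stacks, so alignment-level
# simulation would add nothing verifiable. Two evidence forms are produced:
# full per-read stacks (simulate_pileups, for small regions and unit tests)
# and per-site (quality tier x base) count matrices (simulate_pileup_matrix,
# for genome-scale runs). The genotype likelihood factorises exactly over
# (base, quality) groups, so the two forms are interchangeable for scoring.

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline is designed around:
#' a somatic burden of 42 SSNVs per megabase dominated by the UV C>T
#' signature, a pure cell-culture tumor plus a tissue tumor containing 42%
#' normal cells (purity 0.58), 96% of somatic SSNVs shared between the two
#' tumor samples, ~48x normal and ~30x tumor coverage, and an Illumina-like
#' base-quality mixture.
#'
#' @param genome_length Bases per synthetic chromosome.
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param germline_het_rate Per-base probability of a germline heterozygous
#'   site.
#' @param known_fraction Fraction of germline variants present in the
#'   known-variant (dbSNP-style) list.
#' @param somatic_rate Somatic SSNVs per megabase per tumor sample.
#' @param uv_fraction Fraction of somatic SSNVs drawn as C>T (G>A on the
#'   opposite strand).
#' @param shared_fraction Fraction of each tumor sample's somatic SSNVs
#'   shared with the other sample.
#' @param purity Named numeric vector of tumor-cell fractions in `[0,1]`,
#'   one per tumor sample.
#' @param mean_depth Named numeric vector with elements `normal` and `tumor`:
#'   mean retained reads per site.
#' @param base_q_model Named numeric vector: Phred base-quality tiers
#'   (names) and their probabilities (values, summing to 1).
#' @param low_mapq_fraction Fraction of reads with low mapping quality
#'   (below the Q30 calling threshold but at least Q1).
#' @param mapq_high,mapq_low Mapping quality assigned to the high/low tier.
#' @param base_comp Named base-composition probabilities for the reference.
#' @param cnv_spec Data frame of planted tumor copy-number segments with
#'   columns `chrom`, `start`, `end`, `cn`, `sample`; `NULL` plants a
#'   default set when the genome is large enough.
#' @param germline_indel_rate,somatic_indel_rate Indels per megabase.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chroms = 5,
                       germline_het_rate = 1 / 1500,
                       known_fraction = 0.9,
                       somatic_rate = 42,
                       uv_fraction = 0.75,
                       shared_fraction = 0.96,
                       purity = c(culture = 1.0, tissue = 0.58),
                       mean_depth = c(normal = 48, tumor = 30),
                       base_q_model = c("40" = 0.7, "30" = 0.2, "20" = 0.1),
                       low_mapq_fraction = 0.05,
                       mapq_high = 60, mapq_low = 10,
                       base_comp = c(A = 0.295, C = 0.205,
                                     G = 0.205, T = 0.295),
                       cnv_spec = NULL,
                       germline_indel_rate = 100,
                       somatic_indel_rate = 1,
                       seed = 1L) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (n_chroms < 1) stop("n_chroms must be at least 1")
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  if (is.null(names(purity))) stop("purity must be a named vector")
  if (somatic_rate < 0) stop("somatic_rate must be non-negative")
  if (abs(sum(base_q_model) - 1) > 1e-8) {
    stop("base_q_model probabilities must sum to 1")
  }
  if (is.null(cnv_spec)) {
    cnv_spec <- default_cnv_spec(genome_length, n_chroms, names(purity))
  }
  if (nrow(cnv_spec)) {
    if (any(cnv_spec$end > genome_length) || any(cnv_spec$start < 1)) {
      stop("cnv_spec intervals fall outside the genome")
    }
    for (s in unique(cnv_spec$sample)) {
      seg <- cnv_spec[cnv_spec$sample == s, ]
      seg <- seg[order(seg$chrom, seg$start), ]
      same <- duplicated(seg$chrom) &
        seg$start <= c(-Inf, head(seg$end, -1))
      if (any(same)) stop("cnv_spec intervals must be disjoint per sample")
    }
  }
  cfg <- list(genome_length = as.integer(genome_length),
              n_chroms = as.integer(n_chroms),
              germline_het_rate = germline_het_rate,
              known_fraction = known_fraction,
              somatic_rate = somatic_rate,
              uv_fraction = uv_fraction,
              shared_fraction = shared_fraction,
              purity = purity,
              mean_depth = mean_depth,
              base_q_model = base_q_model,
              low_mapq_fraction = low_mapq_fraction,
              mapq_high = mapq_high, mapq_low = mapq_low,
              base_comp = base_comp,
              cnv_spec = cnv_spec,
              germline_indel_rate = germline_indel_rate,
              somatic_indel_rate = somatic_indel_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# planted copy-number segments used when the genome is large enough to hold
# them: a shared single-copy deletion, a tissue-specific CN3 amplification
# and a culture-specific CN4 amplification
default_cnv_spec <- function(genome_length, n_chroms, samples) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), cn = integer(), sample = character(),
                      stringsAsFactors = FALSE)
  if (genome_length < 1.5e6 || n_chroms < 2 || length(samples) < 1) {
    return(empty)
  }
  spec <- rbind(
    data.frame(chrom = "chr1", start = 300001L, end = 500000L, cn = 1L,
               sample = samples, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = 1200001L, end = 1350000L, cn = 3L,
               sample = samples[length(samples)], stringsAsFactors = FALSE),
    data.frame(chrom = "chr2", start = 200001L, end = 300000L, cn = 4L,
               sample = samples[1L], stringsAsFactors = FALSE))
  spec
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

sim_chrom_lengths <- function(config) {
  setNames(rep(config$genome_length, config$n_chroms),
           sim_chrom_names(config))
}

#' Simulate the reference sequence set
#'
#' One random sequence per chromosome over `{A,C,G,T}` at the configured
#' base composition, reproducible under the configured seed.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named `chr1..chrN`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(BASES, config$genome_length, replace = TRUE,
                 prob = config$base_comp), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, sim_chrom_names(config)))
}

# per-position base characters of one chromosome
ref_chars <- function(ref, chrom) {
  strsplit(as.character(ref[[chrom]]), "", fixed = TRUE)[[1L]]
}

#' Simulate the truth set
#'
#' Plants germline heterozygous sites, somatic SSNVs (shared and
#' sample-specific, with the UV C>T bias), germline and somatic indels, and
#' the configured copy-number segments. Somatic positions are disjoint from
#' germline positions and every somatic alternate allele differs from the
#' reference.
#'
#' @param config A [sim_config()].
#' @param ref Reference from [simulate_reference()].
#' @return A `truth_set`: list with data frames `germline` (chrom, pos, ref,
#'   alt, genotype, known), `somatic` (chrom, pos, ref, alt, origin),
#'   `indels` (chrom, pos, size, origin), `cnv` (the cnv_spec), plus
#'   `purity` and `chrom_lengths`.
#' @export
simulate_truth <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  L <- config$genome_length
  samples <- names(config$purity)
  germ <- list(); som <- list(); ind <- list()
  for (chrom in sim_chrom_names(config)) {
    rc <- ref_chars(ref, chrom)

    n_het <- rbinom(1L, L, config$germline_het_rate)
    gpos <- sort(sample.int(L, n_het))
    gref <- rc[gpos]
    galt <- random_alt(gref)
    germ[[chrom]] <- data.frame(
      chrom = rep(chrom, n_het), pos = gpos, ref = gref, alt = galt,
      genotype = sorted_gt(gref, galt),
      known = runif(n_het) < config$known_fraction,
      stringsAsFactors = FALSE)

    lam <- L / 1e6 * config$somatic_rate
    n_shared <- rpois(1L, lam * config$shared_fraction)
    n_spec <- rpois(length(samples), lam * (1 - config$shared_fraction))
    origin <- c(rep("shared", n_shared), rep(samples, n_spec))
    n_som <- length(origin)
    spos <- draw_somatic_positions(n_som, rc, config$uv_fraction,
                                   exclude = gpos)
    som[[chrom]] <- data.frame(
      chrom = rep(chrom, n_som), pos = spos$pos, ref = spos$ref,
      alt = spos$alt,
      origin = origin, stringsAsFactors = FALSE)

    n_gi <- rpois(1L, L / 1e6 * config$germline_indel_rate)
    n_si <- rpois(1L, L / 1e6 * config$somatic_indel_rate *
                        length(samples))
    iorig <- c(rep("germline", n_gi),
               sample(c("shared", samples), n_si, replace = TRUE,
                      prob = c(config$shared_fraction,
                               rep((1 - config$shared_fraction) /
                                     length(samples), length(samples)))))
    ipos <- sample.int(L, n_gi + n_si)
    ind[[chrom]] <- data.frame(
      chrom = rep(chrom, n_gi + n_si), pos = ipos,
      size = sample(c(-3L, -2L, -1L, 1L, 2L, 3L), n_gi + n_si,
                    replace = TRUE,
                    prob = c(0.05, 0.1, 0.35, 0.35, 0.1, 0.05)),
      origin = iorig, stringsAsFactors = FALSE)
  }
  out <- list(germline = do.call(rbind, germ),
              somatic = do.call(rbind, som),
              indels = do.call(rbind, ind),
              cnv = config$cnv_spec,
              purity = config$purity,
              chrom_lengths = sim_chrom_lengths(config))
  rownames(out$germline) <- rownames(out$somatic) <- NULL
  class(out) <- "truth_set"
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "<truth_set> %d chrom(s), %s bp | germline het: %d | somatic SSNV: %d | indels: %d | CNV segments: %d\n",
    length(x$chrom_lengths), format(sum(x$chrom_lengths), big.mark = ","),
    nrow(x$germline), nrow(x$somatic), nrow(x$indels), nrow(x$cnv)))
  invisible(x)
}

# uniform alternate allele differing from ref
random_alt <- function(refbase) {
  off <- sample.int(3L, length(refbase), replace = TRUE)
  BASES[((match(refbase, BASES) - 1L + off) %% 4L) + 1L]
}

sorted_gt <- function(a, b) {
  paste0(pmin(a, b), pmax(a, b))
}

# somatic positions with a UV-biased spectrum: uv mutations are C>T
# (or G>A when the pyrimidine is on the opposite strand)
draw_somatic_positions <- function(n, rc, uv_fraction, exclude) {
  if (n == 0L) {
    return(list(pos = integer(), ref = character(), alt = character()))
  }
  is_uv <- runif(n) < uv_fraction
  n_uv <- sum(is_uv)
  cg <- which(rc == "C" | rc == "G")
  cg <- setdiff(cg, exclude)
  pos_uv <- sample(cg, n_uv)
  ref_uv <- rc[pos_uv]
  alt_uv <- ifelse(ref_uv == "C", "T", "A")
  n_bg <- n - n_uv
  avail <- setdiff(seq_along(rc), c(exclude, pos_uv))
  pos_bg <- if (n_bg) sample(avail, n_bg) else integer()
  ref_bg <- rc[pos_bg]
  alt_bg <- random_alt(ref_bg)
  o <- order(c(pos_uv, pos_bg))
  list(pos = c(pos_uv, pos_bg)[o],
       ref = c(ref_uv, ref_bg)[o],
       alt = c(alt_uv, alt_bg)[o])
}

# expected somatic/germline alt-read fraction for a sample at a site
# inside a tumor CNV of copy number cn (mutated allele on one copy)
somatic_alt_fraction <- function(purity, cn = 2) {
  purity / (purity * cn + (1 - purity) * 2)
}

# per-site copy-number weight vector for a tumor sample on one chromosome
cn_weights <- function(config, truth, sample, chrom) {
  w <- rep(1, config$genome_length)
  if (sample == "normal" || !nrow(truth$cnv)) return(w)
  seg <- truth$cnv[truth$cnv$sample == sample & truth$cnv$chrom == chrom, ]
  p <- config$purity[[sample]]
  for (i in seq_len(nrow(seg))) {
    w[seg$start[i]:seg$end[i]] <- p * seg$cn[i] / 2 + (1 - p)
  }
  w
}

# copy number of a tumor sample at given positions (2 outside segments)
cn_at <- function(truth, sample, chrom, pos) {
  cn <- rep(2L, length(pos))
  seg <- truth$cnv[truth$cnv$sample == sample & truth$cnv$chrom == chrom, ]
  for (i in seq_len(nrow(seg))) {
    cn[pos >= seg$start[i] & pos <= seg$end[i]] <- seg$cn[i]
  }
  cn
}

# truth alt-allele fraction for every variant site of one sample/chromosome;
# returns data.frame(pos, ref, alt, frac, origin_type)
variant_site_table <- function(config, truth, sample, chrom) {
  g <- truth$germline[truth$germline$chrom == chrom, ]
  gtab <- data.frame(pos = g$pos, ref = g$ref, alt = g$alt,
                     frac = rep(0.5, nrow(g)),
                     origin_type = rep("germline", nrow(g)),
                     stringsAsFactors = FALSE)
  if (sample == "normal") return(gtab[order(gtab$pos), ])
  s <- truth$somatic[truth$somatic$chrom == chrom &
                       (truth$somatic$origin == "shared" |
                          truth$somatic$origin == sample), ]
  p <- config$purity[[sample]]
  cn <- cn_at(truth, sample, chrom, s$pos)
  frac <- ifelse(cn == 0, 0, somatic_alt_fraction(p, cn))
  stab <- data.frame(pos = s$pos, ref = s$ref, alt = s$alt,
                     frac = frac, origin_type = rep("somatic", nrow(s)),
                     stringsAsFactors = FALSE)
  out <- rbind(gtab, stab)
  out[order(out$pos), ]
}

#' Simulate per-read pileup evidence at chosen positions
#'
#' Full per-read stacks for one sample: read count Poisson around the mean
#' depth (scaled by tumor copy number and purity inside CNV segments),
#' alleles drawn with the truth alt fraction, sequencing errors at the
#' Phred rate `10^(-Q/10)` spread uniformly over the three non-template
#' bases, strands 50/50, and a two-point mapping-quality mixture.
#'
#' @param ref Reference from [simulate_reference()].
#' @param truth Truth set from [simulate_truth()].
#' @param config A [sim_config()].
#' @param sample `"normal"` or one of the tumor sample names.
#' @param chrom Chromosome name.
#' @param positions Integer positions to emit (default: all variant
#'   positions of the sample on that chromosome).
#' @return Named list (`chrom:pos`) of [site_evidence()] objects.
#' @export
simulate_pileups <- function(ref, truth, config, sample, chrom,
                             positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  vt <- variant_site_table(config, truth, sample, chrom)
  if (is.null(positions)) positions <- vt$pos
  if (any(positions < 1 | positions > L)) {
    stop("position outside the reference sequence")
  }
  set.seed(config$seed + 11L + match(chrom, sim_chrom_names(config)))
  rc <- ref_chars(ref, chrom)
  w <- cn_weights(config, truth, sample, chrom)
  md <- if (sample == "normal") config$mean_depth[["normal"]] else
    config$mean_depth[["tumor"]]
  quals <- as.numeric(names(config$base_q_model))
  out <- vector("list", length(positions))
  names(out) <- paste0(chrom, ":", positions)
  for (i in seq_along(positions)) {
    pos <- positions[i]
    j <- match(pos, vt$pos)
    frac <- if (is.na(j)) 0 else vt$frac[j]
    alt <- if (is.na(j)) NA_character_ else vt$alt[j]
    depth <- rpois(1L, md * w[pos])
    if (depth == 0L) {
      out[[i]] <- site_evidence(chrom, pos, rc[pos])
      next
    }
    bq <- quals[sample.int(length(quals), depth, replace = TRUE,
                           prob = config$base_q_model)]
    mq <- ifelse(runif(depth) < config$low_mapq_fraction,
                 config$mapq_low, config$mapq_high)
    allele <- ifelse(runif(depth) < frac, alt, rc[pos])
    e <- 10^(-bq / 10)
    err <- runif(depth) < e
    obs <- allele
    if (any(err)) obs[err] <- random_alt(allele[err])
    out[[i]] <- site_evidence(chrom, pos, rc[pos], base = obs, baseq = bq,
                              mapq = mq,
                              strand = sample(c("+", "-"), depth,
                                              replace = TRUE))
  }
  out
}

# multinomial split of per-site read counts into quality tiers
split_tiers <- function(n, probs) {
  k <- length(probs)
  out <- matrix(0L, nrow = length(n), ncol = k)
  rem <- n
  prem <- 1
  for (j in seq_len(k - 1L)) {
    out[, j] <- rbinom(length(n), rem, probs[j] / prem)
    rem <- rem - out[, j]
    prem <- prem - probs[j]
  }
  out[, k] <- rem
  out
}

#' Simulate a compact per-site pileup count matrix for one chromosome
#'
#' Genome-scale evidence for one sample: per-site counts of retained
#' (mapQ-pass) reads grouped by base-quality tier and observed base, the
#' low-mapQ read count, and a per-variant-site table carrying the alternate
#' read counts, their strand split, and low-mapQ alternate counts needed by
#' the validation filters and the purity estimator.
#'
#' @inheritParams simulate_pileups
#' @return A `pileup_matrix`: list with `chrom`, `sample`, `ref` (per-site
#'   base characters), `quals`, `counts` (sites x 4*tiers integer matrix,
#'   base-fastest layout as in [score_sites()]), `depth` (retained), `n_low`
#'   (low-mapQ depth), and `variant_sites` (data.frame pos, ref, alt,
#'   origin_type, frac, alt_count, alt_plus, alt_minus, alt_low).
#' @export
simulate_pileup_matrix <- function(ref, truth, config, sample, chrom) {
  stopifnot(inherits(config, "sim_config"))
  ci <- match(chrom, sim_chrom_names(config))
  si <- match(sample, c("normal", names(config$purity)))
  if (is.na(ci) || is.na(si)) stop("unknown sample or chromosome")
  set.seed(config$seed + 1000L + 101L * si + ci)
  L <- config$genome_length
  rc <- ref_chars(ref, chrom)
  refcode <- match(rc, BASES)
  quals <- as.numeric(names(config$base_q_model))
  k <- length(quals)
  err_rates <- 10^(-quals / 10)

  md <- if (sample == "normal") config$mean_depth[["normal"]] else
    config$mean_depth[["tumor"]]
  w <- cn_weights(config, truth, sample, chrom)
  depth_all <- rpois(L, md * w)
  n_low <- rbinom(L, depth_all, config$low_mapq_fraction)
  n_pass <- depth_all - n_low
  tiers <- split_tiers(n_pass, config$base_q_model)

  counts <- matrix(0L, nrow = L, ncol = 4L * k)
  for (j in seq_len(k)) {
    err <- rbinom(L, tiers[, j], err_rates[j])
    counts[cbind(seq_len(L), (j - 1L) * 4L + refcode)] <- tiers[, j] - err
    has <- which(err > 0L)
    if (length(has)) {
      idx <- rep(has, err[has])
      off <- sample.int(3L, length(idx), replace = TRUE)
      col <- (j - 1L) * 4L + ((refcode[idx] - 1L + off) %% 4L) + 1L
      key <- (col - 1L) * L + idx
      uk <- unique(key)
      add <- tabulate(match(key, uk), length(uk))
      counts[uk] <- counts[uk] + add
    }
  }

  # overwrite variant sites with the two-allele model
  vt <- variant_site_table(config, truth, sample, chrom)
  nv <- nrow(vt)
  alt_hi <- integer(nv)
  if (nv) {
    v <- vt$pos
    refc_v <- match(vt$ref, BASES)
    altc_v <- match(vt$alt, BASES)
    counts[v, ] <- 0L
    for (j in seq_len(k)) {
      n_tier <- tiers[v, j]
      e <- err_rates[j]
      p_alt <- vt$frac * (1 - e) + (1 - vt$frac) * e / 3
      n_alt <- rbinom(nv, n_tier, p_alt)
      rem <- n_tier - n_alt
      p_o <- (e / 3) / (1 - p_alt)
      n_o1 <- rbinom(nv, rem, p_o)
      rem <- rem - n_o1
      n_o2 <- rbinom(nv, rem, (e / 3) / (1 - p_alt - e / 3))
      n_ref <- rem - n_o2
      base_cols <- (j - 1L) * 4L
      counts[cbind(v, base_cols + altc_v)] <-
        counts[cbind(v, base_cols + altc_v)] + n_alt
      counts[cbind(v, base_cols + refc_v)] <-
        counts[cbind(v, base_cols + refc_v)] + n_ref
      oth1 <- ((altc_v - 1L + 1L) %% 4L) + 1L
      oth1[oth1 == refc_v] <- ((altc_v[oth1 == refc_v] - 1L + 2L) %% 4L) + 1L
      oth2 <- 6L + 4L - altc_v - refc_v - oth1  # remaining base: codes sum 10
      counts[cbind(v, base_cols + oth1)] <-
        counts[cbind(v, base_cols + oth1)] + n_o1
      counts[cbind(v, base_cols + oth2)] <-
        counts[cbind(v, base_cols + oth2)] + n_o2
      alt_hi <- alt_hi + n_alt
    }
    vt$depth <- n_pass[v]
    vt$alt_count <- alt_hi
    vt$alt_plus <- rbinom(nv, alt_hi, 0.5)
    vt$alt_minus <- alt_hi - vt$alt_plus
    # low-mapQ reads carrying the alt allele (true alt draws + errors)
    e_mean <- sum(config$base_q_model * err_rates)
    vt$alt_low <- rbinom(nv, n_low[v],
                         vt$frac * (1 - e_mean) + (1 - vt$frac) * e_mean / 3)
  } else {
    vt$depth <- vt$alt_count <- vt$alt_plus <- vt$alt_minus <-
      vt$alt_low <- integer()
  }

  structure(list(chrom = chrom, sample = sample, ref = rc, quals = quals,
                 counts = counts, depth = n_pass, n_low = n_low,
                 variant_sites = vt),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat(sprintf(
    "<pileup_matrix> %s %s: %s sites, mean retained depth %.1f, %d variant sites\n",
    x$sample, x$chrom, format(length(x$depth), big.mark = ","),
    mean(x$depth), nrow(x$variant_sites)))
  invisible(x)
}
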