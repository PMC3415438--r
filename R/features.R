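# Interval algebra over annotation landscapes: hierarchical genic-landmark
# partitioning, chromatin-state masks, non-genic constraint-decile tiling,
# regression of mutation accumulation on genomic covariates, transcript
# distance profiles, and per-state mutation rates.

LANDMARK_ORDER <- c("coding", "utr5", "utr3", "intron",
                    "tss_proximal", "tss_distal")

#' Hierarchical genic-landmark partition
#'
#' Assigns every base (or every target interval) to exactly one category in
#' the fixed priority order: coding, 5' UTR, 3' UTR, intron, intergenic
#' TSS-proximal (within `tss_window` bp of any TSS), intergenic TSS-distal.
#' Earlier categories claim their bases first, so an interval overlapping
#' both coding and intronic territory is coding. With `targets` supplied
#' (e.g. a DHS set), each target interval is assigned whole to the
#' highest-priority category it overlaps by at least 1 bp.
#'
#' @param genes A [gene_models()] object.
#' @param genome GRanges of whole chromosomes ([genome_ranges()]) or a
#'   named vector of chromosome lengths.
#' @param targets Optional GRanges of intervals to classify.
#' @param tss_window TSS-proximal window in bp (inclusive).
#' @return With `targets = NULL`, a `landmark_partition`: named list of
#'   disjoint GRanges per category plus `unassigned`, with the genome in
#'   attribute `genome`. Otherwise a factor of category labels parallel to
#'   `targets`.
#' @export
partition_by_landmark <- function(genes, genome, targets = NULL,
                                  tss_window = 5000) {
  if (!is(genome, "GRanges")) genome <- genome_ranges(genome)
  ex <- genes$exons
  red <- function(gr) GenomicRanges::reduce(gr, ignore.strand = TRUE)
  dif <- function(a, b) GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
  coding <- red(ex[ex$type == "cds"])
  utr5 <- dif(red(ex[ex$type == "utr5"]), coding)
  utr3 <- dif(dif(red(ex[ex$type == "utr3"]), coding), utr5)
  genic <- red(genes$genes)
  exonic <- red(ex)
  intron <- dif(genic, exonic)
  claimed <- red(c(coding, utr5, utr3, intron))
  tss_zone <- red(GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(genes$tss),
      IRanges::ranges(genes$tss),
      seqinfo = GenomeInfoDb::seqinfo(genome)),
      width = 2L * tss_window + 1L, fix = "center"))))
  tss_proximal <- dif(dif(tss_zone, claimed), genic)
  tss_distal <- dif(dif(genome, claimed), c(tss_zone, genic))
  unassigned <- dif(genome, red(c(coding, utr5, utr3, intron,
                                  tss_proximal, tss_distal)))
  part <- list(coding = coding, utr5 = utr5, utr3 = utr3, intron = intron,
               tss_proximal = tss_proximal, tss_distal = tss_distal,
               unassigned = unassigned)
  if (is.null(targets)) {
    attr(part, "genome") <- genome
    class(part) <- "landmark_partition"
    return(part)
  }
  lab <- rep("unassigned", length(targets))
  for (cat in rev(LANDMARK_ORDER)) {
    hit <- IRanges::overlapsAny(targets, part[[cat]], ignore.strand = TRUE)
    lab[hit] <- cat
  }
  factor(lab, levels = c(LANDMARK_ORDER, "unassigned"))
}

#' @export
print.landmark_partition <- function(x, ...) {
  w <- vapply(unclass(x), territory_width, numeric(1))
  cat("<landmark_partition>\n")
  print(round(w / 1e6, 3))
  invisible(x)
}

#' Per-state chromatin masks with repeat states dropped
#'
#' Splits a chromatin-state segmentation into one interval set per state,
#' removing the repeat-region states (14 and 15 by default) whose variant
#' calls are unreliable.
#'
#' @param states GRanges with integer mcol `state`.
#' @param drop_states States to remove.
#' @return Named list of GRanges, one per retained state
#'   (`state1`..`state13`), reduced.
#' @export
chromatin_state_mask <- function(states, drop_states = c(14, 15)) {
  keep <- sort(setdiff(unique(states$state), drop_states))
  out <- lapply(keep, function(s) {
    GenomicRanges::reduce(states[states$state == s], ignore.strand = TRUE)
  })
  setNames(out, paste0("state", keep, recycle0 = TRUE))
}

#' Non-genic 50 kb tiles binned by evolutionary constraint
#'
#' Masks all territory within `mask_window` bp of any part of a gene or
#' TSS, carves non-overlapping `tile_width` tiles from the remaining
#' territory, computes each tile's constrained-base fraction, discards
#' tiles with no constrained overlap, sorts the rest by constrained
#' fraction and splits them into `n_bins` equal-sized bins (remainder
#' tiles joining the last bin).
#'
#' @param genes A [gene_models()] object.
#' @param constrained GRanges of evolutionarily constrained regions.
#' @param genome GRanges of whole chromosomes or named length vector.
#' @param mask_window Gene/TSS exclusion flank in bp.
#' @param tile_width Tile width in bp.
#' @param n_bins Number of constraint bins.
#' @return Data frame of surviving tiles: `chrom`, `start`, `end`,
#'   `constrained_fraction`, `bin` (1 = least constrained).
#' @export
nongenic_constraint_bins <- function(genes, constrained, genome,
                                     mask_window = 10000,
                                     tile_width = 50000, n_bins = 10) {
  if (!is(genome, "GRanges")) genome <- genome_ranges(genome)
  # flanked gene ranges may poke past chromosome ends; work without
  # seqlengths so the set algebra needs no trimming
  genome_plain <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genome),
                                         IRanges::ranges(genome))
  masked <- GenomicRanges::reduce(
    c(GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes$genes),
                             IRanges::ranges(genes$genes) + mask_window),
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes$tss),
                             IRanges::ranges(genes$tss) + mask_window)),
    ignore.strand = TRUE)
  free <- GenomicRanges::setdiff(genome_plain, masked, ignore.strand = TRUE)
  tiles <- list()
  for (i in seq_along(free)) {
    w <- GenomicRanges::width(free)[i]
    k <- w %/% tile_width
    if (k == 0L) next
    s <- GenomicRanges::start(free)[i] + (seq_len(k) - 1L) * tile_width
    tiles[[length(tiles) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(free))[i],
      start = s, end = s + tile_width - 1L, stringsAsFactors = FALSE)
  }
  if (!length(tiles)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), constrained_fraction = numeric(),
                      bin = integer()))
  }
  tl <- do.call(rbind, tiles)
  gr <- GenomicRanges::GRanges(tl$chrom, IRanges::IRanges(tl$start, tl$end))
  tl$constrained_fraction <- overlap_fraction(gr, constrained)
  tl <- tl[tl$constrained_fraction > 0, , drop = FALSE]
  tl <- tl[order(tl$constrained_fraction), , drop = FALSE]
  n <- nrow(tl)
  size <- n %/% n_bins
  if (size == 0L) stop("too few surviving tiles for the requested bins")
  bin <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_bins)
  tl$bin <- bin
  rownames(tl) <- NULL
  tl
}

#' Fraction of each interval covered by a feature set
#'
#' @param gr Query GRanges.
#' @param features Feature GRanges (reduced internally).
#' @return Numeric vector of covered fractions parallel to `gr`.
#' @export
overlap_fraction <- function(gr, features) {
  feats <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, feats, ignore.strand = TRUE)
  ov <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(feats)[S4Vectors::subjectHits(hits)]))
  agg <- tapply(ov, factor(S4Vectors::queryHits(hits),
                           levels = seq_along(gr)), sum)
  as.vector(ifelse(is.na(agg), 0, agg)) / GenomicRanges::width(gr)
}

#' GC fraction of tiles
#'
#' @param ref A [Biostrings::DNAStringSet] reference.
#' @param tiles Data frame with `chrom`, `start`, `end`.
#' @return Numeric vector of GC fractions.
#' @export
tile_gc <- function(ref, tiles) {
  vapply(seq_len(nrow(tiles)), function(i) {
    sub <- Biostrings::subseq(ref[[tiles$chrom[i]]], tiles$start[i],
                              tiles$end[i])
    sum(Biostrings::letterFrequency(sub, c("G", "C"))) /
      (tiles$end[i] - tiles$start[i] + 1)
  }, numeric(1))
}

#' Multiple regression of mutation accumulation on genomic covariates
#'
#' Ordinary least squares of a per-bin (or per-tile) mutation measure on
#' evolutionary constraint, GC content and transcribed-base fraction, with
#' partial correlations derived from the t statistics, plus the Spearman
#' rank correlation of the response with transcribed fraction.
#'
#' @param data Data frame with columns `response`, `constraint`, `gc`,
#'   `transcribed`.
#' @return List with `coefficients` (estimate, std.error, t, p, partial_r
#'   per covariate), `spearman_transcribed`, and the fitted `lm` object.
#' @export
regress_mutation_rate <- function(data) {
  stopifnot(all(c("response", "constraint", "gc", "transcribed")
                %in% names(data)))
  fit <- stats::lm(response ~ constraint + gc + transcribed, data = data)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  tv <- sm[-1, "t value"]
  coefs <- data.frame(term = rownames(sm)[-1],
                      estimate = sm[-1, "Estimate"],
                      std.error = sm[-1, "Std. Error"],
                      t = tv, p = sm[-1, "Pr(>|t|)"],
                      partial_r = tv / sqrt(tv^2 + df),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs,
       spearman_transcribed = stats::cor(data$response, data$transcribed,
                                         method = "spearman"),
       fit = fit)
}

#' Mutation rate along transcripts
#'
#' Bins each variant falling inside a gene body by its distance from the
#' TSS measured in the direction of transcription (minus-strand distances
#' run leftward from the gene end), and normalises per-bin counts by the
#' transcript territory contributing to that bin.
#'
#' @param variants Data frame with `chrom`, `pos`.
#' @param genes A [gene_models()] object.
#' @param bin_width Bin width in bp.
#' @return Data frame: `bin` (0-based index), `distance` (bin start in
#'   bp), `count`, `territory` (bp), `rate_per_mb`.
#' @export
transcript_distance_profile <- function(variants, genes, bin_width = 5000) {
  g <- genes$genes
  pos_gr <- positions_to_granges(variants$chrom, variants$pos)
  hits <- GenomicRanges::findOverlaps(pos_gr, g, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  strand <- as.character(BiocGenerics::strand(g))[sh]
  d <- ifelse(strand == "+",
              variants$pos[qh] - GenomicRanges::start(g)[sh],
              GenomicRanges::end(g)[sh] - variants$pos[qh])
  bins <- d %/% bin_width
  max_bin <- max(c(bins, (GenomicRanges::width(g) - 1L) %/% bin_width))
  count <- tabulate(bins + 1L, nbins = max_bin + 1L)
  territory <- vapply(0:max_bin, function(b) {
    sum(pmax(0L, pmin(GenomicRanges::width(g) - b * bin_width,
                      bin_width)))
  }, numeric(1))
  data.frame(bin = 0:max_bin, distance = (0:max_bin) * bin_width,
             count = count, territory = territory,
             rate_per_mb = ifelse(territory > 0,
                                  count / (territory / 1e6), NA_real_))
}

#' Mutation rate per chromatin state
#'
#' SSNV count and rate per megabase in each state mask; the
#' heterochromatin low-signal state (state 13) approximates the background
#' passenger rate.
#'
#' @param variants Data frame with `chrom`, `pos`.
#' @param state_masks Named list of GRanges (see
#'   [chromatin_state_mask()]).
#' @return Data frame: `state`, `count`, `territory_mb`, `rate_per_mb`.
#' @export
per_state_rate <- function(variants, state_masks) {
  rows <- lapply(names(state_masks), function(nm) {
    mask <- state_masks[[nm]]
    cnt <- sum(positions_in_mask(variants$chrom, variants$pos, mask))
    mb <- territory_width(mask) / 1e6
    data.frame(state = nm, count = cnt, territory_mb = mb,
               rate_per_mb = if (mb > 0) cnt / mb else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
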