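# Tile-based somatic copy-number analysis: 5 kb depth tiles with a
# mappability gate, log2 tumor/normal ratios normalised by the genome-wide
# median, run-length merging of same-direction tiles, purity-adjusted copy
# number, the cross-sample specificity filter and the non-CNV mask.

#' Summarise tumor/normal depth in fixed tiles
#'
#' Computes mean retained depth per sample in non-overlapping tiles
#' (default 5 kb) and the depth-normalised log2 tumor/normal ratio. The
#' ratio is defined only for tiles with at least `min_mappable` (default
#' 80%) uniquely mappable bases and positive normal depth; other tiles are
#' uncallable (`NA` ratio). Library-size differences are removed by
#' dividing by the genome-wide median tumor/normal depth ratio before
#' taking log2.
#'
#' @param normal_depth,tumor_depth Named lists of per-chromosome integer
#'   vectors of per-site retained depth.
#' @param mappability GRanges of uniquely mappable territory.
#' @param tile_width Tile width in bp.
#' @param min_mappable Minimum mappable fraction for a callable tile
#'   (inclusive).
#' @return Data frame of tiles: `chrom`, `start`, `end`, `normal_depth`,
#'   `tumor_depth`, `mappable_fraction`, `log2_ratio`.
#' @export
tile_depths <- function(normal_depth, tumor_depth, mappability,
                        tile_width = 5000, min_mappable = 0.8) {
  stopifnot(identical(names(normal_depth), names(tumor_depth)))
  out <- list()
  for (chrom in names(normal_depth)) {
    nd <- normal_depth[[chrom]]; td <- tumor_depth[[chrom]]
    stopifnot(length(nd) == length(td))
    L <- length(nd)
    n_tiles <- L %/% tile_width
    if (n_tiles == 0L) next
    used <- n_tiles * tile_width
    idx <- rep(seq_len(n_tiles), each = tile_width)
    nmean <- as.vector(rowsum(nd[seq_len(used)], idx)) / tile_width
    tmean <- as.vector(rowsum(td[seq_len(used)], idx)) / tile_width
    starts <- (seq_len(n_tiles) - 1L) * tile_width + 1L
    tiles <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(starts,
                                                     starts + tile_width - 1L))
    cov <- GenomicRanges::intersect(
      tiles, mappability[GenomeInfoDb::seqnames(mappability) == chrom],
      ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(tiles, cov)
    ov <- tapply(GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(tiles)[S4Vectors::queryHits(hits)],
      IRanges::ranges(cov)[S4Vectors::subjectHits(hits)])),
      factor(S4Vectors::queryHits(hits), levels = seq_len(n_tiles)), sum)
    mf <- as.vector(ifelse(is.na(ov), 0, ov)) / tile_width
    out[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + tile_width - 1L,
                               normal_depth = nmean, tumor_depth = tmean,
                               mappable_fraction = mf,
                               stringsAsFactors = FALSE)
  }
  tl <- do.call(rbind, out)
  rownames(tl) <- NULL
  callable <- tl$mappable_fraction >= min_mappable & tl$normal_depth > 0
  ratio <- ifelse(callable, tl$tumor_depth / tl$normal_depth, NA_real_)
  med <- median(ratio, na.rm = TRUE)
  tl$log2_ratio <- log2(ratio / med)
  tl
}

#' Call merged copy-number segments from tiles
#'
#' Classifies callable tiles as amplified (log2 ratio at or above
#' `amp_threshold`) or deleted (at or below `del_threshold`), merges
#' maximal runs of genomically consecutive same-direction tiles (an
#' uncallable tile breaks a run), drops single-tile runs, and converts the
#' mean log2 ratio to a purity-adjusted copy number
#' `CN = (2 * 2^log2r - 2 * (1 - purity)) / purity`, clipped at 0.
#'
#' @param tiles Tile table from [tile_depths()].
#' @param amp_threshold,del_threshold Log2-ratio call thresholds
#'   (inclusive).
#' @param purity Tumor-cell fraction used for the copy-number adjustment.
#' @return Data frame of segments: `chrom`, `start`, `end`, `direction`,
#'   `mean_log2`, `n_tiles`, `copy_number`.
#' @export
call_cnv_segments <- function(tiles, amp_threshold = 0.25,
                              del_threshold = -0.25, purity = 1) {
  stopifnot(amp_threshold > 0, del_threshold < 0, purity > 0, purity <= 1)
  lab <- ifelse(is.na(tiles$log2_ratio), "na",
                ifelse(tiles$log2_ratio >= amp_threshold, "amplification",
                       ifelse(tiles$log2_ratio <= del_threshold,
                              "deletion", "neutral")))
  run_key <- paste(tiles$chrom, lab)
  r <- rle(run_key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$lengths >= 2L &
                  grepl("(amplification|deletion)$", r$values))
  segs <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    ml <- mean(tiles$log2_ratio[i])
    data.frame(chrom = tiles$chrom[i[1L]], start = tiles$start[i[1L]],
               end = tiles$end[i[length(i)]],
               direction = lab[i[1L]], mean_log2 = ml,
               n_tiles = length(i),
               copy_number = purity_adjusted_cn(ml, purity),
               stringsAsFactors = FALSE)
  })
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), mean_log2 = numeric(),
               n_tiles = integer(), copy_number = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Purity-adjusted copy number
#'
#' Inverts the mixture expectation of the observed log2 depth ratio for a
#' tumor-cell fraction `purity`: observed relative depth
#' `2^log2r = purity * CN / 2 + (1 - purity)`, so
#' `CN = (2 * 2^log2r - 2 * (1 - purity)) / purity`, clipped at 0.
#'
#' @param log2r Observed log2 tumor/normal depth ratio.
#' @param purity Tumor-cell fraction in (0, 1].
#' @return Estimated copy number in tumor cells.
#' @export
purity_adjusted_cn <- function(log2r, purity) {
  pmax(0, (2 * 2^log2r - 2 * (1 - purity)) / purity)
}

#' Label segments as shared or sample-specific
#'
#' A segment called in sample A is sample-specific only if every overlapped
#' tile of sample B with a defined log2 ratio lies strictly inside
#' (-`window`, +`window`); a B tile at or beyond the window in either
#' direction marks the segment as shared (CNV-like in both samples) even if
#' B was never called.
#'
#' @param segments_a Segment table from [call_cnv_segments()] for sample A.
#' @param tiles_b Tile table from [tile_depths()] for sample B (same grid).
#' @param window Log2-ratio window; the boundary is inclusive on the shared
#'   side (|ratio| >= window means shared).
#' @return `segments_a` with an added `specificity` column
#'   (`sample_specific`/`shared`).
#' @export
sample_specific_filter <- function(segments_a, tiles_b, window = 0.1) {
  if (!nrow(segments_a)) {
    segments_a$specificity <- character()
    return(segments_a)
  }
  seg_gr <- GenomicRanges::GRanges(segments_a$chrom,
                                   IRanges::IRanges(segments_a$start,
                                                    segments_a$end))
  tile_gr <- GenomicRanges::GRanges(tiles_b$chrom,
                                    IRanges::IRanges(tiles_b$start,
                                                     tiles_b$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, tile_gr)
  spec <- rep(TRUE, nrow(segments_a))
  for (i in seq_len(nrow(segments_a))) {
    r <- tiles_b$log2_ratio[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    r <- r[!is.na(r)]
    if (length(r) && any(abs(r) >= window)) spec[i] <- FALSE
  }
  segments_a$specificity <- ifelse(spec, "sample_specific", "shared")
  segments_a
}

#' Copy-number-neutral territory mask
#'
#' Tiles where the log2 ratio of every supplied sample is defined and lies
#' strictly within (-`window`, +`window`); used to restrict indel calling
#' and allele-fraction analysis to diploid territory.
#'
#' @param tiles_list List of tile tables from [tile_depths()], one per
#'   tumor sample, on the same grid.
#' @param window Strict log2-ratio window.
#' @return GRanges of retained (neutral) tiles, reduced.
#' @export
non_cnv_mask <- function(tiles_list, window = 0.1) {
  if (is.data.frame(tiles_list)) tiles_list <- list(tiles_list)
  base <- tiles_list[[1L]]
  ok <- rep(TRUE, nrow(base))
  for (tl in tiles_list) {
    stopifnot(nrow(tl) == nrow(base))
    ok <- ok & !is.na(tl$log2_ratio) & tl$log2_ratio > -window &
      tl$log2_ratio < window
  }
  if (!any(ok)) return(GenomicRanges::GRanges(character(),
                                              IRanges::IRanges()))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    base$chrom[ok], IRanges::IRanges(base$start[ok], base$end[ok])))
}
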