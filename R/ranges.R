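# Interval helpers shared across modules. All interval sets are GRanges
# (1-based, closed); BED import/export through rtracklayer performs the
# 0-based half-open conversion at the file boundary.

#' Genome as a GRanges of whole chromosomes
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return GRanges covering every chromosome end to end.
#' @export
genome_ranges <- function(chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  GenomicRanges::GRanges(
    seqnames = names(chrom_lengths),
    ranges = IRanges::IRanges(start = 1L, end = as.integer(chrom_lengths)),
    seqinfo = GenomeInfoDb::Seqinfo(names(chrom_lengths),
                                    as.integer(chrom_lengths)))
}

# GRanges from a per-chromosome logical vector (TRUE = included)
mask_from_logical <- function(flags, chrom) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(GenomicRanges::GRanges(character(), IRanges::IRanges()))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts[keep], ends[keep]))
}

#' Intersect two callable masks
#'
#' The common callable territory of two samples: positions callable in both.
#'
#' @param mask_a,mask_b GRanges callable masks.
#' @return GRanges of the intersection, reduced and sorted.
#' @export
common_callable_territory <- function(mask_a, mask_b) {
  GenomicRanges::reduce(GenomicRanges::intersect(mask_a, mask_b,
                                                 ignore.strand = TRUE))
}

# point positions (chrom, pos) -> GRanges of width 1
positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos),
                                                 as.integer(pos)))
}

# TRUE for positions falling inside a mask
positions_in_mask <- function(chrom, pos, mask) {
  IRanges::overlapsAny(positions_to_granges(chrom, pos), mask,
                       ignore.strand = TRUE)
}

# total width of a GRanges after reduction
territory_width <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr,
                                      ignore.strand = TRUE))))
}
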