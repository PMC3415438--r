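# Block-sampling enrichment of variant positions in feature sets.
#
# The null preserves the variants' clustering structure: per chromosome,
# every variant position is rotated by one uniform random offset through
# the concatenated callable territory (circular), so inter-variant spacing
# within the callable space is conserved. Enrichment is reported as
# log2(observed / mean of the null), with +/- one null SD as the error
# scale, and is suppressed when fewer than `min_overlap` variants overlap
# the feature set.

# per-chromosome territory coordinate maps for circular rotation
territory_map <- function(territory) {
  territory <- GenomicRanges::reduce(GenomicRanges::sort(territory),
                                     ignore.strand = TRUE)
  if (!length(territory)) stop("empty territory")
  split_gr <- split(territory, as.character(GenomeInfoDb::seqnames(territory)))
  lapply(split_gr, function(gr) {
    w <- GenomicRanges::width(gr)
    list(starts = GenomicRanges::start(gr), ends = GenomicRanges::end(gr),
         cum = cumsum(w) - w, L = sum(w))
  })
}

# genome position -> territory coordinate (1..L); NA outside territory
to_territory <- function(map, pos) {
  k <- findInterval(pos, map$starts)
  ok <- k >= 1L & pos <= map$ends[pmax(k, 1L)]
  out <- rep(NA_real_, length(pos))
  out[ok] <- map$cum[k[ok]] + (pos[ok] - map$starts[k[ok]]) + 1
  out
}

# territory coordinate -> genome position
from_territory <- function(map, tc) {
  k <- findInterval(tc - 1, map$cum)
  map$starts[k] + (tc - map$cum[k] - 1)
}

#' Rotate variant positions within callable territory
#'
#' The enrichment null: per chromosome, all variant positions are mapped
#' into concatenated-callable-territory coordinates, shifted by one
#' uniform random offset (modulo the territory length), and mapped back.
#' The multiset of inter-variant spacings within the territory is
#' preserved; an offset of 0 is the identity.
#'
#' @param variants Data frame with `chrom`, `pos` (all inside the
#'   territory).
#' @param territory GRanges callable territory.
#' @param offsets Named integer vector of offsets per chromosome, or
#'   `NULL` to draw uniformly.
#' @return Data frame `chrom`, `pos` of rotated positions.
#' @export
sample_null <- function(variants, territory, offsets = NULL) {
  maps <- territory_map(territory)
  out <- variants[, c("chrom", "pos")]
  for (chrom in unique(out$chrom)) {
    map <- maps[[chrom]]
    if (is.null(map)) stop("variants on a chromosome absent from territory")
    i <- out$chrom == chrom
    tc <- to_territory(map, out$pos[i])
    if (anyNA(tc)) stop("variant position outside callable territory")
    off <- if (is.null(offsets)) sample.int(map$L, 1L) - 1L else
      offsets[[chrom]]
    out$pos[i] <- from_territory(map, ((tc - 1 + off) %% map$L) + 1)
  }
  out
}

# features -> per-chromosome sorted disjoint intervals in territory coords
features_in_territory <- function(maps, features) {
  features <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  out <- list()
  for (chrom in names(maps)) {
    map <- maps[[chrom]]
    f <- features[as.character(GenomeInfoDb::seqnames(features)) == chrom]
    if (!length(f)) { out[[chrom]] <- NULL; next }
    # clip features to territory segments, then translate both endpoints
    terr <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(map$starts, map$ends))
    clip <- GenomicRanges::intersect(f, terr, ignore.strand = TRUE)
    if (!length(clip)) { out[[chrom]] <- NULL; next }
    ts <- to_territory(map, GenomicRanges::start(clip))
    te <- to_territory(map, GenomicRanges::end(clip))
    # merge intervals adjacent in territory space (gap removed by clipping)
    o <- order(ts)
    ts <- ts[o]; te <- te[o]
    merged_s <- ts[1]; merged_e <- te[1]
    ms <- c(); me <- c()
    for (i in seq_along(ts)[-1]) {
      if (ts[i] <= merged_e + 1) {
        merged_e <- max(merged_e, te[i])
      } else {
        ms <- c(ms, merged_s); me <- c(me, merged_e)
        merged_s <- ts[i]; merged_e <- te[i]
      }
    }
    out[[chrom]] <- list(starts = c(ms, merged_s), ends = c(me, merged_e))
  }
  out
}

count_in_features <- function(feat, tc) {
  if (is.null(feat) || !length(tc)) return(0L)
  k <- findInterval(tc, feat$starts)
  sum(k >= 1L & tc <= feat$ends[pmax(k, 1L)])
}

#' Block-sampling enrichment of variants in a feature set
#'
#' Counts variant positions overlapping the features (intersected with the
#' callable territory), builds an empirical null by circularly rotating
#' the variants within the territory `n_samplings` times, and reports the
#' log2 ratio of observed to null-mean overlap with the null standard
#' deviation. Results with fewer than `min_overlap` observed overlaps are
#' gated (suppressed: `log2_enrichment` is `NA` and `gated` is `TRUE`).
#'
#' @param variants Data frame with `chrom`, `pos`; positions outside the
#'   territory are dropped.
#' @param features GRanges feature set.
#' @param territory GRanges callable territory (must be non-empty).
#' @param n_samplings Number of null rotations.
#' @param seed Optional RNG seed for the null draws.
#' @param min_overlap Observed-overlap gate (inclusive lower bound).
#' @param label Feature label carried into the result.
#' @return An `enrichment_result`: list with `label`, `observed`,
#'   `null_mean`, `null_sd`, `log2_enrichment`, `n_samplings`,
#'   `n_variants`, `gated`.
#' @export
enrichment <- function(variants, features, territory, n_samplings = 10000,
                       seed = NULL, min_overlap = 10, label = "features") {
  if (!length(territory)) stop("empty territory")
  if (!is.null(seed)) set.seed(seed)
  maps <- territory_map(territory)
  keep <- positions_in_mask(variants$chrom, variants$pos, territory)
  v <- variants[keep, , drop = FALSE]
  feats <- features_in_territory(maps, features)

  tcs <- lapply(names(maps), function(chrom) {
    to_territory(maps[[chrom]], v$pos[v$chrom == chrom])
  })
  names(tcs) <- names(maps)
  observed <- sum(vapply(names(maps), function(chrom) {
    count_in_features(feats[[chrom]], tcs[[chrom]])
  }, numeric(1)))

  null_counts <- rep(0, n_samplings)
  for (chrom in names(maps)) {
    tc <- tcs[[chrom]]
    if (!length(tc)) next
    map <- maps[[chrom]]
    feat <- feats[[chrom]]
    offs <- sample.int(map$L, n_samplings, replace = TRUE) - 1L
    rot <- outer(tc - 1, offs, `+`) %% map$L + 1   # n_var x n_samplings
    if (is.null(feat)) next
    k <- findInterval(rot, feat$starts)
    hit <- k >= 1L & rot <= feat$ends[pmax(k, 1L)]
    null_counts <- null_counts + colSums(matrix(hit, ncol = n_samplings))
  }
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  gated <- observed < min_overlap
  structure(list(label = label, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 log2_enrichment = if (gated || null_mean <= 0) NA_real_
                 else log2(observed / null_mean),
                 n_samplings = n_samplings, n_variants = nrow(v),
                 gated = gated),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$gated) {
    cat(sprintf(
      "<enrichment_result> %s: %d overlaps (< gate) -- suppressed\n",
      x$label, x$observed))
  } else {
    cat(sprintf(
      "<enrichment_result> %s: obs %d, null %.1f +/- %.1f, log2 %.3f [%d samplings]\n",
      x$label, x$observed, x$null_mean, x$null_sd, x$log2_enrichment,
      x$n_samplings))
  }
  invisible(x)
}

#' Enrichment profile across feature families
#'
#' One enrichment result per named feature set for the somatic variants
#' and, when given, for a common-SNP control set over the identical
#' territory.
#'
#' @param variants Somatic variant positions (`chrom`, `pos`).
#' @param feature_sets Named list of GRanges.
#' @param territory GRanges callable territory.
#' @param control Optional control position set (`chrom`, `pos`).
#' @param n_samplings,seed,min_overlap Passed to [enrichment()].
#' @return Data frame with one row per (set, feature): `set`, `feature`,
#'   `observed`, `null_mean`, `null_sd`, `log2_enrichment`, `gated`.
#' @export
enrichment_profile <- function(variants, feature_sets, territory,
                               control = NULL, n_samplings = 10000,
                               seed = NULL, min_overlap = 10) {
  if (!is.null(seed)) set.seed(seed)
  sets <- list(somatic = variants)
  if (!is.null(control)) sets$control <- control
  rows <- list()
  for (set_name in names(sets)) {
    for (feat_name in names(feature_sets)) {
      r <- enrichment(sets[[set_name]], feature_sets[[feat_name]],
                      territory, n_samplings = n_samplings, seed = NULL,
                      min_overlap = min_overlap, label = feat_name)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, feature = feat_name, observed = r$observed,
        null_mean = r$null_mean, null_sd = r$null_sd,
        log2_enrichment = r$log2_enrichment, gated = r$gated,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter a variant table to common SNPs by allele frequency
#'
#' Helper for building the common-SNP control set: keeps positions whose
#' minor allele frequency is at least `min_maf`.
#'
#' @param snps Data frame with `chrom`, `pos` and an allele-frequency
#'   column `af`.
#' @param min_maf Minimum minor allele frequency (inclusive).
#' @return The filtered data frame.
#' @export
filter_common_snps <- function(snps, min_maf = 0.05) {
  stopifnot("af" %in% names(snps))
  maf <- pmin(snps$af, 1 - snps$af)
  snps[maf >= min_maf, , drop = FALSE]
}
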