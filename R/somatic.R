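# Somatic SSNV and indel detection: tumor-vs-normal genotype comparison,
# subtraction of known variants and indel-proximal positions, the
# three-filter validation cascade, callable-territory accounting and
# callset comparison.

#' Detect somatic single-nucleotide variants
#'
#' Compares MPV-scored tumor genotypes to the MPG-scored normal genotype at
#' each site. A site is somatic when the tumor's best variant genotype
#' carries an allele absent from the normal genotype; sites whose tumor
#' allele set is a subset of the normal alleles are dropped (loss of
#' heterozygosity contributes no novel somatic allele). Positions present
#' in the known-variant list, or within `indel_window` bases (inclusive) of
#' a tumor indel, are subtracted.
#'
#' @param tumor_calls Data frame of per-site tumor calls with columns
#'   `chrom`, `pos`, `ref`, `var_genotype`, `mpv` (from [score_sites()] or
#'   [call_mpv()] rows).
#' @param normal_calls Data frame of normal calls with columns `chrom`,
#'   `pos`, `genotype`, `mpg`, `ratio`; only positions present and
#'   MPG-callable are usable.
#' @param known_variants Data frame with columns `chrom`, `pos` of known
#'   (dbSNP-style) positions, or `NULL`.
#' @param tumor_indels Data frame with columns `chrom`, `pos` of tumor
#'   indel calls used for proximity subtraction, or `NULL`.
#' @param min_mpg,min_ratio,min_mpv Callability thresholds (inclusive).
#' @param indel_window Subtraction window around indels, inclusive.
#' @return Data frame of somatic variants: `chrom`, `pos`, `ref`,
#'   `normal_genotype`, `somatic_allele`, `tumor_genotype`, `mpv`.
#' @export
detect_ssnv <- function(tumor_calls, normal_calls, known_variants = NULL,
                        tumor_indels = NULL, min_mpg = 10, min_ratio = 0.5,
                        min_mpv = 10, indel_window = 10) {
  check_sorted(tumor_calls); check_sorted(normal_calls)
  tc <- tumor_calls[!is.na(tumor_calls$mpv) & tumor_calls$mpv >= min_mpv, ,
                    drop = FALSE]
  nc <- normal_calls[!is.na(normal_calls$mpg) &
                       normal_calls$mpg >= min_mpg &
                       normal_calls$ratio >= min_ratio, , drop = FALSE]
  key_t <- paste0(tc$chrom, ":", tc$pos)
  key_n <- paste0(nc$chrom, ":", nc$pos)
  m <- match(key_t, key_n)
  ok <- !is.na(m)
  tc <- tc[ok, , drop = FALSE]
  ngt <- nc$genotype[m[ok]]

  novel <- vapply(seq_len(nrow(tc)), function(i) {
    alts <- setdiff(gt_alleles(tc$var_genotype[i]), gt_alleles(ngt[i]))
    if (length(alts)) alts[1L] else NA_character_
  }, character(1))
  keep <- !is.na(novel)
  out <- data.frame(chrom = tc$chrom, pos = tc$pos, ref = tc$ref,
                    normal_genotype = ngt, somatic_allele = unname(novel),
                    tumor_genotype = tc$var_genotype, mpv = tc$mpv,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  if (!is.null(known_variants) && nrow(out)) {
    kk <- paste0(known_variants$chrom, ":", known_variants$pos)
    out <- out[!(paste0(out$chrom, ":", out$pos) %in% kk), , drop = FALSE]
  }
  if (!is.null(tumor_indels) && nrow(out) && nrow(tumor_indels)) {
    near <- near_indel(out$chrom, out$pos, tumor_indels, indel_window)
    out <- out[!near, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

check_sorted <- function(calls) {
  o <- order(calls$chrom, calls$pos)
  if (!identical(o, seq_len(nrow(calls)))) {
    stop("call tables must be sorted by (chrom, pos)")
  }
  invisible(TRUE)
}

# TRUE where a position lies within `window` bases (inclusive) of any indel
near_indel <- function(chrom, pos, indels, window) {
  if (!length(pos) || !nrow(indels)) return(rep(FALSE, length(pos)))
  q <- positions_to_granges(chrom, pos)
  s <- GenomicRanges::GRanges(
    indels$chrom,
    IRanges::IRanges(pmax(1L, indels$pos - as.integer(window)),
                     indels$pos + as.integer(window)))
  IRanges::overlapsAny(q, s, ignore.strand = TRUE)
}

# reduce read-stack evidence lists to the per-site summaries the filters use
evidence_summary <- function(variants, normal_evidence, tumor_evidence) {
  key <- paste0(variants$chrom, ":", variants$pos)
  summarise <- function(ev, where) {
    missing <- key[!key %in% names(ev)]
    if (length(missing)) {
      stop(sprintf("missing %s evidence at site(s): %s", where,
                   paste(head(missing, 3), collapse = ", ")))
    }
    ev[key]
  }
  ne <- summarise(normal_evidence, "normal")
  te <- summarise(tumor_evidence, "tumor")
  alt <- variants$somatic_allele
  data.frame(
    normal_alt_mapq1 = vapply(seq_along(ne), function(i) {
      r <- ne[[i]]
      sum(r$mapq >= 1 & r$base == alt[i])
    }, numeric(1)),
    tumor_alt_plus = vapply(seq_along(te), function(i) {
      r <- te[[i]]
      sum(r$base == alt[i] & r$strand == "+")
    }, numeric(1)),
    tumor_alt_minus = vapply(seq_along(te), function(i) {
      r <- te[[i]]
      sum(r$base == alt[i] & r$strand == "-")
    }, numeric(1)))
}

#' Apply the three-filter somatic validation cascade
#'
#' Flags candidate somatic calls using the three validation filters:
#' \describe{
#'   \item{normal_lookup}{at least one normal-sample read of any mapping
#'     quality Q1 or greater carries the somatic allele;}
#'   \item{indel_proximity}{an indel called from low-mapping-quality reads
#'     (mapQ >= 1) with MPV score >= 10 lies within `indel_window` bases
#'     (inclusive);}
#'   \item{strand_bias}{all tumor reads carrying the somatic allele map to
#'     a single strand, with at least `min_strand_reads` such reads (a
#'     single read is insufficient evidence of bias).}
#' }
#' Flagged calls are removed from the pass set but retained with flags.
#'
#' @param variants Data frame of candidate calls (`chrom`, `pos`, `ref`,
#'   `somatic_allele`, ...), e.g. from [detect_ssnv()] or a
#'   [make_validation_fixture()].
#' @param normal_evidence,tumor_evidence Either named lists (`chrom:pos`)
#'   of per-read data frames (`base`, `baseq`, `mapq`, `strand`), or a
#'   single data.frame with columns `normal_alt_mapq1`, `tumor_alt_plus`,
#'   `tumor_alt_minus` aligned to `variants` (pass it as
#'   `normal_evidence`, leaving `tumor_evidence` `NULL`).
#' @param indels Data frame of low-mapQ indel calls (`chrom`, `pos`,
#'   `mpv`), or `NULL`.
#' @param indel_window Proximity window, inclusive.
#' @param min_indel_mpv Minimum indel MPV score for the proximity filter.
#' @param min_strand_reads Minimum somatic-allele reads before the
#'   strand-bias filter may trigger.
#' @return `variants` with added logical columns `flag_normal_lookup`,
#'   `flag_indel_proximity`, `flag_strand_bias` and `pass`, classed
#'   `somatic_filter_result`.
#' @export
apply_validation_filters <- function(variants, normal_evidence,
                                     tumor_evidence = NULL, indels = NULL,
                                     indel_window = 10, min_indel_mpv = 10,
                                     min_strand_reads = 2) {
  if (is.data.frame(normal_evidence)) {
    ev <- normal_evidence
    stopifnot(nrow(ev) == nrow(variants))
  } else {
    ev <- evidence_summary(variants, normal_evidence, tumor_evidence)
  }
  flag_nl <- ev$normal_alt_mapq1 >= 1
  if (!is.null(indels) && nrow(indels)) {
    qual <- indels[indels$mpv >= min_indel_mpv, , drop = FALSE]
    flag_ip <- near_indel(variants$chrom, variants$pos, qual, indel_window)
  } else {
    flag_ip <- rep(FALSE, nrow(variants))
  }
  n_alt <- ev$tumor_alt_plus + ev$tumor_alt_minus
  flag_sb <- n_alt >= min_strand_reads &
    (ev$tumor_alt_plus == 0 | ev$tumor_alt_minus == 0)
  out <- variants
  out$flag_normal_lookup <- flag_nl
  out$flag_indel_proximity <- flag_ip
  out$flag_strand_bias <- flag_sb
  out$pass <- !(flag_nl | flag_ip | flag_sb)
  class(out) <- c("somatic_filter_result", class(variants))
  out
}

#' @export
print.somatic_filter_result <- function(x, ...) {
  cat(sprintf(
    "<somatic_filter_result> %d calls: %d pass, %d flagged (normal_lookup %d, indel_proximity %d, strand_bias %d)\n",
    nrow(x), sum(x$pass), sum(!x$pass), sum(x$flag_normal_lookup),
    sum(x$flag_indel_proximity), sum(x$flag_strand_bias)))
  invisible(as.data.frame(x))
}

#' Summarise a filtered validation set
#'
#' Counts removed/retained calls by Sanger concordance label and computes
#' the post-filter concordance rate among retained calls.
#'
#' @param filtered A `somatic_filter_result` whose variants carry a
#'   `sanger_concordant` column.
#' @return List with `n_retained`, `n_removed`,
#'   `discordant_removed`, `concordant_removed`, and
#'   `post_filter_concordance_pct`.
#' @export
validation_summary <- function(filtered) {
  stopifnot("sanger_concordant" %in% names(filtered))
  conc <- filtered$sanger_concordant
  list(n_retained = sum(filtered$pass),
       n_removed = sum(!filtered$pass),
       discordant_removed = sum(!filtered$pass & !conc),
       concordant_removed = sum(!filtered$pass & conc),
       post_filter_concordance_pct =
         100 * sum(filtered$pass & conc) / sum(filtered$pass))
}

#' Compare two somatic callsets over common callable territory
#'
#' Restricts both position sets to the intersection mask (and to non-CNV
#' territory when supplied) before computing shared and sample-unique
#' fractions of the union.
#'
#' @param set_a,set_b Data frames with columns `chrom`, `pos`.
#' @param common_mask GRanges common callable territory.
#' @param non_cnv_mask Optional GRanges; when given both sets are further
#'   restricted to it.
#' @return List with counts `shared`, `a_only`, `b_only`, `union`, and
#'   fractions `shared_frac`, `a_only_frac`, `b_only_frac` (of the union;
#'   `NA` when the union is empty).
#' @export
compare_callsets <- function(set_a, set_b, common_mask,
                             non_cnv_mask = NULL) {
  restrict <- function(s) {
    keep <- positions_in_mask(s$chrom, s$pos, common_mask)
    if (!is.null(non_cnv_mask)) {
      keep <- keep & positions_in_mask(s$chrom, s$pos, non_cnv_mask)
    }
    unique(paste0(s$chrom, ":", s$pos)[keep])
  }
  a <- restrict(set_a); b <- restrict(set_b)
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(shared = shared, a_only = length(setdiff(a, b)),
       b_only = length(setdiff(b, a)), union = uni,
       shared_frac = if (uni) shared / uni else NA_real_,
       a_only_frac = if (uni) length(setdiff(a, b)) / uni else NA_real_,
       b_only_frac = if (uni) length(setdiff(b, a)) / uni else NA_real_)
}

#' Detect somatic indels outside copy-number variable territory
#'
#' Merges candidate indel positions across samples, keeps tumor
#' non-reference calls at or above the score threshold that differ from the
#' normal call at the same position (an absent normal call is treated as
#' reference), restricts to the non-CNV mask, and reports per-size counts.
#'
#' @param tumor_indels Data frame of tumor indel calls: `chrom`, `pos`,
#'   `size` (signed, non-zero), `score` (MPV).
#' @param normal_indels Data frame of normal indel calls: `chrom`, `pos`,
#'   `size`, `score` (MPG).
#' @param non_cnv_mask GRanges of territory with neutral copy number, or
#'   `NULL` to skip the restriction.
#' @param min_score Score threshold (inclusive) for a supported call.
#' @return List with `somatic` (data frame of somatic indel calls) and
#'   `size_histogram` (table of counts per signed size).
#' @export
detect_somatic_indels <- function(tumor_indels, normal_indels,
                                  non_cnv_mask = NULL, min_score = 10) {
  tc <- tumor_indels[!is.na(tumor_indels$score) &
                       tumor_indels$score >= min_score &
                       tumor_indels$size != 0L, , drop = FALSE]
  key_n <- paste0(normal_indels$chrom, ":", normal_indels$pos)
  m <- match(paste0(tc$chrom, ":", tc$pos), key_n)
  normal_size <- ifelse(is.na(m), 0L, normal_indels$size[m])
  normal_supported <- !is.na(m) & normal_indels$score[m] >= min_score
  somatic <- tc[!(normal_supported & normal_size == tc$size), ,
                drop = FALSE]
  if (!is.null(non_cnv_mask)) {
    keep <- positions_in_mask(somatic$chrom, somatic$pos, non_cnv_mask)
    somatic <- somatic[keep, , drop = FALSE]
  }
  rownames(somatic) <- NULL
  list(somatic = somatic,
       size_histogram = table(factor(somatic$size,
                                     levels = sort(unique(somatic$size)))))
}
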