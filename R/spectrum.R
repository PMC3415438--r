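# Mutational spectrum: the 12 stranded substitution types collapsed into 6
# pyrimidine-keyed classes (key mutation + its reverse complement), optional
# orientation relative to the transcribed strand, and exact binomial tests
# of key-versus-complement strand asymmetry.

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# "G>A" -> list(class = "C>T", slot = "complement"); pyrimidine-keyed
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt), all(ref != alt))
  is_key <- ref %in% c("C", "T")
  class <- ifelse(is_key, paste0(ref, ">", alt),
                  paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt]))
  data.frame(class = class,
             slot = ifelse(is_key, "key", "complement"),
             stringsAsFactors = FALSE)
}

#' Collapse substitutions into the six pyrimidine-keyed classes
#'
#' Each `ref>alt` substitution is mapped to one of six classes keyed by the
#' pyrimidine of the mutated pair (C>A, C>G, C>T, T>A, T>C, T>G); a
#' purine-reference substitution (e.g. G>A) counts in the complement slot
#' of its class (C>T). The UV signature appears as dominance of the C>T
#' class.
#'
#' @param variants Data frame with columns `ref` and `alt` (or
#'   `somatic_allele`, used when `alt` is absent), single bases.
#' @return A `spectrum_counts`: data frame with one row per class and
#'   columns `class`, `key`, `complement`, `total`, plus attribute
#'   `n_input`.
#' @export
collapse_spectrum <- function(variants) {
  alt <- if ("alt" %in% names(variants)) variants$alt else
    variants$somatic_allele
  ref <- variants$ref
  out <- data.frame(class = SPECTRUM_CLASSES, key = 0L, complement = 0L,
                    stringsAsFactors = FALSE)
  if (length(ref)) {
    cl <- classify_substitution(ref, alt)
    tab <- table(factor(cl$class, levels = SPECTRUM_CLASSES),
                 factor(cl$slot, levels = c("key", "complement")))
    out$key <- as.integer(tab[, "key"])
    out$complement <- as.integer(tab[, "complement"])
  }
  out$total <- out$key + out$complement
  attr(out, "n_input") <- length(ref)
  class(out) <- c("spectrum_counts", "data.frame")
  out
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf("<spectrum_counts> %d substitutions\n", sum(x$total)))
  print.data.frame(x)
  invisible(x)
}

#' Orient intronic variants by the transcribed strand
#'
#' Restricts variants to intronic positions of single-strand gene
#' territory (positions covered by genes on both strands cannot be
#' oriented and are excluded), reverse-complements substitutions falling
#' in minus-strand genes so that `ref>alt` reads along the coding
#' (untranscribed) strand, and collapses the result. Key/complement slots
#' of the returned spectrum are then strand-informative: under
#' transcription-coupled repair of UV damage the two slots of the C>T
#' class become asymmetric.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref` and `alt` (or
#'   `somatic_allele`).
#' @param genes A [gene_models()] object.
#' @return A `spectrum_counts` over the oriented intronic variants.
#' @export
orient_by_transcript <- function(variants, genes) {
  alt <- if ("alt" %in% names(variants)) variants$alt else
    variants$somatic_allele
  pos_gr <- positions_to_granges(variants$chrom, variants$pos)
  g <- genes$genes
  exonic <- GenomicRanges::reduce(genes$exons, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(pos_gr, g, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  strands <- as.character(BiocGenerics::strand(g))[S4Vectors::subjectHits(hits)]
  n_genes <- tabulate(qh, nbins = length(pos_gr))
  strand_of <- rep(NA_character_, length(pos_gr))
  strand_of[qh] <- strands          # last hit wins; only used when unique
  ok <- n_genes == 1L &
    !IRanges::overlapsAny(pos_gr, exonic, ignore.strand = TRUE)
  v <- data.frame(ref = variants$ref[ok], alt = alt[ok],
                  strand = strand_of[ok], stringsAsFactors = FALSE)
  minus <- v$strand == "-"
  v$ref[minus] <- unname(COMPLEMENT[v$ref[minus]])
  v$alt[minus] <- unname(COMPLEMENT[v$alt[minus]])
  collapse_spectrum(v)
}

#' Exact binomial test of key-versus-complement strand asymmetry
#'
#' For each class with at least one observation, a two-sided exact
#' binomial test of the key count against a 50% expectation of the class
#' total. Classes with no observations are omitted.
#'
#' @param spectrum A `spectrum_counts` (see [collapse_spectrum()]).
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data frame with `class`, `key`, `complement`, `p_value`,
#'   `significant`.
#' @export
strand_bias_test <- function(spectrum, alpha = 0.05) {
  keep <- spectrum$total >= 1L
  s <- spectrum[keep, , drop = FALSE]
  p <- vapply(seq_len(nrow(s)), function(i) {
    stats::binom.test(s$key[i], s$total[i], p = 0.5,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(class = s$class, key = s$key, complement = s$complement,
             p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}
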