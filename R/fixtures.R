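# Sanger-validation fixtures: candidate somatic call sets whose per-site
# evidence encodes the validation outcomes of the tumor/normal study —
# a tissue set of 73 calls (43 concordant with Sanger re-sequencing, 30
# discordant, 29 of which carry evidence triggering at least one of the
# three validation filters) and a cell-culture set of 78 calls (75
# concordant, 3 discordant, 2 filter-triggering).

#' Build a labeled Sanger-validation candidate call set
#'
#' Constructs a deterministic candidate SSNV set with per-site tumor and
#' normal read evidence and an indel call list, laid out so that the
#' three-filter validation cascade ([apply_validation_filters()])
#' reproduces the study's validation bookkeeping: for the tissue set, 29 of
#' 30 Sanger-discordant calls carry filter-triggering evidence (spread over
#' the normal-lookup, indel-proximity and strand-bias filters) and no
#' concordant call does; for the cell-culture set, 2 of 3 discordant calls
#' trigger a filter and none of the 75 concordant calls do.
#'
#' @param which `"tissue"` or `"cell_culture"`.
#' @return A `validation_fixture`: list with `variants` (data.frame chrom,
#'   pos, ref, normal_genotype, somatic_allele, origin,
#'   sanger_concordant), `normal_evidence` and `tumor_evidence` (named
#'   lists of per-read data frames keyed `chrom:pos`), and `indels`
#'   (data.frame chrom, pos, size, mpv of low-mapQ indel calls).
#' @export
make_validation_fixture <- function(which = c("tissue", "cell_culture")) {
  which <- match.arg(which)
  chrom <- if (which == "tissue") "chrT" else "chrC"
  if (which == "tissue") {
    n <- 73L
    concordant <- c(rep(TRUE, 43L), rep(FALSE, 30L))
    trigger <- c(rep("none", 43L),
                 rep("normal_lookup", 10L), rep("indel_proximity", 10L),
                 rep("strand_bias", 9L), "none")
  } else {
    n <- 78L
    concordant <- c(rep(TRUE, 75L), rep(FALSE, 3L))
    trigger <- c(rep("none", 75L), "normal_lookup", "strand_bias", "none")
  }
  pos <- 1000L * seq_len(n) + 500L
  variants <- data.frame(
    chrom = chrom, pos = pos, ref = "A", normal_genotype = "AA",
    somatic_allele = "G", origin = which, sanger_concordant = concordant,
    stringsAsFactors = FALSE)

  normal_evidence <- list(); tumor_evidence <- list()
  indels <- data.frame(chrom = character(), pos = integer(),
                       size = integer(), mpv = numeric(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    key <- paste0(chrom, ":", pos[i])
    nref <- 30L
    normal <- data.frame(
      base = rep("A", nref), baseq = 40, mapq = 60,
      strand = rep(c("+", "-"), length.out = nref),
      stringsAsFactors = FALSE)
    alt_n <- 8L
    tumor <- data.frame(
      base = c(rep("A", 20L), rep("G", alt_n)), baseq = 40, mapq = 60,
      strand = c(rep(c("+", "-"), length.out = 20L),
                 rep(c("+", "-"), length.out = alt_n)),
      stringsAsFactors = FALSE)
    if (trigger[i] == "normal_lookup") {
      normal <- rbind(normal, data.frame(base = c("G", "G"), baseq = 30,
                                         mapq = 10, strand = c("+", "-")))
    } else if (trigger[i] == "indel_proximity") {
      indels <- rbind(indels, data.frame(chrom = chrom, pos = pos[i] + 7L,
                                         size = 1L, mpv = 15))
    } else if (trigger[i] == "strand_bias") {
      tumor <- data.frame(
        base = c(rep("A", 25L), rep("G", 5L)), baseq = 40, mapq = 60,
        strand = c(rep(c("+", "-"), length.out = 25L), rep("+", 5L)),
        stringsAsFactors = FALSE)
    }
    normal_evidence[[key]] <- normal
    tumor_evidence[[key]] <- tumor
  }
  # a distant indel (11 bp away, outside the inclusive 10 bp window) near
  # the first concordant call exercises the boundary without triggering
  indels <- rbind(indels, data.frame(chrom = chrom, pos = pos[1L] + 11L,
                                     size = -1L, mpv = 20))
  structure(list(variants = variants, normal_evidence = normal_evidence,
                 tumor_evidence = tumor_evidence, indels = indels,
                 set = which),
            class = "validation_fixture")
}

#' @export
print.validation_fixture <- function(x, ...) {
  cat(sprintf(
    "<validation_fixture> %s set: %d calls (%d Sanger-concordant, %d discordant)\n",
    x$set, nrow(x$variants), sum(x$variants$sanger_concordant),
    sum(!x$variants$sanger_concordant)))
  invisible(x)
}
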