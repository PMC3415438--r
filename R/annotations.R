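# Synthetic annotation landscapes: gene models, chromatin-state tilings,
# per-cell-type DHS sets with controllable sharing structure, constrained
# regions, mappability, and RNA read intervals.

#' Gene model container
#'
#' Gene bodies, typed exon sub-features (`cds`, `utr5`, `utr3`) and TSS
#' positions. Sub-features must nest within their gene.
#'
#' @param genes GRanges of gene bodies with mcol `gene_id` and strand.
#' @param exons GRanges of exon sub-features with mcols `gene_id`, `type`.
#' @param tss Width-1 GRanges of transcription start sites with `gene_id`.
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons, tss) {
  stopifnot(all(exons$type %in% c("cds", "utr5", "utr3")))
  if (length(exons)) {
    hit <- GenomicRanges::findOverlaps(exons, genes, type = "within",
                                       ignore.strand = TRUE)
    if (length(unique(S4Vectors::queryHits(hit))) < length(exons)) {
      stop("every exon sub-feature must nest within a gene")
    }
  }
  structure(list(genes = sort(genes), exons = sort(exons), tss = sort(tss)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d typed exon features\n",
              length(x$genes), length(x$exons)))
  invisible(x)
}

#' Annotation-landscape configuration
#'
#' Defaults give a gene roughly every 100 kb, chromatin states with mean
#' segment length 10 kb over 15 states (the two repeat states together
#' occupying ~0.5% of the genome), 30 DHS archetypes per Mb across 12 cell
#' types (three GM lymphoblastoid lines serving as the clustering outgroup,
#' a melanocyte line as the focal type), ~5% evolutionary constrained
#' territory and ~95% mappable territory.
#'
#' @param gene_spacing Mean spacing between gene starts (bp).
#' @param gene_min_len,gene_max_len Gene length range (bp).
#' @param n_exons Exons per gene.
#' @param state_mean_len Mean chromatin-state segment length (bp).
#' @param cell_types Cell type labels for the DHS atlas.
#' @param focal Focal (melanocyte) cell type.
#' @param outgroup Outgroup cell types used to re-root the signature tree.
#' @param dhs_per_mb DHS archetypes per megabase.
#' @param dhs_width DHS width (bp).
#' @param dhs_ubiq_frac,dhs_specific_frac Fractions of archetypes present in
#'   all cell types / exactly one cell type (the remainder are clade-shared).
#' @param dhs_focal_specific If non-`NULL`, force exactly this many
#'   focal-cell-type-specific archetypes.
#' @param constrained_frac,constrained_mean_len Constrained-territory
#'   fraction and mean interval length.
#' @param low_mappability_frac,low_map_mean_len Unmappable-territory fraction
#'   and mean interval length.
#' @param transcribed_gene_frac Fraction of genes emitting RNA reads.
#' @param rna_reads_per_gene,rna_read_len RNA read count per transcribed
#'   gene and read length (bp).
#' @param rna_high_mapq_frac Fraction of RNA reads at high (Q60) mapping
#'   quality; the rest are Q10.
#' @param rna_dhs_frac Fraction of DHS archetypes that are transcribed.
#' @return An `ann_config` list.
#' @export
ann_config <- function(gene_spacing = 1e5,
                       gene_min_len = 5000, gene_max_len = 30000,
                       n_exons = 5,
                       state_mean_len = 10000,
                       cell_types = c("melano", "nhek", "k562", "hepg2",
                                      "huvec", "h1esc", "mcf7", "fibro",
                                      "hsmm", "gm12878", "gm12891",
                                      "gm12892"),
                       focal = "melano",
                       outgroup = c("gm12878", "gm12891", "gm12892"),
                       dhs_per_mb = 30, dhs_width = 300,
                       dhs_ubiq_frac = 0.2, dhs_specific_frac = 0.3,
                       dhs_focal_specific = NULL,
                       constrained_frac = 0.05, constrained_mean_len = 200,
                       low_mappability_frac = 0.05, low_map_mean_len = 500,
                       transcribed_gene_frac = 0.6,
                       rna_reads_per_gene = 30, rna_read_len = 200,
                       rna_high_mapq_frac = 0.9,
                       rna_dhs_frac = 0.3) {
  stopifnot(focal %in% cell_types, all(outgroup %in% cell_types),
            dhs_ubiq_frac + dhs_specific_frac <= 1)
  structure(as.list(environment()), class = "ann_config")
}

#' Simulate the annotation landscape
#'
#' Generates gene models whose sub-features nest within genes, a chromatin
#' state tiling that partitions each chromosome, per-cell-type DHS sets
#' with configurable sharing structure (cell-type-specific, clade-shared,
#' ubiquitous), constrained regions, a mappability mask and RNA read
#' intervals.
#'
#' @param ref Reference from [simulate_reference()].
#' @param config A [sim_config()].
#' @param ann An [ann_config()].
#' @return An `annotation_bundle`: list with `genes` ([gene_models()]),
#'   `states` (GRanges, mcol `state`), `dhs` (named list of GRanges per cell
#'   type), `dhs_archetypes` (data.frame of truth clusters), `constrained`,
#'   `mappability`, `rna` (GRanges, mcol `mapq`), and `ann`.
#' @export
simulate_annotations <- function(ref, config, ann = ann_config()) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "ann_config"))
  set.seed(config$seed + 3L)
  chroms <- sim_chrom_names(config)
  L <- config$genome_length

  gm <- sim_genes(chroms, L, ann)
  states <- sim_states(chroms, L, ann)
  dhs <- sim_dhs(chroms, L, ann)
  constrained <- sim_interval_cover(chroms, L, ann$constrained_frac,
                                    ann$constrained_mean_len)
  lowmap <- sim_interval_cover(chroms, L, ann$low_mappability_frac,
                               ann$low_map_mean_len)
  genome <- genome_ranges(setNames(rep(L, length(chroms)), chroms))
  mappability <- GenomicRanges::setdiff(genome, lowmap,
                                        ignore.strand = TRUE)
  rna <- sim_rna(gm, dhs$archetypes, L, ann)

  structure(list(genes = gm, states = states, dhs = dhs$atlas,
                 dhs_archetypes = dhs$archetypes, constrained = constrained,
                 mappability = mappability, rna = rna, ann = ann),
            class = "annotation_bundle")
}

sim_genes <- function(chroms, L, ann) {
  genes <- list(); exons <- list(); tss <- list()
  gid <- 0L
  for (chrom in chroms) {
    n_slots <- max(1L, floor(L / ann$gene_spacing))
    for (i in seq_len(n_slots)) {
      gid <- gid + 1L
      slot0 <- (i - 1L) * ann$gene_spacing
      glen <- round(runif(1, ann$gene_min_len, ann$gene_max_len))
      s <- slot0 + sample.int(ann$gene_spacing - glen - 1L, 1L)
      e <- s + glen - 1L
      if (e > L) next
      strand <- sample(c("+", "-"), 1L)
      ex <- gene_exon_layout(s, e, strand, ann$n_exons)
      id <- sprintf("gene%04d", gid)
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, strand = strand, gene_id = id)
      ex$chrom <- chrom; ex$gene_id <- id; ex$strand <- strand
      exons[[length(exons) + 1L]] <- ex
      tss[[length(tss) + 1L]] <- data.frame(
        chrom = chrom, pos = if (strand == "+") s else e,
        strand = strand, gene_id = id)
    }
  }
  g <- do.call(rbind, genes); x <- do.call(rbind, exons)
  t <- do.call(rbind, tss)
  gene_models(
    genes = GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                   strand = g$strand, gene_id = g$gene_id),
    exons = GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end),
                                   strand = x$strand, gene_id = x$gene_id,
                                   type = x$type),
    tss = GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$pos, t$pos),
                                 strand = t$strand, gene_id = t$gene_id))
}

# exon intervals for one gene; 10% of exonic bases are 5'UTR and 20% 3'UTR
# in transcription order, the remainder coding
gene_exon_layout <- function(s, e, strand, n_exons) {
  glen <- e - s + 1L
  block <- glen %/% n_exons
  ws <- pmin(round(runif(n_exons, 200, 1500)), block - 50L)
  ws <- pmax(ws, 50L)
  starts <- s + (seq_len(n_exons) - 1L) * block
  ends <- starts + ws - 1L
  ends[n_exons] <- e
  starts[n_exons] <- max(starts[n_exons], e - ws[n_exons] + 1L)
  exonic <- sum(ends - starts + 1L)
  u5 <- max(50L, round(0.1 * exonic)); u3 <- max(50L, round(0.2 * exonic))
  # walk exons in transcription order assigning utr5 | cds | utr3 spans
  ord <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  out <- list()
  consumed <- 0L
  for (i in ord) {
    w <- ends[i] - starts[i] + 1L
    offs <- consumed + seq_len(w) - 1L       # transcript coordinates
    type <- ifelse(offs < u5, "utr5",
                   ifelse(offs >= exonic - u3, "utr3", "cds"))
    if (strand == "-") type <- rev(type)
    r <- rle(type)
    en <- starts[i] + cumsum(r$lengths) - 1L
    st <- en - r$lengths + 1L
    out[[length(out) + 1L]] <- data.frame(start = st, end = en,
                                          type = r$values)
    consumed <- consumed + w
  }
  do.call(rbind, out)
}

sim_states <- function(chroms, L, ann) {
  w <- c(rep((1 - 0.0054) / 13, 13), 0.0027, 0.0027)
  out <- list()
  for (chrom in chroms) {
    n_guess <- ceiling(L / ann$state_mean_len * 2)
    lens <- pmax(200L, round(stats::rexp(n_guess, 1 / ann$state_mean_len)))
    cs <- cumsum(lens)
    n <- which(cs >= L)[1L]
    lens <- lens[seq_len(n)]
    lens[n] <- lens[n] - (cs[n] - L)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, ends),
      state = sample(1:15, n, replace = TRUE, prob = w))
  }
  suppressWarnings(do.call(c, unname(out)))
}

sim_dhs <- function(chroms, L, ann) {
  total <- L * length(chroms)
  n <- max(1L, round(ann$dhs_per_mb * total / 1e6))
  spacing <- total %/% n
  if (spacing <= ann$dhs_width + 2L) stop("DHS archetypes do not fit")
  gstart <- (seq_len(n) - 1L) * spacing +
    sample.int(spacing - ann$dhs_width - 1L, n, replace = TRUE)
  chrom_i <- pmin(gstart %/% L + 1L, length(chroms))
  start <- gstart - (chrom_i - 1L) * L + 1L
  start <- pmin(start, L - ann$dhs_width)
  end <- start + ann$dhs_width - 1L

  types <- ann$cell_types
  nt <- length(types)
  clades <- dyadic_clades(nt)
  kind <- sample(c("ubiquitous", "specific", "clade"), n, replace = TRUE,
                 prob = c(ann$dhs_ubiq_frac, ann$dhs_specific_frac,
                          1 - ann$dhs_ubiq_frac - ann$dhs_specific_frac))
  members <- vector("list", n)
  spec_idx <- which(kind == "specific")
  spec_type <- sample(types, length(spec_idx), replace = TRUE)
  if (!is.null(ann$dhs_focal_specific)) {
    k <- ann$dhs_focal_specific
    if (k > length(spec_idx)) stop("too few specific archetypes for request")
    spec_type[] <- sample(setdiff(types, ann$focal), length(spec_idx),
                          replace = TRUE)
    if (k > 0) spec_type[seq_len(k)] <- ann$focal
  }
  members[spec_idx] <- as.list(spec_type)
  members[kind == "ubiquitous"] <- list(types)
  for (i in which(kind == "clade")) {
    members[[i]] <- types[clades[[sample.int(length(clades), 1L)]]]
  }

  atlas <- lapply(setNames(types, types), function(ct) {
    has <- vapply(members, function(m) ct %in% m, logical(1))
    GenomicRanges::GRanges(chroms[chrom_i[has]],
                           IRanges::IRanges(start[has], end[has]))
  })
  archetypes <- data.frame(
    chrom = chroms[chrom_i], start = start, end = end, kind = kind,
    n_members = lengths(members), stringsAsFactors = FALSE)
  archetypes$members <- vapply(members, paste, character(1), collapse = ",")
  list(atlas = atlas, archetypes = archetypes)
}

# contiguous dyadic blocks of 1..n with 2 <= size < n (balanced clades)
dyadic_clades <- function(n) {
  out <- list()
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < 2L) return()
    if (hi - lo + 1L < n) out[[length(out) + 1L]] <<- lo:hi
    mid <- (lo + hi) %/% 2L
    recurse(lo, mid); recurse(mid + 1L, hi)
  }
  recurse(1L, n)
  out
}

sim_interval_cover <- function(chroms, L, frac, mean_len) {
  out <- list()
  for (chrom in chroms) {
    n <- max(1L, round(frac * L / mean_len))
    w <- pmax(50L, round(stats::rexp(n, 1 / mean_len)))
    s <- sample.int(L, n)
    e <- pmin(s + w - 1L, L)
    out[[chrom]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  }
  GenomicRanges::reduce(suppressWarnings(do.call(c, unname(out))))
}

sim_rna <- function(gm, archetypes, L, ann) {
  reads <- list()
  genes <- gm$genes
  n_tx <- round(ann$transcribed_gene_frac * length(genes))
  tx <- sort(sample.int(length(genes), n_tx))
  for (i in tx) {
    g <- genes[i]
    w <- GenomicRanges::width(g)
    if (w <= ann$rna_read_len + 1L) next
    s <- GenomicRanges::start(g) +
      sample.int(w - ann$rna_read_len, ann$rna_reads_per_gene,
                 replace = TRUE) - 1L
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(g)), start = s,
      end = s + ann$rna_read_len - 1L)
  }
  tx_dhs <- which(runif(nrow(archetypes)) < ann$rna_dhs_frac)
  for (i in tx_dhs) {
    s <- max(1L, archetypes$start[i] - 50L)
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = archetypes$chrom[i],
      start = s + c(0L, 40L, 80L),
      end = pmin(s + c(0L, 40L, 80L) + ann$rna_read_len - 1L, L))
  }
  r <- do.call(rbind, reads)
  mapq <- ifelse(runif(nrow(r)) < ann$rna_high_mapq_frac, 60, 10)
  sort(GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end),
                              mapq = mapq))
}
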