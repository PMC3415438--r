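# Format readers/writers: BED and GFF3 through rtracklayer, a minimal VCF
# dialect (CHROM POS ID REF ALT QUAL FILTER INFO), the per-read pileup TSV
# dialect, Newick through ape, and YAML pipeline configuration.

#' Read a BED file as GRanges
#'
#' @param file Path to a BED file (0-based half-open on disk; returned as
#'   1-based closed GRanges).
#' @return GRanges.
#' @export
read_bed <- function(file) {
  tryCatch(suppressWarnings(rtracklayer::import(file, format = "BED")),
           error = function(e) {
             stop(sprintf("failed to read BED file '%s': %s", file,
                          conditionMessage(e)))
           })
}

#' Write GRanges to a BED file
#'
#' @param gr GRanges (optionally with mcols `name`, `score`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bed <- function(gr, file) {
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Write somatic variants as VCF
#'
#' Minimal VCF 4.2 dialect: `ID` carries the origin label when present,
#' `INFO` the MPV score, and `FILTER` either `PASS` or the
#' semicolon-joined validation-filter flags.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`,
#'   `somatic_allele` (or `alt`), optional `mpv`, `origin` and filter-flag
#'   columns from [apply_validation_filters()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(variants, file) {
  alt <- if ("alt" %in% names(variants)) variants$alt else
    variants$somatic_allele
  filt <- rep("PASS", nrow(variants))
  flags <- intersect(c("flag_normal_lookup", "flag_indel_proximity",
                       "flag_strand_bias"), names(variants))
  if (length(flags)) {
    short <- sub("^flag_", "", flags)
    for (i in seq_len(nrow(variants))) {
      on <- short[unlist(variants[i, flags])]
      if (length(on)) filt[i] <- paste(on, collapse = ";")
    }
  }
  info <- if ("mpv" %in% names(variants)) {
    sprintf("MPV=%.2f", variants$mpv)
  } else rep(".", nrow(variants))
  id <- if ("origin" %in% names(variants)) variants$origin else
    rep(".", nrow(variants))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MPV,Number=1,Type=Float,Description=\"MPV score\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(variants)) {
    writeLines(paste(variants$chrom, variants$pos, id, variants$ref, alt,
                     ".", filt, info, sep = "\t"), con)
  }
  invisible(file)
}

#' Read the minimal VCF dialect
#'
#' @param file Path to a VCF written by [write_vcf()] or any
#'   tab-delimited VCF with the eight fixed columns.
#' @return Data frame: `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter`, `info`.
#' @export
read_vcf <- function(file) {
  lines <- readLines(file)
  body <- which(!startsWith(lines, "#"))
  cols <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(cols) < 8L)
  if (length(bad)) {
    stop(sprintf("malformed VCF line %d in '%s'", body[bad[1L]], file))
  }
  m <- do.call(rbind, cols)
  if (is.null(m)) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), qual = character(),
                      filter = character(), info = character()))
  }
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), id = m[, 3],
             ref = m[, 4], alt = m[, 5], qual = m[, 6], filter = m[, 7],
             info = m[, 8], stringsAsFactors = FALSE)
}

#' Write per-read pileup evidence as TSV
#'
#' Dialect: `chrom  pos  ref  depth  reads` with `reads` a comma-separated
#' list of `base:baseQ:mapQ:strand` tuples and 1-based positions.
#'
#' @param sites List of [site_evidence()] objects.
#' @param file Output path (plain or `.gz`).
#' @return `file`, invisibly.
#' @export
write_pileup <- function(sites, file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  for (s in sites) {
    r <- s$reads
    tup <- if (nrow(r)) {
      paste(sprintf("%s:%g:%g:%s", r$base, r$baseq, r$mapq, r$strand),
            collapse = ",")
    } else "."
    writeLines(paste(s$chrom, s$pos, s$ref, nrow(r), tup, sep = "\t"), con)
  }
  invisible(file)
}

#' Read the per-read pileup TSV dialect
#'
#' @param file Path written by [write_pileup()].
#' @return Named list (`chrom:pos`) of [site_evidence()] objects.
#' @export
read_pileup <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "r") else file(file, "r")
  on.exit(close(con))
  lines <- readLines(con)
  out <- vector("list", length(lines))
  keys <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L) {
      stop(sprintf("malformed pileup line %d in '%s'", i, file))
    }
    if (f[5] == ".") {
      out[[i]] <- site_evidence(f[1], as.integer(f[2]), f[3])
    } else {
      tup <- strsplit(strsplit(f[5], ",", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
      if (any(lengths(tup) != 4L)) {
        stop(sprintf("malformed read tuple on line %d in '%s'", i, file))
      }
      m <- do.call(rbind, tup)
      out[[i]] <- site_evidence(f[1], as.integer(f[2]), f[3],
                                base = m[, 1], baseq = as.numeric(m[, 2]),
                                mapq = as.numeric(m[, 3]), strand = m[, 4])
    }
    keys[i] <- paste0(f[1], ":", f[2])
  }
  setNames(out, keys)
}

#' Write gene models as GFF3
#'
#' @param genes A [gene_models()] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gene_models <- function(genes, file) {
  type_map <- c(cds = "CDS", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")
  g <- genes$genes
  g$type <- "gene"
  g$ID <- g$gene_id
  ex <- genes$exons
  ex$ID <- paste0(ex$gene_id, ".", seq_along(ex))
  ex$Parent <- ex$gene_id
  ex$type <- unname(type_map[ex$type])
  ex$phase <- ifelse(ex$type == "CDS", 0L, NA_integer_)
  mcols(ex) <- mcols(ex)[, c("type", "ID", "Parent", "gene_id", "phase")]
  mcols(g)$Parent <- NA_character_
  mcols(g)$phase <- NA_integer_
  mcols(g) <- mcols(g)[, c("type", "ID", "Parent", "gene_id", "phase")]
  rtracklayer::export(c(g, ex), file, format = "gff3")
  invisible(file)
}

#' Read gene models from GFF3
#'
#' Expects `gene` records plus `CDS`/`five_prime_UTR`/`three_prime_UTR`
#' sub-features linked by `Parent`; the TSS is the strand-aware gene
#' start.
#'
#' @param file Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(file) {
  gr <- tryCatch(rtracklayer::import(file, format = "gff3"),
                 error = function(e) {
                   stop(sprintf("failed to read GFF3 file '%s': %s", file,
                                conditionMessage(e)))
                 })
  rev_map <- c(CDS = "cds", five_prime_UTR = "utr5",
               three_prime_UTR = "utr3")
  g <- gr[gr$type == "gene"]
  gene_id <- if (!is.null(g$gene_id)) g$gene_id else as.character(g$ID)
  genes <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                                  IRanges::ranges(g),
                                  strand = BiocGenerics::strand(g),
                                  gene_id = gene_id)
  ex <- gr[as.character(gr$type) %in% names(rev_map)]
  parent <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1))
  exons <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex),
                                  IRanges::ranges(ex),
                                  strand = BiocGenerics::strand(ex),
                                  gene_id = parent,
                                  type = unname(rev_map[as.character(ex$type)]))
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  tpos <- ifelse(plus, GenomicRanges::start(genes),
                 GenomicRanges::end(genes))
  tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(tpos, tpos),
                                strand = BiocGenerics::strand(genes),
                                gene_id = genes$gene_id)
  gene_models(genes, exons, tss)
}

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis with their standard defaults:
#' MPG score >= 10 with coverage ratio >= 0.5, MPV score >= 10, a 10 bp
#' indel subtraction window, 5 kb copy-number tiles at 80% mappability,
#' the +/-0.1 log2 cross-sample CNV window, 10000 enrichment samplings
#' gated at 10 overlaps, a 5 kb TSS-proximal window, a 10 kb non-genic
#' mask with 50 kb constraint tiles, and a Q30 RNA mapping-quality
#' threshold.
#'
#' @param sim A [sim_config()] describing the synthetic genome.
#' @param ann An [ann_config()] describing the annotation landscape.
#' @param min_mpg,min_ratio,min_mpv Callability thresholds.
#' @param indel_window Indel subtraction/proximity window (bp, inclusive).
#' @param cnv_window Cross-sample CNV specificity log2 window.
#' @param cnv_amp,cnv_del Segment-calling log2 thresholds.
#' @param tile_width CNV tile width (bp).
#' @param min_mappable Minimum mappable tile fraction.
#' @param n_samplings Enrichment null samplings.
#' @param min_overlap Enrichment observed-overlap gate.
#' @param tss_window TSS-proximal window (bp).
#' @param nongenic_mask_window Gene/TSS exclusion flank (bp).
#' @param nongenic_tile_width Constraint tile width (bp).
#' @param rna_mapq RNA-read mapping-quality threshold.
#' @param purity_min_sites,purity_min_depth,purity_bandwidth Purity
#'   estimator controls.
#' @param control_max_sites Common-SNP control positions retained for
#'   enrichment (thinned deterministically when more are available).
#' @param seed Pipeline seed (defaults to the simulation seed).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), ann = ann_config(),
                            min_mpg = 10, min_ratio = 0.5, min_mpv = 10,
                            indel_window = 10, cnv_window = 0.1,
                            cnv_amp = 0.25, cnv_del = -0.25,
                            tile_width = 5000, min_mappable = 0.8,
                            n_samplings = 10000, min_overlap = 10,
                            tss_window = 5000,
                            nongenic_mask_window = 10000,
                            nongenic_tile_width = 50000,
                            rna_mapq = 30,
                            purity_min_sites = 100,
                            purity_min_depth = 10,
                            purity_bandwidth = 0.02,
                            control_max_sites = 2000,
                            seed = sim$seed) {
  cfg <- as.list(environment())
  stopifnot(min_mpg >= 0, min_mpv >= 0, min_ratio >= 0, indel_window >= 0,
            cnv_window > 0, tile_width > 0, n_samplings > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pipeline_config <- function(config, file) {
  flat <- unclass(config)
  flat$sim <- unclass(flat$sim)
  for (nm in c("purity", "mean_depth", "base_q_model", "base_comp")) {
    flat$sim[[nm]] <- as.list(flat$sim[[nm]])  # keep names in the YAML map
  }
  flat$sim$cnv_spec <- if (nrow(config$sim$cnv_spec)) {
    as.list(config$sim$cnv_spec)
  } else NULL
  flat$ann <- unclass(flat$ann)
  yaml::write_yaml(flat, file)
  invisible(file)
}

#' Read a pipeline configuration from YAML
#'
#' @param file Path written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  sim_args <- raw$sim
  for (nm in c("purity", "mean_depth", "base_q_model", "base_comp")) {
    sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  if (!is.null(names(sim_args$base_q_model))) {
    names(sim_args$base_q_model) <- names(raw$sim$base_q_model)
  }
  sim_args$cnv_spec <- if (length(raw$sim$cnv_spec) &&
                             length(raw$sim$cnv_spec$chrom)) {
    as.data.frame(lapply(raw$sim$cnv_spec, unlist),
                  stringsAsFactors = FALSE)
  } else NULL
  sim <- do.call(sim_config, sim_args)
  ann_args <- raw$ann
  ann_args$cell_types <- unlist(ann_args$cell_types)
  ann_args$outgroup <- unlist(ann_args$outgroup)
  ann <- do.call(ann_config, ann_args)
  rest <- raw[setdiff(names(raw), c("sim", "ann"))]
  do.call(pipeline_config, c(list(sim = sim, ann = ann), rest))
}
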