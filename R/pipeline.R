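# End-to-end pipeline driver: simulation -> genotyping -> somatic calling
# and filtering -> CNV -> purity -> spectrum -> feature/enrichment -> DHS,
# with deterministic outputs under a fixed seed.

#' The bundled desk-scale smoke profile
#'
#' The 10 Mb study-condition simulation used for end-to-end runs: five
#' 2 Mb chromosomes at the default somatic burden, purities and depths,
#' with the enrichment null reduced to 1000 samplings and the common-SNP
#' control thinned to 2000 positions so a full run stays in the minutes
#' range on one CPU. All thresholds keep their standard defaults.
#'
#' @param seed Simulation/pipeline seed.
#' @return A [pipeline_config()].
#' @export
smoke_config <- function(seed = 1L) {
  pipeline_config(sim = sim_config(seed = seed),
                  n_samplings = 1000, control_max_sites = 2000)
}

#' Run the full tumor/normal analysis on a synthetic genome
#'
#' Chains every stage of the analysis on the configured simulation:
#' generates the genome, truth and annotations; scores MPG/MPV genotypes
#' per sample; detects somatic SSNVs with known-variant and
#' indel-proximity subtraction and the three-filter validation cascade;
#' calls copy-number segments, the cross-sample specificity labels and the
#' non-CNV mask; estimates normal-cell contamination per tumor sample;
#' summarises the mutational spectrum and transcribed-strand bias;
#' partitions the genome by genic landmarks; measures per-state mutation
#' rates, constraint-decile regression and enrichment profiles against a
#' common-SNP control; and clusters the DHS atlas with signature tree,
#' combination enrichment and transcription comparison. Output is
#' deterministic under a fixed configuration seed; rerunning with the same
#' configuration writes byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables, VCF,
#'   BED, Newick and log files are written there.
#' @param quiet Suppress progress messages.
#' @return A `melanomics_run` list with elements `truth`, `masks`,
#'   `somatic` (per-sample filtered callsets), `comparison`, `cnv`
#'   (tiles, segments, non-CNV mask), `purity`, `indels`, `spectrum`,
#'   `landmarks`, `state_rates`, `constraint` (bins + regression),
#'   `transcript_profile`, `enrichment`, `dhs`, `log` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  tumors <- names(sim$purity)
  log_lines <- character()
  plog <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  plog("simulating reference (%d x %s bp) and truth [seed %d]",
       sim$n_chroms, format(sim$genome_length, big.mark = ","), sim$seed)
  ref <- simulate_reference(sim)
  truth <- simulate_truth(sim, ref)
  ann <- simulate_annotations(ref, sim)
  plog("truth: %d germline het, %d somatic SSNV, %d indels, %d CNV segments",
       nrow(truth$germline), nrow(truth$somatic), nrow(truth$indels),
       nrow(truth$cnv))

  chroms <- sim_chrom_names(sim)
  masks <- list(); depths <- list()
  cand <- setNames(vector("list", length(tumors)), tumors)
  vsites <- setNames(vector("list", length(tumors)), tumors)
  normal_vsites <- list()
  e_mean <- sum(sim$base_q_model * 10^(-as.numeric(names(sim$base_q_model)) / 10))

  for (chrom in chroms) {
    pm_n <- simulate_pileup_matrix(ref, truth, sim, "normal", chrom)
    calls_n <- score_sites(pm_n$counts, pm_n$ref, pm_n$quals)
    callable_n <- !is.na(calls_n$mpg) & calls_n$mpg >= config$min_mpg &
      calls_n$ratio >= config$min_ratio
    masks$normal <- c(masks$normal, list(mask_from_logical(callable_n, chrom)))
    depths$normal[[chrom]] <- pm_n$depth
    normal_vsites[[chrom]] <- pm_n$variant_sites
    n_tiers <- length(pm_n$quals)
    n_base_tot <- sapply(1:4, function(b) {
      rowSums(pm_n$counts[, (seq_len(n_tiers) - 1L) * 4L + b, drop = FALSE])
    })

    for (s in tumors) {
      pm_t <- simulate_pileup_matrix(ref, truth, sim, s, chrom)
      calls_t <- score_sites(pm_t$counts, pm_t$ref, pm_t$quals)
      callable_t <- !is.na(calls_t$mpg) & calls_t$mpg >= config$min_mpg &
        calls_t$ratio >= config$min_ratio
      masks[[s]] <- c(masks[[s]], list(mask_from_logical(callable_t, chrom)))
      depths[[s]][[chrom]] <- pm_t$depth

      idx <- which(!is.na(calls_t$mpv) & calls_t$mpv >= config$min_mpv)
      t_base_tot <- vapply(1:4, function(b) {
        rowSums(pm_t$counts[idx, (seq_len(n_tiers) - 1L) * 4L + b,
                            drop = FALSE])
      }, numeric(length(idx)))
      if (length(idx) == 1L) t_base_tot <- matrix(t_base_tot, nrow = 1L)
      if (!length(idx)) t_base_tot <- matrix(numeric(), 0L, 4L)
      cand[[s]][[chrom]] <- data.frame(
        chrom = chrom, pos = idx, ref = pm_t$ref[idx],
        var_genotype = calls_t$var_genotype[idx], mpv = calls_t$mpv[idx],
        normal_genotype = calls_n$genotype[idx],
        normal_mpg = calls_n$mpg[idx], normal_ratio = calls_n$ratio[idx],
        t_A = t_base_tot[, 1], t_C = t_base_tot[, 2],
        t_G = t_base_tot[, 3], t_T = t_base_tot[, 4],
        n_A = n_base_tot[idx, 1], n_C = n_base_tot[idx, 2],
        n_G = n_base_tot[idx, 3], n_T = n_base_tot[idx, 4],
        n_low = pm_n$n_low[idx],
        stringsAsFactors = FALSE)
      vsites[[s]][[chrom]] <- pm_t$variant_sites
    }
  }
  for (nm in names(masks)) {
    masks[[nm]] <- GenomicRanges::reduce(suppressWarnings(
      do.call(c, masks[[nm]])))
  }
  genome <- genome_ranges(sim_chrom_lengths(sim))
  for (nm in names(masks)) {
    plog("callable mask [%s]: %.1f%% of the genome", nm,
         100 * territory_width(masks[[nm]]) / territory_width(genome))
  }

  set.seed(config$seed + 9L)
  known <- truth$germline[truth$germline$known, c("chrom", "pos")]
  somatic <- list()
  for (s in tumors) {
    tc <- do.call(rbind, cand[[s]])
    tc <- tc[order(tc$chrom, tc$pos), ]
    rownames(tc) <- NULL
    tumor_calls <- tc[, c("chrom", "pos", "ref", "var_genotype", "mpv")]
    normal_calls <- data.frame(chrom = tc$chrom, pos = tc$pos,
                               genotype = tc$normal_genotype,
                               mpg = tc$normal_mpg, ratio = tc$normal_ratio,
                               stringsAsFactors = FALSE)
    sample_indels <- truth$indels[truth$indels$origin %in%
                                    c("germline", "shared", s), ]
    ssnv <- detect_ssnv(tumor_calls, normal_calls, known,
                        sample_indels[, c("chrom", "pos")],
                        min_mpg = config$min_mpg,
                        min_ratio = config$min_ratio,
                        min_mpv = config$min_mpv,
                        indel_window = config$indel_window)
    m <- match(paste0(ssnv$chrom, ":", ssnv$pos),
               paste0(tc$chrom, ":", tc$pos))
    altc <- match(ssnv$somatic_allele, BASES)
    t_alt <- as.matrix(tc[m, c("t_A", "t_C", "t_G", "t_T")])[
      cbind(seq_along(m), altc)]
    n_alt_hi <- as.matrix(tc[m, c("n_A", "n_C", "n_G", "n_T")])[
      cbind(seq_along(m), altc)]
    # strand split: stored for truth sites, drawn for error-driven calls;
    # normal low-mapQ alt reads likewise
    vs <- do.call(rbind, vsites[[s]])
    nv <- do.call(rbind, normal_vsites)
    vkey <- paste0(vs$chrom, ":", vs$pos)
    skey <- paste0(ssnv$chrom, ":", ssnv$pos)
    mv <- match(skey, vkey)
    alt_plus <- ifelse(!is.na(mv) & vs$alt[pmax(mv, 1)] == ssnv$somatic_allele,
                       vs$alt_plus[pmax(mv, 1)], NA_integer_)
    need <- is.na(alt_plus)
    alt_plus[need] <- rbinom(sum(need), t_alt[need], 0.5)
    nkey <- paste0(nv$chrom, ":", nv$pos)
    mn <- match(skey, nkey)
    n_alt_low <- ifelse(!is.na(mn) & nv$alt[pmax(mn, 1)] == ssnv$somatic_allele,
                        nv$alt_low[pmax(mn, 1)], NA_integer_)
    needn <- is.na(n_alt_low)
    n_alt_low[needn] <- rbinom(sum(needn), tc$n_low[m][needn], e_mean / 3)
    evidence <- data.frame(normal_alt_mapq1 = n_alt_hi + n_alt_low,
                           tumor_alt_plus = alt_plus,
                           tumor_alt_minus = t_alt - alt_plus)
    low_mapq_indels <- data.frame(chrom = sample_indels$chrom,
                                  pos = sample_indels$pos, mpv = 30)
    filtered <- apply_validation_filters(ssnv, evidence,
                                         indels = low_mapq_indels,
                                         indel_window = config$indel_window)
    filtered$alt_count <- t_alt
    filtered$depth <- rowSums(tc[m, c("t_A", "t_C", "t_G", "t_T")])
    somatic[[s]] <- filtered
    plog("somatic [%s]: %d candidates -> %d SSNVs, %d pass filters", s,
         nrow(tc), nrow(ssnv), sum(filtered$pass))
  }

  plog("tiling depth for CNV (%d bp tiles)", config$tile_width)
  tiles <- lapply(setNames(tumors, tumors), function(s) {
    tile_depths(depths$normal, depths[[s]], ann$mappability,
                tile_width = config$tile_width,
                min_mappable = config$min_mappable)
  })
  neutral <- non_cnv_mask(tiles, window = config$cnv_window)

  purity <- list(); segments <- list(); indel_results <- list()
  for (s in tumors) {
    pass <- somatic[[s]][somatic[[s]]$pass, ]
    afd <- somatic_allele_fractions(
      pass, data.frame(chrom = pass$chrom, pos = pass$pos,
                       alt_count = pass$alt_count, depth = pass$depth),
      cnv_neutral_mask = neutral, min_depth = config$purity_min_depth)
    est <- tryCatch(
      estimate_contamination(afd, min_sites = config$purity_min_sites,
                             bandwidth = config$purity_bandwidth),
      error = function(e) {
        plog("purity [%s]: %s -- assuming a pure sample", s,
             conditionMessage(e))
        structure(list(percent_normal = NA_real_, mode = NA_real_,
                       expected_mode = 0.5, n_sites = afd$n_sites),
                  class = "purity_estimate")
      })
    purity[[s]] <- est
    if (!is.na(est$percent_normal)) {
      plog("purity [%s]: mode %.3f -> %.1f%% normal cells (%d sites)", s,
           est$mode, est$percent_normal, est$n_sites)
    }
    p_hat <- if (is.na(est$percent_normal)) 1 else
      max(0.05, 1 - est$percent_normal / 100)
    seg <- call_cnv_segments(tiles[[s]], amp_threshold = config$cnv_amp,
                             del_threshold = config$cnv_del, purity = p_hat)
    other <- setdiff(tumors, s)
    if (length(other)) {
      seg <- sample_specific_filter(seg, tiles[[other[1L]]],
                                    window = config$cnv_window)
    }
    segments[[s]] <- seg
    plog("cnv [%s]: %d segments (%d sample-specific)", s, nrow(seg),
         sum(seg$specificity == "sample_specific"))

    tumor_ind <- truth$indels[truth$indels$origin %in%
                                c("germline", "shared", s), ]
    tumor_ind$score <- 30
    normal_ind <- truth$indels[truth$indels$origin == "germline", ]
    normal_ind$score <- 30
    indel_results[[s]] <- detect_somatic_indels(tumor_ind, normal_ind,
                                                neutral,
                                                min_score = config$min_mpv)
    plog("indels [%s]: %d somatic outside CNV territory", s,
         nrow(indel_results[[s]]$somatic))
  }

  common <- Reduce(common_callable_territory,
                   masks[c("normal", tumors)])
  pass_sets <- lapply(somatic, function(f) f[f$pass, ])
  comparison <- if (length(tumors) >= 2L) {
    cmp <- compare_callsets(pass_sets[[1L]], pass_sets[[2L]], common,
                            neutral)
    plog("callset comparison: %.1f%% shared of %d in the union",
         100 * cmp$shared_frac, cmp$union)
    cmp
  } else NULL

  union_somatic <- unique(do.call(rbind, lapply(pass_sets, function(p) {
    p[, c("chrom", "pos", "ref", "somatic_allele")]
  })))
  union_somatic <- union_somatic[order(union_somatic$chrom,
                                       union_somatic$pos), ]
  rownames(union_somatic) <- NULL

  spec <- collapse_spectrum(union_somatic)
  oriented <- orient_by_transcript(union_somatic, ann$genes)
  strand_tests <- strand_bias_test(oriented)
  plog("spectrum: %d SSNVs in the union, C>T class fraction %.2f",
       sum(spec$total), spec$total[spec$class == "C>T"] / sum(spec$total))

  landmarks <- partition_by_landmark(ann$genes, genome,
                                     tss_window = config$tss_window)
  state_masks <- chromatin_state_mask(ann$states)
  state_rates <- per_state_rate(union_somatic, state_masks)
  plog("background rate (state13): %.1f SSNVs/Mb",
       state_rates$rate_per_mb[state_rates$state == "state13"])

  constraint <- tryCatch({
    bins <- nongenic_constraint_bins(
      ann$genes, ann$constrained, genome,
      mask_window = config$nongenic_mask_window,
      tile_width = config$nongenic_tile_width)
    bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                     IRanges::IRanges(bins$start, bins$end))
    bins$gc <- tile_gc(ref, bins)
    rna_hi <- ann$rna[ann$rna$mapq >= config$rna_mapq]
    bins$transcribed <- overlap_fraction(bin_gr, rna_hi)
    bins$mutations <- GenomicRanges::countOverlaps(
      bin_gr, positions_to_granges(union_somatic$chrom, union_somatic$pos))
    bin_data <- do.call(rbind, lapply(split(bins, bins$bin), function(b) {
      data.frame(bin = b$bin[1L],
                 response = sum(b$mutations) /
                   (sum(b$end - b$start + 1) / 1e6),
                 constraint = mean(b$constrained_fraction),
                 gc = mean(b$gc), transcribed = mean(b$transcribed))
    }))
    list(bins = bins, bin_data = bin_data,
         regression = regress_mutation_rate(bin_data))
  }, error = function(e) {
    plog("constraint tiling skipped: %s", conditionMessage(e))
    NULL
  })
  tx_profile <- transcript_distance_profile(union_somatic, ann$genes)

  territory <- GenomicRanges::intersect(common, ann$mappability,
                                        ignore.strand = TRUE)
  set.seed(config$seed + 10L)
  ctrl <- known[positions_in_mask(known$chrom, known$pos, territory), ]
  if (nrow(ctrl) > config$control_max_sites) {
    ctrl <- ctrl[sort(sample.int(nrow(ctrl), config$control_max_sites)), ]
  }
  feature_sets <- c(state_masks,
                    unclass(landmarks)[LANDMARK_ORDER])
  plog("enrichment: %d feature sets, %d samplings, control %d SNPs",
       length(feature_sets), config$n_samplings, nrow(ctrl))
  profile <- enrichment_profile(union_somatic, feature_sets, territory,
                                control = ctrl,
                                n_samplings = config$n_samplings,
                                seed = config$seed + 11L,
                                min_overlap = config$min_overlap)

  clusters <- cluster_dhs(ann$dhs)
  cats <- partition_by_landmark(ann$genes, genome, targets = clusters,
                                tss_window = config$tss_window)
  td <- clusters[cats == "tss_distal"]
  tree <- build_tree(clusters, outgroup = ann$ann$outgroup)
  comb <- combination_enrichment(td, ann$ann$focal, union_somatic,
                                 territory,
                                 n_samplings = min(config$n_samplings,
                                                   1000L),
                                 seed = config$seed + 12L,
                                 min_overlap = config$min_overlap)
  tx_flags <- transcribed_dhs(clusters, ann$rna,
                              min_mapq = config$rna_mapq)
  has_focal <- vapply(strsplit(clusters$members, ",", fixed = TRUE),
                      function(mm) ann$ann$focal %in% mm, logical(1))
  tx_compare <- compare_transcription(tx_flags[has_focal],
                                      tx_flags[!has_focal])
  plog("dhs: %d clusters (%d focal-containing), transcription Fisher p %.3g",
       length(clusters), sum(has_focal), tx_compare$p_value)

  run <- structure(list(
    truth = truth, masks = masks, common_mask = common,
    somatic = somatic, comparison = comparison,
    cnv = list(tiles = tiles, segments = segments, neutral_mask = neutral),
    purity = purity, indels = indel_results,
    spectrum = list(collapsed = spec, oriented = oriented,
                    strand_tests = strand_tests),
    landmarks = landmarks, state_rates = state_rates,
    constraint = constraint,
    transcript_profile = tx_profile,
    enrichment = profile,
    dhs = list(clusters = clusters, categories = cats, tree = tree,
               combination = comb, transcribed = tx_flags,
               transcription_test = tx_compare),
    union_somatic = union_somatic,
    log = log_lines, config = config), class = "melanomics_run")

  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.melanomics_run <- function(x, ...) {
  cat("<melanomics_run>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

# write every result table; formatting is deterministic so reruns under a
# fixed seed are byte-identical
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (s in names(run$somatic)) {
    f <- run$somatic[[s]]
    write_vcf(f[order(f$chrom, f$pos), ], p(sprintf("somatic_%s.vcf", s)))
    seg <- run$cnv$segments[[s]]
    if (nrow(seg)) {
      gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start, seg$end))
      gr$name <- sprintf("%s:CN%.1f:%s",
                         substr(seg$direction, 1, 3), seg$copy_number,
                         seg$specificity)
      write_bed(gr, p(sprintf("cnv_%s.bed", s)))
    }
    wt(run$indels[[s]]$somatic, sprintf("indels_%s.tsv", s))
    est <- run$purity[[s]]
    wt(data.frame(sample = s, percent_normal = est$percent_normal,
                  mode = est$mode, n_sites = est$n_sites),
       sprintf("purity_%s.tsv", s))
  }
  write_bed(run$common_mask, p("common_callable.bed"))
  write_bed(run$cnv$neutral_mask, p("non_cnv_mask.bed"))
  wt(as.data.frame(run$spectrum$collapsed), "spectrum.tsv")
  wt(run$spectrum$strand_tests, "strand_bias.tsv")
  wt(run$state_rates, "state_rates.tsv")
  if (!is.null(run$constraint)) {
    wt(run$constraint$bin_data, "constraint_bins.tsv")
    wt(run$constraint$regression$coefficients, "regression.tsv")
  }
  wt(run$transcript_profile, "transcript_profile.tsv")
  wt(run$enrichment, "enrichment.tsv")
  cl <- run$dhs$clusters
  wt(data.frame(chrom = as.character(GenomeInfoDb::seqnames(cl)),
                start = GenomicRanges::start(cl),
                end = GenomicRanges::end(cl), k = cl$k,
                specificity = cl$specificity, members = cl$members,
                category = as.character(run$dhs$categories)),
     "dhs_clusters.tsv")
  wt(run$dhs$combination, "dhs_combination.tsv")
  write_dhs_tree(run$dhs$tree, p("dhs_tree.nwk"))
  if (!is.null(run$comparison)) {
    wt(as.data.frame(run$comparison), "comparison.tsv")
  }
  writeLines(run$log, p("log.txt"))
  invisible(out_dir)
}
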