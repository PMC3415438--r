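# Cross-cell-type DHS analysis: single-linkage interval clustering into
# regions active in single, multiple or all cell types; binary-profile
# hierarchical signature trees with outgroup re-rooting; enrichment as a
# function of the number of active cell contexts; and DHS transcription
# classification with Fisher comparison.

#' Single-linkage clustering of DHSs across cell types
#'
#' Links any two DHS intervals overlapping by at least 1 bp; connected
#' components become clusters spanning the union interval, with the member
#' set given by the contributing cell types. Specificity is
#' `cell_type_specific` (one member), `ubiquitous` (all members) or
#' `shared_k` otherwise.
#'
#' @param atlas Named list of GRanges, one per cell type, each
#'   non-overlapping within the type.
#' @return GRanges of cluster intervals with mcols `members` (comma-joined
#'   cell types), `k` (member count) and `specificity`; the atlas names
#'   are recorded in `metadata(...)$cell_types` (see
#'   [cluster_cell_types()]).
#' @export
cluster_dhs <- function(atlas) {
  stopifnot(is.list(atlas), !is.null(names(atlas)))
  for (ct in names(atlas)) {
    if (any(GenomicRanges::countOverlaps(atlas[[ct]], atlas[[ct]]) > 1L)) {
      stop(sprintf("DHS intervals overlap within cell type '%s'", ct))
    }
  }
  all_gr <- unlist(GenomicRanges::GRangesList(lapply(atlas, function(g) {
    GenomicRanges::granges(g)
  })), use.names = FALSE)
  all_gr$cell_type <- rep(names(atlas), lengths(atlas))
  # connected components under >=1 bp overlap = reduce with min.gapwidth=0
  clusters <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L,
                                    ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(clusters, all_gr,
                                      ignore.strand = TRUE)
  members <- unname(as.list(tapply(
    all_gr$cell_type[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    function(x) sort(unique(x)), simplify = FALSE)))
  n_types <- length(atlas)
  clusters$members <- unname(vapply(members, paste, character(1),
                                    collapse = ","))
  clusters$k <- as.integer(lengths(members))
  clusters$specificity <- ifelse(
    clusters$k == 1L, "cell_type_specific",
    ifelse(clusters$k == n_types, "ubiquitous",
           paste0("shared_", clusters$k)))
  S4Vectors::metadata(clusters)$cell_types <- names(atlas)
  clusters
}

#' Cell types recorded in a DHS cluster set
#'
#' @param clusters A [cluster_dhs()] result.
#' @return Character vector of cell type labels.
#' @export
cluster_cell_types <- function(clusters) {
  S4Vectors::metadata(clusters)$cell_types
}

# logical membership matrix: cell types x clusters
cluster_membership_matrix <- function(clusters,
                                      cell_types =
                                        cluster_cell_types(clusters)) {
  memb <- strsplit(clusters$members, ",", fixed = TRUE)
  m <- vapply(seq_along(memb), function(j) cell_types %in% memb[[j]],
              logical(length(cell_types)))
  m <- matrix(as.numeric(m), nrow = length(cell_types))
  rownames(m) <- cell_types
  m
}

#' Build the DHS signature tree
#'
#' Each cell type becomes a binary vector over the clusters (1 = the type
#' contributes a DHS to the cluster); Euclidean distance between those
#' vectors is clustered agglomeratively (average linkage, with rows in
#' lexicographic label order for deterministic tie-breaking) and the tree
#' is optionally re-rooted on an outgroup clade. Branch lengths derive
#' from merge heights.
#'
#' @param clusters A [cluster_dhs()] result.
#' @param outgroup Character vector of outgroup cell types (e.g. the GM
#'   lymphoblastoid lines), or `NULL` to keep the hclust rooting.
#' @return A `dhs_tree`: list with `phylo` (ape tree), `matrix` (binary
#'   profile matrix), `dist` (Euclidean distances).
#' @export
build_tree <- function(clusters, outgroup = NULL) {
  cts <- sort(cluster_cell_types(clusters))
  m <- cluster_membership_matrix(clusters, cts)
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, phy$tip.label)
    if (length(missing)) stop("outgroup tips absent from the tree")
    # when the outgroup is not monophyletic in the unrooted tree, fall
    # back to rooting on its first member
    phy <- tryCatch(ape::root(phy, outgroup = outgroup,
                              resolve.root = TRUE),
                    error = function(e) {
                      warning("outgroup not monophyletic; rooting on '",
                              outgroup[1L], "'", call. = FALSE)
                      ape::root(phy, outgroup = outgroup[1L],
                                resolve.root = TRUE)
                    })
  }
  structure(list(phylo = phy, matrix = m, dist = d), class = "dhs_tree")
}

#' @export
print.dhs_tree <- function(x, ...) {
  cat(sprintf("<dhs_tree> %d cell types over %d clusters\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Serialise a DHS signature tree to Newick
#'
#' @param tree A [build_tree()] result.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_dhs_tree <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree$phylo))
  ape::write.tree(tree$phylo, file = file)
  invisible(ape::write.tree(tree$phylo))
}

#' Mutational load across cell-type combinations of DHS activity
#'
#' For each number of active cell types k, computes the enrichment of the
#' variants in the union territory of clusters with exactly k members,
#' split into clusters containing versus not containing the focal cell
#' type. Each series entry obeys the minimum-overlap gate; combinations
#' with no clusters are omitted.
#'
#' @param clusters A [cluster_dhs()] result (typically pre-filtered, e.g.
#'   to intergenic TSS-distal clusters).
#' @param focal Focal cell type (e.g. the melanocyte line).
#' @param variants Data frame with `chrom`, `pos`.
#' @param territory GRanges callable territory.
#' @param n_samplings,seed,min_overlap Passed to [enrichment()].
#' @return Data frame: `k`, `focal` (`containing`/`absent`), `n_clusters`,
#'   `observed`, `null_mean`, `null_sd`, `log2_enrichment`, `gated`.
#' @export
combination_enrichment <- function(clusters, focal, variants, territory,
                                   n_samplings = 1000, seed = NULL,
                                   min_overlap = 10) {
  if (!is.null(seed)) set.seed(seed)
  has_focal <- vapply(strsplit(clusters$members, ",", fixed = TRUE),
                      function(m) focal %in% m, logical(1))
  rows <- list()
  for (k in sort(unique(clusters$k))) {
    for (side in c("containing", "absent")) {
      sel <- clusters$k == k & (if (side == "containing") has_focal
                                else !has_focal)
      if (!any(sel)) next
      r <- enrichment(variants, GenomicRanges::granges(clusters[sel]),
                      territory, n_samplings = n_samplings, seed = NULL,
                      min_overlap = min_overlap,
                      label = sprintf("k=%d %s", k, side))
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, focal = side, n_clusters = sum(sel),
        observed = r$observed, null_mean = r$null_mean,
        null_sd = r$null_sd, log2_enrichment = r$log2_enrichment,
        gated = r$gated, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag transcribed DHS clusters
#'
#' A cluster is transcribed when at least one RNA read interval with
#' mapping quality at or above `min_mapq` overlaps it.
#'
#' @param clusters A [cluster_dhs()] result (or any GRanges).
#' @param rna GRanges of RNA read intervals with numeric mcol `mapq`.
#' @param min_mapq Mapping-quality threshold (inclusive).
#' @return Logical vector parallel to `clusters`.
#' @export
transcribed_dhs <- function(clusters, rna, min_mapq = 30) {
  qual <- rna[rna$mapq >= min_mapq]
  IRanges::overlapsAny(clusters, qual, ignore.strand = TRUE)
}

#' Fisher comparison of transcription between two cluster sets
#'
#' Two-sided Fisher exact test on the 2x2 table of set membership versus
#' transcribed status.
#'
#' @param transcribed_a,transcribed_b Logical vectors of transcribed flags
#'   for the two cluster sets.
#' @return List with `table` (2x2 matrix), `p_value`, `odds_ratio`.
#' @export
compare_transcription <- function(transcribed_a, transcribed_b) {
  tab <- matrix(c(sum(transcribed_a), sum(!transcribed_a),
                  sum(transcribed_b), sum(!transcribed_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("a", "b"),
                                transcribed = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}
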