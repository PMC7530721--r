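#' Group CPuORF-containing genes into ortholog groups (mORF clusters)
#'
#' Built-in fallback for an external ortholog-grouping engine: connected
#' components of the reciprocal-hit graph from an all-vs-all protein search of
#' the genes' (longest) mORF peptides at E < `e_max`. Two genes are linked
#' when each hits the other. Singleton genes form singleton clusters.
#'
#' @param morf_peptides named character vector: one (longest) mORF peptide per
#'   gene, names are gene ids
#' @param engine a `cpuorf_engine`
#' @param e_max cutoff for the all-vs-all search (strict `<`)
#' @return tibble: `gene_id`, `morf_cluster` (integer, deterministic:
#'   clusters numbered by their lexicographically smallest member)
#' @export
cluster_orthologs <- function(morf_peptides, engine, e_max = 1e-3) {
  genes <- sort(names(morf_peptides))
  if (length(genes) == 0L) {
    return(tibble::tibble(gene_id = character(0), morf_cluster = integer(0)))
  }
  hits <- search_protein(engine, morf_peptides[genes], morf_peptides[genes],
                         e_max = e_max)
  hits <- dplyr::filter(hits, .data$evalue < e_max,
                        .data$query_id != .data$subject_id)
  edge_key <- paste(pmin(hits$query_id, hits$subject_id),
                    pmax(hits$query_id, hits$subject_id))
  reciprocal <- names(which(table(edge_key) >= 2L))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
  if (length(reciprocal) > 0L) {
    ends <- do.call(rbind, strsplit(reciprocal, " ", fixed = TRUE))
    g <- g + igraph::edges(as.vector(t(ends)))
  }
  memb <- igraph::components(g)$membership[genes]
  first_member <- vapply(split(genes, memb), min, character(1))
  relabel <- match(memb, memb[match(sort(first_member), genes)])
  tibble::tibble(gene_id = genes, morf_cluster = relabel)
}

#' Binarized uORF peptide distance matrix within one mORF cluster
#'
#' All-vs-all protein comparison of the uORF peptides; distance 0 when either
#' direction yields a hit with E < `e_max` (OR-symmetrized), else 1; diagonal
#' 0.
#'
#' @param uorf_peptides named character vector of uORF peptides
#' @param engine a `cpuorf_engine`
#' @param e_max permissive cutoff (default 2000, strict `<`)
#' @return symmetric binary matrix with dimnames
#' @export
uorf_distance_matrix <- function(uorf_peptides, engine, e_max = 2000) {
  ids <- names(uorf_peptides)
  n <- length(ids)
  d <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (n > 1L) {
    hits <- search_protein(engine, uorf_peptides, uorf_peptides, e_max = e_max)
    hits <- dplyr::filter(hits, .data$evalue < e_max)
    for (k in seq_len(nrow(hits))) {
      i <- hits$query_id[k]; j <- hits$subject_id[k]
      d[i, j] <- 0; d[j, i] <- 0
    }
  }
  d
}

#' Cut a single-linkage dendrogram of a binary distance matrix
#'
#' Hierarchical clustering with single linkage cut at height `h`. With 0/1
#' distances and `h = 0.5` the result provably equals the connected components
#' of the distance-0 graph (single-linkage chaining); the generic
#' `hclust`/`cutree` route is used so any distance matrix works.
#'
#' @param mat symmetric distance matrix (typically binary)
#' @param h cut height
#' @return integer cluster labels named by the matrix dimnames
#' @export
single_linkage_cut <- function(mat, h = 0.5) {
  n <- nrow(mat)
  ids <- rownames(mat) %||% as.character(seq_len(n))
  if (n == 1L) return(setNames(1L, ids))
  hc <- hclust(as.dist(mat), method = "single")
  setNames(as.integer(cutree(hc, h = h)), ids)
}

#' Resolve overlapping splice-variant uORFs of a gene
#'
#' Within each group of same-gene records whose genomic spans overlap: if all
#' records share the reading frame, the record with the longest conserved
#' region survives (ties broken by the lowest aggregated Ka/Ks ratio); records
#' overlapping in different reading frames are resolved by the lowest ratio
#' directly. The conserved-region length is the number of peptide positions at
#' which at least half of the representative putative uORFs agree with the
#' original (a declared proxy for by-eye alignment curation).
#'
#' @param records tibble with `uorf_id`, `gene_id`, `chrom`, `strand`,
#'   `utr_start` (any per-record coordinate), `span_start`, `span_end`
#'   (genomic span), `frame_phase` (genomic frame identifier),
#'   `conserved_len`, `median_ratio`
#' @return surviving rows
#' @export
resolve_splice_variants <- function(records) {
  if (nrow(records) <= 1L) return(records)
  keep <- character(0)
  for (gene in unique(records$gene_id)) {
    g <- records[records$gene_id == gene, , drop = FALSE]
    g <- dplyr::arrange(g, .data$span_start, .data$span_end, .data$uorf_id)
    # overlap components by interval sweep
    comp <- integer(nrow(g)); cur <- 0L; cur_end <- -Inf
    for (i in seq_len(nrow(g))) {
      if (g$span_start[i] >= cur_end) cur <- cur + 1L
      comp[i] <- cur
      cur_end <- max(cur_end, g$span_end[i])
    }
    for (cc in unique(comp)) {
      gg <- g[comp == cc, , drop = FALSE]
      if (nrow(gg) == 1L) { keep <- c(keep, gg$uorf_id); next }
      same_frame <- length(unique(gg$frame_phase)) == 1L
      r <- ifelse(is.na(gg$median_ratio), Inf, gg$median_ratio)
      ord <- if (same_frame) {
        order(-gg$conserved_len, r, gg$uorf_id)
      } else {
        order(r, -gg$conserved_len, gg$uorf_id)
      }
      keep <- c(keep, gg$uorf_id[ord[1]])
    }
  }
  records[records$uorf_id %in% keep, , drop = FALSE]
}

# conserved-region length: peptide positions of `orig_aa` where >= 50% of the
# representative peptides carry the identical residue (via pairwise global
# alignments mapped back onto the original coordinates)
conserved_region_length <- function(orig_aa, rep_aas) {
  if (length(rep_aas) == 0L || nchar(orig_aa) == 0L) return(0L)
  match_mat <- vapply(rep_aas, function(rep) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(orig_aa),
      subject = Biostrings::AAString(rep),
      type = "global", substitutionMatrix = aa_score_matrix(),
      gapOpening = 11, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    m <- logical(nchar(orig_aa))
    m[cumsum(ap != "-")[ap != "-" & ap == as_]] <- TRUE
    m
  }, logical(nchar(orig_aa)))
  sum(rowMeans(match_mat) >= 0.5)
}

#' Assign homology-group (HG) numbers to CPuORF families
#'
#' Families (uORF clusters) are sorted by descending taxonomic distality of
#' their aggregated conservation range, then by descending total order count,
#' then by ascending representative (smallest) gene id. mORF clusters take
#' their rank from their best family; within an mORF cluster the sub-numbers
#' 1..k follow the same sort, giving labels like `HG0004.1`, `HG0004.2`.
#' The numbering is a deterministic function of the input set: permuting the
#' input rows never changes a label.
#'
#' @param families tibble with one row per CPuORF: `uorf_id`, `gene_id`,
#'   `morf_cluster`, `uorf_cluster`, `range_label`, `n_orders_total`
#' @param query_category the query species' own category (distality reference)
#' @return `families` with `hg_number`, `hg_subnumber` and `label`
#'   (`HG%04d.%d`) added
#' @export
assign_hg_numbers <- function(families, query_category) {
  if (nrow(families) == 0L) {
    return(dplyr::mutate(families, hg_number = integer(0),
                         hg_subnumber = integer(0), label = character(0)))
  }
  cats <- animal_categories()
  depth <- vapply(cats, chain_overlap, integer(1), cat_b = query_category)
  fam <- dplyr::summarise(
    dplyr::group_by(families, .data$morf_cluster, .data$uorf_cluster),
    distality = min(depth[.data$range_label], na.rm = TRUE),
    n_orders = max(.data$n_orders_total),
    rep_gene = min(.data$gene_id),
    .groups = "drop")
  fam <- dplyr::arrange(fam, .data$distality, dplyr::desc(.data$n_orders),
                        .data$rep_gene)
  fam$fam_rank <- seq_len(nrow(fam))
  morf_rank <- dplyr::summarise(dplyr::group_by(fam, .data$morf_cluster),
                                best = min(.data$fam_rank), .groups = "drop")
  morf_rank <- dplyr::arrange(morf_rank, .data$best)
  morf_rank$hg_number <- seq_len(nrow(morf_rank))
  fam <- dplyr::left_join(fam, dplyr::select(morf_rank, "morf_cluster",
                                             "hg_number"),
                          by = "morf_cluster")
  fam <- dplyr::group_by(fam, .data$morf_cluster)
  fam <- dplyr::mutate(fam, hg_subnumber = rank(.data$fam_rank))
  fam <- dplyr::ungroup(fam)
  fam$label <- sprintf("HG%04d.%d", fam$hg_number, fam$hg_subnumber)
  dplyr::left_join(families,
                   dplyr::select(fam, "morf_cluster", "uorf_cluster",
                                 "hg_number", "hg_subnumber", "label"),
                   by = c("morf_cluster", "uorf_cluster"))
}
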