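#' Keep uORFs conserved in mORF homologs from at least two other orders
#'
#' @param confirmed tibble of mORF-confirmed hits with columns `uorf_id` and
#'   `order` (the subject's taxonomic order); rows with a missing order are
#'   ignored for counting (and reported via a message)
#' @param original_order order of the query species (e.g. "Primates")
#' @param min_other minimum number of distinct orders other than
#'   `original_order`
#' @return character vector of surviving `uorf_id`s
#' @export
filter_order_conservation <- function(confirmed, original_order,
                                      min_other = 2L) {
  if (nrow(confirmed) == 0L) return(character(0))
  missing_order <- is.na(confirmed$order) | confirmed$order == ""
  if (any(missing_order)) {
    message(sum(missing_order), " hit(s) without a taxonomic order ignored")
  }
  ok <- dplyr::filter(confirmed, !missing_order,
                      .data$order != original_order)
  tal <- dplyr::summarise(dplyr::group_by(ok, .data$uorf_id),
                          n_orders = dplyr::n_distinct(.data$order),
                          .groups = "drop")
  tal$uorf_id[tal$n_orders >= min_other]
}

#' Collapse identical uORFs across splice variants of a gene
#'
#' Among records of one gene with identical nucleotide sequence, the record
#' whose uORF-tBLASTn hits have the lowest median E-value survives; ties are
#' broken by lexicographic transcript id. Records with no hits rank last
#' (median E treated as infinite).
#'
#' @param uorfs tibble from [extract_uorfs()]
#' @param uorf_hits hit tibble from [uorf_homology_search()] (columns
#'   `query_id`, `evalue`)
#' @return surviving rows of `uorfs`
#' @export
dedupe_identical_uorfs <- function(uorfs, uorf_hits) {
  med <- dplyr::summarise(dplyr::group_by(uorf_hits, .data$query_id),
                          med_e = median(.data$evalue), .groups = "drop")
  u <- dplyr::left_join(uorfs, med, by = c(uorf_id = "query_id"))
  u$med_e[is.na(u$med_e)] <- Inf
  u <- dplyr::group_by(u, .data$gene_id, .data$nt_seq)
  u <- dplyr::arrange(u, .data$med_e, .data$transcript_id, .by_group = TRUE)
  u <- dplyr::slice_head(u, n = 1L)
  dplyr::select(dplyr::ungroup(u), -"med_e")
}

#' Select one representative mORF-confirmed hit per taxonomic order
#'
#' Per (uORF, order): the hit with the lowest mORF-confirmation E-value wins;
#' ties go to the longer putative-uORF peptide, then to the lexicographically
#' smallest subject id.
#'
#' @param confirmed tibble with columns `uorf_id`, `order`, `subject_id`,
#'   `morf_evalue` and `putative_aa`
#' @return one row per (uORF, order)
#' @export
select_representatives <- function(confirmed) {
  if (nrow(confirmed) == 0L) return(confirmed)
  x <- dplyr::mutate(confirmed, .plen = nchar(.data$putative_aa))
  x <- dplyr::group_by(x, .data$uorf_id, .data$order)
  x <- dplyr::arrange(x, .data$morf_evalue, dplyr::desc(.data$.plen),
                      .data$subject_id, .by_group = TRUE)
  x <- dplyr::slice_head(x, n = 1L)
  dplyr::select(dplyr::ungroup(x), -".plen")
}

#' Pairwise Ka/Ks of each uORF against its per-order representatives
#'
#' Aligns each original uORF to the putative uORF of every representative hit
#' ([codon_align()]), computes NG86 Ka/Ks ([compute_kaks()]) and the
#' permutation p-value ([permutation_null()]), then Benjamini-Hochberg adjusts
#' the p-values across all pairs of the run.
#'
#' @param uorfs tibble from [extract_uorfs()] (`uorf_id`, `nt_seq`)
#' @param representatives tibble from [select_representatives()] carrying
#'   `uorf_id`, `subject_id`, `order`, `putative_nt`
#' @param n_perm permutations per pair
#' @param seed integer; per-pair seeds are derived deterministically from it
#' @return tibble with one row per (uORF, representative) pair: `uorf_id`,
#'   `subject_id`, `order`, `Ka`, `Ks`, `ratio`, `flag`, `n_codons`,
#'   `p_perm`, `q`
#' @export
kaks_pairs <- function(uorfs, representatives, n_perm = 1000L, seed = 1L) {
  if (nrow(representatives) == 0L) {
    return(tibble::tibble(uorf_id = character(0), subject_id = character(0),
                          order = character(0), Ka = numeric(0),
                          Ks = numeric(0), ratio = numeric(0),
                          flag = character(0), n_codons = integer(0),
                          p_perm = numeric(0), q = numeric(0)))
  }
  nt_by_uorf <- setNames(uorfs$nt_seq, uorfs$uorf_id)
  reps <- dplyr::arrange(representatives, .data$uorf_id, .data$order,
                         .data$subject_id)
  rows <- purrr::pmap(
    list(reps$uorf_id, reps$subject_id, reps$order, reps$putative_nt,
         seq_len(nrow(reps))),
    function(uid, sid, ord, pnt, k) {
      aln <- codon_align(nt_by_uorf[[uid]], pnt)
      kk <- compute_kaks(aln)
      pp <- permutation_null(aln, n_perm = n_perm,
                             seed = (seed + 7919L * k) %% .Machine$integer.max)
      tibble::tibble(uorf_id = uid, subject_id = sid, order = ord,
                     Ka = kk$Ka, Ks = kk$Ks, ratio = kk$ratio,
                     flag = kk$flag, n_codons = kk$n_codons,
                     p_perm = pp$p_perm)
    })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p_perm)
  out
}

#' Aggregate per-pair Ka/Ks results per uORF
#'
#' The per-uORF summary is the median ratio and the median q across the
#' uORF's representative pairs (undefined ratios excluded; a uORF whose every
#' pair is undefined gets `NA` and can never be a candidate). The median is
#' robust to one aberrant order.
#'
#' @param pairs tibble from [kaks_pairs()]
#' @return tibble: `uorf_id`, `median_ratio`, `median_q`, `n_pairs`
#' @export
aggregate_kaks <- function(pairs) {
  g <- dplyr::group_by(pairs, .data$uorf_id)
  dplyr::summarise(
    g,
    median_ratio = if (all(is.na(.data$ratio))) NA_real_ else
      median(.data$ratio, na.rm = TRUE),
    median_q = median(.data$q),
    n_pairs = dplyr::n(),
    .groups = "drop")
}

#' Select candidate CPuORFs
#'
#' A uORF is a candidate when its aggregated Ka/Ks ratio is strictly below
#' `ratio_max` and its aggregated q-value strictly below `q_max` (both
#' boundaries excluded).
#'
#' @param summary tibble from [aggregate_kaks()]
#' @param ratio_max Ka/Ks threshold (default 0.5)
#' @param q_max q-value threshold (default 0.05)
#' @return character vector of candidate `uorf_id`s
#' @export
select_candidates <- function(summary, ratio_max = 0.5, q_max = 0.05) {
  ok <- !is.na(summary$median_ratio) & summary$median_ratio < ratio_max &
    summary$median_q < q_max
  summary$uorf_id[ok]
}
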