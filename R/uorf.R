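#' Scan a 5'-UTR for upstream open reading frames
#'
#' Finds every ATG whose nearest downstream in-frame stop codon lies entirely
#' within the UTR. Nested and overlapping uORFs are all reported. Codons
#' containing N never match ATG nor a stop codon; uORFs that span an internal
#' N-containing codon are retained and flagged. ATGs whose nearest in-frame
#' stop falls downstream of the UTR (i.e. ORFs running into the mORF) produce
#' no uORF.
#'
#' @param utr5_seq nucleotide string over A,C,G,T,N (5' to 3')
#' @param min_codons minimum uORF length in codons including the stop codon;
#'   the default 2 accepts an ATG immediately followed by a stop (a 1-residue
#'   peptide)
#' @return tibble ordered by `start` with columns `start`, `end` (0-based
#'   half-open offsets within the UTR; `end` is one past the stop codon),
#'   `nt_seq` (ATG..stop inclusive), `aa_seq` (no stop symbol), `has_n`
#' @export
#' @examples
#' scan_uorfs("CCATGAAATGACC")  # one uORF, peptide "MK"
#' scan_uorfs("ATGATGTAA")      # two uORFs sharing a stop codon
scan_uorfs <- function(utr5_seq, min_codons = 2L) {
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          nt_seq = character(0), aa_seq = character(0),
                          has_n = logical(0))
  if (length(utr5_seq) != 1L || is.na(utr5_seq)) return(empty)
  L <- nchar(utr5_seq)
  if (L < 3L * min_codons) return(empty)
  su <- toupper(utr5_seq)
  out <- list()
  for (f in 0:2) {
    if (L - f < 6L) next
    pos <- seq(f, L - 3L, by = 3L)                 # 0-based codon starts
    cods <- substring(su, pos + 1L, pos + 3L)
    atg <- which(cods == "ATG")
    stp <- which(cods %in% STOP_CODONS)
    if (length(atg) == 0L || length(stp) == 0L) next
    nxt <- stp[findInterval(atg, stp) + 1L]        # first stop strictly after
    keep <- !is.na(nxt) & (nxt - atg + 1L) >= min_codons
    if (!any(keep)) next
    a <- atg[keep]; s <- nxt[keep]
    out[[length(out) + 1L]] <- tibble::tibble(
      start = pos[a], end = pos[s] + 3L
    )
  }
  if (length(out) == 0L) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
  res$nt_seq <- substring(su, res$start + 1L, res$end)
  res$aa_seq <- vapply(res$nt_seq,
                       function(x) sub("\\*$", "", translate_nt(x)),
                       character(1), USE.NAMES = FALSE)
  res$has_n <- grepl("N", res$nt_seq, fixed = TRUE)
  res
}

#' Extract all uORFs from all splice variants of a set of transcript models
#'
#' Each uORF is tied to its transcript; genomic start/stop-codon coordinates
#' are computed through the exon structure, so codons split across introns get
#' multi-block intervals. String keys (`start_key`, `stop_key`) canonically
#' encode the genomic codon blocks and are what the shared start/stop counting
#' rule operates on.
#'
#' @param models tibble from [read_transcript_models()]
#' @param min_codons see [scan_uorfs()]
#' @return tibble with one row per uORF instance: `uorf_id`
#'   (`<gene>|<transcript>|<utr_start>`), `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `utr_start`, `utr_stop_end`, `start_blocks`, `stop_blocks`
#'   (list-columns of genomic 0-based half-open interval matrices),
#'   `start_key`, `stop_key`, `nt_seq`, `aa_seq`, `has_n`
#' @export
extract_uorfs <- function(models, min_codons = 2L) {
  rows <- purrr::pmap(models, function(transcript_id, gene_id, chrom, strand,
                                       exons, cds, utr5_seq, ...) {
    hits <- scan_uorfs(utr5_seq, min_codons = min_codons)
    if (nrow(hits) == 0L) return(NULL)
    sb <- purrr::map2(hits$start, hits$start + 3L,
                      ~tx_to_genomic(exons, strand, .x, .y))
    eb <- purrr::map2(hits$end - 3L, hits$end,
                      ~tx_to_genomic(exons, strand, .x, .y))
    tibble::tibble(
      uorf_id = paste(gene_id, transcript_id, hits$start, sep = "|"),
      gene_id = gene_id, transcript_id = transcript_id,
      chrom = chrom, strand = strand,
      utr_start = hits$start, utr_stop_end = hits$end,
      start_blocks = sb, stop_blocks = eb,
      start_key = purrr::map_chr(sb, ~blocks_key(chrom, strand, .x)),
      stop_key = purrr::map_chr(eb, ~blocks_key(chrom, strand, .x)),
      nt_seq = hits$nt_seq, aa_seq = hits$aa_seq, has_n = hits$has_n
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) {
    return(tibble::tibble(uorf_id = character(0), gene_id = character(0),
                          transcript_id = character(0), chrom = character(0),
                          strand = character(0), utr_start = integer(0),
                          utr_stop_end = integer(0), start_blocks = list(),
                          stop_blocks = list(), start_key = character(0),
                          stop_key = character(0), nt_seq = character(0),
                          aa_seq = character(0), has_n = logical(0)))
  }
  dplyr::bind_rows(rows)
}

#' Count uORFs under the shared start/stop merging rule
#'
#' Within each gene, uORF records that share the same genomic start codon or
#' the same genomic stop codon are counted as one: counting collapses the
#' connected components of the share graph (a record sharing a start with one
#' record and a stop with another merges all three). Records themselves are
#' never deleted; this is purely a counting rule.
#'
#' @param uorfs tibble from [extract_uorfs()]
#' @return one-row tibble with `n_uorfs` (components summed over genes) and
#'   `n_genes` (genes with at least one record)
#' @export
count_distinct_uorfs <- function(uorfs) {
  if (nrow(uorfs) == 0L) {
    return(tibble::tibble(n_uorfs = 0L, n_genes = 0L))
  }
  per_gene <- dplyr::group_by(uorfs, .data$gene_id)
  counts <- dplyr::summarise(per_gene, n = shared_codon_components(
    .data$start_key, .data$stop_key), .groups = "drop")
  tibble::tibble(n_uorfs = sum(counts$n), n_genes = nrow(counts))
}

# number of connected components among records linked by equal start OR stop
# key; bipartite trick: records connect through key vertices
shared_codon_components <- function(start_key, stop_key) {
  n <- length(start_key)
  if (n <= 1L) return(n)
  rec <- paste0("r", seq_len(n))
  edges <- c(rbind(rec, paste0("S:", start_key)),
             rbind(rec, paste0("E:", stop_key)))
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  length(unique(comp$membership[rec]))
}
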