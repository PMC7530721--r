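#' Permissive translated homology search of uORF peptides (uORF-tBLASTn step)
#'
#' Runs every uORF peptide against the transcript evidence collection at a
#' very permissive cutoff (default E <= 2000) and keeps hits from species
#' other than the query species (the query's own records carry no evidence of
#' cross-species conservation). One best-E hit is kept per (uORF, subject
#' record) pair.
#'
#' @param uorfs tibble from [extract_uorfs()] (only `uorf_id`/`aa_seq` used)
#' @param collection named character vector of nucleotide records
#' @param taxonomy tibble from [read_taxonomy()] (record_id, species, ...)
#' @param engine a `cpuorf_engine`
#' @param query_species species binomial of the query genome
#' @param e_max E-value cutoff
#' @return hit tibble (see [search_translated()]) joined with `species` and
#'   `order` of each subject
#' @export
uorf_homology_search <- function(uorfs, collection, taxonomy, engine,
                                 query_species, e_max = 2000) {
  queries <- setNames(uorfs$aa_seq, uorfs$uorf_id)
  hits <- search_translated(engine, queries, collection, e_max = e_max)
  tax <- dplyr::select(taxonomy, subject_id = "record_id", "species", "order")
  hits <- dplyr::inner_join(hits, tax, by = "subject_id")
  hits <- dplyr::filter(hits, .data$species != query_species)
  hits <- dplyr::group_by(hits, .data$query_id, .data$subject_id)
  hits <- dplyr::slice_min(hits, .data$evalue, n = 1L, with_ties = FALSE)
  dplyr::ungroup(hits)
}

#' Extract the putative uORF containing a translated-search HSP
#'
#' In the frame of the hit, the maximal stop-free codon segment containing the
#' HSP is located; the 5' boundary is the first (most upstream) in-frame ATG
#' of that segment at or before the HSP start. If the segment has no such ATG
#' but reaches the subject 5' end, the ORF is returned 5'-partial (ESTs are
#' frequently truncated); with no ATG and no 5' truncation, no putative uORF
#' is extracted. The 3' boundary is the first in-frame stop after the HSP
#' (stop included in `orf_nt`), or the subject end (flagged 3'-partial).
#'
#' @param hit one-row hit tibble from [search_translated()]
#' @param subject_seq full nucleotide sequence of `hit$subject_id`
#' @return one-row tibble (`subject_id`, `orf_nt`, `orf_aa`, `s_begin`,
#'   `s_end` reading-direction 0-based half-open nt interval,
#'   `five_prime_partial`, `three_prime_partial`, `sframe`) or `NULL`
#' @export
extract_putative_uorf <- function(hit, subject_seq) {
  fr <- hit$sframe
  L <- nchar(subject_seq)
  if (any(c(hit$sstart, hit$send) < 1L) || any(c(hit$sstart, hit$send) > L)) {
    stop("HSP coordinates fall outside the subject sequence")
  }
  rseq <- if (fr > 0) toupper(subject_seq) else revcomp(toupper(subject_seq))
  off <- abs(fr) - 1L
  n_cod <- (L - off) %/% 3L
  if (n_cod == 0L) return(NULL)
  pos <- off + 3L * (seq_len(n_cod) - 1L)          # 0-based codon starts
  cods <- substring(rseq, pos + 1L, pos + 3L)
  b <- frame_codon_bounds(fr, hit$sstart, hit$send, L)
  c1 <- max(1L, b$aa_start); c2 <- min(n_cod, b$aa_end)
  stops <- which(cods %in% STOP_CODONS)
  prev_stop <- suppressWarnings(max(stops[stops < c1]))
  seg_start <- if (is.finite(prev_stop)) prev_stop + 1L else 1L
  next_stop <- suppressWarnings(min(stops[stops > c2]))
  three_partial <- !is.finite(next_stop)
  seg_end <- if (three_partial) n_cod else next_stop
  atg <- which(cods[seg_start:c1] == "ATG")
  if (length(atg) > 0L) {
    orf_start <- seg_start + atg[1] - 1L
    five_partial <- FALSE
  } else if (seg_start == 1L) {
    orf_start <- 1L
    five_partial <- TRUE
  } else {
    return(NULL)
  }
  nt <- paste(cods[orf_start:seg_end], collapse = "")
  aa <- sub("\\*$", "", translate_nt(nt))
  tibble::tibble(
    subject_id = hit$subject_id,
    orf_nt = nt, orf_aa = aa,
    s_begin = pos[orf_start], s_end = pos[seg_end] + 3L,
    five_prime_partial = five_partial, three_prime_partial = three_partial,
    sframe = fr
  )
}

#' Confirm a putative uORF by searching the mORF downstream of it
#'
#' The subject region downstream of the putative uORF (reading direction) is
#' searched with the original transcript's mORF peptide; the best hit with
#' `evalue < e_max` (default 0.1, strict) confirms that the uORF-tBLASTn hit
#' comes from a homolog of the uORF-containing gene. Returns `NULL` when the
#' putative uORF sits at the subject 3' end or nothing passes the cutoff.
#'
#' @param morf_aa mORF peptide of the original transcript
#' @param putative one-row tibble from [extract_putative_uorf()]
#' @param subject_seq full nucleotide sequence of the subject record
#' @param engine a `cpuorf_engine`
#' @param e_max mORF-confirmation cutoff (strict `<`)
#' @param search_space effective search space (amino acids) for the E-value;
#'   pass the total translated length of all downstream regions being
#'   confirmed in the same analysis so that E-values match a single
#'   database-wide search (the pipeline does this)
#' @return best one-row hit tibble (coordinates relative to the downstream
#'   region) or `NULL`
#' @export
confirm_morf <- function(morf_aa, putative, subject_seq, engine, e_max = 0.1,
                         search_space = NULL) {
  fr <- putative$sframe
  rseq <- if (fr > 0) toupper(subject_seq) else revcomp(toupper(subject_seq))
  down <- substr(rseq, putative$s_end + 1L, nchar(rseq))
  if (nchar(down) < 3L) return(NULL)
  hits <- search_translated(engine, c(morf = morf_aa),
                            setNames(down, putative$subject_id),
                            e_max = e_max, search_space = search_space)
  hits <- dplyr::filter(hits, .data$evalue < e_max)
  if (nrow(hits) == 0L) return(NULL)
  hits[which.min(hits$evalue), ]
}

#' Remove contaminant-derived hits
#'
#' Drops hits whose subject lineage lies outside Metazoa, hits whose record
#' carries a species/lineage conflict flag (supplied by the collection
#' builder, e.g. a nematode parasite record inside a mammalian EST library)
#' and hits whose record has no lineage at all (unclassifiable).
#'
#' @param hits hit tibble with a `subject_id` column
#' @param taxonomy tibble from [read_taxonomy()]; must contain `record_id`,
#'   `lineage` (semicolon-joined clades) and optionally `contaminant_flag`
#' @return the surviving hit rows
#' @export
filter_contaminants <- function(hits, taxonomy) {
  tax <- dplyr::select(taxonomy, subject_id = "record_id", "lineage",
                       dplyr::any_of("contaminant_flag"))
  h <- dplyr::left_join(hits, tax, by = "subject_id")
  no_lineage <- is.na(h$lineage) | h$lineage == ""
  non_metazoan <- !no_lineage &
    !purrr::map_lgl(strsplit(h$lineage, ";", fixed = TRUE),
                    ~"Metazoa" %in% trimws(.x))
  flagged <- if ("contaminant_flag" %in% names(h)) {
    !is.na(h$contaminant_flag) & h$contaminant_flag
  } else rep(FALSE, nrow(h))
  if (any(no_lineage)) {
    message(sum(no_lineage), " hit(s) removed: subject without lineage")
  }
  keep <- !(no_lineage | non_metazoan | flagged)
  dplyr::select(h[keep, , drop = FALSE], -dplyr::any_of(c("lineage", "contaminant_flag")))
}

#' Read a collection taxonomy sidecar table
#'
#' Expected tab-separated columns: `record_id`, `taxid`, `species`, `order`,
#' `lineage` (semicolon-joined, Metazoa downward), `source`
#' (refseq/est/tsa/contig) and optionally `contaminant_flag`.
#'
#' @param path TSV path
#' @return tibble
#' @export
read_taxonomy <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c",
                                                contaminant_flag = "l"),
                  progress = FALSE)
}

#' Read a transcript evidence collection FASTA
#' @param path FASTA path
#' @return named character vector of nucleotide sequences
#' @export
read_collection <- function(path) {
  read_fasta(path)
}
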