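#' Find collection records matching both a uORF and its downstream mORF
#'
#' A record qualifies when it has at least one HSP against the uORF peptide
#' and at least one HSP against the mORF peptide, on the same strand, with the
#' mORF HSP subject-downstream of the uORF HSP in reading direction (a
#' one-codon boundary wobble is tolerated). The uORF side is searched at the
#' permissive regime (`uorf_e`, default 2000); the mORF side at `morf_e`
#' (default 0.1), mirroring the downstream pipeline steps.
#'
#' @param uorf_aa uORF peptide (character scalar)
#' @param morf_aa mORF peptide of the same transcript
#' @param collection named character vector of nucleotide records (the
#'   RefSeq-class subset)
#' @param engine a `cpuorf_engine`
#' @param uorf_e,morf_e E-value cutoffs for the two sides
#' @return tibble with one row per qualifying (record, uORF-HSP, mORF-HSP)
#'   pair: `subject_id` plus the two hits' frames and reading-direction codon
#'   bounds (`u_frame`, `u_aa_start`, `u_aa_end`, `m_frame`, `m_aa_start`,
#'   `m_aa_end`)
#' @export
find_matching_records <- function(uorf_aa, morf_aa, collection, engine,
                                  uorf_e = 2000, morf_e = 0.1) {
  empty <- tibble::tibble(subject_id = character(0), u_frame = integer(0),
                          u_aa_start = integer(0), u_aa_end = integer(0),
                          m_frame = integer(0), m_aa_start = integer(0),
                          m_aa_end = integer(0))
  if (length(collection) == 0L) return(empty)
  uh <- search_translated(engine, c(uorf = uorf_aa), collection, e_max = uorf_e)
  if (nrow(uh) == 0L) return(empty)
  mh <- search_translated(engine, c(morf = morf_aa),
                          collection[unique(uh$subject_id)], e_max = morf_e)
  if (nrow(mh) == 0L) return(empty)
  uh <- dplyr::mutate(uh, slen = nchar(collection[.data$subject_id]))
  mh <- dplyr::mutate(mh, slen = nchar(collection[.data$subject_id]))
  add_codon_bounds <- function(h, prefix) {
    b <- frame_codon_bounds(h$sframe, h$sstart, h$send, h$slen)
    h[[paste0(prefix, "_frame")]] <- h$sframe
    h[[paste0(prefix, "_aa_start")]] <- b$aa_start
    h[[paste0(prefix, "_aa_end")]] <- b$aa_end
    h
  }
  uh <- add_codon_bounds(uh, "u")
  mh <- add_codon_bounds(mh, "m")
  pairs <- dplyr::inner_join(
    dplyr::select(uh, "subject_id", "u_frame", "u_aa_start", "u_aa_end"),
    dplyr::select(mh, "subject_id", "m_frame", "m_aa_start", "m_aa_end"),
    by = "subject_id", relationship = "many-to-many")
  pairs <- dplyr::filter(pairs,
                         sign(.data$u_frame) == sign(.data$m_frame),
                         .data$m_aa_start > .data$u_aa_end - 3L)
  pairs
}

# reading-direction codon indices (1-based, in the hit's own frame
# translation) for orientation-encoded nt coordinates
frame_codon_bounds <- function(sframe, sstart, send, slen) {
  off <- abs(sframe) - 1L
  rd_start <- ifelse(sframe > 0, sstart, slen - sstart + 1L)
  rd_end <- ifelse(sframe > 0, send, slen - send + 1L)
  list(aa_start = (rd_start - 1L - off) %/% 3L + 1L,
       aa_end = (rd_end - off) %/% 3L)
}

#' Decide whether a uORF HSP and an mORF HSP are fused on a subject
#'
#' Fused means: the two HSPs lie in the same reading frame of the subject and
#' no stop codon occurs in that frame between the end of the uORF HSP and the
#' start of the mORF HSP — i.e. the subject carries the uORF peptide as an
#' N-terminal extension of the mORF protein rather than as a separate ORF.
#'
#' @param uorf_hit,morf_hit one-row hit tibbles (or lists) with `sframe`,
#'   `sstart`, `send` as produced by [search_translated()]
#' @param subject_seq the full nucleotide sequence of the shared subject
#' @return logical scalar
#' @export
is_fused <- function(uorf_hit, morf_hit, subject_seq) {
  uf <- uorf_hit$sframe; mf <- morf_hit$sframe
  if (is.null(uf) || is.null(mf) || is.na(uf) || is.na(mf) ||
      uf == 0L || mf == 0L) {
    stop("is_fused() requires translated hits carrying a subject frame")
  }
  if (uf != mf) return(FALSE)
  L <- nchar(subject_seq)
  ub <- frame_codon_bounds(uf, uorf_hit$sstart, uorf_hit$send, L)
  mb <- frame_codon_bounds(mf, morf_hit$sstart, morf_hit$send, L)
  gap_fused_in_frame(uf, ub$aa_end, mb$aa_start, subject_seq)
}

# TRUE iff no stop codon in frame `fr` between codon indices (u_end, m_start)
gap_fused_in_frame <- function(fr, u_aa_end, m_aa_start, subject_seq) {
  if (m_aa_start <= u_aa_end + 1L) return(TRUE)  # adjacent or overlapping
  rseq <- if (fr > 0) toupper(subject_seq) else revcomp(toupper(subject_seq))
  off <- abs(fr) - 1L
  from <- off + 3L * u_aa_end + 1L
  to <- off + 3L * (m_aa_start - 1L)
  gap <- substr(rseq, from, to)
  cods <- codon_split(gap)
  !any(cods %in% STOP_CODONS)
}

#' Compute uORF-mORF fusion statistics against a RefSeq-class collection
#'
#' For each uORF, counts the collection records matching both the uORF and its
#' downstream mORF (`n_matching`) and, among those, the records in which the
#' two matches are fused into one reading frame (`n_fused`; a record is fused
#' if any of its HSP pairs is). The fusion ratio is `n_fused / n_matching`,
#' undefined when `n_matching == 0`.
#'
#' @param uorfs tibble from [extract_uorfs()]
#' @param models tibble from [read_transcript_models()] (source of each
#'   transcript's mORF peptide)
#' @param collection named character vector of nucleotide records restricted
#'   to RefSeq-class entries
#' @param engine a `cpuorf_engine`
#' @param threshold discard threshold on the ratio (discard when
#'   `ratio >= threshold`)
#' @param uorf_e,morf_e search cutoffs, see [find_matching_records()]
#' @return tibble: `uorf_id`, `n_matching`, `n_fused`, `ratio` (NA when
#'   undefined), `verdict` ("pass"/"discard")
#' @export
fusion_stats <- function(uorfs, models, collection, engine, threshold = 0.3,
                         uorf_e = 2000, morf_e = 0.1) {
  empty <- tibble::tibble(uorf_id = uorfs$uorf_id, n_matching = 0L,
                          n_fused = 0L, ratio = NA_real_, verdict = "pass")
  if (nrow(uorfs) == 0L || length(collection) == 0L) return(empty)
  morf_by_tx <- setNames(models$morf_aa, models$transcript_id)
  # batched searches: every uORF and every distinct mORF at once
  uh <- search_translated(engine, setNames(uorfs$aa_seq, uorfs$uorf_id),
                          collection, e_max = uorf_e)
  morfs <- setNames(morf_by_tx[unique(uorfs$transcript_id)],
                    unique(uorfs$transcript_id))
  mh <- search_translated(engine, morfs, collection, e_max = morf_e)
  if (nrow(uh) == 0L || nrow(mh) == 0L) return(empty)
  slen <- nchar(collection)
  ub <- frame_codon_bounds(uh$sframe, uh$sstart, uh$send, slen[uh$subject_id])
  uh$u_frame <- uh$sframe; uh$u_aa_start <- ub$aa_start; uh$u_aa_end <- ub$aa_end
  mb <- frame_codon_bounds(mh$sframe, mh$sstart, mh$send, slen[mh$subject_id])
  mh$m_frame <- mh$sframe; mh$m_aa_start <- mb$aa_start; mh$m_aa_end <- mb$aa_end

  res <- purrr::pmap(list(uorfs$uorf_id, uorfs$transcript_id),
                     function(uid, tid) {
    pairs <- dplyr::inner_join(
      dplyr::select(dplyr::filter(uh, .data$query_id == uid),
                    "subject_id", "u_frame", "u_aa_start", "u_aa_end"),
      dplyr::select(dplyr::filter(mh, .data$query_id == tid),
                    "subject_id", "m_frame", "m_aa_start", "m_aa_end"),
      by = "subject_id", relationship = "many-to-many")
    pairs <- dplyr::filter(pairs,
                           sign(.data$u_frame) == sign(.data$m_frame),
                           .data$m_aa_start > .data$u_aa_end - 3L)
    if (nrow(pairs) == 0L) {
      return(tibble::tibble(uorf_id = uid, n_matching = 0L, n_fused = 0L,
                            ratio = NA_real_))
    }
    pairs$fused <- pairs$u_frame == pairs$m_frame &
      purrr::pmap_lgl(list(pairs$u_frame, pairs$u_aa_end, pairs$m_aa_start,
                           pairs$subject_id),
                      function(fr, ue, ms, sid)
                        gap_fused_in_frame(fr, ue, ms, collection[[sid]]))
    per_rec <- dplyr::summarise(dplyr::group_by(pairs, .data$subject_id),
                                fused = any(.data$fused), .groups = "drop")
    tibble::tibble(uorf_id = uid,
                   n_matching = nrow(per_rec),
                   n_fused = sum(per_rec$fused),
                   ratio = sum(per_rec$fused) / nrow(per_rec))
  })
  out <- dplyr::bind_rows(res)
  out$verdict <- ifelse(!is.na(out$ratio) & out$ratio >= threshold,
                        "discard", "pass")
  out
}

#' Apply the fusion-ratio filter
#'
#' Removes uORFs whose defined fusion ratio is greater than or equal to
#' `threshold` (0.3 by default; the boundary value is discarded). uORFs with
#' no matching records (undefined ratio) are retained: there is no evidence of
#' fusion.
#'
#' @param uorfs tibble from [extract_uorfs()]
#' @param stats tibble from [fusion_stats()]
#' @param threshold discard threshold
#' @return the surviving rows of `uorfs`
#' @export
fusion_filter <- function(uorfs, stats, threshold = 0.3) {
  bad <- stats$uorf_id[!is.na(stats$ratio) & stats$ratio >= threshold]
  dplyr::filter(uorfs, !.data$uorf_id %in% bad)
}
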