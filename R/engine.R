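#' Built-in translated/protein homology search engine
#'
#' A small BLAST-like engine used for fixtures and tests, and usable for real
#' (small) collections. A query/subject pair is examined only when the two
#' share at least one exact amino-acid word of length `word_size` (the seeding
#' step that carries BLAST's discrimination at very permissive E-value
#' cutoffs); seeded pairs are aligned locally (Smith-Waterman via
#' \pkg{Biostrings}, BLOSUM62, affine gaps) and the raw score is converted to
#' an E-value with the Karlin-Altschul formula \eqn{E = K m n e^{-\lambda S}}
#' using gapped BLOSUM62 constants.
#'
#' @param word_size exact-word seed length (amino acids)
#' @param gap_open,gap_ext affine gap penalties
#' @param lambda,K Karlin-Altschul parameters
#' @return an object of class `cpuorf_engine`
#' @seealso [blast_engine()] for the external NCBI BLAST+ wrapper
#' @export
builtin_engine <- function(word_size = 3L, gap_open = 11, gap_ext = 1,
                           lambda = 0.267, K = 0.041) {
  structure(list(name = "builtin", word_size = as.integer(word_size),
                 gap_open = gap_open, gap_ext = gap_ext,
                 lambda = lambda, K = K),
            class = "cpuorf_engine")
}

#' External NCBI BLAST+ engine
#'
#' Shells out to `tblastn`/`blastp` (which must be on the PATH) with the
#' reference configuration for very short peptide queries at permissive
#' cutoffs: `-seg no -word_size 2 -matrix BLOSUM62 -comp_based_stats F`.
#'
#' @return an object of class `cpuorf_engine`
#' @export
blast_engine <- function() {
  structure(list(name = "blast"), class = "cpuorf_engine")
}

#' @export
print.cpuorf_engine <- function(x, ...) {
  cat("<cpuorf search engine:", x$name, ">\n")
  invisible(x)
}

hit_cols <- function() {
  tibble::tibble(query_id = character(0), subject_id = character(0),
                 pident = numeric(0), length = integer(0),
                 mismatch = integer(0), gapopen = integer(0),
                 qstart = integer(0), qend = integer(0),
                 sstart = integer(0), send = integer(0),
                 evalue = numeric(0), bitscore = numeric(0),
                 sframe = integer(0), subject_aa = character(0))
}

kmer_set <- function(x, w) {
  n <- nchar(x)
  if (n < w) return(character(0))
  unique(substring(x, 1:(n - w + 1L), w:n))
}

# exact shared word test
has_seed <- function(q, s, w) {
  any(kmer_set(q, w) %in% kmer_set(s, w))
}

# align peptide queries (named chr) against one aa subject string; returns
# rows in aa coordinates of the subject
align_block <- function(engine, queries, subject_aa_str, e_max, subject_id,
                        sframe, search_space = NULL) {
  sw <- kmer_set(subject_aa_str, engine$word_size)
  seeded <- vapply(queries, function(q)
    any(kmer_set(q, engine$word_size) %in% sw), logical(1))
  queries <- queries[seeded]
  if (length(queries) == 0L) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject_aa_str),
    type = "local", substitutionMatrix = aa_score_matrix(),
    gapOpening = engine$gap_open, gapExtension = engine$gap_ext)
  S <- Biostrings::score(pa)
  m <- nchar(queries)
  n <- search_space %||% nchar(subject_aa_str)
  evalue <- engine$K * m * n * exp(-engine$lambda * S)
  keep <- which(S > 0 & evalue <= e_max)
  if (length(keep) == 0L) return(NULL)
  ali_len <- Biostrings::nchar(pa)[keep]
  nmat <- Biostrings::nmatch(pa)[keep]
  nmis <- Biostrings::nmismatch(pa)[keep]
  indel <- Biostrings::nindel(pa)
  gopen <- (Biostrings::insertion(indel)[, "Length"] +
              Biostrings::deletion(indel)[, "Length"])[keep]
  qa <- Biostrings::pattern(pa)
  sa <- Biostrings::subject(pa)
  s1 <- BiocGenerics::start(sa)[keep]
  s2 <- BiocGenerics::end(sa)[keep]
  tibble::tibble(
    query_id = names(queries)[keep],
    subject_id = subject_id,
    pident = round(100 * nmat / ali_len, 2),
    length = ali_len,
    mismatch = nmis, gapopen = gopen,
    qstart = BiocGenerics::start(qa)[keep], qend = BiocGenerics::end(qa)[keep],
    sstart = s1, send = s2,
    evalue = evalue[keep],
    bitscore = (engine$lambda * S[keep] - log(engine$K)) / log(2),
    sframe = sframe,
    subject_aa = substring(subject_aa_str, s1, s2)
  )
}

#' Translated homology search (tblastn-like)
#'
#' Searches peptide queries against the six-frame translations of a nucleotide
#' collection. Subject coordinates are reported 1-based inclusive in
#' nucleotides, orientation-encoded (for minus frames `sstart > send`);
#' `sframe` follows the BLAST convention (+1..+3 counted from the 5' end,
#' -1..-3 from the 3' end).
#'
#' @param engine a `cpuorf_engine`
#' @param queries named character vector of peptide sequences
#' @param subjects named character vector of nucleotide sequences
#' @param e_max E-value cutoff (hits with `evalue <= e_max` are reported)
#' @param search_space effective database size in amino acids for the
#'   Karlin-Altschul E-value; defaults to the total translated length of
#'   `subjects` (six frames), so E scales with the collection searched as in
#'   BLAST. Pass the full-collection value when scoring a sub-search whose
#'   E-values must be comparable with a larger search.
#' @return hit tibble with the 12 standard tabular columns plus `sframe` and
#'   `subject_aa` (the translated subject segment of the HSP)
#' @export
search_translated <- function(engine, queries, subjects, e_max = 2000,
                              search_space = NULL) {
  stopifnot(inherits(engine, "cpuorf_engine"))
  if (length(queries) == 0L || length(subjects) == 0L) return(hit_cols())
  if (identical(engine$name, "blast")) {
    return(blast_search(queries, subjects, e_max, protein_db = FALSE))
  }
  # translate all frames once; the sum of frame lengths is the search space
  frames <- list()
  for (sid in names(subjects)) {
    sseq <- toupper(subjects[[sid]])
    L <- nchar(sseq)
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      rseq <- if (fr > 0) sseq else revcomp(sseq)
      off <- abs(fr) - 1L
      if (L - off < 3L) next
      aa <- translate_nt(substr(rseq, off + 1L, L))
      if (nchar(aa) == 0L) next
      frames[[length(frames) + 1L]] <- list(sid = sid, fr = fr, aa = aa,
                                            L = L)
    }
  }
  n_eff <- search_space %||% sum(vapply(frames, function(f) nchar(f$aa),
                                        numeric(1)))
  out <- list()
  for (f in frames) {
    sid <- f$sid; fr <- f$fr; L <- f$L
    off <- abs(fr) - 1L
    {
      blk <- align_block(engine, queries, f$aa, e_max, sid, fr,
                         search_space = n_eff)
      if (is.null(blk)) next
      # aa positions -> nt positions on the original strand
      if (fr > 0) {
        blk$sstart <- off + 3L * (blk$sstart - 1L) + 1L
        blk$send <- off + 3L * blk$send
      } else {
        a1 <- blk$sstart; a2 <- blk$send
        blk$sstart <- L - (off + 3L * (a1 - 1L))
        blk$send <- L - (off + 3L * a2) + 1L
      }
      out[[length(out) + 1L]] <- blk
    }
  }
  if (length(out) == 0L) return(hit_cols())
  dplyr::arrange(dplyr::bind_rows(out), .data$query_id, .data$evalue)
}

#' Protein-protein homology search (blastp-like)
#'
#' @inheritParams search_translated
#' @param subjects named character vector of peptide sequences
#' @return hit tibble as in [search_translated()]; `sstart`/`send` are amino
#'   acid positions and `sframe` is 0
#' @export
search_protein <- function(engine, queries, subjects, e_max = 2000,
                           search_space = NULL) {
  stopifnot(inherits(engine, "cpuorf_engine"))
  if (length(queries) == 0L || length(subjects) == 0L) return(hit_cols())
  if (identical(engine$name, "blast")) {
    return(blast_search(queries, subjects, e_max, protein_db = TRUE))
  }
  n_eff <- search_space %||% sum(nchar(subjects))
  out <- list()
  for (sid in names(subjects)) {
    blk <- align_block(engine, queries, toupper(subjects[[sid]]), e_max,
                       sid, 0L, search_space = n_eff)
    if (!is.null(blk)) out[[length(out) + 1L]] <- blk
  }
  if (length(out) == 0L) return(hit_cols())
  dplyr::arrange(dplyr::bind_rows(out), .data$query_id, .data$evalue)
}

# external NCBI BLAST+ tabular run
blast_search <- function(queries, subjects, e_max, protein_db) {
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "query.fa"); sf <- file.path(td, "db.fa")
  write_fasta(queries, qf)
  write_fasta(subjects, sf)
  dbtype <- if (protein_db) "prot" else "nucl"
  res <- system2("makeblastdb", c("-in", sf, "-dbtype", dbtype),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status"))) {
    stop("makeblastdb failed: ", paste(res, collapse = "\n"))
  }
  prog <- if (protein_db) "blastp" else "tblastn"
  outf <- file.path(td, "hits.tsv")
  fmt <- "6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore sframe sseq"
  args <- c("-query", qf, "-db", sf, "-evalue", format(e_max, scientific = FALSE),
            "-seg", "no", "-word_size", "2", "-matrix", "BLOSUM62",
            "-comp_based_stats", "F", "-outfmt", shQuote(fmt), "-out", outf)
  res <- system2(prog, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status"))) {
    stop(prog, " failed: ", paste(res, collapse = "\n"))
  }
  if (!file.exists(outf) || file.size(outf) == 0L) return(hit_cols())
  h <- readr::read_tsv(outf, col_names = c("query_id", "subject_id", "pident",
                                           "length", "mismatch", "gapopen",
                                           "qstart", "qend", "sstart", "send",
                                           "evalue", "bitscore", "sframe",
                                           "subject_aa"),
                       col_types = "ccdiiiiiiiddic", progress = FALSE)
  h$subject_aa <- gsub("[-*]", "", h$subject_aa)
  dplyr::arrange(h, .data$query_id, .data$evalue)
}
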