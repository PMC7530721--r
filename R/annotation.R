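#' Assemble transcript models from a genome FASTA and Ensembl-dialect GFF3
#'
#' Parses `gene`/`mRNA` (or `transcript`)/`exon`/`CDS` features, splices exon
#' sequences in transcription direction and slices out the 5'-UTR and main ORF
#' (mORF) of every splice variant that carries at least one CDS segment.
#' Minus-strand transcripts are reverse-complemented so that every stored
#' sequence reads 5' to 3'. GFF3 coordinates (1-based inclusive) are converted
#' once, here, to the package-internal 0-based half-open convention.
#'
#' The phase column of the first CDS segment (transcription order) is honoured
#' by trimming that many nucleotides off the mORF 5' end. Transcripts whose CDS
#' length is not a multiple of three after phase adjustment are skipped with a
#' warning. `five_prime_UTR` features, when present, are cross-checked against
#' the UTR inferred from exon/CDS structure; on conflict the inference wins and
#' the conflict is recorded in `attr(models, "utr_conflicts")`.
#'
#' @param gff3_path path to a GFF3 annotation (plain or gzip)
#' @param genome_path path to the genome FASTA (plain or gzip)
#' @return a tibble with one row per protein-coding splice variant: columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` and `cds`
#'   (list-columns of 0-based half-open genomic interval matrices in
#'   transcription order), `utr5_seq`, `morf_nt`, `morf_aa`, `utr5_len`,
#'   `morf_len`, `non_atg_start`. Attributes: `n_skipped_cds` (transcripts
#'   dropped for out-of-frame CDS), `n_non_atg` (annotated non-ATG starts,
#'   retained), `utr_conflicts` (transcript ids).
#' @export
read_transcript_models <- function(gff3_path, genome_path) {
  gff <- rtracklayer::import(gff3_path)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  strip_id <- function(x) sub("^(transcript|gene|CDS|exon):", "", x)
  type <- as.character(gff$type)
  first_parent <- function(g) {
    vapply(as.list(g$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else strip_id(p[[1]])
    }, character(1))
  }

  mrna <- gff[type %in% c("mRNA", "transcript")]
  mrna_id <- strip_id(mrna$ID)
  mrna_gene <- first_parent(mrna)
  # transcripts without a gene parent stand for themselves
  mrna_gene[is.na(mrna_gene)] <- mrna_id[is.na(mrna_gene)]
  tx_meta <- tibble::tibble(
    transcript_id = mrna_id,
    gene_id = mrna_gene,
    chrom = as.character(GenomeInfoDb::seqnames(mrna)),
    strand = as.character(BiocGenerics::strand(mrna))
  )

  feat_tbl <- function(what) {
    f <- gff[type == what]
    tibble::tibble(
      parent = first_parent(f),
      start = BiocGenerics::start(f) - 1L,  # -> 0-based half-open
      end = BiocGenerics::end(f),
      phase = if (!is.null(f$phase)) as.integer(f$phase) else NA_integer_
    )
  }
  exon_tbl <- feat_tbl("exon")
  cds_tbl <- feat_tbl("CDS")
  utr_tbl <- feat_tbl("five_prime_UTR")

  exon_by_tx <- split(exon_tbl, exon_tbl$parent)
  cds_by_tx <- split(cds_tbl, cds_tbl$parent)
  utr_by_tx <- split(utr_tbl, utr_tbl$parent)

  n_skipped <- 0L
  n_non_atg <- 0L
  utr_conflicts <- character(0)
  rows <- list()

  for (k in seq_len(nrow(tx_meta))) {
    tid <- tx_meta$transcript_id[k]
    cds_k <- cds_by_tx[[tid]]
    if (is.null(cds_k) || nrow(cds_k) == 0L) next  # non-coding variant
    strand <- tx_meta$strand[k]
    chrom <- tx_meta$chrom[k]
    if (!chrom %in% names(genome)) {
      stop("genome FASTA is missing sequence for seqid '", chrom, "'")
    }
    exon_k <- exon_by_tx[[tid]]
    if (is.null(exon_k) || nrow(exon_k) == 0L) {
      # CDS without exon features: treat CDS segments as exons
      exon_k <- cds_k
    }
    ord <- order(exon_k$start, decreasing = (strand == "-"))
    exons <- cbind(start = exon_k$start[ord], end = exon_k$end[ord])

    # spliced transcript sequence, 5'->3'
    plus_order <- exons[order(exons[, 1]), , drop = FALSE]
    segs <- vapply(seq_len(nrow(plus_order)), function(i) {
      as.character(Biostrings::subseq(genome[[chrom]],
                                      start = plus_order[i, 1] + 1L,
                                      end = plus_order[i, 2]))
    }, character(1))
    spliced <- paste(segs, collapse = "")
    if (strand == "-") spliced <- revcomp(spliced)

    # CDS bounds in transcript coordinates
    cds_ord <- order(cds_k$start, decreasing = (strand == "-"))
    cds <- cbind(start = cds_k$start[cds_ord], end = cds_k$end[cds_ord])
    first5 <- if (strand == "+") cds[1, 1] else cds[1, 2] - 1L
    last3 <- if (strand == "+") cds[nrow(cds), 2] - 1L else cds[nrow(cds), 1]
    t_start <- genomic_to_tx(exons, strand, first5)
    t_end <- genomic_to_tx(exons, strand, last3)
    if (is.na(t_start) || is.na(t_end)) {
      warning("CDS of transcript '", tid, "' falls outside its exons; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    t_end <- t_end + 1L
    phase <- cds_k$phase[cds_ord][1]
    if (!is.na(phase) && phase > 0L) t_start <- t_start + phase
    cds_len <- sum(cds[, 2] - cds[, 1]) - (if (is.na(phase)) 0L else phase)
    if ((t_end - t_start) != cds_len) {
      warning("CDS of transcript '", tid, "' is not contiguous on the spliced transcript; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    if (cds_len %% 3L != 0L) {
      warning("CDS of transcript '", tid,
              "' is not divisible by 3 after phase adjustment; skipped")
      n_skipped <- n_skipped + 1L
      next
    }

    utr5 <- substr(spliced, 1L, t_start)
    morf <- substr(spliced, t_start + 1L, t_end)
    aa <- translate_nt(morf)
    aa <- sub("\\*$", "", aa)
    if (!startsWith(morf, "ATG")) n_non_atg <- n_non_atg + 1L

    utr_k <- utr_by_tx[[tid]]
    if (!is.null(utr_k) && nrow(utr_k) > 0L) {
      if (sum(utr_k$end - utr_k$start) != nchar(utr5)) {
        utr_conflicts <- c(utr_conflicts, tid)
      }
    }

    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = tid, gene_id = tx_meta$gene_id[k],
      chrom = chrom, strand = strand,
      exons = list(exons), cds = list(cds),
      utr5_seq = utr5, morf_nt = morf, morf_aa = aa,
      utr5_len = nchar(utr5), morf_len = nchar(morf),
      non_atg_start = !startsWith(morf, "ATG")
    )
  }

  models <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(transcript_id = character(0), gene_id = character(0),
                   chrom = character(0), strand = character(0),
                   exons = list(), cds = list(),
                   utr5_seq = character(0), morf_nt = character(0),
                   morf_aa = character(0), utr5_len = integer(0),
                   morf_len = integer(0), non_atg_start = logical(0))
  attr(models, "n_skipped_cds") <- n_skipped
  attr(models, "n_non_atg") <- n_non_atg
  attr(models, "utr_conflicts") <- utr_conflicts
  models
}

#' Count distinct protein-coding genes among transcript models
#'
#' A gene is protein-coding when at least one of its splice variants carries a
#' translatable mORF (all models returned by [read_transcript_models()] do).
#'
#' @param models tibble from [read_transcript_models()]
#' @return integer count of distinct gene ids
#' @export
count_coding_genes <- function(models) {
  dplyr::n_distinct(models$gene_id)
}

#' Write the per-transcript table and sequence files
#'
#' Emits `transcripts.tsv` (transcript_id, gene_id, utr5_len, morf_len), a
#' 5'-UTR nucleotide FASTA and a mORF peptide FASTA into `dir`.
#'
#' @param models tibble from [read_transcript_models()]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_model_outputs <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "transcripts.tsv")
  readr::write_tsv(dplyr::select(models, "transcript_id", "gene_id",
                                 "utr5_len", "morf_len"), tsv)
  utr <- file.path(dir, "utr5.fa")
  write_fasta(setNames(models$utr5_seq, models$transcript_id), utr)
  pep <- file.path(dir, "morf_protein.fa")
  write_fasta(setNames(models$morf_aa, models$transcript_id), pep)
  invisible(c(tsv, utr, pep))
}
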