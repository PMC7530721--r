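STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#' @param x character scalar over {A,C,G,T,N}
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string with the standard code
#'
#' Trailing incomplete codons are dropped; codons containing N translate to X;
#' stop codons translate to `*`.
#' @param nt character scalar
#' @return character scalar (amino acids, possibly containing `*` and `X`)
#' @keywords internal
translate_nt <- function(nt) {
  n <- 3L * (nchar(nt) %/% 3L)
  if (n == 0L) return("")
  cods <- codon_split(substr(nt, 1L, n))
  aa <- codon_table()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# character vector of codons (assumes nchar %% 3 == 0)
codon_split <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# named chr: codon -> aa ('*' stop, 'X' ambiguous), covering all 4^3 codons
# plus every codon containing N
codon_table <- function() {
  if (!is.null(.cpuorf_cache$codon_table)) return(.cpuorf_cache$codon_table)
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(cods, function(cd) {
    # no.init.codon: a lone CTG/TTG must translate as L, not initiator M
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1))
  # codons with N: translate to X unless all completions agree
  basesN <- c(bases, "N")
  all_cods <- as.vector(outer(outer(basesN, basesN, paste0), basesN, paste0))
  ncods <- setdiff(all_cods, cods)
  aaN <- vapply(ncods, function(cd) {
    parts <- strsplit(cd, "")[[1]]
    opts <- lapply(parts, function(b) if (b == "N") bases else b)
    combos <- expand.grid(opts, stringsAsFactors = FALSE)
    res <- unique(aa[paste0(combos[[1]], combos[[2]], combos[[3]])])
    if (length(res) == 1L) res else "X"
  }, character(1))
  tab <- c(aa, aaN)
  .cpuorf_cache$codon_table <- tab
  tab
}

# Amino-acid scoring matrix: BLOSUM62 guaranteed to cover '*' and 'X'
aa_score_matrix <- function() {
  if (!is.null(.cpuorf_cache$blosum62)) return(.cpuorf_cache$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  for (ltr in c("X", "*")) {
    if (!ltr %in% rownames(m)) {
      sc <- if (ltr == "*") -4L else -1L
      m <- rbind(m, sc)
      m <- cbind(m, sc)
      rownames(m)[nrow(m)] <- ltr
      colnames(m)[ncol(m)] <- ltr
    }
  }
  # stops must never align silently against residues
  m["*", ] <- -8L
  m[, "*"] <- -8L
  m["*", "*"] <- 1L
  .cpuorf_cache$blosum62 <- m
  m
}

#' Map a transcript-coordinate interval to genomic blocks
#'
#' @param exons matrix with columns start,end: 0-based half-open genomic exon
#'   intervals in transcription order (for minus-strand transcripts the rows
#'   run 3'-most genomic block first).
#' @param strand "+" or "-"
#' @param t0,t1 transcript interval, 0-based half-open (0 = transcript 5' end)
#' @return matrix of 0-based half-open genomic intervals in transcription order
#' @keywords internal
tx_to_genomic <- function(exons, strand, t0, t1) {
  lens <- exons[, 2] - exons[, 1]
  ends_t <- cumsum(lens)
  starts_t <- c(0, head(ends_t, -1L))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(t0, starts_t[i]); b <- min(t1, ends_t[i])
    if (a >= b) next
    la <- a - starts_t[i]; lb <- b - starts_t[i]
    if (strand == "+") {
      out[[length(out) + 1L]] <- c(exons[i, 1] + la, exons[i, 1] + lb)
    } else {
      out[[length(out) + 1L]] <- c(exons[i, 2] - lb, exons[i, 2] - la)
    }
  }
  do.call(rbind, out)
}

# inverse: genomic position (0-based) -> transcript offset, or NA
genomic_to_tx <- function(exons, strand, gpos) {
  lens <- exons[, 2] - exons[, 1]
  starts_t <- c(0, head(cumsum(lens), -1L))
  for (i in seq_len(nrow(exons))) {
    if (gpos >= exons[i, 1] && gpos < exons[i, 2]) {
      if (strand == "+") return(starts_t[i] + (gpos - exons[i, 1]))
      return(starts_t[i] + (exons[i, 2] - 1L - gpos))
    }
  }
  NA_integer_
}

# canonical string key for a set of genomic blocks
blocks_key <- function(chrom, strand, blocks) {
  paste0(chrom, strand, ":",
         paste(paste0(blocks[, 1], "-", blocks[, 2]), collapse = ","))
}

#' Write a named character vector as FASTA
#' @keywords internal
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) { writeLines("", con); next }
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @keywords internal
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
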