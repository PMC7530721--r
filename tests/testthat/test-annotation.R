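# transcript-model assembly from genome FASTA + GFF3

write_mini_genome <- function(dir, chr1) {
  path <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chr1), path)
  path
}

gff_line <- function(chrom, type, start, end, strand, attrs, phase = ".") {
  paste(chrom, "test", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

test_that("plus-strand multi-exon model slices UTR and mORF correctly", {
  dir <- withr::local_tempdir()
  # exons 1-30 and 41-70 (1-based inclusive), CDS 11-30 + 41-59 (39 nt)
  set.seed(1)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  genome <- write_mini_genome(dir, chr1)
  gff <- c("##gff-version 3",
           gff_line("chr1", "gene", 1, 70, "+", "ID=gene:gA"),
           gff_line("chr1", "mRNA", 1, 70, "+", "ID=transcript:tA;Parent=gene:gA"),
           gff_line("chr1", "exon", 1, 30, "+", "Parent=transcript:tA"),
           gff_line("chr1", "exon", 41, 70, "+", "Parent=transcript:tA"),
           gff_line("chr1", "CDS", 11, 30, "+", "Parent=transcript:tA", "0"),
           gff_line("chr1", "CDS", 41, 59, "+", "Parent=transcript:tA", "0"))
  gff3 <- file.path(dir, "a.gff3")
  writeLines(gff, gff3)
  m <- read_transcript_models(gff3, genome)
  expect_equal(nrow(m), 1L)
  expect_equal(m$utr5_seq, substr(chr1, 1, 10))
  expect_equal(m$morf_nt, paste0(substr(chr1, 11, 30), substr(chr1, 41, 59)))
  expect_equal(nchar(m$morf_nt) %% 3L, 0L)
  # round trip: re-splicing exons and slicing by CDS bounds reproduces
  # utr5 + morf exactly
  spliced <- paste0(substr(chr1, 1, 30), substr(chr1, 41, 70))
  expect_equal(paste0(m$utr5_seq, m$morf_nt), substr(spliced, 1, 49))
})

test_that("minus-strand single-exon model is reverse-complemented 5'->3'", {
  dir <- withr::local_tempdir()
  # design on the transcript strand, then place its reverse complement
  utr <- "CCTTACCTT"
  morf <- "ATGAAACCCTGA"
  tail3 <- "GGTT"
  tx <- paste0(utr, morf, tail3)
  chr1 <- paste0("ACGT", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tx))), "TTTT")
  genome <- write_mini_genome(dir, chr1)
  # exon occupies 5..(4 + nchar(tx)); CDS is inside it
  e1 <- 5L; e2 <- 4L + nchar(tx)
  cds1 <- e1 + nchar(tail3); cds2 <- e2 - nchar(utr)
  gff <- c("##gff-version 3",
           gff_line("chr1", "gene", e1, e2, "-", "ID=gene:gB"),
           gff_line("chr1", "mRNA", e1, e2, "-", "ID=transcript:tB;Parent=gene:gB"),
           gff_line("chr1", "exon", e1, e2, "-", "Parent=transcript:tB"),
           gff_line("chr1", "CDS", cds1, cds2, "-", "Parent=transcript:tB", "0"))
  gff3 <- file.path(dir, "b.gff3")
  writeLines(gff, gff3)
  m <- read_transcript_models(gff3, genome)
  expect_equal(m$utr5_seq, utr)
  expect_equal(m$morf_nt, morf)
  expect_equal(m$morf_aa, "MKP")
  expect_false(m$non_atg_start)
})

test_that("mRNA without CDS is excluded and gene counting follows", {
  dir <- withr::local_tempdir()
  set.seed(2)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  substr(chr1, 11, 13) <- "ATG"
  substr(chr1, 29, 31) <- "TAA"
  genome <- write_mini_genome(dir, chr1)
  gff <- c("##gff-version 3",
           gff_line("chr1", "gene", 1, 40, "+", "ID=gene:gC"),
           gff_line("chr1", "mRNA", 1, 40, "+", "ID=transcript:tC1;Parent=gene:gC"),
           gff_line("chr1", "exon", 1, 40, "+", "Parent=transcript:tC1"),
           gff_line("chr1", "CDS", 11, 31, "+", "Parent=transcript:tC1", "0"),
           gff_line("chr1", "mRNA", 1, 40, "+", "ID=transcript:tC2;Parent=gene:gC"),
           gff_line("chr1", "exon", 1, 40, "+", "Parent=transcript:tC2"),
           gff_line("chr1", "gene", 41, 60, "+", "ID=gene:gD"),
           gff_line("chr1", "mRNA", 41, 60, "+", "ID=transcript:tD;Parent=gene:gD"),
           gff_line("chr1", "exon", 41, 60, "+", "Parent=transcript:tD"))
  gff3 <- file.path(dir, "c.gff3")
  writeLines(gff, gff3)
  m <- read_transcript_models(gff3, genome)
  expect_equal(m$transcript_id, "tC1")   # tC2 and tD lack CDS
  expect_equal(count_coding_genes(m), 1L)
  expect_equal(count_coding_genes(m[0, ]), 0L)
})

test_that("CDS phase shifts the mORF start; out-of-frame CDS is skipped", {
  dir <- withr::local_tempdir()
  set.seed(3)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  genome <- write_mini_genome(dir, chr1)
  gff <- c("##gff-version 3",
           gff_line("chr1", "gene", 1, 40, "+", "ID=gene:gE"),
           gff_line("chr1", "mRNA", 1, 40, "+", "ID=transcript:tE;Parent=gene:gE"),
           gff_line("chr1", "exon", 1, 40, "+", "Parent=transcript:tE"),
           gff_line("chr1", "CDS", 11, 32, "+", "Parent=transcript:tE", "1"),
           gff_line("chr1", "gene", 41, 60, "+", "ID=gene:gF"),
           gff_line("chr1", "mRNA", 41, 60, "+", "ID=transcript:tF;Parent=gene:gF"),
           gff_line("chr1", "exon", 41, 60, "+", "Parent=transcript:tF"),
           gff_line("chr1", "CDS", 45, 58, "+", "Parent=transcript:tF", "0"))
  gff3 <- file.path(dir, "d.gff3")
  writeLines(gff, gff3)
  expect_warning(m <- read_transcript_models(gff3, genome),
                 "not divisible by 3")
  # tE: CDS 11-32 is 22 nt, phase 1 -> 21 nt starting at base 12
  expect_equal(m$transcript_id, "tE")
  expect_equal(m$morf_nt, substr(chr1, 12, 32))
  expect_equal(m$utr5_seq, substr(chr1, 1, 11))
  expect_equal(attr(m, "n_skipped_cds"), 1L)
})

test_that("missing chromosome is fatal with the offending seqid", {
  dir <- withr::local_tempdir()
  genome <- write_mini_genome(dir, "ACGTACGTACGT")
  gff <- c("##gff-version 3",
           gff_line("chrMISSING", "gene", 1, 9, "+", "ID=gene:gX"),
           gff_line("chrMISSING", "mRNA", 1, 9, "+", "ID=transcript:tX;Parent=gene:gX"),
           gff_line("chrMISSING", "exon", 1, 9, "+", "Parent=transcript:tX"),
           gff_line("chrMISSING", "CDS", 1, 9, "+", "Parent=transcript:tX", "0"))
  gff3 <- file.path(dir, "e.gff3")
  writeLines(gff, gff3)
  expect_error(read_transcript_models(gff3, genome), "chrMISSING")
})

test_that("five_prime_UTR conflicts are logged and inference wins", {
  dir <- withr::local_tempdir()
  set.seed(4)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  genome <- write_mini_genome(dir, chr1)
  gff <- c("##gff-version 3",
           gff_line("chr1", "gene", 1, 40, "+", "ID=gene:gG"),
           gff_line("chr1", "mRNA", 1, 40, "+", "ID=transcript:tG;Parent=gene:gG"),
           gff_line("chr1", "exon", 1, 40, "+", "Parent=transcript:tG"),
           gff_line("chr1", "five_prime_UTR", 1, 7, "+", "Parent=transcript:tG"),
           gff_line("chr1", "CDS", 11, 31, "+", "Parent=transcript:tG", "0"))
  gff3 <- file.path(dir, "f.gff3")
  writeLines(gff, gff3)
  m <- read_transcript_models(gff3, genome)
  expect_equal(m$utr5_len, 10L)                 # inference, not the feature
  expect_equal(attr(m, "utr_conflicts"), "tG")
})

test_that("fixture genome round-trips: splicing reproduces planted sequences", {
  fx <- make_fixture(fixture_spec(seed = 11L), dir = withr::local_tempdir())
  m <- read_transcript_models(fx$gff3, fx$genome)
  truth <- fx$truth_tbl
  expect_equal(count_coding_genes(m), nrow(truth))
  expect_equal(attr(m, "n_skipped_cds"), 0L)
  expect_equal(attr(m, "n_non_atg"), 0L)
  # every mORF translates cleanly
  expect_true(all(!grepl("\\*", m$morf_aa)))
  expect_true(all(vapply(seq_len(nrow(m)), function(i) {
    startsWith(m$morf_nt[i], "ATG")
  }, logical(1))))
})
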