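# steps 3.1-4.2: permissive uORF search, putative uORF extraction,
# mORF confirmation, contaminant removal

toy_tax <- function() {
  tibble::tibble(
    record_id = c("mouse1", "human1", "worm1", "nolineage", "flagged"),
    taxid = as.character(1:5),
    species = c("Mus musculus", "Homo sapiens", "Caenorhabditis elegans",
                "Unknown sp.", "Mus musculus"),
    order = c("Rodentia", "Primates", "Rhabditida", "", "Rodentia"),
    lineage = c("Metazoa;Eumetazoa;Bilateria;Deuterostomia;Chordata;Vertebrata;Euteleostomi;Sarcopterygii;Tetrapoda;Mammalia;Eutheria;Euarchontoglires;Rodentia",
                "Metazoa;Eumetazoa;Bilateria;Deuterostomia;Chordata;Vertebrata;Euteleostomi;Sarcopterygii;Tetrapoda;Mammalia;Eutheria;Euarchontoglires;Primates",
                "Eukaryota;Opisthokonta;Fungi;Sordariomycetes",
                "", "Metazoa;Eumetazoa;Bilateria;Protostomia;Ecdysozoa"),
    source = "refseq",
    contaminant_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

test_that("uORF homology search keeps only other-species hits, best per subject", {
  eng <- builtin_engine()
  uorf_nt <- "ATGAAAACTGCTTATATTGCTAAACAACGTTGGTGA"
  uorf_aa <- sub("\\*$", "", cpuorf:::translate_nt(uorf_nt))
  rec <- paste0("CCTTA", uorf_nt, "GGAATTCC")
  coll <- c(mouse1 = rec, human1 = rec, worm1 = rec)
  uorfs <- tibble::tibble(uorf_id = "u1", aa_seq = uorf_aa)
  hits <- uorf_homology_search(uorfs, coll, toy_tax(), eng,
                               query_species = "Homo sapiens")
  expect_setequal(hits$subject_id, c("mouse1", "worm1"))  # human1 excluded
  expect_equal(sum(hits$subject_id == "mouse1"), 1L)      # deduped best-E
  expect_true(all(hits$evalue <= 2000))
  # no hits at all: the uORF simply drops out
  none <- uorf_homology_search(
    tibble::tibble(uorf_id = "u2", aa_seq = "MWWWCCWWWCW"),
    coll, toy_tax(), eng, query_species = "Homo sapiens")
  expect_equal(nrow(none), 0L)
})

test_that("extract_putative_uorf recovers ORF boundaries around the HSP", {
  eng <- builtin_engine()
  # subject: leader with in-frame stop, ATG, 4 codons, HSP region, stop
  hsp_pep <- "KTAYIAKQRW"
  hsp_nt <- "AAAACTGCTTATATTGCTAAACAACGTTGG"
  subj <- paste0("CCTAA",                  # stop in frame +3 at codons
                 "ATG", "GCTGCAGCCGCA",    # ATG + 4 codons upstream of HSP
                 hsp_nt,
                 "GCCGCAGCC",              # 3 codons downstream
                 "TGA", "CCTTCC")
  hit <- search_translated(eng, c(q = hsp_pep), c(s = subj), e_max = 10)
  expect_equal(nrow(hit), 1L)
  p <- extract_putative_uorf(hit[1, ], subj)
  # boundaries: the upstream ATG and the first in-frame stop after the HSP
  expect_false(p$five_prime_partial)
  expect_false(p$three_prime_partial)
  expect_equal(p$orf_nt, paste0("ATGGCTGCAGCCGCA", hsp_nt, "GCCGCAGCCTGA"))
  expect_equal(substr(p$orf_aa, 1, 1), "M")
  # the putative ORF always contains the HSP interval
  expect_lte(p$s_begin + 1L, min(hit$sstart, hit$send))
  expect_gte(p$s_end, max(hit$sstart, hit$send))

  # exact full-ORF copy: putative equals that ORF
  uorf_nt <- "ATGAAAACTGCTTATATTGCTAAACAACGTTGGTGA"
  subj2 <- paste0("CCTAACC", uorf_nt, "GGTTCC")
  uorf_aa <- sub("\\*$", "", cpuorf:::translate_nt(uorf_nt))
  hit2 <- search_translated(eng, c(q = uorf_aa), c(s = subj2), e_max = 10)
  p2 <- extract_putative_uorf(hit2[1, ], subj2)
  expect_equal(p2$orf_nt, uorf_nt)
  expect_equal(p2$orf_aa, uorf_aa)

  # segment without ATG, not reaching the subject 5' end -> none
  # (leader carries a stop in all three frames, so the stop-free segment
  # never reaches the subject 5' end whatever frame the hit lands in)
  subj3 <- paste0("TTAATTAATTAA", substr(uorf_nt, 4, nchar(uorf_nt)), "GGTTCC")
  hit3 <- search_translated(eng, c(q = uorf_aa), c(s = subj3), e_max = 10)
  expect_null(extract_putative_uorf(hit3[1, ], subj3))

  # segment reaching the 5' end without ATG -> 5'-partial
  subj4 <- paste0(substr(uorf_nt, 7, nchar(uorf_nt)), "GGTTCC")
  hit4 <- search_translated(eng, c(q = uorf_aa), c(s = subj4), e_max = 10)
  p4 <- extract_putative_uorf(hit4[1, ], subj4)
  expect_true(p4$five_prime_partial)

  # malformed coordinates error
  bad <- hit2[1, ]
  bad$send <- nchar(subj2) + 30L
  expect_error(extract_putative_uorf(bad, subj2), "outside")
})

test_that("putative-uORF boundaries agree with six-frame ORF enumeration", {
  # derived oracle: enumerate all maximal ORFs (first ATG of each stop-free
  # segment) in all six frames and pick the one containing the HSP
  eng <- builtin_engine()
  set.seed(77)
  pep <- "MKTAYIAKQRWLED"
  nt_pep <- "ATGAAAACTGCTTATATTGCTAAACAACGTTGGCTGGAAGAT"
  for (rep in 1:10) {
    lead <- paste(sample(c("A","C","G","T"), 30, TRUE), collapse = "")
    tail_ <- paste(sample(c("A","C","G","T"), 30, TRUE), collapse = "")
    subj <- paste0(lead, nt_pep, "TGA", tail_)
    hit <- search_translated(eng, c(q = pep), c(s = subj), e_max = 1e-3)
    if (nrow(hit) == 0L) next
    hit <- hit[which.min(hit$evalue), ]
    p <- extract_putative_uorf(hit, subj)
    expect_false(is.null(p))
    # oracle in the hit frame
    fr <- hit$sframe
    rseq <- if (fr > 0) subj else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(subj)))
    off <- abs(fr) - 1L
    n_cod <- (nchar(rseq) - off) %/% 3L
    cods <- substring(rseq, off + 3 * (0:(n_cod - 1)) + 1,
                      off + 3 * (0:(n_cod - 1)) + 3)
    stops <- which(cods %in% c("TAA", "TAG", "TGA"))
    b <- cpuorf:::frame_codon_bounds(fr, hit$sstart, hit$send, nchar(subj))
    prev <- suppressWarnings(max(stops[stops < b$aa_start]))
    seg0 <- if (is.finite(prev)) prev + 1L else 1L
    nxt <- suppressWarnings(min(stops[stops > b$aa_end]))
    seg1 <- if (is.finite(nxt)) nxt else n_cod
    atgs <- which(cods[seg0:b$aa_start] == "ATG")
    expect_gt(length(atgs), 0L)
    orf_oracle <- paste(cods[(seg0 + atgs[1] - 1L):seg1], collapse = "")
    expect_equal(p$orf_nt, orf_oracle)
  }
})

test_that("mORF confirmation enforces the strict E threshold and position", {
  eng <- builtin_engine()
  morf_nt <- "ATGGGTCTGCTGGAAGAGCGTCTGGGTATTCCGAAAGCGGCTGCTTTTGATTAA"
  morf_aa <- sub("\\*$", "", cpuorf:::translate_nt(morf_nt))
  uorf_nt <- "ATGAAAACTGCTTATATTGCTAAACAACGTTGGTGA"
  uorf_aa <- sub("\\*$", "", cpuorf:::translate_nt(uorf_nt))
  subj <- paste0("CCGTA", uorf_nt, "TTAATTAATTAA", morf_nt, "CCGGTT")
  hit <- search_translated(eng, c(q = uorf_aa), c(s = subj), e_max = 10)
  p <- extract_putative_uorf(hit[which.min(hit$evalue), ], subj)
  conf <- confirm_morf(morf_aa, p, subj, eng)
  expect_false(is.null(conf))
  expect_lt(conf$evalue, 0.1)
  # an unrelated mORF is not confirmed
  expect_null(confirm_morf("MWWPCWHMYWDNQEWRIP", p, subj, eng))
  # putative uORF at the subject 3' end: nothing downstream -> none
  subj_end <- paste0("CCGTA", uorf_nt)
  hit_e <- search_translated(eng, c(q = uorf_aa), c(s = subj_end), e_max = 10)
  p_e <- extract_putative_uorf(hit_e[which.min(hit_e$evalue), ], subj_end)
  expect_null(confirm_morf(morf_aa, p_e, subj_end, eng))
})

test_that("contaminant filter removes non-metazoan, flagged and lineage-less hits", {
  hits <- tibble::tibble(
    uorf_id = "u1",
    subject_id = c("mouse1", "worm1", "nolineage", "flagged"))
  expect_message(out <- filter_contaminants(hits, toy_tax()),
                 "without lineage")
  expect_equal(out$subject_id, "mouse1")
})

test_that("hit sets only shrink along steps 3.1 -> 4.1 -> 4.2 on the fixture", {
  fx <- make_fixture(fixture_spec(seed = 23L), dir = withr::local_tempdir())
  m <- read_transcript_models(fx$gff3, fx$genome)
  u <- extract_uorfs(m)
  coll <- read_collection(fx$collection)
  tax <- read_taxonomy(fx$taxonomy)
  eng <- builtin_engine()
  hits <- uorf_homology_search(u, coll, tax, eng,
                               query_species = "Homo sapiens")
  put <- dplyr::bind_rows(purrr::compact(purrr::map(
    seq_len(nrow(hits)), function(k) {
      p <- extract_putative_uorf(hits[k, ], coll[[hits$subject_id[k]]])
      if (is.null(p)) return(NULL)
      dplyr::bind_cols(tibble::tibble(uorf_id = hits$query_id[k]), p)
    })))
  morf_by_tx <- stats::setNames(m$morf_aa, m$transcript_id)
  tx_by_uorf <- stats::setNames(u$transcript_id, u$uorf_id)
  conf <- dplyr::bind_rows(purrr::compact(purrr::map(
    seq_len(nrow(put)), function(k) {
      p <- put[k, ]
      h <- confirm_morf(morf_by_tx[[tx_by_uorf[[p$uorf_id]]]], p,
                        coll[[p$subject_id]], eng)
      if (is.null(h)) return(NULL)
      p
    })))
  decont <- filter_contaminants(conf, tax)
  key <- function(d) unique(paste(d$uorf_id, d$subject_id))
  k31 <- unique(paste(hits$query_id, hits$subject_id))
  expect_true(all(key(put) %in% k31))
  expect_true(all(key(conf) %in% key(put)))
  expect_true(all(key(decont) %in% key(conf)))
  # contaminant records are gone after 4.2
  expect_false(any(grepl("^C_", decont$subject_id)))
  expect_true(any(grepl("^C_", conf$subject_id)))
})
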