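# ortholog grouping, uORF clustering, HG numbering, splice resolution

test_that("ortholog clustering groups similar mORFs via reciprocal hits", {
  eng <- builtin_engine()
  set.seed(41)
  base <- paste(sample(cpuorf:::NONSTOP_CODONS(), 60, TRUE), collapse = "")
  peps <- c(
    A = sub("\\*$", "", cpuorf:::translate_nt(base)),
    B = sub("\\*$", "", cpuorf:::translate_nt(mutate_coding(base, 0.3, 0.15))),
    C = "MWNDPQECRIKHYLSTVWAGFEDNQKRLIMPSHYTCVAGWDEKRNQLIPFSA")
  cl <- cluster_orthologs(peps, eng)
  expect_equal(cl$morf_cluster[cl$gene_id == "A"],
               cl$morf_cluster[cl$gene_id == "B"])
  expect_false(cl$morf_cluster[cl$gene_id == "C"] ==
                 cl$morf_cluster[cl$gene_id == "A"])
  # all unrelated -> all singletons; one gene -> one cluster
  un <- cluster_orthologs(c(A = peps[["C"]],
                            B = "MKKKEEEDDDRRRHHHAAAGGGPPPLLLVVV"), eng)
  expect_equal(dplyr::n_distinct(un$morf_cluster), 2L)
  one <- cluster_orthologs(c(Z = peps[["A"]]), eng)
  expect_equal(one$morf_cluster, 1L)
})

test_that("uORF distance matrix is binary, symmetric, OR-symmetrized", {
  eng <- builtin_engine()
  p1 <- "MKTAYIAKQRWLEDSTVNN"
  p2 <- "MKTAYIAKQRWLEDSAVNQ"
  p3 <- "MWWPCHHGDDNEYRIQPLC"
  d <- uorf_distance_matrix(c(a = p1, b = p2, c = p3), eng)
  expect_true(all(d %in% c(0, 1)))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 1)
  expect_equal(unname(d["b", "c"]), 1)
  # identical peptides: all-zero matrix
  d2 <- uorf_distance_matrix(c(x = p1, y = p1), eng)
  expect_true(all(d2 == 0))
})

test_that("single-linkage cut at 0.5 equals zero-graph components", {
  # forced examples
  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(single_linkage_cut(m3)), rep(1L, 3))
  m <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m) <- 0; m["a", "b"] <- m["b", "a"] <- 0
  expect_equal(length(unique(single_linkage_cut(m))), 2L)
  # chain a-b, b-c with a-c distant: chaining joins all three
  ch <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(ch) <- 0
  ch["a", "b"] <- ch["b", "a"] <- 0
  ch["b", "c"] <- ch["c", "b"] <- 0
  expect_equal(length(unique(single_linkage_cut(ch))), 1L)
  # single element
  expect_equal(unname(single_linkage_cut(matrix(0, 1, 1))), 1L)

  # property: random binary matrices vs transitive-closure oracle
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:14, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- sample(0:1, n * (n - 1) / 2, TRUE)
    m <- m + t(m)
    m[m > 1] <- 1
    labs <- single_linkage_cut(m, 0.5)
    expect_true(same_partition(labs, oracle_zero_components(m)))
  }
})

fam_tbl <- function() {
  tibble::tibble(
    uorf_id = c("u1", "u2", "u3", "u4"),
    gene_id = c("gA", "gB", "gC", "gD"),
    morf_cluster = c(1L, 1L, 2L, 3L),
    uorf_cluster = c(1L, 2L, 1L, 1L),
    range_label = c("Euarchontoglires", "Bilateria other than Protostomia and Deuterostomia",
                    "Aves", "Aves"),
    n_orders_total = c(2L, 8L, 10L, 3L))
}

test_that("HG numbering orders by range distality, then order count, then gene", {
  hg <- assign_hg_numbers(fam_tbl(), query_category = "Euarchontoglires")
  lab <- stats::setNames(hg$label, hg$uorf_id)
  # u2 (Bilateria-level) is most distal -> HG0001; its ortholog-group sib u1
  # shares the HG number with subnumber 2
  expect_equal(unname(lab["u2"]), "HG0001.1")
  expect_equal(unname(lab["u1"]), "HG0001.2")
  # u3 and u4 tie on range (Aves); more orders wins the smaller number
  expect_equal(unname(lab["u3"]), "HG0002.1")
  expect_equal(unname(lab["u4"]), "HG0003.1")
})

test_that("HG numbering is invariant to input row order", {
  f <- fam_tbl()
  a <- assign_hg_numbers(f, "Euarchontoglires")
  set.seed(7)
  for (rep in 1:5) {
    b <- assign_hg_numbers(f[sample(nrow(f)), ], "Euarchontoglires")
    expect_equal(dplyr::arrange(a, uorf_id)$label,
                 dplyr::arrange(b, uorf_id)$label)
  }
  # bijection onto 1..K at the family level
  fams <- unique(a[, c("morf_cluster", "uorf_cluster", "hg_number",
                       "hg_subnumber")])
  expect_setequal(unique(a$hg_number), seq_len(dplyr::n_distinct(a$morf_cluster)))
  expect_true(all(fams$hg_subnumber >= 1L))
})

test_that("splice-variant resolution follows the stated precedence", {
  base <- tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+",
    span_start = c(100, 110), span_end = c(160, 170))
  # same frame: longest conserved region wins
  r1 <- dplyr::mutate(base, uorf_id = c("a", "b"),
                      frame_phase = "+1",
                      conserved_len = c(30L, 18L),
                      median_ratio = c(0.3, 0.1))
  expect_equal(resolve_splice_variants(r1)$uorf_id, "a")
  # equal conserved length: lowest ratio wins
  r2 <- dplyr::mutate(r1, conserved_len = 20L)
  expect_equal(resolve_splice_variants(r2)$uorf_id, "b")
  # different frames: lowest ratio wins outright
  r3 <- dplyr::mutate(r1, frame_phase = c("+1", "+2"),
                      median_ratio = c(0.4, 0.2))
  expect_equal(resolve_splice_variants(r3)$uorf_id, "b")
  # non-overlapping records both survive
  r4 <- dplyr::mutate(r1, span_start = c(100, 300), span_end = c(160, 360))
  expect_setequal(resolve_splice_variants(r4)$uorf_id, c("a", "b"))
})
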