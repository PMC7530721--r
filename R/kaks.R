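# ---- NG86 lookup tables -----------------------------------------------------
#
# Nei-Gojobori (1986) pathway counting. Built once per session:
#   * per-codon synonymous site counts (changes to stop codons count as
#     nonsynonymous; stop codons themselves carry NA)
#   * per-codon-pair synonymous/nonsynonymous difference counts averaged over
#     all minimal mutational pathways, excluding pathways that pass through a
#     stop codon (all pathways are used as a fallback when every one is
#     blocked)

ng86_tables <- function() {
  if (!is.null(.cpuorf_cache$ng86)) return(.cpuorf_cache$ng86)
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  tab <- codon_table()[cods]
  is_stop <- tab == "*"

  syn_sites <- rep(NA_real_, 64)
  for (i in seq_along(cods)) {
    if (is_stop[i]) next
    s <- 0
    parts <- strsplit(cods[i], "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, parts[pos])) {
        alt <- parts; alt[pos] <- b
        alt_cod <- paste(alt, collapse = "")
        if (!is_stop[match(alt_cod, cods)] &&
            tab[alt_cod] == tab[cods[i]]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  sd <- matrix(0, 64, 64); nd <- matrix(0, 64, 64)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  split_c <- strsplit(cods, "")
  for (i in seq_along(cods)) {
    if (is_stop[i]) next
    for (j in seq_along(cods)) {
      if (is_stop[j] || i == j) next
      diff_pos <- which(split_c[[i]] != split_c[[j]])
      k <- length(diff_pos)
      if (k == 0L) next
      path_counts <- list()
      for (ord in perms[[as.character(k)]]) {
        cur <- split_c[[i]]
        s_cnt <- 0; n_cnt <- 0; blocked <- FALSE
        for (step in ord) {
          pos <- diff_pos[step]
          prev_cod <- paste(cur, collapse = "")
          cur[pos] <- split_c[[j]][pos]
          new_cod <- paste(cur, collapse = "")
          if (tab[new_cod] == "*") blocked <- TRUE
          if (tab[new_cod] == tab[prev_cod]) s_cnt <- s_cnt + 1
          else n_cnt <- n_cnt + 1
        }
        path_counts[[length(path_counts) + 1L]] <-
          c(s = s_cnt, n = n_cnt, blocked = blocked)
      }
      pc <- do.call(rbind, path_counts)
      ok <- pc[, "blocked"] == 0
      use <- if (any(ok)) pc[ok, , drop = FALSE] else pc
      sd[i, j] <- mean(use[, "s"])
      nd[i, j] <- mean(use[, "n"])
    }
  }
  dimnames(sd) <- dimnames(nd) <- list(cods, cods)
  res <- list(codons = cods, aa = tab, is_stop = is_stop,
              syn_sites = syn_sites, sd = sd, nd = nd)
  .cpuorf_cache$ng86 <- res
  res
}

# ---- operations -------------------------------------------------------------

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Globally aligns the two encoded peptides (Needleman-Wunsch, BLOSUM62,
#' affine gaps) and back-translates the alignment to codons. Terminal stop
#' codons are stripped before alignment. Gap columns are kept as `NA` codon
#' entries and are dropped by [compute_kaks()].
#'
#' @param nt1,nt2 nucleotide strings starting at a codon boundary, length a
#'   multiple of three
#' @param gap_open,gap_ext affine gap penalties for the peptide alignment
#' @return tibble with columns `codon1`, `codon2` (NA at gaps), one row per
#'   alignment column; the peptide alignment score is in `attr(,"score")`
#' @export
codon_align <- function(nt1, nt2, gap_open = 11, gap_ext = 1) {
  strip_stop <- function(x) {
    x <- toupper(x)
    if (nchar(x) %% 3L != 0L) {
      stop("coding sequence length is not a multiple of 3")
    }
    cods <- codon_split(x)
    if (length(cods) && cods[length(cods)] %in% STOP_CODONS) {
      cods <- cods[-length(cods)]
    }
    cods
  }
  c1 <- strip_stop(nt1); c2 <- strip_stop(nt2)
  aa1 <- paste(codon_table()[c1], collapse = "")
  aa2 <- paste(codon_table()[c2], collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(aa1), subject = Biostrings::AAString(aa2),
    type = "global", substitutionMatrix = aa_score_matrix(),
    gapOpening = gap_open, gapExtension = gap_ext)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i1 <- cumsum(ap != "-"); i2 <- cumsum(as_ != "-")
  tib <- tibble::tibble(
    codon1 = ifelse(ap == "-", NA_character_, c1[i1]),
    codon2 = ifelse(as_ == "-", NA_character_, c2[i2])
  )
  attr(tib, "score") <- Biostrings::score(pa)
  tib
}

# usable codon columns: both codons present, unambiguous, non-stop
kaks_indices <- function(aln) {
  tabs <- ng86_tables()
  i1 <- match(aln$codon1, tabs$codons)
  i2 <- match(aln$codon2, tabs$codons)
  ok <- !is.na(i1) & !is.na(i2) & !tabs$is_stop[i1] & !tabs$is_stop[i2]
  list(i1 = i1[ok], i2 = i2[ok], n_dropped = sum(!ok))
}

kaks_from_indices <- function(i1, i2, tabs = ng86_tables()) {
  n_cod <- length(i1)
  if (n_cod == 0L) {
    return(list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                flag = "empty", n_codons = 0L, pn = NA_real_, ps = NA_real_))
  }
  S <- (sum(tabs$syn_sites[i1]) + sum(tabs$syn_sites[i2])) / 2
  N <- 3 * n_cod - S
  Sd <- sum(tabs$sd[cbind(i1, i2)])
  Nd <- sum(tabs$nd[cbind(i1, i2)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps)
  Ka <- jc(pn)
  res <- if (is.infinite(Ka)) {
    list(Ka = Ka, Ks = Ks, ratio = NA_real_, flag = "ka_saturated")
  } else if (is.infinite(Ks)) {
    list(Ka = Ka, Ks = Ks, ratio = 0, flag = "ks_saturated")
  } else if (Ks == 0 && Ka == 0) {
    list(Ka = 0, Ks = 0, ratio = 0, flag = "degenerate")
  } else if (Ks == 0) {
    list(Ka = Ka, Ks = 0, ratio = NA_real_, flag = "ks_zero")
  } else {
    list(Ka = Ka, Ks = Ks, ratio = Ka / Ks, flag = "ok")
  }
  c(res, list(n_codons = n_cod, pn = pn, ps = ps))
}

# total-ordered comparison key for the permutation test: the uncorrected
# proportion ratio pN/pS, defined for every codon pairing (0 when both are 0,
# +Inf when only pS is 0), concordant with Ka/Ks where the JC correction
# exists. Shuffled pairings routinely saturate the JC correction, so the
# corrected ratio cannot order them.
perm_key <- function(pn, ps) {
  if (ps > 0) pn / ps else if (pn == 0) 0 else Inf
}

# fast null-key computation: only Sd/Nd change under codon shuffling
perm_key_indices <- function(i1, i2, S, N, tabs) {
  Sd <- sum(tabs$sd[cbind(i1, i2)])
  Nd <- sum(tabs$nd[cbind(i1, i2)])
  perm_key(if (N > 0) Nd / N else 0, if (S > 0) Sd / S else 0)
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting with Jukes-Cantor correction
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the two
#' sequences; substitution counts are averaged over all minimal mutational
#' pathways between each codon pair, excluding pathways through stop codons.
#' Raw proportions are Jukes-Cantor corrected. Alignment columns with a gap,
#' an ambiguous codon or a stop codon are dropped.
#'
#' Degenerate outcomes: a fully identical pair has Ka = Ks = 0 and the ratio
#' is defined as 0 (flag `degenerate`; perfect conservation is the strongest
#' purifying signal). Ks = 0 with Ka > 0 leaves the ratio undefined (`NA`,
#' flag `ks_zero`). A saturated Jukes-Cantor argument (raw proportion >= 3/4)
#' yields an infinite Ks (ratio 0, flag `ks_saturated`) or infinite Ka (ratio
#' `NA`, flag `ka_saturated`).
#'
#' @param aln codon alignment tibble from [codon_align()]
#' @return one-row tibble: `Ka`, `Ks`, `ratio`, `flag`, `n_codons`
#' @export
compute_kaks <- function(aln) {
  idx <- kaks_indices(aln)
  res <- kaks_from_indices(idx$i1, idx$i2)
  tibble::as_tibble(res[c("Ka", "Ks", "ratio", "flag", "n_codons")])
}

#' Empirical permutation null for a Ka/Ks ratio
#'
#' For each permutation the codon order of each sequence is shuffled
#' independently (preserving codon composition) and columns are re-paired by
#' index; the permuted pairing's Ka/Ks forms the null. The one-sided p-value
#' is `(1 + #\{null <= observed\}) / (n_perm + 1)`. Because shuffled pairings
#' routinely saturate the Jukes-Cantor correction, null and observed values
#' are ordered on the uncorrected proportion ratio pN/pS (a total order
#' concordant with Ka/Ks wherever the correction exists; 0 when both
#' proportions are 0, +Inf when only pS is 0). Deterministic under a fixed
#' seed. Alignments with two or fewer usable columns return p = 1 (flagged).
#'
#' @param aln codon alignment tibble from [codon_align()]
#' @param n_perm number of permutations
#' @param seed optional integer seed (local to this call)
#' @return one-row tibble: `p_perm`, `observed_ratio` (NG86/JC ratio, possibly
#'   NA), `flag`
#' @export
permutation_null <- function(aln, n_perm = 1000L, seed = NULL) {
  idx <- kaks_indices(aln)
  tabs <- ng86_tables()
  obs <- kaks_from_indices(idx$i1, idx$i2, tabs)
  n <- length(idx$i1)
  if (n <= 2L) {
    return(tibble::tibble(p_perm = 1, observed_ratio = obs$ratio,
                          flag = "degenerate_alignment"))
  }
  S <- (sum(tabs$syn_sites[idx$i1]) + sum(tabs$syn_sites[idx$i2])) / 2
  N <- 3 * n - S
  obs_key <- perm_key(obs$pn, obs$ps)
  run <- function() {
    null_le <- vapply(seq_len(n_perm), function(b) {
      perm_key_indices(idx$i1[sample.int(n)], idx$i2[sample.int(n)],
                       S, N, tabs) <= obs_key
    }, logical(1))
    (1 + sum(null_le)) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(p_perm = p, observed_ratio = obs$ratio, flag = obs$flag)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up BH with monotonicity enforcement:
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1]
#' @return numeric vector of q-values, same order as input
#' @export
bh_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * pvals[o]))[ro]
}
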