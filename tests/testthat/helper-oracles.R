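# Independent oracles used across the suite. These deliberately share no code
# with the package internals: the genetic code comes from
# Biostrings::GENETIC_CODE, alignments from a hand-rolled Gotoh DP, graph
# components from a naive transitive closure.

BASES <- c("A", "C", "G", "T")
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

random_utr <- function(len) {
  paste(sample(c(BASES, "N"), len, replace = TRUE,
               prob = c(rep(0.2475, 4), 0.01)), collapse = "")
}

# brute force: every (i, j) with j - i a positive multiple of 3, substring
# starting ATG, ending at a stop, with no internal in-frame stop
oracle_scan_uorfs <- function(utr, min_codons = 2L) {
  L <- nchar(utr)
  out <- list()
  for (i in seq_len(max(0L, L - 5L))) {
    if (substr(utr, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= L) {
      cod <- substr(utr, j, j + 2L)
      if (cod %in% ORACLE_STOPS) {
        if ((j + 3L - i) / 3L >= min_codons) {
          out[[length(out) + 1L]] <- c(i - 1L, j + 2L)  # 0-based half-open
        }
        break
      }
      j <- j + 3L
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, out)
}

# transitive closure over "shares start or stop key"
oracle_share_components <- function(start_key, stop_key) {
  n <- length(start_key)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          (start_key[i] == start_key[j] || stop_key[i] == stop_key[j])) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# ---- independent NG86 implementation ---------------------------------------

oracle_codon_aa <- function(cod) unname(Biostrings::GENETIC_CODE[cod])

oracle_syn_sites <- function(cod) {
  s <- 0
  parts <- strsplit(cod, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(BASES, parts[pos])) {
      alt <- parts; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (!alt %in% ORACLE_STOPS &&
          oracle_codon_aa(alt) == oracle_codon_aa(cod)) s <- s + 1 / 3
    }
  }
  s
}

oracle_path_counts <- function(c1, c2) {
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  diff <- which(p1 != p2)
  if (length(diff) == 0L) return(c(s = 0, n = 0))
  orders <- if (length(diff) == 1L) list(diff) else {
    perms <- combinat_permutations(diff)
    perms
  }
  counts <- list()
  for (ord in orders) {
    cur <- p1; s <- 0; n <- 0; blocked <- FALSE
    for (pos in ord) {
      old <- paste(cur, collapse = "")
      cur[pos] <- p2[pos]
      new <- paste(cur, collapse = "")
      if (new %in% ORACLE_STOPS) blocked <- TRUE
      if (oracle_codon_aa(new) == oracle_codon_aa(old)) s <- s + 1 else n <- n + 1
    }
    counts[[length(counts) + 1L]] <- c(s = s, n = n, blocked = blocked)
  }
  m <- do.call(rbind, counts)
  ok <- m[, "blocked"] == 0
  use <- if (any(ok)) m[ok, , drop = FALSE] else m
  c(s = mean(use[, "s"]), n = mean(use[, "n"]))
}

combinat_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# full NG86 with Jukes-Cantor on two equal-length gap-free coding sequences
oracle_ng86 <- function(nt1, nt2) {
  c1 <- substring(nt1, seq(1, nchar(nt1) - 2, 3), seq(3, nchar(nt1), 3))
  c2 <- substring(nt2, seq(1, nchar(nt2) - 2, 3), seq(3, nchar(nt2), 3))
  keep <- !(c1 %in% ORACLE_STOPS) & !(c2 %in% ORACLE_STOPS) &
    !grepl("N", c1) & !grepl("N", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- (sum(vapply(c1, oracle_syn_sites, numeric(1))) +
          sum(vapply(c2, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (k in seq_along(c1)) {
    pc <- oracle_path_counts(c1[k], c2[k])
    sd <- sd + pc["s"]; nd <- nd + pc["n"]
  }
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  sd <- unname(sd); nd <- unname(nd)
  list(Ka = jc(nd / N), Ks = jc(sd / S), S = S, N = N, Sd = sd, Nd = nd)
}

# ---- Gotoh global alignment score (affine gaps) -----------------------------

oracle_nw_score <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  # Biostrings convention: cost of a gap of length k = gap_open + k * gap_ext
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# single-linkage oracle: connected components of the d == 0 graph
oracle_zero_components <- function(mat) {
  n <- nrow(mat)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (mat[i, j] == 0 && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
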