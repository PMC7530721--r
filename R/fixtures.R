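# ---- built-in taxa for fixtures --------------------------------------------

#' Taxa available to the fixture generator
#'
#' A small panel of orders spanning the metazoan category ladder (plus one
#' non-metazoan contaminant order), each with a species and an NCBI-style
#' lineage string.
#'
#' @return tibble: `order`, `species`, `lineage`, `category` (NA for the
#'   contaminant order)
#' @export
fixture_taxa <- function() {
  vert <- "Metazoa;Eumetazoa;Bilateria;Deuterostomia;Chordata;Vertebrata;Euteleostomi"
  tetra <- paste0(vert, ";Sarcopterygii;Tetrapoda")
  euth <- paste0(tetra, ";Mammalia;Eutheria")
  tab <- tibble::tribble(
    ~order, ~species, ~lineage,
    "Primates", "Homo sapiens", paste0(euth, ";Euarchontoglires;Primates"),
    "Rodentia", "Mus musculus", paste0(euth, ";Euarchontoglires;Rodentia"),
    "Carnivora", "Canis lupus", paste0(euth, ";Laurasiatheria;Carnivora"),
    "Artiodactyla", "Bos taurus", paste0(euth, ";Laurasiatheria;Artiodactyla"),
    "Didelphimorphia", "Monodelphis domestica",
    paste0(tetra, ";Mammalia;Metatheria;Didelphimorphia"),
    "Galliformes", "Gallus gallus",
    paste0(tetra, ";Sauropsida;Aves;Galliformes"),
    "Squamata", "Anolis carolinensis",
    paste0(tetra, ";Sauropsida;Lepidosauria;Squamata"),
    "Anura", "Xenopus tropicalis", paste0(tetra, ";Amphibia;Anura"),
    "Cypriniformes", "Danio rerio",
    paste0(vert, ";Actinopterygii;Ostarioclupeomorpha;Cypriniformes"),
    "Tetraodontiformes", "Takifugu rubripes",
    paste0(vert, ";Actinopterygii;Neoteleostei;Tetraodontiformes"),
    "Diptera", "Drosophila melanogaster",
    "Metazoa;Eumetazoa;Bilateria;Protostomia;Ecdysozoa;Arthropoda;Insecta;Diptera",
    "Actiniaria", "Nematostella vectensis",
    "Metazoa;Eumetazoa;Cnidaria;Anthozoa;Actiniaria",
    "Eucoccidiorida", "Toxoplasma gondii",
    "Eukaryota;Alveolata;Apicomplexa;Conoidasida;Eucoccidiorida"
  )
  tab$category <- vapply(tab$lineage, function(l) {
    if (!grepl("Metazoa", l)) return(NA_character_)
    assign_category(l)
  }, character(1), USE.NAMES = FALSE)
  tab
}

# ---- sequence simulation ----------------------------------------------------

NONSTOP_CODONS <- function() {
  tabs <- ng86_tables()
  tabs$codons[!tabs$is_stop]
}

random_codons <- function(n) {
  paste(sample(NONSTOP_CODONS(), n, replace = TRUE), collapse = "")
}

# random UTR-like sequence guaranteed to contain no ATG
random_noatg <- function(len) {
  if (len == 0L) return("")
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

#' Mutate a coding sequence under a simple omega-controlled process
#'
#' Every nucleotide position receives a substitution proposal with probability
#' `rate` (uniform over the three alternative bases, applied left to right).
#' Proposals creating a stop codon are rejected; synonymous proposals are
#' always accepted; nonsynonymous proposals are accepted with probability
#' `omega`. The realized Ka/Ks of a (sequence, mutated copy) pair therefore
#' estimates `omega`.
#'
#' @param nt coding nucleotide string, length a multiple of 3, no internal
#'   stop codons
#' @param omega nonsynonymous acceptance probability (true dN/dS)
#' @param rate per-site proposal probability
#' @return mutated nucleotide string
#' @export
mutate_coding <- function(nt, omega, rate) {
  tab <- codon_table()
  bases <- c("A", "C", "G", "T")
  cur <- strsplit(toupper(nt), "")[[1]]
  n <- length(cur)
  stopifnot(n %% 3L == 0L)
  hit <- which(runif(n) < rate)
  for (p in hit) {
    cod_i <- (p - 1L) %/% 3L
    old_cod <- paste(cur[cod_i * 3L + 1:3], collapse = "")
    new_base <- sample(setdiff(bases, cur[p]), 1L)
    new <- cur; new[p] <- new_base
    new_cod <- paste(new[cod_i * 3L + 1:3], collapse = "")
    if (tab[new_cod] == "*") next
    if (tab[new_cod] == tab[old_cod] || runif(1) < omega) cur <- new
  }
  paste(cur, collapse = "")
}

#' Simulate a codon-aligned sequence pair with known true omega
#'
#' Draws a random stop-free coding sequence and a mutated copy (see
#' [mutate_coding()]); the pair is aligned by construction (no indels).
#'
#' @param n_codons number of codons
#' @param omega true dN/dS of the divergence process
#' @param rate per-site proposal probability
#' @param seed optional integer seed (local to this call)
#' @return list with `nt1`, `nt2`
#' @export
simulate_codon_pair <- function(n_codons, omega, rate, seed = NULL) {
  run <- function() {
    nt1 <- random_codons(n_codons)
    list(nt1 = nt1, nt2 = mutate_coding(nt1, omega, rate))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# remove every ATG from `seq` except the one starting at `keep_start`
# (0-based); positions inside [keep_start, keep_start+keep_len) other than the
# start itself are re-randomized codon-wise via `recode`, others are point-
# edited. Used to keep fixture 5'-UTRs free of unplanned uORFs.
scrub_atg <- function(s, keep_start = -1L) {
  for (iter in 1:200) {
    m <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    m <- m[m > 0L]
    m <- m[m - 1L != keep_start]
    if (length(m) == 0L) return(s)
    p <- m[1] + 2L  # the G
    substr(s, p, p) <- sample(c("C", "A"), 1L)
  }
  stop("could not scrub unplanned ATGs from fixture sequence")
}

# ---- fixture specification --------------------------------------------------

#' Default per-gene plans for the 20-gene fixture
#'
#' Six conserved plants (with one split-start-codon gene, one minus-strand
#' gene and two paralog pairs), four neutral plants, three fusion plants,
#' three contaminant plants and four uORF-less genes, for a human-like query.
#'
#' @return tibble with columns `gene_id`, `plan`, `orders` (list-column)
#' @export
default_fixture_plans <- function() {
  tibble::tribble(
    ~gene_id, ~plan, ~orders,
    "g01", "conserved_uorf", c("Rodentia", "Rodentia", "Carnivora", "Galliformes"),
    "g02", "conserved_uorf", c("Rodentia", "Artiodactyla"),
    "g03", "conserved_uorf", c("Rodentia", "Carnivora", "Anura", "Cypriniformes"),
    "g04", "conserved_uorf", c("Rodentia", "Carnivora", "Diptera"),
    "g05", "conserved_uorf", c("Rodentia", "Carnivora"),
    "g06", "conserved_uorf", c("Rodentia", "Didelphimorphia", "Actiniaria"),
    "g07", "nonconserved_uorf", c("Rodentia", "Carnivora", "Galliformes"),
    "g08", "nonconserved_uorf", c("Rodentia", "Carnivora", "Squamata"),
    "g09", "nonconserved_uorf", c("Rodentia", "Artiodactyla", "Anura"),
    "g10", "nonconserved_uorf", c("Rodentia", "Carnivora", "Tetraodontiformes"),
    "g11", "fused_homologs", c("Rodentia", "Carnivora"),
    "g12", "fused_homologs", c("Rodentia", "Galliformes"),
    "g13", "fused_homologs", c("Rodentia", "Artiodactyla"),
    "g14", "contaminant_homolog", "Rodentia",
    "g15", "contaminant_homolog", c("Rodentia", "Carnivora"),
    "g16", "contaminant_homolog", "Rodentia",
    "g17", "no_uorf", character(0),
    "g18", "no_uorf", character(0),
    "g19", "no_uorf", character(0),
    "g20", "no_uorf", character(0)
  )
}

#' Specify a synthetic fixture
#'
#' The defaults state the fixture's world: 20 genes of a human-like query
#' (order Primates, category Euarchontoglires), uORFs of 24 residues, mORFs
#' of 60 codons, conserved homologs diverged under strong purifying selection
#' (omega 0.05), non-conserved homologs under neutrality (omega 1), per-site
#' proposal rate 0.4 for uORFs and 0.15 (omega 0.2) for mORFs, and half of a
#' fusion plant's RefSeq-class records fused.
#'
#' @param plans tibble (`gene_id`, `plan`, `orders`) as in
#'   [default_fixture_plans()]; plans are `conserved_uorf`,
#'   `nonconserved_uorf`, `fused_homologs`, `contaminant_homolog`, `no_uorf`
#' @param seed integer seed; the fixture is a pure function of the spec
#' @param query_species,query_order identity of the query genome
#' @param uorf_aa_len uORF peptide length (residues incl. the initiator Met)
#' @param morf_codons mORF length in codons (excl. stop)
#' @param omega_conserved,omega_neutral true dN/dS for conserved /
#'   non-conserved uORF homologs
#' @param rate_uorf,rate_morf per-site proposal probabilities
#' @param omega_morf dN/dS for mORF homologs (always conserved)
#' @param fused_fraction fraction of a fusion plant's RefSeq records that are
#'   fused (>= 0.3 so the plant is discarded)
#' @return object of class `cpuorf_fixture_spec`
#' @export
fixture_spec <- function(plans = default_fixture_plans(), seed = 1L,
                         query_species = "Homo sapiens",
                         query_order = "Primates",
                         uorf_aa_len = 24L, morf_codons = 60L,
                         omega_conserved = 0.05, omega_neutral = 1,
                         rate_uorf = 0.4, rate_morf = 0.15, omega_morf = 0.2,
                         fused_fraction = 0.5) {
  taxa <- fixture_taxa()
  bad_plan <- setdiff(unique(plans$plan),
                      c("conserved_uorf", "nonconserved_uorf",
                        "fused_homologs", "contaminant_homolog", "no_uorf"))
  if (length(bad_plan)) stop("unknown plan(s): ", paste(bad_plan, collapse = ", "))
  bad_ord <- setdiff(unlist(plans$orders), taxa$order)
  if (length(bad_ord)) stop("unknown order(s): ", paste(bad_ord, collapse = ", "))
  for (i in seq_len(nrow(plans))) {
    p <- plans$plan[i]
    other <- setdiff(unique(plans$orders[[i]]), query_order)
    if (p == "conserved_uorf" && length(other) < 2L) {
      stop("conserved plant '", plans$gene_id[i],
           "' needs homologs in at least 2 non-query orders")
    }
    if (p != "no_uorf" && length(plans$orders[[i]]) == 0L) {
      stop("plant '", plans$gene_id[i], "' needs at least one order")
    }
  }
  structure(list(plans = plans, seed = as.integer(seed),
                 query_species = query_species, query_order = query_order,
                 uorf_aa_len = as.integer(uorf_aa_len),
                 morf_codons = as.integer(morf_codons),
                 omega_conserved = omega_conserved,
                 omega_neutral = omega_neutral,
                 rate_uorf = rate_uorf, rate_morf = rate_morf,
                 omega_morf = omega_morf, fused_fraction = fused_fraction),
            class = "cpuorf_fixture_spec")
}

# ---- generation -------------------------------------------------------------

#' Generate a self-contained synthetic fixture
#'
#' Writes a toy genome FASTA, an Ensembl-dialect GFF3, a homolog transcript
#' collection FASTA, its taxonomy sidecar TSV and a truth table TSV into
#' `dir`. Every planted conserved uORF is recoverable end-to-end; fusion
#' plants are discarded at the fusion-ratio step, contaminant plants at the
#' contaminant/order steps and neutral plants at the Ka/Ks step. Output is
#' byte-identical under a fixed spec (including the seed).
#'
#' Structural features exercised on top of the plans: gene `g01` (or the
#' first gene) has two splice variants sharing the identical uORF, the second
#' gene's uORF start codon is split by an intron, and the third gene sits on
#' the minus strand.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory (created)
#' @return list with paths (`genome`, `gff3`, `collection`, `taxonomy`,
#'   `truth`) and the truth tibble (`truth_tbl`)
#' @export
make_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "cpuorf_fixture_spec"))
  withr::with_seed(spec$seed, make_fixture_impl(spec, dir))
}

make_fixture_impl <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taxa <- fixture_taxa()
  taxa_by_order <- split(taxa, taxa$order)
  plans <- spec$plans
  n_genes <- nrow(plans)

  # --- design per-gene sequences
  # a planted uORF has intact ATG/TGA bookends, no internal in-frame stop and
  # no ATG anywhere but position 0 (so the fixture plants no unplanned uORFs)
  gen_uorf <- function() {
    repeat {
      u <- scrub_atg(paste0("ATG", random_codons(spec$uorf_aa_len - 1L),
                            "TGA"), keep_start = 0L)
      cods <- codon_split(u)
      if (cods[1] == "ATG" && cods[length(cods)] == "TGA" &&
          !any(cods[-length(cods)] %in% STOP_CODONS)) return(u)
    }
  }
  genes <- vector("list", n_genes)
  uorf_nt_len <- 3L * (spec$uorf_aa_len + 1L)
  for (i in seq_len(n_genes)) {
    plan <- plans$plan[i]
    has_uorf <- plan != "no_uorf"
    morf <- paste0("ATG", random_codons(spec$morf_codons - 1L), "TAA")
    uorf <- if (has_uorf) gen_uorf() else NULL
    # paralog pairing: an even-positioned conserved gene immediately after
    # another conserved gene shares its mORF family but not its uORF family
    if (plan == "conserved_uorf" && i > 1L &&
        plans$plan[i - 1L] == "conserved_uorf" && i %% 2L == 1L) {
      prev_morf <- genes[[i - 1L]]$morf
      morf <- paste0("ATG",
                     mutate_coding(substr(prev_morf, 4L, nchar(prev_morf) - 3L),
                                   omega = 0.3, rate = 0.15), "TAA")
      prev_aa <- sub("\\*$", "", translate_nt(genes[[i - 1L]]$uorf))
      for (try in 1:100) {
        this_aa <- sub("\\*$", "", translate_nt(uorf))
        if (!has_seed(prev_aa, this_aa, 3L)) break
        uorf <- gen_uorf()
      }
      genes[[i - 1L]]$paralog <- plans$gene_id[i]
    }
    pre <- random_noatg(30L)
    post <- if (has_uorf) random_noatg(21L) else ""
    utr <- if (has_uorf) paste0(pre, uorf, post) else random_noatg(90L)
    utr <- scrub_atg(utr, keep_start = if (has_uorf) nchar(pre) else -1L)
    genes[[i]] <- list(gene_id = plans$gene_id[i], plan = plan,
                       orders = plans$orders[[i]],
                       uorf = if (has_uorf)
                         substr(utr, nchar(pre) + 1L,
                                nchar(pre) + uorf_nt_len) else NULL,
                       uorf_utr_start = if (has_uorf) nchar(pre) else NA_integer_,
                       utr = utr, morf = morf, paralog = NA_character_)
  }

  # --- genome + GFF3
  gff <- c("##gff-version 3")
  chrom_seqs <- list(chr1 = "", chr2 = "")
  for (i in seq_len(n_genes)) {
    g <- genes[[i]]
    tx_seq <- paste0(g$utr, g$morf, random_noatg(24L))
    strand <- if (i == 3L) "-" else "+"
    chrom <- if (i == 3L) "chr2" else "chr1"
    two_variants <- (i == 1L && g$plan != "no_uorf")
    split_start <- (i == 2L && g$plan != "no_uorf")

    cur <- chrom_seqs[[chrom]]
    offset <- nchar(cur) + 60L           # intergenic spacer
    spacer <- random_noatg(60L)

    cds_t0 <- nchar(g$utr)               # transcript coords, 0-based
    cds_t1 <- cds_t0 + nchar(g$morf)

    if (split_start) {
      # intron after the A of the uORF ATG
      cut <- g$uorf_utr_start + 1L
      intron <- paste0("GT", random_noatg(36L), "AG")
      genomic <- paste0(substr(tx_seq, 1L, cut), intron,
                        substr(tx_seq, cut + 1L, nchar(tx_seq)))
      ex1 <- c(offset, offset + cut)     # 0-based half-open genomic
      ex2 <- c(offset + cut + nchar(intron), offset + nchar(tx_seq) + nchar(intron))
      exons <- rbind(ex1, ex2)
      cds_g <- c(ex2[1] + (cds_t0 - cut), ex2[1] + (cds_t1 - cut))
      cds_rows <- rbind(cds_g)
    } else {
      genomic <- tx_seq
      exons <- rbind(c(offset, offset + nchar(tx_seq)))
      cds_rows <- rbind(c(offset + cds_t0, offset + cds_t1))
    }
    if (strand == "-") genomic <- revcomp(genomic)
    chrom_seqs[[chrom]] <- paste0(cur, spacer, genomic)
    if (strand == "-") {
      # the segment was laid out forward then reverse-complemented in place:
      # mirror each block within the segment [offset, seg_end)
      seg_end <- offset + nchar(genomic)
      flip <- function(b) cbind(offset + seg_end - b[, 2],
                                offset + seg_end - b[, 1])
      exons <- flip(exons)[rev(seq_len(nrow(exons))), , drop = FALSE]
      cds_rows <- flip(rbind(cds_rows))[rev(seq_len(nrow(rbind(cds_rows)))), , drop = FALSE]
    }

    gid <- g$gene_id
    g_lo <- min(exons[, 1]) + 1L; g_hi <- max(exons[, 2])
    gff <- c(gff, paste(chrom, "fixture", "gene", g_lo, g_hi, ".", strand, ".",
                        paste0("ID=gene:", gid), sep = "\t"))
    tx_ids <- paste0(gid, ".t1")
    if (two_variants) tx_ids <- c(tx_ids, paste0(gid, ".t2"))
    for (tid in tx_ids) {
      # variant 2: identical structure but UTR shortened by trimming the
      # first exon's 5' end (same uORF genomic codons)
      ex <- exons
      trim <- if (endsWith(tid, ".t2")) 9L else 0L
      if (trim > 0L) {
        if (strand == "+") ex[1, 1] <- ex[1, 1] + trim
        else ex[1, 2] <- ex[1, 2] - trim
      }
      gff <- c(gff, paste(chrom, "fixture", "mRNA", min(ex[, 1]) + 1L,
                          max(ex[, 2]), ".", strand, ".",
                          paste0("ID=transcript:", tid, ";Parent=gene:", gid),
                          sep = "\t"))
      for (r in seq_len(nrow(ex))) {
        gff <- c(gff, paste(chrom, "fixture", "exon", ex[r, 1] + 1L, ex[r, 2],
                            ".", strand, ".", paste0("Parent=transcript:", tid),
                            sep = "\t"))
      }
      for (r in seq_len(nrow(cds_rows))) {
        gff <- c(gff, paste(chrom, "fixture", "CDS", cds_rows[r, 1] + 1L,
                            cds_rows[r, 2], ".", strand, "0",
                            paste0("ID=CDS:", tid, ";Parent=transcript:", tid),
                            sep = "\t"))
      }
    }
  }

  # --- homolog collection + taxonomy
  coll <- character(0)
  tax_rows <- list()
  add_record <- function(rid, seq, order, source, contaminant = FALSE) {
    coll[[rid]] <<- seq
    tx <- taxa_by_order[[order]]
    tax_rows[[length(tax_rows) + 1L]] <<- tibble::tibble(
      record_id = rid, taxid = as.character(10000L + match(order, taxa$order)),
      species = tx$species, order = tx$order, lineage = tx$lineage,
      source = source, contaminant_flag = contaminant)
  }
  homolog_uorf <- function(uorf, omega) {
    body <- substr(uorf, 4L, nchar(uorf) - 3L)
    paste0("ATG", mutate_coding(body, omega = omega, rate = spec$rate_uorf),
           "TGA")
  }
  homolog_morf <- function(morf) {
    body <- substr(morf, 4L, nchar(morf) - 3L)
    paste0("ATG", mutate_coding(body, omega = spec$omega_morf,
                                rate = spec$rate_morf), "TAA")
  }
  plain_record <- function(uorf_h, morf_h) {
    # the spacer carries a stop codon in all three frames, so a non-fused
    # record can never look fused whatever frame a chance uORF HSP lands in
    paste0(random_noatg(15L), uorf_h, "TTAATTAATTAA", morf_h,
           random_noatg(15L))
  }
  fused_record <- function(uorf_h, morf_h) {
    repeat {  # in-frame bridge: no stop codon, no ATG
      bridge <- random_codons(4L)
      if (!grepl("ATG", bridge, fixed = TRUE)) break
    }
    paste0(random_noatg(15L), substr(uorf_h, 1L, nchar(uorf_h) - 3L), bridge,
           morf_h, random_noatg(15L))
  }

  for (i in seq_len(n_genes)) {
    g <- genes[[i]]
    if (g$plan == "no_uorf") next
    ords <- g$orders
    if (g$plan == "fused_homologs") {
      n_rec <- max(4L, length(ords))
      n_fused <- ceiling(spec$fused_fraction * n_rec)
      for (k in seq_len(n_rec)) {
        ord <- ords[(k - 1L) %% length(ords) + 1L]
        uh <- homolog_uorf(g$uorf, spec$omega_conserved)
        mh <- homolog_morf(g$morf)
        seq <- if (k <= n_fused) fused_record(uh, mh) else plain_record(uh, mh)
        add_record(sprintf("R_%s_%s_%d", g$gene_id, ord, k), seq, ord, "refseq")
      }
    } else if (g$plan == "contaminant_homolog") {
      # one legitimate record per listed order (at most one metazoan order
      # survives the contaminant screen when a second one is flag-tainted)
      for (k in seq_along(ords)) {
        uh <- homolog_uorf(g$uorf, spec$omega_conserved)
        mh <- homolog_morf(g$morf)
        add_record(sprintf("R_%s_%s_%d", g$gene_id, ords[k], k),
                   plain_record(uh, mh), ords[k], "refseq",
                   contaminant = (k > 1L))
      }
      for (k in 1:3) {
        uh <- homolog_uorf(g$uorf, spec$omega_conserved)
        mh <- homolog_morf(g$morf)
        add_record(sprintf("C_%s_%d", g$gene_id, k),
                   plain_record(uh, mh), "Eucoccidiorida", "est")
      }
    } else {
      omega_u <- if (g$plan == "conserved_uorf") spec$omega_conserved else
        spec$omega_neutral
      for (k in seq_along(ords)) {
        uh <- homolog_uorf(g$uorf, omega_u)
        mh <- homolog_morf(g$morf)
        src <- if (k <= 2L) "refseq" else c("est", "tsa")[k %% 2L + 1L]
        add_record(sprintf("R_%s_%s_%d", g$gene_id, ords[k], k),
                   plain_record(uh, mh), ords[k], src)
      }
    }
  }

  # --- truth table
  status_of <- function(plan) switch(plan,
    conserved_uorf = "cpuorf",
    nonconserved_uorf = "rejected_selection",
    fused_homologs = "fusion_discarded",
    contaminant_homolog = "rejected_orders",
    no_uorf = "no_uorf")
  query_cat <- taxa$category[taxa$order == spec$query_order]
  expected_range <- function(g) {
    if (g$plan != "conserved_uorf") return(NA_character_)
    cats <- unique(vapply(g$orders, function(o)
      taxa_by_order[[o]]$category, character(1)))
    cc <- animal_categories()
    depth <- vapply(cc, chain_overlap, integer(1), cat_b = query_cat)
    cats[order(depth[cats], match(cats, cc))][1]
  }
  truth <- dplyr::bind_rows(lapply(genes, function(g) tibble::tibble(
    gene_id = g$gene_id, plan = g$plan,
    expected_final_status = status_of(g$plan),
    expected_range_label = expected_range(g),
    uorf_utr_start = g$uorf_utr_start,
    uorf_aa = if (is.null(g$uorf)) NA_character_ else
      sub("\\*$", "", translate_nt(g$uorf)),
    n_orders = length(unique(g$orders)))))

  # --- write everything
  paths <- list(genome = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "annotation.gff3"),
                collection = file.path(dir, "collection.fa"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_fasta(unlist(chrom_seqs), paths$genome)
  writeLines(gff, paths$gff3)
  write_fasta(coll, paths$collection)
  # a record-less row for the query species so its category is derivable
  qt <- taxa[taxa$order == spec$query_order, ]
  tax_tbl <- dplyr::bind_rows(
    tibble::tibble(record_id = "query_genome", taxid = "9999",
                   species = qt$species, order = qt$order,
                   lineage = qt$lineage, source = "query",
                   contaminant_flag = FALSE),
    dplyr::bind_rows(tax_rows))
  readr::write_tsv(tax_tbl, paths$taxonomy)
  readr::write_tsv(truth, paths$truth)
  c(paths, list(truth_tbl = truth, dir = dir))
}
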