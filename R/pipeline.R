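#' Configure a CPuORF pipeline run
#'
#' Thresholds default to the published search regime: fusion-ratio cutoff 0.3
#' (discard at or above), uORF translated-search cutoff E <= 2000, mORF
#' confirmation E < 0.1, conservation in >= 2 orders other than the query's,
#' Ka/Ks < 0.5 with q < 0.05, uORF-family clustering at BLASTp E < 2000 with
#' single linkage cut at h = 0.5.
#'
#' @param genome,gff3 query genome FASTA and annotation GFF3 paths
#' @param collection transcript evidence collection FASTA path
#' @param taxonomy taxonomy sidecar TSV path (see [read_taxonomy()])
#' @param query_species,query_order identity of the query genome
#' @param query_category the query's own taxonomic category; derived from the
#'   taxonomy table (first record of `query_order`) when `NULL`
#' @param outdir optional output directory for per-step tables and caches
#' @param fusion_ratio_max,uorf_evalue,morf_evalue,kaks_max,q_max,min_other_orders,cluster_h,blastp_e,ortholog_e
#'   pipeline thresholds
#' @param n_perm permutations for the Ka/Ks null
#' @param seed integer seed for all randomness in the run
#' @param engine a `cpuorf_engine` ([builtin_engine()] or [blast_engine()])
#' @param min_codons minimum uORF length in codons (incl. stop)
#' @param removal_file optional TSV (`uorf_id`, `subject_id`) of putative
#'   uORFs struck by manual alignment validation
#' @return object of class `cpuorf_config`
#' @export
pipeline_config <- function(genome, gff3, collection, taxonomy,
                            query_species, query_order,
                            query_category = NULL, outdir = NULL,
                            fusion_ratio_max = 0.3, uorf_evalue = 2000,
                            morf_evalue = 0.1, kaks_max = 0.5, q_max = 0.05,
                            min_other_orders = 2L, cluster_h = 0.5,
                            blastp_e = 2000, ortholog_e = 1e-3,
                            n_perm = 1000L, seed = 1L,
                            engine = builtin_engine(), min_codons = 2L,
                            removal_file = NULL) {
  for (p in c(genome, gff3, collection, taxonomy, removal_file)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(genome = genome, gff3 = gff3, collection = collection,
                 taxonomy = taxonomy, query_species = query_species,
                 query_order = query_order, query_category = query_category,
                 outdir = outdir, fusion_ratio_max = fusion_ratio_max,
                 uorf_evalue = uorf_evalue, morf_evalue = morf_evalue,
                 kaks_max = kaks_max, q_max = q_max,
                 min_other_orders = as.integer(min_other_orders),
                 cluster_h = cluster_h, blastp_e = blastp_e,
                 ortholog_e = ortholog_e, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), engine = engine,
                 min_codons = as.integer(min_codons),
                 removal_file = removal_file),
            class = "cpuorf_config")
}

#' Run the whole CPuORF identification pipeline
#'
#' Executes, in order: transcript-model assembly and uORF extraction (step 1),
#' the fusion-ratio filter against the RefSeq-class records (step 2), the
#' permissive uORF translated search excluding the query species (step 3.1),
#' putative-uORF extraction (step 3.2), mORF confirmation on the downstream
#' sequence (step 4.1), contaminant removal (step 4.2), the >= 2-other-orders
#' filter with splice-variant deduplication (step 4.3), per-order
#' representative selection, pairwise NG86 Ka/Ks with the permutation null and
#' BH correction, and candidate selection (step 5), taxonomic range
#' determination (step 6), optional manual-removal reprocessing and
#' splice-variant resolution (step 7 support), and homology-group
#' classification with systematic HG numbering.
#'
#' When `config$outdir` is set, per-step tables are written there and the
#' expensive search steps are cached; a re-run with the same outdir reuses
#' completed caches unless `force = TRUE`.
#'
#' @param config a [pipeline_config()]
#' @param force recompute cached steps
#' @return object of class `cpuorf_run`; see [tidy.cpuorf_run()],
#'   [glance.cpuorf_run()], [autoplot.cpuorf_run()]
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "cpuorf_config"))
  eng <- config$engine
  cache <- function(name, expr) {
    if (is.null(config$outdir)) return(expr)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(config$outdir, paste0("cache_", name, ".rds"))
    if (file.exists(f) && !force) return(readRDS(f))
    val <- expr
    saveRDS(val, f)
    val
  }

  models <- read_transcript_models(config$gff3, config$genome)
  collection <- read_collection(config$collection)
  taxonomy <- read_taxonomy(config$taxonomy)
  query_category <- config$query_category %||% {
    lin <- taxonomy$lineage[taxonomy$order == config$query_order]
    if (length(lin) > 0L) assign_category(lin[1]) else
      stop("query_category not given and query_order absent from taxonomy")
  }

  # step 1 -- uORF extraction
  uorfs <- extract_uorfs(models, min_codons = config$min_codons)

  # step 2 -- fusion ratio against RefSeq-class records
  refseq <- collection[intersect(names(collection),
                                 taxonomy$record_id[taxonomy$source == "refseq"])]
  fstats <- cache("fusion", fusion_stats(uorfs, models, refseq, eng,
                                         threshold = config$fusion_ratio_max,
                                         uorf_e = config$uorf_evalue,
                                         morf_e = config$morf_evalue))
  u_step2 <- fusion_filter(uorfs, fstats, threshold = config$fusion_ratio_max)

  # step 3.1 -- permissive uORF translated search, other species only
  hits <- cache("uorf_search",
                uorf_homology_search(u_step2, collection, taxonomy, eng,
                                     query_species = config$query_species,
                                     e_max = config$uorf_evalue))
  u_step31 <- dplyr::filter(u_step2, .data$uorf_id %in% hits$query_id)

  # step 3.2 -- putative uORF extraction from every hit
  putative <- cache("putative", {
    rows <- purrr::map(seq_len(nrow(hits)), function(k) {
      h <- hits[k, ]
      p <- extract_putative_uorf(h, collection[[h$subject_id]])
      if (is.null(p)) return(NULL)
      dplyr::bind_cols(tibble::tibble(uorf_id = h$query_id), p,
                       tibble::tibble(uorf_evalue = h$evalue,
                                      order = h$order, species = h$species))
    })
    dplyr::bind_rows(purrr::compact(rows))
  })
  u_step32 <- dplyr::filter(u_step31, .data$uorf_id %in% putative$uorf_id)

  # step 4.1 -- mORF confirmation downstream of each putative uORF
  morf_by_tx <- setNames(models$morf_aa, models$transcript_id)
  tx_by_uorf <- setNames(uorfs$transcript_id, uorfs$uorf_id)
  confirmed <- cache("confirm", {
    # E-values are scored against the pooled downstream dataset, mirroring a
    # single database-wide mORF search
    down_space <- sum(2 * pmax(0, nchar(collection[putative$subject_id]) -
                                 putative$s_end))
    rows <- purrr::map(seq_len(nrow(putative)), function(k) {
      p <- putative[k, ]
      hit <- confirm_morf(morf_by_tx[[tx_by_uorf[[p$uorf_id]]]], p,
                          collection[[p$subject_id]], eng,
                          e_max = config$morf_evalue,
                          search_space = down_space)
      if (is.null(hit)) return(NULL)
      dplyr::mutate(p, morf_evalue = hit$evalue)
    })
    dplyr::bind_rows(purrr::compact(rows))
  })
  u_step41 <- dplyr::filter(u_step32, .data$uorf_id %in% confirmed$uorf_id)

  # step 4.2 -- contaminant removal
  confirmed <- filter_contaminants(confirmed, taxonomy)
  u_step42 <- dplyr::filter(u_step41, .data$uorf_id %in% confirmed$uorf_id)

  # step 4.3 -- conservation in >= 2 other orders + splice-variant dedupe
  keep_ids <- filter_order_conservation(confirmed, config$query_order,
                                        min_other = config$min_other_orders)
  u_conf <- dplyr::filter(u_step42, .data$uorf_id %in% keep_ids)
  u_step43 <- dedupe_identical_uorfs(u_conf, hits)

  # step 5 -- representatives, Ka/Ks, permutation q, candidate selection
  reps <- select_representatives(
    dplyr::rename(dplyr::filter(confirmed,
                                .data$uorf_id %in% u_step43$uorf_id,
                                .data$order != config$query_order),
                  putative_aa = "orf_aa", putative_nt = "orf_nt"))
  pairs <- cache("kaks", kaks_pairs(u_step43, reps, n_perm = config$n_perm,
                                    seed = config$seed))
  ksum <- aggregate_kaks(pairs)
  cand_ids <- select_candidates(ksum, ratio_max = config$kaks_max,
                                q_max = config$q_max)
  u_step5 <- dplyr::filter(u_step43, .data$uorf_id %in% cand_ids)

  # step 6 -- taxonomic range of conservation
  tax_lin <- dplyr::select(taxonomy, subject_id = "record_id", "lineage")
  reps_cand <- dplyr::left_join(
    dplyr::filter(reps, .data$uorf_id %in% cand_ids), tax_lin,
    by = "subject_id")
  profile <- conservation_profile(reps_cand)
  ranges <- taxonomic_range(profile, query_category)

  # step 7 support -- manual removals, then splice-variant resolution
  if (!is.null(config$removal_file)) {
    removed <- readr::read_tsv(config$removal_file,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
    upd <- recompute_after_removal(reps_cand, removed)
    reps_cand <- upd$representatives
    profile <- upd$profile
    ranges <- taxonomic_range(profile, query_category)
    still <- filter_order_conservation(reps_cand, config$query_order,
                                       min_other = config$min_other_orders)
    u_step5 <- dplyr::filter(u_step5, .data$uorf_id %in% still)
  }
  final <- resolve_step7(u_step5, reps_cand, ksum)
  u_final <- dplyr::filter(u_step5, .data$uorf_id %in% final)
  ranges <- dplyr::filter(ranges, .data$uorf_id %in% final)

  # homology groups
  hg <- classify_families(u_final, models, ranges, eng, query_category,
                          blastp_e = config$blastp_e,
                          ortholog_e = config$ortholog_e,
                          h = config$cluster_h)

  count_row <- function(step, u, extra_records = NA_integer_) {
    cc <- count_distinct_uorfs(u)
    tibble::tibble(step = step, n_uorfs = cc$n_uorfs, n_genes = cc$n_genes,
                   n_records = extra_records)
  }
  report <- dplyr::bind_rows(
    tibble::tibble(step = "Before selection", n_uorfs = NA_integer_,
                   n_genes = count_coding_genes(models),
                   n_records = NA_integer_),
    count_row("Step 1", uorfs),
    count_row("Step 2", u_step2),
    count_row("Step 3.1", u_step31, dplyr::n_distinct(hits$subject_id)),
    count_row("Step 3.2", u_step32, dplyr::n_distinct(putative$subject_id)),
    count_row("Step 4.1", u_step41, dplyr::n_distinct(confirmed$subject_id)),
    count_row("Step 4.2", u_step42, dplyr::n_distinct(confirmed$subject_id)),
    count_row("Step 4.3", u_step43),
    count_row("Step 5", u_step5, dplyr::n_distinct(reps_cand$subject_id)),
    count_row("Step 7-support", u_final)
  )

  res <- structure(list(
    config = config, query_category = query_category,
    models = models, uorfs = uorfs, fusion = fstats, hits = hits,
    putative = putative, confirmed = confirmed, representatives = reps_cand,
    kaks = pairs, kaks_summary = ksum, candidates = cand_ids,
    profile = profile, ranges = ranges, hg = hg, report = report,
    cpuorfs = build_final_table(u_final, ksum, ranges, hg)
  ), class = "cpuorf_run")
  if (!is.null(config$outdir)) write_run_outputs(res)
  res
}

# step-7 splice-variant resolution on candidate records
resolve_step7 <- function(u_cand, reps_cand, ksum) {
  if (nrow(u_cand) == 0L) return(character(0))
  aas <- split(reps_cand$putative_aa, reps_cand$uorf_id)
  recs <- dplyr::mutate(
    u_cand,
    span_start = purrr::map2_dbl(.data$start_blocks, .data$stop_blocks,
                                 ~min(.x[, 1], .y[, 1])),
    span_end = purrr::map2_dbl(.data$start_blocks, .data$stop_blocks,
                               ~max(.x[, 2], .y[, 2])),
    frame_phase = paste0(.data$strand,
                         purrr::map_dbl(.data$start_blocks, ~.x[1, 1]) %% 3),
    conserved_len = purrr::map2_int(
      .data$aa_seq, .data$uorf_id,
      ~conserved_region_length(.x, aas[[.y]] %||% character(0))))
  recs <- dplyr::left_join(recs,
                           dplyr::select(ksum, "uorf_id", "median_ratio"),
                           by = "uorf_id")
  resolve_splice_variants(recs)$uorf_id
}

# ortholog grouping + uORF clustering + HG numbering of the final CPuORFs
classify_families <- function(u_final, models, ranges, engine, query_category,
                              blastp_e = 2000, ortholog_e = 1e-3, h = 0.5) {
  if (nrow(u_final) == 0L) {
    return(tibble::tibble(uorf_id = character(0), gene_id = character(0),
                          morf_cluster = integer(0), uorf_cluster = integer(0),
                          range_label = character(0),
                          n_orders_total = integer(0), hg_number = integer(0),
                          hg_subnumber = integer(0), label = character(0)))
  }
  gene_pep <- dplyr::slice_max(
    dplyr::group_by(dplyr::filter(models,
                                  .data$gene_id %in% u_final$gene_id),
                    .data$gene_id),
    nchar(.data$morf_aa), n = 1L, with_ties = FALSE)
  gene_pep <- dplyr::ungroup(gene_pep)
  morf_clusters <- cluster_orthologs(
    setNames(gene_pep$morf_aa, gene_pep$gene_id), engine, e_max = ortholog_e)
  fam <- dplyr::left_join(
    dplyr::select(u_final, "uorf_id", "gene_id", "aa_seq"),
    morf_clusters, by = "gene_id")
  fam <- dplyr::bind_rows(lapply(split(fam, fam$morf_cluster), function(mc) {
    peps <- setNames(mc$aa_seq, mc$uorf_id)
    d <- uorf_distance_matrix(peps, engine, e_max = blastp_e)
    labels <- single_linkage_cut(d, h = h)
    dplyr::mutate(mc, uorf_cluster = as.integer(labels[.data$uorf_id]))
  }))
  fam <- dplyr::left_join(dplyr::select(fam, -"aa_seq"), ranges, by = "uorf_id")
  assign_hg_numbers(fam, query_category)
}

build_final_table <- function(u_final, ksum, ranges, hg) {
  out <- dplyr::select(u_final, "uorf_id", "gene_id", "transcript_id",
                       "utr_start", "aa_seq")
  out <- dplyr::left_join(out, dplyr::select(ksum, "uorf_id", "median_ratio",
                                             "median_q"), by = "uorf_id")
  out <- dplyr::left_join(out, ranges, by = "uorf_id")
  dplyr::left_join(out, dplyr::select(hg, "uorf_id", "label"), by = "uorf_id")
}

write_run_outputs <- function(res) {
  out <- res$config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  drop_lists <- function(x) x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(res$report, file.path(out, "report.tsv"))
  readr::write_tsv(drop_lists(res$uorfs), file.path(out, "step1_uorfs.tsv"))
  readr::write_tsv(res$fusion, file.path(out, "step2_fusion.tsv"))
  readr::write_tsv(res$hits, file.path(out, "step3_hits.tsv"))
  readr::write_tsv(res$confirmed, file.path(out, "step4_confirmed.tsv"))
  readr::write_tsv(res$kaks, file.path(out, "step5_kaks.tsv"))
  readr::write_tsv(res$profile, file.path(out, "step6_profile.tsv"))
  readr::write_tsv(res$cpuorfs, file.path(out, "cpuorfs.tsv"))
  cfg <- res$config
  cfg_tbl <- tibble::tibble(
    key = names(cfg),
    value = vapply(cfg, function(v)
      if (inherits(v, "cpuorf_engine")) v$name else
        paste(format(v), collapse = ","), character(1)))
  readr::write_tsv(cfg_tbl, file.path(out, "config.tsv"))
  write_alignment_exports(res, file.path(out, "alignments"))
  invisible(out)
}

# per-CPuORF alignment FASTA exports supporting manual validation
write_alignment_exports <- function(res, dir) {
  if (nrow(res$cpuorfs) == 0L) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (uid in res$cpuorfs$uorf_id) {
    reps <- dplyr::filter(res$representatives, .data$uorf_id == uid)
    orig <- res$cpuorfs$aa_seq[res$cpuorfs$uorf_id == uid]
    seqs <- c(setNames(orig, paste0("query|", uid)),
              setNames(reps$putative_aa,
                       paste0(reps$subject_id, "|", reps$order)))
    write_fasta(seqs, file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", uid),
                                            ".fa")))
  }
  invisible(dir)
}

#' @export
print.cpuorf_run <- function(x, ...) {
  cat("<cpuorf pipeline run>\n")
  cat("  query:", x$config$query_species, "(", x$config$query_order, ")\n")
  print(x$report)
  cat("CPuORFs identified:", nrow(x$cpuorfs), "\n")
  invisible(x)
}

#' Tidy the final CPuORF table of a pipeline run
#'
#' @param x a `cpuorf_run`
#' @param ... unused
#' @return tibble with one row per identified CPuORF: ids, peptide, Ka/Ks
#'   summary, taxonomic range and HG label
#' @method tidy cpuorf_run
#' @export
tidy.cpuorf_run <- function(x, ...) {
  x$cpuorfs
}

#' One-row summary of a pipeline run
#'
#' @param x a `cpuorf_run`
#' @param ... unused
#' @return one-row tibble: gene and uORF counts at entry, candidate and final
#'   CPuORF counts, number of HGs
#' @method glance cpuorf_run
#' @export
glance.cpuorf_run <- function(x, ...) {
  tibble::tibble(
    n_genes = x$report$n_genes[x$report$step == "Before selection"],
    n_uorfs_step1 = x$report$n_uorfs[x$report$step == "Step 1"],
    n_candidates = length(x$candidates),
    n_cpuorfs = nrow(x$cpuorfs),
    n_hgs = dplyr::n_distinct(x$hg$label)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-step survivor counts of a pipeline run
#'
#' @param object a `cpuorf_run`
#' @param ... unused
#' @return a ggplot: uORF (merged-count) survivors per pipeline step
#' @method autoplot cpuorf_run
#' @export
autoplot.cpuorf_run <- function(object, ...) {
  d <- dplyr::filter(object$report, !is.na(.data$n_uorfs))
  d$step <- factor(d$step, levels = d$step)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$n_uorfs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_uorfs), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "uORFs (shared start/stop merged)",
                  title = "uORF survivors per pipeline step") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of per-pair Ka versus Ks
#'
#' @param pairs tibble from [kaks_pairs()] (or `run$kaks`)
#' @param ratio_max threshold line to draw
#' @return a ggplot
#' @export
plot_kaks <- function(pairs, ratio_max = 0.5) {
  d <- dplyr::filter(pairs, is.finite(.data$Ka), is.finite(.data$Ks))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$Ks, y = .data$Ka,
                                  colour = .data$q < 0.05)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = ratio_max, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(colour = "q < 0.05",
                  title = "Pairwise Ka vs Ks of uORF / putative-uORF pairs",
                  subtitle = paste0("dashed line: Ka/Ks = ", ratio_max)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a taxonomic conservation profile
#'
#' @param profile tibble from [conservation_profile()]
#' @param uorf_id optional single uORF to plot (default: all, faceted)
#' @return a ggplot
#' @export
plot_taxonomic_profile <- function(profile, uorf_id = NULL) {
  d <- if (is.null(uorf_id)) profile else
    dplyr::filter(profile, .data$uorf_id %in% !!uorf_id)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$category,
                                       y = .data$n_orders)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "orders with representative hits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (is.null(uorf_id) && dplyr::n_distinct(d$uorf_id) > 1L) {
    p <- p + ggplot2::facet_wrap(~uorf_id)
  }
  p
}
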