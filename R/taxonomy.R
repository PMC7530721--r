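# ---- the fixed metazoan category ladder ------------------------------------
#
# 20 animal taxonomic categories. Each category is "membership in a named
# clade minus the clades already claimed earlier on the ladder", so testing
# them in ladder order against a lineage gives a partition of Metazoa.
# "Ctenophora" (Eumetazoa other than Cnidaria and Bilateria) is retained in
# code and reported as zero on real data. Each category also carries its
# backbone chain (nested clades from Metazoa down) from which distality along
# the metazoan cladogram is computed.

category_ladder <- function() {
  if (!is.null(.cpuorf_cache$ladder)) return(.cpuorf_cache$ladder)
  base <- c("Metazoa", "Eumetazoa", "Bilateria")
  deut <- c(base, "Deuterostomia")
  chor <- c(deut, "Chordata")
  vert <- c(chor, "Vertebrata")
  eutel <- c(vert, "Euteleostomi")
  actin <- c(eutel, "Actinopterygii")
  sarco <- c(eutel, "Sarcopterygii")
  tetra <- c(sarco, "Tetrapoda")
  mamm <- c(tetra, "Mammalia")
  euth <- c(mamm, "Eutheria")
  proto <- c(base, "Protostomia")
  ecdy <- c(proto, "Ecdysozoa")
  arth <- c(ecdy, "Arthropoda")
  ladder <- list(
    list(name = "Euarchontoglires", clade = "Euarchontoglires",
         chain = c(euth, "Euarchontoglires")),
    list(name = "Eutheria other than Euarchontoglires", clade = "Eutheria",
         chain = euth),
    list(name = "Mammalia other than Eutheria", clade = "Mammalia",
         chain = mamm),
    list(name = "Aves", clade = "Aves", chain = c(tetra, "Sauropsida", "Aves")),
    list(name = "Sauropsida other than Aves", clade = "Sauropsida",
         chain = c(tetra, "Sauropsida")),
    list(name = "Amphibia", clade = "Tetrapoda", chain = tetra),
    list(name = "Sarcopterygii other than Tetrapoda", clade = "Sarcopterygii",
         chain = sarco),
    list(name = "Ostarioclupeomorpha", clade = "Ostarioclupeomorpha",
         chain = c(actin, "Ostarioclupeomorpha")),
    list(name = "Actinopterygii other than Ostarioclupeomorpha",
         clade = "Actinopterygii", chain = actin),
    list(name = "Vertebrata other than Euteleostomi", clade = "Vertebrata",
         chain = vert),
    list(name = "Chordata other than Vertebrata", clade = "Chordata",
         chain = chor),
    list(name = "Deuterostomia other than Chordata", clade = "Deuterostomia",
         chain = deut),
    list(name = "Insecta", clade = "Insecta", chain = c(arth, "Insecta")),
    list(name = "Arthropoda other than Insecta", clade = "Arthropoda",
         chain = arth),
    list(name = "Ecdysozoa other than Arthropoda", clade = "Ecdysozoa",
         chain = ecdy),
    list(name = "Lophotrochozoa", clade = "Protostomia", chain = proto),
    list(name = "Bilateria other than Protostomia and Deuterostomia",
         clade = "Bilateria", chain = base),
    list(name = "Cnidaria", clade = "Cnidaria",
         chain = c("Metazoa", "Eumetazoa", "Cnidaria")),
    list(name = "Ctenophora", clade = "Eumetazoa",
         chain = c("Metazoa", "Eumetazoa")),
    list(name = "Metazoa other than Eumetazoa", clade = "Metazoa",
         chain = "Metazoa")
  )
  .cpuorf_cache$ladder <- ladder
  ladder
}

#' The 20 metazoan taxonomic categories, in ladder order
#'
#' @return character vector of length 20 ("Euarchontoglires" first,
#'   "Metazoa other than Eumetazoa" last); "Ctenophora" is included although
#'   it is expected to stay empty on real data
#' @export
animal_categories <- function() {
  vapply(category_ladder(), `[[`, character(1), "name")
}

#' Classify a lineage into its metazoan taxonomic category
#'
#' The lineage is tested against the named clades in ladder order; the first
#' clade it belongs to, minus the clades already claimed by earlier rungs
#' ("X other than Y" = in X, not in Y), decides the category. Every metazoan
#' lineage maps to exactly one of the 20 categories.
#'
#' @param lineage either a character vector of clade names (Metazoa downward)
#'   or a single semicolon-joined string
#' @return category name (character scalar)
#' @export
#' @examples
#' assign_category("Metazoa;Eumetazoa;Bilateria;Deuterostomia;Chordata;Vertebrata;Euteleostomi;Sarcopterygii;Tetrapoda;Mammalia;Eutheria;Euarchontoglires;Rodentia")
assign_category <- function(lineage) {
  if (length(lineage) == 1L && grepl(";", lineage)) {
    lineage <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  }
  lineage <- trimws(lineage)
  if (!"Metazoa" %in% lineage) {
    stop("lineage lies outside Metazoa (contaminant not removed upstream?)")
  }
  for (cat in category_ladder()) {
    if (cat$clade %in% lineage) return(cat$name)
  }
  "Metazoa other than Eumetazoa"  # unreachable: last rung matches Metazoa
}

# number of chain clades shared between two categories (smaller = more
# distal); used to order categories by distality relative to a query category
chain_overlap <- function(cat_a, cat_b) {
  ladder <- category_ladder()
  nm <- animal_categories()
  ca <- ladder[[match(cat_a, nm)]]$chain
  cb <- ladder[[match(cat_b, nm)]]$chain
  n <- min(length(ca), length(cb))
  shared <- 0L
  for (i in seq_len(n)) {
    if (ca[i] == cb[i]) shared <- i else break
  }
  shared
}

#' Taxonomic conservation profile of a uORF
#'
#' Counts, per category, the number of distinct taxonomic orders with
#' representative mORF-confirmed hits. Duplicate hits within an order never
#' change the profile: orders, not sequences, are counted.
#'
#' @param representatives tibble with columns `uorf_id`, `order`, `lineage`
#'   (one row per representative hit)
#' @return tibble with one row per (uORF, category) over all 20 categories:
#'   `uorf_id`, `category` (factor in ladder order), `n_orders`
#' @export
conservation_profile <- function(representatives) {
  cats <- animal_categories()
  if (nrow(representatives) == 0L) {
    return(tibble::tibble(uorf_id = character(0),
                          category = factor(character(0), levels = cats),
                          n_orders = integer(0)))
  }
  x <- dplyr::mutate(representatives,
                     category = purrr::map_chr(.data$lineage, assign_category))
  tal <- dplyr::summarise(
    dplyr::group_by(x, .data$uorf_id, .data$category),
    n_orders = dplyr::n_distinct(.data$order), .groups = "drop")
  grid <- tidyr::expand_grid(uorf_id = unique(representatives$uorf_id),
                             category = cats)
  out <- dplyr::left_join(grid, tal, by = c("uorf_id", "category"))
  out$n_orders <- dplyr::coalesce(out$n_orders, 0L)
  out$category <- factor(out$category, levels = cats)
  dplyr::arrange(out, .data$uorf_id, .data$category)
}

#' Most distal conserved category of a profile
#'
#' Distality is measured along the metazoan cladogram relative to the query
#' species' own category: the nonzero category whose backbone chain shares the
#' fewest clades with the query chain is the farthest. Ties at equal depth are
#' broken by the fixed ladder order (documented choice; the full profile is
#' the complete answer).
#'
#' @param profile tibble from [conservation_profile()] for one or more uORFs
#' @param query_category category of the query species (e.g.
#'   "Euarchontoglires" for human)
#' @return tibble: `uorf_id`, `range_label` (NA when the profile is all zero),
#'   `n_orders_total`
#' @export
taxonomic_range <- function(profile, query_category) {
  cats <- animal_categories()
  depth <- vapply(cats, chain_overlap, integer(1), cat_b = query_category)
  per <- dplyr::group_by(profile, .data$uorf_id)
  dplyr::summarise(per, range_label = {
    nz <- as.character(.data$category[.data$n_orders > 0])
    if (length(nz) == 0L) NA_character_ else {
      d <- depth[nz]
      nz[order(d, match(nz, cats))][1]
    }
  }, n_orders_total = sum(.data$n_orders), .groups = "drop")
}

#' Recompute a conservation profile after manual removal of hits
#'
#' Manual validation of the per-CPuORF alignments can strike putative uORF
#' sequences; the taxonomic range is then re-determined on the surviving
#' representatives. Removing every representative of a uORF yields an all-zero
#' profile (the record is flagged for discard upstream).
#'
#' @param representatives tibble as for [conservation_profile()], with
#'   `subject_id`
#' @param removed_subjects character vector of subject ids to exclude, or a
#'   two-column tibble (`uorf_id`, `subject_id`) for per-uORF removal
#' @return list with elements `representatives` (the survivors) and `profile`
#'   (recomputed)
#' @export
recompute_after_removal <- function(representatives, removed_subjects) {
  if (is.data.frame(removed_subjects)) {
    keep <- !paste(representatives$uorf_id, representatives$subject_id) %in%
      paste(removed_subjects$uorf_id, removed_subjects$subject_id)
  } else {
    keep <- !representatives$subject_id %in% removed_subjects
  }
  surv <- representatives[keep, , drop = FALSE]
  prof <- conservation_profile(surv)
  # uORFs whose every representative was removed: keep an all-zero profile row
  gone <- setdiff(unique(representatives$uorf_id), unique(surv$uorf_id))
  if (length(gone) > 0L) {
    cats <- animal_categories()
    zero <- tidyr::expand_grid(uorf_id = gone, category = cats)
    zero$n_orders <- 0L
    zero$category <- factor(zero$category, levels = cats)
    prof <- dplyr::arrange(dplyr::bind_rows(prof, zero), .data$uorf_id,
                           .data$category)
  }
  list(representatives = surv, profile = prof)
}
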