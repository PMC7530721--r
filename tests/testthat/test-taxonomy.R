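# the 20-category metazoan ladder and conservation ranges

lin <- function(...) paste(c(...), collapse = ";")
VERT <- c("Metazoa", "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata",
          "Vertebrata", "Euteleostomi")

test_that("category assignment follows the ladder with subtraction", {
  expect_equal(assign_category(lin(VERT, "Sarcopterygii", "Tetrapoda",
                                   "Mammalia", "Eutheria",
                                   "Euarchontoglires", "Rodentia")),
               "Euarchontoglires")
  expect_equal(assign_category(lin(VERT, "Sarcopterygii", "Tetrapoda",
                                   "Mammalia", "Eutheria", "Laurasiatheria",
                                   "Artiodactyla")),
               "Eutheria other than Euarchontoglires")
  expect_equal(assign_category(lin(VERT, "Actinopterygii",
                                   "Ostarioclupeomorpha", "Cypriniformes")),
               "Ostarioclupeomorpha")   # zebrafish
  expect_equal(assign_category(lin(VERT, "Sarcopterygii", "Tetrapoda",
                                   "Sauropsida", "Aves", "Galliformes")),
               "Aves")
  expect_equal(assign_category(lin(VERT, "Sarcopterygii", "Tetrapoda",
                                   "Amphibia", "Anura")),
               "Amphibia")
  expect_equal(assign_category(lin("Metazoa", "Eumetazoa", "Bilateria",
                                   "Protostomia", "Ecdysozoa", "Arthropoda",
                                   "Insecta", "Diptera")),
               "Insecta")
  expect_equal(assign_category(lin("Metazoa", "Eumetazoa", "Cnidaria")),
               "Cnidaria")
  expect_equal(assign_category(lin("Metazoa", "Porifera")),
               "Metazoa other than Eumetazoa")
  expect_error(assign_category(lin("Eukaryota", "Alveolata", "Apicomplexa")),
               "outside Metazoa")
})

test_that("the 20 categories partition synthetic lineages exhaustively", {
  cats <- animal_categories()
  expect_length(cats, 20L)
  expect_true("Ctenophora" %in% cats)
  # one synthetic lineage per category, built from its defining clades
  fixtures <- list(
    c(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Eutheria",
      "Euarchontoglires"),
    c(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Eutheria",
      "Laurasiatheria"),
    c(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Metatheria"),
    c(VERT, "Sarcopterygii", "Tetrapoda", "Sauropsida", "Aves"),
    c(VERT, "Sarcopterygii", "Tetrapoda", "Sauropsida", "Lepidosauria"),
    c(VERT, "Sarcopterygii", "Tetrapoda", "Amphibia"),
    c(VERT, "Sarcopterygii", "Dipnomorpha"),
    c(VERT, "Actinopterygii", "Ostarioclupeomorpha"),
    c(VERT, "Actinopterygii", "Neoteleostei"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata",
      "Vertebrata", "Cyclostomata"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata",
      "Tunicata"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Deuterostomia", "Echinodermata"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Protostomia", "Ecdysozoa",
      "Arthropoda", "Insecta"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Protostomia", "Ecdysozoa",
      "Arthropoda", "Chelicerata"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Protostomia", "Ecdysozoa",
      "Nematoda"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Protostomia", "Lophotrochozoa",
      "Mollusca"),
    c("Metazoa", "Eumetazoa", "Bilateria", "Xenacoelomorpha"),
    c("Metazoa", "Eumetazoa", "Cnidaria"),
    c("Metazoa", "Eumetazoa", "Ctenophora_clade"),
    c("Metazoa", "Porifera"))
  got <- vapply(fixtures, function(l) assign_category(lin(l)), character(1))
  expect_equal(got, cats)               # bijective onto the ladder
})

test_that("conservation profile counts orders, not sequences", {
  rod <- lin(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Eutheria",
             "Euarchontoglires", "Rodentia")
  car <- lin(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Eutheria",
             "Laurasiatheria", "Carnivora")
  aves <- lin(VERT, "Sarcopterygii", "Tetrapoda", "Sauropsida", "Aves",
              "Galliformes")
  reps <- tibble::tibble(
    uorf_id = "u1",
    subject_id = c("r1", "r2", "c1", "g1"),
    order = c("Rodentia", "Rodentia", "Carnivora", "Galliformes"),
    lineage = c(rod, rod, car, aves))
  prof <- conservation_profile(reps)
  expect_equal(nrow(prof), 20L)
  cnt <- stats::setNames(prof$n_orders, as.character(prof$category))
  expect_equal(unname(cnt["Euarchontoglires"]), 1L)   # two records, one order
  expect_equal(unname(cnt["Eutheria other than Euarchontoglires"]), 1L)
  expect_equal(unname(cnt["Aves"]), 1L)
  expect_equal(sum(cnt), 3L)

  rng <- taxonomic_range(prof, "Euarchontoglires")
  expect_equal(rng$range_label, "Aves")
  expect_equal(rng$n_orders_total, 3L)

  # without the bird, the range contracts to the mammalian side
  upd <- recompute_after_removal(reps, "g1")
  rng2 <- taxonomic_range(upd$profile, "Euarchontoglires")
  expect_equal(rng2$range_label, "Eutheria other than Euarchontoglires")
  # removing one of two Rodentia records changes nothing
  upd3 <- recompute_after_removal(reps, "r2")
  expect_equal(taxonomic_range(upd3$profile, "Euarchontoglires"),
               taxonomic_range(prof, "Euarchontoglires"))
  # removing everything leaves an all-zero profile (flag for discard)
  upd4 <- recompute_after_removal(reps, c("r1", "r2", "c1", "g1"))
  expect_equal(sum(upd4$profile$n_orders), 0L)
  expect_true(is.na(taxonomic_range(upd4$profile,
                                    "Euarchontoglires")$range_label))
})

test_that("range distality is measured along the cladogram, not the ladder", {
  # a Cnidaria hit is farther from Euarchontoglires than an Insecta hit
  cn <- lin("Metazoa", "Eumetazoa", "Cnidaria", "Anthozoa", "Actiniaria")
  ins <- lin("Metazoa", "Eumetazoa", "Bilateria", "Protostomia", "Ecdysozoa",
             "Arthropoda", "Insecta", "Diptera")
  rod <- lin(VERT, "Sarcopterygii", "Tetrapoda", "Mammalia", "Eutheria",
             "Euarchontoglires", "Rodentia")
  reps <- tibble::tibble(uorf_id = "u",
                         subject_id = c("x", "y", "z"),
                         order = c("Actiniaria", "Diptera", "Rodentia"),
                         lineage = c(cn, ins, rod))
  rng <- taxonomic_range(conservation_profile(reps), "Euarchontoglires")
  expect_equal(rng$range_label, "Cnidaria")
  reps2 <- reps[2:3, ]
  rng2 <- taxonomic_range(conservation_profile(reps2), "Euarchontoglires")
  expect_equal(rng2$range_label, "Insecta")
})
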