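# A tiny hand-built comparison used throughout: T1 has species x, m1,
# m2, c1 in two genera; T2 has the split products p, q, the merged
# species, the congruent species and an addition.
toy_comparison <- function() {
  t1 <- taxonomy(tibble::tibble(
    taxon_id = c("g1", "x", "m1", "m2", "g2", "c1"),
    parent_id = c(NA, "g1", "g1", "g1", NA, "g2"),
    rank = c("genus", "species", "species", "species", "genus", "species"),
    name = c("Rana", "Rana prima", "Rana alta", "Rana brevis",
             "Hyla", "Hyla cinerea"),
    author = c(NA, "Smith", "Gray", "Cope", NA, "Schneider"),
    year = c(NA, 1800, 1820, 1830, NA, 1799)))
  t2 <- taxonomy(tibble::tibble(
    taxon_id = c("G1", "p", "q", "m", "G2", "C1", "a"),
    parent_id = c(NA, "G1", "G1", "G1", NA, "G2", "G2"),
    rank = c("genus", "species", "species", "species", "genus", "species",
             "species"),
    name = c("Rana", "Rana nova", "Rana altera", "Rana alta",
             "Hyla", "Hyla cinerea", "Hyla addita"),
    author = c(NA, "Noble", "Noble", "Gray", NA, "Schneider", "Taylor"),
    year = c(NA, 2001, 2001, 1820, NA, 1799, 2005)))
  comparison(t1, t2, tibble::tibble(
    type = c("split", "merge", "congruent", "added"),
    origin_ids = list("x", c("m1", "m2"), "c1", character()),
    destination_ids = list(c("p", "q"), "m", "C1", "a")))
}

test_that("an identity comparison of a taxonomy with itself validates cleanly", {
  tx <- build_seed(seed_spec(12, 4, 2, rng_seed = 3))
  sp <- tx$taxa$taxon_id[tx$taxa$rank == "species"]
  cmp <- comparison(tx, tx, tibble::tibble(
    type = rep("congruent", length(sp)),
    origin_ids = as.list(sp), destination_ids = as.list(sp)))
  expect_equal(nrow(validate_comparison(cmp)), 0)
})

test_that("arity violations and uncovered taxa are reported, not raised", {
  cmp <- toy_comparison()
  expect_equal(nrow(validate_comparison(cmp)), 0)

  # a split into a single destination is an arity violation
  bad <- cmp
  bad$relations$destination_ids[[1]] <- "p"
  v <- validate_comparison(bad)
  expect_true("arity" %in% v$rule)
  expect_true("uncovered_taxon" %in% v$rule)  # q is now uncovered

  # dropping a relation leaves its species uncovered on both sides
  short <- cmp
  short$relations <- short$relations[-3, ]
  v2 <- validate_comparison(short)
  expect_setequal(v2$taxon_id[v2$rule == "uncovered_taxon"], c("c1", "C1"))

  # non-species ids are violations too
  wrong <- cmp
  wrong$relations$origin_ids[[3]] <- "g2"
  expect_true("not_origin_species" %in% validate_comparison(wrong)$rule)
})

test_that("summarize_changes counts relations by type and sums to the total", {
  s <- summarize_changes(toy_comparison())
  expect_equal(s$counts[["split"]], 1)
  expect_equal(s$counts[["merge"]], 1)
  expect_equal(s$counts[["congruent"]], 1)
  expect_equal(s$counts[["added"]], 1)
  expect_equal(s$counts[["excluded"]], 0)
  expect_equal(s$relation_total, 4)

  empty <- comparison(toy_comparison()$origin, toy_comparison()$destination,
                      tibble::tibble(type = character(), origin_ids = list(),
                                     destination_ids = list()))
  s0 <- summarize_changes(empty)
  expect_true(all(s0$counts == 0))
  expect_equal(s0$relation_total, 0)
})

test_that("a generator run requested with the study's change mix summarizes to exactly that mix", {
  seed <- build_seed(seed_spec(66, 20, 8, rng_seed = 2))
  v <- generate_variant(seed, generator_spec(
    split = 6, merge = 7, move = 6, rename = 7, added = 6, excluded = 4,
    rng_seed = 21))
  s <- summarize_changes(v$comparison)
  expect_equal(s$counts[["split"]], 6)
  expect_equal(s$counts[["merge"]], 7)
  expect_equal(s$counts[["move"]], 6)
  expect_equal(s$counts[["rename"]], 7)
  expect_equal(s$counts[["added"]], 6)
  expect_equal(s$counts[["excluded"]], 4)
})

test_that("filtering by type restricts relations and unions back to the whole", {
  cmp <- toy_comparison()
  expect_identical(filter_by_types(cmp, CHANGE_TYPES)$relations,
                   cmp$relations)
  only_split <- filter_by_types(cmp, "split")
  expect_equal(only_split$relations$type, "split")
  expect_equal(nrow(filter_by_types(cmp, character())$relations), 0)

  # union over singleton filters reproduces the full relation list
  pieces <- lapply(CHANGE_TYPES, function(t) filter_by_types(cmp, t)$relations)
  expect_setequal(
    canon_relations(cmp),
    canon_relations(list(relations = dplyr::bind_rows(pieces))))

  # summarize after filtering is zero except for the kept type
  s <- summarize_changes(filter_by_types(cmp, "merge"))
  expect_equal(s$counts[["merge"]], 1)
  expect_equal(sum(s$counts), 1)
})

test_that("changes_for_taxon finds the unique relation on either side", {
  cmp <- toy_comparison()
  hit <- changes_for_taxon(cmp, "p")  # a split product
  expect_equal(hit$relation$type, "split")
  expect_equal(hit$side, "destination")
  expect_setequal(hit$relation$destination_ids[[1]], c("p", "q"))

  hit2 <- changes_for_taxon(cmp, "c1")
  expect_equal(hit2$relation$type, "congruent")
  expect_equal(hit2$side, "origin")
  expect_error(changes_for_taxon(cmp, "g1"),
               class = "taxodiff_lookup_error")

  # agrees with a brute-force scan over every species and relation
  rel <- cmp$relations
  for (id in c("x", "m1", "m2", "c1", "p", "q", "m", "C1", "a")) {
    scan <- which(vapply(seq_len(nrow(rel)), function(i) {
      id %in% rel$origin_ids[[i]] || id %in% rel$destination_ids[[i]]
    }, logical(1)))
    expect_equal(changes_for_taxon(cmp, id)$relation_index, scan)
  }
})

test_that("most_common_change_type returns all argmax types and respects ties", {
  mk <- function(counts) {
    structure(list(counts = counts, relation_total = sum(counts)),
              class = "change_summary")
  }
  # one study dataset's mix: splits clearly dominate
  t5 <- setNames(c(0L, 9L, 3L, 6L, 6L, 6L, 8L), CHANGE_TYPES)
  expect_equal(most_common_change_type(mk(t5)), "split")
  # another mix ties merges and renames at 7
  t2 <- setNames(c(0L, 6L, 7L, 6L, 7L, 6L, 4L), CHANGE_TYPES)
  expect_setequal(most_common_change_type(mk(t2)), c("merge", "rename"))
  # congruent wins only when explicitly included
  cg <- setNames(c(40L, 2L, 1L, 0L, 0L, 0L, 0L), CHANGE_TYPES)
  expect_equal(most_common_change_type(mk(cg)), "split")
  expect_equal(most_common_change_type(mk(cg), include_congruent = TRUE),
               "congruent")
  zero <- setNames(rep(0L, 7), CHANGE_TYPES)
  expect_length(most_common_change_type(mk(zero)), 0)
})

test_that("comparison JSON round trips relations and conflicts", {
  cmp <- toy_comparison()
  f <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, f, origin_file = "t1.csv",
                   destination_file = "t2.csv")
  rt <- read_comparison(f, cmp$origin, cmp$destination)
  expect_equal(canon_relations(rt), canon_relations(cmp))
})

test_that("the species accounting identity holds for valid generated comparisons", {
  for (r in 4:6) {
    case <- random_variant_case(r)
    expect_true(taxodiff:::species_accounting_ok(case$variant$comparison))
  }
})
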