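test_that("resolve_spec converts percentages with round-half-up and passes counts through", {
  seed <- build_seed(seed_spec(66, 20, 8, rng_seed = 1))
  pct <- generator_spec(split = 0.1, merge = 0.1, move = 0, rename = 0,
                        added = 0, excluded = 0,
                        amount_mode = "percentages", rng_seed = 1)
  counts <- resolve_spec(pct, seed)
  expect_equal(counts[["split"]], 7)  # 6.6 rounds half-up to 7
  expect_equal(counts[["merge"]], 7)

  zero <- resolve_spec(generator_spec(amount_mode = "percentages"), seed)
  expect_true(all(zero == 0))

  cnt <- generator_spec(split = 3, rename = 2)
  expect_equal(resolve_spec(cnt, seed)[["split"]], 3)
})

test_that("resolve_spec raises a capacity error when demand exceeds the species pool", {
  tiny <- build_seed(seed_spec(3, 1, 1, rng_seed = 1))
  spec <- generator_spec(split = 2, merge = 1, merge_width = c(2, 2),
                         rng_seed = 1)
  expect_error(resolve_spec(spec, tiny), class = "taxodiff_capacity_error")
  expect_error(generate_variant(tiny, spec),
               class = "taxodiff_capacity_error")
})

test_that("build_seed produces valid, fully attributed taxonomies of the requested shape", {
  minimal <- build_seed(seed_spec(1, 1, 1, rng_seed = 9))
  expect_equal(sum(minimal$taxa$rank == "species"), 1)
  expect_equal(nrow(validate_taxonomy(minimal)), 0)

  seed <- build_seed(seed_spec(66, 20, 8, rng_seed = 4))
  expect_equal(sum(seed$taxa$rank == "species"), 66)
  expect_equal(sum(seed$taxa$rank == "genus"), 20)
  expect_equal(sum(seed$taxa$rank == "family"), 8)
  expect_equal(nrow(validate_taxonomy(seed)), 0)
  expect_equal(nrow(find_inconsistencies(seed)), 0)

  # binomials unique, epithets globally unique
  sp <- seed$taxa$name[seed$taxa$rank == "species"]
  expect_false(any(duplicated(sp)))
  expect_false(any(duplicated(taxodiff:::epithet_part(sp))))
})

test_that("equal seeds give byte-identical taxonomies and variants", {
  a <- build_seed(seed_spec(30, 10, 4, rng_seed = 77))
  b <- build_seed(seed_spec(30, 10, 4, rng_seed = 77))
  expect_identical(a, b)
  expect_false(identical(a, build_seed(seed_spec(30, 10, 4, rng_seed = 78))))

  spec <- generator_spec(split = 2, merge = 1, move = 2, rename = 2,
                         added = 1, excluded = 1, rng_seed = 5)
  expect_identical(generate_variant(a, spec), generate_variant(a, spec))
})

test_that("an all-zero spec yields an identical destination and an all-congruent ground truth", {
  seed <- build_seed(seed_spec(15, 5, 2, rng_seed = 8))
  v <- generate_variant(seed, generator_spec(rng_seed = 3))
  expect_equal(v$destination$taxa$name, seed$taxa$name)
  expect_equal(v$destination$taxa$rank, seed$taxa$rank)
  s <- summarize_changes(v$comparison)
  expect_equal(s$counts[["congruent"]], 15)
  expect_equal(sum(s$counts), 15)
})

test_that("the destination species count follows the accounting identity", {
  seed <- build_seed(seed_spec(20, 6, 2, rng_seed = 12))
  v <- generate_variant(seed, generator_spec(
    split = 2, split_fanout = c(2, 2), merge = 1, merge_width = c(2, 2),
    move = 1, rename = 1, added = 1, excluded = 1, rng_seed = 13))
  # 20 + 2 splits * (2-1) - 1 merge * (2-1) + 1 added - 1 excluded = 21
  expect_equal(sum(v$destination$taxa$rank == "species"), 21)
})

test_that("change semantics record the evidence the diff engine needs", {
  seed <- build_seed(seed_spec(30, 8, 3, rng_seed = 20))
  v <- generate_variant(seed, generator_spec(
    split = 2, merge = 2, move = 2, rename = 2, added = 2, excluded = 2,
    rng_seed = 21))
  rel <- v$comparison$relations
  dtx <- v$destination
  stx <- seed
  name_of <- function(tx, id) tx$taxa$name[match(id, tx$taxa$taxon_id)]
  syn_of <- function(tx, id) tx$taxa$synonyms[[match(id, tx$taxa$taxon_id)]]

  for (i in which(rel$type == "split")) {
    src <- rel$origin_ids[[i]]
    for (p in rel$destination_ids[[i]]) {
      expect_equal(syn_of(dtx, p)$full_name, name_of(stx, src))
      # products stay in the source's genus
      expect_equal(taxodiff:::genus_part(name_of(dtx, p)),
                   taxodiff:::genus_part(name_of(stx, src)))
    }
  }
  for (i in which(rel$type == "merge")) {
    d <- rel$destination_ids[[i]]
    survivor_name <- name_of(dtx, d)
    expect_true(survivor_name %in% name_of(stx, rel$origin_ids[[i]]))
    others <- setdiff(name_of(stx, rel$origin_ids[[i]]), survivor_name)
    expect_setequal(syn_of(dtx, d)$full_name, others)
  }
  for (i in which(rel$type == "move")) {
    src <- rel$origin_ids[[i]]
    d <- rel$destination_ids[[i]]
    expect_equal(taxodiff:::epithet_part(name_of(dtx, d)),
                 taxodiff:::epithet_part(name_of(stx, src)))
    expect_false(taxodiff:::genus_part(name_of(dtx, d)) ==
                   taxodiff:::genus_part(name_of(stx, src)))
    expect_equal(syn_of(dtx, d)$full_name, name_of(stx, src))
  }
  for (i in which(rel$type == "rename")) {
    src <- rel$origin_ids[[i]]
    d <- rel$destination_ids[[i]]
    expect_equal(taxodiff:::genus_part(name_of(dtx, d)),
                 taxodiff:::genus_part(name_of(stx, src)))
    expect_false(name_of(dtx, d) == name_of(stx, src))
    expect_equal(syn_of(dtx, d)$full_name, name_of(stx, src))
  }
  for (i in which(rel$type == "excluded")) {
    expect_false(name_of(stx, rel$origin_ids[[i]]) %in% dtx$taxa$name)
  }
})

test_that("no species receives more than one change", {
  for (r in 7:9) {
    case <- random_variant_case(r)
    rel <- case$variant$comparison$relations
    o <- unlist(rel$origin_ids)
    d <- unlist(rel$destination_ids)
    expect_false(any(duplicated(o)))
    expect_false(any(duplicated(d)))
  }
})

test_that("pruning drops genera emptied by exclusion, default keeps them", {
  seed <- build_seed(seed_spec(6, 3, 1, rng_seed = 31))
  # exclude every species so some genus must end up empty
  keep <- generate_variant(seed, generator_spec(excluded = 6, rng_seed = 1))
  expect_equal(sum(keep$destination$taxa$rank == "genus"), 3)
  prune <- generate_variant(seed, generator_spec(excluded = 6, rng_seed = 1,
                                                 prune_empty_genera = TRUE))
  expect_equal(sum(prune$destination$taxa$rank == "genus"), 0)
  expect_equal(nrow(validate_taxonomy(prune$destination)), 0)
})

test_that("mutate_epithet keeps the genus and stays within edit distance 1-3", {
  set.seed(42)
  for (i in 1:1000) {
    old <- paste("Rana", paste(sample(letters, sample(4:9, 1),
                                      replace = TRUE), collapse = ""))
    new <- mutate_epithet(old)
    expect_false(new == old)
    expect_equal(taxodiff:::genus_part(new), "Rana")
    d <- edit_distance(taxodiff:::epithet_part(old),
                       taxodiff:::epithet_part(new))
    expect_gte(d, 1)
    expect_lte(d, 3)
    expect_match(taxodiff:::epithet_part(new), "^[a-z]+$")
  }
  set.seed(7)
  a <- mutate_epithet("Rana tempora")
  set.seed(7)
  b <- mutate_epithet("Rana tempora")
  expect_identical(a, b)
})
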