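# Synthetic taxonomy construction and controlled mutation.
#
# The seed builder manufactures a ranked taxonomy (kingdom -> phylum ->
# class -> order -> family -> genus -> species) with pronounceable
# pseudo-Latin names, unique binomials and full authorship, standing in
# for a small checklist export. The variant generator then derives a
# destination version by injecting a requested mix of changes, at most
# one change per species, and emits the ground-truth comparison.

AUTHOR_POOL <- c(
  "Linnaeus", "Cuvier", "Boulenger", "Cope", "Duméril", "Peters", "Gray",
  "Günther", "Wagler", "Fitzinger", "Schneider", "Laurenti", "Daudin",
  "Tschudi", "Bibron", "Smith", "Stejneger", "Barbour", "Noble", "Taylor"
)

syllable <- function() {
  cons <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  paste0(resample(cons, 1), resample(vow, 1))
}

random_word <- function(n_syllables) {
  paste(vapply(seq_len(n_syllables), function(i) syllable(), character(1)),
        collapse = "")
}

# Draw words until one not yet in `used`; deterministic under the RNG.
fresh_word <- function(used, n_syllables = 3) {
  repeat {
    w <- random_word(n_syllables)
    if (!w %in% used) return(w)
  }
}

capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

# sample() treats a length-1 numeric as 1:x; this does not.
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

#' Specify a synthetic seed taxonomy
#'
#' @param n_species,n_genera,n_families Sizes of the three lower levels;
#'   `n_species >= n_genera >= n_families >= 1`. One kingdom, phylum,
#'   class and order are always generated above the families, so the
#'   total node count is `n_species + n_genera + n_families + 4`.
#' @param rng_seed Integer seed; equal seeds give byte-identical output.
#' @return A list of class `seed_spec`.
#' @seealso [build_seed()]
#' @export
seed_spec <- function(n_species = 66, n_genera = 20, n_families = 8,
                      rng_seed = 1) {
  if (!(n_species >= n_genera && n_genera >= n_families && n_families >= 1)) {
    abort("need n_species >= n_genera >= n_families >= 1")
  }
  structure(list(n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 n_families = as.integer(n_families),
                 rng_seed = as.integer(rng_seed)),
            class = "seed_spec")
}

#' Build a synthetic seed taxonomy
#'
#' Deterministically generates a valid ranked taxonomy from a
#' [seed_spec()]: a single kingdom-to-order chain, the requested numbers
#' of families, genera and species, every genus holding at least one
#' species, unique genus names and globally unique specific epithets
#' (hence unique binomials whose genus part matches the parent genus),
#' and author/year attribution on every species. The default sizes give
#' a taxonomy of roughly a hundred nodes, the scale of a small
#' checklist download.
#'
#' @param spec A [seed_spec()].
#' @return A [taxonomy()] object that passes [validate_taxonomy()] and
#'   [find_inconsistencies()] with no findings.
#' @export
build_seed <- function(spec = seed_spec()) {
  if (!inherits(spec, "seed_spec")) abort("`spec` must come from seed_spec()")
  with_rng_seed(spec$rng_seed, {
    used <- character()
    word <- function(n = 3) {
      w <- fresh_word(used, n)
      used <<- c(used, w)
      w
    }
    acc <- list(parent_id = character(), rank = character(),
                name = character(), author = character(), year = integer())
    nid <- 0L
    add_row <- function(parent_id, rank, name, author = NA_character_,
                        year = NA_integer_) {
      nid <<- nid + 1L
      id <- sprintf("t%04d", nid)
      acc$parent_id[nid] <<- parent_id
      acc$rank[nid] <<- rank
      acc$name[nid] <<- name
      acc$author[nid] <<- author
      acc$year[nid] <<- year
      id
    }
    kingdom <- add_row(NA_character_, "kingdom", capitalize(word()))
    phylum <- add_row(kingdom, "phylum", capitalize(word()))
    class_ <- add_row(phylum, "class", capitalize(word()))
    order_ <- add_row(class_, "order", paste0(capitalize(word()), "iformes"))

    # every family gets >= 1 genus, every genus >= 1 species
    genus_family <- c(seq_len(spec$n_families),
                      resample(seq_len(spec$n_families),
                               spec$n_genera - spec$n_families,
                               replace = TRUE))
    species_genus <- c(seq_len(spec$n_genera),
                       resample(seq_len(spec$n_genera),
                                spec$n_species - spec$n_genera,
                                replace = TRUE))
    genus_names <- character(spec$n_genera)
    for (g in seq_len(spec$n_genera)) {
      genus_names[g] <- capitalize(word())
    }
    # rows emitted in preorder: each family directly followed by its
    # genera and their species
    for (f in seq_len(spec$n_families)) {
      family_id <- add_row(order_, "family",
                           paste0(capitalize(word()), "idae"))
      for (g in which(genus_family == f)) {
        gid <- add_row(family_id, "genus", genus_names[g])
        for (s in which(species_genus == g)) {
          add_row(gid, "species", paste(genus_names[g], word()),
                  author = resample(AUTHOR_POOL, 1),
                  year = resample(1758:2015, 1))
        }
      }
    }
    taxonomy(tibble::tibble(
      taxon_id = sprintf("t%04d", seq_len(nid)),
      parent_id = acc$parent_id, rank = acc$rank, name = acc$name,
      author = acc$author, year = acc$year,
      synonyms = replicate(nid, empty_synonyms(), simplify = FALSE)))
  })
}

#' Specify a mix of taxonomic changes to inject
#'
#' @param split,merge,move,rename,added,excluded Requested amounts of
#'   each change type, either absolute counts (`amount_mode = "counts"`)
#'   or fractions of the seed's species count
#'   (`amount_mode = "percentages"`, resolved with round-half-up).
#' @param amount_mode How to interpret the amounts.
#' @param split_fanout Integer range (length-2 vector) of products per
#'   split; default 2 to 3.
#' @param merge_width Integer range of sources per merge; default 2 to 3.
#' @param prune_empty_genera Drop destination genera left without
#'   species? Off by default so the upper hierarchy stays comparable.
#' @param rng_seed Integer seed making the variant reproducible.
#' @return A list of class `generator_spec`.
#' @seealso [generate_variant()], [resolve_spec()]
#' @export
generator_spec <- function(split = 0, merge = 0, move = 0, rename = 0,
                           added = 0, excluded = 0,
                           amount_mode = c("counts", "percentages"),
                           split_fanout = c(2L, 3L), merge_width = c(2L, 3L),
                           prune_empty_genera = FALSE, rng_seed = 1) {
  amount_mode <- match.arg(amount_mode)
  amounts <- c(split = split, merge = merge, move = move, rename = rename,
               added = added, excluded = excluded)
  if (any(amounts < 0)) abort("requested amounts must be non-negative")
  if (length(split_fanout) != 2 || split_fanout[1] < 2 ||
      split_fanout[2] < split_fanout[1]) {
    abort("`split_fanout` must be an increasing range with minimum >= 2")
  }
  if (length(merge_width) != 2 || merge_width[1] < 2 ||
      merge_width[2] < merge_width[1]) {
    abort("`merge_width` must be an increasing range with minimum >= 2")
  }
  structure(list(amounts = amounts, amount_mode = amount_mode,
                 split_fanout = as.integer(split_fanout),
                 merge_width = as.integer(merge_width),
                 prune_empty_genera = isTRUE(prune_empty_genera),
                 rng_seed = as.integer(rng_seed)),
            class = "generator_spec")
}

#' Resolve a generator specification to exact change counts
#'
#' Converts percentage amounts to counts via round-half-up on
#' `fraction * species count` (counts mode passes through) and checks the
#' demand against the seed's species pool: each split, move, rename and
#' exclusion consumes one species, each merge consumes at least the
#' minimum merge width, additions consume none.
#'
#' @param spec A [generator_spec()].
#' @param seed The seed [taxonomy()].
#' @return Named integer vector of counts over the six mutating change
#'   types.
#' @export
resolve_spec <- function(spec, seed) {
  if (!inherits(spec, "generator_spec")) {
    abort("`spec` must come from generator_spec()")
  }
  assert_taxonomy(seed, "seed")
  n_sp <- length(species_ids(seed))
  counts <- if (spec$amount_mode == "percentages") {
    as.integer(round_half_up(spec$amounts * n_sp))
  } else {
    as.integer(spec$amounts)
  }
  counts <- setNames(counts, names(spec$amounts))
  demand <- counts[["split"]] + counts[["merge"]] * spec$merge_width[1] +
    counts[["move"]] + counts[["rename"]] + counts[["excluded"]]
  if (demand > n_sp) {
    abort(sprintf(
      "requested changes need %d species but the seed has only %d (shortfall %d)",
      demand, n_sp, demand - n_sp), class = "taxodiff_capacity_error")
  }
  counts
}

#' Mutate the specific epithet of a binomial
#'
#' Emulates the small spelling corrections behind a rename: applies one
#' to three random single-character edits (substitution, insertion or
#' deletion of a lowercase letter) to the epithet, guaranteeing the
#' result differs from the input, stays a valid lowercase epithet, and
#' sits within character edit distance 3 of the original. The genus part
#' is untouched. Uses the current RNG state; seed it for reproducibility.
#'
#' @param full_name A species binomial, e.g. `"Rana tempora"`.
#' @return The mutated binomial.
#' @export
mutate_epithet <- function(full_name) {
  genus <- genus_part(full_name)
  epi <- epithet_part(full_name)
  if (!nzchar(epi)) abort("`full_name` must be a binomial with an epithet")
  alphabet <- letters
  repeat {
    chars <- strsplit(epi, "")[[1]]
    n_edits <- resample(1:3, 1)
    for (e in seq_len(n_edits)) {
      ops <- c("substitute", "insert")
      if (length(chars) > 3) ops <- c(ops, "delete")
      op <- resample(ops, 1)
      if (op == "substitute") {
        i <- resample(seq_along(chars), 1)
        chars[i] <- resample(setdiff(alphabet, chars[i]), 1)
      } else if (op == "insert") {
        i <- resample(seq_len(length(chars) + 1), 1)
        chars <- append(chars, resample(alphabet, 1), after = i - 1)
      } else {
        i <- resample(seq_along(chars), 1)
        chars <- chars[-i]
      }
    }
    new_epi <- paste(chars, collapse = "")
    if (new_epi != epi) return(paste(genus, new_epi))
  }
}

#' Derive a taxonomy variant with known ground truth
#'
#' The core of the synthetic study setup: starting from a seed taxonomy
#' (T1), injects the resolved mix of changes to produce a destination
#' version (T2) together with the ground-truth [comparison()]. Species
#' to change are selected at random but each species receives at most
#' one change, so the emitted relations are conflict-free by
#' construction.
#'
#' Change semantics, all at species rank:
#' * **split** — the source species disappears; `split_fanout` new
#'   species appear under the same genus, each citing the source name as
#'   a synonym.
#' * **merge** — `merge_width` congeneric species are replaced by one
#'   species bearing a randomly chosen survivor's name; the other
#'   sources become its synonyms.
#' * **move** — the species is re-parented under a different genus, the
#'   binomial's genus part follows, and the original binomial is kept as
#'   a synonym.
#' * **rename** — the epithet is mutated in place (see
#'   [mutate_epithet()]); the original name is kept as a synonym.
#' * **added** — a fresh species appears under a random existing genus.
#' * **excluded** — the species is absent from the destination; genera
#'   emptied this way are retained unless `prune_empty_genera`.
#'
#' Untouched species become explicit congruent relations. The
#' destination preserves the seed's order, with in-place replacements;
#' moved-in and added species are appended at the end of their genus.
#'
#' @param seed The origin [taxonomy()] (T1).
#' @param spec A [generator_spec()]; equal seed + spec give
#'   byte-identical output.
#' @return A list with elements `destination` (the derived [taxonomy()])
#'   and `comparison` (the ground truth, with `seed` as origin).
#' @export
generate_variant <- function(seed, spec) {
  assert_taxonomy(seed, "seed")
  counts <- resolve_spec(spec, seed)
  with_rng_seed(spec$rng_seed, {
    taxa <- seed$taxa
    sp_ids <- species_ids(seed)
    sp_genus <- vapply(sp_ids, function(id) {
      g <- ancestor_at_rank(seed, id, "genus")
      if (is.na(g)) "" else g
    }, character(1))
    genus_ids <- taxa$taxon_id[taxa$rank == "genus"]
    genus_name <- setNames(taxa$name[taxa$rank == "genus"], genus_ids)

    used_epithets <- unique(epithet_part(taxa$name[taxa$rank == "species"]))
    used_words <- used_epithets
    fresh_epithet <- function() {
      w <- fresh_word(used_words, 3)
      used_words <<- c(used_words, w)
      w
    }

    available <- sp_ids
    take <- function(ids) available <<- setdiff(available, ids)

    # merges first: each needs `width` species within a single genus
    merge_groups <- list()
    if (counts[["merge"]] > 0) {
      for (m in seq_len(counts[["merge"]])) {
        w <- resample(spec$merge_width[1]:spec$merge_width[2], 1)
        grp <- NULL
        for (width in rev(seq(spec$merge_width[1], w))) {
          by_genus <- split(intersect(available, sp_ids),
                            sp_genus[match(intersect(available, sp_ids),
                                           sp_ids)])
          ok <- names(by_genus)[vapply(by_genus, length,
                                       integer(1)) >= width]
          ok <- ok[nzchar(ok)]
          if (length(ok) > 0) {
            g <- resample(ok, 1)
            grp <- resample(by_genus[[g]], width)
            break
          }
        }
        if (is.null(grp)) {
          abort("no genus holds enough unchanged species for a merge",
                class = "taxodiff_capacity_error")
        }
        merge_groups[[m]] <- grp
        take(grp)
      }
    }
    pick <- function(n) {
      if (n > length(available)) {
        abort("species pool exhausted while selecting change targets",
              class = "taxodiff_capacity_error")
      }
      out <- resample(available, n)
      take(out)
      out
    }
    split_ids <- pick(counts[["split"]])
    move_ids <- pick(counts[["move"]])
    rename_ids <- pick(counts[["rename"]])
    excluded_ids <- pick(counts[["excluded"]])
    if (counts[["move"]] > 0 && length(genus_ids) < 2) {
      abort("moves need at least two genera in the seed",
            class = "taxodiff_capacity_error")
    }

    change_of <- setNames(rep("congruent", length(sp_ids)), sp_ids)
    change_of[split_ids] <- "split"
    change_of[move_ids] <- "move"
    change_of[rename_ids] <- "rename"
    change_of[excluded_ids] <- "excluded"
    for (grp in merge_groups) change_of[grp] <- "merge"
    merge_index <- setNames(rep(NA_integer_, length(sp_ids)), sp_ids)
    for (m in seq_along(merge_groups)) {
      merge_index[merge_groups[[m]]] <- m
    }
    merge_survivor <- vapply(merge_groups, function(grp) resample(grp, 1),
                             character(1))

    # --- build the destination ---------------------------------------
    did <- 0L
    dacc <- list(parent_id = character(), rank = character(),
                 name = character(), author = character(), year = integer(),
                 synonyms = list())
    id_map <- character()  # seed id -> destination id (higher taxa)
    syn_of <- function(ids) {
      i <- match(ids, taxa$taxon_id)
      tibble::tibble(full_name = taxa$name[i], author = taxa$author[i],
                     year = taxa$year[i])
    }
    add_dest <- function(parent, rank, name, author = NA_character_,
                         year = NA_integer_, synonyms = empty_synonyms()) {
      did <<- did + 1L
      dacc$parent_id[did] <<- parent
      dacc$rank[did] <<- rank
      dacc$name[did] <<- name
      dacc$author[did] <<- author
      dacc$year[did] <<- year
      dacc$synonyms[[did]] <<- synonyms
      sprintf("d%04d", did)
    }

    # destinations of moves and additions, decided up front
    move_dest_genus <- vapply(move_ids, function(id) {
      resample(setdiff(genus_ids, sp_genus[[match(id, sp_ids)]]), 1)
    }, character(1))
    added_genus <- if (counts[["added"]] > 0) {
      vapply(seq_len(counts[["added"]]),
             function(i) resample(genus_ids, 1), character(1))
    } else {
      character()
    }

    racc <- list(type = character(), origin_ids = list(),
                 destination_ids = list())
    nrel <- 0L
    merge_done <- logical(length(merge_groups))
    add_rel <- function(type, origin_ids, destination_ids) {
      nrel <<- nrel + 1L
      racc$type[nrel] <<- type
      racc$origin_ids[[nrel]] <<- origin_ids
      racc$destination_ids[[nrel]] <<- destination_ids
    }

    # walk the seed preorder; species of each genus handled in order
    pre <- preorder_ids(seed)
    for (sid in pre) {
      i <- match(sid, taxa$taxon_id)
      rk <- taxa$rank[i]
      if (rk != "species") {
        parent <- taxa$parent_id[i]
        dparent <- if (is.na(parent)) NA_character_ else id_map[[parent]]
        id_map[[sid]] <- add_dest(dparent, rk, taxa$name[i], taxa$author[i],
                                  taxa$year[i])
        next
      }
      change <- change_of[[sid]]
      gid <- sp_genus[[match(sid, sp_ids)]]
      dparent <- id_map[[taxa$parent_id[i]]]
      if (change == "congruent") {
        d <- add_dest(dparent, "species", taxa$name[i], taxa$author[i],
                      taxa$year[i])
        add_rel("congruent", sid, d)
      } else if (change == "split") {
        fan <- resample(spec$split_fanout[1]:spec$split_fanout[2], 1)
        prods <- vapply(seq_len(fan), function(f) {
          add_dest(dparent, "species",
                   paste(genus_name[[gid]], fresh_epithet()),
                   resample(AUTHOR_POOL, 1), resample(1990:2020, 1),
                   synonyms = syn_of(sid))
        }, character(1))
        add_rel("split", sid, prods)
      } else if (change == "merge") {
        m <- merge_index[[sid]]
        if (!merge_done[m] && sid == merge_survivor[m]) {
          others <- setdiff(merge_groups[[m]], sid)
          d <- add_dest(dparent, "species", taxa$name[i], taxa$author[i],
                        taxa$year[i], synonyms = syn_of(others))
          add_rel("merge", merge_groups[[m]], d)
          merge_done[m] <- TRUE
        }
        # non-survivor sources vanish at their position
      } else if (change == "rename") {
        new_name <- repeat_until_unique(taxa$name[i], used_words)
        used_words <- c(used_words, epithet_part(new_name))
        d <- add_dest(dparent, "species", new_name, taxa$author[i],
                      taxa$year[i], synonyms = syn_of(sid))
        add_rel("rename", sid, d)
      }
      # move: emitted later under the destination genus
      # excluded: no destination row
    }
    for (sid in excluded_ids) add_rel("excluded", sid, character())

    # moved-in species, appended at the end of their destination genus
    for (j in seq_along(move_ids)) {
      sid <- move_ids[j]
      i <- match(sid, taxa$taxon_id)
      g2 <- move_dest_genus[j]
      d <- add_dest(id_map[[g2]], "species",
                    paste(genus_name[[g2]], epithet_part(taxa$name[i])),
                    taxa$author[i], taxa$year[i], synonyms = syn_of(sid))
      add_rel("move", sid, d)
    }
    # additions, appended likewise
    for (j in seq_along(added_genus)) {
      g <- added_genus[j]
      d <- add_dest(id_map[[g]], "species",
                    paste(genus_name[[g]], fresh_epithet()),
                    resample(AUTHOR_POOL, 1), resample(1990:2020, 1))
      add_rel("added", character(), d)
    }

    dest_taxa <- tibble::tibble(
      taxon_id = sprintf("d%04d", seq_len(did)),
      parent_id = dacc$parent_id, rank = dacc$rank, name = dacc$name,
      author = dacc$author, year = dacc$year, synonyms = dacc$synonyms)
    # restore genus-block order: in-place rows were emitted in seed order,
    # moved/added rows at the end; reorder so each genus's children stay
    # contiguous (appended members go last within their genus)
    dest <- taxonomy(dest_taxa, role = "destination")
    ord <- match(preorder_ids(dest), dest$taxa$taxon_id)
    dest$taxa <- dest$taxa[ord, ]

    if (spec$prune_empty_genera) {
      keep_looking <- TRUE
      while (keep_looking) {
        g <- dest$taxa$taxon_id[dest$taxa$rank == "genus"]
        empty <- g[!g %in% dest$taxa$parent_id]
        if (length(empty) == 0) {
          keep_looking <- FALSE
        } else {
          dest$taxa <- dest$taxa[!dest$taxa$taxon_id %in% empty, ]
        }
      }
    }

    rel <- tibble::tibble(type = racc$type, origin_ids = racc$origin_ids,
                          destination_ids = racc$destination_ids)
    cmp <- comparison(seed, dest, rel)
    list(destination = dest, comparison = cmp)
  })
}

# Mutate an epithet until it collides with no name already in use.
repeat_until_unique <- function(full_name, used) {
  repeat {
    cand <- mutate_epithet(full_name)
    if (!epithet_part(cand) %in% used) return(cand)
  }
}
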