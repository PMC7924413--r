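# Change detection between two independently given taxonomy versions.
#
# The evidence channels are accepted names and synonym lists: a species
# record carries at least name, author and year, and each accepted
# species may cite former names as synonyms. Matching works on a
# normalized concept key — by default (full_name, author, year), since
# authorship identifies the taxonomic judgment; a lenient name-only key
# is available for real-world data with inconsistent attribution.

norm_text <- function(x) {
  x <- ifelse(is.na(x), "", x)
  tolower(gsub(" +", " ", trimws(x)))
}

concept_key <- function(full_name, author, year, lenient = FALSE) {
  if (lenient) {
    norm_text(full_name)
  } else {
    paste(norm_text(full_name), norm_text(author),
          ifelse(is.na(year), "", as.character(year)), sep = "\r")
  }
}

#' Index the species concepts of a taxonomy
#'
#' Builds the lookup structure change detection runs on: a map from each
#' normalized concept key (case-folded, whitespace-collapsed name plus
#' authorship) to the accepted species bearing it, and a map from keys
#' cited as synonyms to the set of citing species. A key borne by more
#' than one accepted species is recorded as a conflict; indexing
#' continues.
#'
#' @param taxonomy A valid [taxonomy()] object.
#' @param lenient Match on names only, ignoring author and year?
#' @return A list of class `concept_index` with elements `accepted`
#'   (named character: key -> taxon_id), `via_synonym` (named list:
#'   key -> character vector of citing taxon_ids) and `conflicts`
#'   (tibble of duplicate accepted keys).
#' @export
index_concepts <- function(taxonomy, lenient = FALSE) {
  assert_taxonomy(taxonomy)
  taxa <- taxonomy$taxa
  sp <- taxa[taxa$rank == "species", ]
  keys <- concept_key(sp$name, sp$author, sp$year, lenient)
  conflicts <- list()
  accepted <- character()
  for (i in seq_len(nrow(sp))) {
    k <- keys[i]
    if (k %in% names(accepted)) {
      conflicts[[length(conflicts) + 1]] <- tibble::tibble(
        key = k, taxon_id = sp$taxon_id[i],
        message = paste0("accepted key already borne by ", accepted[[k]]))
    } else {
      accepted[[k]] <- sp$taxon_id[i]
    }
  }
  via_synonym <- list()
  for (i in seq_len(nrow(sp))) {
    syn <- sp$synonyms[[i]]
    if (nrow(syn) == 0) next
    skeys <- concept_key(syn$full_name, syn$author, syn$year, lenient)
    for (k in skeys) {
      via_synonym[[k]] <- c(via_synonym[[k]], sp$taxon_id[i])
    }
  }
  structure(list(
    accepted = accepted,
    via_synonym = via_synonym,
    conflicts = if (length(conflicts) == 0) {
      tibble::tibble(key = character(), taxon_id = character(),
                     message = character())
    } else {
      dplyr::bind_rows(conflicts)
    },
    lenient = lenient
  ), class = "concept_index")
}

#' Recover the typed changes between two taxonomy versions
#'
#' Classifies every species of the origin (T1) and destination (T2)
#' versions into one relation each, using accepted-name matches and
#' synonym citations as evidence:
#'
#' * accepted keys equal, same parent genus — **congruent**;
#' * accepted keys equal, different parent genus — **move**;
#' * a T1 concept associated with exactly one T2 species via synonymy
#'   (either species may cite the other's accepted name, so the
#'   comparison is symmetric in its arguments): same parent —
#'   **rename**; different parent with the same epithet — **move**;
#'   different parent and different epithet is a compound change and
#'   becomes a conflict;
#' * a T1 concept associated with two or more T2 species — **split**;
#' * a T2 species associated with two or more T1 concepts (its accepted
#'   key matching one and/or citing others as synonyms) — **merge**;
#' * unmatched T1 species — **excluded**; unmatched T2 species —
#'   **added**.
#'
#' A taxon implicated in both split and merge evidence is never silently
#' resolved: all species involved are reported in the comparison's
#' `conflicts` table and appear in no relation, so the output either
#' satisfies the coverage rules of [validate_comparison()] or carries
#' explicit conflicts.
#'
#' @param origin,destination [taxonomy()] objects (T1 and T2).
#' @param lenient Match concepts on names only (see [index_concepts()]).
#' @return A [comparison()] object.
#' @export
diff_taxonomies <- function(origin, destination, lenient = FALSE) {
  assert_taxonomy(origin, "origin")
  assert_taxonomy(destination, "destination")
  sp1 <- species_ids(origin)
  sp2 <- species_ids(destination)
  t1 <- origin$taxa[match(sp1, origin$taxa$taxon_id), ]
  t2 <- destination$taxa[match(sp2, destination$taxa$taxon_id), ]
  key1 <- setNames(concept_key(t1$name, t1$author, t1$year, lenient), sp1)
  key2 <- setNames(concept_key(t2$name, t2$author, t2$year, lenient), sp2)
  idx1 <- index_concepts(origin, lenient)
  idx2 <- index_concepts(destination, lenient)
  syn_keys <- function(tbl, i) {
    syn <- tbl$synonyms[[i]]
    if (nrow(syn) == 0) character() else
      concept_key(syn$full_name, syn$author, syn$year, lenient)
  }
  hits <- function(idx, keys) {
    a <- unname(idx$accepted[keys])
    c(a[!is.na(a)], unlist(idx$via_synonym[keys], use.names = FALSE))
  }
  # association is symmetric: two species are linked when their accepted
  # keys are equal or either one cites the other's accepted name as a
  # synonym, so role inversion preserves the evidence
  m1 <- lapply(seq_along(sp1), function(i) {
    unique(c(hits(idx2, key1[[i]]),
             unname(idx2$accepted[syn_keys(t1, i)])))
  })
  m1 <- lapply(m1, function(x) x[!is.na(x)])
  names(m1) <- sp1
  m2 <- lapply(seq_along(sp2), function(j) {
    unique(c(hits(idx1, key2[[j]]),
             unname(idx1$accepted[syn_keys(t2, j)])))
  })
  m2 <- lapply(m2, function(x) x[!is.na(x)])
  names(m2) <- sp2

  genus1 <- vapply(sp1, function(id) parent_genus_name(origin, id),
                   character(1))
  genus2 <- vapply(sp2, function(id) parent_genus_name(destination, id),
                   character(1))

  relations <- list()
  conflicts <- list()
  add_rel <- function(type, o, d) {
    relations[[length(relations) + 1]] <<- tibble::tibble(
      type = type, origin_ids = list(o), destination_ids = list(d))
  }
  add_conf <- function(ids, side, reason) {
    conflicts[[length(conflicts) + 1]] <<- tibble::tibble(
      taxon_id = ids, side = side, reason = reason)
  }
  claimed1 <- character()
  claimed2 <- character()

  for (x in sp1) {
    if (x %in% claimed1) next
    partners <- m1[[x]]
    if (length(partners) == 0) {
      add_rel("excluded", x, character())
      claimed1 <- c(claimed1, x)
    } else if (length(partners) >= 2) {
      back <- unique(unlist(m2[partners]))
      if (setequal(back, x)) {
        add_rel("split", x, partners)
        claimed1 <- c(claimed1, x)
        claimed2 <- c(claimed2, partners)
      } else {
        add_conf(x, "origin", "split and merge evidence for the same taxa")
        add_conf(partners, "destination",
                 "split and merge evidence for the same taxa")
        claimed1 <- c(claimed1, x, setdiff(back, x))
        claimed2 <- c(claimed2, partners)
      }
    } else {
      s <- partners
      sources <- m2[[s]]
      if (length(sources) >= 2) {
        fan_out <- unique(unlist(m1[sources]))
        if (setequal(fan_out, s)) {
          add_rel("merge", sources, s)
          claimed1 <- c(claimed1, sources)
          claimed2 <- c(claimed2, s)
        } else {
          add_conf(sources, "origin",
                   "split and merge evidence for the same taxa")
          add_conf(s, "destination",
                   "split and merge evidence for the same taxa")
          claimed1 <- c(claimed1, sources)
          claimed2 <- c(claimed2, s, setdiff(fan_out, s))
        }
      } else {
        j <- match(s, sp2)
        i <- match(x, sp1)
        same_key <- key1[[x]] ==
          concept_key(t2$name[j], t2$author[j], t2$year[j], lenient)
        same_genus <- genus1[[i]] == genus2[[j]]
        if (same_key) {
          add_rel(if (same_genus) "congruent" else "move", x, s)
          claimed1 <- c(claimed1, x)
          claimed2 <- c(claimed2, s)
        } else {
          same_epithet <- epithet_part(t1$name[i]) == epithet_part(t2$name[j])
          if (same_genus) {
            add_rel("rename", x, s)
            claimed1 <- c(claimed1, x)
            claimed2 <- c(claimed2, s)
          } else if (same_epithet) {
            add_rel("move", x, s)
            claimed1 <- c(claimed1, x)
            claimed2 <- c(claimed2, s)
          } else {
            add_conf(x, "origin",
                     "simultaneous epithet and placement change")
            add_conf(s, "destination",
                     "simultaneous epithet and placement change")
            claimed1 <- c(claimed1, x)
            claimed2 <- c(claimed2, s)
          }
        }
      }
    }
  }
  for (s in setdiff(sp2, claimed2)) {
    add_rel("added", character(), s)
  }
  comparison(
    origin, destination,
    dplyr::bind_rows(c(list(empty_relations()), relations)),
    if (length(conflicts) == 0) empty_conflicts() else
      dplyr::bind_rows(conflicts)
  )
}
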