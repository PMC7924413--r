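#' The seven taxonomic change types
#'
#' Typed relations between species of two taxonomy versions: `congruent`
#' (same concept in both), `split` (one origin species to two or more
#' destination species), `merge` (two or more origin species to one),
#' `move` (re-classified under a different genus), `rename` (epithet
#' corrected in place), `added` (present only in the destination) and
#' `excluded` (present only in the origin). "All" is a filtering concept,
#' not a change type.
#'
#' @format Character vector of length 7.
#' @export
CHANGE_TYPES <- c("congruent", "split", "merge", "move", "rename",
                  "added", "excluded")

# Expected arities (origin side, destination side); NA means ">= 2".
change_arity <- list(
  congruent = c(1, 1), split = c(1, NA), merge = c(NA, 1),
  move = c(1, 1), rename = c(1, 1), added = c(0, 1), excluded = c(1, 0)
)

#' Create a comparison between two taxonomy versions
#'
#' A comparison binds an origin taxonomy (T1), a destination taxonomy
#' (T2) and an ordered list of typed relations between their species.
#' In a valid comparison the relations partition both species sets:
#' every T1 species sits on the origin side of exactly one relation and
#' every T2 species on the destination side of exactly one (congruences
#' are materialized explicitly, not implied). Only species-rank taxa
#' participate; changes at higher ranks are out of scope.
#'
#' @param origin,destination [taxonomy()] objects (T1 and T2).
#' @param relations A data frame with columns `type` (one of
#'   [CHANGE_TYPES]), `origin_ids` and `destination_ids` (list columns of
#'   character vectors of species identifiers).
#' @param conflicts Optional tibble of unresolved classification
#'   conflicts (see [diff_taxonomies()]); taxa listed here appear in no
#'   relation.
#' @return An object of class `comparison`.
#' @seealso [validate_comparison()], [summarize_changes()],
#'   [diff_taxonomies()]
#' @export
comparison <- function(origin, destination, relations,
                       conflicts = empty_conflicts()) {
  assert_taxonomy(origin, "origin")
  assert_taxonomy(destination, "destination")
  relations <- tibble::as_tibble(relations)
  if (nrow(relations) == 0 && !all(c("type", "origin_ids", "destination_ids")
                                   %in% names(relations))) {
    relations <- empty_relations()
  }
  relations$type <- as.character(relations$type)
  relations$origin_ids <- lapply(relations$origin_ids, as.character)
  relations$destination_ids <- lapply(relations$destination_ids, as.character)
  origin$role <- "origin"
  destination$role <- "destination"
  structure(
    list(origin = origin, destination = destination,
         relations = relations, conflicts = tibble::as_tibble(conflicts)),
    class = "comparison"
  )
}

empty_relations <- function() {
  tibble::tibble(type = character(), origin_ids = list(),
                 destination_ids = list())
}

empty_conflicts <- function() {
  tibble::tibble(taxon_id = character(), side = character(),
                 reason = character())
}

is_comparison <- function(x) inherits(x, "comparison")

assert_comparison <- function(x, arg = "comparison") {
  if (!is_comparison(x)) abort(paste0("`", arg, "` must be a comparison"))
  invisible(x)
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %d relations (%d conflicts)\n",
              nrow(x$relations), nrow(x$conflicts)))
  s <- summarize_changes(x)
  print(s)
  invisible(x)
}

#' Validate a comparison's arity and coverage rules
#'
#' Checks, without raising, that a comparison is internally consistent:
#' each relation's arity matches its type (1-to-1 for congruent, move and
#' rename; 1-to-many for split; many-to-1 for merge; one-sided for added
#' and excluded), every referenced identifier is a species of the
#' corresponding taxonomy, and the relations cover each species of both
#' versions exactly once (the one-change-per-taxon rule). An empty result
#' means the comparison is valid.
#'
#' @param comparison A [comparison()] object.
#' @return A tibble with columns `rule`, `relation_index`, `taxon_id`,
#'   `message`; zero rows when valid.
#' @export
validate_comparison <- function(comparison) {
  assert_comparison(comparison)
  rel <- comparison$relations
  sp1 <- species_ids(comparison$origin)
  sp2 <- species_ids(comparison$destination)
  v <- list()
  add <- function(rule, relation_index, taxon_id, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      rule = rule, relation_index = as.integer(relation_index),
      taxon_id = taxon_id, message = message)
  }
  for (i in seq_len(nrow(rel))) {
    ty <- rel$type[i]
    o <- rel$origin_ids[[i]]
    d <- rel$destination_ids[[i]]
    if (!ty %in% CHANGE_TYPES) {
      add("unknown_type", i, NA_character_, paste0("type '", ty, "'"))
      next
    }
    ar <- change_arity[[ty]]
    ok_o <- if (is.na(ar[1])) length(o) >= 2 else length(o) == ar[1]
    ok_d <- if (is.na(ar[2])) length(d) >= 2 else length(d) == ar[2]
    if (!ok_o || !ok_d) {
      add("arity", i, NA_character_,
          sprintf("%s relation with %d origin and %d destination taxa",
                  ty, length(o), length(d)))
    }
    for (id in setdiff(o, sp1)) {
      add("not_origin_species", i, id,
          "origin id is not a species of the origin taxonomy")
    }
    for (id in setdiff(d, sp2)) {
      add("not_destination_species", i, id,
          "destination id is not a species of the destination taxonomy")
    }
  }
  all_o <- unlist(rel$origin_ids)
  all_d <- unlist(rel$destination_ids)
  for (id in unique(all_o[duplicated(all_o)])) {
    add("multiple_changes", NA, id, "origin species in more than one relation")
  }
  for (id in unique(all_d[duplicated(all_d)])) {
    add("multiple_changes", NA, id,
        "destination species in more than one relation")
  }
  conflicted1 <- comparison$conflicts$taxon_id[
    comparison$conflicts$side == "origin"]
  conflicted2 <- comparison$conflicts$taxon_id[
    comparison$conflicts$side == "destination"]
  for (id in setdiff(sp1, c(all_o, conflicted1))) {
    add("uncovered_taxon", NA, id, "origin species covered by no relation")
  }
  for (id in setdiff(sp2, c(all_d, conflicted2))) {
    add("uncovered_taxon", NA, id,
        "destination species covered by no relation")
  }
  if (length(v) == 0) {
    tibble::tibble(rule = character(), relation_index = integer(),
                   taxon_id = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Count relations by change type
#'
#' Produces the numerical summary curators ask for ("how much changed?"):
#' the number of relations of each type, congruences counted like any
#' other type, plus their total.
#'
#' @param comparison A [comparison()] object.
#' @return An object of class `change_summary`: a list with `counts`
#'   (named integer vector over [CHANGE_TYPES]) and `relation_total`.
#' @export
summarize_changes <- function(comparison) {
  assert_comparison(comparison)
  counts <- table(factor(comparison$relations$type, levels = CHANGE_TYPES))
  counts <- setNames(as.integer(counts), CHANGE_TYPES)
  structure(list(counts = counts, relation_total = sum(counts)),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat("<change summary>\n")
  for (t in CHANGE_TYPES) cat(sprintf("  %-10s %d\n", t, x$counts[[t]]))
  cat(sprintf("  total      %d\n", x$relation_total))
  invisible(x)
}

#' Restrict a comparison to selected change types
#'
#' The analogue of the per-type toggle buttons of a comparison interface:
#' keeps exactly the relations whose type is in `show`, in their original
#' order. Passing all seven types is the "all" toggle and returns the
#' relations unchanged; an empty `show` yields an empty relation list.
#' The result intentionally does not claim the coverage (partition)
#' property, since filtered-out species are covered by no retained
#' relation.
#'
#' @param comparison A [comparison()] object.
#' @param show Character vector of change types to keep.
#' @return A `comparison` with the restricted relation list.
#' @export
filter_by_types <- function(comparison, show) {
  assert_comparison(comparison)
  bad <- setdiff(show, CHANGE_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown change type(s): ", paste(bad, collapse = ", ")))
  }
  keep <- comparison$relations$type %in% show
  out <- comparison
  out$relations <- comparison$relations[keep, ]
  out
}

#' Find the relation a species participates in
#'
#' Answers "what happened to taxon t?": returns the single relation whose
#' origin or destination side contains the species (guaranteed unique in
#' a valid comparison), together with the side on which the taxon sits.
#'
#' @param comparison A valid [comparison()] object.
#' @param taxon_id A species identifier of either taxonomy version.
#' @return A list with `relation` (one-row tibble), `relation_index` and
#'   `side` (`"origin"` or `"destination"`).
#' @export
changes_for_taxon <- function(comparison, taxon_id) {
  assert_comparison(comparison)
  rel <- comparison$relations
  i_o <- which(vapply(rel$origin_ids, function(x) taxon_id %in% x,
                      logical(1)))
  i_d <- which(vapply(rel$destination_ids, function(x) taxon_id %in% x,
                      logical(1)))
  if (length(i_o) + length(i_d) == 0) {
    abort(paste0("taxon '", taxon_id,
                 "' is not a species of either version covered by a relation"),
          class = "taxodiff_lookup_error")
  }
  if (length(i_o) > 0) {
    list(relation = rel[i_o[1], ], relation_index = i_o[1], side = "origin")
  } else {
    list(relation = rel[i_d[1], ], relation_index = i_d[1],
         side = "destination")
  }
}

#' Most common change type(s) in a summary
#'
#' Returns every change type achieving the maximum count — a set rather
#' than an arbitrary pick, because ties are possible. Congruent relations
#' are excluded by default since "no change" is rarely the change of
#' interest.
#'
#' @param summary A `change_summary` from [summarize_changes()].
#' @param include_congruent Count congruences as a candidate type?
#' @return Character vector of change types (empty when all counts are
#'   zero).
#' @export
most_common_change_type <- function(summary, include_congruent = FALSE) {
  if (!inherits(summary, "change_summary")) {
    abort("`summary` must come from summarize_changes()")
  }
  counts <- summary$counts
  if (!include_congruent) counts <- counts[names(counts) != "congruent"]
  if (all(counts == 0)) return(character())
  names(counts)[counts == max(counts)]
}

#' Write a comparison's relations to JSON
#'
#' Serializes the relation list (and any conflicts) as
#' `{schema_version, origin_file, destination_file, relations: [...]}`.
#' The taxonomies themselves are stored separately; the JSON records the
#' file names they came from, when known.
#'
#' @param comparison A [comparison()] object.
#' @param path Output path.
#' @param origin_file,destination_file Optional provenance file names.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, origin_file = NA,
                             destination_file = NA) {
  assert_comparison(comparison)
  rel <- comparison$relations
  doc <- list(
    schema_version = "1",
    origin_file = if (is.na(origin_file)) NULL else origin_file,
    destination_file = if (is.na(destination_file)) NULL else destination_file,
    relations = purrr::pmap(rel, function(type, origin_ids, destination_ids) {
      list(type = type, origin_ids = as.list(origin_ids),
           destination_ids = as.list(destination_ids))
    }),
    conflicts = purrr::pmap(comparison$conflicts,
                            function(taxon_id, side, reason) {
      list(taxon_id = taxon_id, side = side, reason = reason)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a comparison's relations from JSON
#'
#' @param path Path to a JSON document written by [write_comparison()].
#' @param origin,destination The two [taxonomy()] objects the relations
#'   refer to.
#' @return A [comparison()] object.
#' @export
read_comparison <- function(path, origin, destination) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rel <- purrr::map_dfr(doc$relations %||% list(), function(r) {
    tibble::tibble(type = as.character(r$type),
                   origin_ids = list(as.character(unlist(r$origin_ids))),
                   destination_ids =
                     list(as.character(unlist(r$destination_ids))))
  })
  if (nrow(rel) == 0) rel <- empty_relations()
  conf <- purrr::map_dfr(doc$conflicts %||% list(), function(cf) {
    tibble::tibble(taxon_id = as.character(cf$taxon_id),
                   side = as.character(cf$side),
                   reason = as.character(cf$reason))
  })
  if (nrow(conf) == 0) conf <- empty_conflicts()
  comparison(origin, destination, rel, conf)
}

# Species bookkeeping identity linking the two versions' species counts:
# |S2| = |S1| - excluded - sum(merge widths - 1) + sum(split fanouts - 1)
#        + added. Used by tests and the generator's self-checks.
species_accounting_ok <- function(comparison) {
  rel <- comparison$relations
  n1 <- length(species_ids(comparison$origin))
  n2 <- length(species_ids(comparison$destination))
  widths <- vapply(rel$origin_ids[rel$type == "merge"], length, integer(1))
  fans <- vapply(rel$destination_ids[rel$type == "split"], length, integer(1))
  expected <- n1 - sum(rel$type == "excluded") - sum(widths - 1L) +
    sum(fans - 1L) + sum(rel$type == "added")
  n2 == expected
}
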