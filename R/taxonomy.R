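#' Taxonomic ranks, highest to lowest
#'
#' The ordered set of ranks supported by [taxonomy()] objects, from the
#' broadest (`domain`) to the narrowest (`species`). Rank order is total:
#' every taxon's parent must sit at a strictly higher rank, although ranks
#' may be skipped (e.g. a species directly under a family), as real
#' checklist exports frequently do.
#'
#' @format A character vector of length 8.
#' @export
TAXON_RANKS <- c(
  "domain", "kingdom", "phylum", "class", "order", "family", "genus", "species"
)

rank_level <- function(rank) match(rank, TAXON_RANKS)

#' Create a taxonomy object
#'
#' A taxonomy is a rooted, rank-ordered forest of taxa stored as a flat
#' table. Each row is one taxon with an opaque identifier, a parent
#' identifier (`NA` for roots), a rank, a scientific name with optional
#' authorship, and an ordered list of synonyms. Child order is the input
#' row order and is preserved by all operations and by file round trips;
#' no alphabetisation is ever applied.
#'
#' @param taxa A data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`, and optionally `author` (character), `year` (integer) and
#'   `synonyms` (a list column of data frames with columns `full_name`,
#'   `author`, `year`).
#' @param role Optional label, `"origin"` (the T1 version) or
#'   `"destination"` (T2).
#'
#' @return An object of class `taxonomy`.
#' @details Construction fails on schema-level defects: duplicate
#'   `taxon_id`, unknown rank tokens, unresolvable `parent_id`, or parent
#'   cycles. Softer structural rules (rank monotonicity, binomial form,
#'   synonym/accepted-name distinctness) are reported by
#'   [validate_taxonomy()] rather than raised, so that defective
#'   taxonomies can be inspected.
#' @seealso [read_taxonomy()], [validate_taxonomy()], [taxon_details()]
#' @export
#' @examples
#' cat_lineage <- tibble::tibble(
#'   taxon_id = paste0("t", 1:7),
#'   parent_id = c(NA, paste0("t", 1:6)),
#'   rank = c("kingdom", "phylum", "class", "order", "family", "genus", "species"),
#'   name = c("Animalia", "Chordata", "Mammalia", "Carnivora", "Felidae",
#'            "Feliz", "Feliz catus")
#' )
#' tx <- taxonomy(cat_lineage)
#' validate_taxonomy(tx)
taxonomy <- function(taxa, role = NA_character_) {
  taxa <- tibble::as_tibble(taxa)
  required <- c("taxon_id", "parent_id", "rank", "name")
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols) > 0) {
    abort(paste0("taxonomy table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"author" %in% names(taxa)) taxa$author <- NA_character_
  if (!"year" %in% names(taxa)) taxa$year <- NA_integer_
  if (!"synonyms" %in% names(taxa)) {
    taxa$synonyms <- replicate(nrow(taxa), empty_synonyms(), simplify = FALSE)
  }
  taxa$taxon_id <- as.character(taxa$taxon_id)
  taxa$parent_id <- as.character(taxa$parent_id)
  taxa$parent_id[!is.na(taxa$parent_id) & taxa$parent_id == ""] <- NA_character_
  taxa$rank <- as.character(taxa$rank)
  taxa$name <- as.character(taxa$name)
  taxa$author <- as.character(taxa$author)
  taxa$year <- suppressWarnings(as.integer(taxa$year))
  taxa$synonyms <- lapply(taxa$synonyms, as_synonym_tbl)

  dup <- taxa$taxon_id[duplicated(taxa$taxon_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate taxon_id: ", paste(unique(dup), collapse = ", ")),
          class = "taxodiff_schema_error")
  }
  bad_rank <- unique(taxa$rank[!taxa$rank %in% TAXON_RANKS])
  if (length(bad_rank) > 0) {
    abort(paste0("unknown rank token: ", paste(bad_rank, collapse = ", ")),
          class = "taxodiff_schema_error")
  }
  unresolved <- !is.na(taxa$parent_id) & !taxa$parent_id %in% taxa$taxon_id
  if (any(unresolved)) {
    abort(paste0("unresolvable parent_id for taxon ",
                 paste(taxa$taxon_id[unresolved], collapse = ", ")),
          class = "taxodiff_structure_error")
  }
  tx <- structure(list(taxa = taxa, role = role), class = "taxonomy")
  if (anyNA(depths(tx))) {
    abort("parent links contain a cycle", class = "taxodiff_structure_error")
  }
  tx
}

.empty_synonyms <- NULL

empty_synonyms <- function() {
  if (is.null(.empty_synonyms)) {
    # cached: one immutable zero-row tibble shared by every taxon
    utils::assignInMyNamespace(".empty_synonyms", tibble::tibble(
      full_name = character(), author = character(), year = integer()))
  }
  .empty_synonyms
}

as_synonym_tbl <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(empty_synonyms())
  if (tibble::is_tibble(x) &&
      identical(names(x), c("full_name", "author", "year")) &&
      is.character(x$full_name) && is.character(x$author) &&
      is.integer(x$year)) {
    return(x)
  }
  x <- tibble::as_tibble(x)
  if (!"author" %in% names(x)) x$author <- NA_character_
  if (!"year" %in% names(x)) x$year <- NA_integer_
  tibble::tibble(full_name = as.character(x$full_name),
                 author = as.character(x$author),
                 year = suppressWarnings(as.integer(x$year)))
}

#' @export
print.taxonomy <- function(x, ...) {
  n_sp <- sum(x$taxa$rank == "species")
  cat(sprintf("<taxonomy> %d taxa (%d species)%s\n", nrow(x$taxa), n_sp,
              if (!is.na(x$role)) paste0(", role = ", x$role) else ""))
  print(utils::head(x$taxa, 10))
  invisible(x)
}

#' @export
format.taxonomy <- function(x, ...) {
  sprintf("<taxonomy: %d taxa>", nrow(x$taxa))
}

is_taxonomy <- function(x) inherits(x, "taxonomy")

assert_taxonomy <- function(x, arg = "taxonomy") {
  if (!is_taxonomy(x)) abort(paste0("`", arg, "` must be a taxonomy object"))
  invisible(x)
}

root_ids <- function(tx) tx$taxa$taxon_id[is.na(tx$taxa$parent_id)]

species_ids <- function(tx) tx$taxa$taxon_id[tx$taxa$rank == "species"]

taxon_row <- function(tx, taxon_id) {
  i <- match(taxon_id, tx$taxa$taxon_id)
  if (is.na(i)) {
    abort(paste0("unknown taxon_id: ", taxon_id),
          class = "taxodiff_lookup_error")
  }
  tx$taxa[i, ]
}

# Depth of every taxon (root depth 0), NA when an ancestor chain cycles.
depths <- function(tx) {
  ids <- tx$taxa$taxon_id
  parent <- tx$taxa$parent_id
  idx <- match(parent, ids)
  d <- rep(NA_integer_, length(ids))
  d[is.na(parent)] <- 0L
  n <- length(ids)
  for (pass in seq_len(n)) {
    todo <- which(is.na(d) & !is.na(idx))
    if (length(todo) == 0) break
    ready <- todo[!is.na(d[idx[todo]])]
    if (length(ready) == 0) break
    d[ready] <- d[idx[ready]] + 1L
  }
  d
}

# Taxon ids in preorder: parents before children, siblings in table order.
preorder_ids <- function(tx) {
  ids <- tx$taxa$taxon_id
  kids <- split(ids, factor(tx$taxa$parent_id, levels = ids))
  out <- character(length(ids))
  n <- 0L
  stack <- rev(root_ids(tx))
  while (length(stack) > 0) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    n <- n + 1L
    out[n] <- id
    ch <- kids[[id]]
    if (!is.null(ch) && length(ch) > 0) stack <- c(stack, rev(ch))
  }
  out[seq_len(n)]
}

# Ancestor chain root -> taxon (inclusive), as a vector of ids.
lineage_ids <- function(tx, taxon_id) {
  ids <- tx$taxa$taxon_id
  parent <- tx$taxa$parent_id
  i <- match(taxon_id, ids)
  if (is.na(i)) {
    abort(paste0("unknown taxon_id: ", taxon_id),
          class = "taxodiff_lookup_error")
  }
  chain <- character()
  while (!is.na(i)) {
    chain <- c(ids[i], chain)
    i <- match(parent[i], ids)
  }
  chain
}

# The nearest ancestor (or self) at `rank`, NA_character_ when absent.
ancestor_at_rank <- function(tx, taxon_id, rank) {
  chain <- lineage_ids(tx, taxon_id)
  rk <- tx$taxa$rank[match(chain, tx$taxa$taxon_id)]
  hit <- chain[rk == rank]
  if (length(hit) == 0) NA_character_ else hit[[length(hit)]]
}

# Parent genus name of a species (the genus node's accepted name),
# falling back to the binomial's genus part when no genus ancestor exists.
parent_genus_name <- function(tx, taxon_id) {
  g <- ancestor_at_rank(tx, taxon_id, "genus")
  if (!is.na(g) && g != taxon_id) {
    tx$taxa$name[match(g, tx$taxa$taxon_id)]
  } else {
    genus_part(tx$taxa$name[match(taxon_id, tx$taxa$taxon_id)])
  }
}

genus_part <- function(full_name) {
  vapply(strsplit(full_name, " +"), function(p) p[[1]], character(1))
}

epithet_part <- function(full_name) {
  vapply(strsplit(full_name, " +"),
         function(p) if (length(p) >= 2) paste(p[-1], collapse = " ") else "",
         character(1))
}

#' Validate the structural invariants of a taxonomy
#'
#' Checks every structural rule a well-formed taxonomy must satisfy and
#' returns the violations as a table instead of raising, so that broken
#' inputs can be triaged. An empty result means the taxonomy is valid.
#'
#' Rules checked: unique identifiers; known rank tokens; resolvable,
#' acyclic parent links; parent rank strictly higher than the taxon's own
#' rank (skipping intermediate ranks is allowed); species names in
#' binomial form (exactly one genus part and one epithet); synonyms
#' distinct from the bearer's accepted name.
#'
#' @param taxonomy A [taxonomy()] object.
#' @return A tibble with columns `taxon_id`, `rule`, `message`; zero rows
#'   when the taxonomy is valid.
#' @export
validate_taxonomy <- function(taxonomy) {
  assert_taxonomy(taxonomy)
  taxa <- taxonomy$taxa
  v <- list()
  add <- function(taxon_id, rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      taxon_id = taxon_id, rule = rule, message = message)
  }
  dup <- unique(taxa$taxon_id[duplicated(taxa$taxon_id)])
  for (id in dup) add(id, "duplicate_id", "taxon_id occurs more than once")
  bad_rank <- which(!taxa$rank %in% TAXON_RANKS)
  for (i in bad_rank) {
    add(taxa$taxon_id[i], "unknown_rank", paste0("rank '", taxa$rank[i], "'"))
  }
  unresolved <- which(!is.na(taxa$parent_id) &
                        !taxa$parent_id %in% taxa$taxon_id)
  for (i in unresolved) {
    add(taxa$taxon_id[i], "unresolved_parent",
        paste0("parent '", taxa$parent_id[i], "' not present"))
  }
  d <- depths(taxonomy)
  cyc <- which(is.na(d) & !is.na(taxa$parent_id) &
                 taxa$parent_id %in% taxa$taxon_id)
  for (i in cyc) add(taxa$taxon_id[i], "cycle", "parent chain forms a cycle")

  pidx <- match(taxa$parent_id, taxa$taxon_id)
  own <- rank_level(taxa$rank)
  par <- rank_level(taxa$rank[pidx])
  bad_order <- which(!is.na(pidx) & !is.na(own) & !is.na(par) & par >= own)
  for (i in bad_order) {
    add(taxa$taxon_id[i], "rank_order",
        paste0("parent rank '", taxa$rank[pidx[i]],
               "' is not higher than '", taxa$rank[i], "'"))
  }
  sp <- which(taxa$rank == "species")
  parts <- strsplit(taxa$name[sp], " +")
  bad_binomial <- sp[vapply(parts, length, integer(1)) != 2]
  for (i in bad_binomial) {
    add(taxa$taxon_id[i], "binomial_form",
        paste0("species name '", taxa$name[i],
               "' is not a two-part binomial"))
  }
  for (i in seq_len(nrow(taxa))) {
    syn <- taxa$synonyms[[i]]
    if (nrow(syn) > 0 && any(syn$full_name == taxa$name[i])) {
      add(taxa$taxon_id[i], "synonym_equals_accepted",
          "a synonym repeats the accepted name")
    }
  }
  if (length(v) == 0) {
    tibble::tibble(taxon_id = character(), rule = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Scan a taxonomy for curation inconsistencies
#'
#' Beyond structural validity, curators look for rule violations in the
#' data itself: repeated names, missing attribution, and binomials that
#' disagree with their placement. This reports three kinds of finding:
#'
#' * `repeated_name` — two or more taxa at the same rank share an accepted
#'   name (one finding per name, listing all bearers);
#' * `missing_attribution` — a species lacking its author or year of
#'   publication, without which the taxonomic judgment cannot be traced;
#' * `binomial_genus_mismatch` — a species whose binomial's genus part
#'   differs from the name of its ancestral genus.
#'
#' @param taxonomy A structurally valid [taxonomy()] object.
#' @return A tibble with columns `finding`, `taxon_ids` (list column of
#'   implicated identifiers) and `message`; zero rows when clean.
#' @export
find_inconsistencies <- function(taxonomy) {
  assert_taxonomy(taxonomy)
  taxa <- taxonomy$taxa
  out <- list()
  add <- function(finding, taxon_ids, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      finding = finding, taxon_ids = list(taxon_ids), message = message)
  }
  key <- paste(taxa$rank, taxa$name, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    ids <- taxa$taxon_id[key == k]
    add("repeated_name", ids,
        paste0("name '", taxa$name[match(ids[1], taxa$taxon_id)],
               "' repeated at rank ", taxa$rank[match(ids[1], taxa$taxon_id)]))
  }
  sp <- which(taxa$rank == "species")
  for (i in sp) {
    no_author <- is.na(taxa$author[i]) || !nzchar(trimws(taxa$author[i]))
    if (no_author || is.na(taxa$year[i])) {
      add("missing_attribution", taxa$taxon_id[i],
          paste0("species '", taxa$name[i], "' lacks author and/or year"))
    }
  }
  for (i in sp) {
    g <- ancestor_at_rank(taxonomy, taxa$taxon_id[i], "genus")
    if (!is.na(g)) {
      gname <- taxa$name[match(g, taxa$taxon_id)]
      if (genus_part(taxa$name[i]) != gname) {
        add("binomial_genus_mismatch", taxa$taxon_id[i],
            paste0("species '", taxa$name[i], "' placed under genus '",
                   gname, "'"))
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(finding = character(), taxon_ids = list(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Retrieve the full record of one taxon
#'
#' Returns the attributes a curator inspects when focusing on a single
#' concept: its accepted name with authorship, rank, synonym list, and
#' full lineage from the root down to the taxon itself.
#'
#' @param taxonomy A [taxonomy()] object.
#' @param taxon_id Identifier of the taxon to look up.
#' @return A list with elements `taxon_id`, `name`, `author`, `year`,
#'   `rank`, `synonyms` (tibble) and `lineage` (tibble with `taxon_id`,
#'   `rank`, `name`, ordered root to taxon).
#' @export
taxon_details <- function(taxonomy, taxon_id) {
  assert_taxonomy(taxonomy)
  row <- taxon_row(taxonomy, taxon_id)
  chain <- lineage_ids(taxonomy, taxon_id)
  idx <- match(chain, taxonomy$taxa$taxon_id)
  list(
    taxon_id = row$taxon_id,
    name = row$name,
    author = row$author,
    year = row$year,
    rank = row$rank,
    synonyms = row$synonyms[[1]],
    lineage = tibble::tibble(
      taxon_id = chain,
      rank = taxonomy$taxa$rank[idx],
      name = taxonomy$taxa$name[idx]
    )
  )
}
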