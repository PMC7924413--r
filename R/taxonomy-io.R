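#' Read a taxonomy from CSV or JSON
#'
#' The CSV schema is a UTF-8 comma-delimited table with a header row and
#' columns exactly `taxon_id,parent_id,rank,name,author,year,synonyms`.
#' `parent_id` is empty for roots. The `synonyms` field holds entries
#' joined by `";"`, each entry `"full_name|author|year"` with empty
#' sub-fields allowed; literal `";"` or `"|"` inside a name are
#' backslash-escaped on write and unescaped here. Standard CSV quoting
#' applies to the field as a whole. The JSON schema is
#' `{schema_version, role, taxa: [...]}` with nested name and synonym
#' objects; `schema_version` starts at `"1"`.
#'
#' Input row order is preserved as child order.
#'
#' @param path Path to the document.
#' @param format `"csv"` or `"json"`; by default inferred from the file
#'   extension.
#' @param role Optional role label (`"origin"` or `"destination"`)
#'   overriding any role stored in the document.
#' @return A [taxonomy()] object.
#' @seealso [write_taxonomy()]
#' @export
read_taxonomy <- function(path, format = c("auto", "csv", "json"),
                          role = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    cols <- readr::cols(
      taxon_id = readr::col_character(),
      parent_id = readr::col_character(),
      rank = readr::col_character(),
      name = readr::col_character(),
      author = readr::col_character(),
      year = readr::col_integer(),
      synonyms = readr::col_character()
    )
    df <- readr::read_csv(path, col_types = cols, progress = FALSE)
    need <- c("taxon_id", "parent_id", "rank", "name", "author", "year",
              "synonyms")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("taxonomy CSV lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "taxodiff_schema_error")
    }
    df$synonyms <- lapply(df$synonyms, parse_synonym_field)
    stored_role <- NA_character_
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$taxa)) {
      abort("taxonomy JSON lacks a 'taxa' array",
            class = "taxodiff_schema_error")
    }
    scal <- function(x, default) {
      if (is.null(x) || length(x) == 0) default else x
    }
    df <- purrr::map_dfr(doc$taxa, function(t) {
      tibble::tibble(
        taxon_id = as.character(t$taxon_id),
        parent_id = as.character(scal(t$parent_id, NA_character_)),
        rank = as.character(t$rank),
        name = as.character(t$name$full_name),
        author = as.character(scal(t$name$author, NA_character_)),
        year = as.integer(scal(t$name$year, NA_integer_)),
        synonyms = list(purrr::map_dfr(scal(t$synonyms, list()),
                                       function(s) {
          tibble::tibble(full_name = as.character(s$full_name),
                         author = as.character(scal(s$author,
                                                    NA_character_)),
                         year = as.integer(scal(s$year, NA_integer_)))
        }))
      )
    })
    stored_role <- as.character(scal(doc$role, NA_character_))
  }
  taxonomy(df, role = role %||% stored_role)
}

#' Write a taxonomy to CSV or JSON
#'
#' Emits rows in preorder (parents before children, siblings in stored
#' child order), so that reading the document back reproduces the
#' taxonomy field for field. Synonym entries are serialized as
#' `"full_name|author|year"` joined by `";"`; literal `";"`, `"|"` or
#' backslashes inside sub-fields are backslash-escaped rather than
#' dropped.
#'
#' @param taxonomy A [taxonomy()] object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path, format = c("auto", "csv", "json")) {
  assert_taxonomy(taxonomy)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  ord <- match(preorder_ids(taxonomy), taxonomy$taxa$taxon_id)
  taxa <- taxonomy$taxa[ord, ]
  if (format == "csv") {
    df <- tibble::tibble(
      taxon_id = taxa$taxon_id,
      parent_id = taxa$parent_id,
      rank = taxa$rank,
      name = taxa$name,
      author = taxa$author,
      year = taxa$year,
      synonyms = vapply(taxa$synonyms, format_synonym_field, character(1))
    )
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    doc <- purrr::compact(list(
      schema_version = "1",
      role = if (is.na(taxonomy$role)) NULL else taxonomy$role,
      taxa = purrr::pmap(taxa, function(taxon_id, parent_id, rank, name,
                                        author, year, synonyms, ...) {
        purrr::compact(list(
          taxon_id = taxon_id,
          parent_id = if (is.na(parent_id)) NULL else parent_id,
          rank = rank,
          name = purrr::compact(
            list(full_name = name,
                 author = if (is.na(author)) NULL else author,
                 year = if (is.na(year)) NULL else year)),
          synonyms = purrr::pmap(synonyms, function(full_name, author,
                                                    year) {
            purrr::compact(
              list(full_name = full_name,
                   author = if (is.na(author)) NULL else author,
                   year = if (is.na(year)) NULL else year))
          })
        ))
      })
    ))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

escape_syn <- function(x) {
  gsub("([;|\\\\])", "\\\\\\1", x)
}

unescape_syn <- function(x) {
  gsub("\\\\(.)", "\\1", x)
}

format_synonym_field <- function(syn) {
  if (nrow(syn) == 0) return("")
  entries <- vapply(seq_len(nrow(syn)), function(i) {
    paste(escape_syn(syn$full_name[i]),
          if (is.na(syn$author[i])) "" else escape_syn(syn$author[i]),
          if (is.na(syn$year[i])) "" else as.character(syn$year[i]),
          sep = "|")
  }, character(1))
  paste(entries, collapse = ";")
}

# Split on unescaped delimiters only (an escaped "\;" stays inside a name).
split_unescaped <- function(x, delim) {
  chars <- strsplit(x, "")[[1]]
  parts <- character()
  buf <- character()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      buf <- c(buf, ch, chars[i + 1])
      i <- i + 2
    } else if (ch == delim) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character()
      i <- i + 1
    } else {
      buf <- c(buf, ch)
      i <- i + 1
    }
  }
  c(parts, paste(buf, collapse = ""))
}

parse_synonym_field <- function(field) {
  if (is.na(field) || !nzchar(field)) return(empty_synonyms())
  entries <- split_unescaped(field, ";")
  purrr::map_dfr(entries, function(e) {
    sub <- split_unescaped(e, "|")
    length(sub) <- 3
    tibble::tibble(
      full_name = unescape_syn(sub[1] %||% ""),
      author = if (is.na(sub[2]) || !nzchar(sub[2])) NA_character_ else
        unescape_syn(sub[2]),
      year = if (is.na(sub[3]) || !nzchar(sub[3])) NA_integer_ else
        suppressWarnings(as.integer(sub[3]))
    )
  })
}
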