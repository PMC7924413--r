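# The four comparison layouts. All four consume a comparison plus a set
# of change types to show (the toggle-button filter) and produce pure
# data structures; rendering to SVG lives in render.R.

#' Indented-list rows of a taxonomy
#'
#' Taxonomies are displayed as indented lists: one row per taxon in
#' preorder (parents before children, siblings in stored child order),
#' indented by depth. Row indices (`y_index`) are consecutive from 0.
#'
#' @param taxonomy A [taxonomy()] object.
#' @return An object of class `row_layout`: a tibble with columns
#'   `taxon_id`, `rank`, `depth`, `label`, `y_index`.
#' @export
indented_rows <- function(taxonomy) {
  assert_taxonomy(taxonomy)
  ids <- preorder_ids(taxonomy)
  idx <- match(ids, taxonomy$taxa$taxon_id)
  d <- depths(taxonomy)[idx]
  out <- tibble::tibble(
    taxon_id = ids,
    rank = taxonomy$taxa$rank[idx],
    depth = d,
    label = taxonomy$taxa$name[idx],
    y_index = seq_along(ids) - 1L
  )
  class(out) <- c("row_layout", class(out))
  out
}

# relation table expanded to one row per (origin, destination) pair,
# restricted to two-sided relation types in `show`
expand_pairs <- function(relations, show) {
  two_sided <- c("congruent", "split", "merge", "move", "rename")
  keep <- relations$type %in% intersect(show, two_sided)
  rel <- relations[keep, ]
  if (nrow(rel) == 0) {
    return(tibble::tibble(origin_id = character(),
                          destination_id = character(), type = character()))
  }
  purrr::map_dfr(seq_len(nrow(rel)), function(i) {
    tidyr::expand_grid(origin_id = rel$origin_ids[[i]],
                       destination_id = rel$destination_ids[[i]]) |>
      dplyr::mutate(type = rel$type[i])
  })
}

one_sided_marks <- function(relations, show) {
  marks <- list()
  if ("excluded" %in% show) {
    ids <- unlist(relations$origin_ids[relations$type == "excluded"])
    if (length(ids) > 0) {
      marks[[length(marks) + 1]] <- tibble::tibble(
        side = "origin", taxon_id = ids, type = "excluded")
    }
  }
  if ("added" %in% show) {
    ids <- unlist(relations$destination_ids[relations$type == "added"])
    if (length(ids) > 0) {
      marks[[length(marks) + 1]] <- tibble::tibble(
        side = "destination", taxon_id = ids, type = "added")
    }
  }
  if (length(marks) == 0) {
    tibble::tibble(side = character(), taxon_id = character(),
                   type = character())
  } else {
    dplyr::bind_rows(marks)
  }
}

#' Edge-drawing layout of a comparison
#'
#' Juxtaposes the two versions as indented lists (T1 left, T2 right) and
#' connects related species with one typed edge per
#' (origin, destination) pair — a split of `x` into `p`, `q`, `r` yields
#' three edges from `x`'s row. Additions and exclusions involve only one
#' side and therefore produce node marks (on the T2 and T1 list
#' respectively) instead of edges.
#'
#' @param comparison A valid [comparison()] object.
#' @param show Change types to display; defaults to all seven.
#' @return An object of class `edge_layout`: a list with `left` and
#'   `right` [indented_rows()] layouts, `edges` (tibble `origin_id`,
#'   `destination_id`, `origin_row`, `destination_row`, `type`) and
#'   `node_marks` (tibble `side`, `taxon_id`, `row`, `type`).
#' @export
build_edge_drawing <- function(comparison, show = CHANGE_TYPES) {
  assert_comparison(comparison)
  left <- indented_rows(comparison$origin)
  right <- indented_rows(comparison$destination)
  pairs <- expand_pairs(comparison$relations, show)
  edges <- tibble::tibble(
    origin_id = pairs$origin_id,
    destination_id = pairs$destination_id,
    origin_row = left$y_index[match(pairs$origin_id, left$taxon_id)],
    destination_row = right$y_index[match(pairs$destination_id,
                                          right$taxon_id)],
    type = pairs$type
  )
  marks <- one_sided_marks(comparison$relations, show)
  marks$row <- ifelse(
    marks$side == "origin",
    left$y_index[match(marks$taxon_id, left$taxon_id)],
    right$y_index[match(marks$taxon_id, right$taxon_id)]
  )
  structure(list(left = left, right = right, edges = edges,
                 node_marks = marks),
            class = "edge_layout")
}

#' Matrix layout of a comparison
#'
#' Cross-tabulates the two versions: T1 rows run down the vertical axis,
#' T2 columns across the top. Every (origin, destination) pair of a
#' displayed two-sided relation becomes one typed cell — the same split
#' of `x` into `p`, `q`, `r` appears as cells (x;p), (x;q), (x;r) —
#' while additions and exclusions become marks in the margin of their
#' own axis. Congruent pairs, when shown, produce congruent-hue cells.
#'
#' @inheritParams build_edge_drawing
#' @return An object of class `matrix_layout`: a list with `row_axis`
#'   and `col_axis` [indented_rows()] layouts, `cells` (tibble `row`,
#'   `col`, `origin_id`, `destination_id`, `type`) and `margin_marks`
#'   (tibble `axis`, `index`, `taxon_id`, `type`).
#' @export
build_matrix <- function(comparison, show = CHANGE_TYPES) {
  assert_comparison(comparison)
  row_axis <- indented_rows(comparison$origin)
  col_axis <- indented_rows(comparison$destination)
  pairs <- expand_pairs(comparison$relations, show)
  cells <- tibble::tibble(
    row = row_axis$y_index[match(pairs$origin_id, row_axis$taxon_id)],
    col = col_axis$y_index[match(pairs$destination_id, col_axis$taxon_id)],
    origin_id = pairs$origin_id,
    destination_id = pairs$destination_id,
    type = pairs$type
  )
  marks <- one_sided_marks(comparison$relations, show)
  margin <- tibble::tibble(
    axis = ifelse(marks$side == "origin", "row", "col"),
    index = ifelse(
      marks$side == "origin",
      row_axis$y_index[match(marks$taxon_id, row_axis$taxon_id)],
      col_axis$y_index[match(marks$taxon_id, col_axis$taxon_id)]
    ),
    taxon_id = marks$taxon_id,
    type = marks$type
  )
  structure(list(row_axis = row_axis, col_axis = col_axis, cells = cells,
                 margin_marks = margin),
            class = "matrix_layout")
}

#' Agglomerated layout of a comparison
#'
#' Interleaves both versions into one integrated indented list. Taxa
#' present identically in both versions (higher taxa matched by rank,
#' name and lineage; congruent species) occupy a single shared row;
#' every other participant appears as a side-specific row carrying the
#' light variant of its change-type hue when it belongs to the origin
#' (T1) and the dark variant when it belongs to the destination (T2) —
#' a split shows `x` in light pink followed by its products in dark
#' pink. The origin rows read in T1 order and the destination rows in
#' T2 order; filtering with `show` only blanks the colour annotation of
#' hidden types, it never removes rows.
#'
#' @inheritParams build_edge_drawing
#' @return An object of class `agglo_layout`: a tibble with columns
#'   `origin_id`, `destination_id`, `side`
#'   (`origin`/`destination`/`shared`), `rank`, `depth`, `label`, `type`,
#'   `variant` (`light`/`dark`/`base` or `NA`), `y_index`.
#' @export
build_agglomeration <- function(comparison, show = CHANGE_TYPES) {
  assert_comparison(comparison)
  left <- indented_rows(comparison$origin)
  right <- indented_rows(comparison$destination)
  rel <- comparison$relations

  # shared pairs: congruent species ...
  cong <- rel[rel$type == "congruent", ]
  shared_map <- setNames(
    vapply(cong$destination_ids, function(x) x[[1]], character(1)),
    vapply(cong$origin_ids, function(x) x[[1]], character(1))
  )
  # ... plus higher taxa matched on (rank, name, lineage-of-names)
  sig <- function(tx, ids) {
    vapply(ids, function(id) {
      chain <- lineage_ids(tx, id)
      paste(tx$taxa$rank[match(id, tx$taxa$taxon_id)],
            paste(tx$taxa$name[match(chain, tx$taxa$taxon_id)],
                  collapse = ">"), sep = "\r")
    }, character(1))
  }
  hi1 <- left$taxon_id[left$rank != "species"]
  hi2 <- right$taxon_id[right$rank != "species"]
  sig1 <- sig(comparison$origin, hi1)
  sig2 <- sig(comparison$destination, hi2)
  common <- intersect(sig1, sig2)
  shared_map <- c(shared_map,
                  setNames(hi2[match(common, sig2)], hi1[match(common, sig1)]))

  type_of_origin <- setNames(rep(NA_character_, nrow(left)), left$taxon_id)
  type_of_dest <- setNames(rep(NA_character_, nrow(right)), right$taxon_id)
  for (i in seq_len(nrow(rel))) {
    type_of_origin[rel$origin_ids[[i]]] <- rel$type[i]
    type_of_dest[rel$destination_ids[[i]]] <- rel$type[i]
  }

  shared1 <- names(shared_map)
  shared2 <- unname(shared_map)
  rows <- list()
  emit <- function(origin_id, destination_id, side, rank, depth, label,
                   type, variant) {
    if (!is.na(type) && !type %in% show) {
      type <- NA_character_
      variant <- NA_character_
    }
    rows[[length(rows) + 1]] <<- tibble::tibble(
      origin_id = origin_id, destination_id = destination_id, side = side,
      rank = rank, depth = depth, label = label, type = type,
      variant = variant)
  }
  emitted2 <- character()
  emit_shared <- function(i1) {
    o <- left$taxon_id[i1]
    d <- shared_map[[o]]
    ty <- type_of_origin[[o]]
    emit(o, d, "shared", left$rank[i1], left$depth[i1], left$label[i1],
         ty, if (is.na(ty)) NA_character_ else "base")
    emitted2 <<- c(emitted2, d)
  }
  i <- 1L
  j <- 1L
  n1 <- nrow(left)
  n2 <- nrow(right)
  while (i <= n1 || j <= n2) {
    if (j <= n2 && right$taxon_id[j] %in% emitted2) {
      j <- j + 1L
    } else if (i <= n1 && !left$taxon_id[i] %in% shared1) {
      ty <- type_of_origin[[left$taxon_id[i]]]
      emit(left$taxon_id[i], NA_character_, "origin", left$rank[i],
           left$depth[i], left$label[i], ty,
           if (is.na(ty)) NA_character_ else "light")
      i <- i + 1L
    } else if (j <= n2 && !right$taxon_id[j] %in% shared2) {
      ty <- type_of_dest[[right$taxon_id[j]]]
      emit(NA_character_, right$taxon_id[j], "destination", right$rank[j],
           right$depth[j], right$label[j], ty,
           if (is.na(ty)) NA_character_ else "dark")
      j <- j + 1L
    } else if (i <= n1 && j <= n2) {
      if (shared_map[[left$taxon_id[i]]] == right$taxon_id[j]) {
        emit_shared(i)
        i <- i + 1L
        j <- j + 1L
      } else {
        emit_shared(i)
        i <- i + 1L
      }
    } else if (i <= n1) {
      emit_shared(i)
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  out$y_index <- seq_len(nrow(out)) - 1L
  class(out) <- c("agglo_layout", class(out))
  out
}

#' Animation timeline of a comparison
#'
#' Builds the "animation by movement" schedule: each displayed relation
#' contributes tracks whose positions interpolate linearly from the T1
#' indented list (`x = 0`, row index as `y`) to the T2 list (`x = 1`).
#' Splits fork at the midpoint of their schedule — the origin track
#' reaches a fork point at local time 0.5 and disappears, the product
#' tracks appear there and travel on to their destination rows; merges
#' mirror this with a join. Additions fade in at their destination row
#' and exclusions fade out in place. At `t = 0` all origin-side tracks
#' sit exactly on the T1 layout, and at `t = 1` every surviving track
#' sits exactly on the T2 layout.
#'
#' @inheritParams build_edge_drawing
#' @param frame_count Number of sampled frames (at least 2); keyframes
#'   are emitted at `seq(0, 1, length.out = frame_count)`.
#' @param mode `"simultaneous"` plays every relation over the whole
#'   `[0, 1]` interval; `"one_by_one"` gives each displayed relation its
#'   own consecutive time slot.
#' @return An object of class `animation_timeline`: a list with `tracks`
#'   (tibble `track_id`, `relation_index`, `taxon_id`, `side`, `label`,
#'   `type`), `keyframes` (tibble `track_id`, `t`, `x`, `y`, `opacity`),
#'   `events` (tibble `relation_index`, `event`, `t`), `frame_count`,
#'   `mode`.
#' @export
build_animation <- function(comparison, show = CHANGE_TYPES,
                            frame_count = 11,
                            mode = c("simultaneous", "one_by_one")) {
  assert_comparison(comparison)
  mode <- match.arg(mode)
  if (!is.numeric(frame_count) || frame_count < 2) {
    abort("`frame_count` must be at least 2")
  }
  frame_count <- as.integer(frame_count)
  left <- indented_rows(comparison$origin)
  right <- indented_rows(comparison$destination)
  y1 <- setNames(left$y_index, left$taxon_id)
  y2 <- setNames(right$y_index, right$taxon_id)
  lab1 <- setNames(left$label, left$taxon_id)
  lab2 <- setNames(right$label, right$taxon_id)

  rel <- comparison$relations
  shown <- which(rel$type %in% show)
  n_shown <- length(shown)
  tracks <- list()
  events <- list()
  add_track <- function(relation_index, taxon_id, side, label, type,
                        u_from, u_to, x0, yy0, x1, yy1, op_rule) {
    tracks[[length(tracks) + 1]] <<- tibble::tibble(
      relation_index = relation_index, taxon_id = taxon_id, side = side,
      label = label, type = type, u_from = u_from, u_to = u_to,
      x0 = x0, y0 = yy0, x1 = x1, y1 = yy1, op_rule = op_rule)
  }
  for (s in seq_along(shown)) {
    r <- shown[s]
    ty <- rel$type[r]
    o <- rel$origin_ids[[r]]
    d <- rel$destination_ids[[r]]
    if (ty %in% c("congruent", "move", "rename")) {
      add_track(r, d, "destination", lab2[[d]], ty,
                0, 1, 0, y1[[o]], 1, y2[[d]], "full")
    } else if (ty == "split") {
      fy <- (y1[[o]] + mean(y2[d])) / 2
      add_track(r, o, "origin", lab1[[o]], ty,
                0, 0.5, 0, y1[[o]], 0.5, fy, "fade_out_half")
      for (p in d) {
        add_track(r, p, "destination", lab2[[p]], ty,
                  0.5, 1, 0.5, fy, 1, y2[[p]], "fade_in_half")
      }
      events[[length(events) + 1]] <- tibble::tibble(
        relation_index = r, event = "fork", t = NA_real_, slot = s)
    } else if (ty == "merge") {
      fy <- (mean(y1[o]) + y2[[d]]) / 2
      for (q in o) {
        add_track(r, q, "origin", lab1[[q]], ty,
                  0, 0.5, 0, y1[[q]], 0.5, fy, "fade_out_half")
      }
      add_track(r, d, "destination", lab2[[d]], ty,
                0.5, 1, 0.5, fy, 1, y2[[d]], "fade_in_half")
      events[[length(events) + 1]] <- tibble::tibble(
        relation_index = r, event = "join", t = NA_real_, slot = s)
    } else if (ty == "added") {
      add_track(r, d, "destination", lab2[[d]], ty,
                0, 1, 1, y2[[d]], 1, y2[[d]], "fade_in_linear")
    } else if (ty == "excluded") {
      add_track(r, o, "origin", lab1[[o]], ty,
                0, 1, 0, y1[[o]], 0, y1[[o]], "fade_out_linear")
    }
  }
  tracks <- if (length(tracks) == 0) {
    tibble::tibble(relation_index = integer(), taxon_id = character(),
                   side = character(), label = character(),
                   type = character(), u_from = double(), u_to = double(),
                   x0 = double(), y0 = double(), x1 = double(),
                   y1 = double(), op_rule = character())
  } else {
    dplyr::bind_rows(tracks)
  }
  tracks$track_id <- seq_len(nrow(tracks))

  slot_of <- match(tracks$relation_index, shown)
  if (mode == "one_by_one" && n_shown > 0) {
    starts <- (slot_of - 1) / n_shown
    lens <- rep(1 / n_shown, nrow(tracks))
  } else {
    starts <- rep(0, nrow(tracks))
    lens <- rep(1, nrow(tracks))
  }
  tracks$slot_start <- starts
  tracks$slot_len <- lens

  ev <- if (length(events) == 0) {
    tibble::tibble(relation_index = integer(), event = character(),
                   t = double())
  } else {
    ev <- dplyr::bind_rows(events)
    if (mode == "one_by_one" && n_shown > 0) {
      ev$t <- (ev$slot - 1) / n_shown + 0.5 / n_shown
    } else {
      ev$t <- 0.5
    }
    ev$slot <- NULL
    ev
  }

  grid <- seq(0, 1, length.out = frame_count)
  kf <- purrr::map_dfr(seq_len(nrow(tracks)), function(i) {
    tr <- tracks[i, ]
    st <- track_state(tr, grid)
    tibble::tibble(track_id = tr$track_id, t = grid,
                   x = st$x, y = st$y, opacity = st$opacity)
  })
  keep <- c("track_id", "relation_index", "taxon_id", "side", "label",
            "type")
  structure(list(tracks = tracks[, c(keep, "u_from", "u_to", "x0", "y0",
                                     "x1", "y1", "op_rule", "slot_start",
                                     "slot_len")],
                 keyframes = kf, events = ev, frame_count = frame_count,
                 mode = mode),
            class = "animation_timeline")
}

# Position and opacity of one track at global times `t`.
track_state <- function(tr, t) {
  u <- pmin(1, pmax(0, (t - tr$slot_start) / tr$slot_len))
  s <- pmin(1, pmax(0, (u - tr$u_from) / max(tr$u_to - tr$u_from, 1e-12)))
  x <- tr$x0 + s * (tr$x1 - tr$x0)
  y <- tr$y0 + s * (tr$y1 - tr$y0)
  opacity <- switch(tr$op_rule,
    full = rep(1, length(u)),
    fade_out_half = as.numeric(u < 0.5),
    fade_in_half = as.numeric(u >= 0.5),
    fade_in_linear = u,
    fade_out_linear = 1 - u
  )
  list(x = x, y = y, opacity = opacity)
}
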