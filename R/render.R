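# Static SVG rendering of the four layouts. Geometry is deliberately
# plain: fixed row height, indent step and label column widths. The
# documents are regular XML, so they can be parsed and counted in tests.

ROW_H <- 18
INDENT <- 12
LABEL_X <- 10
LEFT_W <- 280
GAP_W <- 220
FONT <- "font-family=\"sans-serif\" font-size=\"12\""

svg_root <- function(width, height) {
  xml2::xml_new_root("svg", xmlns = "http://www.w3.org/2000/svg",
                     width = as.character(ceiling(width)),
                     height = as.character(ceiling(height)))
}

svg_text <- function(root, x, y, label, fill = "#222222", opacity = NULL,
                     class = "row") {
  node <- xml2::xml_add_child(root, "text",
                              x = format(x, trim = TRUE),
                              y = format(y, trim = TRUE),
                              fill = fill, class = class)
  xml2::xml_set_attr(node, "font-family", "sans-serif")
  xml2::xml_set_attr(node, "font-size", "12")
  if (!is.null(opacity)) {
    xml2::xml_set_attr(node, "fill-opacity", format(opacity, trim = TRUE))
  }
  xml2::xml_set_text(node, label)
  node
}

row_y <- function(y_index) (y_index + 1) * ROW_H

render_row_column <- function(root, rows, x0, fills = NULL) {
  for (i in seq_len(nrow(rows))) {
    fill <- if (!is.null(fills) && !is.na(fills[i])) fills[i] else "#222222"
    svg_text(root, x0 + rows$depth[i] * INDENT, row_y(rows$y_index[i]),
             rows$label[i], fill = fill)
  }
}

finish_svg <- function(root, path) {
  out <- as.character(root)
  if (!is.null(path)) {
    writeLines(out, path)
    invisible(path)
  } else {
    out
  }
}

#' Render a comparison layout to SVG
#'
#' Produces a static SVG document for any of the four layouts, using
#' the change-type hues of a [color_scheme()]: one `line` element per
#' edge of an edge-drawing layout, one `rect` per cell of a matrix
#' layout, one `text` row per list row; agglomerated rows are filled
#' with the light/dark variant of their change hue; an animation
#' timeline is rendered as the snapshot of one sampled frame (use
#' [write_timeline_json()] for the full schedule).
#'
#' @param layout A layout built by [build_edge_drawing()],
#'   [build_matrix()], [build_agglomeration()], [build_animation()] or
#'   [indented_rows()].
#' @param scheme A [color_scheme()].
#' @param path Optional output path; when `NULL` the SVG text is
#'   returned.
#' @param ... Method-specific options: `frame` (frame number to render,
#'   animation only, default the last frame).
#' @return The SVG document as a character scalar, or `path` invisibly
#'   when written to a file.
#' @export
render_svg <- function(layout, scheme = color_scheme(), path = NULL, ...) {
  UseMethod("render_svg")
}

#' @export
render_svg.row_layout <- function(layout, scheme = color_scheme(),
                                  path = NULL, ...) {
  root <- svg_root(LEFT_W, row_y(nrow(layout)) + ROW_H)
  render_row_column(root, layout, LABEL_X)
  finish_svg(root, path)
}

#' @export
render_svg.edge_layout <- function(layout, scheme = color_scheme(),
                                   path = NULL, ...) {
  height <- row_y(max(nrow(layout$left), nrow(layout$right))) + ROW_H
  root <- svg_root(2 * LEFT_W + GAP_W, height)
  left_fill <- rep(NA_character_, nrow(layout$left))
  right_fill <- rep(NA_character_, nrow(layout$right))
  m <- layout$node_marks
  left_fill[match(m$taxon_id[m$side == "origin"], layout$left$taxon_id)] <-
    scheme$base_hue[m$type[m$side == "origin"]]
  right_fill[match(m$taxon_id[m$side == "destination"],
                   layout$right$taxon_id)] <-
    scheme$base_hue[m$type[m$side == "destination"]]
  render_row_column(root, layout$left, LABEL_X, left_fill)
  render_row_column(root, layout$right, LEFT_W + GAP_W + LABEL_X, right_fill)
  for (i in seq_len(nrow(layout$edges))) {
    e <- layout$edges[i, ]
    xml2::xml_add_child(
      root, "line", class = "edge",
      x1 = format(LEFT_W, trim = TRUE),
      y1 = format(row_y(e$origin_row) - 4, trim = TRUE),
      x2 = format(LEFT_W + GAP_W, trim = TRUE),
      y2 = format(row_y(e$destination_row) - 4, trim = TRUE),
      stroke = unname(scheme$base_hue[e$type]),
      `stroke-width` = "1.5")
  }
  finish_svg(root, path)
}

#' @export
render_svg.matrix_layout <- function(layout, scheme = color_scheme(),
                                     path = NULL, ...) {
  cell <- 14
  x0 <- LEFT_W
  y0 <- 80
  width <- x0 + cell * nrow(layout$col_axis) + 40
  height <- y0 + ROW_H * nrow(layout$row_axis) + 40
  root <- svg_root(width, height)
  for (i in seq_len(nrow(layout$row_axis))) {
    svg_text(root, LABEL_X + layout$row_axis$depth[i] * INDENT,
             y0 + row_y(layout$row_axis$y_index[i]),
             layout$row_axis$label[i])
  }
  for (j in seq_len(nrow(layout$col_axis))) {
    # horizontal column labels, abbreviated to the cell pitch
    svg_text(root, x0 + layout$col_axis$y_index[j] * cell, y0 - 8,
             substr(layout$col_axis$label[j], 1, 2), class = "col")
  }
  for (i in seq_len(nrow(layout$cells))) {
    cl <- layout$cells[i, ]
    xml2::xml_add_child(
      root, "rect", class = "cell",
      x = format(x0 + cl$col * cell, trim = TRUE),
      y = format(y0 + cl$row * ROW_H + 4, trim = TRUE),
      width = format(cell - 2, trim = TRUE),
      height = format(ROW_H - 6, trim = TRUE),
      fill = unname(scheme$base_hue[cl$type]))
  }
  for (i in seq_len(nrow(layout$margin_marks))) {
    mm <- layout$margin_marks[i, ]
    if (mm$axis == "row") {
      x <- x0 - 16
      y <- y0 + mm$index * ROW_H + 4
    } else {
      x <- x0 + mm$index * cell
      y <- y0 - 30
    }
    xml2::xml_add_child(
      root, "rect", class = "margin",
      x = format(x, trim = TRUE), y = format(y, trim = TRUE),
      width = format(cell - 2, trim = TRUE),
      height = format(ROW_H - 6, trim = TRUE),
      fill = unname(scheme$base_hue[mm$type]))
  }
  finish_svg(root, path)
}

#' @export
render_svg.agglo_layout <- function(layout, scheme = color_scheme(),
                                    path = NULL, ...) {
  root <- svg_root(LEFT_W + 120, row_y(nrow(layout)) + ROW_H)
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    fill <- if (is.na(r$type)) {
      "#222222"
    } else {
      switch(r$variant,
             light = unname(scheme$light[r$type]),
             dark = unname(scheme$dark[r$type]),
             base = unname(scheme$base_hue[r$type]))
    }
    svg_text(root, LABEL_X + r$depth * INDENT, row_y(r$y_index), r$label,
             fill = fill)
  }
  finish_svg(root, path)
}

#' @export
render_svg.animation_timeline <- function(layout, scheme = color_scheme(),
                                          path = NULL, ...,
                                          frame = layout$frame_count) {
  if (frame < 1 || frame > layout$frame_count) {
    abort("`frame` out of range")
  }
  t <- (frame - 1) / (layout$frame_count - 1)
  kf <- layout$keyframes[abs(layout$keyframes$t - t) < 1e-9, ]
  ymax <- max(c(kf$y, 1))
  root <- svg_root(2 * LEFT_W + GAP_W, row_y(ymax) + 2 * ROW_H)
  for (i in seq_len(nrow(kf))) {
    tr <- layout$tracks[match(kf$track_id[i], layout$tracks$track_id), ]
    svg_text(root,
             LABEL_X + kf$x[i] * (LEFT_W + GAP_W),
             row_y(kf$y[i]),
             tr$label,
             fill = unname(scheme$base_hue[tr$type]),
             opacity = kf$opacity[i],
             class = "track")
  }
  finish_svg(root, path)
}

#' Write an animation timeline as JSON
#'
#' Serializes the tracks, keyframes and fork/join events of a
#' [build_animation()] timeline to a JSON document, the machine-readable
#' companion of the per-frame SVG snapshots.
#'
#' @param timeline An `animation_timeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeline_json <- function(timeline, path) {
  if (!inherits(timeline, "animation_timeline")) {
    abort("`timeline` must come from build_animation()")
  }
  doc <- list(
    schema_version = "1",
    mode = timeline$mode,
    frame_count = timeline$frame_count,
    tracks = purrr::pmap(
      timeline$tracks[, c("track_id", "relation_index", "taxon_id", "side",
                          "label", "type")],
      function(track_id, relation_index, taxon_id, side, label, type) {
        list(track_id = track_id, relation_index = relation_index,
             taxon_id = taxon_id, side = side, label = label, type = type)
      }),
    keyframes = purrr::pmap(timeline$keyframes,
                            function(track_id, t, x, y, opacity) {
      list(track_id = track_id, t = t, x = x, y = y, opacity = opacity)
    }),
    events = purrr::pmap(timeline$events, function(relation_index, event, t) {
      list(relation_index = relation_index, event = event, t = t)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
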