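# Colour coding shared by all four comparison layouts: one hue per
# change type, plus, for the agglomerated view, a light/dark variant
# pair distinguishing origin-side (light) from destination-side (dark)
# rows of the same change.

#' Default colour scheme for change types
#'
#' One fixed hue per change type — blue for congruences, pink for
#' splits, orange for merges, light green for moves, light brownish
#' purple for renames, red for exclusions, green for additions — and a
#' light/dark variant pair per type for the agglomerated layout, where
#' the light variant (base hue raised by 25 lightness points in HSL)
#' marks origin-side rows and the dark variant (the base hue itself)
#' marks destination-side rows.
#'
#' @param base Optional named character vector overriding any of the
#'   seven base hues (names from [CHANGE_TYPES], values hex colours).
#' @return A list of class `color_scheme` with elements `base_hue`,
#'   `light` and `dark`, each a named character vector over
#'   [CHANGE_TYPES].
#' @export
color_scheme <- function(base = NULL) {
  hues <- c(congruent = "#4477aa", split = "#ee6699", merge = "#ee8833",
            move = "#88cc88", rename = "#aa88aa", added = "#33aa33",
            excluded = "#cc3333")
  if (!is.null(base)) {
    bad <- setdiff(names(base), CHANGE_TYPES)
    if (length(bad) > 0) {
      abort(paste0("unknown change type(s): ", paste(bad, collapse = ", ")))
    }
    hues[names(base)] <- base
  }
  structure(list(
    base_hue = hues,
    light = vapply(hues, lighten_hex, character(1), amount = 25),
    dark = hues
  ), class = "color_scheme")
}

# hex -> HSL -> hex with lightness raised by `amount` points (0-100).
lighten_hex <- function(hex, amount = 25) {
  rgb <- grDevices::col2rgb(hex)[, 1] / 255
  mx <- max(rgb); mn <- min(rgb)
  l <- (mx + mn) / 2
  if (mx == mn) {
    h <- 0; s <- 0
  } else {
    d <- mx - mn
    s <- if (l > 0.5) d / (2 - mx - mn) else d / (mx + mn)
    h <- if (mx == rgb[1]) {
      ((rgb[2] - rgb[3]) / d) %% 6
    } else if (mx == rgb[2]) {
      (rgb[3] - rgb[1]) / d + 2
    } else {
      (rgb[1] - rgb[2]) / d + 4
    }
    h <- h * 60
  }
  l2 <- min(1, l + amount / 100)
  c2 <- (1 - abs(2 * l2 - 1)) * s
  x <- c2 * (1 - abs((h / 60) %% 2 - 1))
  m <- l2 - c2 / 2
  rgb2 <- switch(1 + (h %/% 60) %% 6,
                 c(c2, x, 0), c(x, c2, 0), c(0, c2, x),
                 c(0, x, c2), c(x, 0, c2), c(c2, 0, x))
  grDevices::rgb(rgb2[1] + m, rgb2[2] + m, rgb2[3] + m)
}

# Relative luminance, used to assert light < dark ordering.
luminance <- function(hex) {
  rgb <- grDevices::col2rgb(hex)[, 1] / 255
  sum(c(0.2126, 0.7152, 0.0722) * rgb)
}
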