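test_that("indented rows are preorder with depth equal to lineage length minus one", {
  one <- taxonomy(tibble::tibble(taxon_id = "k", parent_id = NA,
                                 rank = "kingdom", name = "Plantae"))
  r1 <- indented_rows(one)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$depth, 0)
  expect_equal(r1$y_index, 0)

  cat7 <- indented_rows(taxonomy(cat_lineage()))
  expect_equal(nrow(cat7), 7)
  expect_equal(cat7$depth, 0:6)
  expect_equal(cat7$y_index, 0:6)

  for (r in 1:3) {
    tx <- build_seed(seed_spec(20 + r, 6, 2, rng_seed = r))
    rows <- indented_rows(tx)
    expect_equal(nrow(rows), nrow(tx$taxa))
    expect_equal(rows$y_index, seq_len(nrow(rows)) - 1L)
  }
})

test_that("edge and matrix layouts expand two-sided relations pair by pair", {
  case <- random_variant_case(50)
  cmp <- case$variant$comparison
  rel <- cmp$relations
  two_sided <- c("congruent", "split", "merge", "move", "rename")

  pair_count <- function(show) {
    keep <- rel$type %in% intersect(show, two_sided)
    sum(vapply(which(keep), function(i) {
      length(rel$origin_ids[[i]]) * length(rel$destination_ids[[i]])
    }, numeric(1)))
  }
  for (show in list(CHANGE_TYPES, "split", c("merge", "move"),
                    character(), c("added", "excluded"))) {
    ed <- build_edge_drawing(cmp, show)
    mx <- build_matrix(cmp, show)
    expect_equal(nrow(ed$edges), pair_count(show))
    expect_equal(nrow(mx$cells), pair_count(show))
    # one-sided changes appear as marks on their own side only
    expect_true(all(ed$node_marks$side[ed$node_marks$type == "excluded"]
                    == "origin"))
    expect_true(all(ed$node_marks$side[ed$node_marks$type == "added"]
                    == "destination"))
    expect_true(all(mx$margin_marks$axis[mx$margin_marks$type == "excluded"]
                    == "row"))
  }
})

test_that("a split draws one edge and one cell per product", {
  t1 <- taxonomy(tibble::tibble(
    taxon_id = c("g", "x"), parent_id = c(NA, "g"),
    rank = c("genus", "species"), name = c("Rana", "Rana prima"),
    author = c(NA, "Smith"), year = c(NA, 1900)))
  syn <- tibble::tibble(full_name = "Rana prima", author = "Smith",
                        year = 1900L)
  t2 <- taxonomy(tibble::tibble(
    taxon_id = c("G", "p", "q", "r"), parent_id = c(NA, "G", "G", "G"),
    rank = c("genus", rep("species", 3)),
    name = c("Rana", "Rana secunda", "Rana tertia", "Rana quarta"),
    author = c(NA, rep("Noble", 3)), year = c(NA, rep(2000, 3)),
    synonyms = list(NULL, syn, syn, syn)))
  cmp <- diff_taxonomies(t1, t2)
  ed <- build_edge_drawing(cmp, "split")
  expect_equal(nrow(ed$edges), 3)
  expect_true(all(ed$edges$type == "split"))
  expect_true(all(ed$edges$origin_id == "x"))
  mx <- build_matrix(cmp, "split")
  expect_setequal(mx$cells$destination_id, c("p", "q", "r"))
})

test_that("filtering commutes with edge and matrix building", {
  case <- random_variant_case(51)
  cmp <- case$variant$comparison
  show <- c("split", "rename", "added")
  full_ed <- build_edge_drawing(cmp, CHANGE_TYPES)
  filt_ed <- build_edge_drawing(cmp, show)
  restricted <- full_ed$edges[full_ed$edges$type %in% show, ]
  expect_equal(dplyr::arrange(filt_ed$edges, origin_id, destination_id),
               dplyr::arrange(restricted, origin_id, destination_id))
})

test_that("agglomeration shares congruent rows and preserves both source orders", {
  tx <- build_seed(seed_spec(14, 5, 2, rng_seed = 60))
  ident <- diff_taxonomies(tx, tx)
  ag0 <- build_agglomeration(ident)
  sp_rows <- ag0[ag0$rank == "species", ]
  expect_equal(nrow(sp_rows), 14)           # one shared row per species
  expect_true(all(sp_rows$side == "shared"))

  case <- random_variant_case(61)
  cmp <- case$variant$comparison
  ag <- build_agglomeration(cmp)
  l1 <- indented_rows(cmp$origin)
  l2 <- indented_rows(cmp$destination)
  o_seq <- ag$origin_id[!is.na(ag$origin_id)]
  d_seq <- ag$destination_id[!is.na(ag$destination_id)]
  expect_identical(o_seq, l1$taxon_id)      # T1 order as a subsequence
  expect_identical(d_seq, l2$taxon_id[l2$taxon_id %in% d_seq])
  expect_true(all(l2$taxon_id %in% d_seq))  # and every T2 row present

  # row accounting: shared + per-side participants + one-sided changes
  rel <- cmp$relations
  shared <- sum(rel$type == "congruent")
  per_side <- sum(vapply(which(rel$type %in%
                                 c("split", "merge", "move", "rename")),
                         function(i) {
    length(rel$origin_ids[[i]]) + length(rel$destination_ids[[i]])
  }, numeric(1)))
  added <- sum(rel$type == "added")
  excluded <- sum(rel$type == "excluded")
  expect_equal(nrow(ag[ag$rank == "species", ]),
               shared + per_side + added + excluded)
})

test_that("agglomeration colours origin rows light and destination rows dark", {
  case <- random_variant_case(62)
  ag <- build_agglomeration(case$variant$comparison)
  typed <- ag[!is.na(ag$type) & ag$type != "congruent", ]
  expect_true(all(typed$variant[typed$side == "origin"] == "light"))
  expect_true(all(typed$variant[typed$side == "destination"] == "dark"))
  # split products directly follow their origin under the common genus
  rel <- case$variant$comparison$relations
  for (i in which(rel$type == "split")) {
    x_row <- which(!is.na(ag$origin_id) & ag$origin_id == rel$origin_ids[[i]])
    prods <- which(!is.na(ag$destination_id) &
                     ag$destination_id %in% rel$destination_ids[[i]])
    expect_true(all(ag$variant[prods] == "dark"))
    expect_equal(ag$variant[x_row], "light")
  }
  # filtering blanks the annotation but keeps the rows
  ag_f <- build_agglomeration(case$variant$comparison, show = "split")
  expect_equal(nrow(ag_f), nrow(ag))
  expect_true(all(is.na(ag_f$type) | ag_f$type == "split"))
})

test_that("light colour variants are lighter than their dark counterparts", {
  sch <- color_scheme()
  expect_false(any(duplicated(sch$base_hue)))
  for (t in CHANGE_TYPES) {
    expect_gt(taxodiff:::luminance(sch$light[[t]]),
              taxodiff:::luminance(sch$dark[[t]]))
  }
})

test_that("animation keyframes start on the T1 layout and end on the T2 layout", {
  case <- random_variant_case(63)
  cmp <- case$variant$comparison
  l1 <- indented_rows(cmp$origin)
  l2 <- indented_rows(cmp$destination)
  y1 <- setNames(l1$y_index, l1$taxon_id)
  y2 <- setNames(l2$y_index, l2$taxon_id)
  for (mode in c("simultaneous", "one_by_one")) {
    an <- build_animation(cmp, frame_count = 5, mode = mode)
    tr <- an$tracks
    kf0 <- an$keyframes[an$keyframes$t == 0 & an$keyframes$opacity > 0, ]
    t0 <- tr[match(kf0$track_id, tr$track_id), ]
    org <- t0$side == "origin" | t0$type %in% c("congruent", "move", "rename")
    origin_taxon <- ifelse(t0$side == "origin", t0$taxon_id, NA)
    expect_true(all(kf0$x[org] == 0))

    kf1 <- an$keyframes[an$keyframes$t == 1 & an$keyframes$opacity > 0, ]
    t1r <- tr[match(kf1$track_id, tr$track_id), ]
    surv <- t1r$side == "destination"
    expect_true(all(abs(kf1$y[surv] - y2[t1r$taxon_id[surv]]) < 1e-9))
    expect_true(all(abs(kf1$x[surv] - 1) < 1e-9))
  }
})

test_that("two frames give keyframes only at the endpoints and splits fork midway", {
  case <- random_variant_case(64)
  cmp <- case$variant$comparison
  an2 <- build_animation(cmp, frame_count = 2)
  expect_setequal(unique(an2$keyframes$t), c(0, 1))
  expect_error(build_animation(cmp, frame_count = 1))

  an <- build_animation(cmp, frame_count = 11)
  rel <- cmp$relations
  splits <- which(rel$type == "split")
  if (length(splits) > 0) {
    forks <- an$events[an$events$event == "fork", ]
    expect_setequal(forks$relation_index, splits)
    expect_true(all(forks$t == 0.5))
    # origin track vanishes at the fork, products appear
    i <- splits[1]
    otr <- an$tracks[an$tracks$relation_index == i &
                       an$tracks$side == "origin", ]
    kf <- an$keyframes[an$keyframes$track_id == otr$track_id, ]
    expect_equal(kf$opacity[kf$t < 0.5], rep(1, sum(kf$t < 0.5)))
    expect_equal(kf$opacity[kf$t >= 0.5], rep(0, sum(kf$t >= 0.5)))
    ptr <- an$tracks[an$tracks$relation_index == i &
                       an$tracks$side == "destination", ]
    expect_equal(nrow(ptr), length(rel$destination_ids[[i]]))
  }
})

test_that("SVG documents contain one mark per layout element", {
  case <- random_variant_case(65)
  cmp <- case$variant$comparison
  ed <- build_edge_drawing(cmp)
  doc <- xml2::read_xml(render_svg(ed))
  lines <- xml2::xml_find_all(doc, "//*[local-name()='line']")
  expect_length(lines, nrow(ed$edges))
  texts <- xml2::xml_find_all(doc, "//*[local-name()='text']")
  expect_length(texts, nrow(ed$left) + nrow(ed$right))

  mx <- build_matrix(cmp)
  mdoc <- xml2::read_xml(render_svg(mx))
  cells <- xml2::xml_find_all(mdoc, "//*[local-name()='rect'][@class='cell']")
  expect_length(cells, nrow(mx$cells))

  ag <- build_agglomeration(cmp)
  adoc <- xml2::read_xml(render_svg(ag))
  expect_length(xml2::xml_find_all(adoc, "//*[local-name()='text']"),
                nrow(ag))

  an <- build_animation(cmp, frame_count = 3)
  fdoc <- xml2::read_xml(render_svg(an, frame = 3))
  expect_length(xml2::xml_find_all(fdoc, "//*[local-name()='text']"),
                nrow(an$tracks))
})

test_that("split edges carry the split hue and empty layouts render valid SVG", {
  t1 <- taxonomy(tibble::tibble(
    taxon_id = c("g", "x"), parent_id = c(NA, "g"),
    rank = c("genus", "species"), name = c("Rana", "Rana prima"),
    author = c(NA, "Smith"), year = c(NA, 1900)))
  syn <- tibble::tibble(full_name = "Rana prima", author = "Smith",
                        year = 1900L)
  t2 <- taxonomy(tibble::tibble(
    taxon_id = c("G", "p", "q", "r"), parent_id = c(NA, "G", "G", "G"),
    rank = c("genus", rep("species", 3)),
    name = c("Rana", "Rana secunda", "Rana tertia", "Rana quarta"),
    author = c(NA, rep("Noble", 3)), year = c(NA, rep(2000, 3)),
    synonyms = list(NULL, syn, syn, syn)))
  cmp <- diff_taxonomies(t1, t2)
  sch <- color_scheme()
  doc <- xml2::read_xml(render_svg(build_edge_drawing(cmp, "split"), sch))
  lines <- xml2::xml_find_all(doc, "//*[local-name()='line']")
  expect_length(lines, 3)
  expect_equal(unique(xml2::xml_attr(lines, "stroke")),
               unname(sch$base_hue[["split"]]))

  empty <- build_edge_drawing(cmp, character())
  edoc <- xml2::read_xml(render_svg(empty))
  expect_length(xml2::xml_find_all(edoc, "//*[local-name()='line']"), 0)

  f <- withr::local_tempfile(fileext = ".json")
  write_timeline_json(build_animation(cmp, frame_count = 2), f)
  tl <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(tl$frame_count, 2)
  expect_equal(length(tl$tracks), 4)  # origin + three products
})
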