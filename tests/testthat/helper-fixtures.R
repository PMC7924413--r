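# Shared fixtures and small independent oracles used across test files.

# The domestic cat's classification, kingdom down to species.
cat_lineage <- function() {
  tibble::tibble(
    taxon_id = paste0("t", 1:7),
    parent_id = c(NA, paste0("t", 1:6)),
    rank = c("kingdom", "phylum", "class", "order", "family", "genus",
             "species"),
    name = c("Animalia", "Chordata", "Mammalia", "Carnivora", "Felidae",
             "Feliz", "Feliz catus"),
    author = c(rep(NA, 6), "Linnaeus"),
    year = c(rep(NA, 6), 1758)
  )
}

# Canonical form of a relation list for set equality between comparisons.
canon_relations <- function(cmp) {
  rel <- cmp$relations
  sort(vapply(seq_len(nrow(rel)), function(i) {
    paste(rel$type[i],
          paste(sort(rel$origin_ids[[i]]), collapse = ","),
          paste(sort(rel$destination_ids[[i]]), collapse = ","),
          sep = "|")
  }, character(1)))
}

# Deterministic random study case: a seed taxonomy of 20-100 species and
# a within-capacity change mix, both derived from `r`.
random_variant_case <- function(r) {
  set.seed(r)
  n_sp <- sample(20:100, 1)
  n_g <- max(2, round(n_sp / 4))
  n_f <- max(1, round(n_g / 3))
  seed <- build_seed(seed_spec(n_sp, n_g, n_f, rng_seed = r))
  budget <- floor(0.5 * n_sp)
  pool <- budget
  n_merge <- sample(0:min(3, pool %/% 3), 1)
  pool <- pool - 3 * n_merge
  draw <- function() {
    a <- sample(0:min(4, pool), 1)
    pool <<- pool - a
    a
  }
  spec <- generator_spec(
    split = draw(), merge = n_merge, move = draw(), rename = draw(),
    added = sample(0:4, 1), excluded = draw(),
    prune_empty_genera = sample(c(TRUE, FALSE), 1),
    rng_seed = 10000 + r
  )
  list(seed = seed, spec = spec, variant = generate_variant(seed, spec))
}

# Dynamic-programming Levenshtein distance (independent of the package).
edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# All permutations of 1..k, one per row (enumeration oracle helper).
perm_rows <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perm_rows(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

# Independent Cochran Q / Friedman statistics for oracles (re-derived
# from their textbook definitions, not calls into the package).
oracle_cochran_stat <- function(m) {
  k <- ncol(m)
  Cj <- colSums(m)
  Ri <- rowSums(m)
  den <- k * sum(Ri) - sum(Ri^2)
  if (den == 0) return(0)
  (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / den
}

oracle_friedman_stat <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))
  ties <- sum(apply(r, 1, function(u) {
    tt <- table(u)
    sum(tt^3 - tt)
  }))
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) return(0)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / den
}
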