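# Nonparametric repeated-measures statistics for method-evaluation
# studies: every participant works through the same tasks under k
# conditions, producing either binary success indicators (Cochran's Q)
# or ordinal ratings (Friedman), followed by Dunn's pairwise post hoc
# with Bonferroni correction.

as_binary_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("responses must be numeric 0/1")
  if (anyNA(m)) abort("responses contain missing entries")
  if (!all(m %in% c(0, 1))) abort("responses must be binary (0/1)")
  if (ncol(m) < 2) abort("need at least 2 conditions")
  m
}

as_ordinal_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("ratings must be numeric")
  if (anyNA(m)) abort("ratings contain missing entries")
  m
}

cochran_q_stat <- function(m) {
  k <- ncol(m)
  Cj <- colSums(m)
  Ri <- rowSums(m)
  den <- k * sum(Ri) - sum(Ri^2)
  if (den == 0) return(0)  # all-saturated or all-zero rows only
  (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / den
}

#' Cochran's Q test for k matched binary outcomes
#'
#' Omnibus test for differences among k conditions when the same N
#' participants produce a dichotomous outcome (success/failure) under
#' each condition. The statistic is
#' \deqn{Q = (k-1)\,\frac{k\sum_j C_j^2 - (\sum_j C_j)^2}
#'                       {k\sum_i R_i - \sum_i R_i^2}}
#' over column totals \eqn{C_j} and row totals \eqn{R_i}, referred to a
#' chi-square distribution with `k - 1` degrees of freedom. Rows in
#' which every condition succeeded (or every condition failed) carry no
#' information; when only such rows are present the denominator
#' vanishes and Q is defined as 0 with p = 1.
#'
#' A permutation mode is provided for small samples: outcomes are
#' permuted within each participant's row and the p-value is the
#' fraction of resamples with `Q` at least the observed value.
#'
#' @param x An N x k matrix (or data frame) of 0/1 outcomes, rows =
#'   participants, columns = conditions.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_resample Resamples for the permutation mode.
#' @return An `htest`-like object of class `c("taxodiff_test", "htest")`
#'   with `statistic` (Q), `parameter` (df), `p.value`, `n` and
#'   `method`.
#' @export
cochran_q <- function(x, method = c("asymptotic", "permutation"),
                      n_resample = 10000) {
  method <- match.arg(method)
  m <- as_binary_matrix(x)
  k <- ncol(m)
  q <- cochran_q_stat(m)
  df <- k - 1
  p <- if (q == 0 && all(rowSums(m) %in% c(0, k))) {
    1
  } else if (method == "asymptotic") {
    pchisq(q, df, lower.tail = FALSE)
  } else {
    perm <- replicate(n_resample, {
      cochran_q_stat(t(apply(m, 1, sample)))
    })
    mean(perm >= q - 1e-9)
  }
  structure(list(
    statistic = c(Q = q), parameter = c(df = df), p.value = p,
    n = nrow(m),
    method = paste0("Cochran's Q test (", method, ")"),
    data.name = deparse(substitute(x))
  ), class = c("taxodiff_test", "htest"))
}

friedman_stat <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))  # midranks within participants
  ties <- sum(apply(r, 1, function(u) {
    tt <- table(u)
    sum(tt^3 - tt)
  }))
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) return(0)  # every row completely tied
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / den
}

#' Friedman rank test for k matched ordinal conditions
#'
#' Omnibus test for within-subjects designs with three or more
#' conditions and ordinal responses (such as Likert ratings): responses
#' are ranked within each participant (midranks on ties), and the
#' tie-corrected rank statistic is referred to a chi-square
#' distribution with `k - 1` degrees of freedom. An exact mode
#' enumerates all \eqn{(k!)^N} within-row orderings when that count is
#' at most `exact_limit`, falling back to Monte-Carlo permutation
#' otherwise.
#'
#' @param x An N x k numeric matrix (or data frame) of ratings, rows =
#'   participants, columns = conditions; no missing entries.
#' @param method `"asymptotic"` (default), `"exact"` or
#'   `"permutation"`.
#' @param n_resample Resamples for the permutation mode.
#' @param exact_limit Largest enumeration size accepted by the exact
#'   mode.
#' @return An `htest`-like object as for [cochran_q()], with the
#'   chi-square statistic.
#' @export
friedman <- function(x, method = c("asymptotic", "exact", "permutation"),
                     n_resample = 10000, exact_limit = 1e6) {
  method <- match.arg(method)
  m <- as_ordinal_matrix(x)
  if (ncol(m) < 3) abort("the Friedman test needs at least 3 conditions")
  k <- ncol(m)
  n <- nrow(m)
  s <- friedman_stat(m)
  df <- k - 1
  all_tied <- all(apply(m, 1, function(u) length(unique(u)) == 1))
  p <- if (all_tied) {
    1
  } else if (method == "asymptotic") {
    pchisq(s, df, lower.tail = FALSE)
  } else if (method == "exact") {
    if (factorial(k)^n > exact_limit) {
      abort("enumeration too large for the exact mode; use permutation")
    }
    perms <- all_permutations(k)
    choices <- rep(list(seq_len(nrow(perms))), n)
    grid <- expand.grid(choices)
    stats <- apply(grid, 1, function(sel) {
      mm <- do.call(rbind, lapply(seq_len(n),
                                  function(i) m[i, perms[sel[i], ]]))
      friedman_stat(mm)
    })
    mean(stats >= s - 1e-9)
  } else {
    perm <- replicate(n_resample, friedman_stat(t(apply(m, 1, sample))))
    mean(perm >= s - 1e-9)
  }
  structure(list(
    statistic = c(`Friedman chi-squared` = s), parameter = c(df = df),
    p.value = p, n = n,
    method = paste0("Friedman rank test (", method, ")"),
    data.name = deparse(substitute(x))
  ), class = c("taxodiff_test", "htest"))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

#' Dunn's pairwise post hoc with Bonferroni correction
#'
#' Rank-based pairwise comparison of all `k(k-1)/2` condition pairs
#' following a significant omnibus test on matched data. Responses are
#' ranked within participants (midranks on ties); the z statistic for a
#' pair is the difference of mean ranks divided by its standard error
#' \eqn{\sqrt{k(k+1)/(6N)}}, scaled by the same tie-correction factor
#' as the Friedman statistic. Raw two-sided normal p-values are
#' Bonferroni-adjusted by multiplying by the number of comparisons
#' (capped at 1).
#'
#' @param x An N x k matrix of binary outcomes or ordinal ratings.
#' @param alpha Family-wise significance level for the `significant`
#'   flag.
#' @return A tibble with one row per pair: `condition_a`,
#'   `condition_b`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_bonferroni <- function(x, alpha = 0.05) {
  m <- as_ordinal_matrix(x)
  k <- ncol(m)
  if (k < 2) abort("need at least 2 conditions")
  n <- nrow(m)
  labels <- colnames(m) %||% paste0("cond", seq_len(k))
  r <- t(apply(m, 1, rank))
  mean_rank <- colMeans(r)
  ties <- sum(apply(r, 1, function(u) {
    tt <- table(u)
    sum(tt^3 - tt)
  }))
  correction <- 1 - ties / (n * k * (k^2 - 1))
  se <- sqrt(k * (k + 1) / (6 * n) * max(correction, 1e-12))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_pairs), function(pi) {
    a <- pairs[1, pi]
    b <- pairs[2, pi]
    z <- (mean_rank[a] - mean_rank[b]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble::tibble(
      condition_a = labels[a], condition_b = labels[b],
      z = unname(z), p_raw = p_raw,
      p_adjusted = min(1, n_pairs * p_raw))
  })
  out$significant <- out$p_adjusted < alpha
  out
}

#' Per-condition effectiveness totals and percentages
#'
#' Aggregates a table of per-exercise correct-answer counts (one row per
#' exercise, one column per condition) into overall totals and integer
#' percentages of the maximum attainable score
#' (`n_participants * number of exercises`), rounding half up as in
#' printed study tables.
#'
#' @param per_exercise_counts An exercises x conditions matrix or data
#'   frame of correct counts.
#' @param n_participants Number of participants; no count may exceed
#'   it.
#' @return A tibble with columns `condition`, `total`, `percentage`.
#' @export
effectiveness_summary <- function(per_exercise_counts, n_participants) {
  m <- as.matrix(per_exercise_counts)
  if (any(m < 0) || any(m > n_participants)) {
    abort("counts must lie in [0, n_participants]")
  }
  labels <- colnames(m) %||% paste0("cond", seq_len(ncol(m)))
  total <- colSums(m)
  pct <- round_half_up(100 * total / (n_participants * nrow(m)))
  tibble::tibble(condition = labels, total = as.integer(total),
                 percentage = as.integer(pct))
}

#' Reconstruct a binary response matrix from per-condition totals
#'
#' Builds an N x k 0/1 matrix whose column totals match the given
#' correct counts, filling each column's successes from the top. When
#' all but one column are saturated (every participant correct), the
#' matrix is unique up to row order, so tests computed from it are
#' exact reconstructions of the underlying data.
#'
#' @param correct Named or unnamed vector of per-condition correct
#'   counts.
#' @param n_participants Number of participants (rows).
#' @return An `n_participants` x `length(correct)` binary matrix.
#' @export
response_matrix_from_totals <- function(correct, n_participants) {
  if (any(correct < 0) || any(correct > n_participants)) {
    abort("counts must lie in [0, n_participants]")
  }
  m <- vapply(correct, function(cc) {
    c(rep(1, cc), rep(0, n_participants - cc))
  }, numeric(n_participants))
  colnames(m) <- names(correct) %||% paste0("cond", seq_along(correct))
  m
}

#' Location summaries of ordinal rating columns
#'
#' Published summaries of 1-5 rating scales sometimes print fractional
#' "medians" (e.g. 3.29) that no plain sample median of integers can
#' attain; such values are either means or interpolated medians.
#' Rather than guess, this reports all three per condition: the plain
#' median, the grouped (interpolated) median treating each integer
#' rating as the midpoint of a unit interval, and the mean.
#'
#' @param x An N x k matrix or data frame of ratings.
#' @return A tibble with columns `condition`, `median`,
#'   `interpolated_median`, `mean`.
#' @export
rating_location <- function(x) {
  m <- as_ordinal_matrix(x)
  labels <- colnames(m) %||% paste0("cond", seq_len(ncol(m)))
  interp_median <- function(v) {
    n <- length(v)
    md <- stats::median(v)
    below <- sum(v < md)
    at <- sum(v == md)
    if (at == 0) return(md)
    (md - 0.5) + (n / 2 - below) / at
  }
  tibble::tibble(
    condition = labels,
    median = unname(apply(m, 2, stats::median)),
    interpolated_median = unname(apply(m, 2, interp_median)),
    mean = unname(colMeans(m))
  )
}

#' @export
print.taxodiff_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("%s = %.4f, df = %d, p-value = %.4g, N = %d\n",
              names(x$statistic), x$statistic, x$parameter, x$p.value, x$n))
  invisible(x)
}

#' Pivot long-form study responses to per-exercise matrices
#'
#' Converts a long table (one row per participant x exercise x
#' condition) into a named list of participant x condition matrices,
#' one per exercise, with participants ordered by first appearance.
#'
#' @param long A data frame with columns `participant_id`, the grouping
#'   column named by `item`, `method`, and the value column named by
#'   `value`.
#' @param item,value Names of the grouping and value columns
#'   (`"exercise"`/`"correct"` for responses,
#'   `"question"`/`"rating"` for ratings).
#' @return Named list of numeric matrices.
#' @export
study_matrices <- function(long, item = "exercise", value = "correct") {
  need <- c("participant_id", item, "method", value)
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols) > 0) {
    abort(paste0("long table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  items <- unique(long[[item]])
  out <- lapply(items, function(it) {
    sub <- long[long[[item]] == it, ]
    parts <- unique(sub$participant_id)
    methods <- unique(sub$method)
    m <- matrix(NA_real_, length(parts), length(methods),
                dimnames = list(parts, methods))
    for (i in seq_len(nrow(sub))) {
      m[as.character(sub$participant_id[i]),
        as.character(sub$method[i])] <- sub[[value]][i]
    }
    m
  })
  names(out) <- as.character(items)
  out
}
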