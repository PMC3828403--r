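#' Vargha-Delaney A-test
#'
#' Nonparametric effect-magnitude statistic contrasting two samples. `a_test`
#' returns the probability that a randomly selected value from `x` exceeds a
#' randomly selected value from `y`, counting ties as one half:
#' \deqn{A = P(x > y) + \tfrac{1}{2} P(x = y).}
#' It is computed from the midrank sum of `x` in the pooled sample,
#' `A = (R1/n - (n+1)/2)/m`, which is algebraically identical to the pairwise
#' definition. The statistic is independent of sample size, which is why it is
#' used for "scientific significance" of simulation experiments where any
#' difference becomes statistically significant at large replicate counts.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return An object of class `"a_test"`: a list with `A` (the score),
#'   `effect` (band from [classify_effect()]), and `direction` (`sign(A - 0.5)`).
#' @seealso [classify_effect()] for the small/medium/large bands.
#' @examples
#' a_test(c(5, 6, 7), c(1, 2, 3))   # A = 1, large
#' a_test(1:10, 1:10)               # A = 0.5, no effect
#' @export
a_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("a_test() requires two nonempty samples")
  if (anyNA(x) || anyNA(y)) stop("a_test() samples must not contain NA")
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))                       # midranks for ties
  r1 <- sum(r[seq_len(n)])
  A <- (r1 / n - (n + 1) / 2) / m
  structure(
    list(A = A, effect = classify_effect(A), direction = sign(A - 0.5)),
    class = "a_test"
  )
}

#' @export
print.a_test <- function(x, ...) {
  cat(sprintf("Vargha-Delaney A = %.4f (%s effect)\n", x$A, x$effect))
  invisible(x)
}

#' Classify an A-test score into an effect-magnitude band
#'
#' Bands follow the conventional cutoffs, symmetric about 0.5: scores <= 0.44
#' or >= 0.56 are a small effect, <= 0.36 or >= 0.64 medium, and <= 0.29 or
#' >= 0.71 large. Scores strictly inside (0.44, 0.56) carry no effect.
#'
#' @param A numeric vector of A-test scores in \[0, 1\].
#' @return character vector with levels `"none"`, `"small"`, `"medium"`,
#'   `"large"`.
#' @export
classify_effect <- function(A) {
  if (any(A < 0 | A > 1, na.rm = TRUE))
    stop("A-test scores must lie in [0, 1]")
  d <- abs(A - 0.5)
  eps <- 1e-9   # keep the printed cutoffs exact despite binary rounding
  out <- rep("none", length(A))
  out[d >= 0.5 - 0.44 - eps] <- "small"
  out[d >= 0.5 - 0.36 - eps] <- "medium"
  out[d >= 0.5 - 0.29 - eps] <- "large"
  out[is.na(A)] <- NA_character_
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test of stochastic equality between two samples. For small samples
#' the permutation null distribution of the U statistic is enumerated
#' exhaustively (ties handled through midranks); for larger samples the normal
#' approximation with the usual tie correction is used, without continuity
#' correction. When group comparisons concern counts of clinical episodes the
#' test consumes the raw per-run counts, never percentages.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param method `"auto"` (exact when `choose(n + m, n) <= 5e5`, otherwise
#'   approximate), `"exact"`, or `"approx"`.
#' @return list with `U` (statistic for `x`), `p_value` (two-sided), and
#'   `method` used.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n <- length(x)
  m <- length(y)
  if (n == 0L || m == 0L) stop("mann_whitney_u() requires two nonempty samples")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (method == "auto")
    method <- if (choose(n + m, n) <= 5e5) "exact" else "approx"
  if (method == "exact") {
    ## exhaustive permutation distribution of U over group assignments
    idx <- utils::combn(n + m, n)
    base <- n * (n + 1) / 2
    us <- colSums(matrix(r[idx], nrow = n)) - base
    lo <- mean(us <= U + 1e-9)
    hi <- mean(us >= U - 1e-9)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    tie_adj <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
    sigma2 <- n * m / 12 * (n + m + 1 - tie_adj)
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence of difference
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p_value = max(p, .Machine$double.xmin), method = method)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Used to compare mortality rates between groups: rows are groups, columns
#' are died/survived counts. Two-sided p-value by hypergeometric tail
#' summation over all tables with probability no greater than the observed
#' table (the convention of [stats::fisher.test()], which performs the
#' computation).
#'
#' @param table 2x2 matrix of nonnegative integer counts, or four counts
#'   `c(a, b, c, d)` filled by row.
#' @return list with `p_value` and the odds `ratio` estimate.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  if (!all(dim(table) == c(2L, 2L))) stop("fisher_exact() needs a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact() needs nonnegative integer counts")
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, ratio = unname(ft$estimate))
}

#' Significance stars for p-values
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001, `""`
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Summarize a group of simulation outcomes
#'
#' Computes the per-metric median and inter-quartile range over a group of
#' replicate runs, plus mortality and relapse rates as percentages of the
#' group. Groups of 500 replicates are conventional for full experiments;
#' any size >= 1 is accepted.
#'
#' @param outcomes data frame as returned by [run_group()]/[extract_outcomes()]
#'   with at least columns `max_score`, `n_episodes`, `relapse_count`, `died`,
#'   `first_episode_duration_d`.
#' @return list with `n`, a `metrics` data frame (metric, median, q1, q3,
#'   iqr), `mortality_pct` and `relapse_pct`.
#' @export
summarize_group <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 1L)
  num_cols <- intersect(
    c("max_score", "n_episodes", "relapse_count", "first_episode_duration_d",
      "death_time_h"),
    names(outcomes)
  )
  metrics <- do.call(rbind, lapply(num_cols, function(cl) {
    v <- outcomes[[cl]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) v <- NA_real_
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(metric = cl, median = q[2], q1 = q[1], q3 = q[3],
               iqr = q[3] - q[1])
  }))
  list(
    n = nrow(outcomes),
    metrics = metrics,
    mortality_pct = 100 * mean(outcomes$died),
    relapse_pct = 100 * mean(outcomes$relapse_count >= 1)
  )
}

#' Compare two groups of simulation outcomes
#'
#' The standard group-versus-group report: per-metric A-test scores with
#' effect-magnitude bands, Mann-Whitney U p-values with significance stars,
#' and Fisher's exact test on mortality. Episode counts are compared on the
#' raw per-run counts.
#'
#' @param control,experimental outcome data frames (see [summarize_group()]).
#' @param metrics character vector of outcome columns to compare.
#' @return An object of class `"group_comparison"`: list with a `tests` data
#'   frame (metric, A, effect, U, p, stars) and `mortality` (2x2 table,
#'   p-value, stars).
#' @export
compare_groups <- function(control, experimental,
                           metrics = c("max_score", "n_episodes",
                                       "first_episode_duration_d")) {
  metrics <- intersect(metrics, intersect(names(control), names(experimental)))
  tests <- do.call(rbind, lapply(metrics, function(cl) {
    xv <- experimental[[cl]]
    yv <- control[[cl]]
    xv <- xv[!is.na(xv)]
    yv <- yv[!is.na(yv)]
    if (length(xv) == 0L || length(yv) == 0L)
      return(data.frame(metric = cl, A = NA_real_, effect = NA_character_,
                        U = NA_real_, p = NA_real_, stars = ""))
    at <- a_test(xv, yv)
    mw <- mann_whitney_u(xv, yv)
    data.frame(metric = cl, A = at$A, effect = at$effect, U = mw$U,
               p = mw$p_value, stars = p_stars(mw$p_value))
  }))
  tab <- matrix(c(sum(control$died), sum(!control$died),
                  sum(experimental$died), sum(!experimental$died)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("control", "experimental"),
                                c("died", "survived")))
  fe <- fisher_exact(tab)
  structure(
    list(tests = tests,
         mortality = list(table = tab, p_value = fe$p_value,
                          stars = p_stars(fe$p_value))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (experimental vs control)\n")
  print(x$tests, row.names = FALSE)
  cat(sprintf("Mortality: Fisher exact p = %.4g %s\n",
              x$mortality$p_value, x$mortality$stars))
  invisible(x)
}
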