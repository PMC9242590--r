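# Statistics used throughout the pipeline, implemented from their defining
# formulas: unit-count proportions, Pearson chi-square on contingency
# tables, two-sample and paired t tests, Holm-Sidak step-down correction,
# and a seeded permutation test. p-values use the chi-square / t survival
# functions; everything else is explicit arithmetic so the computations are
# fully specified by this file.

#' Percentage from a unit count
#'
#' `100 * k / n`, rounded half-even to the requested number of decimals.
#' The raw ratio is returned alongside, since printed percentages in the
#' literature mix rounding conventions.
#'
#' @param k,n Counts with `0 <= k <= n`, `n > 0`.
#' @param decimals Decimals for the rounded percentage.
#' @return List with `percent` (rounded) and `raw` (exact).
#' @export
proportion_percent <- function(k, n, decimals = 1) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]")
  raw <- 100 * k / n
  list(percent = round(raw, decimals), raw = raw)
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df,
                 p = min(max(p, 0), 1), adjusted_p = NULL, method = method),
            class = "etho_test")
}

#' @export
print.etho_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Statistic `sum((O - E)^2 / E)` with expected counts from the row/column
#' margins, `df = (r - 1)(c - 1)`, and the p-value from the chi-square
#' survival function. No continuity correction by default; `correct = TRUE`
#' applies the Yates correction on 2 x 2 tables.
#'
#' @param counts Matrix (at least 2 x 2) of non-negative counts.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return An `etho_test` result.
#' @export
chi_square <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin: expected counts undefined")
  expected <- outer(rs, cs) / sum(counts)
  dev <- abs(counts - expected)
  if (correct && nrow(counts) == 2 && ncol(counts) == 2)
    dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  test_result(stat, df, pchisq(stat, df, lower.tail = FALSE),
              if (correct) "chi-square (Yates)" else "chi-square")
}

#' Two-sample and paired t tests
#'
#' Two-sided by default. `unpaired_welch` uses the Welch-Satterthwaite
#' degrees of freedom; `unpaired_pooled` assumes equal variances; `paired`
#' tests the mean of the elementwise differences.
#'
#' @param x,y Numeric samples (equal length for `paired`; at least 2 each).
#' @param mode One of `unpaired_welch`, `unpaired_pooled`, `paired`.
#' @return An `etho_test` result.
#' @export
t_tests <- function(x, y, mode = c("unpaired_welch", "unpaired_pooled",
                                   "paired")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per group")
  if (mode == "paired") {
    if (nx != ny) stop("paired mode requires equal lengths")
    d <- x - y
    se <- sd(d) / sqrt(nx)
    if (se == 0) return(test_result(0, nx - 1, 1, "paired t"))
    stat <- mean(d) / se
    df <- nx - 1
    method <- "paired t"
  } else {
    vx <- stats::var(x)
    vy <- stats::var(y)
    if (mode == "unpaired_welch") {
      se2 <- vx / nx + vy / ny
      if (se2 == 0) return(test_result(0, nx + ny - 2, 1, "Welch t"))
      stat <- (mean(x) - mean(y)) / sqrt(se2)
      df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
      method <- "Welch t"
    } else {
      sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
      if (sp2 == 0) return(test_result(0, nx + ny - 2, 1, "pooled t"))
      stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
      df <- nx + ny - 2
      method <- "pooled t"
    }
  }
  test_result(stat, df, 2 * pt(abs(stat), df, lower.tail = FALSE), method)
}

#' Holm-Sidak step-down adjustment
#'
#' Sort the m p-values ascending; the i-th smallest is adjusted to
#' `1 - (1 - p_(i))^(m - i + 1)`; a running maximum enforces step-down
#' monotonicity and the result is returned in the input order. Adjusted
#' values are never below the raw ones and the smallest p receives exactly
#' the single-step Sidak correction.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Seeded permutation test for a difference in means
#'
#' Two-sided p-value `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)` over
#' random relabelings of the pooled sample; with `exact = TRUE` all
#' distinct group assignments are enumerated instead and the p-value is the
#' exact proportion. Degenerate input (all pooled values identical) gives
#' p = 1.
#'
#' @param x,y Numeric samples.
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @param exact Enumerate all assignments (feasible for small samples).
#' @return An `etho_test` result (statistic = mean(x) - mean(y), df = NA).
#' @export
permutation_test <- function(x, y, n_perm = 999L, seed = NULL,
                             exact = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!exact && n_perm < 100) stop("n_perm must be at least 100")
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  t_obs <- mean(x) - mean(y)
  if (max(pooled) - min(pooled) == 0)
    return(test_result(0, NA_real_, 1, "permutation (degenerate)"))
  eps <- 1e-12 * (max(pooled) - min(pooled))
  if (exact) {
    idx <- utils::combn(n, nx)
    tot <- sum(pooled)
    stats_perm <- apply(idx, 2, function(ii) {
      mx <- mean(pooled[ii])
      my <- (tot - sum(pooled[ii])) / (n - nx)
      mx - my
    })
    p <- mean(abs(stats_perm) >= abs(t_obs) - eps)
    return(test_result(t_obs, NA_real_, p, "permutation (exact)"))
  }
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      ii <- sample.int(n, nx)
      tp <- mean(pooled[ii]) - mean(pooled[-ii])
      if (abs(tp) >= abs(t_obs) - eps) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else with_local_seed(seed, run())
  test_result(t_obs, NA_real_, p, "permutation")
}
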