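# The comparative statistical engine: Mann-Whitney U, chi-square test of
# independence with observed/expected accounting, Spearman rank
# correlation, and normality checks (Anderson-Darling and a
# Lilliefors-corrected Kolmogorov-Smirnov; the proprietary Ryan-Joiner
# correlation test is deliberately substituted by these two documented
# tests). No multiple-testing correction is applied anywhere.

.test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                         alternative = NA_character_, extra = NULL) {
  out <- c(list(statistic = unname(statistic), p_value = unname(p_value),
                method = method, n1 = n1, n2 = n2,
                alternative = alternative), extra)
  class(out) <- "thermbond_test"
  out
}

#' @export
print.thermbond_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), sep = "")
  if (!is.na(x$n2)) cat(", n1 =", x$n1, ", n2 =", x$n2)
  else cat(", n =", x$n1)
  if (!is.na(x$alternative)) cat(", alternative =", x$alternative)
  cat("\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. With `n1 + n2 <= 20` and no ties the exact
#' null distribution of U is used; otherwise the normal approximation with
#' tie correction and continuity correction. `alternative = "greater"`
#' means the first sample is stochastically larger.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return A `thermbond_test` with the U statistic of `x`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  if (!ties && n1 + n2 <= 20) {
    p <- switch(alternative,
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(u, n1, n2),
      two_sided = {
        if (u > n1 * n2 / 2) {
          min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, n1, n2))
        }
      })
    method <- "Mann-Whitney U (exact)"
  } else {
    nt <- table(c(x, y))
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      # all observations identical: no evidence either way
      return(.test_result(u, 1, "Mann-Whitney U (degenerate: constant data)",
                          n1, n2, alternative))
    }
    z <- u - mu
    cc <- switch(alternative,
                 two_sided = sign(z) * 0.5,
                 greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two_sided = min(1, 2 * stats::pnorm(-abs(z))))
    method <- paste0("Mann-Whitney U (normal approximation",
                     if (ties) ", tie-corrected" else "",
                     ", continuity-corrected)")
  }
  .test_result(u, p, method, n1, n2, alternative)
}

#' Chi-square test of independence with observed/expected accounting
#'
#' Expected cell counts are the standard contingency expectations
#' `E[i, j] = row_i * col_j / total`. Rows or columns summing to zero are
#' dropped with a warning before testing. Alongside the test, the per-cell
#' deviations (observed minus expected) and, for two-column tables, the
#' percentage-point difference in column-wise use rates are returned.
#'
#' @param observed Non-negative count matrix (r x c).
#' @return A `thermbond_test` with extra elements `df`, `expected`,
#'   `deviations`, and (for 2 columns) `use_rate_delta`.
#' @export
chi_square_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || anyNA(observed)) {
    stop("observed counts must be non-negative and complete")
  }
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping ", sum(rs == 0), " zero row(s) and ", sum(cs == 0),
            " zero column(s) before testing")
    observed <- observed[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(observed); cs <- colSums(observed)
  }
  total <- sum(observed)
  if (total <= 0 || nrow(observed) < 2 || ncol(observed) < 2) {
    stop("need a table with at least 2 non-empty rows and columns")
  }
  expected <- outer(rs, cs) / total
  stat <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)

  extra <- list(df = df, expected = expected,
                deviations = observed - expected)
  if (ncol(observed) == 2) {
    extra$use_rate_delta <-
      100 * (observed[, 1] / cs[1] - observed[, 2] / cs[2])
  }
  .test_result(stat, p, "Chi-square test of independence",
               nrow(observed), ncol(observed), "two_sided", extra)
}

# all permutations of 1..n (n <= 9), matrix with one permutation per row
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation
#'
#' Midrank-based rho (Pearson correlation of the rank vectors, which
#' handles ties). For `n < 10` the two-sided p-value is exact by
#' enumeration of all permutations of one rank vector; for `n >= 10` the
#' t-distribution approximation is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A list of class `thermbond_cor` with rho, p_value, n, method.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain NA")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (n < 10) {
    perms <- .permutations(n)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum((ry - mean(ry))^2))
    # rho for permuted y reduces to the cross term: sum(rx_c) = 0, and the
    # means and denominator are permutation-invariant
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    rho_all <- (ry_perm %*% rx_c) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    method <- "Spearman rank correlation (t approximation)"
  }
  structure(list(rho = unname(rho), p_value = p, n = n, method = method),
            class = "thermbond_cor")
}

#' @export
print.thermbond_cor <- function(x, ...) {
  cat(x$method, "\n  rho = ", format(x$rho), ", p = ",
      format.pval(x$p_value), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Normality checks (Anderson-Darling and Lilliefors)
#'
#' Runs the Anderson-Darling test for the composite normal hypothesis
#' (estimated mean and variance, with the Stephens small-sample
#' modification and the D'Agostino p-value approximation) and the
#' Lilliefors-corrected Kolmogorov-Smirnov test (Dallal-Wilkinson p-value
#' approximation). Both are documented substitutes for proprietary
#' normality tests; they are used to gate the recommendation of the
#' nonparametric comparison path.
#'
#' @param x Numeric vector, n >= 8.
#' @return List of two `thermbond_test` objects, `anderson_darling` and
#'   `lilliefors`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("input must not contain NA")
  n <- length(x)
  if (n < 8) stop("need at least 8 observations")
  s <- sort(x)
  m <- mean(x); sd_ <- stats::sd(x)
  if (sd_ == 0) stop("normality check undefined for constant data")
  p_i <- stats::pnorm((s - m) / sd_)
  p_i <- pmin(pmax(p_i, 1e-300), 1 - 1e-16)

  # Anderson-Darling, composite case
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p_i) + log(1 - rev(p_i))))
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p_ad <- if (Astar < 0.2) {
    1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  } else if (Astar < 0.34) {
    1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  } else if (Astar < 0.6) {
    exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  } else if (Astar < 10) {
    exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  } else {
    3.7e-24
  }
  ad <- .test_result(A2, min(max(p_ad, 0), 1),
                     "Anderson-Darling normality test (estimated parameters)",
                     n)

  # Lilliefors-corrected Kolmogorov-Smirnov (Dallal-Wilkinson, with the
  # Stephens branch for large p)
  D <- max(i / n - p_i, p_i - (i - 1) / n)
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  p_l <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p_l > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p_l <- if (KK <= 0.302) {
      1
    } else if (KK <= 0.5) {
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 - 138.55152 * KK^3 +
        81.218052 * KK^4
    } else if (KK <= 0.9) {
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 + 94.029866 * KK^3 -
        32.355711 * KK^4
    } else if (KK <= 1.31) {
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 - 12.234627 * KK^3 +
        2.423045 * KK^4
    } else {
      0
    }
  }
  lf <- .test_result(D, min(max(p_l, 0), 1),
                     "Lilliefors (Kolmogorov-Smirnov) normality test", n)
  list(anderson_darling = ad, lilliefors = lf)
}
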