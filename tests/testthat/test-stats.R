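# statistical engine: Mann-Whitney U, chi-square, Spearman, normality

# enumeration oracle for the exact Mann-Whitney p-value: all C(n1+n2, n1)
# assignments of the pooled ranks to group x
enumerate_mwu <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) sum(pooled[ix])) -
    n1 * (n1 + 1) / 2
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two_sided = min(1, 2 * min(mean(u_all <= u_obs),
                                    mean(u_all >= u_obs))))
}

test_that("Mann-Whitney exact path matches the enumeration oracle", {
  t <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 0.05)  # 1/20, all three ranks at the bottom
  expect_equal(t$p_value, enumerate_mwu(c(1, 2, 3), c(4, 5, 6), "less"))
  expect_match(t$method, "exact")

  set.seed(31)
  for (rep in 1:8) {
    x <- round(rnorm(sample(3:6, 1)), 4)
    y <- round(rnorm(sample(3:6, 1)) + runif(1, -1, 1), 4)
    for (alt in c("less", "greater", "two_sided")) {
      expect_equal(mann_whitney_u(x, y, alt)$p_value,
                   enumerate_mwu(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney identical samples give U = n1 n2 / 2 and p near 1", {
  x <- c(2, 5, 9, 9, 12)
  t <- mann_whitney_u(x, x)
  expect_equal(t$statistic, length(x)^2 / 2)
  expect_gt(t$p_value, 0.9)
})

test_that("Mann-Whitney approximate path agrees with the reference
           implementation", {
  set.seed(7)
  for (rep in 1:6) {
    x <- rnorm(30); y <- rnorm(30, 0.3)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, ref$p.value,
                 tolerance = 1e-6)
    # with ties (tie-corrected variance)
    xt <- round(x, 1); yt <- round(y, 1)
    reft <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                                correct = TRUE))
    expect_equal(mann_whitney_u(xt, yt)$p_value, reft$p.value,
                 tolerance = 1e-6)
  }
})

test_that("Mann-Whitney invariants: U additivity and label swap", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(15)
    ux <- mann_whitney_u(x, y)$statistic
    uy <- mann_whitney_u(y, x)$statistic
    expect_equal(ux + uy, length(x) * length(y))
    expect_equal(mann_whitney_u(x, y)$p_value,
                 mann_whitney_u(y, x)$p_value)
    expect_equal(mann_whitney_u(x, y, "greater")$p_value,
                 mann_whitney_u(y, x, "less")$p_value)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("chi-square statistic, expected matrix and conservation", {
  obs <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  t <- chi_square_independence(obs)
  expect_equal(t$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(t$df, 1)
  expect_true(all(t$expected == 15))
  # proportional table: statistic 0, p = 1
  t0 <- chi_square_independence(matrix(c(20, 10, 40, 20), 2, 2,
                                       byrow = TRUE))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # conservation: expected margins equal observed margins
  set.seed(2)
  m <- matrix(rpois(40, 30), 20, 2)
  tm <- chi_square_independence(m)
  expect_equal(rowSums(tm$expected), rowSums(m))
  expect_equal(colSums(tm$expected), colSums(m))
  expect_equal(sum(tm$deviations), 0, tolerance = 1e-9)
  # agreement with the reference implementation on a 20x2 usage matrix
  ref <- stats::chisq.test(m, correct = FALSE)
  expect_equal(tm$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(tm$p_value, ref$p.value, tolerance = 1e-9)
  # permutation invariance
  perm <- m[sample(20), 2:1]
  expect_equal(chi_square_independence(perm)$statistic, tm$statistic)
})

test_that("chi-square drops empty rows/columns and validates input", {
  m <- rbind(c(10, 20), c(0, 0), c(5, 5))
  expect_warning(t <- chi_square_independence(m), "zero row")
  expect_equal(t$df, 1)
  expect_error(chi_square_independence(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
})

test_that("Spearman rho values and exact permutation p", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)   # monotone transform
  expect_equal(spearman_rho(1:8, -(1:8))$rho, -1)
  t <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(t$rho, 0.6)
  # oracle: exact permutation two-sided p for n = 4
  ref <- stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman")
  expect_equal(t$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y)$rho, base$rho)
  expect_equal(spearman_rho(x, 3 * y + 2)$rho, base$rho)
  expect_equal(spearman_rho(x, y)$p_value, base$p_value)
})

test_that("normality checks separate normal from exponential data", {
  # under the null, both tests should usually retain; under a skewed
  # alternative at n = 5000 they should essentially always reject
  set.seed(1234)
  retain <- reject <- matrix(NA, 60, 2)
  for (r in 1:60) {
    nm <- normality_check(rnorm(5000))
    ex <- normality_check(rexp(5000))
    retain[r, ] <- c(nm$anderson_darling$p_value > 0.05,
                     nm$lilliefors$p_value > 0.05)
    reject[r, ] <- c(ex$anderson_darling$p_value < 0.05,
                     ex$lilliefors$p_value < 0.05)
  }
  expect_gte(mean(retain[, 1]), 0.9)
  expect_gte(mean(retain[, 2]), 0.9)
  expect_equal(mean(reject), 1)
  # near-constant data is emphatically non-normal
  x <- c(rep(1, 40), 1 + 1e-6 * rnorm(10))
  nc <- normality_check(x)
  expect_lt(nc$anderson_darling$p_value, 0.05)
  expect_lt(nc$lilliefors$p_value, 0.05)
  expect_error(normality_check(1:5), "at least 8")
})
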