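test_that("item correlations match a direct summation oracle and handle edge cases", {
  # perfect correlation and sign symmetry
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  r <- item_correlations(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))

  # 4 respondents x 3 items, element-by-element covariance oracle
  y <- cbind(p = c(1, 3, 2, 5), q = c(2, 2, 4, 4), s = c(5, 1, 4, 2))
  r2 <- item_correlations(y)
  cov_oracle <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  }
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(
        r2[i, j],
        cov_oracle(y[, i], y[, j]) /
          sqrt(cov_oracle(y[, i], y[, i]) * cov_oracle(y[, j], y[, j])),
        tolerance = 1e-12
      )
    }
  }

  # zero-variance item named in the error
  z <- cbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(item_correlations(z), "flat")
  expect_error(item_correlations(x[1, , drop = FALSE]), "respondents")
})

test_that("Cronbach's alpha matches hand arithmetic and its invariances", {
  # k identical items: exactly 1
  x <- cbind(c(1, 2, 5, 3), c(1, 2, 5, 3), c(1, 2, 5, 3))
  expect_equal(cronbach_alpha(x), 1)

  # hand-summed variance oracle on a 4-respondent, 2-item set
  y <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  svar <- function(v) sum((v - mean(v))^2) / (length(v) - 1)
  alpha_oracle <- (2 / 1) * (1 - (svar(y[, 1]) + svar(y[, 2])) /
                               svar(y[, 1] + y[, 2]))
  expect_equal(cronbach_alpha(y), alpha_oracle, tolerance = 1e-12)

  # invariance to adding a constant to any item
  y2 <- y
  y2[, 2] <- y2[, 2] + 7
  expect_equal(cronbach_alpha(y2), cronbach_alpha(y), tolerance = 1e-12)

  # population limit: two uncorrelated equal-variance items -> alpha ~ 0
  big <- withr::with_seed(11, cbind(rnorm(20000), rnorm(20000)))
  expect_lt(abs(cronbach_alpha(big)), 0.05)

  # degenerate input
  expect_error(cronbach_alpha(cbind(c(1, 2), c(2, 1))), "variance")
  expect_error(cronbach_alpha(y[, 1, drop = FALSE]), "2 items")
})

test_that("KMO matches an explicit partial-correlation oracle", {
  r <- matrix(c(1, 0.6, 0.3,
                0.6, 1, 0.4,
                0.3, 0.4, 1), 3, 3)
  # oracle: for 3 variables the anti-image partial of (i, j) conditions on
  # the single remaining variable k, with the textbook closed form
  partial <- function(rij, rik, rjk) {
    (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  }
  q12 <- partial(r[1, 2], r[1, 3], r[2, 3])
  q13 <- partial(r[1, 3], r[1, 2], r[3, 2])
  q23 <- partial(r[2, 3], r[2, 1], r[3, 1])
  r2 <- 2 * (r[1, 2]^2 + r[1, 3]^2 + r[2, 3]^2)
  q2 <- 2 * (q12^2 + q13^2 + q23^2)
  expect_equal(kmo(r)$overall, r2 / (r2 + q2), tolerance = 1e-12)

  # identity: 0/0 resolved to 0 with a warning
  expect_warning(k0 <- kmo(diag(4)), "KMO")
  expect_equal(k0$overall, 0)

  # one-common-factor structure beats the identity
  one <- matrix(0.5, 3, 3); diag(one) <- 1
  expect_gt(kmo(one)$overall, 0)
})

test_that("Bartlett's sphericity statistic follows the chi-square formula", {
  # identity correlation: statistic exactly 0, p = 1
  b0 <- bartlett_sphericity(diag(5), n = 100)
  expect_equal(b0$statistic, 0)
  expect_equal(b0$p.value, 1)
  expect_equal(b0$df, 10)

  # p = 3, n = 50, determinant hand-computed by the rule of Sarrus
  r <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.3,
                0.2, 0.3, 1), 3, 3)
  det_oracle <- 1 * (1 - 0.3^2) - 0.5 * (0.5 - 0.3 * 0.2) +
    0.2 * (0.5 * 0.3 - 0.2)
  stat_oracle <- -(50 - 1 - (2 * 3 + 5) / 6) * log(det_oracle)
  b <- bartlett_sphericity(r, n = 50)
  expect_equal(b$statistic, stat_oracle, tolerance = 1e-9)
  expect_equal(b$df, 3)

  # strictly increasing in n for fixed R with |R| < 1
  expect_gt(bartlett_sphericity(r, 60)$statistic, b$statistic)

  expect_error(bartlett_sphericity(r, n = 3), "respondents")
})

test_that("EFA retains by rule, preserves trace, and recovers block structure", {
  # identity: all eigenvalues exactly 1, strict rule retains none
  expect_error(efa(diag(4)), "0 factors")

  # two within-block-0.8 blocks of size 3: two factors, clean simple structure
  r <- diag(6)
  r[1:3, 1:3] <- 0.8
  r[4:6, 4:6] <- 0.8
  diag(r) <- 1
  ef <- efa(r)
  expect_identical(ef$retained_k, 2L)
  expect_equal(sum(ef$eigenvalues), 6, tolerance = 1e-9)  # trace preserved
  for (j in 1:2) {
    block <- abs(ef$loadings[, j]) >= 0.8
    expect_true(identical(unname(block), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)) ||
                identical(unname(block), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)))
  }
  # contribution columns: 100 * eigenvalue / p and its prefix sums
  expect_equal(ef$contribution, 100 * ef$eigenvalues / 6, tolerance = 1e-12)
  expect_equal(ef$cumulative, cumsum(ef$contribution), tolerance = 1e-12)

  # cumulative retention rule
  ef2 <- efa(r, retention = "cumulative", cum_target = 85)
  expect_gte(ef2$cumulative[ef2$retained_k], 85)
})

test_that("varimax rotation preserves communalities and ascends its criterion", {
  # single factor: identity rotation
  l1 <- matrix(c(0.9, 0.5, 0.3), 3, 1)
  expect_identical(varimax_rotate(l1), l1)

  # rotated-away simple structure is recovered; criterion never decreases
  # (unequal loadings keep the start away from the criterion's saddle point)
  simple <- cbind(c(0.8, 0.7, 0, 0), c(0, 0, 0.8, 0.6))
  theta <- pi / 6
  rot45 <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  mixed <- simple %*% rot45
  back <- varimax_rotate(mixed)
  expect_gte(varimax_criterion(back), varimax_criterion(mixed) - 1e-12)
  expect_equal(rowSums(back^2), rowSums(mixed^2), tolerance = 1e-9)

  # closed-form oracle: the optimum over all planar rotations of `mixed`
  crit_at <- function(phi) {
    g <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
    varimax_criterion(mixed %*% g)
  }
  best <- max(vapply(seq(-pi / 4, pi / 4, length.out = 20001), crit_at,
                     numeric(1)))
  expect_equal(varimax_criterion(back), best, tolerance = 1e-6)
  # and the recovered structure matches the planted one up to column order/sign
  expect_equal(sort(abs(as.vector(back))), sort(abs(as.vector(simple))),
               tolerance = 1e-4)
})

test_that("reliability report aggregates overall and per-dimension statistics", {
  lambda <- rbind(
    matrix(rep(c(0.7, 0, 0), each = 3), 3, 3),
    matrix(rep(c(0, 0.7, 0), each = 3), 3, 3),
    matrix(rep(c(0, 0, 0.7), each = 3), 3, 3)
  )
  x <- generate_responses(300, lambda, noise_sd = 0.5, seed = 5)
  dims <- stats::setNames(rep(c("d1", "d2", "d3"), each = 3), colnames(x))
  rep_ <- reliability_report(x, dims)
  expect_equal(rep_$n_respondents, 300)
  expect_length(rep_$alpha_by_dimension, 3)
  expect_true(all(rep_$alpha_by_dimension > 0.5))
  expect_true(rep_$kmo_overall > 0 && rep_$kmo_overall < 1)
  expect_lt(rep_$bartlett$p.value, 1e-6)
})
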