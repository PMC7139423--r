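test_that("pairwise NAP matches hand-enumerated examples", {
  expect_equal(nap(c(4, 5, 6), c(1, 2, 3), "decrease")$nap, 1)
  expect_equal(nap(c(3, 3, 3), c(3, 3, 3), "decrease")$nap, 0.5)
  r <- nap(c(3, 4, 5), c(2, 3, 6), "decrease")
  expect_equal(r$nap, 5.5 / 9)
  expect_equal(r$n_ties, 1L)
  expect_error(nap(numeric(0), 1), "empty")
})

test_that("NAP equals the rank-sum AUC and respects direction symmetry", {
  set.seed(61)
  for (rep in 1:60) {
    a <- sample(seq(0, 10, 0.5), sample(3:25, 1L), replace = TRUE)
    b <- sample(seq(0, 10, 0.5), sample(3:25, 1L), replace = TRUE)
    dec <- nap(a, b, "decrease")$nap
    inc <- nap(a, b, "increase")$nap
    expect_equal(dec + inc, 1)
    expect_equal(dec, nap_rank_oracle(a, b, "decrease"), tolerance = 1e-13)
    # invariant under joint strictly monotone transforms
    f <- function(x) x^3 + 2 * x
    expect_equal(nap(f(a), f(b), "decrease")$nap, dec)
  }
})

test_that("pooled A-phase NAP is the pair-weighted combination of groups", {
  set.seed(62)
  a0 <- runif(8, 0, 10); a1 <- runif(5, 0, 10); b <- runif(6, 0, 10)
  pooled <- nap(c(a0, a1), b, "decrease")$nap
  w0 <- length(a0) * length(b); w1 <- length(a1) * length(b)
  combo <- (w0 * nap(a0, b, "decrease")$nap + w1 * nap(a1, b, "decrease")$nap) /
    (w0 + w1)
  expect_equal(pooled, combo)
})

test_that("the asymptotic interval behaves at the boundary and centre", {
  at1 <- nap_ci(1, 10, 8)
  expect_equal(at1$se, 0)
  expect_equal(c(at1$lower, at1$upper), c(1, 1))
  mid <- nap_ci(0.5, 12, 12)
  expect_equal(0.5 - mid$lower, mid$upper - 0.5)
  expect_true(mid$se > 0)
})

test_that("the asymptotic SE agrees with a bootstrap on fixed data", {
  # groups realizing NAP = 0.75 with n_A = 15, n_B = 18
  set.seed(63)
  a <- seq(2, 6, length.out = 15)
  b <- seq(2, 6, length.out = 18) - 1.25
  r <- nap(a, b, "decrease")
  expect_equal(round(r$nap, 2), 0.75)
  boot <- replicate(4000, {
    nap(sample(a, replace = TRUE), sample(b, replace = TRUE), "decrease")$nap
  })
  expect_lt(abs(sd(boot) - r$se) / sd(boot), 0.25)
})

test_that("effect bands follow the published cut points after rounding", {
  expect_equal(classify_effect(0.82), "medium")
  expect_equal(classify_effect(0.58), "weak")
  expect_equal(classify_effect(0.95), "strong")
  expect_equal(classify_effect(0.655), "medium")  # rounds to 0.66
  expect_equal(classify_effect(0.652), "weak")    # rounds to 0.65
  expect_equal(classify_effect(0.92), "medium")
  expect_equal(classify_effect(0.921), "medium")  # rounds to 0.92
})

test_that("carryover is flagged exactly for discordant effect bands", {
  mk <- function(nap_val, comparison) {
    a <- seq(0, 10, length.out = 21)
    structure(list(nap = nap_val, n_A = 21, n_B = 21, n_ties = 0,
                   se = 0.1, ci = c(nap_val - 0.2, nap_val + 0.2), level = 0.95,
                   band = classify_effect(nap_val), direction = "decrease",
                   comparison = comparison), class = "nap_result")
  }
  # participant-5-like pattern: weak all-A contrast, medium baseline contrast
  expect_true(carryover_flag(mk(0.58, "allA_vs_B"), mk(0.81, "A0_vs_B"))$flagged)
  # both medium: no carryover signal
  expect_false(carryover_flag(mk(0.72, "allA_vs_B"), mk(0.82, "A0_vs_B"))$flagged)
  expect_false(carryover_flag(mk(0.40, "allA_vs_B"), mk(0.40, "A0_vs_B"))$flagged)
  expect_error(carryover_flag(mk(0.5, "A0_vs_B"), mk(0.5, "A0_vs_B")),
               "mismatched comparison")
})
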