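series_from <- function(scores, phases) {
  data.frame(participant_id = "p", day_index = seq_along(scores),
             slot_index = 1L, time_index = seq_along(scores),
             phase_kind = phases, score = scores, missing = is.na(scores),
             stringsAsFactors = FALSE)
}

test_that("phase statistics pool occurrences and use the n-1 denominator", {
  s <- series_from(c(1, 2, 3, 9, 9, 4, 4), c("A0", "A0", "A0", "B", "B", "A1", "A1"))
  ps <- phase_stats(s)
  expect_equal(ps$mean[ps$phase_kind == "A0"], 2)
  expect_equal(ps$sd[ps$phase_kind == "A0"], 1)
  expect_equal(ps$n[ps$phase_kind == "B"], 2L)

  const <- series_from(rep(2, 6), c("A0", "A0", "B", "B", "A1", "A1"))
  pc <- phase_stats(const)
  expect_true(all(pc$mean == 2) && all(pc$sd == 0))
})

test_that("degenerate phases are reported as absent or variance-undefined", {
  s <- series_from(c(1, 2, 3, 5), c("A0", "A0", "A0", "B"))
  ps <- phase_stats(s)
  expect_false("A1" %in% ps$phase_kind)            # no A1 data -> absent row
  expect_true(is.na(ps$sd[ps$phase_kind == "B"]))  # n = 1 -> sd undefined
  # all-missing phase drops out rather than contributing zeros
  s2 <- series_from(c(1, 2, 3, NA), c("A0", "A0", "A0", "B"))
  expect_false("B" %in% phase_stats(s2)$phase_kind)
})

test_that("PEM counts points beyond the baseline median with 0.5 tie weight", {
  expect_equal(pem(c(4, 5, 6), c(1, 2, 3), "decrease")$pem_pct, 100)
  expect_equal(pem(c(4, 5, 6), c(5, 5), "decrease")$pem_pct, 50)
  r <- pem(c(2, 4, 6, 8), c(3, 5, 9), "decrease")
  # brute-force oracle: median 5; one point strictly below, one tie
  expect_equal(r$n_in_direction, 1L)
  expect_equal(r$n_ties, 1L)
  expect_equal(r$pem_pct, 100 * 1.5 / 3)
  expect_equal(r$pem_strict_pct, 100 / 3)
  expect_error(pem(numeric(0), 1), "baseline")
  expect_error(pem(1, numeric(0)), "intervention")
})

test_that("PEM directions are complementary and transform-invariant", {
  set.seed(31)
  for (rep in 1:40) {
    a <- sample(0:10, sample(3:12, 1L), replace = TRUE)
    b <- sample(0:10, sample(3:12, 1L), replace = TRUE)
    expect_equal(pem(a, b, "decrease")$pem_pct + pem(a, b, "increase")$pem_pct, 100)
    # monotone invariance is exact when the baseline median is an order
    # statistic (odd n); the even-n interpolated midpoint is not equivariant
    a_odd <- if (length(a) %% 2L == 0L) a[-1L] else a
    f <- function(x) exp(x / 3) + x  # strictly increasing
    expect_equal(pem(f(a_odd), f(b), "decrease")$pem_pct,
                 pem(a_odd, b, "decrease")$pem_pct)
  }
})

test_that("complete separation yields PEM 100 regardless of baseline shape", {
  set.seed(32)
  for (rep in 1:10) {
    a <- runif(sample(3:10, 1L), 4, 9)
    b <- runif(sample(2:8, 1L), 0, min(a) - 0.01)
    expect_equal(pem(a, b, "decrease")$pem_pct, 100)
  }
})
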