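test_that("state-anxiety scoring recodes items 1, 4, 5 and averages", {
  expect_equal(score_stai6(c(5, 5, 5, 5, 5, 5)), 5)        # fixed point
  expect_equal(score_stai6(c(0, 10, 10, 0, 0, 10)), 10)    # recoded vector all 10s
  expect_equal(score_stai6(rep(0, 6)), 5)                  # (10,0,0,10,10,0)/6
  # matrix input scores row-wise
  m <- rbind(c(5, 5, 5, 5, 5, 5), c(0, 10, 10, 0, 0, 10))
  expect_equal(score_stai6(m), c(5, 10))
  expect_error(score_stai6(c(1, 2, 3)), "6 items")
  expect_error(score_stai6(c(11, 0, 0, 0, 0, 0)), "\\[0, 10\\]")
})

test_that("anxiety score is monotone in each item with the keyed direction", {
  set.seed(7)
  base <- runif(6, 1, 9)
  for (j in 1:6) {
    up <- base; up[j] <- up[j] + 1
    d <- score_stai6(up) - score_stai6(base)
    if (j %in% c(1, 4, 5)) expect_lt(d, 0) else expect_gt(d, 0)
  }
})

test_that("behavior scoring reverses as 5 - x and validates range", {
  expect_equal(score_behavior(3, FALSE), 3L)
  expect_equal(score_behavior(0, TRUE), 5L)
  expect_equal(score_behavior(2, TRUE), 3L)
  expect_error(score_behavior(6), "0..5")
  expect_error(score_behavior(2.5), "0..5")
})

test_that("double application of either recoding is the identity", {
  for (x in seq(0, 10, by = 0.5)) expect_equal(10 - (10 - x), x)
  for (x in 0:5) expect_equal(score_behavior(score_behavior(x, TRUE), TRUE), x)
  set.seed(11)
  items <- runif(6, 0, 10)
  twice <- scedab:::recode_stai6(scedab:::recode_stai6(items))
  expect_equal(twice, items)
})

test_that("score_dataset scores both outcomes and honours reversal flags", {
  rr <- random_records(2L, missing_rate = 0.3)
  scored <- score_dataset(rr$records,
                          behavior_reverse = rr$spec$participants[[1L]]$id)
  anx <- scored[scored$outcome == "anxiety" & !scored$missing, ]
  expect_equal(anx$score, unname(rowMeans(anx[paste0("item_", 1:6)])))
  raw <- rr$records[rr$records$outcome_kind == "behavior" & !rr$records$missing, ]
  beh <- scored[scored$outcome == "behavior" & !scored$missing, ]
  raw <- raw[order(raw$participant_id, raw$day_index, raw$slot_index), ]
  beh <- beh[order(beh$participant_id, beh$day_index, beh$slot_index), ]
  rev_id <- rr$spec$participants[[1L]]$id
  expect_equal(beh$score,
               ifelse(raw$participant_id == rev_id, 5 - raw$item_1, raw$item_1))
  expect_true(all(is.na(scored$score[scored$missing])))
})
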