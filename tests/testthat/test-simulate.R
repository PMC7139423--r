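noiseless <- function(...) {
  sim_config("anxiety", sigma = 0, tau_u = 0, tau_v = 0, carryover = 0,
             trend = 0, ar1_rho = 0, items = FALSE, ...)
}

test_that("the noiseless generator reproduces the generative identity", {
  cfg <- noiseless(mu0 = 5, beta = -2, decay = c(1, 1, 1))
  obs <- simulate_participant(cfg, "1")
  expect_true(all(obs$score[obs$phase_kind != "B"] == 5))
  expect_true(all(obs$score[obs$phase_kind == "B"] == 3))
})

test_that("decay multipliers scale the intervention effect per slot", {
  cfg <- noiseless(mu0 = 5, beta = -2, decay = c(1, 0.5, 0))
  obs <- simulate_participant(cfg, "1")
  b <- obs[obs$phase_kind == "B", ]
  expect_equal(as.numeric(tapply(b$score, b$slot_index, unique)), c(3, 4, 5))
})

test_that("carryover shifts withdrawal days by the stated fraction", {
  cfg <- sim_config("anxiety", sigma = 0, tau_u = 0, tau_v = 0, trend = 0,
                    ar1_rho = 0, items = FALSE, mu0 = 5, beta = -2,
                    carryover = 0.5, decay = c(1, 1, 1))
  obs <- simulate_participant(cfg, "1")
  expect_true(all(obs$score[obs$phase_kind == "A1"] == 4))
  expect_true(all(obs$score[obs$phase_kind == "A0"] == 5))
})

test_that("the generator is deterministic and substream-stable", {
  cfg <- sim_config("anxiety", seed = 9L)
  a <- simulate_participant(cfg, "3")
  b <- simulate_participant(cfg, "3")
  expect_identical(a, b)
  # a different participant's draw does not perturb participant 3
  invisible(simulate_participant(cfg, "7"))
  expect_identical(simulate_participant(cfg, "3"), a)
})

test_that("item backfill preserves the score identity and item ranges", {
  cfg <- sim_config("anxiety", seed = 5L)
  obs <- simulate_participant(cfg, "2")
  items <- as.matrix(obs[paste0("item_", 1:6)])
  expect_equal(rowMeans(items), obs$score, tolerance = 1e-12)
  expect_true(all(items >= 0 & items <= 10))
  expect_true(all(abs(items * 10 - round(items * 10)) < 1e-9))  # tenths grid
  beh <- simulate_participant(sim_config("behavior", seed = 5L), "2")
  expect_true(all(beh$score %in% 0:5))
})

test_that("missingness injection hits the degenerate rates exactly", {
  cfg <- sim_config("anxiety", items = FALSE, seed = 2L)
  obs <- simulate_participant(cfg, "1")
  expect_equal(sum(inject_missingness(obs, 0, 1L)$missing), 0L)
  expect_equal(sum(inject_missingness(obs, 1, 1L)$missing), nrow(obs))
})

test_that("missingness frequency is binomial around the configured rate", {
  long <- design_spec(participant_design("L", "A0", 2000L), slots_per_day = 3L)
  cfg <- sim_config("anxiety", design = long, items = FALSE, seed = 4L)
  obs <- inject_missingness(simulate_participant(cfg, "L"), 0.27, 11L)
  n <- nrow(obs)  # 6000 scheduled slots
  ci99 <- qnorm(0.995) * sqrt(0.27 * 0.73 / n)
  expect_lt(abs(mean(obs$missing) - 0.27), ci99)
})

test_that("residual autocorrelation converges to ar1_rho on long series", {
  long <- design_spec(participant_design("L", "A0", 4000L), slots_per_day = 3L)
  cfg <- sim_config("anxiety", design = long, mu0 = 5, sigma = 1, tau_u = 0,
                    tau_v = 0, trend = 0, ar1_rho = 0.6, ar1_persist = TRUE,
                    floor = -Inf, ceiling = Inf, items = FALSE, seed = 8L)
  x <- simulate_participant(cfg, "L")$score
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.6), 0.05)  # ~3 Monte-Carlo SDs at n = 12000
  # and the marginal SD matches sigma
  expect_lt(abs(sd(x) - 1), 0.05)
})

test_that("clipping is inactive when the bounds are far from the mean", {
  cfg_b <- sim_config("anxiety", mu0 = 5, sigma = 0.5, tau_u = 0.2, seed = 6L,
                      items = FALSE)
  cfg_u <- sim_config("anxiety", mu0 = 5, sigma = 0.5, tau_u = 0.2, seed = 6L,
                      items = FALSE, floor = -Inf, ceiling = Inf)
  for (id in c("1", "5", "8"))
    expect_identical(simulate_participant(cfg_b, id)$score,
                     simulate_participant(cfg_u, id)$score)
})

test_that("simulate_study emits 492 slots per outcome and an exact sidecar", {
  study <- simulate_study(sim_config("anxiety", seed = 12L, items = FALSE),
                          behavior = NULL)
  expect_equal(nrow(study$scored), 492L)
  tr <- study$truth$anxiety
  cfg <- tr$config
  expect_identical(tr$delta, cfg$beta / sqrt(cfg$tau_u^2 + cfg$sigma^2))
  expect_named(tr$u, vapply(cfg$design$participants, `[[`, "", "id"))
  path <- withr::local_tempfile()
  write_truth_sidecar(study$truth, path)
  expect_true(any(grepl("^anxiety\\.delta=", readLines(path))))
})

test_that("zero between-case variance makes trajectories exchangeable", {
  cfg <- noiseless(mu0 = 4, beta = -1, decay = c(1, 1, 1))
  # participants 1 and 2 share the same phase plan
  expect_equal(simulate_participant(cfg, "1")$score,
               simulate_participant(cfg, "2")$score)
})

test_that("configuration files round-trip through flat key-value text", {
  cfg <- sim_config("behavior", mu0 = 2.2, beta = -0.8, decay = c(1, 0.4, 0.1),
                    seed = 77L)
  path <- withr::local_tempfile()
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back[setdiff(names(back), "design")],
               cfg[setdiff(names(cfg), "design")])
  expect_equal(build_design_grid(back$design), build_design_grid(cfg$design))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config("anxiety", sigma = -1), "standard deviations")
  expect_error(sim_config("anxiety", missing_rate = 1.2), "missing_rate")
  expect_error(sim_config("anxiety", decay = c(1, 2, 0)), "decay")
  expect_error(sim_config("anxiety", ar1_rho = 1), "ar1_rho")
  expect_error(simulate_participant(sim_config("anxiety"), "zz"), "not in the design")
})
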