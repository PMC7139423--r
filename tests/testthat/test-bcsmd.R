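test_that("the REML fit agrees with an independent mixed-model oracle", {
  skip_if_not_installed("lme4")
  set.seed(371)
  d <- draw_model_data(m = 8L, n_per = 40L)
  fit <- fit_reversal_model(d)
  lf <- lme4::lmer(score ~ treat + (treat | case), REML = TRUE,
                   data = data.frame(score = d$score,
                                     treat = as.numeric(d$phase_kind == "B"),
                                     case = factor(d$participant_id)))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$beta, unname(lme4::fixef(lf)[2]), tolerance = 1e-5)
  expect_equal(fit$tau_u_sq, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$tau_v_sq, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$tau_uv, vc$vcov[3], tolerance = 1e-4)
  expect_equal(fit$sigma_sq, vc$vcov[4], tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("degenerate no-effect data give a null fit on the boundary", {
  pattern <- c(rep(0, 10), rep(0, 10))
  d <- data.frame(participant_id = rep(1:4, each = 20),
                  score = rep(3, 80) + rep(pattern, 4),
                  phase_kind = rep(rep(c("A0", "B"), each = 10), 4),
                  day_index = rep(1:20, 4), slot_index = 1L, missing = FALSE)
  # identical cases, equal A/B means, plus microscopic jitter to keep
  # sigma^2 positive
  set.seed(72)
  d$score <- d$score + rnorm(80, 0, 1e-3)
  fit <- fit_reversal_model(d)
  expect_lt(abs(fit$beta), 1e-3)
  expect_lt(fit$tau_u_sq, 1e-6)
  expect_lt(fit$tau_v_sq, 1e-6)
})

test_that("the restricted likelihood at the optimum dominates a coarse grid", {
  set.seed(73)
  d <- draw_model_data(m = 3L, n_per = 12L, tau_u = 0.8, tau_v = 0.3)
  fit <- fit_reversal_model(d)
  treat <- as.numeric(d$phase_kind == "B")
  # consistency of the exported evaluator with the fit
  ll_at_fit <- reml_restricted_loglik(d$score, d$participant_id, treat,
                                      fit$tau_u_sq, fit$tau_uv, fit$tau_v_sq,
                                      fit$sigma_sq)
  expect_equal(ll_at_fit, fit$loglik, tolerance = 1e-8)
  for (tu in c(0.05, 0.3, 1, 2)) for (tv in c(0, 0.3, 1)) for (s2 in c(0.5, 1, 2)) {
    ll <- reml_restricted_loglik(d$score, d$participant_id, treat, tu, 0, tv, s2)
    expect_lte(ll, fit$loglik + 1e-6)
  }
})

test_that("REML on balanced random-intercept data equals the ANOVA closed form", {
  set.seed(74)
  for (rep in 1:5) {
    case <- rep(1:8, each = 30)
    y <- 2 + rnorm(8, 0, 1)[case] + rnorm(240)
    fit <- fit_random_intercept(y, case)
    oracle <- anova_moment_oracle(y, case)
    expect_equal(fit$tau_u_sq, oracle$tau_u_sq, tolerance = 1e-5)
    expect_equal(fit$sigma_sq, oracle$sigma_sq, tolerance = 1e-5)
  }
})

test_that("g is shift-invariant and scale-equivariant", {
  set.seed(75)
  d <- draw_model_data(m = 6L, n_per = 24L)
  g0 <- bcsmd_effect(fit_reversal_model(d))$g
  d_shift <- d; d_shift$score <- d$score + 7
  expect_equal(bcsmd_effect(fit_reversal_model(d_shift))$g, g0, tolerance = 1e-4)
  d_scale <- d; d_scale$score <- d$score * 3.5
  expect_equal(bcsmd_effect(fit_reversal_model(d_scale))$g, g0, tolerance = 1e-4)
})

test_that("the effect size obeys its structural identities", {
  set.seed(76)
  d <- draw_model_data(m = 8L, n_per = 30L, beta = -1)
  fit <- fit_reversal_model(d)
  es <- bcsmd_effect(fit)
  expect_equal(es$delta_hat, fit$beta / sqrt(fit$tau_u_sq + fit$sigma_sq))
  expect_equal(es$g, es$J * es$delta_hat)
  expect_true(es$J > 0 && es$J < 1)
  expect_lt(abs(es$g), abs(es$delta_hat))
  expect_equal(es$ci[2] - es$g, es$g - es$ci[1])
  # null effect maps to g = 0 exactly
  fit0 <- fit
  fit0$beta <- 0
  expect_equal(bcsmd_effect(fit0)$g, 0)
})

test_that("validation guards fire for thin and degenerate inputs", {
  d <- draw_model_data(m = 2L, n_per = 10L)
  expect_error(fit_reversal_model(d), "at least 3")
  d5 <- draw_model_data(m = 5L, n_per = 10L)
  d5$phase_kind[d5$participant_id == 1L] <- "A0"  # case 1 never treated
  expect_error(fit_reversal_model(d5), "case.*1")
  expect_warning(fit4 <- fit_reversal_model(d5, drop_insufficient = TRUE),
                 "dropping")
  expect_equal(fit4$n_cases, 4L)
  d5$slot_index <- 2L
  expect_error(stratified_bcsmd(d5, 1L), "slot 1")
})

test_that("AR(1) residual correlation is recovered when requested", {
  set.seed(78)
  m <- 6L; days <- 40L
  rho <- 0.5
  dat <- do.call(rbind, lapply(seq_len(m), function(i) {
    u <- rnorm(1, 0, 0.8)
    treat_day <- rep(sample(rep(c(0, 1), each = days / 2)), each = 3L)
    e <- as.vector(replicate(days, {
      z <- numeric(3); z[1] <- rnorm(1)
      for (s in 2:3) z[s] <- rho * z[s - 1] + rnorm(1, 0, sqrt(1 - rho^2))
      z
    }))
    data.frame(participant_id = i, score = 2 + u - 0.8 * treat_day + e,
               phase_kind = ifelse(treat_day == 1, "B", "A0"),
               day_index = rep(seq_len(days), each = 3L),
               slot_index = rep(1:3, days), missing = FALSE)
  }))
  fit <- fit_reversal_model(dat, cor_struct = "ar1")
  expect_lt(abs(fit$rho - rho), 0.1)
  expect_equal(fit$sigma_sq, 1, tolerance = 0.15)
})
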