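# Between-case standardized mean difference (BC-SMD) for ABAB reversal
# designs.
#
# Hierarchical model for scored observation j of case i:
#
#   Y_ij = (mu + u_i) + (beta + v_i) T_ij + e_ij
#
# with T_ij = 1 on intervention (B-phase) observations, (u_i, v_i) jointly
# mean-zero with covariance [[tau_u^2, tau_uv], [tau_uv, tau_v^2]], and
# e_ij independent N(0, sigma^2) (optionally AR(1) within a day).
# Variance components are estimated by restricted maximum likelihood; the
# design-comparable effect size standardizes beta by the baseline
# between-plus-within variance sqrt(tau_u^2 + sigma^2) and applies the
# small-sample correction J(nu) = 1 - 3 / (4 nu - 1) with Satterthwaite
# degrees of freedom for the variance denominator.
#
# All likelihood evaluations reduce each case to sufficient statistics
# (crossproducts of y, X and Z) so the 2x2 Woodbury identities make the
# optimization cost independent of series length:
#   V = sigma^2 R + Z G Z'
#   log|V| = log|sigma^2 R| + log|I_q + Z'R^{-1}Z G / sigma^2|
#   V^{-1} = R^{-1}/sigma^2 - R^{-1} Z W Z' R^{-1} / sigma^4,
#   W = (G^{-1} + Z'R^{-1}Z/sigma^2)^{-1} = G (I_q + Z'R^{-1}Z G/sigma^2)^{-1}
# (the last form needs no G^{-1}, so boundary G is handled directly).

# Sufficient statistics of one case under working correlation R (identity,
# or AR(1) across within-day slot distances when rho is non-zero).
case_suff_stats <- function(y, X, Z, day, slot, rho = 0) {
  if (rho == 0) {
    list(ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = drop(crossprod(Z, y)),
         XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y * y),
         n = length(y), logdetR = 0)
  } else {
    p <- ncol(X); q <- ncol(Z)
    ZtZ <- matrix(0, q, q); ZtX <- matrix(0, q, p); Zty <- numeric(q)
    XtX <- matrix(0, p, p); Xty <- numeric(p); yty <- 0; logdetR <- 0
    for (d in unique(day)) {
      idx <- which(day == d)
      Rd <- rho^abs(outer(slot[idx], slot[idx], "-"))
      Ri <- solve(Rd)
      logdetR <- logdetR + determinant(Rd, logarithm = TRUE)$modulus
      Zi <- Z[idx, , drop = FALSE]; Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      ZtZ <- ZtZ + t(Zi) %*% Ri %*% Zi
      ZtX <- ZtX + t(Zi) %*% Ri %*% Xi
      Zty <- Zty + drop(t(Zi) %*% Ri %*% yi)
      XtX <- XtX + t(Xi) %*% Ri %*% Xi
      Xty <- Xty + drop(t(Xi) %*% Ri %*% yi)
      yty <- yty + drop(t(yi) %*% Ri %*% yi)
    }
    list(ZtZ = ZtZ, ZtX = ZtX, Zty = Zty, XtX = XtX, Xty = Xty, yty = yty,
         n = length(y), logdetR = as.numeric(logdetR))
  }
}

# Restricted log-likelihood (Harville form) plus GLS fixed effects for
# given variance components.  Returns NULL when V is not positive
# definite at the proposed parameters.
reml_core <- function(stats, G, sigma2, n_total, p) {
  if (!is.finite(sigma2) || sigma2 <= 0) return(NULL)
  q <- nrow(G)
  Iq <- diag(q)
  ld <- 0; A <- matrix(0, p, p); b <- numeric(p); qy <- 0
  for (st in stats) {
    K <- Iq + st$ZtZ %*% G / sigma2
    dk <- det(K)
    if (!is.finite(dk) || dk <= 1e-300) return(NULL)
    W <- G %*% solve(K)
    W <- (W + t(W)) / 2
    ld <- ld + st$n * log(sigma2) + st$logdetR + log(dk)
    A <- A + st$XtX / sigma2 - t(st$ZtX) %*% W %*% st$ZtX / sigma2^2
    b <- b + st$Xty / sigma2 - drop(t(st$ZtX) %*% W %*% st$Zty) / sigma2^2
    qy <- qy + st$yty / sigma2 - drop(t(st$Zty) %*% W %*% st$Zty) / sigma2^2
  }
  dA <- det(A)
  if (!is.finite(dA) || dA <= 0) return(NULL)
  beta <- solve(A, b)
  rss <- qy - sum(b * beta)
  if (!is.finite(rss)) return(NULL)
  rss <- max(rss, 0)
  ll <- -0.5 * (ld + log(dA) + rss) - 0.5 * (n_total - p) * log(2 * pi)
  list(ll = ll, beta = drop(beta), XtVinvX = A)
}

#' Restricted log-likelihood of the reversal model
#'
#' Evaluates the restricted (REML) log-likelihood of the hierarchical
#' ABAB model at user-supplied variance components. Useful for
#' diagnostics and for checking an optimum against grid searches.
#'
#' @param y Numeric outcome scores.
#' @param case Case (participant) identifiers, one per observation.
#' @param treat Logical/0-1 treatment indicator (B-phase observation).
#' @param tau_u_sq,tau_uv,tau_v_sq,sigma_sq Variance components
#'   (`sigma_sq > 0`; the random-effect covariance matrix must keep the
#'   marginal covariance positive definite).
#' @return The restricted log-likelihood (scalar), `-Inf` when the
#'   proposed components are inadmissible.
#' @export
reml_restricted_loglik <- function(y, case, treat, tau_u_sq, tau_uv = 0,
                                   tau_v_sq = 0, sigma_sq = 1) {
  treat <- as.numeric(treat)
  stats <- lapply(split(seq_along(y), as.character(case)), function(idx) {
    X <- cbind(1, treat[idx])
    case_suff_stats(y[idx], X, X, day = NULL, slot = NULL, rho = 0)
  })
  G <- matrix(c(tau_u_sq, tau_uv, tau_uv, tau_v_sq), 2, 2)
  res <- reml_core(stats, G, sigma_sq, length(y), 2L)
  if (is.null(res)) -Inf else res$ll
}

# Two-stage optimization (Nelder-Mead then L-BFGS-B polish) of the REML
# criterion over an unconstrained parameterization: G = sigma^2 L L' with
# L lower-triangular (so G is positive semi-definite by construction) and
# log sigma^2.
reml_optimize <- function(stats_fn, n_total, p, q, start, estimate_rho = FALSE) {
  npar_L <- if (q == 2L) 3L else 1L
  unpack <- function(par) {
    L <- if (q == 2L) matrix(c(par[1L], par[2L], 0, par[3L]), 2, 2)
    else matrix(par[1L], 1, 1)
    sigma2 <- exp(par[npar_L + 1L])
    rho <- if (estimate_rho) tanh(par[npar_L + 2L]) else 0
    list(G = sigma2 * tcrossprod(L), sigma2 = sigma2, rho = rho)
  }
  objective <- function(par) {
    th <- unpack(par)
    res <- reml_core(stats_fn(th$rho), th$G, th$sigma2, n_total, p)
    if (is.null(res)) 1e10 else -res$ll
  }
  o1 <- stats::optim(start, objective, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  lower <- rep(-Inf, length(start))
  lower[1L] <- 0
  if (q == 2L) lower[3L] <- 0
  o2 <- tryCatch(
    stats::optim(o1$par, objective, method = "L-BFGS-B", lower = lower,
                 control = list(factr = 1e4, maxit = 200)),
    error = function(e) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  rel_change <- abs(o1$value - best$value) / max(1, abs(best$value))
  th <- unpack(best$par)
  th$value <- best$value
  th$converged <- rel_change < 1e-8 || best$convergence == 0
  th
}

#' Fit the hierarchical reversal model by REML
#'
#' Estimates the two-level model `Y_ij = (mu + u_i) + (beta + v_i) T_ij +
#' e_ij` by restricted maximum likelihood, where every observation on an
#' intervention (B-phase) day counts as treated. Variance components are
#' constrained non-negative via a Cholesky parameterization; estimates on
#' the boundary are reported, not hidden. The covariance `tau_uv` between
#' case level and case treatment response is estimated by default and is
#' structurally zero when `random_slope = FALSE`.
#'
#' @param data Scored-observation data frame (layout of [score_dataset()])
#'   for one outcome; missing scores are dropped.
#' @param treatment Optional logical treatment indicator; by default
#'   `phase_kind == "B"`.
#' @param random_slope Allow the treatment effect to vary across cases?
#' @param cor_struct `"iid"` (default) or `"ar1"`: residual correlation
#'   across successive within-day slots, estimated jointly.
#' @param drop_insufficient Drop cases lacking two observations per
#'   condition (with a warning) instead of erroring.
#' @return An object of class `reversal_fit`: fixed effects (`mu`,
#'   `beta`), `vcov_beta`, variance components `tau_u_sq`, `tau_uv`,
#'   `tau_v_sq`, `sigma_sq`, residual correlation `rho`, restricted
#'   log-likelihood `loglik`, `converged`, `boundary` flags, the
#'   information-matrix covariance of the variance estimates
#'   (`vcov_varcomp`), case/observation counts.
#' @export
fit_reversal_model <- function(data, treatment = NULL, random_slope = TRUE,
                               cor_struct = c("iid", "ar1"),
                               drop_insufficient = FALSE) {
  cor_struct <- match.arg(cor_struct)
  if (is.null(treatment)) treatment <- data$phase_kind == "B"
  keep <- !is.na(data$score) & !(data$missing %||% FALSE)
  y <- data$score[keep]
  treat <- as.numeric(treatment[keep])
  case <- as.character(data$participant_id[keep])
  day <- data$day_index[keep]
  slot <- data$slot_index[keep]

  counts <- table(case, treat)
  ok <- rownames(counts)[apply(counts >= 2L, 1L, all) & ncol(counts) == 2L]
  if (length(ok) < length(unique(case))) {
    bad <- setdiff(unique(case), ok)
    if (!drop_insufficient)
      stopf("case(s) %s lack two observations per condition",
            paste(bad, collapse = ", "))
    warning(sprintf("dropping case(s) %s: fewer than two observations per condition",
                    paste(bad, collapse = ", ")))
    sel <- case %in% ok
    y <- y[sel]; treat <- treat[sel]; case <- case[sel]
    day <- day[sel]; slot <- slot[sel]
  }
  cases <- unique(case)
  if (length(cases) < 3L)
    stopf("the reversal model needs at least 3 usable cases, got %d", length(cases))

  q <- if (random_slope) 2L else 1L
  idx_by_case <- split(seq_along(y), case)
  stats_for <- function(rho) {
    lapply(idx_by_case, function(idx) {
      X <- cbind(1, treat[idx])
      Z <- if (q == 2L) X else X[, 1L, drop = FALSE]
      case_suff_stats(y[idx], X, Z, day[idx], slot[idx], rho)
    })
  }
  stats0 <- stats_for(0)

  # Moment-based starting values from per-case condition means.
  mA <- vapply(idx_by_case, function(idx) mean(y[idx][treat[idx] == 0]), 0)
  mB <- vapply(idx_by_case, function(idx) mean(y[idx][treat[idx] == 1]), 0)
  res_var <- mean(vapply(idx_by_case, function(idx) {
    r <- y[idx] - ifelse(treat[idx] == 1, mB[case[idx][1L]], mA[case[idx][1L]])
    sum(r^2) / max(1, length(idx) - 2L)
  }, 0))
  sigma0 <- max(res_var, 1e-4)
  tau_u0 <- max(stats::var(mA), 1e-4)
  tau_v0 <- max(stats::var(mB - mA) / 2, 1e-4)
  start <- if (q == 2L)
    c(sqrt(tau_u0 / sigma0), 0, sqrt(tau_v0 / sigma0), log(sigma0))
  else c(sqrt(tau_u0 / sigma0), log(sigma0))
  if (cor_struct == "ar1") start <- c(start, 0)

  opt <- reml_optimize(if (cor_struct == "ar1") stats_for else function(rho) stats0,
                       length(y), 2L, q, start,
                       estimate_rho = cor_struct == "ar1")
  fit_stats <- if (cor_struct == "ar1") stats_for(opt$rho) else stats0
  res <- reml_core(fit_stats, opt$G, opt$sigma2, length(y), 2L)
  if (is.null(res)) stopf("REML optimization failed to locate an admissible optimum")

  G <- opt$G
  tau_u_sq <- if (q == 2L) G[1L, 1L] else G[1L, 1L]
  tau_uv <- if (q == 2L) G[1L, 2L] else 0
  tau_v_sq <- if (q == 2L) G[2L, 2L] else 0
  sigma_sq <- opt$sigma2
  boundary <- c(tau_u_sq = tau_u_sq < 1e-8 * sigma_sq,
                tau_v_sq = q == 2L && tau_v_sq < 1e-8 * sigma_sq)

  # Observed information of the variance components (variance scale), for
  # Satterthwaite degrees of freedom.  Components on the boundary are held
  # fixed; tau_uv is tied to tau_v_sq.
  names_var <- c("tau_u_sq", "tau_uv", "tau_v_sq", "sigma_sq")
  est_var <- c(tau_u_sq, tau_uv, tau_v_sq, sigma_sq)
  free <- c(!boundary[["tau_u_sq"]],
            q == 2L && !boundary[["tau_v_sq"]],
            q == 2L && !boundary[["tau_v_sq"]],
            TRUE)
  f_var <- function(v_free) {
    v <- est_var
    v[free] <- v_free
    Gv <- if (q == 2L) matrix(c(v[1L], v[2L], v[2L], v[3L]), 2, 2)
    else matrix(v[1L], 1, 1)
    r <- reml_core(fit_stats, Gv, v[4L], length(y), 2L)
    if (is.null(r)) NA_real_ else r$ll
  }
  H <- fd_hessian(f_var, est_var[free])
  vcov_free <- tryCatch(solve(-H), error = function(e) ginv_svd(-H))
  vcov_varcomp <- matrix(0, 4L, 4L, dimnames = list(names_var, names_var))
  vcov_varcomp[free, free] <- vcov_free

  structure(list(mu = res$beta[1L], beta = res$beta[2L],
                 vcov_beta = solve(res$XtVinvX),
                 tau_u_sq = tau_u_sq, tau_uv = tau_uv, tau_v_sq = tau_v_sq,
                 sigma_sq = sigma_sq, rho = opt$rho,
                 loglik = res$ll, converged = opt$converged,
                 boundary = boundary, vcov_varcomp = vcov_varcomp,
                 n_cases = length(cases), n_obs = length(y),
                 cases = cases, random_slope = random_slope,
                 cor_struct = cor_struct),
            class = "reversal_fit")
}

#' REML fit of a pure random-intercept model
#'
#' Degenerate special case of the engine behind [fit_reversal_model()]:
#' intercept-only fixed effect and a case-level random intercept. On
#' balanced data the REML estimates coincide with the one-way ANOVA
#' moment estimators whenever those are non-negative.
#'
#' @param y Numeric outcome values.
#' @param case Case identifiers, one per observation.
#' @return List with `mu`, `tau_u_sq`, `sigma_sq`, `loglik`, `converged`.
#' @export
fit_random_intercept <- function(y, case) {
  idx_by_case <- split(seq_along(y), as.character(case))
  if (length(idx_by_case) < 2L) stopf("need at least 2 cases")
  stats0 <- lapply(idx_by_case, function(idx) {
    X <- matrix(1, length(idx), 1L)
    case_suff_stats(y[idx], X, X, day = NULL, slot = NULL, rho = 0)
  })
  m <- vapply(idx_by_case, function(idx) mean(y[idx]), 0)
  s2 <- mean(vapply(idx_by_case, function(idx) stats::var(y[idx]), 0), na.rm = TRUE)
  s2 <- max(s2, 1e-4)
  start <- c(sqrt(max(stats::var(m), 1e-4) / s2), log(s2))
  opt <- reml_optimize(function(rho) stats0, length(y), 1L, 1L, start)
  res <- reml_core(stats0, opt$G, opt$sigma2, length(y), 1L)
  list(mu = res$beta[1L], tau_u_sq = opt$G[1L, 1L], sigma_sq = opt$sigma2,
       loglik = res$ll, converged = opt$converged)
}

#' Design-comparable effect size from a reversal-model fit
#'
#' Standardizes the treatment effect by the baseline variance
#' `S^2 = tau_u^2 + sigma^2` (between-case plus within-case; the
#' treatment-effect variance is excluded), giving
#' `delta_hat = beta / sqrt(S^2)`. The small-sample correction
#' `J = 1 - 3 / (4 nu - 1)` uses Satterthwaite degrees of freedom
#' `nu = 2 S^4 / Var(S^2)` from the information-matrix covariance of the
#' variance estimates; `g = J * delta_hat` with delta-method standard
#' error `J * sqrt(Var(beta)/S^2 + delta_hat^2 / (2 nu))` and a symmetric
#' normal confidence interval.
#'
#' @param fit A [fit_reversal_model()] result.
#' @param level Confidence level.
#' @return An object of class `bcsmd_result`: `delta_hat`, `nu`, `J`, `g`,
#'   `se`, `ci`, plus the variance components carried over from the fit.
#' @export
bcsmd_effect <- function(fit, level = 0.95) {
  if (!inherits(fit, "reversal_fit")) stopf("'fit' must be a reversal_fit")
  if (!fit$converged) warning("effect size computed from a non-converged fit")
  S2 <- fit$tau_u_sq + fit$sigma_sq
  if (S2 <= 0) stopf("undefined effect: tau_u_sq + sigma_sq is zero")
  idx <- c("tau_u_sq", "sigma_sq")
  var_S2 <- sum(fit$vcov_varcomp[idx, idx])
  nu <- if (var_S2 > 0) 2 * S2^2 / var_S2 else Inf
  J <- if (is.finite(nu)) 1 - 3 / (4 * nu - 1) else 1
  delta_hat <- fit$beta / sqrt(S2)
  g <- J * delta_hat
  se <- J * sqrt(fit$vcov_beta[2L, 2L] / S2 +
                   if (is.finite(nu)) delta_hat^2 / (2 * nu) else 0)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(delta_hat = delta_hat, nu = nu, J = J, g = g, se = se,
                 ci = c(g - z * se, g + z * se), level = level,
                 beta = fit$beta, tau_u_sq = fit$tau_u_sq,
                 tau_v_sq = fit$tau_v_sq, sigma_sq = fit$sigma_sq,
                 n_cases = fit$n_cases, n_obs = fit$n_obs),
            class = "bcsmd_result")
}

#' Slot-stratified BC-SMD
#'
#' Restricts estimation to one within-day assessment slot (e.g. the first
#' assessment of each day, taken directly after an intervention session)
#' and runs the identical model and effect-size computation on the subset.
#'
#' @param data Scored-observation data frame.
#' @param slot_index Within-day slot to keep (1-based).
#' @param level Confidence level.
#' @param ... Passed to [fit_reversal_model()].
#' @return A `bcsmd_result`.
#' @export
stratified_bcsmd <- function(data, slot_index, level = 0.95, ...) {
  sub <- data[data$slot_index == slot_index, , drop = FALSE]
  if (!nrow(sub) || all(is.na(sub$score)))
    stopf("slot %s has no usable observations", slot_index)
  fit <- tryCatch(fit_reversal_model(sub, ...),
                  error = function(e) stopf("slot %s: %s", slot_index,
                                            conditionMessage(e)))
  bcsmd_effect(fit, level)
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat(sprintf(paste0("Hierarchical reversal model (REML, %d cases, %d observations)\n",
                     "  fixed: mu = %.3f, beta = %.3f (SE %.3f)\n",
                     "  variance: tau_u^2 = %.4f, tau_uv = %.4f, tau_v^2 = %.4f, sigma^2 = %.4f\n",
                     "  restricted logLik = %.3f%s\n"),
              x$n_cases, x$n_obs, x$mu, x$beta, sqrt(x$vcov_beta[2L, 2L]),
              x$tau_u_sq, x$tau_uv, x$tau_v_sq, x$sigma_sq, x$loglik,
              if (any(x$boundary)) " (boundary estimate)" else ""))
  invisible(x)
}

#' @export
print.bcsmd_result <- function(x, ...) {
  cat(sprintf("BC-SMD: g = %.3f (SE %.3f; %d%% CI %.3f to %.3f), nu = %.1f, J = %.4f\n",
              x$g, x$se, round(100 * x$level), x$ci[1], x$ci[2], x$nu, x$J))
  invisible(x)
}
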