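test_that("sigma_u = 0 reduces the marginal likelihood to plain logistic regression", {
  set.seed(50)
  d <- sim_glmm_data(m = 10, nper = 8, beta_feature = 0.7, sigma_u = 0.5)
  g <- glm.fit(d$X, d$y, family = binomial())
  beta <- g$coefficients
  ll_glm <- sum(dbinom(d$y, 1, g$fitted.values, log = TRUE))
  expect_equal(marginal_loglik(beta, 0, d$X, d$y, d$pid), ll_glm,
               tolerance = 1e-10)
  # continuous limit
  expect_equal(marginal_loglik(beta, 1e-6, d$X, d$y, d$pid), ll_glm,
               tolerance = 1e-4)
})

test_that("Laplace and adaptive Gauss-Hermite agree on random small instances", {
  set.seed(51)
  for (r in 1:20) {
    m <- sample(2:5, 1); nper <- sample(3:10, 1)
    pid <- rep(seq_len(m), each = nper)
    X <- cbind(1, rnorm(m * nper))
    beta <- runif(2, -2, 2); su <- runif(1, 0.1, 2)
    u <- rnorm(m, 0, su)
    y <- rbinom(m * nper, 1, plogis(X %*% beta + u[pid]))
    if (length(unique(y)) < 2) next
    l1 <- marginal_loglik(beta, su, X, y, pid, "laplace")
    l2 <- marginal_loglik(beta, su, X, y, pid, "aghq", nodes = 25)
    expect_lt(abs(l1 - l2), 1e-2)
    # more quadrature nodes do not change the oracle materially
    l3 <- marginal_loglik(beta, su, X, y, pid, "aghq", nodes = 40)
    expect_lt(abs(l2 - l3), 1e-6)
  }
})

test_that("the fitted optimum is a local maximum of the marginal likelihood", {
  set.seed(52)
  d <- sim_glmm_data(m = 15, nper = 12, beta_feature = 0.5, sigma_u = 1)
  f <- fit_glmm(d$y, d$X, d$pid)
  expect_true(f$converged)
  ll_hat <- marginal_loglik(f$coefficients$estimate, f$sigma_u, d$X, d$y, d$pid)
  expect_equal(ll_hat, f$loglik, tolerance = 1e-6)
  for (j in 1:5) {
    pert <- f$coefficients$estimate + rnorm(5, 0, 0.05)
    expect_lte(marginal_loglik(pert, f$sigma_u, d$X, d$y, d$pid),
               ll_hat + 1e-8)
  }
})

test_that("estimates match the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(53)
  d <- sim_glmm_data(m = 25, nper = 20, beta_feature = 0.5, sigma_u = 1)
  f <- fit_glmm(d$y, d$X, d$pid)
  df <- data.frame(y = d$y, x = d$x, tg = factor(d$tg), pid = d$pid)
  ref <- lme4::glmer(y ~ x + tg + (1 | pid), df, binomial, nAGQ = 25)
  ref_beta <- lme4::fixef(ref)[["x"]]
  ref_se <- sqrt(diag(as.matrix(vcov(ref))))[2]
  expect_equal(f$coefficients$estimate[2], ref_beta, tolerance = 0.02)
  expect_equal(f$coefficients$se[2], unname(ref_se), tolerance = 0.05)
  expect_equal(unname(f$sigma_u), sqrt(unname(unlist(lme4::VarCorr(ref))[[1]])),
               tolerance = 0.05)
})

test_that("single-class outcomes and single-patient data are rejected", {
  X <- cbind(1, rnorm(20))
  expect_error(fit_glmm(rep(1, 20), X, rep(1:2, 10)), "single class")
  expect_error(fit_glmm(rbinom(20, 1, 0.5), X, rep(1, 20)), "2 patients")
})

test_that("complete separation is flagged rather than reported as converged", {
  set.seed(54)
  x <- c(rnorm(20, -2), rnorm(20, 2))
  y <- rep(c(0L, 1L), each = 20)
  X <- cbind(1, x)
  pid <- rep(1:4, each = 10)
  f <- fit_glmm(y, X, pid)
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("the screen fits one model per feature x outcome with the right data", {
  set.seed(55)
  n <- 120
  rows <- expand.grid(survey_id = sprintf("s%03d", 1:n),
                      signal = c("hr", "eda_tonic"),
                      feature = c("median", "sd"),
                      stringsAsFactors = FALSE)
  rows$modality <- sub("_.*$", "", rows$signal)
  rows$patient_id <- rep(sprintf("P%02d", rep(1:10, each = 12)), 4)
  rows$z <- rnorm(nrow(rows))
  rows$agitated <- rep(rbinom(n, 1, 0.3), 4)
  rows$motor_agitated <- as.integer(rows$agitated & rbinom(nrow(rows), 1, 0.5))
  rows$verbal_agitated <- 0L
  rows$time_group <- rep(sample(1:4, n, replace = TRUE), 4)
  rows$z_ambient_mean <- rnorm(nrow(rows))
  rows$z_acc_sd <- rnorm(nrow(rows))
  # heart-rate rows with a missing movement confounder must drop out
  drop_sv <- rows$survey_id %in% sprintf("s%03d", 1:10)
  rows$z_acc_sd[drop_sv] <- NA
  scr <- run_feature_screen(rows, outcomes = c("agitated", "motor_agitated"))
  expect_equal(nrow(scr), 8L)   # 2 signals x 2 features x 2 outcomes
  expect_equal(unique(scr$n_obs[scr$modality == "hr"]), 110L)
  expect_equal(unique(scr$n_obs[scr$modality == "eda"]), 120L)
  # deterministic ordering
  expect_identical(scr, scr[order(scr$modality, scr$signal, scr$feature,
                                  scr$outcome), ])
})

test_that("planted effects are recovered on a single simulated data set", {
  set.seed(56)
  d <- sim_glmm_data(m = 30, nper = 30, beta_feature = 0.6, sigma_u = 0.8)
  f <- fit_glmm(d$y, d$X, d$pid)
  est <- f$coefficients[f$coefficients$term == "feature", ]
  expect_true(f$converged)
  expect_lt(abs(est$estimate - 0.6), 3 * est$se)
  expect_gt(est$estimate, 0.2)
  expect_lt(abs(f$sigma_u - 0.8), 0.4)
})
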