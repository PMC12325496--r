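test_that("parameter container enforces its invariants", {
  expect_error(model_params(1.2, 0, 1, 1, 1), "alpha")
  expect_error(model_params(0.5, 0, 1, 1, 0), "sigma")
  expect_error(model_params(0.5, 0, 1, 1, 1, h = 0), "h")
  p <- model_params(0.5, 0, 2, -1, 1)
  # attention weights use absolute magnitudes and sum to 1
  expect_equal(attention_weights(p), c(2 / 3, 1 / 3))
  expect_warning(w0 <- attention_weights(c(0, 0)), "equal attention")
  expect_equal(w0, c(0.5, 0.5))
})

test_that("weighted city-block distance is correct and validates weights", {
  expect_equal(weighted_cityblock(c(2, 3), c(2, 3), c(.5, .5)), 0)
  expect_equal(weighted_cityblock(c(1, 1), c(2, 1), c(.5, .5)), 0.5)
  expect_equal(weighted_cityblock(c(1, 1), c(4, 3), c(.5, .5)), 2.5)
  expect_equal(weighted_cityblock(c(1, 1), c(4, 3), c(1, 0)), 3)
  expect_error(weighted_cityblock(c(1, 1), c(2, 2), c(-.2, 1.2)),
               "non-negative")
  expect_error(weighted_cityblock(c(1, 1), c(2, 2), c(.3, .3)), "sum to 1")
})

test_that("similarity prediction matches a brute-force oracle and never extrapolates", {
  env <- test_env()
  # h = 0: all similarities equal, prediction is the plain exemplar mean
  p0 <- model_params(1, 0, 1, 1, 1, h = 1e-12)
  expect_equal(similarity_prediction(2, 4, env, p0), 12, tolerance = 1e-6)
  # very large h: prediction collapses onto the matching exemplar
  ph <- model_params(1, 0, 1, 1, 1, h = 50)
  expect_equal(similarity_prediction(4, 3, env, ph), 22, tolerance = 1e-6)
  # brute-force oracle over the whole grid for several parameter draws
  set.seed(11)
  g <- stimulus_grid()
  for (k in 1:5) {
    b1 <- runif(1, -2, 6); b2 <- runif(1, -2, 6); h <- runif(1, 0.2, 3)
    p <- model_params(0.5, 0, b1, b2, 1, h = h)
    w <- abs(c(b1, b2)) / sum(abs(c(b1, b2)))
    pred <- similarity_prediction(g$x1, g$x2, env, p)
    oracle <- mapply(oracle_similarity, g$x1, g$x2,
                     MoreArgs = list(exemplars = env$exemplars, w = w, h = h))
    expect_equal(pred, oracle, tolerance = 1e-12)
    expect_true(all(pred >= min(env$exemplars$criterion) - 1e-9))
    expect_true(all(pred <= max(env$exemplars$criterion) + 1e-9))
  }
})

test_that("rule prediction is linear and extrapolates beyond the exemplars", {
  p <- model_params(0, 2, 0, 0, 1)
  expect_equal(rule_prediction(3, 4, p), 2)
  p <- model_params(0, 0, 1, 1, 1)
  expect_equal(rule_prediction(3, 4, p), 7)
  # OLS fit to the four exemplars via an independent normal-equations oracle
  env <- test_env()
  X <- cbind(1, env$exemplars$x1, env$exemplars$x2)
  b <- solve(t(X) %*% X, t(X) %*% env$exemplars$criterion)
  p_ols <- model_params(0, b[1], b[2], b[3], 1)
  expect_equal(rule_prediction(4, 4, p_ols),
               sum(b * c(1, 4, 4)), tolerance = 1e-10)
  expect_gt(rule_prediction(4, 4, p_ols), max(env$exemplars$criterion))
})

test_that("mixture prediction is the alpha blend and monotone in alpha", {
  env <- test_env()
  base <- list(beta0 = -9.25, beta1 = 5.25, beta2 = 3.25, sigma = 2)
  p_rule <- model_params(0, base$beta0, base$beta1, base$beta2, base$sigma)
  p_sim <- model_params(1, base$beta0, base$beta1, base$beta2, base$sigma)
  p_mid <- model_params(.5, base$beta0, base$beta1, base$beta2, base$sigma)
  g <- stimulus_grid()
  m_rule <- mixture_prediction(g$x1, g$x2, env, p_rule)
  m_sim <- mixture_prediction(g$x1, g$x2, env, p_sim)
  m_mid <- mixture_prediction(g$x1, g$x2, env, p_mid)
  expect_equal(m_rule$c_mix, m_rule$c_rule)
  expect_equal(m_sim$c_mix, m_sim$c_sim)
  expect_equal(m_mid$c_mix, (m_rule$c_mix + m_sim$c_mix) / 2)
  # c_mix always between the two process predictions
  expect_true(all(m_mid$c_mix >= pmin(m_mid$c_sim, m_mid$c_rule) - 1e-12))
  expect_true(all(m_mid$c_mix <= pmax(m_mid$c_sim, m_mid$c_rule) + 1e-12))
  # monotone toward c_sim as alpha grows
  alphas <- seq(0, 1, by = 0.25)
  at_11 <- vapply(alphas, function(a) {
    pa <- model_params(a, base$beta0, base$beta1, base$beta2, base$sigma)
    mixture_prediction(1, 1, env, pa)$c_mix
  }, numeric(1))
  gap <- abs(at_11 - m_sim$c_sim[g$x1 == 1 & g$x2 == 1])
  expect_true(all(diff(gap) <= 1e-12))
})

test_that("log-likelihood matches a per-trial density oracle and is order-invariant", {
  env <- test_env()
  p <- model_params(.4, -9.25, 5.25, 3.25, 2)
  # single trial, response at the mean, sigma 1
  p1 <- model_params(.4, -9.25, 5.25, 3.25, 1)
  m <- mixture_prediction(2, 3, env, p1)$c_mix
  one <- tibble::tibble(x1 = 2, x2 = 3, response = m)
  expect_equal(log_likelihood(one, env, p1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # additivity over identical trials
  two <- one[c(1, 1), ]
  expect_equal(log_likelihood(two, env, p1),
               2 * log_likelihood(one, env, p1), tolerance = 1e-12)
  # random table vs. independent per-trial Gaussian density oracle
  set.seed(21)
  d <- tibble::tibble(x1 = sample(1:4, 10, TRUE), x2 = sample(1:4, 10, TRUE),
                      response = runif(10, 1, 30))
  mix <- mixture_prediction(d$x1, d$x2, env, p)$c_mix
  oracle <- sum(-(d$response - mix)^2 / (2 * p$sigma^2) -
                  log(p$sigma * sqrt(2 * pi)))
  expect_equal(log_likelihood(d, env, p), oracle, tolerance = 1e-10)
  # invariant to trial order
  expect_equal(log_likelihood(d[sample(10), ], env, p),
               log_likelihood(d, env, p), tolerance = 1e-12)
  expect_error(log_likelihood(d[0, ], env, p), "empty")
  d$response[1] <- NA
  expect_error(log_likelihood(d, env, p), "non-finite")
})

test_that("truncated likelihood renormalizes to the response scale", {
  env <- test_env()
  p <- model_params(.5, -9.25, 5.25, 3.25, 5)
  d <- tibble::tibble(x1 = c(1, 4), x2 = c(1, 4), response = c(4, 29))
  ll_plain <- log_likelihood(d, env, p)
  ll_trunc <- log_likelihood(d, env, p, truncate = TRUE)
  m <- mixture_prediction(d$x1, d$x2, env, p)$c_mix
  z <- pnorm(30, m, p$sigma) - pnorm(1, m, p$sigma)
  expect_equal(ll_trunc, ll_plain - sum(log(z)), tolerance = 1e-12)
  expect_gt(ll_trunc, ll_plain)
})

test_that("parameters round-trip through a flat list", {
  p <- model_params(.3, 1, 2, 3, 4, h = 2)
  expect_equal(params_from_list(params_to_list(p)), p)
})
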