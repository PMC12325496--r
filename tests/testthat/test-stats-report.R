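test_that("Kendall correlation matches the brute-force pair-counting oracle", {
  expect_equal(kendall_tau(1:8, 1:8)$tau, 1)
  expect_equal(kendall_tau(1:8, 8:1)$tau, -1)
  # fixtures with ties, against the O(n^2) counting oracle
  set.seed(51)
  for (k in 1:10) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:5, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau(x, y)$tau, oracle_kendall(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(kt <- kendall_tau(rep(1, 5), 1:5), "constant")
  expect_true(is.na(kt$tau))
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("rank-sum comparison handles separation, identity, and singletons", {
  # fully separated groups of 5: the rank-sum statistic is extremal.
  # Exhaustive enumeration over all 10-choose-5 assignments gives the
  # attainable W range [0, 25]; full separation must hit an endpoint.
  v <- c(1:5, 101:105)
  lab <- rep(c("a", "b"), each = 5)
  res <- group_compare(v, lab)
  combos <- utils::combn(10, 5)
  all_W <- apply(combos, 2, function(idx) {
    sum(rank(v)[idx]) - 5 * 6 / 2
  })
  expect_true(res$W %in% range(all_W))
  expect_lt(res$p, 0.01)
  # identical groups: p near 1
  res <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(res$p, 0.9)
  # a singleton group still works, with a warning
  expect_warning(res <- group_compare(c(1, 5, 6, 7), c("a", "b", "b", "b")),
                 "single")
  expect_true(is.finite(res$p))
  expect_error(group_compare(1:3, rep("a", 3)), "two groups")
})

test_that("sensitivity power analysis reproduces the design value and inverts", {
  expect_equal(round(sensitivity_power_correlation(48), 2), 0.49)
  # vanishing detectable effect at very large n
  expect_lt(sensitivity_power_correlation(1e6), 0.01)
  # round-trip with the unrounded detectable correlation
  rho <- sensitivity_power_correlation(48)
  expect_equal(required_n_correlation(rho, ceiling = FALSE), 48,
               tolerance = 1e-6)
  expect_identical(required_n_correlation(rho), 48)
  expect_error(sensitivity_power_correlation(3), "exceed 3")
})

test_that("pooled chi-square test compares trial-level proportions", {
  res <- prop_chisq(550, 1000, 310, 1000)
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.001)
  expect_equal(res$prop1, 0.55)
  # no continuity correction: matches the textbook statistic
  m <- matrix(c(550, 450, 310, 690), nrow = 2)
  expect_equal(res$chisq,
               unname(suppressWarnings(
                 chisq.test(m, correct = FALSE)$statistic)))
})

test_that("exemplar accuracy scores exact criterion matches, optionally with location", {
  env <- test_env()
  j <- tibble::tibble(x1 = c(2, 1, 3, 4, 1), x2 = c(1, 4, 2, 3, 1),
                      response = c(5, 9, 10, 22, 4))
  expect_equal(exemplar_accuracy(j, env), 0.75)  # (1,1) is not an exemplar
  expect_equal(exemplar_accuracy(j, env, location_accuracy = 0.25), 0.5)
  expect_error(exemplar_accuracy(j[5, ], env), "no exemplar trials")
})

test_that("critical-stimuli errors for a noiseless rule cohort equal the closed form", {
  env <- test_env()
  spec <- cohort_spec(n_participants = 2, n_blocks = 2,
                      alpha_sampler = function(n) rep(0, n),
                      beta_jitter_sd = 0, sigma = 0, seed = 9)
  truth <- generate_truth(spec, env)
  j <- generate_judgments(spec, env, truth)
  fits <- tibble::tibble(participant = truth$participant,
                         classification = "rule_user")
  tab <- critical_stimuli_table(j, fits, env)
  # signed error = rounded OLS rule prediction minus the true criterion
  p <- model_params(0, truth$beta0[1], truth$beta1[1], truth$beta2[1], 1)
  for (i in seq_len(nrow(tab))) {
    pred <- round_half_away(rule_prediction(tab$x1[i], tab$x2[i], p))
    pred <- pmin(pmax(pred, 1), 30)
    expect_equal(tab$signed_error[i], pred - tab$c_true[i])
  }
  expect_setequal(paste(tab$x1, tab$x2), c("1 1", "1 2", "3 4", "4 4"))
})

test_that("the report assembles correlations, groups and flags end to end", {
  env <- test_env()
  set.seed(61)
  n <- 12
  alpha <- runif(n)
  fits <- tibble::tibble(
    participant = 1:n, alpha = alpha,
    classification = classify_user(alpha),
    single_cue = FALSE
  )
  gaze <- tibble::tibble(
    participant = 1:n,
    lan_presence = pmin(1, 0.1 + 0.6 * alpha + rnorm(n, sd = 0.05)),
    mean_lan_duration = pmin(1, pmax(0, 0.05 + 0.3 * alpha +
                                       rnorm(n, sd = 0.02))),
    mean_lan_strength = runif(n)
  )
  rep <- build_report(fits, gaze)
  expect_s3_class(rep, "lan_report")
  # strong built-in coupling shows up as a positive alpha-duration tau
  expect_gt(rep$correlations$tau["alpha", "mean_lan_duration"], 0)
  expect_equal(rep$correlations$tau, t(rep$correlations$tau))
  expect_true(all(abs(rep$correlations$tau) <= 1, na.rm = TRUE))
  expect_false(is.null(rep$group_comparisons))
  # ID mismatch errors and names the offender
  expect_error(build_report(fits, gaze[-1, ]), "IDs do not align")
  # a single participant still renders, with flags instead of correlations
  rep1 <- build_report(fits[1, ], gaze[1, ])
  expect_true(length(rep1$flags) > 0)
  expect_true(all(is.na(rep1$correlations$p)))
})

test_that("report output files are deterministic", {
  env <- test_env()
  fits <- tibble::tibble(participant = 1:4, alpha = c(.1, .3, .6, .9),
                         classification = classify_user(c(.1, .3, .6, .9)),
                         single_cue = FALSE)
  gaze <- tibble::tibble(participant = 1:4,
                         lan_presence = c(.1, .2, .4, .5),
                         mean_lan_duration = c(.05, .1, .2, .3),
                         mean_lan_strength = c(.3, .4, .5, .6))
  rep <- build_report(fits, gaze)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep, d1); write_report(rep, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
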