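test_that("AOI geometry matches the experiment and stays disjoint", {
  a <- build_aois()
  expect_identical(nrow(a), 5L)
  expect_true(all(a$xmax - a$xmin == 384))
  expect_true(all(a$ymax - a$ymin == 216))
  # center-to-exemplar distance from the (415, 235) offsets
  ctr <- a[a$aoi == "center", ]
  tl <- a[a$aoi == "top_left", ]
  d <- sqrt((mean(c(ctr$xmin, ctr$xmax)) - mean(c(tl$xmin, tl$xmax)))^2 +
              (mean(c(ctr$ymin, ctr$ymax)) - mean(c(tl$ymin, tl$ymax)))^2)
  expect_equal(d, sqrt(415^2 + 235^2), tolerance = 1e-9)
  expect_equal(round(d), 477)
  # margin 0 reproduces the stimulus footprint
  a0 <- build_aois(margin = 0)
  expect_true(all(a0$xmax - a0$xmin == 320))
  # overlapping AOIs are rejected
  expect_error(build_aois(offsets = c(50, 50)), "overlap")
})

test_that("fixations are labelled by containing AOI or outside", {
  a <- build_aois()
  fx <- tibble::tibble(
    x = c(960, 10, 960 - 415, 960 - 415),
    y = c(540, 10, 540 - 235, 540 - 235),
    duration = c(100, 100, 100, 100),
    onset = c(0, 200, 400, 600)
  )
  lab <- assign_fixations(fx, a)
  expect_identical(lab$aoi, c("center", "outside", "top_left", "top_left"))
  # additivity of durations within an AOI
  expect_equal(sum(lab$duration[lab$aoi == "top_left"]), 200)
  # sub-threshold fixations are dropped
  fx$duration[1] <- 50
  expect_identical(nrow(assign_fixations(fx, a)), 3L)
})

test_that("looking-at-nothing duration is the exemplar share of exemplar+center gaze", {
  expect_equal(lan_duration(300, 700), 0.30)
  expect_equal(lan_duration(0, 500), 0)
  expect_equal(lan_duration(400, 0), 1)
  expect_true(is.na(lan_duration(0, 0)))
})

test_that("most similar exemplar minimizes weighted distance with documented tie-breaks", {
  env <- test_env()
  # an old stimulus maps to itself
  ms <- most_similar_exemplar(3, 2, env)
  expect_identical(c(ms$x1, ms$x2), c(3L, 2L))
  # hand-computed distances from (1,1): .5, 1.5, 1.5, 2.5
  ms <- most_similar_exemplar(1, 1, env)
  expect_identical(c(ms$x1, ms$x2), c(2L, 1L))
  # (2,3) is equidistant (1.0) from all four exemplars; unweighted distance
  # ties too (all 2), so the lexicographically smallest exemplar wins
  ms <- most_similar_exemplar(2, 3, env, c(.5, .5))
  expect_identical(c(ms$x1, ms$x2), c(1L, 4L))
  # asymmetric weights move the winner
  ms <- most_similar_exemplar(1, 1, env, c(0.01, 0.99))
  expect_identical(c(ms$x1, ms$x2), c(2L, 1L))
})

test_that("looking-at-nothing strength is the most-similar share of exemplar gaze", {
  ex_ms <- c(top_left = 0, top_right = 0, bottom_left = 300, bottom_right = 0)
  expect_equal(lan_strength(ex_ms, "bottom_left"), 1)
  even <- c(top_left = 100, top_right = 100, bottom_left = 100,
            bottom_right = 100)
  expect_equal(lan_strength(even, "top_right"), 0.25)
  none <- c(top_left = 0, top_right = 0, bottom_left = 0, bottom_right = 0)
  expect_true(is.na(lan_strength(none, "top_left")))
})

test_that("per-trial gaze summaries combine assignment, duration and strength", {
  env <- test_env()
  a <- build_aois()
  in_aoi <- function(nm) {
    r <- a[a$aoi == nm, ]
    c(mean(c(r$xmin, r$xmax)), mean(c(r$ymin, r$ymax)))
  }
  ctr <- in_aoi("center"); tl <- in_aoi("top_left")
  fx <- tibble::tibble(
    participant = 1, trial = c(1, 1, 2),
    onset = c(0, 600, 0), duration = c(700, 300, 500),
    x = c(ctr[1], tl[1], ctr[1]), y = c(ctr[2], tl[2], ctr[2])
  )
  # top_left holds exemplar (2,1); test stimulus (1,1) has it most similar.
  # Stimulus (1,2) is equidistant from three exemplars; the tie-break picks
  # (1,4), which sits top_right.
  trials <- tibble::tibble(participant = 1, trial = c(1, 2),
                           x1 = c(1, 1), x2 = c(1, 2),
                           trial_length = c(1000, 600))
  gz <- trial_gaze(fx, trials, a, env)
  expect_equal(gz$lan_duration, c(0.3, 0))
  expect_equal(gz$lan_strength, c(1, NA_real_))
  expect_equal(gz$n_exemplar_aois, c(1, 0))
  expect_identical(gz$most_similar_aoi, c("top_left", "top_right"))
  expect_true(gz$on_most_similar[1])
})

test_that("time bins split pro rata and conserve total gaze duration", {
  env <- test_env()
  a <- build_aois()
  ctr <- c(960, 540); tl <- c(960 - 415, 540 - 235)
  # one 1000-ms center fixation: all bins have lan 0
  fx <- tibble::tibble(participant = 1, trial = 1, onset = 0,
                       duration = 1000, x = ctr[1], y = ctr[2])
  trials <- tibble::tibble(participant = 1, trial = 1, x1 = 1, x2 = 1,
                           trial_length = 1000)
  tb <- time_binned_lan(fx, trials, a)
  expect_identical(nrow(tb), 5L)
  expect_equal(tb$lan, rep(0, 5))
  expect_equal(tb$center_ms, rep(200, 5))
  # 100-ms exemplar fixation entirely inside bin 4 ([600, 800))
  fx2 <- tibble::tibble(participant = 1, trial = 1,
                        onset = c(0, 650), duration = c(300, 100),
                        x = c(ctr[1], tl[1]), y = c(ctr[2], tl[2]))
  tb2 <- time_binned_lan(fx2, trials, a)
  expect_equal(tb2$lan, c(0, 0, 0, 1, 0))
  # pro-rata conservation for fixations straddling boundaries
  set.seed(31)
  fx3 <- tibble::tibble(
    participant = 1, trial = 1,
    onset = runif(6, 0, 900), duration = runif(6, 50, 400),
    x = rep(c(tl[1], ctr[1]), 3), y = rep(c(tl[2], ctr[2]), 3)
  )
  fx3$duration <- pmax(80, pmin(fx3$duration, 1000 - fx3$onset))
  tb3 <- time_binned_lan(fx3, trials, a)
  lab3 <- assign_fixations(fx3, a)
  expect_equal(sum(tb3$exemplar_ms),
               sum(lab3$duration[lab3$aoi == "top_left"]),
               tolerance = 1e-9)
  expect_equal(sum(tb3$center_ms),
               sum(lab3$duration[lab3$aoi == "center"]), tolerance = 1e-9)
  # onset-bin alternative assigns whole fixations
  tb4 <- time_binned_lan(fx3, trials, a, boundary = "onset")
  expect_equal(sum(tb4$exemplar_ms) + sum(tb4$center_ms),
               sum(lab3$duration), tolerance = 1e-9)
})

test_that("metrics are invariant to fixation order and to splitting fixations", {
  env <- test_env()
  a <- build_aois()
  ctr <- c(960, 540); tl <- c(960 - 415, 540 - 235)
  fx <- tibble::tibble(participant = 1, trial = 1,
                       onset = c(0, 500), duration = c(400, 200),
                       x = c(ctr[1], tl[1]), y = c(ctr[2], tl[2]))
  trials <- tibble::tibble(participant = 1, trial = 1, x1 = 1, x2 = 1,
                           trial_length = 1000)
  g1 <- trial_gaze(fx, trials, a, env)
  g2 <- trial_gaze(fx[2:1, ], trials, a, env)
  expect_equal(g1$lan_duration, g2$lan_duration)
  # split the center fixation into two contiguous halves
  fx_split <- tibble::tibble(participant = 1, trial = 1,
                             onset = c(0, 200, 500),
                             duration = c(200, 200, 200),
                             x = c(ctr[1], ctr[1], tl[1]),
                             y = c(ctr[2], ctr[2], tl[2]))
  g3 <- trial_gaze(fx_split, trials, a, env)
  expect_equal(g3$lan_duration, g1$lan_duration)
  expect_equal(g3$lan_strength, g1$lan_strength)
})

test_that("trial-level statistics count AOI visits as specified", {
  # constructed 4-trial fixture with exemplar-AOI counts {0, 1, 1, 2}
  gz <- tibble::tibble(
    participant = 1, trial = 1:4, x1 = 1, x2 = 1,
    exemplar_ms = c(0, 100, 200, 300), center_ms = c(500, 400, 300, 200),
    lan_duration = lan_duration(c(0, 100, 200, 300), c(500, 400, 300, 200)),
    lan_strength = c(NA, 1, 1, 0.5),
    n_exemplar_aois = c(0, 1, 1, 2),
    dominant_share = c(NA, 1, 1, 2 / 3),
    on_most_similar = c(NA, TRUE, FALSE, TRUE)
  )
  st <- trial_level_stats(gz)
  expect_equal(st$lan_presence, 0.75)
  expect_equal(st$n_aoi_0, 0.25)
  expect_equal(st$n_aoi_1, 0.50)
  expect_equal(st$n_aoi_2, 0.25)
  expect_equal(st$single_aoi_share, 2 / 3)
  expect_equal(st$single_on_most_similar, 0.5)
  expect_equal(st$multi_dominant_share, 2 / 3)
  # all-center cohort: presence 0, every count 0
  gz0 <- gz
  gz0$exemplar_ms <- 0; gz0$n_exemplar_aois <- 0
  gz0$lan_duration <- 0
  st0 <- trial_level_stats(gz0)
  expect_equal(st0$lan_presence, 0)
  expect_equal(st0$n_aoi_0, 1)
})

test_that("split-half reliability pairs odd and even presentations per stimulus", {
  g <- stimulus_grid()
  # identical halves: correlation 1
  gz <- tibble::tibble(
    participant = 1,
    trial = seq_len(32),
    x1 = rep(g$x1, 2), x2 = rep(g$x2, 2),
    lan_duration = rep(seq(0, 1, length.out = 16), 2)
  )
  expect_equal(split_half_reliability(gz), 1)
  # random fixture vs. a hand-rolled pairing-and-correlation oracle
  set.seed(41)
  gz$lan_duration <- runif(32)
  r <- split_half_reliability(gz)
  odd <- gz[1:16, ]; even <- gz[17:32, ]
  key <- paste(odd$x1, odd$x2)
  oracle <- cor(odd$lan_duration[order(key)],
                even$lan_duration[order(paste(even$x1, even$x2))])
  expect_equal(r, oracle, tolerance = 1e-12)
  # stimuli with a single presentation are dropped with a warning
  expect_warning(r2 <- split_half_reliability(gz[-1, ]), "dropped")
  expect_true(is.finite(r2))
})
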