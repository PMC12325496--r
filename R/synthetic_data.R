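# Synthetic cohort generator: judgment and fixation tables with the
# statistical structure the analysis pipeline assumes, so everything runs
# and is testable without any real dataset.

#' Specify a synthetic cohort
#'
#' Each simulated participant gets generating model parameters (mixture
#' weight alpha uniform on `[0, 1]` by default; rule coefficients jittered
#' around the least-squares fit to the exemplars; fixed-level judgment
#' noise) and gaze-coupling parameters. The gaze model is deliberately
#' minimal and entirely synthetic: per trial a center-fixation process plus,
#' with probability `base + slope * alpha`, an exemplar-fixation process
#' biased toward the most similar exemplar and peaking in the fourth fifth
#' of the trial. Its only purpose is to make every downstream metric
#' exercisable and the alpha-gaze association recoverable.
#'
#' @param n_participants Cohort size (default 48).
#' @param n_blocks Test-phase blocks of 16 stimuli each (default 8, i.e.
#'   128 trials).
#' @param alpha_sampler Function of `n` drawing generating alphas.
#' @param beta_jitter_sd SD of the Gaussian jitter applied per participant
#'   to the exemplar-OLS rule coefficients.
#' @param sigma Generating response noise SD; scalar or function of `n`.
#' @param gaze Named list of gaze-coupling constants: `base` (exemplar-gaze
#'   probability at alpha = 0), `slope` (its increase per unit alpha),
#'   `bias` (probability that an exemplar fixation targets the most similar
#'   exemplar), `extra_fix_prob` (chance of a second exemplar fixation),
#'   `fix_meanlog`/`fix_sdlog` (lognormal exemplar-fixation duration, ms),
#'   `center_frac` (range of the initial center fixation as a fraction of
#'   trial length), `trial_meanlog`/`trial_sdlog` (lognormal trial length,
#'   ms; median about 3.8 s).
#' @param seed Master seed; the same seed reproduces the cohort exactly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 48L, n_blocks = 8L,
                        alpha_sampler = stats::runif,
                        beta_jitter_sd = 0.5,
                        sigma = 2,
                        gaze = list(),
                        seed = 1L) {
  stopifnot(n_participants >= 1, n_blocks >= 1)
  gz <- utils::modifyList(
    list(base = 0.1, slope = 0.6, bias = 0.75, extra_fix_prob = 0.25,
         fix_meanlog = log(250), fix_sdlog = 0.4,
         center_frac = c(0.15, 0.35),
         trial_meanlog = log(3800), trial_sdlog = 0.6),
    gaze
  )
  stopifnot(gz$base >= 0, gz$base <= 1, gz$bias >= 0, gz$bias <= 1,
            gz$extra_fix_prob >= 0, gz$extra_fix_prob <= 1)
  structure(
    list(n_participants = as.integer(n_participants),
         n_blocks = as.integer(n_blocks),
         alpha_sampler = alpha_sampler, beta_jitter_sd = beta_jitter_sd,
         sigma = sigma, gaze = gz, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Draw generating parameters for a cohort
#'
#' @param spec A [cohort_spec()].
#' @param env A `rulex_env`.
#' @return A tibble with one row per participant: `participant`, `alpha`,
#'   `beta0`, `beta1`, `beta2`, `sigma`, `p_lan` (the alpha-coupled
#'   exemplar-gaze probability).
#' @export
generate_truth <- function(spec, env) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(env, "rulex_env"))
  n <- spec$n_participants
  set.seed(spec$seed)
  ols <- stats::lm.fit(cbind(1, env$exemplars$x1, env$exemplars$x2),
                       env$exemplars$criterion)$coefficients
  alpha <- spec$alpha_sampler(n)
  stopifnot(all(alpha >= 0 & alpha <= 1))
  sig <- if (is.function(spec$sigma)) spec$sigma(n) else rep(spec$sigma, n)
  tibble::tibble(
    participant = seq_len(n),
    alpha = alpha,
    beta0 = ols[1] + stats::rnorm(n, sd = spec$beta_jitter_sd),
    beta1 = ols[2] + stats::rnorm(n, sd = spec$beta_jitter_sd),
    beta2 = ols[3] + stats::rnorm(n, sd = spec$beta_jitter_sd),
    sigma = sig,
    p_lan = pmin(pmax(spec$gaze$base + spec$gaze$slope * alpha, 0), 1)
  )
}

#' Simulate one participant's test-phase judgments
#'
#' Responses are Gaussian around the mixture prediction, rounded to integers
#' and clipped to the response scale — what a participant could actually
#' enter. (The fitting model treats them as continuous, mirroring its own
#' approximation.) `sigma = 0` yields deterministic rounded predictions.
#'
#' @param params A `rulex_params` (its `sigma` is the generating noise).
#' @param env A `rulex_env`.
#' @param n_blocks Number of 16-stimulus test blocks.
#' @param seed Seed for the schedule and the response noise.
#' @return A judgment tibble: `block`, `trial`, `x1`, `x2`, `response`.
#' @export
simulate_judgments <- function(params, env, n_blocks = 8L, seed = 1L) {
  stopifnot(inherits(params, "rulex_params"))
  sched <- make_schedule("test", env, n_blocks = n_blocks, seed = seed)
  m <- mixture_prediction(sched$x1, sched$x2, env, params)$c_mix
  set.seed(seed + 1L)
  r <- stats::rnorm(length(m), mean = m, sd = params$sigma)
  resp <- pmin(pmax(round_half_away(r), env$scale_min), env$scale_max)
  tibble::tibble(block = sched$block, trial = sched$trial,
                 x1 = sched$x1, x2 = sched$x2, response = as.integer(resp))
}

# simulate_judgments requires sigma > 0 through model_params; allow 0 here
# and make the integer rounding optional (rounding injects a deterministic
# discretization pattern that dominates at sigma near 0)
.simulate_judgments_raw <- function(alpha, beta0, beta1, beta2, sigma, env,
                                    n_blocks, seed, h = 1, round = TRUE) {
  sched <- make_schedule("test", env, n_blocks = n_blocks, seed = seed)
  p <- model_params(alpha, beta0, beta1, beta2, max(sigma, 1e-12), h = h)
  m <- mixture_prediction(sched$x1, sched$x2, env, p)$c_mix
  set.seed(seed + 1L)
  r <- m + if (sigma > 0) stats::rnorm(length(m), sd = sigma) else 0
  if (round) r <- round_half_away(r)
  resp <- pmin(pmax(r, env$scale_min), env$scale_max)
  if (round) resp <- as.integer(resp)
  tibble::tibble(block = sched$block, trial = sched$trial,
                 x1 = sched$x1, x2 = sched$x2, response = resp)
}

#' Generate a cohort's judgment table
#'
#' @param spec A [cohort_spec()].
#' @param env A `rulex_env`.
#' @param truth Optional truth table from [generate_truth()] (regenerated
#'   from the spec's seed if omitted).
#' @return A tibble with `n_participants * 16 * n_blocks` rows:
#'   `participant`, `block`, `trial`, `x1`, `x2`, `response`.
#' @export
generate_judgments <- function(spec, env, truth = NULL) {
  if (is.null(truth)) truth <- generate_truth(spec, env)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    j <- .simulate_judgments_raw(tr$alpha, tr$beta0, tr$beta1, tr$beta2,
                                 tr$sigma, env, spec$n_blocks,
                                 seed = spec$seed * 1000L + i)
    j$participant <- tr$participant
    j[, c("participant", "block", "trial", "x1", "x2", "response")]
  })
  dplyr::bind_rows(rows)
}

# one trial's fixations; returns a small data.frame
.simulate_trial_fixations <- function(tr_len, p_lan, gz, aois, ms_aoi) {
  corner_names <- aois$aoi[aois$aoi != "center"]
  coords_in <- function(a) {
    r <- aois[aois$aoi == a, ]
    c(stats::runif(1, r$xmin, r$xmax), stats::runif(1, r$ymin, r$ymax))
  }
  fix <- list()
  add <- function(onset, duration, a) {
    xy <- coords_in(a)
    fix[[length(fix) + 1L]] <<- data.frame(
      onset = onset, duration = duration, x = xy[1], y = xy[2])
  }
  # early center gaze: participant still at the stimulus location
  ctr_dur <- stats::runif(1, gz$center_frac[1], gz$center_frac[2]) * tr_len
  add(0, max(80, ctr_dur), "center")
  if (stats::runif(1) < p_lan) {
    # exemplar gaze peaking in the fourth fifth of the trial
    target <- if (stats::runif(1) < gz$bias) ms_aoi
              else sample(setdiff(corner_names, ms_aoi), 1)
    onset <- stats::runif(1, 0.6, 0.78) * tr_len
    dur <- max(80, stats::rlnorm(1, gz$fix_meanlog, gz$fix_sdlog))
    add(onset, min(dur, 0.95 * tr_len - onset), target)
    if (stats::runif(1) < gz$extra_fix_prob) {
      target2 <- sample(corner_names, 1)
      onset2 <- onset + dur + 20
      dur2 <- max(80, stats::rlnorm(1, gz$fix_meanlog, gz$fix_sdlog))
      if (onset2 + dur2 < 0.95 * tr_len) add(onset2, dur2, target2)
    }
  }
  # brief return to center before the response click
  back <- stats::runif(1, 0.85, 0.9) * tr_len
  add(back, max(80, min(150, tr_len - back)), "center")
  do.call(rbind, fix)
}

#' Generate a cohort's fixation table
#'
#' Per trial: an initial center fixation (the participant still looks where
#' the test stimulus just disappeared), then — with the alpha-coupled
#' probability `p_lan` — one or two exemplar-location fixations placed so
#' exemplar gaze peaks in the fourth fifth of the trial and directed at the
#' most similar exemplar with probability `bias`, and finally a short
#' center fixation before the response click. Coordinates are uniform
#' within the target AOI; trial lengths are lognormal (median about
#' 3.8 s).
#'
#' @param spec A [cohort_spec()].
#' @param env A `rulex_env`.
#' @param judgments Judgment table from [generate_judgments()].
#' @param truth Truth table from [generate_truth()] (regenerated if
#'   omitted).
#' @param aois An `aoi_set` (default geometry if omitted).
#' @return A fixation tibble: `participant`, `trial`, `onset`, `duration`,
#'   `x`, `y`, `trial_length` (ms / px).
#' @export
generate_fixations <- function(spec, env, judgments, truth = NULL,
                               aois = build_aois(exemplars = env$exemplars)) {
  if (is.null(truth)) truth <- generate_truth(spec, env)
  gz <- spec$gaze
  set.seed(spec$seed + 7L)
  rows <- vector("list", nrow(judgments))
  # per-participant true attention weights for the most-similar target
  w_tab <- lapply(seq_len(nrow(truth)), function(i) {
    .attention_weights(truth$beta1[i], truth$beta2[i])
  })
  ms_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(judgments))) {
    j <- judgments[i, ]
    tr <- truth[truth$participant == j$participant, ]
    key <- paste(j$participant, j$x1, j$x2)
    if (is.null(ms_cache[[key]])) {
      ms <- most_similar_exemplar(j$x1, j$x2, env,
                                  w_tab[[match(j$participant,
                                               truth$participant)]])
      ms_cache[[key]] <- aois$aoi[!is.na(aois$x1) &
                                    aois$x1 == ms$x1 & aois$x2 == ms$x2]
    }
    tr_len <- stats::rlnorm(1, gz$trial_meanlog, gz$trial_sdlog)
    f <- .simulate_trial_fixations(tr_len, tr$p_lan, gz, aois,
                                   ms_cache[[key]])
    f$participant <- j$participant
    f$trial <- j$trial
    f$trial_length <- tr_len
    rows[[i]] <- f
  }
  out <- dplyr::bind_rows(rows)
  tibble::as_tibble(out[, c("participant", "trial", "onset", "duration",
                            "x", "y", "trial_length")])
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper returning the three tables the pipeline consumes.
#'
#' @param spec A [cohort_spec()].
#' @param env A `rulex_env`.
#' @return A list with elements `truth`, `judgments`, `fixations`, `aois`.
#' @examples
#' env <- task_environment()
#' cohort <- generate_cohort(cohort_spec(n_participants = 2, seed = 1), env)
#' head(cohort$judgments)
#' @export
generate_cohort <- function(spec, env) {
  truth <- generate_truth(spec, env)
  judgments <- generate_judgments(spec, env, truth)
  aois <- build_aois(exemplars = env$exemplars)
  fixations <- generate_fixations(spec, env, judgments, truth, aois)
  list(truth = truth, judgments = judgments, fixations = fixations,
       aois = aois)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `judgments.csv`, `fixations.csv` and `truth.csv` (the generating
#' parameters) in the schemas consumed by the fitting and gaze modules.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$judgments, file.path(dir, "judgments.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$fixations, file.path(dir, "fixations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
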