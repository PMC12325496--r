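# Task environment: stimulus space, criterion functions, exemplar sets,
# trial schedules, and the staircase used to calibrate presentation time.

#' Round half away from zero
#'
#' Rounding used by the criterion functions. Unlike [base::round()] (banker's
#' rounding), values at exactly .5 move away from zero. No value of the
#' multiplicative criterion on the 4 x 4 cue grid lands on .5, so the choice
#' only matters for arbitrary coefficients.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

check_cues <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stop("`x1` and `x2` must have the same length", call. = FALSE)
  }
  ok <- function(v) is.numeric(v) && all(is.finite(v)) &&
    all(v == as.integer(v)) && all(v >= 1) && all(v <= 4)
  if (!ok(x1) || !ok(x2)) {
    stop("cue values must be integers in 1..4", call. = FALSE)
  }
  invisible(NULL)
}

#' The 16-stimulus cue grid
#'
#' Every combination of the two cue values \eqn{x_1, x_2 \in \{1,2,3,4\}},
#' each exactly once.
#'
#' @return A tibble with integer columns `x1` and `x2` (16 rows).
#' @export
stimulus_grid <- function() {
  g <- expand.grid(x1 = 1:4, x2 = 1:4, KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g[order(g$x1, g$x2), ])
}

#' Multiplicative criterion function
#'
#' The non-linear cue-criterion link \eqn{c = \lfloor 5/3 \cdot x_1 \cdot x_2
#' + 2 \rceil} (round to nearest integer), mapping the 16 cue combinations to
#' criteria between 4 and 29 on the 1-30 judgment scale.
#'
#' @param x1,x2 Integer cue values in 1..4 (vectorized).
#' @return Integer criterion values.
#' @examples
#' criterion_multiplicative(1, 1) # 4
#' criterion_multiplicative(4, 4) # 29
#' @export
criterion_multiplicative <- function(x1, x2) {
  check_cues(x1, x2)
  as.integer(round_half_away(5 / 3 * x1 * x2 + 2))
}

#' Additive (linear) criterion function
#'
#' A linear cue-criterion link \eqn{c = \lfloor a_0 + a_1 x_1 + a_2 x_2
#' \rceil}, clipped to the response scale. The default coefficients are an
#' arbitrary choice spanning a range comparable to the multiplicative
#' environment; real additive environments should supply their own.
#'
#' @param x1,x2 Integer cue values in 1..4 (vectorized).
#' @param coef Numeric length-3 vector `(a0, a1, a2)`.
#' @param scale_min,scale_max Response-scale bounds used for clipping.
#' @return Integer criterion values within the scale.
#' @export
criterion_additive <- function(x1, x2, coef = c(2, 5 / 3, 5 / 3),
                               scale_min = 1, scale_max = 30) {
  check_cues(x1, x2)
  if (length(coef) != 3 || !all(is.finite(coef))) {
    stop("`coef` must be three finite coefficients (a0, a1, a2)", call. = FALSE)
  }
  c_raw <- round_half_away(coef[1] + coef[2] * x1 + coef[3] * x2)
  as.integer(pmin(pmax(c_raw, scale_min), scale_max))
}

#' Default exemplar set
#'
#' The four training exemplars `(2,1), (1,4), (3,2), (4,3)`: each cue value
#' occurs exactly once per cue, no exemplar is symmetric (so each has a
#' distinct reversed distractor), and the critical extrapolation stimuli
#' `(1,1), (1,2), (3,4), (4,4)` are excluded. Under the multiplicative
#' criterion their values are 5, 9, 12 and 22, so stimuli `(1,1)` (c = 4) and
#' `(4,4)` (c = 29) extrapolate beyond the exemplar range.
#'
#' @param criterion_fn Function of `(x1, x2)` giving the criterion; defaults
#'   to [criterion_multiplicative()].
#' @return A tibble with columns `x1`, `x2`, `criterion` (4 rows).
#' @export
default_exemplars <- function(criterion_fn = criterion_multiplicative) {
  ex <- tibble::tibble(x1 = c(2L, 1L, 3L, 4L), x2 = c(1L, 4L, 2L, 3L))
  ex$criterion <- criterion_fn(ex$x1, ex$x2)
  ex
}

#' Reversed-cue distractor for an exemplar
#'
#' Location-training distractors swap the two cue values (distractor `(1,2)`
#' for exemplar `(2,1)`). A symmetric stimulus has no distinct reversal and
#' is rejected.
#'
#' @param x1,x2 Integer cue values in 1..4 (vectorized).
#' @return A tibble with columns `x1`, `x2` holding the reversed stimuli.
#' @export
reversed_distractor <- function(x1, x2) {
  check_cues(x1, x2)
  if (any(x1 == x2)) {
    stop("symmetric stimulus (x1 == x2): reversal equals the exemplar",
         call. = FALSE)
  }
  rx1 <- as.integer(x2)
  rx2 <- as.integer(x1)
  tibble::tibble(x1 = rx1, x2 = rx2)
}

validate_exemplars <- function(exemplars, scale_min, scale_max) {
  stopifnot(is.data.frame(exemplars),
            all(c("x1", "x2", "criterion") %in% names(exemplars)))
  check_cues(exemplars$x1, exemplars$x2)
  if (!setequal(exemplars$x1, 1:4) || !setequal(exemplars$x2, 1:4)) {
    stop("exemplar set must cover each cue value 1..4 exactly once per cue",
         call. = FALSE)
  }
  if (any(exemplars$x1 == exemplars$x2)) {
    stop("exemplar set must not contain symmetric stimuli (x1 == x2)",
         call. = FALSE)
  }
  if (any(exemplars$criterion < scale_min | exemplars$criterion > scale_max)) {
    stop("exemplar criterion values must lie within the response scale",
         call. = FALSE)
  }
  invisible(exemplars)
}

#' Construct a task environment
#'
#' Bundles the criterion function, the exemplar set (with stored criterion
#' values) and the response-scale bounds. The environment is the single
#' source of truth consumed by the model, the schedules and the generator.
#'
#' @param criterion `"multiplicative"` (default), `"additive"`, or a function
#'   of `(x1, x2)` returning integer criteria.
#' @param exemplars Exemplar tibble with columns `x1`, `x2` (criterion values
#'   are recomputed from the criterion function unless a `criterion` column
#'   is supplied together with a custom function). Defaults to the standard
#'   four-exemplar set.
#' @param additive_coef Coefficients for the additive criterion.
#' @param scale_min,scale_max Judgment scale bounds (1 and 30).
#' @return An object of class `rulex_env`: a list with elements
#'   `criterion_fn`, `exemplars`, `scale_min`, `scale_max`, `criterion_name`.
#' @examples
#' env <- task_environment()
#' env$exemplars
#' @export
task_environment <- function(criterion = c("multiplicative", "additive"),
                             exemplars = NULL,
                             additive_coef = c(2, 5 / 3, 5 / 3),
                             scale_min = 1L, scale_max = 30L) {
  if (is.function(criterion)) {
    criterion_fn <- criterion
    criterion_name <- "custom"
  } else {
    criterion_name <- match.arg(criterion)
    criterion_fn <- switch(
      criterion_name,
      multiplicative = criterion_multiplicative,
      additive = function(x1, x2) {
        criterion_additive(x1, x2, coef = additive_coef,
                           scale_min = scale_min, scale_max = scale_max)
      }
    )
  }
  if (is.null(exemplars)) {
    exemplars <- default_exemplars(criterion_fn)
  } else {
    exemplars <- tibble::as_tibble(exemplars)
    if (!"criterion" %in% names(exemplars)) {
      exemplars$criterion <- criterion_fn(exemplars$x1, exemplars$x2)
    }
  }
  validate_exemplars(exemplars, scale_min, scale_max)
  structure(
    list(criterion_fn = criterion_fn, exemplars = exemplars,
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max),
         criterion_name = criterion_name,
         additive_coef = if (criterion_name == "additive") additive_coef else NULL),
    class = "rulex_env"
  )
}

#' @export
print.rulex_env <- function(x, ...) {
  cat("<rulex_env> criterion:", x$criterion_name,
      sprintf("| scale: %d..%d\n", x$scale_min, x$scale_max))
  print(x$exemplars)
  invisible(x)
}

#' Read a task environment from a YAML config
#'
#' Expected keys: `criterion` (name), optional `additive_coef`, optional
#' `exemplars` (list of `[x1, x2]` pairs), optional `scale_min`/`scale_max`.
#'
#' @param path Path to a YAML file.
#' @return A `rulex_env`.
#' @export
environment_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ex <- NULL
  if (!is.null(cfg$exemplars)) {
    m <- do.call(rbind, lapply(cfg$exemplars, as.integer))
    ex <- tibble::tibble(x1 = m[, 1], x2 = m[, 2])
  }
  task_environment(
    criterion = cfg$criterion %||% "multiplicative",
    exemplars = ex,
    additive_coef = unlist(cfg$additive_coef) %||% c(2, 5 / 3, 5 / 3),
    scale_min = cfg$scale_min %||% 1L,
    scale_max = cfg$scale_max %||% 30L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a trial schedule
#'
#' Location-training blocks contain the four exemplars plus their four
#' reversed-cue distractors (8 items); criterion-training blocks the four
#' exemplars; test blocks all 16 stimuli. Order is randomized independently
#' within each block, driven by `seed`, so the same seed reproduces the
#' schedule exactly. Training termination rules (stop after three consecutive
#' error-free blocks, caps of 15 location / 10 criterion blocks) are carried
#' as attributes, not simulated.
#'
#' @param phase `"location_training"`, `"criterion_training"` or `"test"`.
#' @param env A `rulex_env`.
#' @param n_blocks Number of blocks (>= 1). Defaults: 8 test blocks
#'   (128 trials), matching the experiment.
#' @param seed Integer seed controlling within-block order.
#' @return A tibble with columns `phase`, `block`, `trial`, `x1`, `x2`,
#'   `role` (`"exemplar"`, `"distractor"` or `"test"`).
#' @examples
#' nrow(make_schedule("test", task_environment(), n_blocks = 8, seed = 1))
#' @export
make_schedule <- function(phase, env, n_blocks = 8L, seed = 1L) {
  phases <- c("location_training", "criterion_training", "test")
  if (!is.character(phase) || length(phase) != 1 || !phase %in% phases) {
    stop("`phase` must be one of: ", paste(phases, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(env, "rulex_env"), n_blocks >= 1)
  ex <- env$exemplars
  items <- switch(
    phase,
    location_training = {
      di <- reversed_distractor(ex$x1, ex$x2)
      tibble::tibble(x1 = c(ex$x1, di$x1), x2 = c(ex$x2, di$x2),
                     role = rep(c("exemplar", "distractor"), each = nrow(ex)))
    },
    criterion_training = tibble::tibble(x1 = ex$x1, x2 = ex$x2,
                                        role = "exemplar"),
    test = {
      g <- stimulus_grid()
      tibble::tibble(x1 = g$x1, x2 = g$x2, role = "test")
    }
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    perm <- items[sample.int(nrow(items)), ]
    perm$block <- b
    perm
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out <- out[, c("block", "trial", "x1", "x2", "role")]
  out$phase <- phase
  out <- out[, c("phase", "block", "trial", "x1", "x2", "role")]
  attr(out, "seed") <- seed
  attr(out, "termination") <- switch(
    phase,
    location_training = list(stop_after_perfect_blocks = 3, max_blocks = 15),
    criterion_training = list(stop_after_perfect_blocks = 3, max_blocks = 10),
    test = NULL
  )
  out
}

#' Write a schedule to CSV
#'
#' @param schedule A schedule tibble from [make_schedule()].
#' @param path Output file path.
#' @param participant Optional participant identifier added as first column.
#' @export
write_schedule_csv <- function(schedule, path, participant = NA) {
  out <- cbind(participant = participant, as.data.frame(schedule))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- staircase ---------------------------------------------------------

#' Create a 4-down-1-up staircase state
#'
#' The psychophysics calibration starts at 2000 ms; presentation time drops
#' by 336.60 ms after four consecutive correct responses and rises by 400 ms
#' after any error. Durations are floored at `min_duration` (the procedure
#' itself states no lower bound; 1 ms keeps them positive).
#'
#' @param duration Starting presentation duration in ms.
#' @param step_down,step_up Step sizes in ms.
#' @param n_down Number of consecutive correct responses per decrement.
#' @param min_duration Lower bound on duration in ms.
#' @return An object of class `staircase_state`.
#' @export
staircase_new <- function(duration = 2000, step_down = 336.60, step_up = 400,
                          n_down = 4, min_duration = 1) {
  stopifnot(duration > 0, min_duration > 0, n_down >= 1)
  structure(
    list(duration = duration, consecutive_correct = 0L,
         history = list(),
         step_down = step_down, step_up = step_up, n_down = n_down,
         min_duration = min_duration),
    class = "staircase_state"
  )
}

#' Advance a staircase by one response
#'
#' On an error the duration increases by `step_up` and the correct streak
#' resets; on the `n_down`-th consecutive correct response the duration
#' decreases by `step_down` (floored at the minimum) and the streak resets;
#' otherwise only the streak advances.
#'
#' @param state A `staircase_state`.
#' @param correct Logical, whether the response was correct.
#' @return The updated `staircase_state`.
#' @examples
#' s <- staircase_new(2000)
#' for (r in c(TRUE, TRUE, TRUE, TRUE)) s <- staircase_step(s, r)
#' s$duration # 1663.4
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  if (!correct) {
    state$duration <- state$duration + state$step_up
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$n_down) {
      state$duration <- max(state$duration - state$step_down,
                            state$min_duration)
      state$consecutive_correct <- 0L
    }
  }
  state$history[[length(state$history) + 1L]] <-
    list(duration = state$duration, correct = correct)
  state
}

#' Run a staircase over a response sequence
#'
#' @param state A `staircase_state`.
#' @param responses Logical vector of correct/incorrect responses.
#' @return The final `staircase_state`.
#' @export
staircase_run <- function(state, responses) {
  for (r in responses) state <- staircase_step(state, r)
  state
}

#' Test-phase presentation time from staircase block means
#'
#' The calibrated presentation time is the arithmetic mean of the per-block
#' mean durations.
#'
#' @param block_means Numeric vector of per-block mean durations (ms).
#' @return Presentation time in ms.
#' @export
staircase_presentation_time <- function(block_means) {
  if (length(block_means) == 0 || !is.numeric(block_means)) {
    stop("`block_means` must be a non-empty numeric vector", call. = FALSE)
  }
  mean(block_means)
}
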