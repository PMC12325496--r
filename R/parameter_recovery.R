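# Parameter-recovery simulation: generate judgments from known parameters,
# refit, and quantify how well the mixture weight is recovered.

#' Specify a recovery simulation
#'
#' @param n_participants Simulated participants per noise level (default 30).
#' @param n_blocks Test blocks of 16 stimuli (default 8, i.e. 128 trials).
#' @param sigma_levels Generating response noise SDs to cross with the
#'   participants (default 2, roughly the scale implied by a 1-30 response
#'   range).
#' @param alpha_sampler Function of `n` drawing true alphas (uniform on
#'   `[0, 1]` by default).
#' @param beta_jitter_sd Jitter of the rule coefficients around the
#'   exemplar-OLS values.
#' @param round_responses Round simulated responses to the integers a
#'   participant could enter (default `TRUE`). At noise levels near zero
#'   the rounding residual is a deterministic pattern the mixture can
#'   partially absorb, so estimator checks in the noiseless limit should
#'   disable it.
#' @param seed Master seed.
#' @return A list of class `recovery_design`.
#' @export
recovery_design <- function(n_participants = 30L, n_blocks = 8L,
                            sigma_levels = 2,
                            alpha_sampler = stats::runif,
                            beta_jitter_sd = 0.5, round_responses = TRUE,
                            seed = 1L) {
  if (n_participants < 1 || n_blocks < 1) {
    stop("participant and trial counts must be positive", call. = FALSE)
  }
  if (any(sigma_levels < 0)) stop("sigma levels must be >= 0", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_blocks = as.integer(n_blocks), sigma_levels = sigma_levels,
         alpha_sampler = alpha_sampler, beta_jitter_sd = beta_jitter_sd,
         round_responses = isTRUE(round_responses),
         seed = as.integer(seed)),
    class = "recovery_design"
  )
}

#' Run a parameter-recovery simulation
#'
#' For each noise level and simulated participant: draw true parameters,
#' simulate a full test phase, refit by cross-validated maximum likelihood,
#' and compare the fold-mean estimate with the truth. Recovery of the
#' mixture weight is summarized by Spearman rank correlation, mean bias and
#' RMSE per noise level.
#'
#' @param design A [recovery_design()].
#' @param env A `rulex_env`.
#' @param control A [fit_control()] for the refits.
#' @return A list of class `recovery_result`: `table` (one row per
#'   simulated participant: truth and estimates) and `summary` (one row per
#'   sigma level: `rank_cor`, `bias`, `rmse`).
#' @export
run_recovery <- function(design, env, control = fit_control()) {
  stopifnot(inherits(design, "recovery_design"), inherits(env, "rulex_env"))
  ols <- stats::lm.fit(cbind(1, env$exemplars$x1, env$exemplars$x2),
                       env$exemplars$criterion)$coefficients
  rows <- list()
  for (si in seq_along(design$sigma_levels)) {
    sg <- design$sigma_levels[si]
    set.seed(design$seed + 131L * si)
    n <- design$n_participants
    alpha <- design$alpha_sampler(n)
    b0 <- ols[1] + stats::rnorm(n, sd = design$beta_jitter_sd)
    b1 <- ols[2] + stats::rnorm(n, sd = design$beta_jitter_sd)
    b2 <- ols[3] + stats::rnorm(n, sd = design$beta_jitter_sd)
    for (i in seq_len(n)) {
      dat <- .simulate_judgments_raw(alpha[i], b0[i], b1[i], b2[i], sg, env,
                                     design$n_blocks,
                                     seed = design$seed + 977L * si + i,
                                     round = design$round_responses)
      cv <- fit_crossval(dat, env, control)
      p <- cv$params
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sigma_level = sg, participant = i,
        alpha_true = alpha[i], alpha_est = p$alpha,
        beta0_true = b0[i], beta0_est = p$beta0,
        beta1_true = b1[i], beta1_est = p$beta1,
        beta2_true = b2[i], beta2_est = p$beta2,
        sigma_est = p$sigma, converged = cv$converged
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  smry <- tab |>
    dplyr::group_by(.data$sigma_level) |>
    dplyr::summarise(
      rank_cor = if (stats::sd(.data$alpha_true) == 0 ||
                       stats::sd(.data$alpha_est) == 0) NA_real_
                 else stats::cor(.data$alpha_true, .data$alpha_est,
                                 method = "spearman"),
      bias = mean(.data$alpha_est - .data$alpha_true),
      rmse = sqrt(mean((.data$alpha_est - .data$alpha_true)^2)),
      .groups = "drop"
    )
  structure(list(table = tab, summary = smry), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>\n")
  print(x$summary)
  invisible(x)
}
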