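# RulEx-J judgment equations: exemplar-similarity prediction, linear rule
# prediction, the alpha mixture, and the Gaussian response likelihood.

#' RulEx-J model parameters
#'
#' The model has five free parameters: the mixture weight `alpha` (relative
#' reliance on the similarity over the rule process, in `[0, 1]`), the rule
#' intercept `beta0` and cue weights `beta1`, `beta2` (criterion units per
#' cue step), and the response noise SD `sigma`. The similarity sensitivity
#' `h` (decay rate of similarity with attention-weighted city-block
#' distance) is a fixed constant, not fitted.
#'
#' @param alpha Mixture weight in `[0, 1]`.
#' @param beta0,beta1,beta2 Rule coefficients.
#' @param sigma Response noise SD (> 0).
#' @param h Similarity sensitivity (> 0), default 1.
#' @return An object of class `rulex_params`.
#' @examples
#' p <- model_params(alpha = 0.5, beta0 = -9.25, beta1 = 5.25,
#'                   beta2 = 3.25, sigma = 2)
#' attention_weights(p)
#' @export
model_params <- function(alpha, beta0, beta1, beta2, sigma, h = 1) {
  vals <- c(alpha = alpha, beta0 = beta0, beta1 = beta1, beta2 = beta2,
            sigma = sigma, h = h)
  if (!all(is.finite(vals))) stop("parameters must be finite", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  structure(as.list(vals), class = "rulex_params")
}

#' @export
print.rulex_params <- function(x, ...) {
  cat(sprintf(
    "<rulex_params> alpha=%.3f beta0=%.3f beta1=%.3f beta2=%.3f sigma=%.3f h=%.3f\n",
    x$alpha, x$beta0, x$beta1, x$beta2, x$sigma, x$h))
  invisible(x)
}

# attention weights without the user-facing warning (hot path in fitting)
.attention_weights <- function(beta1, beta2) {
  a1 <- abs(beta1); a2 <- abs(beta2)
  s <- a1 + a2
  if (s == 0) return(c(0.5, 0.5))
  c(a1, a2) / s
}

#' Attention weights from the rule's cue weights
#'
#' The similarity component weights cue dimensions by the fitted cue
#' weights' absolute magnitudes, normalized to sum to 1:
#' \eqn{w_m = |\beta_m| / (|\beta_1| + |\beta_2|)}. If both cue weights are
#' zero the weights are undefined and equal weights `(0.5, 0.5)` are used
#' with a warning.
#'
#' @param params A `rulex_params`, or a numeric vector `c(beta1, beta2)`.
#' @return Numeric vector `c(w1, w2)` summing to 1.
#' @export
attention_weights <- function(params) {
  b <- if (inherits(params, "rulex_params")) {
    c(params$beta1, params$beta2)
  } else {
    stopifnot(is.numeric(params), length(params) == 2)
    params
  }
  if (abs(b[1]) + abs(b[2]) == 0) {
    warning("both cue weights are zero; falling back to equal attention weights",
            call. = FALSE)
  }
  .attention_weights(b[1], b[2])
}

#' Attention-weighted city-block distance
#'
#' \eqn{d(s, e) = w_1 |x_1 - e_1| + w_2 |x_2 - e_2|} with non-negative
#' weights summing to 1.
#'
#' @param s,e Stimuli as length-2 numeric vectors `c(x1, x2)`, or two-column
#'   matrices/data frames with columns `x1`, `x2` (rows are recycled against
#'   each other if one side has a single row).
#' @param w Attention weights `c(w1, w2)`, non-negative, summing to 1.
#' @return Non-negative distances.
#' @examples
#' weighted_cityblock(c(1, 1), c(4, 3), c(.5, .5)) # 2.5
#' @export
weighted_cityblock <- function(s, e, w = c(0.5, 0.5)) {
  if (any(w < 0)) stop("attention weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8) stop("attention weights must sum to 1", call. = FALSE)
  as_mat <- function(z) {
    if (is.data.frame(z)) z <- as.matrix(z[, c("x1", "x2")])
    if (is.null(dim(z))) z <- matrix(z, ncol = 2)
    z
  }
  s <- as_mat(s); e <- as_mat(e)
  w[1] * abs(s[, 1] - e[, 1]) + w[2] * abs(s[, 2] - e[, 2])
}

# exemplar similarity matrix: rows = stimuli, cols = exemplars
.similarity_matrix <- function(x1, x2, ex, w, h) {
  d <- w[1] * abs(outer(x1, ex$x1, "-")) + w[2] * abs(outer(x2, ex$x2, "-"))
  exp(-h * d)
}

#' Similarity-based criterion prediction
#'
#' The exemplar process predicts the mean of the exemplars' criterion
#' values, each weighted by its normalized similarity to the stimulus:
#' \deqn{\hat c^{Sim}(s) = \sum_j S(s, e_j) c_j / \sum_j S(s, e_j),}
#' with \eqn{S(s, e) = \exp(-h \, d_w(s, e))} and \eqn{d_w} the
#' attention-weighted city-block distance. Predictions therefore never leave
#' the range of the exemplars' criterion values (no extrapolation).
#'
#' @param x1,x2 Stimulus cue values (vectorized).
#' @param env A `rulex_env`.
#' @param params A `rulex_params` (attention weights derive from the betas).
#' @return Numeric predictions within the exemplar criterion range.
#' @export
similarity_prediction <- function(x1, x2, env, params) {
  stopifnot(inherits(env, "rulex_env"), inherits(params, "rulex_params"))
  check_cues(x1, x2)
  w <- .attention_weights(params$beta1, params$beta2)
  S <- .similarity_matrix(x1, x2, env$exemplars, w, params$h)
  drop(S %*% env$exemplars$criterion) / rowSums(S)
}

#' Rule-based criterion prediction
#'
#' The rule process is a linear model in the cues:
#' \eqn{\hat c^{Rule}(s) = \beta_0 + \beta_1 x_1 + \beta_2 x_2}. Unlike the
#' similarity process it extrapolates freely beyond the exemplar range.
#'
#' @inheritParams similarity_prediction
#' @return Numeric predictions.
#' @export
rule_prediction <- function(x1, x2, params) {
  stopifnot(inherits(params, "rulex_params"))
  check_cues(x1, x2)
  params$beta0 + params$beta1 * x1 + params$beta2 * x2
}

#' Mixture prediction (RulEx-J)
#'
#' The judged criterion blends the two processes through the mixture weight:
#' \deqn{\hat c = \alpha \, \hat c^{Sim} + (1 - \alpha) \, \hat c^{Rule}.}
#'
#' @inheritParams similarity_prediction
#' @return A tibble with columns `c_sim`, `c_rule`, `c_mix`; `c_mix` always
#'   lies between `c_sim` and `c_rule`.
#' @examples
#' env <- task_environment()
#' p <- model_params(0.5, -9.25, 5.25, 3.25, sigma = 2)
#' mixture_prediction(4, 4, env, p)
#' @export
mixture_prediction <- function(x1, x2, env, params) {
  c_sim <- similarity_prediction(x1, x2, env, params)
  c_rule <- rule_prediction(x1, x2, params)
  tibble::tibble(
    c_sim = c_sim, c_rule = c_rule,
    c_mix = params$alpha * c_sim + (1 - params$alpha) * c_rule
  )
}

#' Model predictions over the full stimulus grid
#'
#' Convenience table in the export shape `(x1, x2, c_true, c_sim, c_rule,
#' c_mix)`.
#'
#' @param env A `rulex_env`.
#' @param params A `rulex_params`.
#' @return A 16-row tibble.
#' @export
predict_grid <- function(env, params) {
  g <- stimulus_grid()
  pred <- mixture_prediction(g$x1, g$x2, env, params)
  tibble::tibble(x1 = g$x1, x2 = g$x2,
                 c_true = env$criterion_fn(g$x1, g$x2),
                 c_sim = pred$c_sim, c_rule = pred$c_rule, c_mix = pred$c_mix)
}

#' Gaussian response log-likelihood
#'
#' Responses are modeled as Gaussian around the mixture prediction with SD
#' `sigma`; the log-likelihood sums the per-trial log densities. With
#' `truncate = TRUE` the density is renormalized to the response scale
#' (off by default: the plain Gaussian is the fitting model).
#'
#' @param data Judgment table with columns `x1`, `x2`, `response`.
#' @param env A `rulex_env`.
#' @param params A `rulex_params`.
#' @param truncate Logical; renormalize the Gaussian to
#'   `[scale_min, scale_max]`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, env, params, truncate = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("x1", "x2", "response") %in% names(data)))
  if (nrow(data) == 0) stop("empty judgment table", call. = FALSE)
  if (!all(is.finite(data$response))) {
    stop("non-finite response values", call. = FALSE)
  }
  m <- mixture_prediction(data$x1, data$x2, env, params)$c_mix
  ll <- sum(stats::dnorm(data$response, mean = m, sd = params$sigma, log = TRUE))
  if (truncate) {
    z <- stats::pnorm(env$scale_max, m, params$sigma) -
      stats::pnorm(env$scale_min, m, params$sigma)
    ll <- ll - sum(log(z))
  }
  ll
}

#' Serialize / restore model parameters
#'
#' Flat named-list round-trip for writing parameters to JSON or YAML.
#'
#' @param params A `rulex_params`.
#' @return `params_to_list()`: a named list; `params_from_list()`: a
#'   `rulex_params`.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "rulex_params"))
  unclass(params)
}

#' @rdname params_to_list
#' @param x Named list with entries `alpha`, `beta0`, `beta1`, `beta2`,
#'   `sigma` and optionally `h`.
#' @export
params_from_list <- function(x) {
  model_params(x$alpha, x$beta0, x$beta1, x$beta2, x$sigma,
               h = x$h %||% 1)
}
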