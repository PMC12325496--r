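# Per-participant maximum-likelihood fitting with stimulus-wise
# cross-validation, out-of-sample model comparison, and classification.

#' Fitting control options
#'
#' @param n_restarts Number of optimizer starts (>= 1). The first three are
#'   deterministic (OLS-derived betas with alpha at .5, .05 and .95); the
#'   remainder are seeded random draws.
#' @param seed Integer seed for the random starts (fitting is deterministic
#'   given data and this seed).
#' @param h Fixed similarity sensitivity passed to the model.
#' @param truncate Use the scale-truncated Gaussian likelihood.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_restarts = 5L, seed = 1L, h = 1, truncate = FALSE,
                        maxit = 300L) {
  stopifnot(n_restarts >= 1)
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 h = h, truncate = truncate, maxit = as.integer(maxit)),
            class = "fit_control")
}

# Sufficient statistics per unique stimulus; makes each likelihood
# evaluation O(#unique stimuli) instead of O(#trials).
.suffstats <- function(data) {
  key <- interaction(data$x1, data$x2, drop = TRUE)
  n_s <- as.vector(tapply(data$response, key, length))
  mean_s <- as.vector(tapply(data$response, key, mean))
  ss_s <- as.vector(tapply(data$response, key,
                           function(r) sum((r - mean(r))^2)))
  idx <- match(levels(key), key)
  list(x1 = data$x1[idx], x2 = data$x2[idx],
       n = n_s, mean = mean_s, ss = ss_s, n_total = nrow(data))
}

# Negative log-likelihood closure over sufficient statistics.
# theta = (alpha, beta0, beta1, beta2, log_sigma); when `fixed_alpha` is
# given, theta drops its first element.
.make_nll <- function(stats, env, h, truncate, fixed_alpha = NULL) {
  ex <- env$exemplars
  D1 <- abs(outer(stats$x1, ex$x1, "-"))
  D2 <- abs(outer(stats$x2, ex$x2, "-"))
  crit <- ex$criterion
  lo <- env$scale_min; hi <- env$scale_max
  function(theta) {
    if (is.null(fixed_alpha)) {
      alpha <- theta[1]; b <- theta[2:4]; ls <- theta[5]
    } else {
      alpha <- fixed_alpha; b <- theta[1:3]; ls <- theta[4]
    }
    sigma <- exp(ls)
    w <- .attention_weights(b[2], b[3])
    S <- exp(-h * (w[1] * D1 + w[2] * D2))
    c_sim <- drop(S %*% crit) / rowSums(S)
    c_rule <- b[1] + b[2] * stats$x1 + b[3] * stats$x2
    m <- alpha * c_sim + (1 - alpha) * c_rule
    nll <- 0.5 * stats$n_total * log(2 * pi * sigma^2) +
      sum((stats$ss + stats$n * (stats$mean - m)^2)) / (2 * sigma^2)
    if (truncate) {
      z <- stats::pnorm(hi, m, sigma) - stats::pnorm(lo, m, sigma)
      nll <- nll + sum(stats$n * log(z))
    }
    if (!is.finite(nll)) 1e10 else nll
  }
}

# OLS-based starting values: betas from response ~ x1 + x2, sigma from the
# residual SD (floored away from zero).
.ols_start <- function(data) {
  fit <- stats::lm.fit(cbind(1, data$x1, data$x2), data$response)
  b <- fit$coefficients
  b[!is.finite(b)] <- 0
  sigma0 <- stats::sd(fit$residuals)
  if (!is.finite(sigma0) || sigma0 < 0.25) sigma0 <- 0.25
  list(beta = unname(b), log_sigma = log(sigma0))
}

#' Maximum-likelihood fit of the RulEx-J model
#'
#' Fits the five free parameters (alpha, beta0, beta1, beta2, sigma) to one
#' participant's judgment table by bounded multi-start quasi-Newton
#' optimization (L-BFGS-B): alpha on its natural `[0, 1]` bound, sigma on
#' the log scale, betas unbounded. The best of all starts is returned; if no
#' start converges the best available optimum is returned with
#' `converged = FALSE` rather than an error.
#'
#' @param data Judgment table with columns `x1`, `x2`, `response`
#'   (>= 2 distinct stimuli).
#' @param env A `rulex_env`.
#' @param control A [fit_control()].
#' @param fixed_alpha Optional value to clamp alpha at (0 fits the pure rule
#'   model, 1 the pure similarity model).
#' @return A list of class `rulex_fit`: `params` (`rulex_params`), `logLik`,
#'   `converged`, `n_restarts`, `model`.
#' @export
fit_mle <- function(data, env, control = fit_control(), fixed_alpha = NULL) {
  stopifnot(inherits(env, "rulex_env"), inherits(control, "fit_control"))
  if (length(unique(paste(data$x1, data$x2))) < 2) {
    stop("need at least 2 distinct stimuli to fit", call. = FALSE)
  }
  st <- .suffstats(data)
  nll <- .make_nll(st, env, control$h, control$truncate, fixed_alpha)
  ols <- .ols_start(data)

  starts <- list(
    c(0.5, ols$beta, ols$log_sigma),
    c(0.05, ols$beta, ols$log_sigma),
    c(0.95, ols$beta, ols$log_sigma)
  )
  n_rand <- max(0L, control$n_restarts - 3L)
  if (n_rand > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(control$seed)
    for (i in seq_len(n_rand)) {
      starts[[length(starts) + 1L]] <- c(
        stats::runif(1),
        ols$beta + stats::rnorm(3, sd = 1),
        ols$log_sigma + stats::rnorm(1, sd = 0.5)
      )
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  starts <- starts[seq_len(min(length(starts), max(control$n_restarts, 3L)))]

  if (is.null(fixed_alpha)) {
    lower <- c(0, -100, -100, -100, log(1e-3))
    upper <- c(1, 100, 100, 100, log(50))
  } else {
    lower <- c(-100, -100, -100, log(1e-3))
    upper <- c(100, 100, 100, log(50))
    starts <- lapply(starts, function(s) s[-1])
  }

  best <- NULL
  converged <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = control$maxit)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  th <- best$par
  if (is.null(fixed_alpha)) {
    params <- model_params(th[1], th[2], th[3], th[4], exp(th[5]),
                           h = control$h)
  } else {
    params <- model_params(fixed_alpha, th[1], th[2], th[3], exp(th[4]),
                           h = control$h)
  }
  structure(
    list(params = params, logLik = -best$value, converged = converged,
         n_restarts = length(starts),
         model = if (is.null(fixed_alpha)) "rulexj"
                 else if (fixed_alpha == 0) "rule_only"
                 else if (fixed_alpha == 1) "similarity_only"
                 else sprintf("alpha_fixed_%.2f", fixed_alpha)),
    class = "rulex_fit"
  )
}

#' Leave-one-stimulus-out cross-validation folds
#'
#' One fold per distinct stimulus: the held-out set contains every trial of
#' that stimulus; the training set the rest. With the full 16-stimulus test
#' phase this is the 16-fold scheme used for parameter estimation.
#'
#' @param data Judgment table with columns `x1`, `x2`.
#' @return A named list of folds, each `list(train = <row idx>, test = <row
#'   idx>, x1, x2)`. Fewer than 16 distinct stimuli yields fewer folds with
#'   a warning.
#' @export
crossval_folds <- function(data) {
  stopifnot(is.data.frame(data), all(c("x1", "x2") %in% names(data)))
  key <- paste(data$x1, data$x2, sep = ",")
  stims <- unique(key)
  if (length(stims) < 16) {
    warning(sprintf("only %d distinct stimuli present; %d folds built",
                    length(stims), length(stims)), call. = FALSE)
  }
  folds <- lapply(stims, function(s) {
    test <- which(key == s)
    xy <- as.integer(strsplit(s, ",")[[1]])
    list(train = setdiff(seq_len(nrow(data)), test), test = test,
         x1 = xy[1], x2 = xy[2])
  })
  names(folds) <- stims
  folds
}

#' Average per-fold parameters
#'
#' Fold-level estimates are aggregated by the component-wise mean; the
#' medians of the cue weights are reported as well (used to derive each
#' participant's attention weights for the gaze analyses).
#'
#' @param fold_params Data frame with columns `alpha`, `beta0`, `beta1`,
#'   `beta2`, `sigma` (one row per fold).
#' @return A list: `mean` (a `rulex_params`), `median_betas` (named numeric
#'   `c(beta1, beta2)`).
#' @export
aggregate_params <- function(fold_params) {
  stopifnot(nrow(fold_params) >= 1)
  m <- vapply(fold_params[c("alpha", "beta0", "beta1", "beta2", "sigma")],
              mean, numeric(1))
  list(
    mean = model_params(m["alpha"], m["beta0"], m["beta1"], m["beta2"],
                        m["sigma"],
                        h = if ("h" %in% names(fold_params))
                          fold_params$h[1] else 1),
    median_betas = c(beta1 = stats::median(fold_params$beta1),
                     beta2 = stats::median(fold_params$beta2))
  )
}

# fit one model across all folds; returns per-fold params + held-out scores
.cv_fit <- function(data, env, control, fixed_alpha = NULL) {
  folds <- crossval_folds(data)
  rows <- vector("list", length(folds))
  ll_heldout <- 0
  sq_err <- 0
  n_test <- 0
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    train <- data[f$train, , drop = FALSE]
    test <- data[f$test, , drop = FALSE]
    fit <- fit_mle(train, env, control, fixed_alpha = fixed_alpha)
    p <- fit$params
    ll_heldout <- ll_heldout +
      log_likelihood(test, env, p, truncate = control$truncate)
    pred <- mixture_prediction(test$x1, test$x2, env, p)$c_mix
    sq_err <- sq_err + sum((test$response - pred)^2)
    n_test <- n_test + nrow(test)
    rows[[i]] <- tibble::tibble(
      fold = i, x1 = f$x1, x2 = f$x2,
      alpha = p$alpha, beta0 = p$beta0, beta1 = p$beta1, beta2 = p$beta2,
      sigma = p$sigma, converged = fit$converged
    )
  }
  list(fold_params = dplyr::bind_rows(rows),
       heldout_ll = ll_heldout,
       heldout_rmse = sqrt(sq_err / n_test))
}

#' Cross-validated RulEx-J fit for one participant
#'
#' Fits the model on each leave-one-stimulus-out training set, evaluates the
#' held-out likelihood, and averages the per-fold parameters (mean across
#' folds; medians of the cue weights kept alongside).
#'
#' @inheritParams fit_mle
#' @return A list of class `rulex_cvfit`: `fold_params` (tibble, one row per
#'   fold), `params` (fold-mean `rulex_params`), `median_betas`,
#'   `heldout_ll`, `heldout_rmse`, `converged` (all folds converged).
#' @export
fit_crossval <- function(data, env, control = fit_control()) {
  cv <- .cv_fit(data, env, control)
  agg <- aggregate_params(cv$fold_params)
  structure(
    list(fold_params = cv$fold_params, params = agg$mean,
         median_betas = agg$median_betas,
         heldout_ll = cv$heldout_ll, heldout_rmse = cv$heldout_rmse,
         converged = all(cv$fold_params$converged)),
    class = "rulex_cvfit"
  )
}

#' @export
print.rulex_cvfit <- function(x, ...) {
  cat(sprintf("<rulex_cvfit> %d folds | fold-mean alpha = %.3f | heldout LL = %.2f\n",
              nrow(x$fold_params), x$params$alpha, x$heldout_ll))
  invisible(x)
}

#' Out-of-sample model comparison
#'
#' Compares the full mixture model against its two restricted variants — the
#' pure rule model (alpha clamped at 0) and the pure similarity model (alpha
#' clamped at 1) — by held-out log-likelihood (and RMSE) summed over the
#' leave-one-stimulus-out folds.
#'
#' @inheritParams fit_mle
#' @param models Character subset of `c("rulexj", "rule_only",
#'   "similarity_only")`.
#' @return A tibble with columns `model`, `heldout_ll`, `heldout_rmse`.
#' @export
compare_models <- function(data, env, control = fit_control(),
                           models = c("rulexj", "rule_only",
                                      "similarity_only")) {
  models <- match.arg(models, several.ok = TRUE)
  clamp <- c(rulexj = NA, rule_only = 0, similarity_only = 1)
  rows <- lapply(models, function(m) {
    fa <- clamp[[m]]
    cv <- .cv_fit(data, env, control,
                  fixed_alpha = if (is.na(fa)) NULL else fa)
    tibble::tibble(model = m, heldout_ll = cv$heldout_ll,
                   heldout_rmse = cv$heldout_rmse)
  })
  dplyr::bind_rows(rows)
}

#' Classify a participant by the fold-mean mixture weight
#'
#' Rule users have alpha < .5, similarity users alpha > .5; the boundary
#' value .5 is left unclassified rather than silently binned.
#'
#' @param alpha Fold-mean alpha in `[0, 1]` (vectorized).
#' @return Character vector: `"rule_user"`, `"similarity_user"` or
#'   `"unclassified"`.
#' @export
classify_user <- function(alpha) {
  stopifnot(all(alpha >= 0 & alpha <= 1))
  dplyr::case_when(
    alpha < 0.5 ~ "rule_user",
    alpha > 0.5 ~ "similarity_user",
    TRUE ~ "unclassified"
  )
}

#' Detect a single-cue strategy
#'
#' Flags participants whose fit shows near-maximal reliance on similarity
#' with one cue essentially ignored: alpha above `alpha_thresh` and the
#' smaller normalized attention weight below `weight_thresh`. Such
#' participants can retrieve a cue-criterion pairing without full exemplar
#' memory, which relaxes the link between similarity use and
#' looking-at-nothing.
#'
#' @param params A `rulex_params`.
#' @param alpha_thresh Alpha threshold (default .9).
#' @param weight_thresh Threshold on the smaller attention weight
#'   (default .05).
#' @return Logical flag.
#' @export
detect_single_cue <- function(params, alpha_thresh = 0.9,
                              weight_thresh = 0.05) {
  stopifnot(inherits(params, "rulex_params"))
  w <- .attention_weights(params$beta1, params$beta2)
  params$alpha > alpha_thresh && min(w) < weight_thresh
}

#' Screen a fit for an inverted cue-criterion pattern
#'
#' Participants who assign larger criterion values to smaller cue values
#' (both fitted cue weights negative) are incompatible with the model's
#' monotone environments and are flagged for exclusion.
#'
#' @param params A `rulex_params`.
#' @return Logical; `TRUE` means the participant should be excluded.
#' @export
screen_exclusion <- function(params) {
  stopifnot(inherits(params, "rulex_params"))
  params$beta1 < 0 && params$beta2 < 0
}

#' Cross-validated fits for a cohort
#'
#' Runs [fit_crossval()] per participant and returns one row per participant
#' with fold-mean parameters, attention weights (from the median cue
#' weights), classification and screening flags.
#'
#' @param judgments Judgment table with columns `participant`, `x1`, `x2`,
#'   `response`.
#' @param env A `rulex_env`.
#' @param control A [fit_control()].
#' @return A tibble with columns `participant`, `alpha`, `beta0`, `beta1`,
#'   `beta2`, `sigma`, `w1`, `w2`, `heldout_ll`, `heldout_rmse`,
#'   `converged`, `classification`, `single_cue`, `excluded`.
#' @export
fit_cohort <- function(judgments, env, control = fit_control()) {
  stopifnot(all(c("participant", "x1", "x2", "response") %in%
                  names(judgments)))
  ids <- unique(judgments$participant)
  rows <- lapply(ids, function(id) {
    d <- judgments[judgments$participant == id, ]
    cv <- fit_crossval(d, env, control)
    p <- cv$params
    w <- .attention_weights(cv$median_betas["beta1"],
                            cv$median_betas["beta2"])
    tibble::tibble(
      participant = id,
      alpha = p$alpha, beta0 = p$beta0, beta1 = p$beta1, beta2 = p$beta2,
      sigma = p$sigma, w1 = w[1], w2 = w[2],
      heldout_ll = cv$heldout_ll, heldout_rmse = cv$heldout_rmse,
      converged = cv$converged,
      classification = classify_user(p$alpha),
      single_cue = detect_single_cue(p),
      excluded = screen_exclusion(p)
    )
  })
  dplyr::bind_rows(rows)
}
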