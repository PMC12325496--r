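# Statistical layer: rank correlations, group comparisons, the sensitivity
# power analysis, and assembly of the association report that ties the
# model's mixture weight to looking-at-nothing.

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with an asymptotic two-sided p value,
#' used throughout because the looking-at-nothing and alpha distributions
#' violate normality. Thin wrapper over [stats::cor.test()] with the exact
#' test disabled so ties are handled by the tie-corrected normal
#' approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `tau`, `p`, `n`. A constant vector yields `tau = NA`
#'   with a warning.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Kendall tau undefined", call. = FALSE)
    return(list(tau = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE)
  )
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Rank-sum comparison of two groups
#'
#' Tie-corrected asymptotic Wilcoxon-Mann-Whitney test (no continuity
#' correction), reporting the W statistic for the first group.
#'
#' @param values Numeric vector.
#' @param labels Grouping vector with exactly two levels.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A list: `W`, `p`, `n1`, `n2`, `groups`.
#' @export
group_compare <- function(values, labels,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) stop("need exactly two groups", call. = FALSE)
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(g1) == 1 || length(g2) == 1) {
    warning("a group has a single observation; the asymptotic p value is crude",
            call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, alternative = alternative,
                       exact = FALSE, correct = FALSE)
  )
  list(W = unname(wt$statistic), p = wt$p.value,
       n1 = length(g1), n2 = length(g2), groups = levels(labels))
}

#' Sensitivity power analysis for a bivariate correlation
#'
#' The smallest population correlation detectable with the given sample
#' size, type-I error rate and power, via the Fisher z approximation:
#' \deqn{\rho = \tanh\left(\frac{z_{1-\alpha/2} + z_{power}}{\sqrt{n-3}}\right).}
#' At n = 48, alpha = .05 and power = .95 (two-sided) this gives .49.
#'
#' @param n Sample size (> 3).
#' @param alpha_level Type-I error rate.
#' @param power Statistical power.
#' @param sides 1 or 2 (two-sided by default).
#' @return Detectable correlation in `(0, 1)`.
#' @examples
#' round(sensitivity_power_correlation(48), 2) # 0.49
#' @export
sensitivity_power_correlation <- function(n, alpha_level = 0.05,
                                          power = 0.95, sides = 2) {
  if (n <= 3) stop("`n` must exceed 3", call. = FALSE)
  stopifnot(alpha_level > 0, alpha_level < 1, power > 0, power < 1,
            sides %in% c(1, 2))
  za <- stats::qnorm(1 - alpha_level / sides)
  zb <- stats::qnorm(power)
  tanh((za + zb) / sqrt(n - 3))
}

#' Required sample size for a bivariate correlation
#'
#' Inverse of [sensitivity_power_correlation()]: the sample size at which a
#' population correlation `rho` is detectable with the given error rate and
#' power.
#'
#' @param rho Target correlation in `(0, 1)`.
#' @param alpha_level Type-I error rate.
#' @param power Statistical power.
#' @param sides 1 or 2.
#' @param ceiling Round up to the next whole participant (default `TRUE`).
#' @return Required sample size.
#' @export
required_n_correlation <- function(rho, alpha_level = 0.05, power = 0.95,
                                   sides = 2, ceiling = TRUE) {
  stopifnot(rho > 0, rho < 1)
  za <- stats::qnorm(1 - alpha_level / sides)
  zb <- stats::qnorm(power)
  n <- ((za + zb) / atanh(rho))^2 + 3
  if (ceiling) base::ceiling(n - 1e-9) else n
}

#' Pooled 2x2 chi-square test of trial-level proportions
#'
#' Compares two trial-level proportions (e.g. looking-at-nothing presence
#' among similarity vs. rule users) by a chi-square test on the pooled 2x2
#' count table, without continuity correction (df = 1 implies pooling
#' across participants).
#'
#' @param success1,n1 Successes and trials in group 1.
#' @param success2,n2 Successes and trials in group 2.
#' @return A list: `chisq`, `df`, `p`, `prop1`, `prop2`.
#' @export
prop_chisq <- function(success1, n1, success2, n2) {
  stopifnot(success1 <= n1, success2 <= n2, n1 > 0, n2 > 0)
  m <- matrix(c(success1, n1 - success1, success2, n2 - success2), nrow = 2)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, prop1 = success1 / n1, prop2 = success2 / n2)
}

#' Exemplar accuracy
#'
#' Test-phase criterion accuracy on exemplar stimuli (exact match of the
#' response with the true criterion value), optionally averaged with a
#' location-test accuracy when one is available — the coarse location
#' measure alone (eight responses) is only vaguely graded.
#'
#' @param judgments One participant's judgment table (`x1`, `x2`,
#'   `response`).
#' @param env A `rulex_env`.
#' @param location_accuracy Optional location-test accuracy in `[0, 1]`.
#' @return Accuracy in `[0, 1]`.
#' @export
exemplar_accuracy <- function(judgments, env, location_accuracy = NULL) {
  ex <- env$exemplars
  key <- paste(judgments$x1, judgments$x2)
  is_ex <- key %in% paste(ex$x1, ex$x2)
  if (!any(is_ex)) stop("no exemplar trials in the judgment table",
                        call. = FALSE)
  truth <- env$criterion_fn(judgments$x1[is_ex], judgments$x2[is_ex])
  crit_acc <- mean(judgments$response[is_ex] == truth)
  if (is.null(location_accuracy)) crit_acc
  else mean(c(crit_acc, location_accuracy))
}

#' Mean responses and signed errors for the critical stimuli
#'
#' The critical extrapolation stimuli `(1,1), (1,2), (3,4), (4,4)` separate
#' the two processes best: the rule extrapolates beyond the exemplar
#' criterion range, similarity cannot. Returns per group (rule vs.
#' similarity users) the mean response and the signed error against the
#' true criterion.
#'
#' @param judgments Cohort judgment table (`participant`, `x1`, `x2`,
#'   `response`).
#' @param fits Per-participant fit table with `participant` and
#'   `classification` columns (from [fit_cohort()]).
#' @param env A `rulex_env`.
#' @param stimuli Two-column matrix/data frame of critical stimuli.
#' @return A tibble: `classification`, `x1`, `x2`, `c_true`,
#'   `mean_response`, `signed_error`, `n`.
#' @export
critical_stimuli_table <- function(judgments, fits, env,
                                   stimuli = rbind(c(1, 1), c(1, 2),
                                                   c(3, 4), c(4, 4))) {
  stimuli <- as.data.frame(stimuli)
  names(stimuli) <- c("x1", "x2")
  j <- dplyr::inner_join(judgments,
                         fits[, c("participant", "classification")],
                         by = "participant")
  j <- dplyr::semi_join(j, stimuli, by = c("x1", "x2"))
  j |>
    dplyr::group_by(.data$classification, .data$x1, .data$x2) |>
    dplyr::summarise(mean_response = mean(.data$response),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(c_true = env$criterion_fn(.data$x1, .data$x2),
                  signed_error = .data$mean_response - .data$c_true) |>
    dplyr::select("classification", "x1", "x2", "c_true",
                  "mean_response", "signed_error", "n")
}

#' Assemble the association report
#'
#' Ties modeling and gaze together for a cohort: the per-participant table
#' (alpha, looking-at-nothing duration and strength, optional exemplar
#' accuracy, classification), the pairwise Kendall tau matrix with p
#' values, Shapiro-Wilk normality screens, the one-sample t-test of alpha
#' against .5, rule- vs. similarity-user group comparisons, the
#' critical-stimuli table, and the association within the
#' weak-reliance subgroup (default window `.1 < alpha < .9`; the cutoffs
#' are admittedly arbitrary and configurable).
#'
#' @param fits Per-participant fit table from [fit_cohort()].
#' @param gaze_summary Per-participant gaze table from
#'   [trial_level_stats()].
#' @param judgments Optional cohort judgment table (enables the
#'   critical-stimuli table and exemplar accuracy).
#' @param env A `rulex_env` (required with `judgments`).
#' @param subgroup_window Alpha window for the subgroup correlation.
#' @return A list of class `lan_report` with elements `participants`,
#'   `correlations` (`tau` and `p` matrices), `normality`, `alpha_t_test`,
#'   `group_comparisons`, `critical_stimuli`, `subgroup`, `flags`.
#' @export
build_report <- function(fits, gaze_summary, judgments = NULL, env = NULL,
                         subgroup_window = c(0.1, 0.9)) {
  missing_ids <- union(setdiff(fits$participant, gaze_summary$participant),
                       setdiff(gaze_summary$participant, fits$participant))
  if (length(missing_ids) > 0) {
    stop("participant IDs do not align across fits and gaze: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::inner_join(
    fits[, c("participant", "alpha", "classification", "single_cue")],
    gaze_summary[, c("participant", "lan_presence", "mean_lan_duration",
                     "mean_lan_strength")],
    by = "participant"
  )
  if (!is.null(judgments)) {
    stopifnot(!is.null(env))
    acc <- vapply(tab$participant, function(id) {
      exemplar_accuracy(judgments[judgments$participant == id, ], env)
    }, numeric(1))
    tab$exemplar_accuracy <- acc
  }

  measures <- intersect(
    c("exemplar_accuracy", "mean_lan_duration", "mean_lan_strength",
      "alpha"),
    names(tab)
  )
  flags <- character()
  k <- length(measures)
  tau_m <- p_m <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  if (nrow(tab) >= 3) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) { tau_m[i, j] <- 1; next }
      kt <- tryCatch(kendall_tau(tab[[measures[i]]], tab[[measures[j]]]),
                     warning = function(w) list(tau = NA, p = NA))
      tau_m[i, j] <- kt$tau; p_m[i, j] <- kt$p
    }
  } else {
    flags <- c(flags, "fewer than 3 participants: correlations undefined")
  }

  normality <- dplyr::bind_rows(lapply(measures, function(m) {
    v <- tab[[m]]
    if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v, na.rm = TRUE) > 0) {
      sw <- stats::shapiro.test(v[!is.na(v)])
      tibble::tibble(measure = m, W = unname(sw$statistic), p = sw$p.value)
    } else {
      tibble::tibble(measure = m, W = NA_real_, p = NA_real_)
    }
  }))

  alpha_t <- if (nrow(tab) >= 2 && stats::sd(tab$alpha) > 0) {
    tt <- stats::t.test(tab$alpha, mu = 0.5)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, ci = unname(tt$conf.int), mean = mean(tab$alpha))
  } else {
    flags <- c(flags, "alpha t-test undefined")
    NULL
  }

  two_groups <- tab[tab$classification %in% c("rule_user", "similarity_user"), ]
  group_comparisons <- NULL
  if (length(unique(two_groups$classification)) == 2) {
    group_comparisons <- list(
      lan_duration = group_compare(two_groups$mean_lan_duration,
                                   two_groups$classification),
      lan_strength = group_compare(two_groups$mean_lan_strength,
                                   two_groups$classification)
    )
  } else {
    flags <- c(flags, "only one user group present: group comparisons skipped")
  }

  critical <- if (!is.null(judgments)) {
    critical_stimuli_table(judgments, fits, env)
  } else NULL

  sub <- tab[tab$alpha > subgroup_window[1] & tab$alpha < subgroup_window[2], ]
  subgroup <- if (nrow(sub) >= 3) {
    kt <- tryCatch(kendall_tau(sub$alpha, sub$mean_lan_duration),
                   warning = function(w) list(tau = NA, p = NA,
                                              n = nrow(sub)))
    c(kt, list(window = subgroup_window))
  } else {
    flags <- c(flags, "subgroup too small for a correlation")
    NULL
  }

  structure(
    list(participants = tab,
         correlations = list(tau = tau_m, p = p_m),
         normality = normality, alpha_t_test = alpha_t,
         group_comparisons = group_comparisons,
         critical_stimuli = critical, subgroup = subgroup,
         flags = flags),
    class = "lan_report"
  )
}

#' @export
print.lan_report <- function(x, ...) {
  cat("<lan_report>", nrow(x$participants), "participants\n")
  if (!all(is.na(x$correlations$tau))) {
    cat("Kendall tau matrix:\n")
    print(round(x$correlations$tau, 3))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Write a report's tables to CSV and markdown
#'
#' Deterministic output: the same report yields byte-identical files.
#'
#' @param report A `lan_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lan_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(report$participants),
                   file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$correlations$tau),
                   file.path(dir, "kendall_tau.csv"))
  utils::write.csv(as.data.frame(report$correlations$p),
                   file.path(dir, "kendall_p.csv"))
  if (!is.null(report$critical_stimuli)) {
    utils::write.csv(as.data.frame(report$critical_stimuli),
                     file.path(dir, "critical_stimuli.csv"),
                     row.names = FALSE)
  }
  md <- c("# Association report", "",
          sprintf("Participants: %d", nrow(report$participants)), "")
  if (!is.null(report$alpha_t_test)) {
    md <- c(md, sprintf(
      "Mean alpha = %.3f (t = %.2f, df = %.0f, p = %.3g vs. .5)",
      report$alpha_t_test$mean, report$alpha_t_test$t,
      report$alpha_t_test$df, report$alpha_t_test$p), "")
  }
  if (!all(is.na(report$correlations$tau)) &&
      all(c("alpha", "mean_lan_duration") %in%
            rownames(report$correlations$tau))) {
    md <- c(md, sprintf(
      "Kendall tau(alpha, looking-at-nothing duration) = %.3f (p = %.3g)",
      report$correlations$tau["alpha", "mean_lan_duration"],
      report$correlations$p["alpha", "mean_lan_duration"]), "")
  }
  if (length(report$flags)) md <- c(md, "Flags:", paste("-", report$flags))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
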