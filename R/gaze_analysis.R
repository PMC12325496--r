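# Looking-at-nothing gaze metrics: AOI geometry, fixation assignment,
# duration/strength measures, time bins, trial-level stats, reliability.

#' Build the five areas of interest
#'
#' Four exemplar AOIs, one per screen corner, plus one center AOI. Exemplar
#' centers sit at the screen center offset by `offsets` (default 415 px
#' horizontally and 235 px vertically, i.e. 477 px center-to-center). Each
#' AOI is the stimulus footprint (default 320 x 180 px) enlarged by `margin`
#' per side, giving 384 x 216 px at the default margin of 0.1. All logic is
#' in screen pixels; the experiment's visual-angle figures assume a 700-mm
#' viewing distance and are converted upstream.
#'
#' @param screen Screen size in px, `c(width, height)`.
#' @param stimulus Stimulus footprint in px, `c(width, height)`.
#' @param margin Enlargement per side as a fraction of the footprint.
#' @param offsets Exemplar-center offsets from screen center, `c(dx, dy)` px.
#' @param exemplars Exemplar tibble (rows are mapped to corners in order
#'   top-left, top-right, bottom-left, bottom-right; randomize upstream if a
#'   per-participant assignment is needed).
#' @return A tibble of class `aoi_set` with columns `aoi`, `x1`, `x2`,
#'   `xmin`, `xmax`, `ymin`, `ymax`; errors if any two AOIs overlap.
#' @examples
#' a <- build_aois()
#' a$xmax - a$xmin # all 384
#' @export
build_aois <- function(screen = c(1920, 1080), stimulus = c(320, 180),
                       margin = 0.1, offsets = c(415, 235),
                       exemplars = default_exemplars()) {
  stopifnot(margin >= 0, length(screen) == 2, length(stimulus) == 2,
            nrow(exemplars) == 4)
  dims <- stimulus * (1 + 2 * margin)
  if (any(dims > screen)) stop("AOI larger than screen", call. = FALSE)
  cx <- screen[1] / 2; cy <- screen[2] / 2
  centers <- rbind(
    top_left     = c(cx - offsets[1], cy - offsets[2]),
    top_right    = c(cx + offsets[1], cy - offsets[2]),
    bottom_left  = c(cx - offsets[1], cy + offsets[2]),
    bottom_right = c(cx + offsets[1], cy + offsets[2]),
    center       = c(cx, cy)
  )
  out <- tibble::tibble(
    aoi = rownames(centers),
    x1 = c(exemplars$x1, NA), x2 = c(exemplars$x2, NA),
    xmin = centers[, 1] - dims[1] / 2, xmax = centers[, 1] + dims[1] / 2,
    ymin = centers[, 2] - dims[2] / 2, ymax = centers[, 2] + dims[2] / 2
  )
  for (i in 1:4) for (j in (i + 1):5) {
    if (out$xmin[i] < out$xmax[j] && out$xmax[i] > out$xmin[j] &&
        out$ymin[i] < out$ymax[j] && out$ymax[i] > out$ymin[j]) {
      stop(sprintf("AOIs overlap: %s and %s", out$aoi[i], out$aoi[j]),
           call. = FALSE)
    }
  }
  class(out) <- c("aoi_set", class(out))
  out
}

#' Label fixations by containing AOI
#'
#' Each fixation is labelled by the AOI containing its coordinates
#' (boundaries inclusive; the AOIs are pairwise disjoint so the label is
#' unique) or `"outside"`. Fixations shorter than `min_duration` are
#' dropped, mirroring the event detector's minimum fixation duration.
#'
#' @param fixations Fixation table with columns `x`, `y`, `duration`
#'   (plus any identifiers, which are preserved).
#' @param aois An `aoi_set`.
#' @param min_duration Minimum fixation duration in ms (default 80).
#' @return The input with an added character column `aoi`.
#' @export
assign_fixations <- function(fixations, aois, min_duration = 80) {
  stopifnot(inherits(aois, "aoi_set"),
            all(c("x", "y", "duration") %in% names(fixations)))
  fixations <- fixations[fixations$duration >= min_duration, , drop = FALSE]
  lab <- rep("outside", nrow(fixations))
  for (i in seq_len(nrow(aois))) {
    hit <- fixations$x >= aois$xmin[i] & fixations$x <= aois$xmax[i] &
      fixations$y >= aois$ymin[i] & fixations$y <= aois$ymax[i]
    lab[hit] <- aois$aoi[i]
  }
  fixations$aoi <- lab
  fixations
}

#' Looking-at-nothing duration
#'
#' Within a trial, the summed gaze duration to the four (blank) exemplar
#' locations divided by the summed gaze duration to the exemplar and
#' test-stimulus (center) locations. Undefined when neither was fixated.
#'
#' @param exemplar_ms Summed exemplar-AOI gaze in ms.
#' @param center_ms Summed center-AOI gaze in ms.
#' @return Proportion in `[0, 1]`, or `NA` when the denominator is 0
#'   (vectorized).
#' @export
lan_duration <- function(exemplar_ms, center_ms) {
  stopifnot(all(exemplar_ms >= 0), all(center_ms >= 0))
  den <- exemplar_ms + center_ms
  ifelse(den > 0, exemplar_ms / den, NA_real_)
}

#' Most similar exemplar to a test stimulus
#'
#' The exemplar minimizing the attention-weighted city-block distance to the
#' stimulus. Ties are broken deterministically: lowest unweighted city-block
#' distance first, then lowest `(x1, x2)` lexicographic order.
#'
#' @param x1,x2 Test-stimulus cue values (scalars).
#' @param env A `rulex_env`.
#' @param w Attention weights `c(w1, w2)` (a participant's normalized median
#'   cue weights; equal weights by default).
#' @return One row of `env$exemplars` (tibble with `x1`, `x2`, `criterion`).
#' @export
most_similar_exemplar <- function(x1, x2, env, w = c(0.5, 0.5)) {
  stopifnot(inherits(env, "rulex_env"), length(x1) == 1, length(x2) == 1)
  ex <- env$exemplars
  d <- weighted_cityblock(c(x1, x2), ex, w)
  d_plain <- abs(x1 - ex$x1) + abs(x2 - ex$x2)
  ord <- order(d, d_plain, ex$x1, ex$x2)
  ex[ord[1], ]
}

#' Looking-at-nothing strength
#'
#' The gaze duration to the location of the exemplar most similar to the
#' test stimulus, divided by the total gaze duration to all exemplar
#' locations. Undefined in trials without any exemplar-location gaze.
#'
#' @param exemplar_ms Named numeric vector of per-exemplar-AOI gaze (ms) for
#'   one trial, or a matrix with one row per trial.
#' @param most_similar Name (or column index) of the most-similar exemplar's
#'   AOI per trial.
#' @return Proportion in `[0, 1]`, or `NA` when no exemplar gaze occurred.
#' @export
lan_strength <- function(exemplar_ms, most_similar) {
  if (is.null(dim(exemplar_ms))) {
    exemplar_ms <- matrix(exemplar_ms, nrow = 1,
                          dimnames = list(NULL, names(exemplar_ms)))
  }
  tot <- rowSums(exemplar_ms)
  idx <- cbind(seq_len(nrow(exemplar_ms)),
               match(most_similar, colnames(exemplar_ms)))
  ifelse(tot > 0, exemplar_ms[idx] / tot, NA_real_)
}

# overlap of fixation [onset, onset+duration] with interval [a, b]
.overlap <- function(onset, duration, a, b) {
  pmax(0, pmin(onset + duration, b) - pmax(onset, a))
}

#' Per-trial gaze summaries
#'
#' Joins labelled fixations with the trial's test-stimulus identity and
#' computes, per trial: per-AOI gaze durations, looking-at-nothing duration
#' and strength (using per-participant attention weights when supplied),
#' the number of distinct exemplar AOIs fixated, the dominant exemplar
#' AOI's share, and whether the single/dominant AOI is the most similar
#' exemplar's.
#'
#' @param fixations Fixation table with columns `participant`, `trial`,
#'   `onset`, `duration`, `x`, `y` (ms / px).
#' @param trials Trial table with columns `participant`, `trial`, `x1`,
#'   `x2` and optionally `trial_length` (ms from stimulus removal to the
#'   response click; defaults to the last fixation offset).
#' @param aois An `aoi_set`.
#' @param env A `rulex_env`.
#' @param weights Either a single `c(w1, w2)` used for everyone, or a data
#'   frame with columns `participant`, `w1`, `w2`.
#' @param min_duration Minimum fixation duration in ms.
#' @return A tibble with one row per trial: identifiers, `x1`, `x2`,
#'   `trial_length`, per-corner gaze columns, `exemplar_ms`, `center_ms`,
#'   `outside_ms`, `lan_duration`, `lan_strength`, `n_exemplar_aois`,
#'   `dominant_share`, `on_most_similar` (dominant AOI is the most
#'   similar exemplar's), `most_similar_aoi`.
#' @export
trial_gaze <- function(fixations, trials, aois, env,
                       weights = c(0.5, 0.5), min_duration = 80) {
  stopifnot(all(c("participant", "trial", "onset", "duration", "x", "y")
                %in% names(fixations)),
            all(c("participant", "trial", "x1", "x2") %in% names(trials)))
  fx <- assign_fixations(fixations, aois, min_duration)
  corner_names <- aois$aoi[aois$aoi != "center"]
  w_for <- function(id) {
    if (is.data.frame(weights)) {
      r <- weights[weights$participant == id, ]
      if (nrow(r) == 0) c(0.5, 0.5) else c(r$w1[1], r$w2[1])
    } else weights
  }
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    f <- fx[fx$participant == tr$participant & fx$trial == tr$trial, ]
    per_aoi <- vapply(corner_names, function(a) {
      sum(f$duration[f$aoi == a])
    }, numeric(1))
    center_ms <- sum(f$duration[f$aoi == "center"])
    outside_ms <- sum(f$duration[f$aoi == "outside"])
    ms <- most_similar_exemplar(tr$x1, tr$x2, env, w_for(tr$participant))
    ms_aoi <- aois$aoi[!is.na(aois$x1) & aois$x1 == ms$x1 & aois$x2 == ms$x2]
    n_aois <- sum(per_aoi > 0)
    dominant <- if (n_aois > 0) corner_names[which.max(per_aoi)] else NA
    tl <- if ("trial_length" %in% names(tr) && !is.na(tr$trial_length)) {
      tr$trial_length
    } else if (nrow(f) > 0) max(f$onset + f$duration) else NA_real_
    rows[[i]] <- tibble::tibble(
      participant = tr$participant, trial = tr$trial,
      x1 = tr$x1, x2 = tr$x2, trial_length = tl,
      !!!stats::setNames(as.list(per_aoi), corner_names),
      exemplar_ms = sum(per_aoi), center_ms = center_ms,
      outside_ms = outside_ms,
      lan_duration = lan_duration(sum(per_aoi), center_ms),
      lan_strength = lan_strength(per_aoi, ms_aoi),
      n_exemplar_aois = n_aois,
      dominant_share = if (n_aois > 0) max(per_aoi) / sum(per_aoi)
                       else NA_real_,
      on_most_similar = if (n_aois > 0) dominant == ms_aoi else NA,
      most_similar_aoi = ms_aoi
    )
  }
  dplyr::bind_rows(rows)
}

#' Time-binned looking-at-nothing
#'
#' Splits each trial's post-removal interval `[0, trial_length]` into
#' `n_bins` bins of equal length and computes the looking-at-nothing
#' duration per bin. Fixations straddling a bin boundary are split pro rata
#' by default (`boundary = "onset"` instead assigns the whole fixation to
#' its onset bin). Bins with no gaze to either exemplar or center AOIs
#' contribute 0, so per-bin curves average over all trials.
#'
#' @inheritParams trial_gaze
#' @param n_bins Number of bins (default 5).
#' @param boundary `"prorata"` or `"onset"`.
#' @return A tibble with one row per trial x bin: `participant`, `trial`,
#'   `bin`, `exemplar_ms`, `center_ms`, `lan`.
#' @export
time_binned_lan <- function(fixations, trials, aois, n_bins = 5,
                            boundary = c("prorata", "onset"),
                            min_duration = 80) {
  boundary <- match.arg(boundary)
  stopifnot(n_bins >= 1)
  fx <- assign_fixations(fixations, aois, min_duration)
  is_ex <- !fx$aoi %in% c("center", "outside")
  is_ctr <- fx$aoi == "center"
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    tl <- tr$trial_length
    if (is.na(tl) || tl <= 0) stop("trial_length must be positive",
                                   call. = FALSE)
    sel <- fx$participant == tr$participant & fx$trial == tr$trial
    f <- fx[sel, ]
    fex <- is_ex[sel]; fct <- is_ctr[sel]
    edges <- seq(0, tl, length.out = n_bins + 1)
    ex_ms <- ctr_ms <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      if (boundary == "prorata") {
        ov <- .overlap(f$onset, f$duration, edges[b], edges[b + 1])
      } else {
        inbin <- f$onset >= edges[b] &
          (f$onset < edges[b + 1] | (b == n_bins & f$onset <= tl))
        ov <- ifelse(inbin, f$duration, 0)
      }
      ex_ms[b] <- sum(ov[fex]); ctr_ms[b] <- sum(ov[fct])
    }
    lan <- ifelse(ex_ms + ctr_ms > 0, ex_ms / (ex_ms + ctr_ms), 0)
    rows[[i]] <- tibble::tibble(participant = tr$participant,
                                trial = tr$trial, bin = seq_len(n_bins),
                                exemplar_ms = ex_ms, center_ms = ctr_ms,
                                lan = lan)
  }
  dplyr::bind_rows(rows)
}

#' Trial-level looking-at-nothing statistics per participant
#'
#' From a per-trial gaze table: the proportion of trials with any
#' exemplar-location gaze, the distribution of the number of distinct
#' exemplar AOIs fixated per trial, the share of single-AOI trials whose
#' AOI belongs to the most similar exemplar, and the dominant AOI's mean
#' share in multi-AOI trials.
#'
#' @param gaze Output of [trial_gaze()].
#' @return A tibble with one row per participant: `lan_presence`,
#'   `mean_lan_duration`, `mean_lan_strength`, `n_aoi_0` .. `n_aoi_4`
#'   (trial proportions), `single_aoi_share`, `single_on_most_similar`,
#'   `multi_dominant_share`, `n_trials`, `n_undefined_duration`,
#'   `n_undefined_strength`.
#' @export
trial_level_stats <- function(gaze) {
  stopifnot(nrow(gaze) >= 1)
  gaze |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      lan_presence = mean(.data$exemplar_ms > 0),
      mean_lan_duration = mean(.data$lan_duration, na.rm = TRUE),
      mean_lan_strength = mean(.data$lan_strength, na.rm = TRUE),
      n_aoi_0 = mean(.data$n_exemplar_aois == 0),
      n_aoi_1 = mean(.data$n_exemplar_aois == 1),
      n_aoi_2 = mean(.data$n_exemplar_aois == 2),
      n_aoi_3 = mean(.data$n_exemplar_aois == 3),
      n_aoi_4 = mean(.data$n_exemplar_aois == 4),
      single_aoi_share = {
        n_lan <- sum(.data$n_exemplar_aois > 0)
        if (n_lan > 0) sum(.data$n_exemplar_aois == 1) / n_lan else NA_real_
      },
      single_on_most_similar = {
        s <- .data$n_exemplar_aois == 1
        if (any(s)) mean(.data$on_most_similar[s]) else NA_real_
      },
      multi_dominant_share = {
        m <- .data$n_exemplar_aois > 1
        if (any(m)) mean(.data$dominant_share[m]) else NA_real_
      },
      n_trials = dplyr::n(),
      n_undefined_duration = sum(is.na(.data$lan_duration)),
      n_undefined_strength = sum(is.na(.data$lan_strength)),
      .groups = "drop"
    )
}

#' Stimulus-wise split-half reliability of looking-at-nothing
#'
#' For one participant: per stimulus, the mean looking-at-nothing duration
#' over odd-numbered presentations versus even-numbered presentations
#' (presentation index in trial order); the reliability is the Pearson
#' correlation of the two means across stimuli. Stimuli with fewer than two
#' presentations are dropped with a warning.
#'
#' @param gaze Per-trial gaze table for one participant (columns `trial`,
#'   `x1`, `x2`, `lan_duration`).
#' @return Scalar correlation (`NA` if fewer than 3 stimuli survive).
#' @export
split_half_reliability <- function(gaze) {
  gaze <- gaze[order(gaze$trial), ]
  key <- paste(gaze$x1, gaze$x2, sep = ",")
  halves <- lapply(split(seq_len(nrow(gaze)), key), function(idx) {
    if (length(idx) < 2) return(NULL)
    pres <- seq_along(idx)
    lan <- gaze$lan_duration[idx]
    c(odd = mean(lan[pres %% 2 == 1], na.rm = TRUE),
      even = mean(lan[pres %% 2 == 0], na.rm = TRUE))
  })
  dropped <- sum(vapply(halves, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d stimulus/stimuli with < 2 presentations dropped",
                    dropped), call. = FALSE)
  }
  m <- do.call(rbind, halves[!vapply(halves, is.null, logical(1))])
  if (is.null(m) || nrow(m) < 3) return(NA_real_)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3 || stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
    return(NA_real_)
  }
  stats::cor(m[, 1], m[, 2])
}

#' Export AOI geometry as JSON-ready list
#'
#' @param aois An `aoi_set`.
#' @return A plain list (one entry per AOI) suitable for
#'   `jsonlite::toJSON()`.
#' @export
aois_to_list <- function(aois) {
  lapply(seq_len(nrow(aois)), function(i) {
    r <- aois[i, ]
    list(aoi = r$aoi, x1 = r$x1, x2 = r$x2,
         xmin = r$xmin, xmax = r$xmax, ymin = r$ymin, ymax = r$ymax)
  })
}
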