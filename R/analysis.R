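#' Neural session container
#'
#' A recording (real or simulated) of time x neuron activity with a pathway
#' label per neuron and a behavioral-syllable label per frame. Syllable
#' instances (onset, end, syllable id) are taken from `instances` if given,
#' otherwise derived as maximal runs of a constant non-missing label.
#'
#' @param activity time x neurons numeric matrix (arbitrary units).
#' @param pathway character vector (length = n neurons), `"dSPN"`/`"iSPN"`.
#' @param syllable integer syllable id per frame; `NA` for unlabeled frames.
#' @param frame_rate nominal frame rate, Hz (30).
#' @param instances optional data.frame with columns `onset`, `end`,
#'   `syllable` (frame indices, onsets strictly increasing).
#' @return object of class `neural_session`.
#' @export
neural_session <- function(activity, pathway, syllable, frame_rate = 30,
                           instances = NULL) {
  activity <- as.matrix(activity)
  stopifnot(length(pathway) == ncol(activity),
            all(pathway %in% c("dSPN", "iSPN")),
            length(syllable) == nrow(activity))
  if (is.null(instances)) {
    r <- rle(ifelse(is.na(syllable), -1L, as.integer(syllable)))
    ends <- cumsum(r$lengths)
    onsets <- ends - r$lengths + 1L
    keep <- r$values != -1L
    instances <- data.frame(onset = onsets[keep], end = ends[keep],
                            syllable = r$values[keep])
  }
  stopifnot(all(diff(instances$onset) > 0),
            all(instances$end >= instances$onset),
            all(instances$end <= nrow(activity)))
  structure(list(activity = activity, pathway = pathway,
                 syllable = syllable, frame_rate = frame_rate,
                 instances = instances, zscored = FALSE),
            class = "neural_session")
}

#' @export
print.neural_session <- function(x, ...) {
  cat("<neural_session>", nrow(x$activity), "frames x", ncol(x$activity),
      "neurons (", sum(x$pathway == "dSPN"), "dSPN /",
      sum(x$pathway == "iSPN"), "iSPN );",
      nrow(x$instances), "syllable instances\n")
  invisible(x)
}

#' Lagged cross-correlation of two traces
#'
#' Pearson correlation of the mean-subtracted traces at each integer lag in
#' `[-max_lag, max_lag]`. A positive lag means `trace_a` leads `trace_b`
#' (present `a` is correlated with future `b`).
#'
#' @param trace_a,trace_b equal-length numeric vectors.
#' @param max_lag maximum lag (frames).
#' @return data.frame with columns `lag` and `cor`.
#' @export
cross_correlation <- function(trace_a, trace_b, max_lag) {
  stopifnot(length(trace_a) == length(trace_b),
            max_lag >= 0, max_lag < length(trace_a))
  if (stats::sd(trace_a) == 0 || stats::sd(trace_b) == 0)
    stop("cross-correlation undefined for a constant trace")
  n <- length(trace_a)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(trace_a[1:(n - k)], trace_b[(1 + k):n])
    else stats::cor(trace_a[(1 - k):n], trace_b[1:(n + k)])
  }, numeric(1))
  data.frame(lag = lags, cor = cc)
}

#' Cross-correlation asymmetry index
#'
#' Scalar summary of lead/lag asymmetry: mean correlation over positive lags
#' minus mean over negative lags. Positive values mean the first trace leads.
#'
#' @param xcorr data.frame from [cross_correlation()] on a symmetric lag grid.
#' @return scalar asymmetry index.
#' @export
asymmetry_index <- function(xcorr) {
  stopifnot(all(c("lag", "cor") %in% names(xcorr)))
  pos <- xcorr$lag > 0
  neg <- xcorr$lag < 0
  if (sum(pos) != sum(neg)) stop("lag grid must be symmetric")
  mean(xcorr$cor[pos]) - mean(xcorr$cor[neg])
}

#' Block-bootstrap confidence interval for the cross-correlation asymmetry
#'
#' Splits the traces into contiguous chunks, computes the asymmetry index
#' per chunk, and bootstraps the chunk mean, respecting the temporal
#' dependence within chunks.
#'
#' @param trace_a,trace_b equal-length traces.
#' @param max_lag maximum lag.
#' @param n_chunks number of contiguous chunks.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return list with `estimate`, `ci` (length 2), and `chunk_values`.
#' @export
asymmetry_bootstrap <- function(trace_a, trace_b, max_lag, n_chunks = 50,
                                n_boot = 1000, conf = 0.95) {
  n <- length(trace_a)
  bounds <- floor(seq(0, n, length.out = n_chunks + 1))
  vals <- vapply(seq_len(n_chunks), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    asymmetry_index(cross_correlation(trace_a[idx], trace_b[idx], max_lag))
  }, numeric(1))
  boots <- vapply(seq_len(n_boot), function(b)
    mean(vals[sample.int(n_chunks, n_chunks, replace = TRUE)]), numeric(1))
  a <- (1 - conf) / 2
  list(estimate = mean(vals),
       ci = unname(stats::quantile(boots, c(a, 1 - a))),
       chunk_values = vals)
}

#' Z-score each neuron across the session
#'
#' Per-neuron mean 0 and variance 1 across all frames. Zero-variance neurons
#' are excluded with a warning.
#'
#' @param session a [neural_session()].
#' @return the session with z-scored activity (`zscored = TRUE`).
#' @export
zscore_neurons <- function(session) {
  stopifnot(inherits(session, "neural_session"))
  sds <- apply(session$activity, 2, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  if (any(bad)) {
    warning(sum(bad), " zero-variance neuron(s) excluded")
    session$activity <- session$activity[, !bad, drop = FALSE]
    session$pathway <- session$pathway[!bad]
    sds <- sds[!bad]
  }
  session$activity <- scale(session$activity)[, , drop = FALSE]
  attr(session$activity, "scaled:center") <- NULL
  attr(session$activity, "scaled:scale") <- NULL
  session$zscored <- TRUE
  session
}

#' Split syllable instances into halves by onset-time parity
#'
#' Each instance is assigned to a half according to whether its onset
#' timestamp, rounded to the nearest second, is even or odd. Frame 1
#' corresponds to time 0.
#'
#' @param session a [neural_session()].
#' @return integer vector per instance: 0 (even half) or 1 (odd half).
#' @export
split_half_by_onset_parity <- function(session) {
  secs <- round((session$instances$onset - 1) / session$frame_rate)
  as.integer(secs %% 2)
}

#' Retained syllable inventory
#'
#' Syllables with at least `min_count` instances in the session.
#'
#' @param session a [neural_session()].
#' @param min_count minimum instances (5).
#' @return sorted integer vector of retained syllable ids.
#' @export
syllable_inventory <- function(session, min_count = 5) {
  tab <- table(session$instances$syllable)
  sort(as.integer(names(tab)[tab >= min_count]))
}

# per-instance, per-neuron activity change: mean during the instance minus
# mean over an equal-length window immediately before onset ("pre_onset"),
# or the raw mean during the instance ("none"). Instances without a full
# baseline window are dropped.
activity_changes <- function(session, which_instances = NULL,
                             baseline = c("pre_onset", "none")) {
  baseline <- match.arg(baseline)
  inst <- session$instances
  idx <- if (is.null(which_instances)) seq_len(nrow(inst)) else which_instances
  inst <- inst[idx, , drop = FALSE]
  act <- session$activity
  keep <- logical(nrow(inst))
  ch <- matrix(NA_real_, nrow(inst), ncol(act))
  for (i in seq_len(nrow(inst))) {
    on <- inst$onset[i]; en <- inst$end[i]
    len <- en - on + 1L
    during <- colMeans(act[on:en, , drop = FALSE])
    if (baseline == "pre_onset") {
      if (on - len < 1L) next
      before <- colMeans(act[(on - len):(on - 1L), , drop = FALSE])
      ch[i, ] <- during - before
    } else {
      ch[i, ] <- during
    }
    keep[i] <- TRUE
  }
  list(changes = ch[keep, , drop = FALSE], syllable = inst$syllable[keep],
       index = idx[keep])
}

#' Behavioral-syllable activity-mode regression
#'
#' Computes, for each syllable in the inventory, the population activity
#' mode that increases the most during that syllable: the per-instance,
#' per-neuron activity change is regressed on a one-hot vector of syllable
#' identity. For a one-hot design the least-squares coefficients are the
#' per-syllable means of the changes; this closed form is used (and is
#' verified against `lm.fit` in the test suite).
#'
#' @param session a [neural_session()] (typically z-scored).
#' @param which_instances optional row indices into `session$instances`
#'   restricting the fit (e.g. one split half).
#' @param inventory syllable ids to fit; default [syllable_inventory()].
#' @param baseline `"pre_onset"` (mean during instance minus mean over an
#'   equal-length pre-onset window) or `"none"` (raw mean during instance).
#' @return object of class `syllable_modes`: a syllables x neurons
#'   coefficient matrix (rownames = syllable ids), with the session pathway
#'   labels attached as attribute `pathway`.
#' @export
syllable_mode_regression <- function(session, which_instances = NULL,
                                     inventory = NULL,
                                     baseline = c("pre_onset", "none")) {
  baseline <- match.arg(baseline)
  if (is.null(inventory)) inventory <- syllable_inventory(session)
  ac <- activity_changes(session, which_instances, baseline)
  sel <- ac$syllable %in% inventory
  ch <- ac$changes[sel, , drop = FALSE]
  syl <- ac$syllable[sel]
  missing <- setdiff(inventory, unique(syl))
  if (length(missing))
    stop("rank-deficient design: no instances for syllable(s) ",
         paste(missing, collapse = ", "))
  f <- factor(syl, levels = inventory)
  modes <- rowsum(ch, f) / as.vector(table(f))
  rownames(modes) <- as.character(inventory)
  structure(modes, class = "syllable_modes", pathway = session$pathway)
}

#' Split-half mode correlation and shuffled null
#'
#' Fits syllable modes separately on the two onset-parity halves and
#' correlates the vectorized mode matrices per pathway. The null
#' distribution is obtained by shuffling the syllable labels across
#' instances and repeating the procedure.
#'
#' @param session a [neural_session()] (z-scored recommended).
#' @param n_shuffle number of label permutations for the null.
#' @param inventory syllable ids; default [syllable_inventory()].
#' @param baseline see [syllable_mode_regression()].
#' @return list with `real` (named correlations, dSPN/iSPN), `null`
#'   (n_shuffle x 2 matrix), and one-sided permutation `p_value` per pathway.
#' @export
split_half_mode_correlation <- function(session, n_shuffle = 100,
                                        inventory = NULL,
                                        baseline = "pre_onset") {
  if (is.null(inventory)) inventory <- syllable_inventory(session)
  half <- split_half_by_onset_parity(session)
  # activity changes are label-independent, so compute them once and only
  # re-group them under each label permutation
  ac <- activity_changes(session, NULL, baseline)
  halfk <- half[ac$index]
  d_idx <- session$pathway == "dSPN"
  corr_for <- function(lab) {
    out <- c(dSPN = NA_real_, iSPN = NA_real_)
    sel <- lab %in% inventory
    f <- factor(lab[sel], levels = inventory)
    h <- halfk[sel]
    if (any(table(f[h == 0]) == 0) || any(table(f[h == 1]) == 0))
      return(out)
    ch <- ac$changes[sel, , drop = FALSE]
    m0 <- rowsum(ch[h == 0, , drop = FALSE], f[h == 0]) /
      as.vector(table(f[h == 0]))
    m1 <- rowsum(ch[h == 1, , drop = FALSE], f[h == 1]) /
      as.vector(table(f[h == 1]))
    out["dSPN"] <- stats::cor(as.vector(m0[, d_idx]), as.vector(m1[, d_idx]))
    out["iSPN"] <- stats::cor(as.vector(m0[, !d_idx]), as.vector(m1[, !d_idx]))
    out
  }
  real <- corr_for(ac$syllable)
  null <- matrix(NA_real_, n_shuffle, 2,
                 dimnames = list(NULL, c("dSPN", "iSPN")))
  for (b in seq_len(n_shuffle))
    null[b, ] <- corr_for(sample(ac$syllable))
  p <- vapply(c("dSPN", "iSPN"), function(pw) {
    nn <- null[, pw]; nn <- nn[!is.na(nn)]
    (sum(nn >= real[[pw]]) + 1) / (length(nn) + 1)
  }, numeric(1))
  list(real = real, null = null, p_value = p)
}

#' Linearly time-warp a session by syllable boundaries
#'
#' Segments the timeline into syllable instances and the unlabeled gaps
#' between them, and linearly interpolates each segment onto exactly
#' `steps_per_syllable` steps, so every syllable occupies the same warped
#' duration. Endpoints are preserved; a one-frame segment becomes a constant
#' trace.
#'
#' @param session a [neural_session()].
#' @param steps_per_syllable warped steps per segment (10).
#' @return a warped `neural_session` whose `instances` refer to warped
#'   frames; extra instance columns (e.g. a half assignment) are carried
#'   through for instance segments.
#' @export
time_warp_syllables <- function(session, steps_per_syllable = 10) {
  inst <- session$instances
  act <- session$activity
  n <- nrow(act)
  # build ordered segment list: gaps and instances covering 1..n
  seg_start <- integer(0); seg_end <- integer(0); seg_inst <- integer(0)
  pos <- 1L
  for (i in seq_len(nrow(inst))) {
    if (inst$onset[i] > pos) {
      seg_start <- c(seg_start, pos); seg_end <- c(seg_end, inst$onset[i] - 1L)
      seg_inst <- c(seg_inst, NA_integer_)
    }
    seg_start <- c(seg_start, inst$onset[i]); seg_end <- c(seg_end, inst$end[i])
    seg_inst <- c(seg_inst, i)
    pos <- inst$end[i] + 1L
  }
  if (pos <= n) {
    seg_start <- c(seg_start, pos); seg_end <- c(seg_end, n)
    seg_inst <- c(seg_inst, NA_integer_)
  }
  k <- steps_per_syllable
  warped <- matrix(0, length(seg_start) * k, ncol(act))
  new_onset <- integer(nrow(inst)); new_end <- integer(nrow(inst))
  for (s in seq_along(seg_start)) {
    L <- seg_end[s] - seg_start[s] + 1L
    rows <- seg_start[s]:seg_end[s]
    tgt <- if (L == 1L) rep(1, k) else seq(1, L, length.out = k)
    lo <- floor(tgt); hi <- ceiling(tgt); w <- tgt - lo
    block <- (1 - w) * act[rows[lo], , drop = FALSE] +
             w * act[rows[hi], , drop = FALSE]
    out_rows <- ((s - 1L) * k + 1L):(s * k)
    warped[out_rows, ] <- block
    if (!is.na(seg_inst[s])) {
      new_onset[seg_inst[s]] <- out_rows[1]
      new_end[seg_inst[s]] <- out_rows[k]
    }
  }
  new_inst <- inst
  new_inst$onset <- new_onset
  new_inst$end <- new_end
  out <- session
  out$activity <- warped
  out$syllable <- rep(NA_integer_, nrow(warped))
  for (i in seq_len(nrow(new_inst)))
    out$syllable[new_inst$onset[i]:new_inst$end[i]] <- new_inst$syllable[i]
  out$instances <- new_inst
  out$steps_per_syllable <- k
  out
}

# mean projection trace around a set of onsets; rows outside the session are
# dropped per-onset
aligned_average <- function(proj_col, onsets, offsets) {
  acc <- numeric(length(offsets))
  cnt <- numeric(length(offsets))
  n <- length(proj_col)
  for (on in onsets) {
    rows <- on + offsets
    ok <- rows >= 1 & rows <= n
    acc[ok] <- acc[ok] + proj_col[rows[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

#' Onset-aligned, time-warped mode projections
#'
#' The cross-validated projection analysis: syllable modes are fit on one
#' onset-parity half of the data and the z-scored, time-warped activity is
#' projected onto them around syllable onsets of the other half — around the
#' onsets of the mode's own (associated) syllable and around all other
#' syllables' onsets — then averaged across syllables and across both split
#' directions. Modes are normalized to unit length per pathway before
#' projection, which together with z-scoring makes the traces invariant to
#' per-neuron rescaling of the raw data.
#'
#' @param session a [neural_session()] (raw; z-scoring is applied here).
#' @param steps_per_syllable warped steps per syllable (10).
#' @param window_syllables half-window width in units of warped syllables (2).
#' @param min_count inventory threshold (5).
#' @param baseline see [syllable_mode_regression()].
#' @return object of class `onset_aligned_traces`: list with `time` (warped
#'   steps relative to onset), matrices `associated` and `other` (time x
#'   {dSPN, iSPN, sum, difference}), and `sem_associated` / `sem_other`
#'   (SEM across syllables, same layout).
#' @export
onset_aligned_projection <- function(session, steps_per_syllable = 10,
                                     window_syllables = 2, min_count = 5,
                                     baseline = "pre_onset") {
  session <- if (session$zscored) session else zscore_neurons(session)
  inventory <- syllable_inventory(session, min_count)
  if (length(inventory) < 2)
    stop("need at least 2 retained syllables")
  half <- split_half_by_onset_parity(session)
  warped <- time_warp_syllables(session, steps_per_syllable)
  w <- window_syllables * steps_per_syllable
  offsets <- (-w):(w - 1L)
  pw <- session$pathway
  d_idx <- pw == "dSPN"; i_idx <- pw == "iSPN"

  # per-direction, per-syllable traces: syllables x time x {d, i}, assoc/other
  n_s <- length(inventory)
  acc_assoc <- array(0, c(n_s, length(offsets), 2))
  acc_other <- array(0, c(n_s, length(offsets), 2))
  n_dir <- 0L
  for (fit_half in 0:1) {
    modes <- syllable_mode_regression(session, which(half == fit_half),
                                      inventory, baseline)
    eval_inst <- which(half != fit_half)
    m_d <- modes[, d_idx, drop = FALSE]
    m_i <- modes[, i_idx, drop = FALSE]
    m_d <- m_d / sqrt(rowSums(m_d^2))
    m_i <- m_i / sqrt(rowSums(m_i^2))
    proj_d <- warped$activity[, d_idx, drop = FALSE] %*% t(m_d)
    proj_i <- warped$activity[, i_idx, drop = FALSE] %*% t(m_i)
    inst <- warped$instances[eval_inst, , drop = FALSE]
    for (s in seq_len(n_s)) {
      own <- inst$onset[inst$syllable == inventory[s]]
      oth <- inst$onset[inst$syllable != inventory[s] &
                        inst$syllable %in% inventory]
      acc_assoc[s, , 1] <- acc_assoc[s, , 1] + aligned_average(proj_d[, s], own, offsets)
      acc_assoc[s, , 2] <- acc_assoc[s, , 2] + aligned_average(proj_i[, s], own, offsets)
      acc_other[s, , 1] <- acc_other[s, , 1] + aligned_average(proj_d[, s], oth, offsets)
      acc_other[s, , 2] <- acc_other[s, , 2] + aligned_average(proj_i[, s], oth, offsets)
    }
    n_dir <- n_dir + 1L
  }
  acc_assoc <- acc_assoc / n_dir
  acc_other <- acc_other / n_dir

  summarize <- function(a) {
    m_d <- colMeans(a[, , 1], na.rm = TRUE)
    m_i <- colMeans(a[, , 2], na.rm = TRUE)
    s_d <- apply(a[, , 1], 2, stats::sd, na.rm = TRUE) / sqrt(n_s)
    s_i <- apply(a[, , 2], 2, stats::sd, na.rm = TRUE) / sqrt(n_s)
    list(mean = cbind(dSPN = m_d, iSPN = m_i,
                      sum = m_d + m_i, difference = m_d - m_i),
         sem = cbind(dSPN = s_d, iSPN = s_i,
                     sum = sqrt(s_d^2 + s_i^2),
                     difference = sqrt(s_d^2 + s_i^2)))
  }
  sa <- summarize(acc_assoc); so <- summarize(acc_other)
  structure(list(time = offsets, associated = sa$mean, other = so$mean,
                 sem_associated = sa$sem, sem_other = so$sem,
                 inventory = inventory,
                 steps_per_syllable = steps_per_syllable),
            class = "onset_aligned_traces")
}

#' Tuning selectivity index
#'
#' For a nonnegative tuning vector \eqn{t} over A syllables, the selectivity
#' is \eqn{(\frac1A\sum_i t_i)^2 / (\frac1A\sum_i t_i^2)}, which lies in
#' [0, 1]; 0/0 is defined as 0. The caller chooses the nonnegative tuning
#' measure (e.g. `abs(a)` or `pmax(a, 0)` of mean z-scored activity).
#'
#' @param t nonnegative tuning vector.
#' @return selectivity in [0, 1].
#' @export
selectivity_index <- function(t) {
  if (any(t < 0)) stop("tuning entries must be nonnegative")
  denom <- mean(t^2)
  if (denom == 0) return(0)
  mean(t)^2 / denom
}
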