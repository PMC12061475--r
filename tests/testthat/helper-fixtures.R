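# shared helpers for the test suite

# a tiny session with hand-placed instances for analysis tests
make_toy_session <- function(n_frames = 600, n_neurons = 4, seed = 1,
                             onsets = c(103, 79)) {
  set.seed(seed)
  act <- matrix(rnorm(n_frames * 2 * n_neurons), n_frames)
  onsets <- sort(onsets)
  inst <- data.frame(onset = onsets, end = onsets + 9L,
                     syllable = rep(1L, length(onsets)))
  syl <- rep(NA_integer_, n_frames)
  for (i in seq_len(nrow(inst))) syl[inst$onset[i]:inst$end[i]] <- 1L
  neural_session(act, rep(c("dSPN", "iSPN"), each = n_neurons), syl,
                 frame_rate = 30, instances = inst)
}

# mean of an onset-aligned trace over the pre-onset / post-onset window
window_mean <- function(oap, column, which = c("pre", "post"),
                        what = c("associated", "other")) {
  which <- match.arg(which)
  what <- match.arg(what)
  w <- oap$steps_per_syllable
  sel <- if (which == "pre") oap$time < 0 & oap$time >= -w
         else oap$time >= 0 & oap$time < w
  mean(oap[[what]][sel, column])
}

# dyadic-rational random values (exactly representable sums) for the
# efference-orthogonality exactness checks
rdyadic <- function(n, denom = 64, max_num = 128) {
  sample.int(max_num, n, replace = TRUE) / denom
}
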