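# Shared fixtures and independent oracles, built in code.

# single positive arch, near-zero (but not flat) ends
bump_template <- function(L = 100, amp = 2) {
  amp * sin(pi * seq_len(L) / (L + 1))
}

# arch with exactly-flat zero tails; concatenated copies join seamlessly
flat_bump_template <- function(L = 100, amp = 2, flat = 10) {
  c(rep(0, flat), amp * sin(pi * seq_len(L - 2 * flat) / (L - 2 * flat + 1)),
    rep(0, flat))
}

# brute-force DTW oracle: plain recursion over every monotone
# boundary-respecting path (no memoisation, independent of the DP core)
dtw_oracle <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# all sequences of the given length over an integer alphabet
all_sequences <- function(len, alphabet = 0:2) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
}

# recording with constant channels
constant_recording <- function(n, values = c(AccX = 0, AccY = 0, AccZ = 9.81,
                                             GyroX = 0, GyroY = 0, GyroZ = 0)) {
  imu_recording(lapply(as.list(values[imu_axes()]), rep, times = n))
}

# six-channel template set from one base waveform with per-axis amplitudes;
# large enough amplitudes that a zero signal exceeds every default threshold
toy_template_set <- function(L = 100,
                             amps = c(AccX = 3, AccY = 3, AccZ = 3,
                                      GyroX = 5, GyroY = 5, GyroZ = 5),
                             flat = TRUE) {
  axes <- lapply(as.list(amps[imu_axes()]), function(a) {
    if (flat) flat_bump_template(L, a) else bump_template(L, a)
  })
  structure(list(activities = list(
    walking = list(reference_length = L, axes = axes))),
    class = "template_set")
}

# recording whose channels are k concatenated copies of a template set's
# walking axes
copies_recording <- function(ts, k) {
  axes <- ts$activities$walking$axes
  imu_recording(lapply(axes, function(x) rep(x, k)))
}

walking_only_axes <- function() {
  axis_config(list(walking = list(
    used = c("AccX", "AccZ", "GyroX", "GyroY", "GyroZ"),
    weights = c(AccZ = 2))))
}

# small, fast simulation schedule used across tests
short_schedule <- function() {
  data.frame(activity = c("standing", "walking", "sitting"),
             duration_s = c(5, 30, 5))
}
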