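# Shared fixtures and independent oracles used across the suite.

# Quick contribution from onset times; constant or per-note durations.
make_contribution <- function(onsets, dur = 0.1, song_id = "s1",
                              individual_id = "A", sex = "male",
                              song_type = "male_solo", group_id = "g1",
                              context = "wild") {
  dur <- rep_len(dur, length(onsets))
  contribution(song_id = song_id, individual_id = individual_id,
               group_id = group_id, sex = sex, song_type = song_type,
               context = context,
               notes = note_intervals(onsets, onsets + dur, "note"))
}

# Independent Granger oracle: explicitly solved normal equations for the
# restricted and full lag regressions, nothing shared with the package path.
bf_granger <- function(src, tgt, L) {
  n <- length(tgt)
  idx <- (L + 1):n
  y <- tgt[idx]
  lags <- function(x) sapply(1:L, function(j) x[idx - j])
  Xr <- cbind(1, lags(tgt))
  Xf <- cbind(Xr, lags(src))
  beta_r <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  beta_f <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  rss_r <- sum((y - Xr %*% beta_r)^2)
  rss_f <- sum((y - Xf %*% beta_f)^2)
  df_den <- (n - L) - 2 * L - 1
  f <- ((rss_r - rss_f) / L) / (rss_f / df_den)
  list(f = f, p = pf(f, L, df_den, lower.tail = FALSE), df_den = df_den)
}

# Discretized intersection oracle: indicator product on a regular grid of
# bin midpoints.
grid_overlap <- function(a, b, step = 0.001) {
  a <- phonation_set(a); b <- phonation_set(b)
  hi <- max(a$intervals$offset, b$intervals$offset)
  mids <- seq(step / 2, hi, by = step)
  inside <- function(ps, t) {
    iv <- ps$intervals
    out <- logical(length(t))
    for (i in seq_len(nrow(iv))) out <- out | (t > iv$onset[i] & t < iv$offset[i])
    out
  }
  sum(inside(a, mids) & inside(b, mids)) * step
}

# Random disjoint interval set on [0, span] for oracle comparisons.
random_interval_set <- function(n, span = 20) {
  bounds <- sort(runif(2 * n, 0, span))
  data.frame(onset = bounds[seq(1, 2 * n, by = 2)],
             offset = bounds[seq(2, 2 * n, by = 2)])
}

quiet_iois <- function(...) suppressWarnings(extract_iois(...))
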