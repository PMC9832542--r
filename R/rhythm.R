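#' Extract inter-onset intervals from a contribution
#'
#' The inter-onset interval (IOI) `t_k` is the time from one note onset to
#' the next. Intervals above the ceiling `max_ioi` — the conventional upper
#' limit for meter perception, 5 s by default — are masked out: they are
#' retained in the sequence with `kept = FALSE` but never bridged, so no
#' downstream ratio spans them.
#'
#' @param x A `"contribution"`, or a numeric vector of onset times.
#' @param max_ioi Ceiling in seconds above which an interval is excluded.
#' @return An object of class `"ioi_seq"`: list with `values` (all t_k, one
#'   per successive onset pair), `kept` (logical mask), `max_ioi`, `source`.
#' @export
extract_iois <- function(x, max_ioi = 5.0) {
  if (inherits(x, "contribution")) {
    onsets <- x$notes$onset
    src <- paste(x$song_id, x$individual_id, sep = "/")
  } else {
    onsets <- as.numeric(x)
    src <- NA_character_
  }
  if (length(onsets) < 2) {
    warning("fewer than 2 notes: empty IOI sequence", call. = FALSE)
    return(structure(list(values = numeric(0), kept = logical(0),
                          max_ioi = max_ioi, source = src),
                     class = "ioi_seq"))
  }
  t_k <- diff(onsets)
  if (any(t_k <= 0)) stop("onsets must be strictly increasing", call. = FALSE)
  structure(list(values = t_k, kept = t_k <= max_ioi, max_ioi = max_ioi,
                 source = src),
            class = "ioi_seq")
}

#' @export
print.ioi_seq <- function(x, ...) {
  cat(sprintf("<ioi_seq> %d intervals (%d kept <= %.3g s)%s\n",
              length(x$values), sum(x$kept), x$max_ioi,
              if (is.na(x$source)) "" else paste0(" from ", x$source)))
  invisible(x)
}

#' Compute rhythm ratios from an IOI sequence
#'
#' The rhythm ratio `r_k = t_k / (t_k + t_{k+1})` compares each interval to
#' its successor: 0.5 marks isochrony (1:1), values near 1/3 or 2/3 mark
#' 1:2 and 2:1 rhythms. Ratios are formed only for interval pairs that are
#' adjacent in the original note sequence and both below the ceiling; a
#' masked gap breaks adjacency, so no ratio mixes non-contiguous rhythm.
#'
#' @param iois An `"ioi_seq"` from [extract_iois()], or a numeric vector of
#'   intervals (all treated as kept).
#' @return An object of class `"ratio_seq"`: list with `values` (each in
#'   (0, 1)) and `pair_index` (index k of the `(t_k, t_{k+1})` pair).
#' @export
compute_ratios <- function(iois) {
  if (!inherits(iois, "ioi_seq")) {
    iois <- structure(list(values = as.numeric(iois),
                           kept = rep(TRUE, length(iois))),
                      class = "ioi_seq")
  }
  v <- iois$values
  k <- iois$kept
  n <- length(v)
  if (n < 2) {
    return(structure(list(values = numeric(0), pair_index = integer(0)),
                     class = "ratio_seq"))
  }
  idx <- which(k[-n] & k[-1])
  structure(list(values = v[idx] / (v[idx] + v[idx + 1L]), pair_index = idx),
            class = "ratio_seq")
}

#' @export
print.ratio_seq <- function(x, ...) {
  cat(sprintf("<ratio_seq> %d ratios", length(x$values)))
  if (length(x$values)) {
    cat(sprintf(", median %.3f", median(x$values)))
  }
  cat("\n")
  invisible(x)
}

#' On/off-isochrony band boundaries
#'
#' Four `r_k` values delimiting the on-isochrony band (centred on the 1:1
#' ratio `r_k = 0.5`) and the flanking off-isochrony bands. Defaults are the
#' standard 0.400 / 0.440 / 0.555 / 0.600 cut points; note they are not
#' symmetric about 0.5 and are used verbatim.
#'
#' @param outer_low,inner_low,inner_high,outer_high Band edges, increasing,
#'   straddling 0.5.
#' @return An object of class `"isochrony_boundaries"`.
#' @export
isochrony_boundaries <- function(outer_low = 0.400, inner_low = 0.440,
                                 inner_high = 0.555, outer_high = 0.600) {
  if (!(outer_low < inner_low && inner_low < 0.5 && 0.5 < inner_high &&
        inner_high < outer_high)) {
    stop("boundaries must satisfy outer_low < inner_low < 0.5 < ",
         "inner_high < outer_high", call. = FALSE)
  }
  structure(list(outer_low = outer_low, inner_low = inner_low,
                 inner_high = inner_high, outer_high = outer_high),
            class = "isochrony_boundaries")
}

#' Tally ratios into on- and off-isochrony bands
#'
#' On-isochrony: `r` in the closed band `[inner_low, inner_high]`.
#' Off-isochrony: `r` in `[outer_low, inner_low)` or `(inner_high,
#' outer_high]`, so every ratio inside `[outer_low, outer_high]` is counted
#' exactly once. Ratios outside the outer band belong to neither class and
#' appear only in `total_ratios`.
#'
#' @param ratios A `"ratio_seq"` or numeric vector of ratios.
#' @param boundaries An [isochrony_boundaries()] object.
#' @param window Optional window identifier carried through to the result.
#' @return An object of class `"isochrony_counts"`: `on_count`, `off_count`,
#'   `total_ratios`, `window`.
#' @export
classify_ratios <- function(ratios, boundaries = isochrony_boundaries(),
                            window = NA) {
  r <- if (inherits(ratios, "ratio_seq")) ratios$values else as.numeric(ratios)
  b <- boundaries
  on <- r >= b$inner_low & r <= b$inner_high
  off <- (r >= b$outer_low & r < b$inner_low) |
    (r > b$inner_high & r <= b$outer_high)
  structure(list(on_count = sum(on), off_count = sum(off),
                 total_ratios = length(r), window = window),
            class = "isochrony_counts")
}

#' @export
print.isochrony_counts <- function(x, ...) {
  cat(sprintf("<isochrony_counts> on %d / off %d (of %d ratios)\n",
              x$on_count, x$off_count, x$total_ratios))
  invisible(x)
}

#' Isochrony rate
#'
#' The ratio of on- to off-isochrony tallies, the per-contribution (or
#' per-chunk) isochrony statistic. With no off-band observations the rate
#' is undefined — the statistic is used log-transformed downstream, so no
#' pseudo-count is invented — and the `defined` flag is `FALSE`.
#'
#' @param counts An `"isochrony_counts"` object.
#' @return An object of class `"isochrony_rate"`: `value` (NA when
#'   undefined), `defined`, plus the input counts.
#' @export
isochrony_rate <- function(counts) {
  stopifnot(inherits(counts, "isochrony_counts"))
  defined <- counts$off_count > 0
  structure(list(value = if (defined) counts$on_count / counts$off_count
                 else NA_real_,
                 defined = defined,
                 on_count = counts$on_count, off_count = counts$off_count,
                 window = counts$window),
            class = "isochrony_rate")
}

#' @export
print.isochrony_rate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<isochrony_rate> %.4g (on %d / off %d)\n", x$value,
                x$on_count, x$off_count))
  } else {
    cat(sprintf("<isochrony_rate> undefined (on %d, off 0)\n", x$on_count))
  }
  invisible(x)
}

#' Call rate per fixed-length chunk
#'
#' Counts note onsets in consecutive non-overlapping windows of `window_s`
#' seconds anchored at the first onset; the rate is `count / window_s` in
#' Hz. The final partial window (relative to the last note offset) is
#' discarded so short remainders do not bias rates downward.
#'
#' @param contribution A `"contribution"` with at least one note.
#' @param window_s Window length in seconds (default 10 s).
#' @return An object of class `"call_rate_series"`: data frame `chunks` with
#'   columns `chunk`, `start`, `end`, `count`, `rate`, plus `window_s` and
#'   the contribution identifiers.
#' @export
call_rate <- function(contribution, window_s = 10.0) {
  stopifnot(inherits(contribution, "contribution"), window_s > 0)
  on <- contribution$notes$onset
  if (!length(on)) stop("contribution has no notes", call. = FALSE)
  t0 <- on[1]
  span <- max(contribution$notes$offset) - t0
  n_win <- floor(span / window_s)
  if (n_win < 1) {
    warning("contribution shorter than one window: empty call-rate series",
            call. = FALSE)
    chunks <- data.frame(chunk = integer(0), start = numeric(0),
                         end = numeric(0), count = integer(0),
                         rate = numeric(0))
  } else {
    starts <- t0 + (seq_len(n_win) - 1) * window_s
    counts <- vapply(starts, function(s) sum(on >= s & on < s + window_s), 0L)
    chunks <- data.frame(chunk = seq_len(n_win), start = starts,
                         end = starts + window_s, count = counts,
                         rate = counts / window_s)
  }
  structure(list(chunks = chunks, window_s = window_s,
                 song_id = contribution$song_id,
                 individual_id = contribution$individual_id,
                 song_type = contribution$song_type),
            class = "call_rate_series")
}

#' @export
print.call_rate_series <- function(x, ...) {
  cat(sprintf("<call_rate_series> %s/%s: %d windows of %.3g s",
              x$song_id, x$individual_id, nrow(x$chunks), x$window_s))
  if (nrow(x$chunks)) cat(sprintf(", mean rate %.3f Hz", mean(x$chunks$rate)))
  cat("\n")
  invisible(x)
}

#' Split chunk call rates at the song-type median
#'
#' Labels each chunk `"high"` when its rate exceeds the median rate of its
#' song type and `"low"` otherwise; chunks exactly at the median are
#' assigned `"low"` (ties go low). Labels do not depend on row order.
#'
#' @param rates A `data.frame` with columns `rate` and `song_type` (e.g. the
#'   row-bound `chunks` tables of several [call_rate()] results), or a list
#'   of `"call_rate_series"` objects.
#' @return The input table with added columns `song_type_median` and
#'   `high_low`.
#' @export
median_split <- function(rates) {
  if (is.list(rates) && !is.data.frame(rates) &&
      all(vapply(rates, inherits, TRUE, "call_rate_series"))) {
    rates <- do.call(rbind, lapply(rates, function(s) {
      if (!nrow(s$chunks)) return(NULL)
      cbind(s$chunks,
            data.frame(song_id = s$song_id, individual_id = s$individual_id,
                       song_type = s$song_type, stringsAsFactors = FALSE))
    }))
  }
  stopifnot(is.data.frame(rates), all(c("rate", "song_type") %in% names(rates)))
  med <- tapply(rates$rate, rates$song_type, median)
  rates$song_type_median <- as.numeric(med[rates$song_type])
  rates$high_low <- ifelse(rates$rate > rates$song_type_median, "high", "low")
  rates
}

#' Tempo peaks from the IOI density
#'
#' Gaussian kernel density estimate of pooled `t_k` values on (0, max_ioi],
#' evaluated on a regular grid; peaks are local maxima whose density exceeds
#' a prominence fraction of the global maximum. The tempo of a peak is the
#' inverse of its IOI (`tempo * peak_ioi = 1` exactly).
#'
#' @param iois Numeric vector of pooled IOIs (seconds), or an `"ioi_seq"`
#'   (kept values are used).
#' @param bandwidth KDE bandwidth: `"silverman"` (the default rule-of-thumb,
#'   `stats::bw.nrd0`) or a positive number in seconds.
#' @param grid_step Density evaluation grid step in seconds (default 1 ms).
#' @param prominence Minimum peak height as a fraction of the global density
#'   maximum (default 0.05).
#' @param max_ioi Upper edge of the evaluation grid.
#' @return An object of class `"tempo_peaks"`: data frame `peaks` with
#'   columns `peak_ioi`, `tempo`, `density`, sorted by `peak_ioi`, plus the
#'   bandwidth used and the full density grid.
#' @export
density_peaks <- function(iois, bandwidth = "silverman", grid_step = 0.001,
                          prominence = 0.05, max_ioi = 5.0) {
  x <- if (inherits(iois, "ioi_seq")) iois$values[iois$kept] else
    as.numeric(iois)
  x <- x[is.finite(x) & x > 0 & x <= max_ioi]
  if (!length(x)) stop("no IOI values in (0, max_ioi]", call. = FALSE)
  if (length(x) < 30) {
    warning("fewer than 30 IOIs: density peaks may be unstable",
            call. = FALSE)
  }
  bw <- if (identical(bandwidth, "silverman")) {
    if (sd(x) == 0) grid_step else stats::bw.nrd0(x)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  n_grid <- max(2L, round(max_ioi / grid_step) + 1L)
  d <- density(x, bw = bw, from = 0, to = max_ioi, n = n_grid)
  y <- d$y
  m <- length(y)
  is_peak <- c(FALSE, y[2:(m - 1)] > y[1:(m - 2)] &
                 y[2:(m - 1)] >= y[3:m], FALSE)
  is_peak <- is_peak & y >= prominence * max(y) & d$x > 0
  peaks <- data.frame(peak_ioi = d$x[is_peak], tempo = 1 / d$x[is_peak],
                      density = y[is_peak])
  peaks <- peaks[order(peaks$peak_ioi), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, bandwidth = bw, grid_step = grid_step,
                 density = d, n = length(x)),
            class = "tempo_peaks")
}

#' @export
print.tempo_peaks <- function(x, ...) {
  cat(sprintf("<tempo_peaks> %d peak(s) from %d IOIs (bw %.4g s)\n",
              nrow(x$peaks), x$n, x$bandwidth))
  if (nrow(x$peaks)) {
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("  t_k = %.3f s  ->  %.3f Hz\n",
                  x$peaks$peak_ioi[i], x$peaks$tempo[i]))
    }
  }
  invisible(x)
}

#' @export
plot.tempo_peaks <- function(x, ...) {
  plot(x$density, main = "IOI density", xlab = "t_k (s)", ...)
  graphics::abline(v = x$peaks$peak_ioi, lty = 2, col = "grey40")
  invisible(x)
}
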