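#' Binarize a contribution into a phonation indicator series
#'
#' Bins time from `t0` to `t1` into `bin_s`-wide bins (10 ms by default);
#' a bin is 1 when the individual phonates during any part of it — any
#' positive intersection between the bin and a note interval — and 0
#' otherwise.
#'
#' @param contribution A `"contribution"`.
#' @param bin_s Bin width in seconds.
#' @param t0,t1 Series start and end; default to the contribution's first
#'   onset and last offset.
#' @return An object of class `"binary_series"`: `values` (integer 0/1),
#'   `bin_s`, `t0`.
#' @export
binarize <- function(contribution, bin_s = 0.010, t0 = NULL, t1 = NULL) {
  stopifnot(inherits(contribution, "contribution"), bin_s > 0)
  nt <- contribution$notes
  if (is.null(t0)) t0 <- if (nrow(nt)) nt$onset[1] else 0
  if (is.null(t1)) t1 <- if (nrow(nt)) max(nt$offset) else t0 + bin_s
  if (t0 >= t1) stop("t0 must be earlier than t1", call. = FALSE)
  n_bins <- as.integer(ceiling((t1 - t0) / bin_s - 1e-9))
  v <- integer(n_bins)
  eps <- 1e-9
  for (i in seq_len(nrow(nt))) {
    ## bins with strictly positive overlap with (onset, offset)
    lo <- floor((nt$onset[i] - t0) / bin_s + eps)
    hi <- ceiling((nt$offset[i] - t0) / bin_s - eps) - 1
    lo <- max(0, lo); hi <- min(n_bins - 1, hi)
    if (hi >= lo) v[(lo + 1):(hi + 1)] <- 1L
  }
  structure(list(values = v, bin_s = bin_s, t0 = t0),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("<binary_series> %d bins of %.3g s from t0 = %.3f (%.1f%% on)\n",
              length(x$values), x$bin_s, x$t0, 100 * mean(x$values)))
  invisible(x)
}

#' Binarize two co-singers on a shared time base
#'
#' Both series share `t0 = ` the earlier first onset and `t1 = ` the later
#' last offset, so they have identical length and bin alignment.
#'
#' @param a,b `"contribution"` objects from the same song.
#' @param bin_s Bin width in seconds.
#' @return A list of two `"binary_series"` of equal length.
#' @export
align_pair <- function(a, b, bin_s = 0.010) {
  stopifnot(inherits(a, "contribution"), inherits(b, "contribution"))
  if (!identical(a$song_id, b$song_id)) {
    stop("contributions belong to different songs ('", a$song_id, "' vs '",
         b$song_id, "')", call. = FALSE)
  }
  if (!nrow(a$notes) || !nrow(b$notes)) {
    stop("both contributions need at least one note", call. = FALSE)
  }
  t0 <- min(a$notes$onset[1], b$notes$onset[1])
  t1 <- max(max(a$notes$offset), max(b$notes$offset))
  list(binarize(a, bin_s, t0, t1), binarize(b, bin_s, t0, t1))
}

#' Granger test configuration
#'
#' @param lag_order Number of lags in the autoregressions (default 5 bins,
#'   i.e. 50 ms of history at the 10-ms bin width).
#' @param alpha Significance threshold for the census (default 0.001).
#' @param max_len Optional truncation: analyse only the first `max_len` bins
#'   of each series.
#' @return An object of class `"granger_spec"`.
#' @export
granger_spec <- function(lag_order = 5L, alpha = 0.001, max_len = NULL) {
  lag_order <- as.integer(lag_order)
  stopifnot(lag_order >= 1, alpha > 0, alpha < 1,
            is.null(max_len) || max_len > 2 * lag_order + 1)
  structure(list(lag_order = lag_order, alpha = alpha, max_len = max_len),
            class = "granger_spec")
}

rss_ols <- function(X, y) {
  fit <- qr(X)
  if (fit$rank < ncol(X)) return(NULL)            # collinear design
  res <- qr.resid(fit, y)
  sum(res^2)
}

#' Directional Granger causality test
#'
#' Tests whether the past of `source` improves least-squares prediction of
#' `target` beyond `target`'s own past: the restricted model regresses the
#' target on its own `lag_order` lags (plus intercept), the full model adds
#' `lag_order` lags of the source, and the improvement is assessed with the
#' nested-model F statistic
#' `F = ((RSS_r - RSS_f) / L) / (RSS_f / (n_used - 2L - 1))`.
#' The 0/1 series are analysed with ordinary least squares, the standard
#' Granger construction.
#'
#' Degenerate designs (constant target, collinear lags) yield a flagged
#' result with `p_value = NA` rather than an error, so census runs never
#' abort on a pathological song.
#'
#' @param source,target Equal-length `"binary_series"` (or numeric vectors).
#' @param spec A [granger_spec()].
#' @param direction Label carried into the result (e.g. `"F_to_M"`).
#' @return An object of class `"granger_result"` with `f_stat`, `p_value`,
#'   `df_num`, `df_den`, `n_used`, `flag`.
#' @export
granger_direction <- function(source, target, spec = granger_spec(),
                              direction = NA_character_) {
  s <- if (inherits(source, "binary_series")) source$values else
    as.numeric(source)
  y <- if (inherits(target, "binary_series")) target$values else
    as.numeric(target)
  if (length(s) != length(y)) {
    stop("source and target series must have equal length", call. = FALSE)
  }
  if (!is.null(spec$max_len) && length(y) > spec$max_len) {
    s <- s[seq_len(spec$max_len)]
    y <- y[seq_len(spec$max_len)]
  }
  L <- spec$lag_order
  n <- length(y)
  n_used <- n - L
  df_den <- n_used - 2L * L - 1L
  res <- structure(
    list(direction = direction, f_stat = NA_real_, p_value = NA_real_,
         df_num = L, df_den = df_den, n_used = n_used, lag_order = L,
         flag = NA_character_),
    class = "granger_result")
  if (df_den < 1) {
    res$flag <- "too_short"
    return(res)
  }
  ## lag matrices: column j of embed(x, L + 1)[, -1] is x lagged by j
  Ey <- stats::embed(y, L + 1L)
  Es <- stats::embed(s, L + 1L)
  yy <- Ey[, 1L]
  Xr <- cbind(1, Ey[, -1L, drop = FALSE])
  Xf <- cbind(Xr, Es[, -1L, drop = FALSE])
  rss_f <- rss_ols(Xf, yy)
  rss_r <- rss_ols(Xr, yy)
  if (is.null(rss_f) || is.null(rss_r) || rss_f <= 0) {
    res$flag <- "degenerate"
    return(res)
  }
  res$f_stat <- ((rss_r - rss_f) / L) / (rss_f / df_den)
  res$p_value <- pf(res$f_stat, L, df_den, lower.tail = FALSE)
  res
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> %s: F(%d, %d) = %.4g, p = %.3g%s\n",
              if (is.na(x$direction)) "?" else x$direction,
              x$df_num, x$df_den, x$f_stat, x$p_value,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Classify a duet's causality pattern
#'
#' `reciprocal` when both directions are significant at `alpha`, `one_way`
#' when exactly one is, `none` otherwise. A flagged direction (undefined p)
#' counts as non-significant.
#'
#' @param f_to_m,m_to_f `"granger_result"` objects for the two directions.
#' @param alpha Significance threshold.
#' @param song_id Optional identifier.
#' @return An object of class `"song_causality"`.
#' @export
classify_song <- function(f_to_m, m_to_f, alpha = 0.001, song_id = NA) {
  sig <- function(r) !is.na(r$p_value) && r$p_value < alpha
  n_sig <- sig(f_to_m) + sig(m_to_f)
  cls <- c("none", "one_way", "reciprocal")[n_sig + 1L]
  structure(list(song_id = song_id, class = cls,
                 f_to_m = f_to_m, m_to_f = m_to_f, alpha = alpha,
                 flagged = c(f_to_m = !is.na(f_to_m$flag),
                             m_to_f = !is.na(m_to_f$flag))),
            class = "song_causality")
}

#' Granger-causality census over a duet collection
#'
#' Runs the bidirectional test on every duet, classifies each song, and
#' aggregates: the proportion of individual contributions that
#' Granger-cause their partner's phonation (per direction), and the
#' proportions of songs classed reciprocal / one-way / none. By default
#' only wild-recorded songs enter the census (captive recordings carry
#' external disturbances); set `wild_only = FALSE` to lift the restriction.
#'
#' @param songs List of `"song_record"` objects (solos are skipped).
#' @param spec A [granger_spec()].
#' @param bin_s Bin width for [align_pair()].
#' @param wild_only Restrict to `context == "wild"` duets.
#' @return An object of class `"causality_census"`: per-song `table`
#'   (song_id, direction, F, p, df, n_used, flag), per-song `classes`,
#'   `prop_significant` per direction, `prop_class` over
#'   reciprocal/one_way/none, `n_songs`.
#' @export
causality_census <- function(songs, spec = granger_spec(), bin_s = 0.010,
                             wild_only = TRUE) {
  duets <- Filter(is_duet, songs)
  if (wild_only) {
    duets <- Filter(function(s) s$contributions[[1]]$context == "wild", duets)
  }
  if (!length(duets)) stop("no duet songs to analyse", call. = FALSE)
  rows <- list()
  classes <- character(length(duets))
  ids <- character(length(duets))
  for (i in seq_along(duets)) {
    song <- duets[[i]]
    f <- duet_female(song); m <- duet_male(song)
    pair <- align_pair(f, m, bin_s)
    f_to_m <- granger_direction(pair[[1]], pair[[2]], spec, "F_to_M")
    m_to_f <- granger_direction(pair[[2]], pair[[1]], spec, "M_to_F")
    cls <- classify_song(f_to_m, m_to_f, spec$alpha, song$song_id)
    classes[i] <- cls$class
    ids[i] <- song$song_id
    for (r in list(f_to_m, m_to_f)) {
      rows[[length(rows) + 1L]] <- data.frame(
        song_id = song$song_id, direction = r$direction, f_stat = r$f_stat,
        p_value = r$p_value, df_num = r$df_num, df_den = r$df_den,
        n_used = r$n_used, flag = if (is.na(r$flag)) "" else r$flag,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sig <- !is.na(tab$p_value) & tab$p_value < spec$alpha
  prop_sig <- c(
    F_to_M = mean(sig[tab$direction == "F_to_M"]),
    M_to_F = mean(sig[tab$direction == "M_to_F"]),
    overall = mean(sig))
  prop_class <- vapply(c(reciprocal = "reciprocal", one_way = "one_way",
                         none = "none"),
                       function(k) mean(classes == k), 0)
  structure(list(table = tab,
                 classes = data.frame(song_id = ids, class = classes,
                                      stringsAsFactors = FALSE),
                 prop_significant = prop_sig, prop_class = prop_class,
                 n_songs = length(duets), spec = spec),
            class = "causality_census")
}

#' @export
print.causality_census <- function(x, ...) {
  cat(sprintf("<causality_census> %d duet songs, alpha = %g\n",
              x$n_songs, x$spec$alpha))
  cat(sprintf("  significant contributions: F->M %.1f%%, M->F %.1f%%, overall %.1f%%\n",
              100 * x$prop_significant[["F_to_M"]],
              100 * x$prop_significant[["M_to_F"]],
              100 * x$prop_significant[["overall"]]))
  cat(sprintf("  songs: reciprocal %.1f%%, one-way %.1f%%, none %.1f%%\n",
              100 * x$prop_class[["reciprocal"]],
              100 * x$prop_class[["one_way"]],
              100 * x$prop_class[["none"]]))
  invisible(x)
}
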