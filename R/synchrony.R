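#' Construct a phonation set
#'
#' The union of an individual's note intervals: sorted, pairwise-disjoint
#' (touching or overlapping input intervals are merged) time intervals with
#' their summed duration.
#'
#' @param x A `"contribution"`, or a two-column matrix / data.frame of
#'   (onset, offset) pairs.
#' @return An object of class `"phonation_set"`: `intervals` (data frame
#'   with `onset`, `offset`), `total_phonation`.
#' @export
phonation_set <- function(x) {
  if (inherits(x, "phonation_set")) return(x)
  iv <- if (inherits(x, "contribution")) {
    x$notes[, c("onset", "offset"), drop = FALSE]
  } else {
    x <- as.data.frame(x)
    stopifnot(ncol(x) >= 2)
    data.frame(onset = as.numeric(x[[1]]), offset = as.numeric(x[[2]]))
  }
  if (nrow(iv)) {
    stopifnot(all(iv$offset > iv$onset))
    iv <- iv[order(iv$onset), , drop = FALSE]
    ## merge any touching/overlapping intervals into a disjoint union
    keep_on <- iv$onset[1]; merged_on <- c(); merged_off <- c()
    cur_off <- iv$offset[1]
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        if (iv$onset[i] > cur_off) {
          merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
          keep_on <- iv$onset[i]; cur_off <- iv$offset[i]
        } else {
          cur_off <- max(cur_off, iv$offset[i])
        }
      }
    }
    merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
    iv <- data.frame(onset = merged_on, offset = merged_off)
  }
  rownames(iv) <- NULL
  structure(list(intervals = iv,
                 total_phonation = sum(iv$offset - iv$onset)),
            class = "phonation_set")
}

#' @export
print.phonation_set <- function(x, ...) {
  cat(sprintf("<phonation_set> %d intervals, total phonation %.3f s\n",
              nrow(x$intervals), x$total_phonation))
  invisible(x)
}

#' Total intersection of two phonation sets
#'
#' Exact summed duration of all pairwise interval intersections, by a
#' linear sweep over the merged sorted endpoints of the two (already
#' disjoint) sets.
#'
#' @param a,b `"phonation_set"` objects (or inputs accepted by
#'   [phonation_set()]).
#' @return Intersection duration in seconds.
#' @export
intersection_duration <- function(a, b) {
  a <- phonation_set(a); b <- phonation_set(b)
  ia <- a$intervals; ib <- b$intervals
  i <- 1L; j <- 1L; tot <- 0
  while (i <= nrow(ia) && j <= nrow(ib)) {
    lo <- max(ia$onset[i], ib$onset[j])
    hi <- min(ia$offset[i], ib$offset[j])
    if (hi > lo) tot <- tot + (hi - lo)
    if (ia$offset[i] < ib$offset[j]) i <- i + 1L else j <- j + 1L
  }
  tot
}

#' Overlap (synchrony) metrics for a co-singing pair
#'
#' From one intersection pass: the raw overlap duration; the per-singer
#' overlap rate (overlap / that singer's total phonation, in `[0, 1]`); and
#' the *normalized overlap*, overlap divided by the summed phonation of
#' both singers, which ranges from 0 (no overlap) to 0.5 (identical
#' phonation sets).
#'
#' @param female,male `"phonation_set"` objects (or inputs accepted by
#'   [phonation_set()]).
#' @return An object of class `"overlap_result"`: `overlap_s`,
#'   `rate_female`, `rate_male` (NA and flagged for a zero-phonation
#'   singer), `normalized_overlap`, `phonation_female`, `phonation_male`.
#' @export
overlap_metrics <- function(female, male) {
  f <- phonation_set(female); m <- phonation_set(male)
  if (f$total_phonation == 0 && m$total_phonation == 0) {
    stop("both singers have zero phonation", call. = FALSE)
  }
  ov <- intersection_duration(f, m)
  flag <- character(0)
  rate_f <- if (f$total_phonation > 0) ov / f$total_phonation else {
    flag <- c(flag, "female_zero_phonation"); NA_real_
  }
  rate_m <- if (m$total_phonation > 0) ov / m$total_phonation else {
    flag <- c(flag, "male_zero_phonation"); NA_real_
  }
  structure(list(overlap_s = ov, rate_female = rate_f, rate_male = rate_m,
                 normalized_overlap = ov / (f$total_phonation +
                                              m$total_phonation),
                 phonation_female = f$total_phonation,
                 phonation_male = m$total_phonation, flag = flag),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("<overlap_result> overlap %.3f s | rate F %.3f, ",
                     "rate M %.3f | normalized %.4f\n"),
              x$overlap_s, x$rate_female, x$rate_male, x$normalized_overlap))
  invisible(x)
}

#' Chunking configuration
#'
#' @param chunk_s Chunk length in seconds (default 180 s, i.e. 3 min).
#' @param min_keep_s Minimum length of the final partial chunk to keep
#'   (default 30 s); at `min_keep_s = 0` chunking conserves total phonation
#'   exactly.
#' @return An object of class `"chunk_spec"`.
#' @export
chunk_spec <- function(chunk_s = 180, min_keep_s = 30) {
  stopifnot(chunk_s > 0, min_keep_s >= 0)
  structure(list(chunk_s = chunk_s, min_keep_s = min_keep_s),
            class = "chunk_spec")
}

#' Cut a contribution into fixed-length chunks
#'
#' Song time is partitioned into consecutive `chunk_s` windows from the
#' song start (`t0`, default 0); notes are clipped at chunk borders and
#' each chunk is re-based to its own zero. The final partial chunk is kept
#' only when at least `min_keep_s` long.
#'
#' @param contribution A `"contribution"`.
#' @param spec A [chunk_spec()].
#' @param t0 Song start time defining the chunk grid.
#' @param song_end Song end time; defaults to the last note offset.
#' @return A list of chunk entries, each a list with `chunk` (1-based
#'   index), `start`, `end` (song time), `span` (chunk length), and
#'   `phonation` (a chunk-relative `"phonation_set"`).
#' @export
chunk_contribution <- function(contribution, spec = chunk_spec(), t0 = 0,
                               song_end = NULL) {
  stopifnot(inherits(contribution, "contribution"))
  nt <- contribution$notes
  if (is.null(song_end)) {
    song_end <- if (nrow(nt)) max(nt$offset) else t0
  }
  out <- list()
  k <- 0L
  start <- t0
  while (start < song_end) {
    end <- min(start + spec$chunk_s, song_end)
    span <- end - start
    k <- k + 1L
    if (span + 1e-12 < spec$chunk_s && span < spec$min_keep_s) break
    on <- pmax(nt$onset, start)
    off <- pmin(nt$offset, end)
    sel <- off > on
    ph <- phonation_set(data.frame(onset = on[sel] - start,
                                   offset = off[sel] - start))
    out[[length(out) + 1L]] <- list(chunk = k, start = start, end = end,
                                    span = span, phonation = ph)
    start <- start + spec$chunk_s
  }
  out
}

#' Build the chunk table for a set of songs
#'
#' Chunks every contribution of every song on the song's own time grid
#' (shared by its co-singers) and returns one flat list of labelled chunks,
#' the input to [permute_duets()].
#'
#' @param songs List of `"song_record"` objects.
#' @param spec A [chunk_spec()].
#' @param wild_only Restrict to wild-recorded songs (default `TRUE`).
#' @return A list of chunk entries with metadata: `song_id`, `group_id`,
#'   `individual_id`, `sex`, `chunk`, `span`, `phonation`.
#' @export
chunk_songs <- function(songs, spec = chunk_spec(), wild_only = TRUE) {
  out <- list()
  for (song in songs) {
    if (wild_only && song$contributions[[1]]$context != "wild") next
    t0 <- min(vapply(song$contributions,
                     function(ct) ct$notes$onset[1], 0))
    song_end <- max(vapply(song$contributions,
                           function(ct) max(ct$notes$offset), 0))
    for (ct in song$contributions) {
      for (ch in chunk_contribution(ct, spec, t0 = t0, song_end = song_end)) {
        out[[length(out) + 1L]] <- list(
          song_id = song$song_id, group_id = song$group_id,
          individual_id = ct$individual_id, sex = ct$sex,
          chunk = ch$chunk, span = ch$span, phonation = ch$phonation)
      }
    }
  }
  out
}

truncate_phonation <- function(ph, span) {
  iv <- ph$intervals
  on <- pmin(iv$onset, span); off <- pmin(iv$offset, span)
  phonation_set(data.frame(onset = on, offset = off)[off > on, , drop = FALSE])
}

#' Permutation scheme for simulated duets
#'
#' @param mode `"real_couples"` (both chunks drawn from the same mated
#'   pair's repertoire, i.e. same group) or `"random_couples"` (chunks from
#'   non-coupled, different-group individuals). Pairings are always
#'   female x male.
#' @param n_permutations Number of simulated pairings (default 1000).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `"permutation_scheme"`.
#' @export
permutation_scheme <- function(mode = c("real_couples", "random_couples"),
                               n_permutations = 1000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 1)
  structure(list(mode = mode, n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "permutation_scheme")
}

#' Simulated-duet null distribution by chunk permutation
#'
#' Draws `n_permutations` simulated duets: each draw pairs a female chunk
#' with a male chunk it did not originally co-occur with — in
#' `real_couples` mode both chunks come from the same group (the mated
#' pair's own repertoire, excluding the original song/chunk pairing); in
#' `random_couples` mode from different groups. Paired chunks are both
#' re-based to zero and truncated to the shorter span before the normalized
#' overlap is computed. Fully reproducible under `seed`.
#'
#' @param chunks Chunk list from [chunk_songs()].
#' @param scheme A [permutation_scheme()].
#' @return An object of class `"null_distribution"`: data frame `draws`
#'   (female/male chunk provenance and `normalized_overlap`, every value in
#'   `[0, 0.5]`), `summary` (mean, sd), and the scheme.
#' @export
permute_duets <- function(chunks, scheme = permutation_scheme()) {
  fem <- Filter(function(ch) ch$sex == "female", chunks)
  mal <- Filter(function(ch) ch$sex == "male", chunks)
  if (length(fem) < 2 || length(mal) < 2) {
    stop("need at least 2 chunks per sex to permute", call. = FALSE)
  }
  f_key <- vapply(fem, function(ch) paste(ch$song_id, ch$chunk), "")
  m_key <- vapply(mal, function(ch) paste(ch$song_id, ch$chunk), "")
  f_grp <- vapply(fem, `[[`, "", "group_id")
  m_grp <- vapply(mal, `[[`, "", "group_id")
  ## eligibility: opposite sexes always; never the original co-occurring
  ## (song, chunk) pairing; group constraint per mode
  eligible <- function(i, j) {
    if (f_key[i] == m_key[j]) return(FALSE)
    if (scheme$mode == "real_couples") f_grp[i] == m_grp[j] else
      f_grp[i] != m_grp[j]
  }
  elig <- outer(seq_along(fem), seq_along(mal), Vectorize(eligible))
  if (!any(elig)) {
    stop("no eligible ", scheme$mode, " pairings among the supplied chunks",
         call. = FALSE)
  }
  pair_idx <- which(elig, arr.ind = TRUE)
  run_seeded(scheme$seed, {
    draw <- pair_idx[sample.int(nrow(pair_idx), scheme$n_permutations,
                                replace = TRUE), , drop = FALSE]
    vals <- numeric(nrow(draw))
    ovs <- numeric(nrow(draw))
    spans <- numeric(nrow(draw))
    for (d in seq_len(nrow(draw))) {
      fi <- fem[[draw[d, 1]]]; mj <- mal[[draw[d, 2]]]
      span <- min(fi$span, mj$span)
      om <- overlap_metrics(truncate_phonation(fi$phonation, span),
                            truncate_phonation(mj$phonation, span))
      vals[d] <- om$normalized_overlap
      ovs[d] <- om$overlap_s
      spans[d] <- span
    }
    draws <- data.frame(
      female_song = vapply(fem[draw[, 1]], `[[`, "", "song_id"),
      female_chunk = vapply(fem[draw[, 1]], `[[`, 0L, "chunk"),
      male_song = vapply(mal[draw[, 2]], `[[`, "", "song_id"),
      male_chunk = vapply(mal[draw[, 2]], `[[`, 0L, "chunk"),
      overlap_s = ovs, span = spans,
      normalized_overlap = vals, stringsAsFactors = FALSE)
    structure(list(draws = draws,
                   summary = c(mean = mean(vals), sd = sd(vals)),
                   n_eligible_pairs = nrow(pair_idx),
                   scheme = scheme),
              class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("<null_distribution> %d %s draws: normalized overlap ",
                     "%.4f +/- %.4f\n"),
              nrow(x$draws), x$scheme$mode, x$summary[["mean"]],
              x$summary[["sd"]]))
  invisible(x)
}

#' Compare real overlap against a permutation null
#'
#' Empirical one-sided test of whether the observed duets overlap more than
#' chance: `p = (1 + #\{null >= mean(real)\}) / (1 + n_null)` (add-one
#' estimator, so p is never exactly zero), plus the mean difference with a
#' bootstrap percentile confidence interval.
#'
#' @param real Numeric vector of observed normalized overlaps (or a list of
#'   `"overlap_result"` objects).
#' @param null A `"null_distribution"` (or numeric vector of null values).
#' @param n_boot Bootstrap replicates for the CI of the mean difference.
#' @param conf Confidence level.
#' @return An object of class `"chance_test"`: `p_value`, `mean_real`,
#'   `mean_null`, `mean_diff`, `ci`, `n_real`, `n_null`, and a long `table`
#'   with one row per real duet and per simulated draw labelled
#'   REAL / SIM_real_couple / SIM_random_couple.
#' @export
chance_test <- function(real, null, n_boot = 1000, conf = 0.95) {
  if (is.list(real) && !is.data.frame(real) &&
      all(vapply(real, inherits, TRUE, "overlap_result"))) {
    real <- vapply(real, `[[`, 0, "normalized_overlap")
  }
  real <- as.numeric(real)
  mode <- "null"
  if (inherits(null, "null_distribution")) {
    mode <- null$scheme$mode
    null <- null$draws$normalized_overlap
  }
  null <- as.numeric(null)
  stopifnot(length(real) >= 1, length(null) >= 1)
  m_real <- mean(real)
  p <- (1 + sum(null >= m_real)) / (1 + length(null))
  boot <- vapply(seq_len(n_boot), function(b) {
    mean(real[sample.int(length(real), replace = TRUE)]) -
      mean(null[sample.int(length(null), replace = TRUE)])
  }, 0)
  a <- (1 - conf) / 2
  tab <- rbind(
    data.frame(label = "REAL", normalized_overlap = real,
               stringsAsFactors = FALSE),
    data.frame(label = paste0("SIM_", sub("^null$", "perm", mode)),
               normalized_overlap = null, stringsAsFactors = FALSE))
  structure(list(p_value = p, mean_real = m_real, mean_null = mean(null),
                 mean_diff = m_real - mean(null),
                 ci = quantile(boot, c(a, 1 - a), names = FALSE),
                 conf = conf, n_real = length(real), n_null = length(null),
                 table = tab),
            class = "chance_test")
}

#' @export
print.chance_test <- function(x, ...) {
  cat(sprintf("<chance_test> real mean %.4f vs null mean %.4f (n = %d/%d)\n",
              x$mean_real, x$mean_null, x$n_real, x$n_null))
  cat(sprintf("  empirical p = %.4g; mean diff %.4f, %d%% CI [%.4f, %.4f]\n",
              x$p_value, x$mean_diff, round(100 * x$conf), x$ci[1], x$ci[2]))
  invisible(x)
}
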