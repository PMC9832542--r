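#' Singer parameters for the song generator
#'
#' Describes one singer as a jittered renewal process: each inter-onset
#' interval is drawn from a one- or two-component tempo mixture plus
#' Gaussian jitter (floored at `ioi_min`), with occasional long
#' inter-phrase pauses; note durations are Gaussian, truncated positive and
#' clipped below the following interval so notes never overlap.
#'
#' @param tempi_s One or two characteristic mean IOIs in seconds.
#' @param mix_weight Probability of drawing the first (fast) tempo when two
#'   are given.
#' @param jitter_sd_s SD of the additive Gaussian jitter on each IOI — the
#'   isochrony dial: 0 gives a metronome, larger values blur the 1:1 ratio.
#' @param note_dur_mean,note_dur_sd Note duration distribution in seconds.
#' @param n_notes Number of notes to generate.
#' @param pause_prob Probability that an interval is an inter-phrase pause
#'   instead of a tempo draw (emulates the long gaps between song phrases
#'   that depress field call rates; set to 0 for a pure renewal process).
#' @param pause_range Uniform range of pause durations in seconds.
#' @param ioi_min Hard floor on any interval (prevents degenerate
#'   zero/negative IOIs under heavy jitter).
#' @return An object of class `"singer_params"`.
#' @export
singer_params <- function(tempi_s, mix_weight = 0.5, jitter_sd_s = 0.02,
                          note_dur_mean = 0.12, note_dur_sd = 0.03,
                          n_notes = 120, pause_prob = 0.1,
                          pause_range = c(2, 8), ioi_min = 0.05) {
  stopifnot(length(tempi_s) %in% 1:2, all(tempi_s > 0),
            mix_weight >= 0, mix_weight <= 1, jitter_sd_s >= 0,
            note_dur_mean > 0, note_dur_sd >= 0, n_notes >= 1,
            pause_prob >= 0, pause_prob < 1, ioi_min > 0)
  structure(list(tempi_s = tempi_s, mix_weight = mix_weight,
                 jitter_sd_s = jitter_sd_s, note_dur_mean = note_dur_mean,
                 note_dur_sd = note_dur_sd, n_notes = as.integer(n_notes),
                 pause_prob = pause_prob, pause_range = pause_range,
                 ioi_min = ioi_min),
            class = "singer_params")
}

#' Default singer parameters per song type
#'
#' Tempo defaults follow the characteristic IOI density peaks of lar-gibbon
#' song types: 0.181 s and 0.503 s for the female contribution to duet,
#' 0.204 s and 0.637 s for the male contribution, and a single 0.322 s peak
#' for the male solo.
#'
#' @param song_type One of `"female_duet"`, `"male_duet"`, `"male_solo"`.
#' @param ... Overrides passed on to [singer_params()].
#' @export
default_singer_params <- function(song_type = song_types, ...) {
  song_type <- match.arg(song_type)
  tempi <- switch(song_type,
                  female_duet = c(0.181, 0.503),
                  male_duet = c(0.204, 0.637),
                  male_solo = 0.322)
  args <- list(...)
  args$tempi_s <- tempi
  if (is.null(args$mix_weight)) {
    args$mix_weight <- if (length(tempi) == 2) 0.5 else 1
  }
  do.call(singer_params, args)
}

#' Coupling parameters for a simulated duet
#'
#' The coupling model is an explicit invention of the generator (real duet
#' coordination has no published quantitative model): when a singer is
#' coupled and its partner has produced an onset since the singer's own
#' last note, the next onset is the convex combination
#' `(1 - c) * (own renewal time) + c * (partner's most recent onset +
#' response_lag)`; otherwise the singer renews independently. Coupling at
#' onset-generation time yields genuine lagged predictability, the property
#' a Granger test detects.
#'
#' @param c Coupling strength in `[0, 1]`; 0 = independent singers.
#' @param response_lag_s Target latency of the response after the partner's
#'   onset (default 0.05 s).
#' @param direction `"none"`, `"F_to_M"` (female drives male), `"M_to_F"`,
#'   or `"bidirectional"`.
#' @return An object of class `"coupling_params"`.
#' @export
coupling_params <- function(c = 0, response_lag_s = 0.05,
                            direction = c("none", "F_to_M", "M_to_F",
                                          "bidirectional")) {
  direction <- match.arg(direction)
  stopifnot(c >= 0, c <= 1, response_lag_s >= 0)
  structure(list(c = c, response_lag_s = response_lag_s,
                 direction = direction),
            class = "coupling_params")
}

#' Duet scenario: singers, coupling and metadata
#'
#' @param female,male [singer_params()] for each sex.
#' @param coupling A [coupling_params()].
#' @param song_id,group_id,female_id,male_id Identifiers.
#' @param context `"wild"` or `"captive"`.
#' @return An object of class `"duet_scenario"`.
#' @export
duet_scenario <- function(female = default_singer_params("female_duet"),
                          male = default_singer_params("male_duet"),
                          coupling = coupling_params(),
                          song_id = "duet_1", group_id = "g1",
                          female_id = "F1", male_id = "M1",
                          context = c("wild", "captive")) {
  context <- match.arg(context)
  structure(list(female = female, male = male, coupling = coupling,
                 song_id = song_id, group_id = group_id,
                 female_id = female_id, male_id = male_id,
                 context = context),
            class = "duet_scenario")
}

draw_increment <- function(p) {
  T_k <- if (p$pause_prob > 0 && runif(1) < p$pause_prob) {
    runif(1, p$pause_range[1], p$pause_range[2])
  } else if (length(p$tempi_s) == 2) {
    if (runif(1) < p$mix_weight) p$tempi_s[1] else p$tempi_s[2]
  } else {
    p$tempi_s[1]
  }
  max(p$ioi_min, T_k + rnorm(1, 0, p$jitter_sd_s))
}

## Durations drawn per note, truncated positive and clipped so that
## offset_k stays a small guard gap before onset_{k+1}.
draw_durations <- function(p, onsets) {
  n <- length(onsets)
  dur <- pmax(0.02, rnorm(n, p$note_dur_mean, p$note_dur_sd))
  if (n > 1) {
    gap_cap <- c(diff(onsets) - 0.005, Inf)
    dur <- pmin(dur, gap_cap)
    dur <- pmax(dur, 0.01)
  }
  dur
}

#' Generate one synthetic contribution
#'
#' Onsets follow `o_{k+1} = o_k + max(ioi_min, T_k + eps_k)` with `T_k`
#' drawn from the tempo mixture (or a pause) and `eps_k ~ N(0,
#' jitter_sd^2)`; durations are drawn and clipped below the next interval.
#' Deterministic under `seed`.
#'
#' @param params A [singer_params()].
#' @param seed RNG seed (`NULL`: use the ambient RNG stream).
#' @param song_id,individual_id,group_id,sex,song_type,context Metadata for
#'   the resulting [contribution()].
#' @param start Time of the first onset.
#' @return A `"contribution"` whose `"truth"` attribute records `params`.
#' @export
generate_contribution <- function(params, seed = NULL, song_id = "song_1",
                                  individual_id = "S1", group_id = "g1",
                                  sex = "male", song_type = "male_solo",
                                  context = "wild", start = 0) {
  stopifnot(inherits(params, "singer_params"))
  run_seeded(seed, {
    incs <- vapply(seq_len(params$n_notes - 1L), function(k)
      draw_increment(params), 0)
    onsets <- start + cumsum(c(0, incs))
    dur <- draw_durations(params, onsets)
    ct <- contribution(song_id = song_id, individual_id = individual_id,
                       group_id = group_id, sex = sex, song_type = song_type,
                       context = context,
                       notes = note_intervals(onsets, onsets + dur, "note"))
    attr(ct, "truth") <- params
    ct
  })
}

is_coupled <- function(direction, sex) {
  switch(direction,
         none = FALSE,
         F_to_M = sex == "male",
         M_to_F = sex == "female",
         bidirectional = TRUE)
}

#' Generate a coupled synthetic duet
#'
#' The two singers are generated jointly in time order. An uncoupled singer
#' renews independently; a coupled singer whose partner has sung since its
#' own last note blends its renewal time toward the partner's most recent
#' onset plus the response lag (see [coupling_params()]). At `c = 1`,
#' `response_lag_s = 0` and deterministic equal durations the two
#' contributions coincide exactly.
#'
#' @param scenario A [duet_scenario()].
#' @param seed RNG seed.
#' @return A `"song_record"` (duet) whose `"truth"` attribute records the
#'   scenario.
#' @export
generate_duet <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "duet_scenario"))
  run_seeded(seed, {
    cp <- scenario$coupling
    par <- list(female = scenario$female, male = scenario$male)
    coupled <- c(female = is_coupled(cp$direction, "female"),
                 male = is_coupled(cp$direction, "male"))
    need <- c(female = scenario$female$n_notes, male = scenario$male$n_notes)
    ons <- list(female = numeric(need[["female"]]),
                male = numeric(need[["male"]]))
    cnt <- c(female = 0L, male = 0L)
    other <- c(female = "male", male = "female")

    tentative <- function(who) {
      p <- par[[who]]
      last_own <- if (cnt[[who]]) ons[[who]][cnt[[who]]] else -Inf
      own <- if (cnt[[who]]) last_own + pending[[who]] else
        pending[[who]]                           # start offset from t = 0
      o2 <- other[[who]]
      anchor <- if (cnt[[o2]]) ons[[o2]][cnt[[o2]]] else NA_real_
      if (coupled[[who]] && !is.na(anchor) && anchor > last_own) {
        raw <- (1 - cp$c) * own + cp$c * (anchor + cp$response_lag_s)
        max(last_own + p$ioi_min, raw)
      } else {
        own
      }
    }

    ## female opens the song at t = 0
    ons$female[1] <- 0
    cnt[["female"]] <- 1L
    pending <- list(female = draw_increment(par$female),
                    male = if (coupled[["male"]]) 0 else
                      draw_increment(par$male))
    while (cnt[["female"]] < need[["female"]] ||
           cnt[["male"]] < need[["male"]]) {
      cand <- c(female = if (cnt[["female"]] < need[["female"]])
        tentative("female") else Inf,
        male = if (cnt[["male"]] < need[["male"]])
          tentative("male") else Inf)
      who <- names(which.min(cand))
      cnt[[who]] <- cnt[[who]] + 1L
      ons[[who]][cnt[[who]]] <- cand[[who]]
      pending[[who]] <- draw_increment(par[[who]])
    }

    mk <- function(who, id, st) {
      o <- ons[[who]]
      ct <- contribution(
        song_id = scenario$song_id, individual_id = id,
        group_id = scenario$group_id, sex = who, song_type = st,
        context = scenario$context,
        notes = note_intervals(o, o + draw_durations(par[[who]], o), "note"))
      ct
    }
    song <- song_record(list(mk("female", scenario$female_id, "female_duet"),
                             mk("male", scenario$male_id, "male_duet")))
    attr(song, "truth") <- scenario
    song
  })
}

#' Generate a synthetic dataset of songs on disk
#'
#' Mirrors the shape of a field study design — per group a number of duets
#' and male solos, wild or captive — and writes one TextGrid per song, a
#' pooled `onsets.csv` (the [export_onsets_csv()] dialect) and a
#' `ground_truth.csv` with one row per contribution recording every
#' generator parameter.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_groups Number of groups.
#' @param duets_per_group,solos_per_group Songs per group and type.
#' @param female,male,solo [singer_params()] used for the respective parts.
#' @param coupling A [coupling_params()] shared by all duets.
#' @param contexts Context label per group, recycled (default alternates
#'   wild/captive is *not* assumed: all wild).
#' @param seed Base seed; each song uses a distinct derived sub-seed.
#' @return Invisibly, a list with the generated `songs` and the written
#'   `files`.
#' @export
generate_dataset <- function(out_dir, n_groups = 2, duets_per_group = 2,
                             solos_per_group = 1,
                             female = default_singer_params("female_duet"),
                             male = default_singer_params("male_duet"),
                             solo = default_singer_params("male_solo"),
                             coupling = coupling_params(0.5, 0.05,
                                                        "bidirectional"),
                             contexts = "wild", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contexts <- rep_len(contexts, n_groups)
  songs <- list()
  truth_rows <- list()
  files <- character(0)
  k <- 0L
  for (g in seq_len(n_groups)) {
    gid <- sprintf("g%02d", g)
    for (d in seq_len(duets_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_duet%02d", gid, d)
      sc <- duet_scenario(female = female, male = male, coupling = coupling,
                          song_id = sid, group_id = gid,
                          female_id = paste0(gid, "_F"),
                          male_id = paste0(gid, "_M"),
                          context = contexts[g])
      song <- generate_duet(sc, seed = sub_seed(seed, k))
      songs[[length(songs) + 1L]] <- song
      path <- file.path(out_dir, paste0(sid, ".TextGrid"))
      write_textgrid(song$contributions, path)
      files <- c(files, path)
      for (ct in song$contributions) {
        p <- if (ct$sex == "female") female else male
        truth_rows[[length(truth_rows) + 1L]] <-
          truth_row(ct, p, coupling$c, coupling$direction)
      }
    }
    for (s in seq_len(solos_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_solo%02d", gid, s)
      ct <- generate_contribution(solo, seed = sub_seed(seed, k),
                                  song_id = sid,
                                  individual_id = paste0(gid, "_M"),
                                  group_id = gid, sex = "male",
                                  song_type = "male_solo",
                                  context = contexts[g])
      songs[[length(songs) + 1L]] <- song_record(list(ct))
      path <- file.path(out_dir, paste0(sid, ".TextGrid"))
      write_textgrid(list(ct), path)
      files <- c(files, path)
      truth_rows[[length(truth_rows) + 1L]] <- truth_row(ct, solo, 0, "none")
    }
  }
  contributions <- unlist(lapply(songs, `[[`, "contributions"),
                          recursive = FALSE)
  onsets_path <- file.path(out_dir, "onsets.csv")
  export_onsets_csv(contributions, onsets_path)
  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(songs = songs,
                 files = c(files, onsets_path, truth_path)))
}

truth_row <- function(ct, p, c, direction) {
  data.frame(song_id = ct$song_id, individual_id = ct$individual_id,
             group_id = ct$group_id, sex = ct$sex, song_type = ct$song_type,
             context = ct$context,
             tempo1_s = p$tempi_s[1],
             tempo2_s = if (length(p$tempi_s) == 2) p$tempi_s[2] else NA,
             mix_weight = p$mix_weight, jitter_sd_s = p$jitter_sd_s,
             note_dur_mean = p$note_dur_mean, n_notes = p$n_notes,
             coupling_c = c, coupling_direction = direction,
             stringsAsFactors = FALSE)
}
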