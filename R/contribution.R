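#' Construct a note-interval table
#'
#' A note is an annotated phonation interval with strictly positive duration.
#' Intervals with empty labels are silences and never enter a note table.
#'
#' @param onset,offset Numeric vectors of interval start/end times in seconds.
#' @param label Character vector of note labels; recycled if length 1.
#' @return A `data.frame` with columns `onset`, `offset`, `label`, sorted by
#'   onset.
#' @export
note_intervals <- function(onset, offset, label = "note") {
  if (length(onset) != length(offset)) {
    stop("`onset` and `offset` must have equal length", call. = FALSE)
  }
  label <- rep_len(as.character(label), length(onset))
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   label = label, stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!is.finite(df$onset)) || any(!is.finite(df$offset))) {
      stop("non-finite onset/offset", call. = FALSE)
    }
    if (any(df$onset < 0)) stop("onsets must be >= 0", call. = FALSE)
    if (any(df$offset <= df$onset)) {
      bad <- which(df$offset <= df$onset)
      stop("notes must have strictly positive duration (rows ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    if (any(trimws(df$label) == "")) {
      stop("note labels must be non-empty (blank labels denote silence)",
           call. = FALSE)
    }
    df <- df[order(df$onset), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

song_types <- c("female_duet", "male_duet", "male_solo")

#' Construct one individual's contribution to a song
#'
#' A contribution is the ordered, non-overlapping note sequence one
#' individual sings within one song, typed by sex and song type (female
#' contribution to duet, male contribution to duet, or male solo).
#'
#' @param song_id,individual_id,group_id Identifiers (coerced to character).
#' @param sex `"female"` or `"male"`.
#' @param song_type One of `"female_duet"`, `"male_duet"`, `"male_solo"`.
#' @param notes A note table from [note_intervals()].
#' @param context Recording context, `"wild"` or `"captive"`.
#' @return An object of class `"contribution"`.
#' @export
contribution <- function(song_id, individual_id, group_id = NA_character_,
                         sex, song_type, notes,
                         context = c("wild", "captive")) {
  sex <- match.arg(sex, c("female", "male"))
  song_type <- match.arg(song_type, song_types)
  context <- match.arg(context)
  x <- structure(
    list(song_id = as.character(song_id),
         individual_id = as.character(individual_id),
         group_id = as.character(group_id),
         sex = sex, song_type = song_type, context = context,
         notes = notes),
    class = "contribution")
  validate_contribution(x)
}

#' Validate a contribution
#'
#' Checks the contribution invariants: notes sorted by strictly increasing
#' onset, no two notes of the same individual overlapping in time (one
#' animal cannot phonate two notes at once), and song type consistent with
#' sex (no female solos occur in this repertoire).
#'
#' @param x A `"contribution"`.
#' @return `x`, invisibly classed, or an error listing every offending note
#'   pair.
#' @export
validate_contribution <- function(x) {
  stopifnot(inherits(x, "contribution"))
  n <- x$notes
  if (nrow(n) > 1) {
    if (is.unsorted(n$onset, strictly = TRUE)) {
      stop("contribution ", x$individual_id, "/", x$song_id,
           ": note onsets must be strictly increasing", call. = FALSE)
    }
    ov <- which(n$offset[-nrow(n)] > n$onset[-1])
    if (length(ov)) {
      stop("contribution ", x$individual_id, "/", x$song_id,
           ": overlapping notes at rows ",
           paste(sprintf("%d-%d", ov, ov + 1), collapse = ", "),
           call. = FALSE)
    }
  }
  if (x$sex == "female" && x$song_type == "male_solo") {
    stop("song_type male_solo is inconsistent with sex female", call. = FALSE)
  }
  if (x$sex == "female" && x$song_type == "male_duet") {
    stop("song_type male_duet is inconsistent with sex female", call. = FALSE)
  }
  if (x$sex == "male" && x$song_type == "female_duet") {
    stop("song_type female_duet is inconsistent with sex male", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.contribution <- function(x, ...) {
  cat(sprintf("<contribution> %s | individual %s (%s, %s, %s)\n",
              x$song_id, x$individual_id, x$sex, x$song_type, x$context))
  n <- nrow(x$notes)
  if (n == 0) {
    cat("  0 notes\n")
  } else {
    cat(sprintf("  %d notes spanning %.3f-%.3f s, total phonation %.3f s\n",
                n, x$notes$onset[1], x$notes$offset[n],
                sum(x$notes$offset - x$notes$onset)))
  }
  invisible(x)
}

#' Number of notes in a contribution
#' @param x A `"contribution"`.
#' @export
n_notes <- function(x) nrow(x$notes)

#' Assemble a song record
#'
#' A song is either a solo (one contribution) or a duet (exactly one female
#' and one male contribution to duet).
#'
#' @param contributions List of `"contribution"` objects sharing `song_id`.
#' @return An object of class `"song_record"` with fields `song_id`,
#'   `group_id`, `contributions`.
#' @export
song_record <- function(contributions) {
  if (!length(contributions)) stop("no contributions", call. = FALSE)
  lapply(contributions, validate_contribution)
  ids <- unique(vapply(contributions, `[[`, "", "song_id"))
  if (length(ids) != 1) {
    stop("contributions belong to different songs: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  types <- vapply(contributions, `[[`, "", "song_type")
  if (length(contributions) == 2) {
    if (!setequal(types, c("female_duet", "male_duet"))) {
      stop("a duet needs exactly one female_duet and one male_duet ",
           "contribution, got: ", paste(types, collapse = ", "),
           call. = FALSE)
    }
  } else if (length(contributions) > 2) {
    stop("a song record holds 1 (solo) or 2 (duet) contributions",
         call. = FALSE)
  }
  structure(
    list(song_id = ids,
         group_id = contributions[[1]]$group_id,
         contributions = contributions),
    class = "song_record")
}

#' @export
print.song_record <- function(x, ...) {
  kind <- if (length(x$contributions) == 2) "duet" else "solo"
  cat(sprintf("<song_record> %s (%s, group %s)\n", x$song_id, kind,
              x$group_id))
  for (ct in x$contributions) print(ct)
  invisible(x)
}

#' Is this song record a duet?
#' @param x A `"song_record"`.
#' @export
is_duet <- function(x) length(x$contributions) == 2

duet_female <- function(song) {
  song$contributions[[which(vapply(song$contributions, `[[`, "", "sex") ==
                              "female")]]
}

duet_male <- function(song) {
  song$contributions[[which(vapply(song$contributions, `[[`, "", "sex") ==
                              "male")]]
}
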