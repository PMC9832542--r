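onset_csv_header <- c("song_id", "individual_id", "group_id", "sex",
                      "song_type", "context", "onset_s", "offset_s")

#' Export note onsets to a flat CSV table
#'
#' One row per note, sorted by (song_id, individual_id, onset), with the
#' fixed header `song_id,individual_id,group_id,sex,song_type,context,
#' onset_s,offset_s`. The export is byte-identical across runs for the same
#' input.
#'
#' @param contributions List of `"contribution"` objects.
#' @param path Output CSV path, or `NULL` to return the table only.
#' @return The exported `data.frame`, invisibly when `path` is given.
#' @export
export_onsets_csv <- function(contributions, path = NULL) {
  lapply(contributions, validate_contribution)
  rows <- lapply(contributions, function(ct) {
    if (!nrow(ct$notes)) return(NULL)
    data.frame(song_id = ct$song_id, individual_id = ct$individual_id,
               group_id = ct$group_id, sex = ct$sex,
               song_type = ct$song_type, context = ct$context,
               onset_s = ct$notes$onset, offset_s = ct$notes$offset,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab)) tab <- as.data.frame(setNames(
    c(rep(list(character(0)), 6), rep(list(numeric(0)), 2)), onset_csv_header))
  tab <- tab[order(tab$song_id, tab$individual_id, tab$onset_s), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read contributions back from an onset CSV table
#'
#' Inverse of [export_onsets_csv()]: rows are grouped by
#' (song_id, individual_id) and each group becomes one [contribution()].
#' Note labels are not stored in the flat table, so re-imported notes carry
#' the placeholder label `"note"`.
#'
#' @param path CSV path with the [export_onsets_csv()] header.
#' @return A list of `"contribution"` objects.
#' @export
read_onsets_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(onset_csv_header, names(tab))
  if (length(missing_cols)) {
    stop("onset table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  contributions_from_onsets(tab)
}

#' Assemble contributions from an in-memory onset table
#'
#' @param tab A `data.frame` with the [export_onsets_csv()] columns.
#' @return A list of `"contribution"` objects.
#' @export
contributions_from_onsets <- function(tab) {
  key <- interaction(tab$song_id, tab$individual_id, drop = TRUE)
  out <- lapply(split(tab, key), function(g) {
    g <- g[order(g$onset_s), , drop = FALSE]
    contribution(
      song_id = g$song_id[1], individual_id = g$individual_id[1],
      group_id = g$group_id[1], sex = g$sex[1], song_type = g$song_type[1],
      context = g$context[1],
      notes = note_intervals(g$onset_s, g$offset_s, "note"))
  })
  names(out) <- NULL
  out
}

#' Group contributions into song records
#'
#' @param contributions List of `"contribution"` objects (any number of
#'   songs).
#' @return A list of [song_record()] objects, one per distinct `song_id`.
#' @export
collect_songs <- function(contributions) {
  ids <- vapply(contributions, `[[`, "", "song_id")
  out <- lapply(split(contributions, ids), song_record)
  names(out) <- NULL
  out
}
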