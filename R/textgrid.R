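## Praat TextGrid reading/writing. Both the verbose ("long") and compact
## ("short") text serialisations are accepted; output is always long format,
## the dialect Praat itself writes by default. Praat saves text files as
## UTF-8 or UTF-16 depending on its preferences, so both encodings are
## detected from the byte-order mark.

tg_encoding <- function(path) {
  bom <- readBin(path, "raw", n = 3L)
  if (length(bom) >= 2 && ((bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) ||
                           (bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)))) {
    return("UTF-16")
  }
  "UTF-8"
}

tg_read_lines <- function(path) {
  con <- file(path, encoding = tg_encoding(path))
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

tg_parse_error <- function(path, line_no, what) {
  stop(sprintf("malformed TextGrid '%s' at line %d: %s",
               path, line_no, what), call. = FALSE)
}

## Unquote a Praat string token; Praat escapes embedded quotes by doubling.
tg_unquote <- function(s) {
  s <- sub('^[^"]*"', "", s)
  s <- sub('"[^"]*$', "", s)
  gsub('""', '"', s)
}

tg_num <- function(s, path, line_no) {
  v <- suppressWarnings(as.numeric(sub("^.*=\\s*", "", trimws(s))))
  if (is.na(v)) tg_parse_error(path, line_no, paste0("expected a number, got '",
                                                     trimws(s), "'"))
  v
}

## Parse the long (verbose) dialect into a list of tiers.
tg_parse_long <- function(lines, path) {
  tiers <- list()
  i <- 1L
  n <- length(lines)
  cur <- NULL
  while (i <= n) {
    ln <- trimws(lines[i])
    if (grepl('^class\\s*=\\s*"IntervalTier"', ln)) {
      if (!is.null(cur)) tiers[[cur$name]] <- cur
      cur <- list(name = NULL, xmin = NA_real_, xmax = NA_real_,
                  intervals = list())
    } else if (grepl('^class\\s*=\\s*"TextTier"', ln)) {
      ## point tiers carry no interval annotation; skip until next tier
      if (!is.null(cur)) tiers[[cur$name]] <- cur
      cur <- NULL
    } else if (!is.null(cur)) {
      if (grepl('^name\\s*=', ln)) {
        cur$name <- tg_unquote(ln)
      } else if (grepl("^intervals\\s*\\[", ln)) {
        if (i + 3L > n) tg_parse_error(path, i, "truncated interval block")
        xmin <- tg_num(lines[i + 1L], path, i + 1L)
        xmax <- tg_num(lines[i + 2L], path, i + 2L)
        txt_ln <- trimws(lines[i + 3L])
        if (!grepl('^text\\s*=', txt_ln)) {
          tg_parse_error(path, i + 3L, "expected 'text =' in interval block")
        }
        cur$intervals[[length(cur$intervals) + 1L]] <-
          list(xmin = xmin, xmax = xmax, text = tg_unquote(txt_ln))
        i <- i + 3L
      } else if (grepl("^xmin\\s*=", ln) && is.na(cur$xmin)) {
        cur$xmin <- tg_num(ln, path, i)
      } else if (grepl("^xmax\\s*=", ln) && is.na(cur$xmax)) {
        cur$xmax <- tg_num(ln, path, i)
      }
    }
    i <- i + 1L
  }
  if (!is.null(cur)) tiers[[cur$name]] <- cur
  tiers
}

## Parse the short (compact) dialect: bare values in fixed positional order.
tg_parse_short <- function(lines, path) {
  vals <- trimws(lines)
  keep <- which(vals != "" & !grepl("^File type", vals) &
                  !grepl("^Object class", vals))
  idx <- keep[-(1:3)]                      # drop global xmin, xmax, <exists>
  take <- function(k) {
    if (k > length(idx)) tg_parse_error(path, length(lines),
                                        "unexpected end of file")
    list(line = idx[k], value = vals[idx[k]])
  }
  num <- function(k) {
    t <- take(k)
    v <- suppressWarnings(as.numeric(t$value))
    if (is.na(v)) tg_parse_error(path, t$line,
                                 paste0("expected a number, got '", t$value, "'"))
    v
  }
  n_tiers <- num(1)
  k <- 2L
  tiers <- list()
  for (t in seq_len(n_tiers)) {
    cls <- tg_unquote(take(k)$value)
    name <- tg_unquote(take(k + 1L)$value)
    xmin <- num(k + 2L); xmax <- num(k + 3L); n_int <- num(k + 4L)
    k <- k + 5L
    if (cls == "IntervalTier") {
      ints <- vector("list", n_int)
      for (j in seq_len(n_int)) {
        ints[[j]] <- list(xmin = num(k), xmax = num(k + 1L),
                          text = tg_unquote(take(k + 2L)$value))
        k <- k + 3L
      }
      tiers[[name]] <- list(name = name, xmin = xmin, xmax = xmax,
                            intervals = ints)
    } else {
      k <- k + 2L * n_int                  # point tier: time + mark per point
    }
  }
  tiers
}

default_tier_map <- function(tier_names) {
  out <- list()
  for (nm in tier_names) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    sex <- tolower(parts[length(parts)])
    if (!sex %in% c("female", "male")) {
      stop("cannot infer metadata from tier name '", nm,
           "'; pass `tier_map` (expected '<individual_id>_<sex>')",
           call. = FALSE)
    }
    out[[nm]] <- list(
      individual_id = paste(parts[-length(parts)], collapse = "_"),
      sex = sex)
  }
  out
}

#' Read song contributions from a Praat TextGrid
#'
#' Accepts both the long and short Praat text serialisations, in UTF-8 or
#' UTF-16. Each mapped interval tier becomes one [contribution()]: intervals
#' with empty or whitespace-only labels are silences and are dropped; the
#' remaining labelled intervals become notes.
#'
#' @param path Path to a `.TextGrid` file.
#' @param tier_map Optional named list mapping tier names to metadata lists
#'   with elements `individual_id`, `sex`, and optionally `song_type`. When
#'   `NULL`, tier names are parsed as `"<individual_id>_<sex>"`. Tiers absent
#'   from an explicit `tier_map` are ignored.
#' @param song_id,group_id,context Song metadata applied to every tier;
#'   `song_id` defaults to the file name without extension.
#' @return A list of `"contribution"` objects, one per mapped interval tier,
#'   with a `"validation"` attribute (a character vector) flagging empty
#'   tiers.
#' @seealso [write_textgrid()] for the inverse operation.
#' @export
read_textgrid <- function(path, tier_map = NULL, song_id = NULL,
                          group_id = NA_character_,
                          context = c("wild", "captive")) {
  context <- match.arg(context)
  if (is.null(song_id)) song_id <- sub("\\.[Tt]ext[Gg]rid$", "", basename(path))
  lines <- tg_read_lines(path)
  if (!length(lines) || !grepl("ooTextFile", lines[1])) {
    tg_parse_error(path, 1L, "missing 'File type = \"ooTextFile\"' header")
  }
  long <- any(grepl("^\\s*item\\s*\\[", lines)) ||
    any(grepl('^\\s*class\\s*=\\s*"', lines))
  tiers <- if (long) tg_parse_long(lines, path) else tg_parse_short(lines, path)
  if (!length(tiers)) tg_parse_error(path, length(lines), "no interval tiers")

  if (is.null(tier_map)) {
    tier_map <- default_tier_map(names(tiers))
  } else {
    missing_tiers <- setdiff(names(tier_map), names(tiers))
    if (length(missing_tiers)) {
      stop("tier(s) named in `tier_map` not present in '", path, "': ",
           paste(missing_tiers, collapse = ", "), call. = FALSE)
    }
    tiers <- tiers[names(tier_map)]
  }

  n_mapped <- length(tier_map)
  flags <- character(0)
  out <- vector("list", n_mapped)
  for (k in seq_len(n_mapped)) {
    nm <- names(tier_map)[k]
    meta <- tier_map[[nm]]
    tier <- tiers[[nm]]
    ints <- tier$intervals
    lab <- vapply(ints, `[[`, "", "text")
    keep <- trimws(lab) != ""
    if (!any(keep)) {
      flags <- c(flags, sprintf("tier '%s': no labelled intervals", nm))
      notes <- note_intervals(numeric(0), numeric(0), character(0))
    } else {
      notes <- note_intervals(
        onset = vapply(ints[keep], `[[`, 0, "xmin"),
        offset = vapply(ints[keep], `[[`, 0, "xmax"),
        label = lab[keep])
    }
    song_type <- meta$song_type
    if (is.null(song_type)) {
      song_type <- if (n_mapped >= 2) {
        if (meta$sex == "female") "female_duet" else "male_duet"
      } else if (meta$sex == "male") "male_solo" else "female_duet"
    }
    out[[k]] <- contribution(
      song_id = song_id, individual_id = meta$individual_id,
      group_id = group_id, sex = meta$sex, song_type = song_type,
      notes = notes, context = context)
  }
  attr(out, "validation") <- flags
  out
}

tg_fmt <- function(x) formatC(x, digits = 15, format = "g", width = -1)

tg_quote <- function(s) paste0('"', gsub('"', '""', s), '"')

#' Write contributions to a long-format Praat TextGrid
#'
#' One interval tier per contribution (named `"<individual_id>_<sex>"`),
#' with empty-label silence intervals filled between notes so the tier
#' covers `[0, xmax]` without gaps.
#'
#' @param contributions Non-empty list of `"contribution"` objects from one
#'   song.
#' @param path Output path.
#' @param xmax Grid end time; defaults to the latest note offset.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(contributions, path, xmax = NULL) {
  if (!length(contributions)) stop("no contributions to write", call. = FALSE)
  lapply(contributions, validate_contribution)
  last <- max(vapply(contributions,
                     function(ct) if (nrow(ct$notes)) max(ct$notes$offset) else 0,
                     0))
  if (is.null(xmax)) xmax <- last
  if (xmax < last) stop("xmax is earlier than the last note offset",
                        call. = FALSE)
  out <- c('File type = "ooTextFile"',
           'Object class = "TextGrid"',
           "",
           "xmin = 0",
           paste0("xmax = ", tg_fmt(xmax)),
           "tiers? <exists>",
           paste0("size = ", length(contributions)),
           "item []:")
  for (k in seq_along(contributions)) {
    ct <- contributions[[k]]
    nt <- ct$notes
    ## silence-fill: alternate blank and labelled intervals over [0, xmax]
    bounds <- c(0, as.vector(rbind(nt$onset, nt$offset)), xmax)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    labels <- rep("", length(starts))
    if (nrow(nt)) labels[seq(2, by = 2, length.out = nrow(nt))] <- nt$label
    keep <- ends > starts                  # drop zero-width silences
    starts <- starts[keep]; ends <- ends[keep]; labels <- labels[keep]
    out <- c(out,
             sprintf("    item [%d]:", k),
             '        class = "IntervalTier"',
             paste0('        name = ',
                    tg_quote(paste0(ct$individual_id, "_", ct$sex))),
             "        xmin = 0",
             paste0("        xmax = ", tg_fmt(xmax)),
             paste0("        intervals: size = ", length(starts)))
    for (j in seq_along(starts)) {
      out <- c(out,
               sprintf("        intervals [%d]:", j),
               paste0("            xmin = ", tg_fmt(starts[j])),
               paste0("            xmax = ", tg_fmt(ends[j])),
               paste0("            text = ", tg_quote(labels[j])))
    }
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}
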