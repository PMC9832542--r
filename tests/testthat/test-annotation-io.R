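test_that("labelled intervals become notes, blanks are silence", {
  tg <- tempfile(fileext = ".TextGrid")
  ct <- make_contribution(c(0.5, 1.2), dur = 0.3, individual_id = "A")
  write_textgrid(list(ct), tg, xmax = 2.0)
  back <- read_textgrid(tg, tier_map = list(A_male = list(
    individual_id = "A", sex = "male", song_type = "male_solo")))
  expect_length(back, 1)
  expect_equal(back[[1]]$notes$onset, c(0.5, 1.2))
  expect_equal(back[[1]]$notes$offset, c(0.8, 1.5))
  # the written file alternates silence and notes over [0, xmax]
  txt <- readLines(tg)
  expect_equal(sum(grepl("intervals \\[", txt)), 5)  # sil,note,sil,note,sil
})

test_that("an all-blank tier yields an empty contribution and is flagged", {
  tg <- tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 2", "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:", '        class = "IntervalTier"',
    '        name = "B_female"', "        xmin = 0", "        xmax = 2",
    "        intervals: size = 1", "        intervals [1]:",
    "            xmin = 0", "            xmax = 2",
    '            text = "  "'), tg)
  out <- read_textgrid(tg)
  expect_equal(nrow(out[[1]]$notes), 0)
  expect_match(attr(out, "validation"), "no labelled intervals")
})

test_that("short-format and UTF-16 TextGrids parse identically to long UTF-8", {
  short <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", "3", "<exists>", "1",
             '"IntervalTier"', '"A_male"', "0", "3", "4",
             "0", "0.5", '""',
             "0.5", "0.9", '"hoo"',
             "0.9", "1.4", '""',
             "1.4", "2.1", '"hoo"')
  f_short <- tempfile(fileext = ".TextGrid")
  writeLines(short, f_short)
  ref <- read_textgrid(f_short)
  expect_equal(ref[[1]]$notes$onset, c(0.5, 1.4))
  expect_equal(ref[[1]]$notes$offset, c(0.9, 2.1))
  expect_equal(ref[[1]]$notes$label, c("hoo", "hoo"))

  # same annotation through the long-format writer
  f_long <- tempfile(fileext = ".TextGrid")
  write_textgrid(ref, f_long, xmax = 3)
  long <- read_textgrid(f_long)
  expect_equal(long[[1]]$notes, ref[[1]]$notes)

  # and as UTF-16LE with byte-order mark, as Praat emits on Windows
  txt <- paste(readLines(f_long), collapse = "\n")
  f16 <- tempfile(fileext = ".TextGrid")
  writeBin(c(as.raw(c(0xFF, 0xFE)),
             iconv(txt, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]),
           f16)
  u16 <- read_textgrid(f16)
  expect_equal(u16[[1]]$notes, ref[[1]]$notes)
})

test_that("TextGrid round-trip preserves times to 1e-9 s on synthetic duets", {
  song <- generate_duet(duet_scenario(), seed = 31)
  tg <- tempfile(fileext = ".TextGrid")
  write_textgrid(song$contributions, tg)
  back <- read_textgrid(tg, song_id = song$song_id)
  expect_length(back, 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$notes$onset, song$contributions[[k]]$notes$onset,
                 tolerance = 1e-9)
    expect_equal(back[[k]]$notes$offset, song$contributions[[k]]$notes$offset,
                 tolerance = 1e-9)
  }
  # and a second round through the writer parses to the same values
  tg2 <- tempfile(fileext = ".TextGrid")
  write_textgrid(back, tg2)
  back2 <- read_textgrid(tg2, song_id = song$song_id)
  expect_equal(back2[[1]]$notes$onset, back[[1]]$notes$onset, tolerance = 1e-9)
})

test_that("malformed and misconfigured TextGrids raise informative errors", {
  bad <- tempfile(fileext = ".TextGrid")
  writeLines(c("not a textgrid"), bad)
  expect_error(read_textgrid(bad), "line 1")

  num_bad <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
               "0", "oops", "<exists>", "0")
  f <- tempfile(fileext = ".TextGrid")
  writeLines(num_bad, f)
  expect_error(read_textgrid(f), "malformed")

  ok <- tempfile(fileext = ".TextGrid")
  write_textgrid(list(make_contribution(c(0.2, 0.8))), ok)
  expect_error(read_textgrid(ok, tier_map = list(
    ghost = list(individual_id = "X", sex = "male"))), "ghost")
})

test_that("overlapping notes within a tier are a validation error", {
  expect_error(
    contribution(song_id = "s", individual_id = "A", sex = "male",
                 song_type = "male_solo",
                 notes = note_intervals(c(0, 0.5), c(0.6, 1.0))),
    "overlapping notes")
  # abutting notes are accepted as distinct
  expect_silent(ct <- contribution(
    song_id = "s", individual_id = "A", sex = "male",
    song_type = "male_solo",
    notes = note_intervals(c(0, 0.5), c(0.5, 1.0))))
  expect_equal(n_notes(ct), 2)
})

test_that("onset CSV export has one row per note and round-trips exactly", {
  song <- generate_duet(duet_scenario(), seed = 12)
  solo <- generate_contribution(default_singer_params("male_solo"),
                                seed = 13, song_id = "solo_1",
                                individual_id = "M9", group_id = "g2")
  cts <- c(song$contributions, list(solo))
  csv <- tempfile(fileext = ".csv")
  tab <- export_onsets_csv(cts, csv)
  expect_equal(nrow(tab), sum(vapply(cts, n_notes, 0L)))
  expect_equal(names(tab), c("song_id", "individual_id", "group_id", "sex",
                             "song_type", "context", "onset_s", "offset_s"))
  # byte-identical re-export
  csv2 <- tempfile(fileext = ".csv")
  export_onsets_csv(cts, csv2)
  expect_identical(readLines(csv), readLines(csv2))
  # re-import reproduces every onset/offset exactly
  back <- read_onsets_csv(csv)
  back_tab <- export_onsets_csv(back)
  expect_equal(back_tab$onset_s, tab$onset_s)
  expect_equal(back_tab$offset_s, tab$offset_s)
})

test_that("song records enforce the duet composition rule", {
  f <- make_contribution(c(0, 1), song_id = "d", individual_id = "F",
                         sex = "female", song_type = "female_duet")
  m <- make_contribution(c(0.5, 1.5), song_id = "d", individual_id = "M",
                         sex = "male", song_type = "male_duet")
  expect_true(is_duet(song_record(list(f, m))))
  expect_error(song_record(list(f, f)), "female_duet")
  expect_error(song_record(list()), "no contributions")
  m2 <- make_contribution(c(0.5), song_id = "other", individual_id = "M",
                          sex = "male", song_type = "male_duet")
  expect_error(song_record(list(f, m2)), "different songs")
})
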