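test_that("IOI extraction applies the 5-s ceiling without bridging", {
  ct <- make_contribution(c(0.0, 0.2, 0.4, 6.0, 6.2), dur = 0.05)
  io <- extract_iois(ct)
  expect_equal(io$values, c(0.2, 0.2, 5.6, 0.2))
  expect_equal(io$kept, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(io$values[io$kept], c(0.2, 0.2, 0.2))

  expect_equal(extract_iois(c(0, 0.5))$values, 0.5)
  expect_warning(empty <- extract_iois(make_contribution(0.3)), "fewer than 2")
  expect_length(empty$values, 0)

  # metronome: all intervals equal the period
  per <- extract_iois(make_contribution(seq(0, 9.9, by = 0.33), dur = 0.05))
  expect_true(all(abs(per$values - 0.33) < 1e-12))
})

test_that("ratios are computed only across adjacent retained intervals", {
  expect_equal(compute_ratios(c(0.2, 0.2))$values, 0.5)
  expect_equal(compute_ratios(c(1.0, 3.0))$values, 0.25)

  # a masked gap breaks adjacency: no ratio spans it
  io <- extract_iois(c(0, 0.2, 0.4, 6.4, 6.6, 6.8))  # t = .2 .2 6.0 .2 .2
  r <- compute_ratios(io)
  expect_equal(r$values, c(0.5, 0.5))
  expect_equal(r$pair_index, c(1L, 4L))

  expect_length(compute_ratios(numeric(0))$values, 0)
  expect_length(compute_ratios(0.4)$values, 0)
})

test_that("ratio identities: reversal and scale invariance", {
  set.seed(41)
  for (rep in 1:20) {
    t_k <- runif(sample(5:40, 1), 0.05, 4.9)
    r_fwd <- compute_ratios(t_k)$values
    r_rev <- compute_ratios(rev(t_k))$values
    expect_equal(r_rev, rev(1 - r_fwd), tolerance = 1e-12)
    lam <- runif(1, 0.1, 10)
    expect_equal(compute_ratios(lam * t_k)$values, r_fwd, tolerance = 1e-12)
    cnt <- classify_ratios(r_fwd)
    cnt_s <- classify_ratios(compute_ratios(lam * t_k))
    expect_equal(cnt_s$on_count, cnt$on_count)
    expect_equal(cnt_s$off_count, cnt$off_count)
  }
})

test_that("band classification counts each ratio in exactly one sector", {
  b <- isochrony_boundaries()
  expect_equal(classify_ratios(0.5, b)$on_count, 1)
  c2 <- classify_ratios(c(0.42, 0.58), b)
  expect_equal(c2$on_count, 0)
  expect_equal(c2$off_count, 2)
  c3 <- classify_ratios(c(0.25, 0.75), b)
  expect_equal(c3$on_count + c3$off_count, 0)
  expect_equal(c3$total_ratios, 2)
  # endpoint rules: on-band closed, off-band owns outer endpoints only
  edges <- classify_ratios(c(0.400, 0.440, 0.555, 0.600, 0.3999, 0.6001), b)
  expect_equal(edges$on_count, 2)   # 0.440, 0.555
  expect_equal(edges$off_count, 2)  # 0.400, 0.600
  expect_error(isochrony_boundaries(0.5, 0.45, 0.55, 0.6), "outer_low")
})

test_that("isochrony rate is on/off and undefined at zero off-count", {
  expect_equal(isochrony_rate(classify_ratios(c(rep(0.5, 10),
                                                rep(0.43, 5))))$value, 2.0)
  r0 <- isochrony_rate(classify_ratios(rep(0.5, 7)))
  expect_false(r0$defined)
  expect_true(is.na(r0$value))
})

test_that("zero-jitter synthetic song is perfectly isochronous", {
  ct <- generate_contribution(
    singer_params(0.4, jitter_sd_s = 0, pause_prob = 0, n_notes = 60),
    seed = 5)
  r <- compute_ratios(extract_iois(ct))
  expect_true(all(abs(r$values - 0.5) < 1e-12))
  cnt <- classify_ratios(r)
  expect_equal(cnt$on_count, cnt$total_ratios)
  expect_equal(cnt$off_count, 0)
  expect_false(isochrony_rate(cnt)$defined)
})

test_that("call rate counts onsets per full window anchored at first onset", {
  ct8 <- make_contribution(seq(0, 9, length.out = 8), dur = 0.1)
  expect_warning(cr8 <- call_rate(ct8, 10), "shorter")  # span 9.1 s < 10 s
  expect_equal(nrow(cr8$chunks), 0)

  ct10 <- make_contribution(c(seq(0, 9, length.out = 8), 10.5), dur = 0.1)
  cr10 <- call_rate(ct10, 10)
  expect_equal(cr10$chunks$count, 8)
  expect_equal(cr10$chunks$rate, 0.8)

  # metronome at 1.3 s over 100 s: every full window holds 7 or 8 onsets
  met <- make_contribution(seq(0, 100, by = 1.3), dur = 0.1)
  crm <- call_rate(met, 10)
  expect_true(all(crm$chunks$count %in% c(7L, 8L)))
  expect_true(all(crm$chunks$rate %in% c(0.7, 0.8)))
})

test_that("median split labels chunks against the song-type median, ties low", {
  tab <- data.frame(rate = c(1, 2, 3), song_type = "male_solo")
  out <- median_split(tab)
  expect_equal(out$high_low, c("low", "low", "high"))
  all_eq <- median_split(data.frame(rate = rep(2, 5), song_type = "male_solo"))
  expect_true(all(all_eq$high_low == "low"))
  # invariance under row order
  tab2 <- data.frame(rate = c(5, 1, 4, 2, 8), song_type = "female_duet")
  perm <- sample(nrow(tab2))
  out1 <- median_split(tab2)$high_low
  out2 <- median_split(tab2[perm, , drop = FALSE])$high_low
  expect_equal(out2, out1[perm])
})

test_that("density peaks invert to tempi and recover a synthetic period", {
  ct <- generate_contribution(
    singer_params(0.322, jitter_sd_s = 0.005, pause_prob = 0, n_notes = 400),
    seed = 17)
  tp <- density_peaks(extract_iois(ct))
  expect_equal(nrow(tp$peaks), 1)
  expect_lt(abs(tp$peaks$peak_ioi - 0.322), tp$grid_step + 1e-12)
  expect_equal(tp$peaks$tempo * tp$peaks$peak_ioi, 1, tolerance = 1e-12)
  expect_error(density_peaks(numeric(0)), "no IOI")
  expect_warning(density_peaks(runif(10, 0.1, 0.5)), "fewer than 30")
})

test_that("rhythm tables join the stage outputs coherently", {
  song <- generate_duet(duet_scenario(), seed = 91)
  tabs <- rhythm_tables(song$contributions, window_s = 10)
  expect_equal(nrow(tabs$isochrony_table), 2)
  # every ratio is labelled and the isochrony tallies match the ratio table
  for (id in tabs$isochrony_table$individual_id) {
    rt <- tabs$ratio_table[tabs$ratio_table$individual_id == id, ]
    it <- tabs$isochrony_table[tabs$isochrony_table$individual_id == id, ]
    expect_equal(sum(rt$band == "on"), it$on_count)
    expect_equal(sum(rt$band == "off"), it$off_count)
    expect_equal(nrow(rt), it$total_ratios)
  }
  expect_true(all(tabs$callrate_table$high_low %in% c("high", "low")))
})
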