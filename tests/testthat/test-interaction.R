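test_that("binarization marks every bin with positive phonation overlap", {
  ct <- make_contribution(0, dur = 0.030)
  b <- binarize(ct, bin_s = 0.010, t0 = 0, t1 = 0.040)
  expect_equal(b$values, c(1L, 1L, 1L, 0L))

  ct2 <- contribution(song_id = "s1", individual_id = "A", sex = "male",
                      song_type = "male_solo",
                      notes = note_intervals(0.005, 0.012))
  b2 <- binarize(ct2, bin_s = 0.010, t0 = 0, t1 = 0.030)
  expect_equal(b2$values, c(1L, 1L, 0L))  # partial overlap counts

  empty <- contribution(song_id = "s1", individual_id = "A", sex = "male",
                        song_type = "male_solo",
                        notes = note_intervals(numeric(0), numeric(0),
                                               character(0)))
  expect_true(all(binarize(empty, 0.010, t0 = 0, t1 = 0.1)$values == 0))
})

test_that("align_pair puts both singers on one shared time base", {
  a <- make_contribution(c(0, 5), dur = 5, song_id = "d", sex = "female",
                         song_type = "female_duet")
  b <- make_contribution(c(5, 15), dur = 5, song_id = "d", sex = "male",
                         song_type = "male_duet", individual_id = "B")
  pair <- align_pair(a, b, bin_s = 0.010)
  expect_equal(pair[[1]]$t0, 0)
  expect_equal(length(pair[[1]]$values), 2000)   # [0, 20] at 10 ms
  expect_equal(length(pair[[1]]$values), length(pair[[2]]$values))

  same <- align_pair(a, a, bin_s = 0.010)
  expect_identical(same[[1]]$values, same[[2]]$values)

  b_other <- make_contribution(c(5, 15), dur = 5, song_id = "other",
                               sex = "male", song_type = "male_duet")
  expect_error(align_pair(a, b_other), "different songs")
})

test_that("Granger F matches brute-force nested OLS and lmtest", {
  set.seed(61)
  for (rep in 1:10) {
    x <- rbinom(50, 1, 0.4)
    y <- rbinom(50, 1, 0.4)
    g <- granger_direction(x, y, granger_spec(lag_order = 5))
    if (!is.na(g$flag)) next
    bf <- bf_granger(x, y, 5)
    expect_equal(g$f_stat, bf$f, tolerance = 1e-8)
    expect_equal(g$p_value, bf$p, tolerance = 1e-8)
    expect_equal(g$df_den, bf$df_den)
  }
  skip_if_not_installed("lmtest")
  set.seed(62)
  x <- rbinom(400, 1, 0.3)
  y <- as.integer(c(rbinom(3, 1, 0.3), head(x, -3)) | rbinom(400, 1, 0.05))
  g <- granger_direction(x, y, granger_spec(lag_order = 5))
  ref <- lmtest::grangertest(x = as.numeric(x), y = as.numeric(y), order = 5)
  expect_equal(g$f_stat, ref$F[2], tolerance = 1e-8)
  expect_equal(g$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("a lagged dependence is detected, and machinery is symmetric", {
  set.seed(63)
  x <- rbinom(5000, 1, 0.3)
  y <- as.integer(c(rep(0, 3), head(x, -3)) | rbinom(5000, 1, 0.02))
  fwd <- granger_direction(x, y, granger_spec(lag_order = 5))
  expect_lt(fwd$p_value, 0.001)
  # swapping source/target is the same computation with labels swapped
  s1 <- granger_direction(x, y, direction = "F_to_M")
  s2 <- granger_direction(y, x, direction = "M_to_F")
  s1_swap <- granger_direction(y, x, direction = "F_to_M")
  expect_equal(s2$f_stat, s1_swap$f_stat)
  expect_equal(s1$direction, "F_to_M")
})

test_that("degenerate designs are flagged, not thrown", {
  const <- rep(0L, 100)
  src <- rbinom(100, 1, 0.5)
  g <- granger_direction(src, const, granger_spec(5))
  expect_true(!is.na(g$flag))
  expect_true(is.na(g$p_value))
  short <- granger_direction(rbinom(8, 1, .5), rbinom(8, 1, .5),
                             granger_spec(5))
  expect_equal(short$flag, "too_short")
  expect_error(granger_direction(rbinom(10, 1, .5), rbinom(12, 1, .5)),
               "equal length")
})

test_that("max_len truncation mirrors the fixed-order analysis variant", {
  set.seed(64)
  x <- rbinom(2000, 1, 0.3)
  y <- as.integer(c(0, head(x, -1)) | rbinom(2000, 1, 0.05))
  full <- granger_direction(x, y, granger_spec(5))
  trunc <- granger_direction(x, y, granger_spec(5, max_len = 500))
  expect_equal(trunc$n_used, 495)
  ref <- granger_direction(x[1:500], y[1:500], granger_spec(5))
  expect_equal(trunc$f_stat, ref$f_stat)
  expect_false(isTRUE(all.equal(full$f_stat, trunc$f_stat)))
})

test_that("song classification follows the two-direction significance rule", {
  mk <- function(p) structure(list(p_value = p, flag = NA_character_),
                              class = "granger_result")
  expect_equal(classify_song(mk(1e-5), mk(1e-4))$class, "reciprocal")
  expect_equal(classify_song(mk(1e-5), mk(0.5))$class, "one_way")
  expect_equal(classify_song(mk(0.2), mk(0.9))$class, "none")
  flagged <- structure(list(p_value = NA_real_, flag = "degenerate"),
                       class = "granger_result")
  expect_equal(classify_song(mk(1e-5), flagged)$class, "one_way")
})

test_that("census proportions are coherent and respond to coupling", {
  fp <- singer_params(0.35, jitter_sd_s = 0.02, pause_prob = 0, n_notes = 100)
  mp <- singer_params(0.40, jitter_sd_s = 0.02, pause_prob = 0, n_notes = 100)
  mk_songs <- function(c, direction, n, seed0) lapply(seq_len(n), function(i)
    generate_duet(duet_scenario(female = fp, male = mp,
                                coupling = coupling_params(c, 0.05, direction),
                                song_id = sprintf("s%02d", i),
                                group_id = sprintf("g%02d", i)),
                  seed = seed0 + i))
  coupled <- causality_census(mk_songs(0.8, "bidirectional", 12, 700))
  expect_equal(sum(coupled$prop_class), 1)
  expect_gt(coupled$prop_class[["reciprocal"]], 0.9)
  indep <- causality_census(mk_songs(0, "none", 12, 800))
  expect_equal(sum(indep$prop_class), 1)
  expect_lt(indep$prop_significant[["overall"]], 0.2)
  expect_equal(nrow(coupled$table), 24)   # two directions per song
})

test_that("census honours the wild-only restriction", {
  fp <- singer_params(0.35, jitter_sd_s = 0.02, pause_prob = 0, n_notes = 80)
  mp <- singer_params(0.40, jitter_sd_s = 0.02, pause_prob = 0, n_notes = 80)
  songs <- lapply(1:4, function(i) generate_duet(
    duet_scenario(female = fp, male = mp,
                  coupling = coupling_params(0.8, 0.05, "bidirectional"),
                  song_id = sprintf("s%d", i),
                  context = if (i <= 2) "wild" else "captive"),
    seed = 900 + i))
  wild <- causality_census(songs, wild_only = TRUE)
  expect_equal(wild$n_songs, 2)
  all_ctx <- causality_census(songs, wild_only = FALSE)
  expect_equal(all_ctx$n_songs, 4)
})
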