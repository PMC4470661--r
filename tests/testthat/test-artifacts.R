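test_that("maternal-movement masking: worked examples", {
  # no MM events: everything retained
  fm <- make_events(c(100, 200), c(1.5, 1))
  out <- mask_maternal_movement(fm, make_events(numeric(0), numeric(0)))
  expect_equal(out$status, c("accepted", "accepted"))

  # direct overlap
  fm <- make_events(100, 1.5)                 # [100, 101.5)
  mm <- make_events(100.5, 2.5, channel = "MM")  # [100.5, 103)
  out <- mask_maternal_movement(fm, mm)
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "maternal_movement")

  # overlap only through the +/- 1 s guard: dilated MM starts at 100.2
  fm <- make_events(100, 0.5)                 # [100, 100.5)
  mm <- make_events(101.2, 0.8, channel = "MM")
  expect_equal(mask_maternal_movement(fm, mm, guard_s = 1.0)$status, "rejected")
  expect_equal(mask_maternal_movement(fm, mm, guard_s = 0.5)$status, "accepted")

  # rejected MM events do not mask
  mm$status <- "rejected"; mm$reason <- "edge_transient"
  expect_equal(mask_maternal_movement(fm, mm, guard_s = 1.0)$status, "accepted")
})

test_that("interval-intersection masking matches a brute-force oracle", {
  set.seed(21)
  for (i in 1:20) {
    fm <- random_events(40, total_s = 1800)
    mm <- random_events(15, total_s = 1800, channel = "MM")
    fm$status <- "accepted"; fm$reason <- ""
    out <- mask_maternal_movement(fm, mm, guard_s = 1.0)
    mma <- mm[mm$status == "accepted", ]
    for (j in seq_len(nrow(fm))) {
      ref <- any(fm$start_s[j] < mma$end_s + 1 & mma$start_s - 1 < fm$end_s[j])
      expect_identical(out$status[j] == "rejected", ref)
    }
  }
})

test_that("PLM runs: worked examples and brute-force equivalence", {
  # 5 events of 1.2 s at 30-s onset intervals -> one run of 5
  mm <- make_events(seq(100, by = 30, length.out = 5), rep(1.2, 5), channel = "MM")
  runs <- detect_plm(mm)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_movements, 5L)

  # 3 qualifying events: below the minimum run length of 4
  mm3 <- make_events(seq(100, by = 30, length.out = 3), rep(1.2, 3), channel = "MM")
  expect_equal(nrow(detect_plm(mm3)), 0L)

  # 6 events at 3-s intervals: interval below 5 s, no run
  mm6 <- make_events(seq(100, by = 3, length.out = 6), rep(1.2, 6), channel = "MM")
  expect_equal(nrow(detect_plm(mm6)), 0L)

  # durations outside [1, 5] s never qualify
  mmd <- make_events(seq(100, by = 30, length.out = 5), rep(0.8, 5), channel = "MM")
  expect_equal(nrow(detect_plm(mmd)), 0L)

  # randomized equivalence with the naive maximal-subsequence oracle
  set.seed(31)
  for (i in 1:20) {
    mm <- random_events(25, total_s = 2400, channel = "MM")
    mm$end_s <- mm$start_s + round(runif(25, 0.3, 6) / 0.05) * 0.05
    got <- detect_plm(mm)
    ref <- brute_plm_runs(mm)
    expect_equal(nrow(got), length(ref))
    if (length(ref)) {
      expect_equal(got$n_movements, lengths(ref))
      expect_equal(unlist(got$members), unlist(ref))
    }
  }
})

test_that("mask_plm rejects FM events near run members", {
  mm <- make_events(seq(100, by = 30, length.out = 5), rep(1.2, 5), channel = "MM")
  runs <- detect_plm(mm)
  fm <- make_events(c(130.5, 115), c(0.5, 0.5))  # near member 2; far from all
  out <- mask_plm(fm, runs, mm, guard_s = 1.0)
  out <- out[order(out$start_s), ]
  expect_equal(out$status, c("accepted", "rejected"))
  expect_equal(out$reason, c("", "plm"))
})

test_that("wake and restroom classification: worked examples", {
  # 3 MM events in a minute: not wake
  mm <- make_events(c(70, 90, 110), rep(1, 3), channel = "MM")
  m <- classify_wake_and_restroom(mm, total_s = 3600)
  expect_equal(nrow(m), 0L)
  expect_equal(analysis_time(m), 3600)

  # no MM events at all
  m0 <- classify_wake_and_restroom(make_events(numeric(0), numeric(0), channel = "MM"),
                                   total_s = 3600)
  expect_equal(analysis_time(m0), 3600)

  # 4 events in one minute: that minute is wake
  mm4 <- make_events(c(63, 75, 90, 110), rep(1, 4), channel = "MM")
  m4 <- classify_wake_and_restroom(mm4, total_s = 3600)
  expect_equal(as.data.frame(m4),
               data.frame(start_s = 60, end_s = 120, reason = "wake",
                          stringsAsFactors = FALSE))
  expect_equal(analysis_time(m4), 3540)

  # 7 consecutive wake minutes -> one 420-s restroom interval
  on <- unlist(lapply(0:6, function(m) 300 + m * 60 + c(5, 20, 35, 50, 55)))
  mm7 <- make_events(on, rep(1, length(on)), channel = "MM")
  m7 <- classify_wake_and_restroom(mm7, total_s = 3600)
  expect_equal(as.data.frame(m7),
               data.frame(start_s = 300, end_s = 720, reason = "restroom",
                          stringsAsFactors = FALSE))
  expect_equal(analysis_time(m7), 3600 - 420)
})

test_that("wake/restroom per-minute counting matches brute force", {
  set.seed(41)
  for (i in 1:10) {
    mm <- random_events(60, total_s = 1800, channel = "MM")
    m <- classify_wake_and_restroom(mm, total_s = 1800)
    acc <- mm[mm$status == "accepted", ]
    for (minute in 0:29) {
      cnt <- sum(acc$start_s >= minute * 60 & acc$start_s < (minute + 1) * 60)
      in_mask <- nrow(m) > 0 &&
        any(m$start_s <= minute * 60 & (minute + 1) * 60 <= m$end_s)
      expect_identical(in_mask, cnt >= 4)
    }
  }
})

test_that("hiccup bouts: worked examples", {
  total <- 3600
  # 30 candidates at 2-s spacing inside one minute -> 1 bout, minute excluded
  fm <- make_events(seq(120, by = 2, length.out = 30), rep(0.3, 30))
  res <- detect_hiccup_bouts(fm, total)
  expect_equal(nrow(res$bouts), 1L)
  expect_equal(res$bouts$start_s, 120)
  expect_equal(res$bouts$n_signals, 30L)
  expect_true(all(res$fm_events$reason == "hiccup"))

  # 10 events in a minute: below the >15/min rule
  fm10 <- make_events(seq(120, by = 5, length.out = 10), rep(0.3, 10))
  expect_equal(nrow(detect_hiccup_bouts(fm10, total)$bouts), 0L)

  # exactly 16/min sustained 10 minutes -> one 600-s bout, 160 rejections
  on <- unlist(lapply(0:9, function(m) 600 + m * 60 + seq(0, by = 3.7, length.out = 16)))
  fm16 <- make_events(on, rep(0.3, length(on)))
  res16 <- detect_hiccup_bouts(fm16, total)
  expect_equal(nrow(res16$bouts), 1L)
  expect_equal(res16$bouts$end_s - res16$bouts$start_s, 600)
  expect_equal(sum(res16$fm_events$reason == "hiccup"), 160L)

  # sub-0.2-s events are not hiccup candidates
  fms <- make_events(seq(120, by = 2, length.out = 30), rep(0.1, 30))
  expect_equal(nrow(detect_hiccup_bouts(fms, total)$bouts), 0L)
})

test_that("rejection cascade conserves events, applies one reason, in precedence order", {
  set.seed(51)
  for (i in 1:8) {
    fm <- random_events(50, total_s = 1800)
    fm$status <- "accepted"; fm$reason <- ""
    mm <- random_events(30, total_s = 1800, channel = "MM")
    res <- apply_artifact_rejection(fm, mm, total_s = 1800, cfg = fm_config())
    out <- res$fm_events
    # conservation
    expect_equal(nrow(out), nrow(fm))
    expect_equal(sum(out$status == "accepted") + sum(out$status == "rejected"),
                 nrow(fm))
    # exactly one reason per rejected event; none on accepted
    expect_true(all(out$reason[out$status == "rejected"] != ""))
    expect_true(all(out$reason[out$status == "accepted"] == ""))
    # precedence: an event inside a wake interval is never labeled
    # maternal_movement/plm/hiccup
    wr <- res$mask[res$mask$reason %in% c("wake", "restroom"), ]
    if (nrow(wr)) {
      inside <- vapply(seq_len(nrow(out)), function(j) {
        any(out$start_s[j] < wr$end_s & wr$start_s < out$end_s[j])
      }, logical(1))
      expect_true(all(out$reason[inside] == "wake"))
    }
  }
})

test_that("rejection is monotone in the MM channel", {
  set.seed(61)
  fm <- random_events(40, total_s = 1800)
  fm$status <- "accepted"; fm$reason <- ""
  mm_small <- random_events(10, total_s = 1800, channel = "MM")
  mm_big <- rbind(mm_small, random_events(20, total_s = 1800, channel = "MM"))
  mm_big <- mm_big[order(mm_big$start_s), ]
  r1 <- mask_maternal_movement(fm, mm_small)
  r2 <- mask_maternal_movement(fm, mm_big)
  expect_true(all(which(r1$status == "rejected") %in% which(r2$status == "rejected")))
})
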