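test_that("synchronising an already-uniform stream is the identity", {
  ch <- matrix(rnorm(300), ncol = 3,
               dimnames = list(NULL, c("x", "y", "z")))
  rec <- raw_recording(seq(0, by = 20, length.out = 100), ch)
  s <- synchronise(rec, rate = 50)
  expect_equal(s$channels[, "x"], ch[, "x"], ignore_attr = TRUE)
  expect_equal(s$channels[, "z"], ch[, "z"], ignore_attr = TRUE)
  expect_equal(diff(s$time_s), rep(0.02, 99), tolerance = 1e-12)
})

test_that("interpolation error on a jittered sinusoid stays below 1%", {
  withr::with_seed(21, {
    n <- 400
    ts_ms <- (seq_len(n) - 1) * 20 + runif(n, -2, 2)
    ts_ms <- sort(ts_ms) # keep strictly increasing
    ts_ms <- ts_ms + seq_len(n) * 1e-6
    amp <- 2.5
    f <- 1.5
    sig <- amp * sin(2 * pi * f * ts_ms / 1000)
    rec <- raw_recording(ts_ms, cbind(x = sig, y = 0 * sig, z = sig))
    s <- synchronise(rec, rate = 50)
    truth <- amp * sin(2 * pi * f * s$time_s)
    expect_lt(max(abs(s$channels[, "x"] - truth)), 0.01 * amp)
  })
})

test_that("disjoint streams and degenerate inputs are rejected", {
  r1 <- raw_recording(c(0, 20, 40), matrix(1, 3, 3))
  r2 <- raw_recording(c(1000, 1020), matrix(1, 2, 3))
  expect_error(synchronise(list(r1, r2)), "overlap")
  expect_error(synchronise(raw_recording(0, matrix(1, 1, 3))),
               "at least 2")
})

test_that("markers map to the first synced sample at or after them", {
  rec <- raw_recording(seq(0, by = 20, length.out = 200),
                       matrix(rnorm(600), ncol = 3))
  s <- synchronise(rec, rate = 50)
  mm <- map_markers(trial_markers(10, 150), rec$timestamps_ms, s)
  # identical axes -> identical indices
  expect_equal(mm$i_start, 10L)
  expect_equal(mm$i_stop, 150L)

  # hand-worked fixture: marker time 0.03 s falls between synced samples
  # at 0.02 and 0.04 -> the next sample (index 3) is chosen
  rec2 <- raw_recording(c(0, 30, 200), matrix(0, 3, 3))
  s2 <- synchronise(rec2, rate = 50)
  mm2 <- map_markers(trial_markers(2, 3), rec2$timestamps_ms, s2)
  expect_equal(mm2$i_start, 3L)
  expect_equal(s2$time_s[mm2$i_start], 0.04)

  expect_error(map_markers(trial_markers(10, 500), rec$timestamps_ms, s),
               "exceeds")
})

test_that("gravity offset shifts z only, and is plain subtraction", {
  s <- structure(list(rate = 50, time_s = seq(0, 1, by = 0.02),
                      channels = cbind(x = rep(1, 51), y = rep(2, 51),
                                       z = rep(9.81, 51))),
                 class = "synced_recording")
  g <- gravity_offset(s)
  expect_equal(g$channels[, "z"], rep(0, 51), ignore_attr = TRUE)
  expect_identical(g$channels[, "x"], s$channels[, "x"])
  expect_identical(g$channels[, "y"], s$channels[, "y"])
  # applying twice shifts the original 9.81 by -19.62 to -9.81:
  # plain arithmetic, no idempotence claimed
  g2 <- gravity_offset(g)
  expect_equal(unique(g2$channels[, "z"]), 9.81 - 19.62)
})

test_that("periodicity scores reflect signal structure", {
  mk_synced <- function(z) {
    n <- length(z)
    structure(list(rate = 50, time_s = (seq_len(n) - 1) / 50,
                   channels = cbind(x = numeric(n), y = numeric(n),
                                    z = z)),
              class = "synced_recording")
  }
  t <- (0:999) / 50
  pure <- mk_synced(sin(2 * pi * 1.8 * t))
  ps <- periodicity_profile(pure)
  expect_true(all(ps$scores > 0.9))
  expect_true(all(ps$scores <= 1 + 1e-9))

  withr::with_seed(5, {
    noise <- mk_synced(rnorm(1000))
    pn <- periodicity_profile(noise)
    expect_true(all(pn$scores < 0.4))
    expect_length(pn$peak_locations, 0L)
  })

  # sinusoid with stationary pads: valid peaks only inside the active part
  withr::with_seed(6, {
    pad <- rnorm(150, 0, 0.01)
    act <- sin(2 * pi * 1.8 * (0:999) / 50)
    padded <- mk_synced(c(pad, act, pad))
    pp <- periodicity_profile(padded)
    centres <- pp$window_centres[pp$peak_locations]
    expect_gt(length(centres), 0L)
    expect_true(all(centres > 150 - 64 & centres < 150 + 1000 + 64))
  })

  expect_error(periodicity_profile(mk_synced(rnorm(50))), "window longer")
})

test_that("steady-segment extraction trims the configured patterns", {
  # 20 evenly spaced peaks, n_trim = 3 -> segment spans peaks 4..17
  centres <- seq(100, by = 50, length.out = 20)
  prof <- structure(list(window_centres = centres,
                         scores = rep(0.9, 20),
                         peak_locations = 1:20),
                    class = "periodicity_profile")
  synced <- structure(list(rate = 50, time_s = (0:1199) / 50,
                           channels = matrix(rnorm(3600), ncol = 3,
                                             dimnames = list(NULL,
                                                             c("x", "y", "z")))),
                      class = "synced_recording")
  seg <- extract_steady_segment(synced, prof, n_trim = 3, label = "none")
  expect_equal(unname(seg$bounds["start"]), centres[4])
  expect_equal(unname(seg$bounds["stop"]), centres[17])
  expect_equal(nrow(seg$values), centres[17] - centres[4] + 1)

  # constant signal: no peaks anywhere -> no-steady-gait error
  const <- structure(list(rate = 50, time_s = (0:999) / 50,
                          channels = matrix(1, 1000, 3,
                                            dimnames = list(NULL,
                                                            c("x", "y", "z")))),
                     class = "synced_recording")
  cp <- periodicity_profile(const)
  expect_error(extract_steady_segment(const, cp), "no steady gait")
})

test_that("extracted segments exclude the stationary pads", {
  tr <- simulate_traversal(flat_participant(), profile_for("green"),
                           length = 2500, pad_duration = 2, seed = 77)
  seg <- preprocess_traversal(tr$recording, tr$markers, label = tr$label)
  pad_idx <- c(seq_len(tr$truth$active_start - 1L),
               (tr$truth$active_stop + 1L):
                 length(tr$recording$timestamps_ms))
  seg_idx <- seg$bounds["start"]:seg$bounds["stop"]
  overlap <- length(intersect(seg_idx, pad_idx))
  expect_lte(overlap, 0.05 * length(pad_idx))
  # and the segment lies inside the true active region
  expect_gte(unname(seg$bounds["start"]), tr$truth$active_start)
  expect_lte(unname(seg$bounds["stop"]), tr$truth$active_stop)
})

test_that("periodicity is invariant to constant channel offsets", {
  tr <- simulate_traversal(flat_participant(), profile_for("none"),
                           length = 1500, seed = 13)
  synced <- synchronise(tr$recording)
  p1 <- periodicity_profile(synced)
  shifted <- synced
  shifted$channels <- sweep(shifted$channels, 2, c(3, -2, 9.81), `+`)
  p2 <- periodicity_profile(shifted)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
})
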