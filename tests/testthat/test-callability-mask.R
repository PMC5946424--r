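test_that("EWMA follows the recursion s[t] = a*x[t] + (1-a)*s[t-1]", {
  expect_equal(compute_ewma(c(0, 10, 10), 0.5), c(0, 5, 7.5))
  expect_equal(compute_ewma(rep(12, 50), 0.123), rep(12, 50))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(compute_ewma(x, 1), x)
  # direct hand recursion at arbitrary alpha
  s <- x[1]
  for (t in 2:length(x)) s[t] <- 0.3 * x[t] + 0.7 * s[t - 1]
  expect_equal(compute_ewma(x, 0.3), s)
  expect_error(compute_ewma(x, 0), "alpha")
  expect_error(compute_ewma(x, 1.5), "alpha")
  expect_error(compute_ewma(numeric(0), 0.5), "non-empty")
})

test_that("MQ0 ratio handles zero depth and saturation", {
  tr <- position_track(0:2, raw_depth = c(50, 0, 30), mq0 = c(5, 0, 30))
  expect_equal(mq0_ratio(tr), c(0.10, 0, 1.0))
})

test_that("position_track validates its invariants", {
  expect_error(position_track(c(0, 2), c(1, 1), c(0, 0)), "contiguous")
  expect_error(position_track(0:1, c(1, 1), c(2, 0)), "mq0")
  expect_error(position_track(integer(0), numeric(0), numeric(0)),
               "non-empty")
})

test_that("uniform tracks give a single pass or fail interval", {
  tr <- position_track(0:99, rep(20, 100), rep(0, 100))
  thr <- mask_thresholds(depth_min = 10, depth_max = 30)
  m <- build_region_mask(tr, thr)
  expect_equal(nrow(m), 1L)
  expect_equal(m$status, "pass")
  expect_equal(c(m$start, m$end), c(0L, 100L))

  tr2 <- position_track(0:99, rep(20, 100), rep(10, 100),
                        filtered_depth = rep(20, 100))
  m2 <- build_region_mask(tr2, thr)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$status, "fail")
  expect_equal(m2$reason, "mq0_ratio")
})

test_that("mask intervals exactly tile the analyzed range", {
  set.seed(11)
  tr <- position_track(0:999, rpois(1000, 20), rbinom(1000, 5, 0.3))
  m <- build_region_mask(tr, mask_thresholds(depth_min = 10, depth_max = 30,
                                             ewma_alpha = 0.05))
  expect_equal(m$start[1], 0L)
  expect_equal(m$end[nrow(m)], 1000L)
  if (nrow(m) > 1) expect_equal(m$start[-1], m$end[-nrow(m)])
  expect_length(mask_status_by_position(m), 1000L)
})

test_that("with alpha=1 the mask equals the positionwise threshold oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- position_track(0:499, rpois(500, 15), rbinom(500, 15, 0.1))
    thr <- mask_thresholds(depth_min = 8, depth_max = 25,
                           mq0_ratio_max = 0.10, ewma_alpha = 1,
                           min_region_len = 1)
    m <- build_region_mask(tr, thr)
    expect_identical(mask_status_by_position(m),
                     oracle_mask_positions(tr, 8, 25, 0.10))
  }
})

test_that("excluded intervals fail with reason excluded", {
  tr <- position_track(0:99, rep(20, 100), rep(0, 100))
  m <- build_region_mask(tr, mask_thresholds(depth_min = 10, depth_max = 30),
                         excluded = data.frame(start = 40, end = 60))
  excl <- m[m$reason == "excluded", ]
  expect_equal(c(excl$start, excl$end), c(40L, 60L))
  expect_equal(sum(mask_status_by_position(m)), 80L)
})

test_that("short pass runs are demoted to the nearest violated filter", {
  # fail / 3bp pass / fail, with min_region_len 5: everything fails
  fd <- c(rep(1, 10), rep(20, 3), rep(1, 10))
  tr <- position_track(0:22, fd + 2, rep(2, 23), filtered_depth = fd)
  thr <- mask_thresholds(depth_min = 10, depth_max = 30, ewma_alpha = 1,
                         min_region_len = 5)
  m <- build_region_mask(tr, thr)
  expect_equal(nrow(m), 1L)
  expect_equal(m$status, "fail")
  expect_equal(m$reason, "depth")
})

test_that("synthetic amplicons are recovered by the mask", {
  cfg <- sim_config(seed = 3)
  track <- simulate_tracks(cfg)
  m <- build_region_mask(track)
  fail <- m[m$status == "fail", ]
  amp <- data.frame(start = 40000, end = 60000)
  expect_gte(interval_jaccard(fail, amp), 0.9)
  # the fail set covers >= 90% of the amplicon (EWMA edge blur allowed)
  cov <- sum(pmax(0, pmin(fail$end, amp$end) - pmax(fail$start, amp$start)))
  expect_gte(cov / (amp$end - amp$start), 0.9)
  expect_true(all(fail$reason %in% c("depth", "mq0_ratio")))
})

test_that("relaxing thresholds never shrinks the pass set", {
  set.seed(21)
  tr <- position_track(0:1999, rpois(2000, 15), rbinom(2000, 15, 0.08))
  base <- mask_thresholds(depth_min = 10, depth_max = 22,
                          mq0_ratio_max = 0.08, ewma_alpha = 0.02)
  p0 <- mask_status_by_position(build_region_mask(tr, base))
  wider_mq0 <- mask_thresholds(depth_min = 10, depth_max = 22,
                               mq0_ratio_max = 0.2, ewma_alpha = 0.02)
  p1 <- mask_status_by_position(build_region_mask(tr, wider_mq0))
  expect_true(all(p1[p0]))
  wider_depth <- mask_thresholds(depth_min = 5, depth_max = 30,
                                 mq0_ratio_max = 0.08, ewma_alpha = 0.02)
  p2 <- mask_status_by_position(build_region_mask(tr, wider_depth))
  expect_true(all(p2[p0]))
})

test_that("mask concordance counts position-level agreement", {
  tr <- position_track(0:999, rpois(1000, 20), rbinom(1000, 5, 0.2))
  thr <- mask_thresholds(depth_min = 10, depth_max = 30, ewma_alpha = 0.1)
  m <- build_region_mask(tr, thr)
  expect_equal(mask_concordance(m, m), 1.0)

  a <- structure(data.frame(start = 0L, end = 100L, status = "pass",
                            reason = "none"),
                 range = c(0L, 100L), class = c("region_mask", "data.frame"))
  b <- structure(data.frame(start = 0L, end = 100L, status = "fail",
                            reason = "depth"),
                 range = c(0L, 100L), class = c("region_mask", "data.frame"))
  expect_equal(mask_concordance(a, b), 0.0)
  c10 <- structure(
    data.frame(start = c(0L, 10L), end = c(10L, 100L),
               status = c("fail", "pass"), reason = c("depth", "none")),
    range = c(0L, 100L), class = c("region_mask", "data.frame"))
  expect_equal(mask_concordance(a, c10), 0.9)
  bad <- structure(data.frame(start = 0L, end = 50L, status = "pass",
                              reason = "none"),
                   range = c(0L, 50L), class = c("region_mask", "data.frame"))
  expect_error(mask_concordance(a, bad), "same range")
})
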