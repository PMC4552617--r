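# Burst classification, peak alignment and phase segmentation.

test_that("burst classes follow the epoch rule", {
  set.seed(36)
  t <- seq(0, 180, by = 5)
  noise <- rnorm(length(t), 0, 1)
  expect_identical(classifyBursts(noise), "none")
  single <- 100 * exp(-(t - 90)^2 / (2 * 15^2)) + rnorm(length(t), 0, 2)
  expect_identical(classifyBursts(single), "single")
  double <- 100 * exp(-(t - 60)^2 / (2 * 10^2)) +
    90 * exp(-(t - 140)^2 / (2 * 10^2)) + rnorm(length(t), 0, 2)
  # oracle: direct run-length scan over the 50% threshold
  above <- double > 0.5 * max(double)
  expect_identical(sum(rle(above)$values), 2L)
  expect_identical(classifyBursts(double), "multiple")
})

test_that("classification accuracy on a mixed population exceeds 90%", {
  set.seed(37)
  t <- seq(0, 180, by = 5)
  mk <- function(kind) {
    switch(kind,
      none = rnorm(length(t), 0, 1),
      single = 80 * exp(-(t - runif(1, 70, 120))^2 / (2 * 12^2)) +
        rnorm(length(t), 0, 3),
      multiple = 80 * exp(-(t - 55)^2 / (2 * 8^2)) +
        70 * exp(-(t - runif(1, 120, 150))^2 / (2 * 8^2)) +
        rnorm(length(t), 0, 3))
  }
  kinds <- rep(c("none", "single", "multiple"), each = 20)
  got <- vapply(kinds, function(k) classifyBursts(mk(k)), character(1))
  expect_gte(mean(got == kinds), 0.9)
})

test_that("peak alignment centers, averages and is idempotent", {
  t <- seq(0, 100, by = 5)
  shape <- exp(-(t - 40)^2 / (2 * 10^2))
  trajs <- lapply(c(0, 10, 25), function(s)
    data.frame(time = t, value = exp(-(t - 40 - s)^2 / (2 * 10^2))))
  al <- alignToPeak(trajs)
  expect_equal(al$times[which.max(al$mean)], 0)
  # identical shifted copies: the mean equals the common shape
  common <- al$times >= -35 & al$times <= 35
  ref <- exp(-al$times[common]^2 / (2 * 10^2))
  expect_equal(al$mean[common], ref, tolerance = 1e-9)
  # single trajectory: its own peak lands at zero
  one <- alignToPeak(trajs[1])
  expect_equal(one$times[which.max(one$mean)], 0)
  # idempotence: re-aligning the aligned trajectories changes nothing
  aligned <- lapply(seq_along(trajs), function(i)
    data.frame(time = al$times[!is.na(al$matrix[i, ])],
               value = al$matrix[i, !is.na(al$matrix[i, ])]))
  al2 <- alignToPeak(aligned)
  expect_equal(al2$mean, al$mean, tolerance = 1e-12)
})

test_that("alignment sharpens the mean peak by at least the onset jitter", {
  set.seed(38)
  t <- seq(0, 300, by = 5)
  peaks <- 150 + rnorm(120, 0, 30)
  trajs <- lapply(peaks, function(peak)
    data.frame(time = t, value = 100 * exp(-(t - peak)^2 / (2 * 10^2)) +
                 rnorm(length(t), 0, 1)))
  fwhm <- function(tt, v) {
    above <- tt[v > max(v) / 2]
    max(above) - min(above)
  }
  unaligned <- rowMeans(vapply(trajs, function(tr) tr$value,
                               numeric(length(t))))
  al <- alignToPeak(trajs)
  wU <- fwhm(t, unaligned)
  wA <- fwhm(al$times, al$mean)
  expect_gt(wU - wA, sd(peaks))
})

test_that("phase segmentation has closed-form boundaries on a triangle", {
  t <- seq(0, 100, by = 5)
  tri <- pmax(0, ifelse(t <= 60, t / 60, (100 - t) / 40)) * 50
  ph <- phaseSegments(t, tri, riseFrac = 0.2)
  expect_equal(ph$tRise, 15)       # first point above 0.2 * 50 = 10
  expect_equal(ph$tPeak, 60)
  expect_false(ph$flagged)
  expect_identical(ph$phaseIII, which(t > 60))
  # monotone trace: empty phase III, flagged
  mono <- phaseSegments(t, t, riseFrac = 0.2)
  expect_true(mono$flagged)
  expect_identical(mono$phaseIII, integer(0))
  zero <- phaseSegments(t, rep(0, length(t)))
  expect_true(zero$flagged)
  expect_identical(zero$phaseII, integer(0))
})
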