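test_that("baseline subtraction zeroes the minimum and keeps shape", {
  tr <- grooveprint:::new_trace(1:3, c(5, 3, 8))
  out <- subtract_baseline(tr)
  expect_equal(out$intensity, c(2, 0, 5))
  flat <- subtract_baseline(grooveprint:::new_trace(1:3, c(7, 7, 7)))
  expect_equal(flat$intensity, c(0, 0, 0))
  expect_error(subtract_baseline(grooveprint:::new_trace(numeric(0),
                                                         numeric(0))),
               "empty")
})

test_that("ladder peak detection finds apexes, leftmost on plateaus", {
  x <- 1:200
  g <- function(c, w, a = 100) a * exp(-0.5 * ((x - c) / w)^2)
  one <- grooveprint:::new_trace(x, g(60, 4))
  expect_equal(detect_ladder_peaks(one, 0.1), 60)
  two <- grooveprint:::new_trace(x, g(50, 4) + g(150, 4, 80))
  expect_equal(detect_ladder_peaks(two, 0.1), c(50, 150))
  # flat-topped peak reports its leftmost sample (raw detection)
  y <- g(60, 4); y[58:62] <- max(y)
  expect_equal(detect_ladder_peaks(grooveprint:::new_trace(x, y), 0.1,
                                   smooth_pts = 1),
               58)
})

test_that("simulated ladder peaks are detected within one data point", {
  s <- make_sim(seq_len = 220, frag_min = 10, frag_max = 200,
                ladder_step = 10, noise_add = 2)  # SNR 50 on amp 100
  lad <- simulate_trace(s$spec, "ladder")
  centers <- detect_ladder_peaks(subtract_baseline(lad$trace), 0.1)
  expect_length(centers, length(s$spec$ladder))
  expect_lte(max(abs(centers - lad$truth$center)), 1)
  # assignment pairs i-th center with i-th length
  asn <- assign_ladder(centers, s$spec$ladder)
  expect_equal(asn$fragment_length, sort(s$spec$ladder))
  expect_lte(max(abs(asn$center - lad$truth$center)), 1)
})

test_that("ladder assignment refuses count mismatches", {
  expect_equal(assign_ladder(c(100, 200), c(50, 60)),
               data.frame(fragment_length = c(50L, 60L),
                          center = c(100, 200)))
  expect_error(assign_ladder(c(100, 200), c(50, 60, 70)), "2.*3")
})

test_that("noiseless ladder fit recovers parameters and width trend", {
  s <- make_sim(seq_len = 220, frag_min = 10, frag_max = 200,
                ladder_step = 10)
  lad <- simulate_trace(s$spec, "ladder")
  lt <- subtract_baseline(lad$trace)
  centers <- detect_ladder_peaks(lt, 0.1)
  fit <- fit_ladder(lt, assign_ladder(centers, s$spec$ladder))
  rel <- function(a, b) max(abs(a - b) / abs(b))
  expect_lt(rel(fit$peaks$amplitude, lad$truth$amplitude), 1e-3)
  expect_lt(rel(fit$peaks$center, lad$truth$center), 1e-3)
  expect_lt(rel(fit$peaks$width, lad$truth$width), 1e-3)
  # widths were generated as w = width0 + width1 * c
  cf <- coef(fit$width_fit)
  expect_equal(unname(cf[1]), s$spec$width0, tolerance = 0.01)
  expect_equal(unname(cf[2]), s$spec$width1, tolerance = 0.01)
})

test_that("a single ladder peak cannot support the width regression", {
  x <- 1:200
  tr <- grooveprint:::new_trace(x, 100 * exp(-0.5 * ((x - 80) / 4)^2))
  expect_error(fit_ladder(tr, data.frame(fragment_length = 50L,
                                         center = 80)),
               "at least 3")
})

test_that("peak initialization interpolates centers and reads amplitudes", {
  # synthetic ladder fit: centers 1000/1100 at lengths 100/110
  lp <- data.frame(fragment_length = c(100L, 105L, 110L),
                   center = c(1000, 1050, 1100),
                   amplitude = 50, width = c(3, 3.05, 3.1))
  wf <- lm(width ~ center, data = lp)
  x <- 900:1200
  y <- rep(10, length(x)); y[x == 1050] <- 37.2
  tr <- grooveprint:::new_trace(x, y)
  lad_fit <- list(peaks = lp, width_fit = wf)
  init <- initialize_peaks(tr, lad_fit, c(100L, 105L))
  expect_equal(init$center, c(1000, 1050))
  expect_equal(init$amplitude[2], 37.2)
  expect_equal(init$width, unname(predict(
    wf, newdata = data.frame(center = c(1000, 1050)))))
  # no extrapolation beyond the ladder span
  expect_error(initialize_peaks(tr, lad_fit, 95L), "outside ladder span")
})

test_that("three-pass fit recovers a noiseless 50-peak trace to 1e-3", {
  s <- make_sim(seq_len = 60, frag_min = 5, frag_max = 54,
                ladder_step = 5)
  sim <- simulate_trace(s$spec, "cleavage")
  lad <- simulate_trace(s$spec, "ladder")
  ps <- fit_channel(sim$trace, lad$trace, s$spec$ladder,
                    s$spec$fragments)
  expect_equal(nrow(ps), 50L)
  rel <- function(a, b) max(abs(a - b) / abs(b))
  expect_lt(rel(ps$amplitude, sim$truth$amplitude), 1e-3)
  expect_lt(rel(ps$center, sim$truth$center), 1e-3)
  expect_lt(rel(ps$width, sim$truth$width), 1e-3)
})

test_that("an exact initialization is a fixed point of the fit", {
  s <- make_sim(seq_len = 40, frag_min = 5, frag_max = 35,
                ladder_step = 5)
  sim <- simulate_trace(s$spec, "cleavage")
  tr <- subtract_baseline(sim$trace)
  init <- peak_set(sim$truth$amplitude, sim$truth$center,
                   sim$truth$width, sim$truth$fragment_length)
  out <- fit_peaks(tr, init, fit_config())
  expect_equal(out$amplitude, init$amplitude, tolerance = 1e-6)
  expect_equal(out$center, init$center, tolerance = 1e-6)
  expect_equal(out$width, init$width, tolerance = 1e-6)
})

test_that("the fit is invariant to a constant intensity offset", {
  s <- make_sim(seq_len = 40, frag_min = 5, frag_max = 35,
                ladder_step = 5)
  sim <- simulate_trace(s$spec, "cleavage")
  lad <- simulate_trace(s$spec, "ladder")
  ps1 <- fit_channel(sim$trace, lad$trace, s$spec$ladder,
                     s$spec$fragments)
  shifted <- sim$trace; shifted$intensity <- shifted$intensity + 123
  ps2 <- fit_channel(shifted, lad$trace, s$spec$ladder,
                     s$spec$fragments)
  expect_equal(ps2$amplitude, ps1$amplitude, tolerance = 1e-8)
  expect_equal(ps2$center, ps1$center, tolerance = 1e-8)
})

test_that("small fits agree with a brute-force grid search oracle", {
  # two Gaussians, fit by the window machinery vs dense grid search
  x <- 1:120
  a_true <- c(80, 50); c_true <- c(45, 70); w_true <- c(4, 5)
  y <- grooveprint:::gauss_sum(x, a_true, c_true, w_true)
  tr <- grooveprint:::new_trace(x, y)
  init <- peak_set(c(70, 60), c(43, 72), c(4.5, 4.5), c(1L, 2L))
  fit <- fit_peaks(tr, init, fit_config(window = 200, shift = 200,
                                        edge_discard = 0))
  # oracle: exhaustive grid around the initialization
  grid_best <- function(k) {
    best <- NULL; best_sse <- Inf
    for (a in seq(40, 90, by = 2))
      for (cc in seq(c_true[k] - 3, c_true[k] + 3, by = 0.25))
        for (w in seq(3, 6, by = 0.25)) {
          p <- list(a = a_true, cc = c_true, w = w_true)
          p$a[k] <- a; p$cc[k] <- cc; p$w[k] <- w
          sse <- sum((grooveprint:::gauss_sum(x, p$a, p$cc, p$w) - y)^2)
          if (sse < best_sse) { best_sse <- sse; best <- c(a, cc, w) }
        }
    best
  }
  for (k in 1:2) {
    b <- grid_best(k)
    expect_equal(fit$amplitude[k], b[1], tolerance = 2)
    expect_equal(fit$center[k], b[2], tolerance = 0.25)
    expect_equal(fit$width[k], b[3], tolerance = 0.25)
  }
})

test_that("fitted composite model reproduces the noiseless trace", {
  s <- make_sim(seq_len = 40, frag_min = 5, frag_max = 35,
                ladder_step = 5)
  sim <- simulate_trace(s$spec, "cleavage")
  lad <- simulate_trace(s$spec, "ladder")
  ps <- fit_channel(sim$trace, lad$trace, s$spec$ladder,
                    s$spec$fragments)
  ct <- subtract_baseline(sim$trace)
  model <- grooveprint:::gauss_sum(ct$data_point, ps$amplitude,
                                   ps$center, ps$width)
  expect_lt(max(abs(model - ct$intensity)), 0.01 * max(ct$intensity))
})

test_that("trapezoidal integration matches the closed-form area", {
  ps <- peak_set(c(1, 0, 2), c(100, 200, 300), c(10, 10, 10), 1:3)
  ps <- integrate_peaks(ps, c(1, 400))
  expect_equal(ps$area[1], sqrt(2 * pi) * 10, tolerance = 1e-3)
  expect_equal(ps$area[2], 0)
  expect_equal(ps$area[3], 2 * ps$area[1], tolerance = 1e-9)
})

test_that("median normalization sets every block median to exactly 1", {
  # 50 equal areas normalize to 1.000
  ps <- peak_set(rep(1, 50), 10 * (1:50), rep(3, 50), 1:50)
  ps$area <- rep(5, 50)
  expect_equal(normalize_areas(ps, 50)$normalized_area, rep(1, 50))

  # random areas: exact block medians, scale invariance
  set.seed(21)
  n <- 137
  ps <- peak_set(rep(1, n), 10 * (1:n), rep(3, n), 1:n)
  ps$area <- exp(rnorm(n, 0, 1))
  out <- normalize_areas(ps, 50)
  blocks <- (out$fragment_length - min(out$fragment_length)) %/% 50
  meds <- as.vector(tapply(out$normalized_area, blocks, median))
  expect_identical(meds, rep(1, length(meds)))
  ps2 <- ps; ps2$area <- ps$area * 17.3
  expect_equal(normalize_areas(ps2, 50)$normalized_area,
               out$normalized_area)

  psz <- ps; psz$area <- rep(0, n)
  expect_error(normalize_areas(psz, 50), "zero median")
})

test_that("peak sets map to profiles with the labeling convention", {
  seqd <- random_duplex(30)
  ps <- peak_set(rep(1, 3), c(10, 20, 30), rep(3, 3), c(5L, 6L, 7L))
  ps$normalized_area <- c(1.1, 0.9, 1.3)
  pf <- peaks_to_profile(ps, "forward", seqd)
  expect_equal(pf$position, c(5L, 6L, 7L))
  pr <- peaks_to_profile(ps, "reverse", seqd)
  # reverse fragment k reports forward coordinate L - k + 1
  expect_equal(pr$position, sort(30L - c(5L, 6L, 7L) + 1L))
  expect_equal(profile_values(pr, 30 - 5 + 1), 1.1)
})

test_that("simulator positions round trip through the profile", {
  s <- make_sim(seq_len = 50, frag_min = 5, frag_max = 45,
                ladder_step = 8, strand = "reverse")
  sim <- simulate_trace(s$spec, "cleavage")
  ps <- normalize_areas(peakset_from_truth(sim$truth))
  prof <- peaks_to_profile(ps, "reverse", s$seq)
  expect_setequal(prof$position, s$seq$length - s$spec$fragments + 1L)
})

test_that("peak set TSV round trips", {
  ps <- peak_set(c(2, 3), c(10, 20), c(1.5, 1.6), c(4L, 5L))
  ps <- integrate_peaks(ps, c(1, 30))
  ps <- normalize_areas(ps, 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peak_set(ps, f)
  back <- read_peak_set(f)
  expect_equal(back$amplitude, ps$amplitude)
  expect_equal(back$normalized_area, ps$normalized_area)
})
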