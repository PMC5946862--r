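test_that("Spearman's rho handles the canonical cases", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1.0)
  expect_equal(spearman_rho(x, -x), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1, 1), "at least 2")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "rank variance")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(40); y <- rnorm(40)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, y^3 + 5 * y), r)
})

test_that("the t approximation matches Pearson on ranks", {
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(25); y <- x + rnorm(25, 0, 2)
    rho <- spearman_rho(x, y)
    sig <- rho_significance(rho, 25)
    ct <- cor.test(rank(x), rank(y), method = "pearson")
    expect_equal(sig$t, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(sig$P, ct$p.value, tolerance = 1e-10)
  }
})

test_that("significance follows the alpha star ladder", {
  expect_equal(rho_significance(0, 10)$t, 0)
  expect_equal(rho_significance(0, 10)$P, 1)
  expect_equal(rho_significance(0, 10)$stars, 0L)
  expect_equal(grooveprint:::stars_for_p(0.0002), 4L)
  expect_equal(grooveprint:::stars_for_p(0.02), 2L)
  expect_equal(grooveprint:::stars_for_p(0.07), 1L)
  expect_equal(grooveprint:::stars_for_p(0.5), 0L)

  s <- rho_significance(0.5, 20)
  expect_equal(s$t, 0.5 * sqrt(18 / 0.75), tolerance = 1e-12)
  expect_equal(s$t, 2.449, tolerance = 1e-3)
  expect_equal(s$P, 2 * pt(-s$t, 18), tolerance = 1e-12)

  d <- rho_significance(1, 10)
  expect_true(d$degenerate)
  expect_equal(d$stars, 4L)
  expect_lte(d$P, .Machine$double.xmin)
})

test_that("P decreases in |rho| and in n", {
  p_rho <- vapply(seq(0.1, 0.9, 0.1),
                  function(r) rho_significance(r, 15)$P, numeric(1))
  expect_true(all(diff(p_rho) < 0))
  p_n <- vapply(c(5, 10, 20, 50),
                function(n) rho_significance(0.4, n)$P, numeric(1))
  expect_true(all(diff(p_n) < 0))
})

test_that("site comparison reports per-site rho and their plain mean", {
  set.seed(22)
  a <- orchid2_profile(1:60, exp(rnorm(60)))
  sites <- list(site_annotation("s1", 1, 20),
                site_annotation("s2", 21, 40),
                site_annotation("s3", 41, 60))
  # identical profiles: all rho 1
  tab <- compare_sites(a, a, sites)
  expect_equal(tab$rho, rep(1, 3))
  expect_equal(attr(tab, "mean_rho"), 1)

  # one agreeing, one reversed site: mean 0
  b <- a
  b$value[21:40] <- -a$value[21:40]
  tab2 <- compare_sites(a, b, sites[1:2])
  expect_equal(tab2$rho, c(1, -1))
  expect_equal(attr(tab2, "mean_rho"), 0)
  expect_equal(attr(tab2, "mean_rho"), mean(tab2$rho))
})

test_that("per-site rho matches the brute-force rank formula", {
  set.seed(23)
  a <- orchid2_profile(1:40, rnorm(40))
  b <- groove_width_profile(1:40, abs(rnorm(40)) + 1)
  sites <- list(site_annotation("s1", 1, 15),
                site_annotation("s2", 16, 40))
  tab <- compare_sites(a, b, sites)
  for (i in seq_len(nrow(tab))) {
    s <- sites[[i]]
    av <- a$value[a$position >= s$start & a$position <= s$end]
    bv <- b$value[b$position >= s$start & b$position <= s$end]
    expect_equal(tab$rho[i], spearman_bruteforce(av, bv),
                 tolerance = 1e-12)
  }
})

test_that("sites with too few common positions are excluded", {
  a <- orchid2_profile(1:10, 1:10)
  b <- groove_width_profile(c(1:5, 9L), c(2, 1, 3, 5, 4, 6))
  sites <- list(site_annotation("ok", 1, 5),
                site_annotation("thin", 8, 10))
  expect_warning(tab <- compare_sites(a, b, sites), "thin")
  expect_equal(tab$site, "ok")
})

test_that("scale calibration recovers affine maps", {
  o <- c(0.4, 0.8, 1.1, 1.6, 2.2)
  cal <- calibrate_scale(o, 2 * o + 1)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 1)
  expect_equal(cal$residual_rms, 0, tolerance = 1e-12)

  ident <- calibrate_scale(o, o)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  expect_error(calibrate_scale(rep(1, 5), 1:5), "zero variance")

  # noisy affine relation: estimates within 3 standard errors
  set.seed(31)
  x <- runif(80, 0, 2)
  y <- 1.8 * x + 3.1 + rnorm(80, 0, 0.2)
  cal2 <- calibrate_scale(x, y)
  se <- summary(lm(y ~ x))$coefficients[, "Std. Error"]
  expect_lt(abs(cal2$slope - 1.8), 3 * se["x"])
  expect_lt(abs(cal2$intercept - 3.1), 3 * se["(Intercept)"])
})

test_that("calibration never changes a rank comparison", {
  set.seed(33)
  a <- orchid2_profile(1:50, exp(rnorm(50)))
  b <- groove_width_profile(1:50, 4 + 2 * abs(rnorm(50)))
  sites <- list(site_annotation("s", 5, 45))
  before <- compare_sites(a, b, sites)
  cal <- calibrate_scale(a$value, b$value)
  after <- compare_sites(apply_calibration(a, cal), b, sites)
  expect_equal(after$rho, before$rho)
  expect_equal(after$P, before$P)
})
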