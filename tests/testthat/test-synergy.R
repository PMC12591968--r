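test_that("reduced-dose Bliss matches direct arithmetic", {
  # no-effect identity
  r <- bliss_reduced_dose(c(1, 1), 1)
  expect_equal(r$s_bliss, 0)
  expect_equal(r$verdict, "additive")
  # geometric mean equal to observed
  r <- bliss_reduced_dose(c(0.25, 0.25), 0.25)
  expect_equal(r$e_exp, 0.25, tolerance = 1e-15)
  expect_equal(r$s_bliss, 0, tolerance = 1e-15)
  # 2-drug worked example
  r <- bliss_reduced_dose(c(0.4, 0.6), 0.3)
  expect_equal(r$e_exp, sqrt(0.4) * sqrt(0.6), tolerance = 1e-15)
  expect_equal(r$s_bliss, sqrt(0.24) - 0.3, tolerance = 1e-15)
  expect_equal(r$verdict, "synergy")
  # 3-drug generalization: cube root of the product
  r <- bliss_reduced_dose(c(0.4, 0.6, 0.5), 0.49)
  expect_equal(r$e_exp, 0.12^(1 / 3), tolerance = 1e-15)
  expect_equal(r$s_bliss, 0.12^(1 / 3) - 0.49, tolerance = 1e-15)
})

test_that("percent inputs are rescaled with a warning; bad inputs error", {
  expect_warning(expect_warning(r <- bliss_reduced_dose(c(40, 60), 30),
                                "percent"), "percent")
  expect_equal(r$s_bliss, sqrt(0.24) - 0.3, tolerance = 1e-12)
  expect_error(bliss_reduced_dose(numeric(0), 0.5), "2 or 3")
  expect_error(bliss_reduced_dose(c(0.4, 0.6, 0.5, 0.3), 0.2), "2 or 3")
  expect_error(suppressWarnings(bliss_reduced_dose(c(0.4, 150), 0.3)), "100")
})

test_that("Bliss surface is zero on its own independence construction", {
  cb <- simulate_checkerboard(test_config(noise_cv = 0), "MitoQ", "DPI")
  s <- bliss_surface(cb)
  expect_lt(mean(abs(s$delta)), 1e-10)
})

test_that("Bliss surface equals a brute-force per-cell recomputation", {
  # 4x4 toy matrix written out by hand (doses 0/1/2/4 each way)
  v <- matrix(c(100, 90, 70, 50,
                 80, 70, 50, 30,
                 60, 50, 35, 20,
                 40, 30, 20, 10), 4, 4, byrow = TRUE)
  cb <- checkerboard_matrix("A", "B", c(0, 1, 2, 4), c(0, 1, 2, 4), v)
  s <- bliss_surface(cb)
  for (i in 2:4) {
    for (j in 2:4) {
      expected <- 100 * ((v[i, 1] / 100) * (v[1, j] / 100) - v[i, j] / 100)
      expect_equal(s$delta[i - 1, j - 1], expected, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("injected synergy and antagonism are recovered with the right sign", {
  syn <- sapply(1:5, function(s) {
    cb <- simulate_checkerboard(
      test_config(seed = s, noise_cv = 0.05, interaction_mode = "synergy",
                  delta = 15), "MitoQ", "DPI")
    bliss_surface(cb)$summary_mean
  })
  expect_lt(abs(mean(syn) - 15), 2)
  ant <- bliss_surface(simulate_checkerboard(
    test_config(seed = 1, noise_cv = 0.05, interaction_mode = "antagonism",
                delta = 10), "MitoQ", "DPI"))$summary_mean
  expect_lt(abs(ant + 10), 2.5)
})

test_that("ZIP surface is near zero on a product-of-margins construction", {
  cb <- simulate_checkerboard(test_config(noise_cv = 0), "MitoQ", "DPI")
  s <- zip_surface(cb)
  expect_lt(mean(abs(s$delta)), 1)
})

test_that("ZIP is invariant to replicate order and recovers injected synergy", {
  cfg <- test_config(seed = 3, noise_cv = 0.05, interaction_mode = "synergy",
                     delta = 15)
  cb <- simulate_checkerboard(cfg, "MitoQ", "DPI")
  cb2 <- cb
  cb2$viability <- cb$viability[, , c(3, 1, 2)]
  expect_equal(zip_surface(cb)$delta, zip_surface(cb2)$delta, tolerance = 1e-10)
  zips <- sapply(1:5, function(s) {
    zip_surface(simulate_checkerboard(
      test_config(seed = s, noise_cv = 0.05, interaction_mode = "synergy",
                  delta = 15), "MitoQ", "DPI"))$summary_mean
  })
  expect_lt(abs(mean(zips) - 15) / 15, 0.20)
})

test_that("ZIP falls back to Bliss when a margin is too short to fit", {
  v <- matrix(90, 4, 4)
  v[1, ] <- c(100, 90, 80, 70)
  v[, 1] <- c(100, 90, 80, 70)
  cb <- checkerboard_matrix("A", "B", c(0, 1, 2, 4), c(0, 1, 2, 4), v)
  expect_warning(s <- zip_surface(cb), "falling back")
  expect_equal(s$model, "Bliss")
})

test_that("Loewe scores a sham self-combination as exactly additive", {
  doses <- c(0, 2^(0:6)) * 10
  f <- function(x) ll4(x, 1.3, 0, 100, 160)
  v <- outer(doses, doses, function(a, b) f(a + b))
  cb <- checkerboard_matrix("drug", "drug", doses, doses, v)
  s <- loewe_surface(cb)
  expect_lt(mean(abs(s$delta)), 1)
})

test_that("Loewe recovers a uniform viability offset below the additive surface", {
  cfg <- test_config(noise_cv = 0, interaction_mode = "loewe_additive")
  cb <- simulate_checkerboard(cfg, "MitoQ", "DPI")
  # push every combination cell 5 points below the additive expectation
  # (5 keeps all cells above the zero-viability clamp on this grid)
  combo_a <- cb$dosesA > 0
  combo_b <- cb$dosesB > 0
  cb$viability[combo_a, combo_b, ] <-
    pmax(cb$viability[combo_a, combo_b, ] - 5, 0)
  s <- loewe_surface(cb)
  expect_lt(abs(s$summary_mean - 5), 1)
})

test_that("peak_score finds the best 3x3 window with deterministic ties", {
  m <- matrix(7, 6, 6)
  pk <- peak_score(m)
  expect_equal(pk$score, 7)
  expect_equal(pk$window, c(1L, 1L))
  m2 <- matrix(0, 8, 8)
  m2[4:6, 5:7] <- 30
  pk2 <- peak_score(m2)
  expect_equal(pk2$score, 30)
  expect_equal(pk2$window, c(4L, 5L))
  # brute-force oracle over every window
  set.seed(1)
  m3 <- matrix(rnorm(64), 8, 8)
  best <- -Inf
  for (i in 1:6) for (j in 1:6) {
    best <- max(best, mean(m3[i:(i + 2), j:(j + 2)]))
  }
  expect_equal(peak_score(m3)$score, best, tolerance = 1e-12)
  # sign symmetry: peak of the negated surface = -(min window mean)
  worst <- Inf
  for (i in 1:6) for (j in 1:6) {
    worst <- min(worst, mean(m3[i:(i + 2), j:(j + 2)]))
  }
  expect_equal(peak_score(-m3)$score, -worst, tolerance = 1e-12)
  expect_warning(peak_score(matrix(1, 2, 2)), "shrunk")
})

test_that("score classification applies the +-10 thresholds inclusively", {
  expect_equal(classify_score(43.2), "synergistic")
  expect_equal(classify_score(0), "additive")
  expect_equal(classify_score(-12), "antagonistic")
  expect_equal(classify_score(c(10, -10, 10.01, -10.01)),
               c("additive", "additive", "synergistic", "antagonistic"))
  expect_error(classify_score(NaN), "finite")
})

test_that("all three models score injected synergy positive and increase with delta", {
  means <- sapply(c(0, 10, 20), function(dl) {
    mode <- if (dl == 0) "independent" else "synergy"
    vals <- sapply(1:3, function(s) {
      cb <- simulate_checkerboard(
        test_config(seed = s, noise_cv = 0.05, interaction_mode = mode,
                    delta = dl), "MitoQ", "DPI")
      c(bliss_surface(cb)$summary_mean, zip_surface(cb)$summary_mean,
        loewe_surface(cb)$summary_mean)
    })
    rowMeans(vals)
  })
  expect_true(all(diff(means[1, ]) > 0))
  expect_true(all(diff(means[2, ]) > 0))
  expect_true(all(diff(means[3, ]) > 0))
  expect_true(all(means[, 3] > 5))
})
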