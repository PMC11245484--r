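test_that("constant signals live entirely in the approximation space", {
  x <- rep(3.7, 256)
  d <- dwt(x, "db4", 3)
  expect_true(all(vapply(d$details, function(cd) max(abs(cd)), numeric(1))
                  < 1e-10))
})

test_that("analysis/synthesis is a perfect-reconstruction filter bank", {
  set.seed(42)
  for (w in c("haar", "db2", "db4", "sym4")) {
    for (n in c(64, 301, 1023, 4096)) {
      x <- rnorm(n)
      k <- min(4L, max_dwt_level(n, w))
      expect_lt(max(abs(idwt(dwt(x, w, k)) - x)), 1e-8)
    }
  }
})

test_that("periodic-mode transform is orthonormal (Parseval)", {
  imp <- c(1, rep(0, 255))
  d <- dwt(imp, "db4", 3, mode = "periodic")
  expect_equal(sum(unlist(d$details)^2) + sum(d$approx^2), 1,
               tolerance = 1e-10)
  set.seed(7)
  for (w in c("haar", "db2", "db4", "sym4")) {
    x <- rnorm(512)
    d <- dwt(x, w, 3, mode = "periodic")
    en <- sum(unlist(d$details)^2) + sum(d$approx^2)
    expect_equal(en, sum(x^2), tolerance = 1e-8 * sum(x^2))
    expect_lt(max(abs(idwt(d) - x)), 1e-8)
  }
})

test_that("dwt rejects over-deep levels, naming the admissible maximum", {
  expect_error(dwt(rnorm(64), "db4", 5), "maximum admissible level is 3")
  expect_error(dwt(rnorm(4), "db4", 1), "shorter than")
})

test_that("noise sigma is the MAD estimate of the detail scale", {
  expect_equal(noise_sigma(c(0, 0, 0)), 0)
  expect_equal(noise_sigma(c(-1, 0, 1)), 1 / 0.6745, tolerance = 1e-12)
  expect_error(noise_sigma(numeric(0)), "empty")
  # finest details of pure white noise recover its standard deviation
  set.seed(8)
  sig <- vapply(1:5, function(i) {
    noise_sigma(dwt(rnorm(8192), "db4", 1)$details[[1]])
  }, numeric(1))
  expect_true(all(abs(sig - 1) < 0.05))
})

test_that("threshold rules give the canonical values", {
  for (rule in c("universal", "sure", "minimax")) {
    expect_equal(threshold_value(0, 100, rule, coeffs = rnorm(100)), 0)
  }
  expect_equal(threshold_value(1, 1024, "universal"), sqrt(2 * log(1024)),
               tolerance = 1e-12)
  expect_equal(threshold_value(2, 1024, "universal"), 2 * sqrt(2 * log(1024)))
  expect_equal(threshold_value(1, 32, "minimax"), 0)
  expect_equal(threshold_value(1, 1024, "minimax"), 0.3936 + 0.1829 * 10)
  expect_error(threshold_value(1, 10, "banana"))
})

test_that("SURE threshold on pure noise is close to the universal one", {
  set.seed(10)
  g_univ <- threshold_value(1, 1024, "universal")
  for (i in 1:5) {
    y <- rnorm(1024)
    g_sure <- threshold_value(1, 1024, "sure", coeffs = y)
    expect_lt(abs(g_sure - g_univ) / g_univ, 0.2)
  }
  # a dense band of real coefficients drives the SURE threshold below the
  # universal one
  y_dense <- rnorm(1024) + rnorm(1024, 0, 2)
  g_dense <- threshold_value(1, 1024, "sure", coeffs = y_dense)
  expect_lt(g_dense, g_univ)
  expect_gte(g_dense, 0)
})

test_that("hard and soft shrinkage follow their defining identities", {
  expect_equal(shrink(2.5, 1, "soft"), 1.5)
  expect_equal(shrink(-2.5, 1, "soft"), -1.5)
  expect_equal(shrink(-3, 1, "hard"), -3)
  expect_equal(shrink(0.5, 1, "hard"), 0)
  x <- rnorm(100)
  expect_equal(shrink(x, 0, "soft"), x)
  expect_equal(shrink(x, 0, "hard"), x)
})

test_that("shrinkage is contractive, monotone in gamma, and hard is idempotent", {
  set.seed(12)
  x <- rnorm(200, sd = 2)
  for (mode in c("soft", "hard")) {
    prev <- abs(shrink(x, 0, mode))
    for (g in c(0.3, 0.8, 1.5, 3)) {
      s <- shrink(x, g, mode)
      expect_true(all(abs(s) <= abs(x) + 1e-15))
      expect_true(all(abs(s) <= prev + 1e-15))
      prev <- abs(s)
    }
  }
  h <- shrink(x, 1.2, "hard")
  expect_identical(shrink(h, 1.2, "hard"), h)
  # soft shrinkage is continuous across the threshold
  eps <- 1e-9
  expect_lt(abs(shrink(1 + eps, 1, "soft") - shrink(1 - eps, 1, "soft")),
            1e-8)
})

test_that("reconstruction handles degenerate coefficient sets", {
  d <- dwt(rnorm(128), "db2", 2)
  d$details <- lapply(d$details, function(cd) cd * 0)
  d$approx <- d$approx * 0
  expect_equal(max(abs(idwt(d))), 0)
  d2 <- dwt(rnorm(128), "db2", 2)
  d2$details[[1]] <- d2$details[[1]][-1]
  expect_error(idwt(d2), "length mismatch")
})

test_that("zeroing details of a noisy constant recovers the constant", {
  set.seed(13)
  x <- 5 + rnorm(512, sd = 0.1)
  d <- dwt(x, "db4", 4)
  d$details <- lapply(d$details, function(cd) cd * 0)
  rec <- idwt(d)
  expect_lt(sd(rec - 5), 0.05)
  expect_equal(mean(rec), 5, tolerance = 0.01)
})

test_that("denoising is deterministic and improves the SNR of noisy PPG", {
  cfg <- synth_config(duration_s = 30, baseline_amp = 0, powerline_amp = 0,
                      white_sd = 0, seed = 30)
  clean <- simulate_record(subject_profile("X", "non_fatigue"), cfg)$clean
  snr <- function(ref, sig) 10 * log10(sum(ref^2) / sum((sig - ref)^2))
  set.seed(14)
  gains <- vapply(1:5, function(i) {
    noise_sd <- sqrt(mean((clean - mean(clean))^2) / 10^(5 / 10))
    noisy <- clean + rnorm(length(clean), 0, noise_sd)
    den <- denoise_signal(noisy, "db4", 4, "universal", "soft")
    snr(clean, den) - snr(clean, noisy)
  }, numeric(1))
  expect_gt(median(gains), 5)

  noisy <- clean + ppgfatigue:::with_seed(15, rnorm(length(clean), 0, 0.2))
  expect_identical(denoise_signal(noisy), denoise_signal(noisy))
  expect_length(denoise_signal(noisy), length(noisy))
})
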