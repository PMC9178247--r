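test_that("permutation entropy matches the hand-enumerated 7-point example", {
  # windows of x under m = 3: patterns {(0,1,2): 2, (2,0,1): 2, (1,0,2): 1}
  # over 5 windows -> H = -(2/5 ln 2/5)*2 - 1/5 ln 1/5 = 1.05492, / ln 6
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expected <- -(2 * (2 / 5) * log(2 / 5) + (1 / 5) * log(1 / 5)) / log(6)
  expect_equal(permutation_entropy(x, m = 3, delay = 1), expected,
               tolerance = 1e-12)
  expect_equal(round(expected, 4), 0.5888)
})

test_that("monotone sequences have zero permutation entropy", {
  expect_equal(permutation_entropy(1:50, m = 3), 0)
  expect_equal(permutation_entropy(seq(5, 1, length.out = 40), m = 5), 0)
  # constant sequence: ties rank by position, again a single pattern
  expect_equal(permutation_entropy(rep(1, 30), m = 4), 0)
})

test_that("i.i.d. noise approaches maximal permutation entropy", {
  set.seed(11)
  x <- stats::runif(1e5)
  expect_gte(permutation_entropy(x, m = 5), 0.99)
})

test_that("permutation entropy rejects too-short input", {
  expect_error(permutation_entropy(c(1, 2), m = 4), "too short")
})

test_that("mode correlation is absolute Pearson with a zero-variance guard", {
  set.seed(3)
  x <- stats::rnorm(500)
  expect_equal(mode_correlation(x, x), 1)
  expect_equal(mode_correlation(-x, x), 1)
  expect_warning(r0 <- mode_correlation(rep(1, 500), x), "constant")
  expect_equal(r0, 0)
  y <- stats::rnorm(1e4)
  z <- cos(2 * pi * 50 * seq_len(1e4) / 2000)
  expect_lte(mode_correlation(y, z), 0.05)
})

test_that("screening index reproduces its limiting cases", {
  expect_equal(screening_index(1, 0, 0.3), 0)
  expect_equal(screening_index(0, 1, 0.3), 1)
  expect_equal(screening_index(0.5, 0.5, 0.3), 0.5)
  expect_error(screening_index(1.2, 0, 0.3), "0, 1")
})

test_that("screening index is monotone: decreasing in rsig, increasing in pec", {
  g <- seq(0, 1, by = 0.1)
  for (b in c(0.2, 0.3, 0.7)) {
    expect_true(all(diff(screening_index(g, 0.5, b)) < 0))
    expect_true(all(diff(screening_index(0.5, g, b)) > 0))
  }
})

test_that("rejection needs both high index and low correlation", {
  fit <- vmd(tone(50, dur = 2), K = 3, max_iter = 30)
  fake <- function(rsp, rsig) {
    # decision rule replicated on explicit score pairs
    rsp > 0.6 & rsig < 0.5
  }
  expect_true(fake(0.7, 0.3))    # noisy and decorrelated -> rejected
  expect_false(fake(0.7, 0.6))   # correlated -> kept despite high index
  expect_false(fake(0.5, 0.3))   # low index -> kept
  # all-clean decomposition keeps everything
  sc <- select_modes(fit, tone(50, dur = 2))
  expect_length(sc$rejected, 0)
  expect_setequal(sc$retained, 1:3)
})

test_that("a constructed pure-noise mode is rejected and reconstruction improves", {
  clean <- generate_clean_pcg(pcg_spec(duration = 6, seed = 2))$signal
  noisy <- add_gaussian_noise(clean, 5, seed = 9)
  fit <- vmd(noisy, K = 6, alpha = 2500, tau = 0)
  sc <- select_modes(fit, noisy)
  # high-frequency modes carry only noise: high entropy, low correlation
  expect_gt(length(sc$rejected), 0)
  expect_true(all(sc$rsp[sc$rejected] > 0.6))
  expect_true(all(sc$rsig[sc$rejected] < 0.5))
  rec <- vmd_reconstruct(fit, sc$retained)
  expect_gt(stats::cor(rec$samples, clean$samples),
            stats::cor(noisy$samples, clean$samples))
})

test_that("scores are invariant to a common positive rescaling", {
  clean <- generate_clean_pcg(pcg_spec(duration = 4, seed = 2))$signal
  noisy <- add_gaussian_noise(clean, 10, seed = 4)
  fit <- vmd(noisy, K = 4, max_iter = 60)
  sc1 <- select_modes(fit, noisy)
  fit2 <- fit
  fit2$modes <- fit$modes * 7
  sc2 <- select_modes(fit2, pcg_signal(noisy$samples * 7, noisy$fs))
  expect_equal(sc2$rsp, sc1$rsp, tolerance = 1e-12)
  expect_identical(sc2$retained, sc1$retained)
})

test_that("rejecting every mode triggers the keep-best-correlated fallback", {
  # construct a decomposition whose modes are all independent noise:
  # every mode then has pec ~ 1 and rsig ~ 0, so the rule rejects all
  set.seed(1)
  K <- 6; n <- 4096
  fake <- structure(list(modes = matrix(stats::rnorm(n * K), n, K),
                         center_freqs = seq(100, 900, length.out = K),
                         fs = 2000, K = K),
                    class = "vmd")
  original <- stats::rnorm(n)
  expect_warning(sc <- select_modes(fake, original), "retaining")
  expect_length(sc$retained, 1)
  expect_equal(sc$retained, which.max(sc$rsig))
  expect_true(sc$fallback)
})
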