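test_that("hemodynamic convolution is linear and time-invariant", {
  kern <- bold_kernel()
  fs <- attr(kern, "fs")
  nk <- length(kern)
  n <- 60 * fs
  # constant input -> constant BOLD after the kernel transient
  b1 <- bold_from_rates(rep(2, n), fs, TR = 1, kernel = kern)
  late <- b1$bold[, 1]
  expect_gt(length(late), 10)
  expect_lt(diff(range(late)), 1e-6 * max(abs(late)) + 1e-9)
  # superposition (first-order kernel is linear)
  set.seed(2)
  a <- pmax(0, rnorm(n, 5)); b <- pmax(0, rnorm(n, 3))
  ya <- bold_from_rates(a, fs, TR = 1, kernel = kern)$bold
  yb <- bold_from_rates(b, fs, TR = 1, kernel = kern)$bold
  yab <- bold_from_rates(a + b, fs, TR = 1, kernel = kern)$bold
  expect_equal(yab, ya + yb, tolerance = 1e-8)
  # a unit-area impulse placed just past the transient cut reproduces the
  # kernel sampled at TR
  x <- numeric(2 * nk + fs)
  x[nk + 1] <- fs
  yi <- bold_from_rates(x, fs, TR = 1, kernel = kern)
  ref <- kern[seq(1, nk, by = fs)]
  expect_equal(as.numeric(yi$bold[seq_along(ref), 1]), as.numeric(ref),
               tolerance = 1e-6)
  expect_error(bold_from_rates(rep(1, 10), fs, TR = 1, kernel = kern),
               "shorter than")
})

test_that("functional connectivity: symmetry, unit diagonal, known limits", {
  set.seed(4)
  x <- rnorm(2000)
  m <- cbind(x, x, rnorm(2000))
  fc <- functional_connectivity(m)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(1, 3), ignore_attr = TRUE)
  expect_lt(abs(fc[1, 3]), 3 / sqrt(2000))
  mz <- cbind(rnorm(100), rep(1, 100))
  expect_warning(fcz <- functional_connectivity(mz), "zero-variance")
  expect_true(is.na(fcz[1, 2]))
})

test_that("SC-FC correlation of upper triangles behaves as a Pearson r", {
  set.seed(5)
  sc <- matrix(runif(64), 8); sc <- (sc + t(sc)) / 2; diag(sc) <- 0
  expect_equal(sc_fc_correlation(2 * sc + 1, sc), 1)
  expect_equal(sc_fc_correlation(-sc, sc), -1)
  perm <- sample(8)
  expect_lt(abs(sc_fc_correlation(sc[perm, perm], sc)), 0.6)
  expect_error(sc_fc_correlation(matrix(0, 3, 3), sc), "shape mismatch")
})

test_that("binarization: null calibration, detection, reproducibility", {
  set.seed(6)
  nulltrials <- 30
  any_sig <- vapply(seq_len(nulltrials), function(i) {
    tr <- matrix(rnorm(600 * 10), 600, 10)
    br <- binarize_response(tr, onset_index = 301, n_shuffles = 200,
                            alpha = 0.05, seed = i)
    sum(br$S) > 0
  }, logical(1))
  # max-statistic control: about alpha of null trials show any crossing
  expect_lt(mean(any_sig), 0.25)
  # a 10-sigma deflection in one region is flagged exactly there
  tr <- matrix(rnorm(600 * 10), 600, 10)
  tr[320:360, 4] <- tr[320:360, 4] + 10
  br <- binarize_response(tr, onset_index = 301, n_shuffles = 200, seed = 1)
  expect_gt(sum(br$S[4, 20:60]), 30)
  expect_lt(sum(br$S[-4, ]), 10)
  br2 <- binarize_response(tr, onset_index = 301, n_shuffles = 200, seed = 1)
  expect_identical(br$S, br2$S)
  # zero pre-stimulus variance flags the region
  trz <- cbind(tr[, 1:9], 0)
  brz <- binarize_response(trz, onset_index = 301, n_shuffles = 50, seed = 2)
  expect_equal(brz$excluded, 10L)
})

test_that("LZ76 counter matches the brute-force parser and its known values", {
  expect_equal(lempel_ziv_complexity(rep(0, 100)), 2L)
  expect_equal(lempel_ziv_complexity(rep(0, 7)), 2L)
  # periodic '01' stays at small constant complexity
  expect_equal(lempel_ziv_complexity(rep(c(0, 1), 50)),
               lempel_ziv_complexity(rep(c(0, 1), 500)))
  # exhaustive equivalence with the substring-search oracle
  for (n in 1:12) {
    bits <- all_bitstrings(n)
    got <- apply(bits, 1, lempel_ziv_complexity)
    want <- apply(bits, 1, lz76_oracle)
    expect_equal(got, want, info = paste("length", n))
  }
  # random strings of length 1000
  set.seed(8)
  for (k in 1:25) {
    s <- sample(0:1, 1000, replace = TRUE)
    expect_equal(lempel_ziv_complexity(s), lz76_oracle(s))
  }
  # asymptotic growth of random sequences: c(n) ~ n / log2(n)
  s <- sample(0:1, 4096, replace = TRUE)
  expect_lt(abs(lempel_ziv_complexity(s) / (4096 / log2(4096)) - 1), 0.25)
})

test_that("source entropy: closed form, symmetry, degenerate cases", {
  expect_equal(source_entropy(rep(0:1, 10)), 1)
  expect_equal(source_entropy(rep(1, 5)), 0)
  expect_equal(source_entropy(rep(0, 5)), 0)
  s <- c(rep(1, 25), rep(0, 75))
  expect_equal(source_entropy(s), -0.25 * log2(0.25) - 0.75 * log2(0.75),
               tolerance = 1e-12)
  expect_equal(source_entropy(s), source_entropy(1 - s))
  p <- seq(0.05, 0.95, by = 0.05)
  h <- vapply(p, function(q) source_entropy(c(rep(1, q * 100), rep(0, (1 - q) * 100))),
              numeric(1))
  expect_equal(p[which.max(h)], 0.5)
})

test_that("PCI pipeline: ordered vs complex responses, undefined handling", {
  set.seed(9)
  n_t <- 600; n_r <- 12
  # one always-significant region, constant in time: ordered, low PCI
  ordered <- matrix(rnorm(n_t * n_r), n_t, n_r)
  ordered[301:600, 3] <- ordered[301:600, 3] + 50
  # many regions flicker incoherently: complex, high PCI
  complexr <- matrix(rnorm(n_t * n_r), n_t, n_r)
  flick <- matrix(sample(c(0, 50), 300 * n_r, replace = TRUE), 300, n_r)
  complexr[301:600, ] <- complexr[301:600, ] + flick
  pc <- compute_pci(list(ordered, complexr), onset_index = 301,
                    n_shuffles = 200, seed = 3)
  expect_equal(pc$n_undefined, 0L)
  expect_lt(pc$pci[1], 0.35)
  expect_gt(pc$pci[2], pc$pci[1] * 2)
  # a null trial has H = 0 -> NA with diagnostic, not a silent zero
  nullt <- matrix(rnorm(n_t * n_r), n_t, n_r)
  pc0 <- compute_pci(nullt, onset_index = 301, n_shuffles = 200, seed = 4)
  if (sum(pc0$p1) == 0) {
    expect_true(is.na(pc0$pci[1]))
    expect_equal(pc0$n_undefined, 1L)
  } else succeed()
})
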