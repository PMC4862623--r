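test_that("notch filter removes the line tone and spares the passband", {
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  line <- eeg_recording(sin(2 * pi * 50 * t), fs)
  pass <- eeg_recording(sin(2 * pi * 10 * t), fs)
  out50 <- get_channel(notch_filter(line, 50))
  out10 <- get_channel(notch_filter(pass, 50))
  expect_lt(sqrt(mean(out50^2)) / sqrt(mean(sin(2 * pi * 50 * t)^2)), 0.1)
  expect_equal(sqrt(mean(out10^2)) / sqrt(mean(sin(2 * pi * 10 * t)^2)), 1,
               tolerance = 0.05)
  zeros <- notch_filter(eeg_recording(numeric(fs), fs), 50)
  expect_equal(get_channel(zeros), numeric(fs))
  expect_error(notch_filter(line, 130), "Nyquist")
})

test_that("stateful notch equals one-shot filtering of the whole record", {
  set.seed(1)
  x <- rnorm(2000)
  cf <- cefp:::notch_coefficients(50, 250)
  whole <- cefp:::notch_apply(x, cf)$y
  st <- c(0, 0)
  pieces <- lapply(split(x, rep(1:4, each = 500)), function(seg) {
    r <- cefp:::notch_apply(seg, cf, st)
    st <<- r$state
    r$y
  })
  expect_equal(unlist(pieces, use.names = FALSE), whole, tolerance = 1e-12)
})

test_that("stockwell amplitude matches a brute-force windowed sum", {
  set.seed(2)
  fs <- 64
  x <- rnorm(2 * fs)
  n <- length(x)
  lag <- 0:(n - 1)
  direct_row <- function(f, support = Inf) {
    if (is.finite(support)) {
      circ <- pmin(lag, n - lag) / fs
      g <- ifelse(circ <= support, exp(-0.5 * (circ * f)^2), 0)
    } else {
      tsec <- ifelse(lag <= n / 2, lag, lag - n) / fs
      g <- 0
      for (k in -2:2) g <- g + exp(-0.5 * ((tsec + k * n / fs) * f)^2)
    }
    g <- g / sum(g)
    vapply(0:(n - 1), function(t0) {
      abs(sum(x * g[((lag - t0) %% n) + 1] * exp(-2i * pi * f * lag / fs)))
    }, numeric(1))
  }
  tf <- stockwell(x, 1, 10, rate_hz = fs)
  for (f in c(1, 5, 10)) {
    expect_equal(tf$amplitude[f, ], direct_row(f), tolerance = 1e-6)
  }
  tft <- stockwell(x, 2, 10, rate_hz = fs, support_s = 0.5)
  expect_equal(tft$amplitude[4, ], direct_row(5, 0.5), tolerance = 1e-6)
})

test_that("stockwell basics: carrier peak, zeros, short-record error", {
  fs <- 100
  x <- sin(2 * pi * 10 * (0:(4 * fs - 1)) / fs)
  tf <- stockwell(x, 1, 30, rate_hz = fs)
  expect_equal(tf$freqs_hz[which.max(rowMeans(tf$amplitude))], 10)
  z <- stockwell(numeric(2 * fs), 1, 30, rate_hz = fs)
  expect_equal(max(z$amplitude), 0)
  expect_error(stockwell(numeric(fs), 1, 30, rate_hz = fs), "short")
})

test_that("equal-area banding follows the cumulative-area oracle", {
  # flat spectrum: exact uniform 4 Hz bands
  flat <- equal_area_bands(rep(1, 40), 10)
  expect_equal(flat$edges_hz, seq(1, 41, by = 4))
  # all mass below 8 Hz pushes the edges down as far as the 1 Hz grid allows
  low <- c(rep(100, 7), rep(1e-4, 33))
  sc <- equal_area_bands(low, 10)
  expect_gte(sum(sc$edges_hz <= 8), 7)
  expect_true(all(sc$edges_hz[2:7] <= 8))
  # any spectrum: band areas deviate from the ideal share by < one bin area
  set.seed(3)
  for (i in 1:10) {
    s <- exp(rnorm(40, sd = 0.8)) / (1:40)^0.8
    sc <- equal_area_bands(s, 10)
    areas <- vapply(1:10, function(b) {
      sum(s[1:40 >= sc$edges_hz[b] & 1:40 < sc$edges_hz[b + 1]])
    }, numeric(1))
    expect_lt(max(abs(areas - sum(s) / 10)), max(s) + 1e-12)
    # bands partition the range exactly
    expect_equal(sc$edges_hz[1], 1)
    expect_equal(sc$edges_hz[11], 41)
    expect_true(all(diff(sc$edges_hz) > 0))
  }
  expect_error(equal_area_bands(rep(1, 5), 10), "fewer")
  expect_error(equal_area_bands(c(1, -1, rep(1, 38)), 10), "positive")
})

test_that("band collapse is the row-group mean", {
  tf <- list(freqs_hz = 1:40, times_s = (0:9) / 10,
             amplitude = matrix(1, 40, 10), rate_hz = 10)
  sc <- uniform_scheme()
  expect_equal(collapse_to_bands(tf, sc), matrix(1, 10, 10))
  # row f holds constant value f: band value = mean of member frequencies
  tf$amplitude <- matrix(rep(1:40, 10), 40, 10)
  got <- collapse_to_bands(tf, sc)
  for (b in 1:10) {
    rows <- which(1:40 >= sc$edges_hz[b] & 1:40 < sc$edges_hz[b + 1])
    expect_equal(got[b, 1], mean(rows))
  }
  # random map equals a brute-force grouping oracle
  set.seed(4)
  tf$amplitude <- matrix(abs(rnorm(400)), 40, 10)
  got <- collapse_to_bands(tf, sc)
  for (b in 1:10) {
    rows <- which(1:40 >= sc$edges_hz[b] & 1:40 < sc$edges_hz[b + 1])
    expect_equal(got[b, ], colMeans(tf$amplitude[rows, , drop = FALSE]))
  }
  # equal-width bands conserve the total mean amplitude
  expect_equal(mean(got), mean(tf$amplitude))
  expect_error(collapse_to_bands(tf, band_scheme(c(1.2, 1.9, 41))), "no frequency row")
})

test_that("resampling to 4 Hz uses block means down and interpolation up", {
  expect_equal(resample_to_4hz(rep(2, 1000), 250), rep(2, 16))
  expect_length(resample_to_4hz(rnorm(1000), 250), 16)
  # block-mean oracle at a rate with integer blocks
  set.seed(5)
  x <- rnorm(200)
  got <- resample_to_4hz(x, 40)  # 10-sample blocks
  expect_equal(got, vapply(1:20, function(i) mean(x[((i - 1) * 10 + 1):(i * 10)]),
                           numeric(1)))
  # BOLD upsampling: TR = 3 s, values 0 and 3 -> 0.75 at t = 0.75 s
  up <- resample_to_4hz(c(0, 3), 1 / 3)
  expect_equal(up[4], 0.75)
  expect_error(resample_to_4hz(c(0, 3), 1 / 2.7), "commensurate")
})

test_that("reference normalization is the invertible affine contract", {
  sc <- uniform_scheme()
  ref <- rest_reference(1:10, rep(2, 10))
  bp <- band_powers(matrix(1:10, 10, 5), sc)
  z <- normalize_bands(bp, ref)
  expect_equal(z$values, matrix(0, 10, 5))
  expect_equal(z$normalization, "reference_normalized")
  bp2 <- band_powers(matrix(1:10 + 2, 10, 5), sc)
  expect_equal(normalize_bands(bp2, ref)$values, matrix(1, 10, 5))
  set.seed(6)
  bp3 <- band_powers(matrix(rnorm(50), 10, 5), sc)
  round_trip <- denormalize_bands(normalize_bands(bp3, ref), ref)
  expect_equal(round_trip$values, bp3$values, tolerance = 1e-12)
  expect_error(rest_reference(1:10, c(rep(1, 9), 0)), "positive")
})

test_that("featurization is shift-equivariant away from the edges", {
  # 250 ms = 50 samples at 200 Hz; compare interior columns 6 s away from
  # the record ends (leaving room for the notch transient to decay)
  set.seed(7)
  fs <- 200
  x <- rnorm(30 * fs)
  shift <- fs / 4
  sc <- uniform_scheme()
  a <- featurize_recording(eeg_recording(x[1:(28 * fs)], fs), sc)
  b <- featurize_recording(eeg_recording(x[(shift + 1):(28 * fs + shift)], fs), sc)
  ta <- round(a$times_s * 4)
  tb <- round(b$times_s * 4) + 1L  # b is x delayed by one 4 Hz sample
  keep <- ta >= 24 & ta <= max(ta) - 24
  m <- match(ta[keep], tb)
  expect_true(all(!is.na(m)))
  expect_equal(a$values[, keep], b$values[, m], tolerance = 1e-6)
})
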