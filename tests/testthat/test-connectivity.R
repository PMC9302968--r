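fs <- 1000

make_recording <- function(data, n_trials = 1,
                           spec = session_spec("REST", n_trials = n_trials)) {
  eeg_recording(data, fs, default_montage(), default_neighbors(), spec)
}

test_that("common average referencing zeroes the channel mean everywhere", {
  n <- 15 * fs
  same <- matrix(rep(sin(seq_len(n) / 50) * 20, 14), n, 14,
                 dimnames = list(NULL, default_montage()))
  pp <- offline_preprocess(make_recording(same))
  expect_equal(max(abs(pp$recording$data)), 0)
  set.seed(1)
  x <- matrix(rnorm(n * 14, sd = 10), n, 14,
              dimnames = list(NULL, default_montage()))
  pp <- offline_preprocess(make_recording(x))
  expect_lt(max(abs(rowMeans(pp$recording$data))), 1e-10)
})

test_that("channels with excursions above 100 uV are rejected per trial", {
  n <- 2 * 15 * fs
  set.seed(2)
  x <- matrix(rnorm(n * 14, sd = 5), n, 14,
              dimnames = list(NULL, default_montage()))
  x[3 * fs, "C1"] <- 150   # trial 1 only
  pp <- offline_preprocess(make_recording(x, n_trials = 2))
  expect_true(any(pp$rejected$trial == 1 & pp$rejected$channel == "C1"))
  expect_false(any(pp$rejected$trial == 2 & pp$rejected$channel == "C1"))
})

test_that("pre-stimulus windows are sliced as specified", {
  n <- 15 * fs
  rec <- make_recording(matrix(0, n, 14,
                               dimnames = list(NULL, default_montage())),
                        spec = session_spec("MID", n_trials = 1))
  w <- prestimulus_window(rec, 1, cs_time = 8.0)  # MI + 2.0 s
  expect_equal(length(w$full_idx), 8 * fs)
  expect_equal(w$last1s_idx, (7 * fs + 1):(8 * fs))
  expect_false(w$padded)
  w2 <- prestimulus_window(rec, 1, cs_time = 6.5)
  expect_true(w2$padded)   # slice reaches into the ready epoch
  expect_error(prestimulus_window(rec, 1, cs_time = 0), "empty")
})

test_that("segment counts match the overlap arithmetic", {
  expect_equal(nrow(segment_epoch(rnorm(4 * fs), fs)), 31)
  expect_equal(nrow(segment_epoch(rnorm(fs), fs)), 1)
  expect_equal(nrow(segment_epoch(rnorm(2 * fs), fs, overlap = 0.5)), 3)
  expect_error(segment_epoch(rnorm(500), fs), "shorter")
  # brute-force enumeration of start positions on a grid
  for (len_s in c(1, 1.5, 2, 3.3)) {
    for (ov in c(0.5, 0.75, 0.9)) {
      n <- round(len_s * fs)
      step <- round((1 - ov) * fs)
      brute <- length(seq(1, n - fs + 1, by = step))
      expect_equal(nrow(segment_epoch(rnorm(n), fs, overlap = ov)), brute)
    }
  }
})

test_that("ciCOH vanishes for zero-lag mixtures and saturates in quadrature", {
  set.seed(11)
  x <- rnorm(4 * fs)
  xs <- segment_epoch(x, fs)
  expect_equal(cicoh(xs, xs, c(8, 13), fs), 0)
  # any instantaneous mixture of the same sources is still zero-lag
  y <- 0.7 * x + 0.3 * rnorm(4 * fs) * 0   # pure rescale
  expect_equal(cicoh(xs, segment_epoch(y, fs), c(8, 13), fs), 0)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 10 * t) + 0.05 * rnorm(length(t))
  b <- -cos(2 * pi * 10 * t) + 0.05 * rnorm(length(t))
  q <- cicoh(segment_epoch(a, fs), segment_epoch(b, fs), c(9, 11), fs)
  expect_gt(abs(q), 0.95)
})

test_that("ciCOH is antisymmetric and amplitude invariant", {
  set.seed(12)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 10 * t) + 0.3 * rnorm(length(t))
  b <- sin(2 * pi * 10 * t + 1) + 0.3 * rnorm(length(t))
  sa <- segment_epoch(a, fs); sb <- segment_epoch(b, fs)
  v <- cicoh(sa, sb, c(9, 11), fs)
  expect_equal(cicoh(sb, sa, c(9, 11), fs), -v, tolerance = 1e-10)
  expect_equal(cicoh(segment_epoch(5 * a, fs), segment_epoch(0.1 * b, fs),
                     c(9, 11), fs), v, tolerance = 1e-10)
  expect_error(cicoh(sa, sb, c(200, 300), fs), NA)  # in-range bands only err below
  expect_error(cicoh(segment_epoch(numeric(fs) , fs),
                     segment_epoch(numeric(fs), fs), c(9, 11), fs))
})

test_that("independent noise gives small ciCOH that shrinks with segments", {
  set.seed(13)
  spread <- function(len_s) {
    sd(replicate(30, {
      cicoh(segment_epoch(rnorm(len_s * fs), fs),
            segment_epoch(rnorm(len_s * fs), fs), c(8, 13), fs)
    }))
  }
  s_short <- spread(2)
  s_long <- spread(8)
  expect_lt(abs(s_long), abs(s_short))
  expect_lt(s_long, 0.25)
})

test_that("surrogate test flags quadrature pairs and passes zero-lag pairs", {
  set.seed(14)
  qp <- quadrature_pair(6 * fs, fs)
  sig <- cicoh_significance(qp$x, qp$y, fs, c(8, 13), n_surrogates = 100,
                            seed = 5)
  expect_gt(abs(sig$cicoh), 0.9)
  expect_true(sig$significant)
  same <- cicoh_significance(qp$x, qp$x, fs, c(8, 13), n_surrogates = 100,
                             seed = 5)
  expect_false(same$significant)
  expect_equal(same$cicoh, 0)
  expect_error(cicoh_significance(qp$x, qp$y, fs, c(8, 13),
                                  n_surrogates = 50),
               "at least 100")
})

test_that("surrogate significance is calibrated near its alpha level", {
  set.seed(15)
  hits <- sum(replicate(40, {
    x <- rnorm(3 * fs); y <- rnorm(3 * fs)
    cicoh_significance(x, y, fs, c(8, 13), n_surrogates = 100,
                       alpha = 0.05, seed = sample.int(1e6, 1))$significant
  }))
  # Binomial(40, 0.05): P(hits <= 7) > 0.999
  expect_lte(hits, 7)
})

test_that("network intensity sums exactly the significant entries", {
  vals <- matrix(0, 7, 7)
  mask <- matrix(FALSE, 7, 7)
  m <- structure(list(values = vals, mask = mask, band = c(8, 13)),
                 class = "cicoh_matrix")
  expect_equal(network_intensity(m)$value, 0)
  m$values[] <- 0.2
  m$mask[] <- TRUE
  expect_equal(network_intensity(m)$value, 49 * 0.2)
  # mixed fixture, hand-summed
  m$values <- matrix(seq(0.01, 0.49, by = 0.01), 7, 7)
  m$mask[] <- FALSE
  m$mask[1, 1] <- m$mask[3, 2] <- m$mask[7, 7] <- TRUE
  expect_equal(network_intensity(m)$value,
               m$values[1, 1] + m$values[3, 2] + m$values[7, 7])
  expect_equal(network_intensity(m)$n_significant, 3)
  # monotone under adding positive entries to the mask
  before <- network_intensity(m)$value
  m$mask[5, 5] <- TRUE
  expect_gt(network_intensity(m)$value, before)
})

test_that("the interhemispheric matrix flags a genuinely lagged pair", {
  set.seed(16)
  n <- 6 * fs
  qp <- quadrature_pair(n, fs)
  contra <- cbind(C3 = 2 * qp$x + 0.3 * rnorm(n), C1 = rnorm(n))
  ipsi <- cbind(C4 = 2 * qp$y + 0.3 * rnorm(n), C2 = rnorm(n))
  m <- cicoh_matrix(contra, ipsi, fs, c(8, 13), n_surrogates = 100, seed = 6)
  expect_true(m$mask["C3", "C4"])
  expect_gt(abs(m$values["C3", "C4"]), 0.5)
})

test_that("offline ERD recovers the simulator depth and its identities", {
  cfg <- high_snr_config(erd_depth = c(contra = 50, ipsi = 50), erd_sd = 0)
  sp <- session_spec("MID", n_trials = 3)
  sim <- generate_eeg(cfg, sp, seed = 91)
  pp <- offline_preprocess(sim$recording)
  prof <- uniform_profile()
  prof$bands <- list(contra = c(9, 11), ipsi = c(9, 11))
  erd <- erd_offline(pp$recording, prof, trial = 2, cs_time = 9,
                     rejected = pp$rejected)
  expect_lt(abs(erd[["ipsi"]] - 50), 12)
  # a rest slice as "pre-stimulus" gives ~0 (use the 4-5 s rest window)
  erd0 <- erd_offline(pp$recording, prof, trial = 2, cs_time = 5,
                      rejected = pp$rejected)
  expect_lt(abs(erd0[["ipsi"]]), 12)
  # rejected channel among the seven excludes the hemisphere
  rej <- data.frame(trial = 2, channel = "C4")
  erdna <- erd_offline(pp$recording, prof, trial = 2, cs_time = 9,
                       rejected = rej)
  expect_true(is.na(erdna[["ipsi"]]))
  expect_false(is.na(erdna[["contra"]]))
})
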