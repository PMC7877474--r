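test_that("synthesis is seeded-deterministic and validates inputs", {
  m <- small_montage()
  e1 <- synthesize_epochs(2, 6, montage = m, seed = 3L)
  e2 <- synthesize_epochs(2, 6, montage = m, seed = 3L)
  expect_identical(e1$data, e2$data)
  e3 <- synthesize_epochs(2, 6, montage = m, seed = 4L)
  expect_false(identical(e1$data, e3$data))
  expect_equal(dim(e1$data), c(2, 2, 6, 4, 602))
  expect_equal(e1$events, c(fixation = 0, stimulus = 0.35, cue = 1.35))
  expect_error(synthesize_epochs(1, 6, montage = m), "2 subjects")
  expect_error(synthesize_epochs(2, 6, effect_spec(osc_band = c(10, 200)),
                                 montage = m), "band")
  expect_error(synthesize_epochs(2, 6, effect_spec(erp_window = c(0.25, 3)),
                                 montage = m), "window")
})

test_that("background noise has the configured scale and 1/f shape", {
  set.seed(42)
  x <- visreason:::shaped_noise(602, 400, 256, 1, 10)
  expect_equal(sqrt(mean(x^2)), 10, tolerance = 0.02)
  ## average periodogram follows 1/f: power at 5 Hz about 4x power at 20 Hz
  pg <- rowMeans(abs(mvfft(x))^2)
  f <- (seq_len(602) - 1) * 256 / 602
  p5 <- mean(pg[f > 4 & f < 6]); p20 <- mean(pg[f > 18 & f < 22])
  expect_equal(p5 / p20, 4, tolerance = 0.35)
})

test_that("the injected oscillation boosts band power by the configured ratio", {
  ## single posterior channel at the spatial peak, no subject variability:
  ## SD/SR band power ratio in the effect window ~ 10^(osc_db/10)
  m <- small_montage("Oz")
  eff <- effect_spec(osc_db = 3, subject_sd = 0, erp_amp = 0,
                     osc_center = c(m$x[1], m$y[1]))
  ep <- synthesize_epochs(2, 120, eff, m, seed = 9L)
  band_power <- function(sig_mat, sfreq, band, sel) {
    sp <- mvfft(sig_mat)
    f <- (seq_len(nrow(sig_mat)) - 1) * sfreq / nrow(sig_mat)
    f <- pmin(f, sfreq - f)
    keep <- f >= band[1] & f <= band[2]
    sp[!keep, ] <- 0
    env <- Re(mvfft(sp, inverse = TRUE)) / nrow(sig_mat)
    mean(env[sel, ]^2)
  }
  sel <- ep$times >= 0.65 & ep$times <= 1.25       # plateau of the window
  p_sd <- band_power(t(ep$data[1, 1, , 1, ]), 256, c(16, 24), sel)
  p_sr <- band_power(t(ep$data[1, 2, , 1, ]), 256, c(16, 24), sel)
  expect_equal(p_sd / p_sr, 10^(3 / 10), tolerance = 0.15)
})

test_that("null effects make the conditions exchangeable in distribution", {
  m <- small_montage()
  eff <- effect_spec(erp_amp = 0, osc_db = 0)
  ep <- synthesize_epochs(3, 80, eff, m, seed = 12L)
  v_sd <- apply(ep$data[, 1, , , ], 1, var)
  v_sr <- apply(ep$data[, 2, , , ], 1, var)
  expect_equal(v_sd, v_sr, tolerance = 0.05)
  m_sd <- mean(ep$data[, 1, , , ])
  m_sr <- mean(ep$data[, 2, , , ])
  expect_lt(abs(m_sd - m_sr), 0.1)
})

test_that("the epochs container round-trips bitwise and detects corruption", {
  ep <- synthesize_epochs(2, 5, montage = small_montage(), seed = 6L)
  path <- tempfile(fileext = ".bin")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_identical(back$data, ep$data)
  expect_identical(back$ch_names, ep$ch_names)
  expect_equal(back$sfreq, ep$sfreq)
  expect_equal(back$events, ep$events)
  expect_equal(back$times, ep$times)
  ## truncated payload is refused
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz - 100)
  trunc_path <- tempfile(fileext = ".bin")
  writeBin(raw, trunc_path)
  expect_error(read_epochs(trunc_path), "truncated")
  ## non-container file is refused
  junk <- tempfile()
  writeLines("not an epochs file", junk)
  expect_error(read_epochs(junk), "magic")
})
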