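## Synthetic multichannel EEG epochs with controllable condition effects.
##
## Each trial is built as: spectrally shaped 1/f background noise + a
## 10 Hz alpha background with random phase + a condition-shared evoked
## response time-locked to stimulus onset. SD trials additionally receive
## (1) a phase-locked late ERP deflection with centro-parietal weighting
## and (2) an induced (non-phase-locked) amplitude boost of band-limited
## noise in the low beta band with occipito-parietal weighting. Effect
## magnitudes vary between subjects.

#' Schematic 64-channel montage
#'
#' The standard 64-label 10-10 set of a BioSemi-style cap (including the
#' midline electrodes Fpz, AFz, Fz, FCz, Cz, CPz, Pz, POz, Oz, Iz) with
#' schematic 2-D layout coordinates (x: left-negative, y: front-positive)
#' for spatial weighting and simple topography maps.
#'
#' @return Data frame with `label`, `x`, `y`.
#' @export
eeg_montage <- function() {
  row <- function(labels, y, xmax) {
    k <- length(labels)
    x <- if (k == 1) 0 else seq(-xmax, xmax, length.out = k)
    data.frame(label = labels, x = x, y = y)
  }
  rbind(
    row(c("Fp1", "Fpz", "Fp2"), 0.95, 0.35),
    row(c("AF7", "AF3", "AFz", "AF4", "AF8"), 0.78, 0.60),
    row(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 0.60, 0.78),
    row(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), 0.32, 0.85),
    row(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), 0.00, 0.90),
    row(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), -0.32, 0.85),
    row(c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"), -0.60, 0.95),
    row(c("PO7", "PO3", "POz", "PO4", "PO8"), -0.78, 0.60),
    row(c("O1", "Oz", "O2"), -0.95, 0.35),
    row("Iz", -1.08, 0)
  )
}

#' Gaussian spatial weighting over a montage
#'
#' @param montage Data frame from [eeg_montage()] (or a subset).
#' @param center `c(x, y)` of the weighting peak.
#' @param sigma Gaussian width in layout units.
#' @return Numeric weights in (0, 1], one per channel, max 1 at the peak.
#' @export
channel_weights <- function(montage, center, sigma) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Condition-effect specification for the EEG generator
#'
#' Defaults emulate the target phenomenology: a late positive ERP
#' difference over centro-parietal sensors from 250 ms after stimulus
#' onset until the response cue, and an induced low-beta (16-24 Hz) power
#' increase between 250 and 950 ms post-stimulus over occipito-parietal
#' sensors. Both are added to SD trials only. Windows are in seconds
#' relative to stimulus onset.
#'
#' @param erp_amp SD-only ERP deflection amplitude, microvolts.
#' @param erp_window ERP effect window (s post-stimulus).
#' @param erp_center,erp_sigma Spatial weighting (centro-parietal default).
#' @param osc_band Oscillatory effect band, Hz.
#' @param osc_window Oscillatory effect window (s post-stimulus).
#' @param osc_db Oscillatory power increase, dB, at the spatial peak.
#' @param osc_center,osc_sigma Spatial weighting (occipito-parietal default).
#' @param noise_exponent 1/f background exponent (power ~ 1/f^exponent).
#' @param noise_scale Background RMS amplitude, microvolts.
#' @param alpha_amp 10 Hz background alpha amplitude, microvolts.
#' @param common_erp_amp Amplitude scale of the condition-shared evoked
#'   response, microvolts.
#' @param subject_sd Between-subject relative SD of the effect scalings.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(erp_amp = 1.5, erp_window = c(0.25, 1.0),
                        erp_center = c(0, -0.45), erp_sigma = 0.5,
                        osc_band = c(16, 24), osc_window = c(0.25, 0.95),
                        osc_db = 3, osc_center = c(0, -0.8), osc_sigma = 0.55,
                        noise_exponent = 1, noise_scale = 10, alpha_amp = 3,
                        common_erp_amp = 3, subject_sd = 0.25) {
  structure(list(erp_amp = erp_amp, erp_window = erp_window,
                 erp_center = erp_center, erp_sigma = erp_sigma,
                 osc_band = osc_band, osc_window = osc_window,
                 osc_db = osc_db, osc_center = osc_center,
                 osc_sigma = osc_sigma, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, alpha_amp = alpha_amp,
                 common_erp_amp = common_erp_amp, subject_sd = subject_sd),
            class = "effect_spec")
}

## Raised-cosine window mask on a time axis (edges ramp over `ramp` s).
cosine_window <- function(times, lo, hi, ramp = 0.05) {
  m <- numeric(length(times))
  core <- times >= lo + ramp & times <= hi - ramp
  m[core] <- 1
  up <- times >= lo & times < lo + ramp
  m[up] <- 0.5 * (1 - cos(pi * (times[up] - lo) / ramp))
  dn <- times > hi - ramp & times <= hi
  m[dn] <- 0.5 * (1 - cos(pi * (hi - times[dn]) / ramp))
  m
}

## Condition-shared evoked template (unit scale), t relative to stimulus.
evoked_template <- function(t_post) {
  -0.6 * exp(-(t_post - 0.12)^2 / (2 * 0.03^2)) +
    1.0 * exp(-(t_post - 0.40)^2 / (2 * 0.12^2))
}

## Spectral gains for 1/f shaping on an n-point FFT grid.
oneoverf_gains <- function(n, sfreq, exponent) {
  f <- c(0, seq_len(n - 1)) * sfreq / n
  f <- pmin(f, sfreq - f)           # two-sided axis
  f[f < 1] <- 1                     # flatten below 1 Hz (avoid DC blowup)
  f^(-exponent / 2)
}

## Gaussian noise with spectral amplitude shape `g` (on an nfft grid),
## synthesized directly in the frequency domain (one inverse FFT on a
## fast-length grid, truncated to n_t) with overall RMS = scale.
spectral_noise <- function(n_t, n_cols, g, scale) {
  nfft <- length(g)
  z <- matrix(complex(real = rnorm(nfft * n_cols),
                      imaginary = rnorm(nfft * n_cols)), nfft, n_cols)
  x <- Re(mvfft(z * g, inverse = TRUE))[seq_len(n_t), , drop = FALSE]
  x * (scale / sqrt(sum(g^2)))
}

## Shaped-noise matrix (n_t x n_cols): 1/f^exponent spectrum, RMS = scale.
shaped_noise <- function(n_t, n_cols, sfreq, exponent, scale) {
  nfft <- stats::nextn(n_t, c(2, 3, 5))
  spectral_noise(n_t, n_cols, oneoverf_gains(nfft, sfreq, exponent), scale)
}

## Band-limited unit-variance noise matrix (n_t x n_cols).
band_noise <- function(n_t, n_cols, sfreq, band) {
  nfft <- stats::nextn(n_t, c(2, 3, 5))
  f <- c(0, seq_len(nfft - 1)) * sfreq / nfft
  f <- pmin(f, sfreq - f)
  spectral_noise(n_t, n_cols, as.numeric(f >= band[1] & f <= band[2]), 1)
}

## Fraction of total 1/f noise power falling inside `band`.
band_power_fraction <- function(n_t, sfreq, exponent, band) {
  nfft <- stats::nextn(n_t, c(2, 3, 5))
  g2 <- oneoverf_gains(nfft, sfreq, exponent)^2
  f <- c(0, seq_len(nfft - 1)) * sfreq / nfft
  f <- pmin(f, sfreq - f)
  sum(g2[f >= band[1] & f <= band[2]]) / sum(g2)
}

#' Synthesize a multichannel EEG epochs set
#'
#' Generates `n_subjects` x 2 conditions (SD, SR) x trials x channels x
#' time epochs at `sfreq` Hz spanning `t0`..`t_end` seconds around
#' fixation onset (stimulus at +350 ms, response cue at +1350 ms).
#' See [effect_spec()] for the signal model. With all effect amplitudes
#' zero the two conditions are statistically exchangeable. Memory grows as
#' the product of all five dimensions; reduce `trials_per_condition` or
#' the montage for large simulation studies.
#'
#' @param n_subjects Number of subjects (>= 2; default 14).
#' @param trials_per_condition Trials per condition per subject
#'   (default 560 = 8 blocks x 70 trials).
#' @param effect An [effect_spec()].
#' @param montage Channel table (default the full 64-channel montage); a
#'   subset selects a reduced montage.
#' @param sfreq Sampling rate, Hz (default 256).
#' @param t0,t_end Epoch span in seconds relative to fixation onset
#'   (defaults -0.35 and 2.0, so both the pre-fixation and the
#'   pre-stimulus baselines exist).
#' @param seed Integer seed; same seed gives identical arrays.
#' @return Object of class `epochs_set` with `data` (5-D array: subject,
#'   condition, trial, channel, time), `times`, `sfreq`, `ch_names`,
#'   `montage`, `events`, `conditions`.
#' @export
synthesize_epochs <- function(n_subjects = 14L, trials_per_condition = 560L,
                              effect = effect_spec(), montage = eeg_montage(),
                              sfreq = 256, t0 = -0.35, t_end = 2.0, seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (effect$osc_band[1] <= 0 || effect$osc_band[2] >= sfreq / 2)
    stop("oscillatory band must lie inside (0, sfreq/2)")
  n_t <- floor((t_end - t0) * sfreq) + 1L
  times <- t0 + (seq_len(n_t) - 1L) / sfreq
  events <- c(fixation = 0, stimulus = 0.35, cue = 1.35)
  stim <- events[["stimulus"]]
  for (wnd in list(effect$erp_window + stim, effect$osc_window + stim))
    if (wnd[1] < t0 || wnd[2] > t_end) stop("effect window outside the epoch")
  n_ch <- nrow(montage)
  ntr <- trials_per_condition
  conditions <- c("SD", "SR")

  w_erp <- channel_weights(montage, effect$erp_center, effect$erp_sigma)
  w_osc <- channel_weights(montage, effect$osc_center, effect$osc_sigma)
  erp_mask <- cosine_window(times, effect$erp_window[1] + stim,
                            effect$erp_window[2] + stim)
  osc_mask <- cosine_window(times, effect$osc_window[1] + stim,
                            effect$osc_window[2] + stim)
  common_erp <- effect$common_erp_amp * evoked_template(times - stim)
  p_band <- effect$noise_scale^2 *
    band_power_fraction(n_t, sfreq, effect$noise_exponent, effect$osc_band)

  data <- array(0, c(n_subjects, 2L, ntr, n_ch, n_t))
  with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      g_erp <- rnorm(1, 1, effect$subject_sd)
      g_osc <- rnorm(1, 1, effect$subject_sd)
      for (ci in 1:2) {
        ## base: (n_t x n_ch*ntr), column index ch + (tr-1)*n_ch
        base <- shaped_noise(n_t, n_ch * ntr, sfreq, effect$noise_exponent,
                             effect$noise_scale)
        phases <- runif(ntr, 0, 2 * pi)
        alpha <- effect$alpha_amp *
          sin(outer(times, rep(1, ntr)) * 2 * pi * 10 +
                outer(rep(1, n_t), phases))
        base <- base + alpha[, rep(seq_len(ntr), each = n_ch)]
        base <- base + as.vector(outer(common_erp, w_erp))  # recycles per trial
        if (ci == 1L) {                                      # SD-only effects
          base <- base + g_erp * effect$erp_amp *
            as.vector(outer(erp_mask, w_erp))
          db_ch <- effect$osc_db * g_osc * w_osc
          amp_ch <- sqrt(pmax(10^(db_ch / 10) - 1, 0) * p_band)
          bn <- band_noise(n_t, ntr, sfreq, effect$osc_band) * osc_mask
          keep <- which(amp_ch > 0.02 * max(amp_ch))
          for (ch in keep) {
            cols <- ch + (seq_len(ntr) - 1L) * n_ch
            base[, cols] <- base[, cols] + amp_ch[ch] * bn
          }
        }
        dim(base) <- c(n_t, n_ch, ntr)
        data[s, ci, , , ] <- aperm(base, c(3, 2, 1))
      }
    }
  })
  structure(list(data = data, times = times, sfreq = sfreq,
                 ch_names = montage$label, montage = montage,
                 events = events, conditions = conditions, effect = effect,
                 seed = as.integer(seed)),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs_set> %d subjects x %s x %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], paste(x$conditions, collapse = "/"), d[3], d[4], d[5], x$sfreq))
  invisible(x)
}

# ------------------------------------------------------------------ IO ----

EPOCHS_MAGIC <- "VREEG01"

#' Write an epochs set to a self-describing binary container
#'
#' Layout: a 7-byte magic string, a 4-byte little-endian header length, a
#' JSON header (dimensions, times, channels, events, metadata), then the
#' data as IEEE-754 little-endian doubles in R array order. The round trip
#' is bitwise lossless.
#'
#' @param set An `epochs_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(set, path) {
  header <- jsonlite::toJSON(list(
    dims = dim(set$data), sfreq = set$sfreq, t_start = set$times[1],
    ch_names = set$ch_names,
    montage_x = set$montage$x, montage_y = set$montage$y,
    events = as.list(set$events), conditions = set$conditions,
    seed = set$seed), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(EPOCHS_MAGIC, con, eos = NULL)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(set$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an epochs set written by [write_epochs()]
#'
#' Validates the magic string and the expected payload size, so a
#' truncated or corrupted file raises an error instead of returning
#' partial data.
#'
#' @param path File path.
#' @return An `epochs_set`.
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(EPOCHS_MAGIC), useBytes = TRUE)
  if (!identical(magic, EPOCHS_MAGIC))
    stop("not an epochs container (bad magic string)")
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hlen) != 1 || hlen <= 0 || hlen > 1e7)
    stop("corrupt epochs container header")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  dims <- header$dims
  n <- prod(dims)
  expected <- nchar(EPOCHS_MAGIC) + 4 + hlen + 8 * n
  if (file.size(path) != expected)
    stop(sprintf("epochs container truncated: expected %.0f bytes, found %.0f",
                 expected, file.size(path)))
  data <- readBin(con, "double", n, size = 8L, endian = "little")
  dim(data) <- dims
  n_t <- dims[5]
  times <- header$t_start + (seq_len(n_t) - 1L) / header$sfreq
  montage <- data.frame(label = header$ch_names, x = header$montage_x,
                        y = header$montage_y)
  structure(list(data = data, times = times, sfreq = header$sfreq,
                 ch_names = header$ch_names, montage = montage,
                 events = unlist(header$events), conditions = header$conditions,
                 effect = NULL, seed = header$seed),
            class = "epochs_set")
}
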