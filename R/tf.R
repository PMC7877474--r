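## Time-frequency analysis: complex Morlet wavelet power, dB baseline
## correction, all-electrode condition-difference maps, cluster-based
## permutation statistics and the within-cluster effect size.

#' Morlet wavelet specification
#'
#' Log-spaced frequency grid with cycle counts increasing linearly in log
#' frequency between the two endpoints (defaults 1 cycle at 1 Hz to 20
#' cycles at 50 Hz). The wavelet at frequency f has Gaussian envelope
#' SD `sigma_t = cycles / (2 pi f)` and is truncated at
#' `support_sigmas * sigma_t`; samples closer than that to an epoch edge
#' are flagged invalid and excluded from statistics.
#'
#' @param n_freqs Number of frequencies (default 50).
#' @param f_range Frequency range in Hz (default 1-50).
#' @param cycles_range Cycle counts at the two range endpoints.
#' @param sfreq Sampling rate, Hz.
#' @param support_sigmas Truncation half-width in envelope SDs.
#' @return A `wavelet_spec` with `freqs`, `cycles`, `sigma_t`.
#' @export
wavelet_spec <- function(n_freqs = 50L, f_range = c(1, 50),
                         cycles_range = c(1, 20), sfreq = 256,
                         support_sigmas = 3) {
  freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freqs))
  cycles <- cycles_range[1] + (cycles_range[2] - cycles_range[1]) *
    (log(freqs) - log(f_range[1])) / (log(f_range[2]) - log(f_range[1]))
  structure(list(freqs = freqs, cycles = cycles,
                 sigma_t = cycles / (2 * pi * freqs), sfreq = sfreq,
                 support_sigmas = support_sigmas),
            class = "wavelet_spec")
}

## Sampled complex Morlet wavelet, unit gain at its center frequency.
morlet_kernel <- function(f, sigma_t, sfreq, support_sigmas) {
  L <- ceiling(support_sigmas * sigma_t * sfreq)
  t <- (-L:L) / sfreq
  env <- exp(-t^2 / (2 * sigma_t^2))
  list(w = env * exp(2i * pi * f * t) / sum(env), L = L)
}

#' Morlet wavelet power of a signal
#'
#' Squared magnitude of the complex Morlet convolution at every grid
#' frequency (FFT-based, same-length output). A unit-amplitude sinusoid at
#' a grid frequency yields power 0.25 there (analytic amplitude 0.5);
#' power scales quadratically with signal amplitude. Samples within the
#' truncated wavelet support of either epoch edge are flagged invalid.
#'
#' @param x Numeric vector (one signal) or matrix (time x signals).
#' @param spec A [wavelet_spec()].
#' @return List with `power` (freqs x times, or freqs x times x signals),
#'   `valid` (freqs x times logical), `freqs`.
#' @export
morlet_power <- function(x, spec) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n_t <- nrow(xm)
  maxL <- ceiling(spec$support_sigmas * max(spec$sigma_t) * spec$sfreq)
  if (n_t <= 2 * maxL)
    stop(sprintf("signal too short: %d samples, longest wavelet needs > %d",
                 n_t, 2 * maxL))
  nf <- length(spec$freqs)
  nfft <- stats::nextn(n_t + 2 * maxL, 2)
  X <- mvfft(rbind(xm, matrix(0, nfft - n_t, ncol(xm))))
  power <- array(NA_real_, c(nf, n_t, ncol(xm)))
  valid <- matrix(FALSE, nf, n_t)
  for (i in seq_len(nf)) {
    k <- morlet_kernel(spec$freqs[i], spec$sigma_t[i], spec$sfreq,
                       spec$support_sigmas)
    wf <- fft(c(k$w, rep(0, nfft - length(k$w))))
    conv <- mvfft(X * wf, inverse = TRUE) / nfft
    ## wavelet center lag is L: output sample t lives at conv row t + L
    rows <- seq_len(n_t) + k$L
    power[i, , ] <- t(abs(conv[rows, , drop = FALSE])^2)
    valid[i, ] <- seq_len(n_t) > k$L & seq_len(n_t) <= n_t - k$L
  }
  if (!is.matrix(x)) power <- power[, , 1]
  list(power = power, valid = valid, freqs = spec$freqs)
}

## Batched, decimated Morlet power via matrix products: power is evaluated
## only at `keep` time indices (every `decim`-th sample), which is what
## makes large simulation studies tractable.
## X: (n_t x n_signals). Returns array (n_freqs x n_keep x n_signals).
morlet_power_batch <- function(X, spec, decim = 1L, kernels = NULL) {
  n_t <- nrow(X)
  if (is.null(kernels)) kernels <- morlet_kernel_mats(spec, n_t, decim)
  keep <- kernels$keep
  nf <- length(spec$freqs)
  out <- array(NA_real_, c(nf, length(keep), ncol(X)))
  for (i in seq_len(nf))
    out[i, , ] <- (kernels$Kre[[i]] %*% X)^2 + (kernels$Kim[[i]] %*% X)^2
  attr(out, "valid") <- kernels$valid
  attr(out, "keep") <- keep
  out
}

## Precomputed sparse-in-time wavelet kernel matrices for a given epoch
## length and decimation: row j of Kre/Kim applies the (real/imaginary)
## wavelet centered at sample keep[j].
morlet_kernel_mats <- function(spec, n_t, decim = 1L) {
  keep <- seq(1L, n_t, by = decim)
  nf <- length(spec$freqs)
  Kre <- Kim <- vector("list", nf)
  valid <- matrix(FALSE, nf, length(keep))
  for (i in seq_len(nf)) {
    k <- morlet_kernel(spec$freqs[i], spec$sigma_t[i], spec$sfreq,
                       spec$support_sigmas)
    lags <- -k$L:k$L
    idx <- outer(keep, lags, "+")
    ok <- idx >= 1 & idx <= n_t
    idx[!ok] <- 1L
    wr <- matrix(Re(k$w)[rep(seq_along(lags), each = length(keep))],
                 length(keep)) * ok
    wi <- matrix(Im(k$w)[rep(seq_along(lags), each = length(keep))],
                 length(keep)) * ok
    Kre[[i]] <- matrix(0, length(keep), n_t)
    Kim[[i]] <- matrix(0, length(keep), n_t)
    ii <- cbind(rep(seq_along(keep), length(lags)), as.vector(idx))
    Kre[[i]][ii] <- Kre[[i]][ii] + as.vector(wr)
    Kim[[i]][ii] <- Kim[[i]][ii] + as.vector(wi)
    valid[i, ] <- keep > k$L & keep <= n_t - k$L
  }
  list(Kre = Kre, Kim = Kim, valid = valid, keep = keep)
}

#' Decibel baseline correction of a power map
#'
#' `10 * log10(power / mean baseline power per frequency)`. The baseline
#' mean is taken over the window samples at each frequency.
#'
#' @param power Matrix (freqs x times).
#' @param times Time axis (s) matching the columns.
#' @param baseline Window `c(lo, hi)` in the same time units.
#' @return Matrix of dB values.
#' @export
db_baseline <- function(power, times, baseline) {
  bidx <- which(times >= baseline[1] & times <= baseline[2])
  if (length(bidx) == 0) stop("baseline window outside the time axis")
  base <- rowMeans(power[, bidx, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(base) | base <= 0))
    stop("nonpositive or undefined baseline power")
  10 * log10(power / base)
}

#' Per-subject all-electrode SD-SR difference maps in dB
#'
#' For each subject and condition: per-trial Morlet power, averaged over
#' trials (induced power) per channel, dB-corrected against the mean
#' power in the pre-fixation baseline window, averaged over all channels;
#' the result is the SD-SR difference map per subject. Edge samples
#' within the wavelet support are NA and excluded from later statistics.
#'
#' @param epochs An `epochs_set`.
#' @param spec A [wavelet_spec()] (use its `sfreq` matching the epochs).
#' @param baseline dB baseline window in epoch time (default the 350 ms
#'   before fixation onset, `c(-0.35, 0)`).
#' @param decim Time decimation factor for the power maps (default 8).
#' @return Array (subjects x freqs x times) with `freqs`, `times`,
#'   `valid` attributes.
#' @export
condition_diff_maps <- function(epochs, spec = wavelet_spec(sfreq = epochs$sfreq),
                                baseline = c(-0.35, 0), decim = 8L) {
  d <- dim(epochs$data)
  n_subj <- d[1]; ntr <- d[3]; n_ch <- d[4]; n_t <- d[5]
  kernels <- morlet_kernel_mats(spec, n_t, decim)
  keep <- kernels$keep
  valid <- kernels$valid
  tk <- epochs$times[keep]
  maps <- array(NA_real_, c(n_subj, length(spec$freqs), length(keep)))
  for (s in seq_len(n_subj)) {
    db <- vector("list", 2)
    for (ci in 1:2) {
      x <- aperm(epochs$data[s, ci, , , ], c(3, 1, 2))   # time x trial x ch
      dim(x) <- c(n_t, ntr * n_ch)
      pw <- morlet_power_batch(x, spec, decim, kernels)
      nf <- length(spec$freqs); nk <- length(keep)
      dim(pw) <- c(nf * nk, ntr, n_ch)
      dbsum <- matrix(0, nf, nk)
      for (ch in seq_len(n_ch)) {                         # induced power:
        avg <- matrix(rowMeans(pw[, , ch]), nf, nk)       # trial-average
        dbsum <- dbsum + db_baseline(avg, tk, baseline)
      }
      db[[ci]] <- dbsum / n_ch                            # channel average
    }
    m <- db[[1]] - db[[2]]
    m[!valid] <- NA_real_
    maps[s, , ] <- m
  }
  attr(maps, "freqs") <- spec$freqs
  attr(maps, "times") <- tk
  attr(maps, "valid") <- valid
  maps
}

#' Cluster-permutation configuration
#'
#' @param t_threshold Cluster-forming threshold on |t| (default 3.5,
#'   two-tailed p < 0.01 at typical subject counts).
#' @param n_permutations Number of sign-flip permutations (default 500).
#' @param alpha Cluster significance level (default 0.05).
#' @param seed Integer seed for the permutation draws.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(t_threshold = 3.5, n_permutations = 500L,
                           alpha = 0.05, seed = 1L) {
  if (n_permutations < 1) stop("need at least 1 permutation")
  structure(list(t_threshold = t_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "cluster_config")
}

## One-sample t map over subjects (rows of a (n x p) matrix); NA cells
## (any subject NA) give NA t.
t_map_of <- function(mat, n) {
  m <- colMeans(mat)
  s2 <- (colSums(mat^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tv <- m / sqrt(s2 / n)
  tv[!is.finite(tv)] <- NA_real_
  tv
}

## Maximal 4-connected components of uniform sign exceeding |thr|.
## tm: (nf x nt) matrix possibly with NA. Returns list of clusters,
## each list(cells = integer vector of linear indices, sign, mass).
find_clusters <- function(tm, thr) {
  nf <- nrow(tm); nt <- ncol(tm)
  lab <- matrix(0L, nf, nt)
  supra <- !is.na(tm) & abs(tm) > thr
  clusters <- list()
  for (start in which(supra)) {
    if (lab[start] > 0L) next
    sgn <- sign(tm[start])
    queue <- start
    lab[start] <- 1L
    cells <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells <- c(cells, cur)
      r <- (cur - 1L) %% nf + 1L
      c <- (cur - 1L) %/% nf + 1L
      for (nb in c(if (r > 1) cur - 1L, if (r < nf) cur + 1L,
                   if (c > 1) cur - nf, if (c < nt) cur + nf)) {
        if (lab[nb] == 0L && supra[nb] && sign(tm[nb]) == sgn) {
          lab[nb] <- 1L
          queue <- c(queue, nb)
        }
      }
    }
    clusters[[length(clusters) + 1L]] <-
      list(cells = sort(cells), sign = sgn, mass = sum(tm[cells]))
  }
  clusters
}

#' Cluster-based permutation test on subject difference maps
#'
#' Forms clusters of adjacent (4-neighbour) time-frequency points whose
#' one-sample two-tailed t values exceed the threshold with uniform sign,
#' scores each by its mass (sum of member t values), and compares against
#' a null distribution of the maximum absolute cluster mass obtained by
#' randomly flipping each subject's difference-map sign (exact label
#' exchange for a paired two-condition design). Cluster p-values are
#' `(1 + #{null >= |mass|}) / (n_permutations + 1)`.
#'
#' @param maps Array (subjects x freqs x times) from
#'   [condition_diff_maps()] (NA cells are excluded).
#' @param config A [cluster_config()].
#' @return Object of class `tf_stat_result`: `t_map`, `clusters` (data
#'   frame: id, sign, mass, p, extents), `cluster_cells`, `sig_mask`,
#'   `null_max`, plus the axes.
#' @export
cluster_permutation_test <- function(maps, config = cluster_config()) {
  dm <- dim(maps)
  n <- dm[1]
  if (n < 2) stop("need at least 2 subjects")
  nf <- dm[2]; nt <- dm[3]
  mat <- matrix(maps, n, nf * nt)
  tv <- matrix(t_map_of(mat, n), nf, nt)
  obs <- find_clusters(tv, config$t_threshold)
  null_max <- with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      tp <- matrix(t_map_of(signs * mat, n), nf, nt)
      cl <- find_clusters(tp, config$t_threshold)
      if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
    }, 0)
  })
  p <- vapply(obs, function(cl)
    (1 + sum(null_max >= abs(cl$mass))) / (config$n_permutations + 1), 0)
  sig_mask <- matrix(FALSE, nf, nt)
  freqs <- attr(maps, "freqs"); times <- attr(maps, "times")
  tab <- NULL
  if (length(obs)) {
    for (i in seq_along(obs))
      if (p[i] <= config$alpha) sig_mask[obs[[i]]$cells] <- TRUE
    tab <- do.call(rbind, lapply(seq_along(obs), function(i) {
      r <- (obs[[i]]$cells - 1L) %% nf + 1L
      cc <- (obs[[i]]$cells - 1L) %/% nf + 1L
      data.frame(id = i, sign = obs[[i]]$sign, n_cells = length(obs[[i]]$cells),
                 mass = obs[[i]]$mass, p = p[i],
                 f_lo = if (is.null(freqs)) min(r) else min(freqs[r]),
                 f_hi = if (is.null(freqs)) max(r) else max(freqs[r]),
                 t_lo = if (is.null(times)) min(cc) else min(times[cc]),
                 t_hi = if (is.null(times)) max(cc) else max(times[cc]))
    }))
    tab <- tab[order(tab$p, -abs(tab$mass)), ]
  } else {
    tab <- data.frame(id = integer(0), sign = numeric(0), n_cells = integer(0),
                      mass = numeric(0), p = numeric(0), f_lo = numeric(0),
                      f_hi = numeric(0), t_lo = numeric(0), t_hi = numeric(0))
  }
  structure(list(t_map = tv, clusters = tab,
                 cluster_cells = lapply(obs, `[[`, "cells"),
                 cluster_p = p, sig_mask = sig_mask, null_max = null_max,
                 config = config, freqs = freqs, times = times),
            class = "tf_stat_result")
}

#' @export
print.tf_stat_result <- function(x, ...) {
  cat(sprintf("<tf_stat_result> %d x %d t-map, %d cluster(s), min p %s\n",
              nrow(x$t_map), ncol(x$t_map), nrow(x$clusters),
              if (nrow(x$clusters)) format(min(x$clusters$p), digits = 3) else "-"))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 5))
  invisible(x)
}

#' Effect size of the significant time-frequency region
#'
#' Averages each subject's map over the masked cells, then runs a
#' two-tailed one-sample t test against zero; Cohen's d is the mean over
#' the SD of those subject means (d = t / sqrt(n)).
#'
#' @param maps Array (subjects x freqs x times).
#' @param sig_mask Logical (freqs x times) mask, e.g. from
#'   [cluster_permutation_test()].
#' @return List with `t`, `df`, `p`, `d`, `subject_means`.
#' @export
cluster_effect_size <- function(maps, sig_mask) {
  if (!any(sig_mask)) stop("empty significance mask")
  n <- dim(maps)[1]
  sm <- vapply(seq_len(n), function(s) {
    m <- maps[s, , ]
    mean(m[sig_mask], na.rm = TRUE)
  }, 0)
  s <- sd(sm)
  if (s == 0) stop("zero variance of subject means: effect size undefined")
  t <- mean(sm) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), d = t / sqrt(n),
       subject_means = sm)
}

#' One-sample t helpers on summary statistics
#'
#' `t_to_p` gives the two-tailed p of a t statistic; `cohens_d_from_t`
#' converts a one-sample t at sample size n to Cohen's d.
#'
#' @param t t statistic.
#' @param df Degrees of freedom.
#' @param n Sample size.
#' @return Numeric scalar.
#' @export
t_to_p <- function(t, df) 2 * pt(-abs(t), df)

#' @rdname t_to_p
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Export a cluster table as CSV
#'
#' The header records the cluster-forming threshold and permutation count.
#' @param result A `tf_stat_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_threshold=%g n_permutations=%d alpha=%g seed=%d",
                     result$config$t_threshold, result$config$n_permutations,
                     result$config$alpha, result$config$seed), con)
  write.csv(result$clusters, con, row.names = FALSE)
  invisible(path)
}
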