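## ERP condition-difference analysis: baseline-subtracted per-subject
## averages, pointwise one-sample t tests on the SD-SR difference over the
## midline electrodes, Benjamini-Hochberg FDR correction, and a window
## topography.

#' The seven midline electrodes used for ERP statistics
#' @export
midline_electrodes <- function() c("Oz", "POz", "Pz", "CPz", "Cz", "FCz", "Fz")

#' Compute per-subject, per-condition ERPs
#'
#' Subtracts each trial's mean over the baseline window, then averages
#' over trials. The default baseline is the 350 ms before stimulus onset
#' (epoch times 0..0.35 s, i.e. the fixation period).
#'
#' @param epochs An `epochs_set`.
#' @param baseline Baseline window `c(lo, hi)` in epoch time (s).
#' @return Array (subject, condition, channel, time) of microvolt ERPs,
#'   with `times` and `ch_names` attributes.
#' @export
compute_erps <- function(epochs, baseline = c(0, 0.35)) {
  d <- dim(epochs$data)
  if (any(d[3] == 0)) stop("empty condition: no trials to average")
  bidx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  if (length(bidx) == 0) stop("baseline window outside the epoch")
  erps <- array(0, c(d[1], d[2], d[4], d[5]))
  for (s in seq_len(d[1]))
    for (ci in seq_len(d[2])) {
      x <- epochs$data[s, ci, , , ]                  # trials x ch x time
      bl <- apply(x[, , bidx, drop = FALSE], c(1, 2), mean)
      erps[s, ci, , ] <- apply(x - as.vector(bl), c(2, 3), mean)
    }
  attr(erps, "times") <- epochs$times
  attr(erps, "ch_names") <- epochs$ch_names
  attr(erps, "conditions") <- epochs$conditions
  erps
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH procedure returning both the rejection mask at level `q`
#' and the adjusted p-values (monotone nondecreasing in raw-p rank).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `mask` (logical) and `p_adj`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(mask = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

#' Pointwise t test of the SD-SR ERP difference with FDR correction
#'
#' For every (electrode, time) point, a two-tailed one-sample t test of
#' the subject-wise SD-SR difference against zero, followed by
#' Benjamini-Hochberg correction pooled jointly over all electrode x time
#' points (or per electrode).
#'
#' @param erps Output of [compute_erps()].
#' @param electrodes Electrode labels to test (default the midline seven).
#' @param q FDR level.
#' @param pool `"joint"` (default) pools p-values across electrodes and
#'   time; `"per_electrode"` corrects each electrode separately.
#' @return Object of class `erp_result`: arrays (electrode x time) of the
#'   mean difference, its standard error, t, p, adjusted p and the
#'   significance mask.
#' @export
erp_difference_test <- function(erps, electrodes = midline_electrodes(),
                                q = 0.05, pool = c("joint", "per_electrode")) {
  pool <- match.arg(pool)
  ch_names <- attr(erps, "ch_names")
  times <- attr(erps, "times")
  idx <- match(electrodes, ch_names)
  if (anyNA(idx)) stop("unknown electrode(s): ",
                       paste(electrodes[is.na(idx)], collapse = ", "))
  n <- dim(erps)[1]
  if (n < 2) stop("need at least 2 subjects")
  diffs <- erps[, 1, idx, , drop = FALSE] - erps[, 2, idx, , drop = FALSE]
  diffs <- array(diffs, c(n, length(idx), length(times)))
  m <- apply(diffs, c(2, 3), mean)
  s <- apply(diffs, c(2, 3), sd)
  se <- s / sqrt(n)
  t_val <- m / se
  zero_var <- s == 0
  if (any(zero_var)) {
    warning("zero variance at ", sum(zero_var), " points; p set to 1")
    t_val[zero_var] <- 0
  }
  p <- 2 * pt(-abs(t_val), df = n - 1)
  p[zero_var] <- 1
  if (pool == "joint") {
    fdr <- bh_fdr(as.vector(p), q)
    mask <- matrix(fdr$mask, nrow(p), ncol(p))
    p_adj <- matrix(fdr$p_adj, nrow(p), ncol(p))
  } else {
    mask <- p_adj <- p * 0
    for (i in seq_len(nrow(p))) {
      fdr <- bh_fdr(p[i, ], q)
      mask[i, ] <- fdr$mask
      p_adj[i, ] <- fdr$p_adj
    }
    mask <- mask > 0
  }
  dimnames(m) <- dimnames(se) <- dimnames(t_val) <- dimnames(p) <-
    dimnames(p_adj) <- dimnames(mask) <- list(electrodes, NULL)
  structure(list(mean = m, se = se, t = t_val, p = p, p_adj = p_adj,
                 mask = mask, electrodes = electrodes, times = times,
                 q = q, pool = pool, n_subjects = n),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf(
    "<erp_result> %d electrodes x %d time points, n=%d; %d significant points (BH q=%g)\n",
    nrow(x$t), ncol(x$t), x$n_subjects, sum(x$mask), x$q))
  invisible(x)
}

#' Per-channel mean SD-SR difference over a time window
#'
#' The topography companion of the midline analysis: the mean difference
#' over all channels within a post-stimulus window (default 250-1000 ms
#' after stimulus onset, i.e. epoch times 0.6-1.35 s).
#'
#' @param erps Output of [compute_erps()].
#' @param window Window in epoch time (s).
#' @return Data frame `label`, `diff` (microvolts).
#' @export
erp_topography <- function(erps, window = c(0.6, 1.35)) {
  times <- attr(erps, "times")
  tidx <- which(times >= window[1] & times <= window[2])
  diffs <- erps[, 1, , tidx, drop = FALSE] - erps[, 2, , tidx, drop = FALSE]
  data.frame(label = attr(erps, "ch_names"),
             diff = apply(diffs, 3, mean))
}

#' Export an ERP result as a long-format CSV
#'
#' @param result An `erp_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_erp_result <- function(result, path) {
  long <- do.call(rbind, lapply(seq_along(result$electrodes), function(i) {
    data.frame(electrode = result$electrodes[i], time = result$times,
               mean = result$mean[i, ], se = result$se[i, ],
               t = result$t[i, ], p = result$p[i, ],
               p_adj = result$p_adj[i, ], sig = result$mask[i, ])
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
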