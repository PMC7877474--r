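# Independent brute-force oracles used across the suite. These deliberately
# use different algorithms and data structures from the package code paths
# they check.

# --- polyomino counting oracle -------------------------------------------
# Enumerate all fixed polyominoes (translation-only canonical form) of size
# n by growth, keyed on a string of the translation-normalized cell set.
oracle_fixed_polyominoes <- function(n) {
  norm_key <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    o <- order(cells[, 1] * 1000 + cells[, 2])
    paste(cells[o, 1] * 1000 + cells[o, 2], collapse = "_")
  }
  shapes <- list(matrix(c(0L, 0L), ncol = 2))
  for (size in seq_len(n)[-1]) {
    seen <- character(0)
    nxt <- list()
    for (cells in shapes) {
      have <- paste(cells[, 1], cells[, 2])
      for (i in seq_len(nrow(cells)))
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          cand <- cells[i, ] + d
          if (paste(cand[1], cand[2]) %in% have) next
          grown <- rbind(cells, cand)
          key <- norm_key(grown)
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            nxt[[length(nxt) + 1L]] <- grown
          }
        }
    }
    shapes <- nxt
  }
  shapes
}

# Free count: group fixed shapes by the minimum over the 8 dihedral images
# of a binary-matrix string key (different canonical key than the package).
oracle_free_count <- function(fixed_shapes) {
  mat_key <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    m <- matrix(0L, max(cells[, 1]) + 1L, max(cells[, 2]) + 1L)
    m[cells + 1L] <- 1L
    paste(dim(m)[1], paste(m, collapse = ""), sep = ":")
  }
  all_images <- function(cells) {
    r <- cells[, 1]; c <- cells[, 2]
    list(cbind(r, c), cbind(c, -r), cbind(-r, -c), cbind(-c, r),
         cbind(r, -c), cbind(-c, -r), cbind(-r, c), cbind(c, r))
  }
  keys <- vapply(fixed_shapes, function(cells)
    min(vapply(all_images(cells), mat_key, character(1))), character(1))
  length(unique(keys))
}

# --- Benjamini-Hochberg oracle -------------------------------------------
# Literal step-up definition: reject H_(1..k*) where k* is the largest k
# with p_(k) <= k q / m.
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(below)) mask[o[seq_len(max(below))]] <- TRUE
  mask
}

# --- connected-component oracle ------------------------------------------
# Label suprathreshold cells of uniform sign by iterative label propagation
# to 4-neighbours until a fixpoint (very different from a BFS queue).
oracle_clusters <- function(tm, thr) {
  nf <- nrow(tm); nt <- ncol(tm)
  supra <- !is.na(tm) & abs(tm) > thr
  lab <- matrix(0L, nf, nt)
  lab[supra] <- seq_len(sum(supra))
  repeat {
    changed <- FALSE
    for (r in seq_len(nf)) for (cc in seq_len(nt)) {
      if (!supra[r, cc]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nf || c2 < 1 || c2 > nt) next
        if (supra[r2, c2] && sign(tm[r2, c2]) == sign(tm[r, cc]) &&
            lab[r2, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[r2, c2]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids <- setdiff(unique(as.vector(lab)), 0L)
  out <- lapply(ids, function(id) sort(which(lab == id)))
  out[order(vapply(out, min, 0L))]
}

# --- direct-convolution Morlet oracle ------------------------------------
# Time-domain dot products with an independently constructed wavelet.
oracle_morlet_power_at <- function(x, f, cycles, sfreq, t_idx) {
  sigma <- cycles / (2 * pi * f)
  L <- ceiling(3 * sigma * sfreq)
  tt <- (-L:L) / sfreq
  env <- exp(-tt^2 / (2 * sigma^2))
  wr <- env * cos(2 * pi * f * tt) / sum(env)
  wi <- env * sin(2 * pi * f * tt) / sum(env)
  vapply(t_idx, function(ti) {
    idx <- ti + (-L:L)
    stopifnot(all(idx >= 1 & idx <= length(x)))
    sum(x[idx] * rev(wr))^2 + sum(x[idx] * rev(wi))^2
  }, 0)
}

# --- misc helpers ---------------------------------------------------------
small_montage <- function(labels = c("Oz", "POz", "Pz", "CPz")) {
  m <- eeg_montage()
  m[m$label %in% labels, ]
}
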