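## Stimulus geometry: pair placement, SD/SR ground truth, 50x80 rendering.
##
## Coordinate conventions (stated once, used everywhere):
##  * math frame: x rightward, y upward, origin at screen/image center;
##    angles in degrees counterclockwise from the horizontal.
##  * raster frame: row 1 = top, column 1 = left; row = center_row - y,
##    col = center_col + x.
## "Vertical" alignment means the inter-item axis is closer to the vertical
## midline than to the horizontal one.

#' Placement specification for an item pair
#'
#' Two items are placed at opposite sides of the screen center, each at
#' distance `rho` from it, along the diagonal `axis` (+45 or -45 degrees)
#' rotated by a signed angular offset `theta` (positive values rotate the
#' inter-item axis toward the vertical). Both items receive the same jitter
#' `(dx, dy)`, so the jitter never changes the inter-item angle or the
#' center-to-center distance (2 * rho).
#'
#' @param rho Eccentricity: distance from center to each item center (> 0).
#' @param theta Signed angular offset from the diagonal, degrees, |theta| <= 45.
#' @param axis Which diagonal: `+45` or `-45`.
#' @param dx,dy Shared jitter applied to both items.
#' @return A `placement_spec` list.
#' @export
placement_spec <- function(rho, theta = 0, axis = 45, dx = 0, dy = 0) {
  if (rho <= 0) stop("rho must be positive")
  if (!axis %in% c(45, -45)) stop("axis must be +45 or -45")
  if (abs(theta) > 45) stop("|theta| must be <= 45 degrees")
  structure(list(rho = rho, theta = theta, axis = axis, dx = dx, dy = dy),
            class = "placement_spec")
}

## Inter-item axis angle in the math frame: rotating by +theta moves the
## axis toward vertical on either diagonal.
axis_angle <- function(spec) spec$axis + sign(spec$axis) * spec$theta

#' Compute the two item-center coordinates for a placement
#'
#' @param spec A [placement_spec()].
#' @return 2x2 matrix; rows are items a and b, columns (x, y) in the math
#'   frame relative to the screen center.
#' @examples
#' p <- place_pair(placement_spec(rho = 5.4, theta = 0, axis = 45))
#' sqrt(sum((p[1, ] - p[2, ])^2))  # exactly 2 * rho
#' @export
place_pair <- function(spec) {
  a <- axis_angle(spec) * pi / 180
  u <- c(cos(a), sin(a))
  rbind(a = c(spec$dx, spec$dy) + spec$rho * u,
        b = c(spec$dx, spec$dy) - spec$rho * u)
}

#' Spatial-relation ground truth label
#'
#' A pair is "vertical" when its inter-item axis is closer to the vertical
#' midline than to the horizontal midline, "horizontal" otherwise. With the
#' signed-theta convention this reduces to the sign of `theta`; `theta = 0`
#' (exactly on the diagonal) has no defined label and is rejected, as is
#' `|theta| > 45`.
#'
#' @param theta_signed Signed offset from the diagonal, degrees.
#' @param axis `+45` or `-45`.
#' @return `"vertical"` or `"horizontal"`.
#' @export
sr_ground_truth <- function(theta_signed, axis = 45) {
  if (abs(theta_signed) > 45) stop("|theta| > 45: spatial-relation label undefined")
  if (theta_signed == 0) stop("theta = 0 lies on the diagonal: label undefined")
  a <- (axis + sign(axis) * theta_signed) * pi / 180
  if (abs(sin(a)) > abs(cos(a))) "vertical" else "horizontal"
}

## Raster footprint of one shape centered at math-frame (x, y):
## list(rows, cols) of the filled pixels (scale x scale per cell).
shape_pixels <- function(shape, center_xy, scale = 1L, height = 50L, width = 80L) {
  cells <- shape$cells
  h <- (max(cells[, 1]) + 1L) * scale
  w <- (max(cells[, 2]) + 1L) * scale
  crow <- (height + 1) / 2 - center_xy[2]
  ccol <- (width + 1) / 2 + center_xy[1]
  r0 <- round(crow - h / 2)
  c0 <- round(ccol - w / 2)
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(nrow(cells))) {
    rr <- r0 + cells[i, 1] * scale + seq_len(scale)
    cc <- c0 + cells[i, 2] * scale + seq_len(scale)
    rows <- c(rows, rep(rr, each = scale))
    cols <- c(cols, rep(cc, times = scale))
  }
  list(rows = rows, cols = cols)
}

#' Render a two-item trial as a 50x80 intensity grid
#'
#' Draws both hexominoes as filled `scale`-pixel cells (no antialiasing) at
#' the positions given by the placement. Pixels are binary: 1 = item ink,
#' 0 = background. With `scale = 1` item extents are a few pixels, matching
#' the network-simulation raster.
#'
#' @param item_a,item_b `hexomino` shapes.
#' @param spec A [placement_spec()].
#' @param scale Pixels per shape cell.
#' @param height,width Image size in pixels (default 50 x 80).
#' @return `height x width` numeric matrix in \[0, 1\].
#' @export
render_trial <- function(item_a, item_b, spec, scale = 1L,
                         height = 50L, width = 80L) {
  centers <- place_pair(spec)
  img <- matrix(0, height, width)
  for (which_item in c("a", "b")) {
    shape <- if (which_item == "a") item_a else item_b
    px <- shape_pixels(shape, centers[which_item, ], scale, height, width)
    if (any(px$rows < 1 | px$rows > height | px$cols < 1 | px$cols > width))
      stop(sprintf("item_%s falls outside the %dx%d image", which_item, height, width))
    idx <- cbind(px$rows, px$cols)
    if (any(img[idx] > 0))
      stop(sprintf("item_%s overlaps the other item", which_item))
    img[idx] <- 1
  }
  img
}

## Single-item image: the item at its position from the composite trial,
## the rest of the image blank (used to build Siamese network inputs).
render_single <- function(shape, center_xy, scale = 1L, height = 50L, width = 80L) {
  img <- matrix(0, height, width)
  px <- shape_pixels(shape, center_xy, scale, height, width)
  if (any(px$rows < 1 | px$rows > height | px$cols < 1 | px$cols > width))
    stop("item falls outside the image")
  img[cbind(px$rows, px$cols)] <- 1
  img
}

#' Default stimulus parameter ranges (image-space pixels and degrees)
#'
#' Trials vary only slightly in eccentricity and jitter around the base
#' geometry, as in the simulation protocol; the ranges keep every item
#' inside the 50x80 raster at `scale = 1` (worst-case offset from center
#' `max(rho) + max(|jitter|) + 3 < 24` pixels).
#'
#' @param rho_range Eccentricity range, pixels.
#' @param theta_range Maximum |theta| for SR trials, degrees.
#' @param theta_min Minimum |theta| for SR trials (bounded away from the
#'   undefined theta = 0 diagonal).
#' @param jitter_range Half-width of the uniform jitter on dx and dy, pixels.
#' @return List of ranges.
#' @export
stimulus_ranges <- function(rho_range = c(10, 14), theta_range = 25,
                            theta_min = 0.5, jitter_range = 2) {
  list(rho_range = rho_range, theta_range = theta_range,
       theta_min = theta_min, jitter_range = jitter_range)
}

#' Generate a balanced SD or SR stimulus dataset
#'
#' Samples `n` trials with uniformly drawn geometry. SD datasets are
#' balanced 50/50 same/different with `theta = 0` (eccentricity is the task
#' parameter); SR datasets are balanced horizontal/vertical with |theta|
#' drawn from `[theta_min, theta_range]` and a random sign fixed by the
#' target label. Item identities are drawn only from `ids` so that train-
#' and test-split datasets share no shape.
#'
#' @param task `"SD"` or `"SR"`.
#' @param n Number of trials.
#' @param shapes The full `hexomino_set` dictionary.
#' @param ids Dictionary ids to sample items from (e.g. a split's train_ids).
#' @param ranges See [stimulus_ranges()].
#' @param seed Integer seed; same seed gives byte-identical trials.
#' @param scale Pixels per shape cell.
#' @return Object of class `stimulus_set`: list of trials, each with
#'   `placement`, `item_a`, `item_b`, `sd_label`, `sr_label`, `image`.
#' @export
generate_dataset <- function(task = c("SD", "SR"), n, shapes, ids,
                             ranges = stimulus_ranges(), seed = 1L,
                             scale = 1L) {
  task <- match.arg(task)
  if (length(ids) == 0) stop("empty id pool")
  trials <- with_seed(seed, {
    labels <- rep(c(TRUE, FALSE), length.out = n)[sample.int(n)]
    lapply(seq_len(n), function(i) {
      rho <- runif(1, ranges$rho_range[1], ranges$rho_range[2])
      axis <- sample(c(45, -45), 1)
      dx <- runif(1, -ranges$jitter_range, ranges$jitter_range)
      dy <- runif(1, -ranges$jitter_range, ranges$jitter_range)
      if (task == "SD") {
        theta <- 0
        if (labels[i]) {           # same
          ia <- ib <- sample(ids, 1)
        } else {
          pick <- sample(ids, 2)   # different
          ia <- pick[1]; ib <- pick[2]
        }
      } else {
        mag <- runif(1, ranges$theta_min, ranges$theta_range)
        theta <- if (labels[i]) mag else -mag   # TRUE = vertical
        ia <- sample(ids, 1); ib <- sample(ids, 1)
      }
      spec <- placement_spec(rho, theta, axis, dx, dy)
      list(placement = spec, item_a = ia, item_b = ib,
           sd_label = if (ia == ib) "same" else "different",
           sr_label = if (theta == 0) NA_character_ else sr_ground_truth(theta, axis),
           image = render_trial(shapes[[ia]], shapes[[ib]], spec, scale))
    })
  })
  structure(trials, class = "stimulus_set",
            task = task, seed = as.integer(seed), scale = as.integer(scale))
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> task=%s n=%d seed=%d\n",
              attr(x, "task"), length(x), attr(x, "seed")))
  invisible(x)
}

#' Convert a stimulus set to training arrays
#'
#' @param trials A `stimulus_set`.
#' @param shapes The dictionary used to generate it (needed for Siamese
#'   single-item inputs).
#' @param siamese If `TRUE`, also return the two single-item images per
#'   trial (each item alone at its true position).
#' @return List with `x` (n x 50 x 80 array), `y` (integer labels: SD task
#'   1 = same, 0 = different; SR task 1 = vertical, 0 = horizontal) and,
#'   when `siamese`, `xa` and `xb` arrays.
#' @export
dataset_arrays <- function(trials, shapes = NULL, siamese = FALSE) {
  n <- length(trials)
  h <- nrow(trials[[1]]$image); w <- ncol(trials[[1]]$image)
  task <- attr(trials, "task")
  x <- array(0, c(n, h, w))
  y <- integer(n)
  for (i in seq_len(n)) {
    x[i, , ] <- trials[[i]]$image
    y[i] <- if (task == "SD") as.integer(trials[[i]]$sd_label == "same")
            else as.integer(trials[[i]]$sr_label == "vertical")
  }
  out <- list(x = x, y = y)
  if (siamese) {
    if (is.null(shapes)) stop("shapes dictionary required for siamese arrays")
    scale <- attr(trials, "scale")
    xa <- array(0, c(n, h, w)); xb <- array(0, c(n, h, w))
    for (i in seq_len(n)) {
      centers <- place_pair(trials[[i]]$placement)
      xa[i, , ] <- render_single(shapes[[trials[[i]]$item_a]], centers[1, ], scale, h, w)
      xb[i, , ] <- render_single(shapes[[trials[[i]]$item_b]], centers[2, ], scale, h, w)
    }
    out$xa <- xa; out$xb <- xb
  }
  out
}

#' Write a stimulus set as PNG images plus a CSV manifest
#'
#' @param trials A `stimulus_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the PNGs.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_stimulus_set <- function(trials, dir, prefix = "trial") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    fn <- sprintf("%s_%04d.png", prefix, i)
    png::writePNG(1 - tr$image, file.path(dir, fn))  # dark items, light bg
    data.frame(trial = i, file = fn, task = attr(trials, "task"),
               rho = tr$placement$rho, theta = tr$placement$theta,
               axis = tr$placement$axis, dx = tr$placement$dx,
               dy = tr$placement$dy, item_a = tr$item_a, item_b = tr$item_b,
               sd_label = tr$sd_label,
               sr_label = ifelse(is.na(tr$sr_label), "", tr$sr_label))
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
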