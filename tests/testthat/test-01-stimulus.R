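shapes <- enumerate_free_hexominoes()

test_that("pair placement geometry is exact", {
  p <- place_pair(placement_spec(rho = 5.4, theta = 0, axis = 45))
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 10.8)
  expect_equal(p[1, ], -p[2, ])                       # symmetric about origin
  expect_equal(p[1, 1], p[1, 2])                      # on the 45-degree diagonal

  ## theta = 45 on the +45 axis puts the pair on the vertical axis
  p <- place_pair(placement_spec(rho = 1, theta = 45, axis = 45))
  expect_equal(unname(p[, 1]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(abs(p[, 2])), c(1, 1))

  expect_error(placement_spec(rho = 0), "positive")
  expect_error(placement_spec(1, theta = 50), "45")
})

test_that("separation is 2*rho for any jitter (property)", {
  set.seed(11)
  for (i in 1:50) {
    spec <- placement_spec(runif(1, 1, 10), runif(1, -45, 45),
                           sample(c(45, -45), 1), runif(1, -5, 5),
                           runif(1, -5, 5))
    p <- place_pair(spec)
    expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 2 * spec$rho)
  }
})

test_that("spatial-relation ground truth follows the axis geometry", {
  expect_equal(sr_ground_truth(6, 45), "vertical")     # axis at 51 degrees
  expect_equal(sr_ground_truth(-6, 45), "horizontal")  # axis at 39 degrees
  expect_equal(sr_ground_truth(6, -45), "vertical")
  expect_equal(sr_ground_truth(-6, -45), "horizontal")
  expect_error(sr_ground_truth(0, 45), "undefined")
  expect_error(sr_ground_truth(46, 45), "undefined")
  ## flipping the sign of theta flips the label (property)
  set.seed(3)
  for (th in runif(20, 0.5, 44.5)) {
    ax <- sample(c(45, -45), 1)
    expect_false(sr_ground_truth(th, ax) == sr_ground_truth(-th, ax))
  }
})

test_that("rendering conserves area, translates items, checks bounds", {
  spec <- placement_spec(rho = 10, theta = 0, axis = 45)
  img <- render_trial(shapes[[3]], shapes[[3]], spec)
  expect_equal(dim(img), c(50L, 80L))
  expect_setequal(unique(as.vector(img)), c(0, 1))
  expect_equal(sum(img), 2 * 6)
  ## same item at both positions: the two components are translates
  on <- which(img == 1, arr.ind = TRUE)
  a <- on[on[, 2] > 40, , drop = FALSE]
  b <- on[on[, 2] <= 40, , drop = FALSE]
  norm <- function(m) {
    m[, 1] <- m[, 1] - min(m[, 1]); m[, 2] <- m[, 2] - min(m[, 2])
    m[order(m[, 1], m[, 2]), ]
  }
  expect_equal(unname(norm(a)), unname(norm(b)))
  ## scaling multiplies the area by scale^2
  img2 <- render_trial(shapes[[3]], shapes[[7]], spec, scale = 2L)
  expect_equal(sum(img2), 2 * 6 * 4)
  expect_error(render_trial(shapes[[1]], shapes[[2]],
                            placement_spec(rho = 40, theta = 0, axis = 45)),
               "outside")
})

test_that("generated datasets are balanced, split-pure and deterministic", {
  split <- split_dictionary(shapes, 5L, seed = 5L)
  sd_set <- generate_dataset("SD", 40, shapes, split$train_ids, seed = 8L)
  labs <- vapply(sd_set, function(tr) tr$sd_label, "")
  expect_equal(sum(labs == "same"), 20)
  used <- unlist(lapply(sd_set, function(tr) c(tr$item_a, tr$item_b)))
  expect_length(intersect(used, split$test_ids), 0)
  thetas <- vapply(sd_set, function(tr) tr$placement$theta, 0)
  expect_true(all(thetas == 0))                     # SD staircases rho only

  sr_set <- generate_dataset("SR", 40, shapes, split$train_ids, seed = 8L)
  srl <- vapply(sr_set, function(tr) tr$sr_label, "")
  expect_equal(sum(srl == "vertical"), 20)
  expect_true(all(abs(vapply(sr_set, function(tr) tr$placement$theta, 0)) >= 0.5))

  again <- generate_dataset("SD", 40, shapes, split$train_ids, seed = 8L)
  expect_identical(lapply(sd_set, `[[`, "image"), lapply(again, `[[`, "image"))
  expect_error(generate_dataset("SD", 10, shapes, integer(0)), "empty")
})

test_that("dataset arrays and the stimulus-set writer are consistent", {
  split <- split_dictionary(shapes, 5L, seed = 5L)
  trials <- generate_dataset("SD", 12, shapes, split$train_ids, seed = 2L)
  arr <- dataset_arrays(trials, shapes, siamese = TRUE)
  expect_equal(dim(arr$x), c(12, 50, 80))
  expect_equal(length(arr$y), 12)
  ## single-item images sum to the composite
  for (i in c(1, 5, 12))
    expect_equal(arr$xa[i, , ] + arr$xb[i, , ], arr$x[i, , ])
  d <- tempfile()
  manifest <- write_stimulus_set(trials, d)
  df <- read.csv(manifest)
  expect_equal(nrow(df), 12)
  img <- png::readPNG(file.path(d, df$file[1]))
  expect_equal(sum(img == 0), sum(trials[[1]]$image))  # dark-ink pixel count
})
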