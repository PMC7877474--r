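test_that("baseline subtraction removes offsets and zeroes the baseline", {
  m <- small_montage()
  ep <- synthesize_epochs(3, 10, montage = m, seed = 2L)
  ## constant-offset trials: ERP identically 0 after baseline subtraction
  ep0 <- ep
  ep0$data[] <- 7.5
  erps0 <- compute_erps(ep0)
  expect_equal(max(abs(erps0)), 0)
  ## real data: baseline-window mean of every ERP is 0
  erps <- compute_erps(ep)
  bidx <- ep$times >= 0 & ep$times <= 0.35
  bl_means <- apply(erps[, , , bidx, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(bl_means)), 1e-10)
})

test_that("an injected deflection is recovered in the subject-mean ERP", {
  m <- small_montage(c("Pz", "CPz", "Fz", "Oz"))
  eff <- effect_spec(erp_amp = 2, erp_window = c(0.3, 0.9), subject_sd = 0,
                     osc_db = 0, erp_center = c(0, -0.45))
  ep <- synthesize_epochs(4, 150, eff, m, seed = 13L)
  erps <- compute_erps(ep)
  w <- channel_weights(m, c(0, -0.45), 0.5)
  sel <- ep$times >= 0.75 & ep$times <= 1.15   # plateau (stimulus at 0.35)
  pz <- which(m$label == "Pz")
  rec <- mean(erps[, 1, pz, sel]) - mean(erps[, 2, pz, sel])
  expect_equal(rec, 2 * w[pz], tolerance = 0.25)
})

test_that("BH correction matches the brute-force step-up rule", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05)$mask,
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bh_fdr(rep(0, 5))$mask))
  expect_false(any(bh_fdr(rep(1, 5))$mask))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:60) {
    n <- sample(c(1, 5, 50, 400), 1)
    p <- switch(sample(3, 1), runif(n), runif(n)^3, pmin(runif(n) * 1.5, 1))
    q <- sample(c(0.01, 0.05, 0.2), 1)
    expect_identical(bh_fdr(p, q)$mask, oracle_bh_mask(p, q))
  }
  ## adjusted p is monotone in raw-p rank
  p <- runif(200)
  adj <- bh_fdr(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH keeps the false discovery proportion near q under the null", {
  set.seed(77)
  fdp <- replicate(300, mean(bh_fdr(runif(40), 0.05)$mask))
  expect_lte(mean(fdp), 0.055)
})

test_that("the midline difference test localizes an injected effect", {
  labels <- c("Oz", "POz", "Pz", "CPz", "Cz", "FCz", "Fz")
  m <- small_montage(labels)
  ## effect tightly centred on Pz/CPz
  eff <- effect_spec(erp_amp = 3, erp_window = c(0.25, 1.0), subject_sd = 0.1,
                     osc_db = 0, erp_center = c(0, -0.45), erp_sigma = 0.25)
  ep <- synthesize_epochs(8, 120, eff, m, seed = 19L)
  res <- erp_difference_test(compute_erps(ep), electrodes = labels, q = 0.05)
  expect_s3_class(res, "erp_result")
  hits <- rowSums(res$mask[, ep$times > 0.6 & ep$times < 1.35])
  names(hits) <- labels
  expect_gt(hits[["Pz"]] + hits[["CPz"]], 50)             # concentrated there
  expect_gt(hits[["Pz"]], hits[["Fz"]])
  expect_gt(sum(res$mask), 0)
  ## and the topography points the same way
  topo <- erp_topography(compute_erps(ep))
  expect_equal(topo$label[which.max(topo$diff)], "Pz")
  ## zero-variance points do not produce NaN
  epz <- ep
  epz$data[, , , 7, ] <- 1
  expect_warning(rz <- erp_difference_test(compute_erps(epz),
                                           electrodes = labels),
                 "zero variance")
  expect_false(anyNA(rz$p))
})

test_that("null data produce (almost) no BH discoveries", {
  m <- small_montage(c("Pz", "CPz", "Oz"))
  eff <- effect_spec(erp_amp = 0, osc_db = 0)
  ep <- synthesize_epochs(6, 60, eff, m, seed = 23L)
  res <- erp_difference_test(compute_erps(ep), electrodes = c("Pz", "CPz", "Oz"))
  expect_lt(mean(res$mask), 0.01)
})

test_that("results export to long CSV", {
  m <- small_montage(c("Pz", "Oz"))
  ep <- synthesize_epochs(3, 20, montage = m, seed = 5L)
  res <- erp_difference_test(compute_erps(ep), electrodes = c("Pz", "Oz"))
  f <- tempfile(fileext = ".csv")
  write_erp_result(res, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2 * length(res$times))
  expect_named(df, c("electrode", "time", "mean", "se", "t", "p", "p_adj", "sig"))
})
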