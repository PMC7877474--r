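test_that("free polyomino enumeration matches known counts and the oracle", {
  counts <- vapply(1:5, function(n)
    length(visreason:::enumerate_free_polyominoes(n)), 0L)
  expect_equal(counts, c(1L, 1L, 2L, 5L, 12L))

  fixed5 <- oracle_fixed_polyominoes(5)
  expect_equal(oracle_free_count(fixed5), 12L)

  dict <- enumerate_free_hexominoes()
  expect_length(dict, 35)
  expect_s3_class(dict, "hexomino_set")
  expect_equal(enumerate_free_hexominoes(1L)[[1]]$cells,
               matrix(c(0L, 0L), ncol = 2))
})

test_that("fixed hexomino count (translations only) is 216", {
  fixed6 <- oracle_fixed_polyominoes(6)
  expect_length(fixed6, 216)
  expect_equal(oracle_free_count(fixed6), 35L)
})

test_that("enumeration is duplicate-free and closed under the dihedral group", {
  dict <- enumerate_free_hexominoes()
  keys <- vapply(dict, function(s) s$key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  set.seed(7)
  for (i in sample(35, 8)) {
    cells <- dict[[i]]$cells
    tr <- visreason:::poly_transforms(cells)[[sample(8, 1)]]
    shift <- matrix(sample(-3:3, 2), nrow(tr), 2, byrow = TRUE)
    recanon <- hex_canonicalize(tr + shift)
    expect_equal(recanon$key, dict[[i]]$key)
  }
})

test_that("canonicalization is transform-invariant, idempotent, validating", {
  bar <- cbind(0L, 0:5)
  expect_equal(hex_canonicalize(bar)$key, hex_canonicalize(cbind(0:5, 0L))$key)
  ell <- rbind(cbind(0:4, 0L), c(4L, 1L))
  mirror <- cbind(ell[, 1], -ell[, 2])
  expect_equal(hex_canonicalize(ell)$key, hex_canonicalize(mirror)$key)
  once <- hex_canonicalize(ell)
  expect_identical(hex_canonicalize(once$cells)$cells, once$cells)
  expect_error(hex_canonicalize(cbind(0L, 0:4)), "expected 6")
  disconnected <- rbind(cbind(0L, 0:4), c(2L, 3L))
  expect_error(hex_canonicalize(disconnected), "connected")
})

test_that("dictionary split is reproducible, disjoint and covering", {
  dict <- enumerate_free_hexominoes()
  s1 <- split_dictionary(dict, 5L, seed = 99L)
  s2 <- split_dictionary(dict, 5L, seed = 99L)
  expect_identical(s1, s2)
  expect_length(s1$train_ids, 30)
  expect_length(s1$test_ids, 5)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), 1:35)
  s0 <- split_dictionary(dict, 0L, seed = 1L)
  expect_length(s0$train_ids, 35)
  expect_error(split_dictionary(dict, 35L, seed = 1L), "smaller")
})

test_that("dictionary exports round-trip", {
  dict <- enumerate_free_hexominoes()
  jf <- tempfile(fileext = ".json")
  write_dictionary_json(dict, jf)
  back <- jsonlite::fromJSON(jf)
  expect_length(back, 35)
  expect_equal(back[["1"]], unname(dict[[1]]$cells))
  pf <- tempfile(fileext = ".png")
  write_dictionary_sprites(dict, pf)
  img <- png::readPNG(pf)
  expect_equal(sum(img == 0), 35 * 6 * 16)  # 35 shapes at 4x4 px per cell
})
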