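#' @useDynLib visreason, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pt sd rnorm runif rbinom rlnorm fft mvfft qnorm quantile
#' @importFrom utils write.csv read.csv head tail
NULL

## A polyomino is stored as an integer matrix with columns (row, col),
## translated so min(row) = min(col) = 0, rows sorted lexicographically.

poly_normalize <- function(cells) {
  dimnames(cells) <- NULL
  cells[, 1] <- cells[, 1] - min(cells[, 1])
  cells[, 2] <- cells[, 2] - min(cells[, 2])
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

## The 8 dihedral transforms of a cell matrix (rotations x optional mirror).
poly_transforms <- function(cells) {
  r <- cells[, 1]; c <- cells[, 2]
  lapply(list(
    cbind(r, c), cbind(c, -r), cbind(-r, -c), cbind(-c, r),
    cbind(r, -c), cbind(-c, -r), cbind(-r, c), cbind(c, r)
  ), poly_normalize)
}

poly_key <- function(cells) paste(cells[, 1], cells[, 2], sep = ",", collapse = ";")

poly_connected <- function(cells) {
  n <- nrow(cells)
  if (n == 1L) return(TRUE)
  key <- paste(cells[, 1], cells[, 2])
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    nb <- rbind(cells[i, ] + c(1L, 0L), cells[i, ] - c(1L, 0L),
                cells[i, ] + c(0L, 1L), cells[i, ] - c(0L, 1L))
    hit <- match(paste(nb[, 1], nb[, 2]), key)
    hit <- hit[!is.na(hit) & !seen[hit]]
    seen[hit] <- TRUE
    queue <- c(queue, hit)
  }
  all(seen)
}

#' Canonicalize a polyomino under rotation and reflection
#'
#' Reduces a set of grid cells to its canonical free-polyomino form: the
#' lexicographically smallest sorted cell list over the eight dihedral
#' transformations (four rotations, each optionally mirrored), translated so
#' the minimum row and column are zero.
#'
#' @param cells Two-column integer matrix (or data frame) of (row, col) cell
#'   coordinates, or a list of length-2 vectors.
#' @param n_cells Required number of cells (default 6, a hexomino). Use
#'   `NA` to skip the size check.
#' @return An object of class `hexomino`: a list with `cells` (canonical
#'   integer matrix) and `key` (string form used for identity tests).
#' @examples
#' bar  <- cbind(0L, 0:5)            # 1 x 6 bar
#' barT <- cbind(0:5, 0L)            # its 90 degree rotation
#' identical(hex_canonicalize(bar)$key, hex_canonicalize(barT)$key)
#' @export
hex_canonicalize <- function(cells, n_cells = 6L) {
  if (is.list(cells) && !is.data.frame(cells)) cells <- do.call(rbind, cells)
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (ncol(cells) != 2L) stop("cells must have two columns (row, col)")
  if (anyDuplicated(paste(cells[, 1], cells[, 2]))) stop("duplicate cells")
  if (!is.na(n_cells) && nrow(cells) != n_cells)
    stop(sprintf("expected %d cells, got %d", n_cells, nrow(cells)))
  if (!poly_connected(cells)) stop("cells are not edge-connected")
  tr <- poly_transforms(cells)
  keys <- vapply(tr, poly_key, character(1))
  best <- which.min(rank(keys, ties.method = "min"))
  structure(list(cells = tr[[best]], key = keys[[best]]), class = "hexomino")
}

## Exhaustive enumeration of free n-ominoes by breadth-first growth:
## start from the monomino and repeatedly add one edge-adjacent cell,
## deduplicating by canonical key at each size.
enumerate_free_polyominoes <- function(n) {
  stopifnot(n >= 1)
  shapes <- list(matrix(c(0L, 0L), ncol = 2))
  if (n > 1) {
    for (size in 2:n) {
      seen <- new.env(parent = emptyenv())
      nxt <- list()
      for (cells in shapes) {
        key <- paste(cells[, 1], cells[, 2])
        cand <- rbind(cbind(cells[, 1] + 1L, cells[, 2]),
                      cbind(cells[, 1] - 1L, cells[, 2]),
                      cbind(cells[, 1], cells[, 2] + 1L),
                      cbind(cells[, 1], cells[, 2] - 1L))
        cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% key), , drop = FALSE]
        cand <- cand[!duplicated(paste(cand[, 1], cand[, 2])), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          grown <- rbind(cells, cand[i, ])
          tr <- poly_transforms(grown)
          k <- min(vapply(tr, poly_key, character(1)))
          if (is.null(seen[[k]])) {
            seen[[k]] <- TRUE
            nxt[[length(nxt) + 1L]] <- poly_normalize(grown)
          }
        }
      }
      shapes <- nxt
    }
  }
  shapes
}

#' Enumerate the free hexomino dictionary
#'
#' Exhaustively enumerates all distinct free hexominoes (6-cell polyominoes
#' counted up to rotation and reflection), the stimulus dictionary used for
#' both network simulations and behavioral sessions. There are exactly 35.
#' Shapes are returned in a deterministic order (sorted by canonical key) so
#' ids are stable across runs.
#'
#' @param n_cells Number of cells per shape; default 6.
#' @return Object of class `hexomino_set`: list of `hexomino` objects, each
#'   with an `id` field (1-based ordinal in enumeration order).
#' @examples
#' dict <- enumerate_free_hexominoes()
#' length(dict)  # 35
#' @export
enumerate_free_hexominoes <- function(n_cells = 6L) {
  shapes <- enumerate_free_polyominoes(n_cells)
  canon <- lapply(shapes, hex_canonicalize, n_cells = n_cells)
  keys <- vapply(canon, function(s) s$key, character(1))
  canon <- canon[order(keys)]
  for (i in seq_along(canon)) canon[[i]]$id <- i
  structure(canon, class = "hexomino_set")
}

#' @export
print.hexomino_set <- function(x, ...) {
  cat(sprintf("<hexomino_set> %d free shapes of %d cells\n",
              length(x), nrow(x[[1]]$cells)))
  invisible(x)
}

#' @export
print.hexomino <- function(x, ...) {
  ext <- apply(x$cells, 2, max) + 1L
  grid <- matrix(".", ext[1], ext[2])
  grid[x$cells + 1L] <- "#"
  cat(sprintf("<hexomino%s>\n", if (!is.null(x$id)) paste0(" id=", x$id) else ""))
  apply(grid, 1, function(r) cat(paste(r, collapse = ""), "\n"))
  invisible(x)
}

#' Randomly split the shape dictionary into train and test sets
#'
#' Uniformly random disjoint partition of dictionary ids into a training set
#' and a held-out test set, reproducible from a seed. Default sizes (30
#' train / 5 test for the 35-item hexomino dictionary) match the
#' generalization experiment, in which networks are evaluated on shapes
#' never used for training.
#'
#' @param shapes A `hexomino_set` (or any list with ids `1..n`).
#' @param n_test Number of held-out shapes (default 5).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `seed`.
#' @export
split_dictionary <- function(shapes, n_test = 5L, seed = 1L) {
  n <- length(shapes)
  if (n_test >= n) stop("n_test must be smaller than the dictionary size")
  ids <- seq_len(n)
  test_ids <- sort(with_seed(seed, sample(ids, n_test)))
  list(train_ids = setdiff(ids, test_ids), test_ids = test_ids,
       seed = as.integer(seed))
}

#' Export a shape dictionary as JSON
#'
#' Writes the dictionary as a JSON object mapping id to cell list.
#' @param shapes A `hexomino_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary_json <- function(shapes, path) {
  obj <- lapply(shapes, function(s) unname(s$cells))
  names(obj) <- vapply(shapes, function(s) as.character(s$id), character(1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Export a shape dictionary as a sprite-sheet PNG
#'
#' Renders every shape into one grid image for documentation.
#' @param shapes A `hexomino_set`.
#' @param path Output PNG path.
#' @param cell_px Pixels per shape cell.
#' @return `path`, invisibly.
#' @export
write_dictionary_sprites <- function(shapes, path, cell_px = 4L) {
  n <- length(shapes)
  ncol_sheet <- ceiling(sqrt(n))
  nrow_sheet <- ceiling(n / ncol_sheet)
  tile <- 8L * cell_px  # 6-cell shapes fit in 6x6 cells + margin
  img <- matrix(1, nrow_sheet * tile, ncol_sheet * tile)
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% ncol_sheet) * tile + cell_px
    c0 <- ((i - 1) %% ncol_sheet) * tile + cell_px
    for (j in seq_len(nrow(shapes[[i]]$cells))) {
      rr <- r0 + shapes[[i]]$cells[j, 1] * cell_px + seq_len(cell_px)
      cc <- c0 + shapes[[i]]$cells[j, 2] * cell_px + seq_len(cell_px)
      img[rr, cc] <- 0
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a bounded substream seed from a master seed and a stream label.
## Keeps everything below 2^31 and decorrelates stages of a pipeline run.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435761) %% 2147483399 + 1)
}
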