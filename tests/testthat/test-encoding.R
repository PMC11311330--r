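test_that("encode/decode round-trips and normalizes a 3-4-5 vector", {
  f <- array(0, c(2, 2, 2))
  f[1, 1, ] <- c(3, 4)
  enc <- encode_field(f, "auto")
  expect_equal(enc$n_max, 5)
  expect_equal(enc$data[1, 1, ], c(0.6, 0.8))
  expect_equal(decode_field(enc), f)
  # all-zero field
  z <- encode_field(array(0, c(3, 3, 2)), "auto")
  expect_equal(z$n_max, 0)
  expect_true(all(z$data == 0))
  expect_true(all(decode_field(z) == 0))
})

test_that("random fields round-trip through the encoding to 1e-12", {
  set.seed(1)
  for (i in 1:20) {
    f <- random_field(8, 6, scale = runif(1, 0.01, 10))
    enc <- encode_field(f, "auto")
    expect_true(all(abs(enc$data) <= 1))
    expect_lt(max(abs(decode_field(enc) - f)), 1e-12)
  }
})

test_that("angular encoding equals direct normalization with slices swapped", {
  f <- array(0, c(1, 1, 2))
  f[1, 1, ] <- c(3, 4)
  a <- encode_angular(f)
  expect_equal(a$data[1, 1, ], c(0.8, 0.6))  # (sin, cos) of the 3-4-5 angle
  # zero vector maps to (0, 0)
  z <- array(0, c(2, 2, 2)); z[1, 1, ] <- c(1, 0)
  az <- encode_angular(z)
  expect_equal(az$data[2, 2, ], c(0, 0))
  set.seed(2)
  for (i in 1:10) {
    f <- random_field(7, 9)
    ang <- encode_angular(f)$data
    dir <- encode_field(f, "auto")$data
    swapped <- dir[, , c(2, 1)]
    expect_lt(max(abs(ang - swapped)), 1e-9)
  }
})

test_that("face masking zeroes exactly the masked vectors", {
  set.seed(3)
  f <- random_field(6, 6)
  none <- matrix(FALSE, 6, 6)
  expect_identical(apply_face_mask(f, none), f)
  all_m <- matrix(TRUE, 6, 6)
  expect_true(all(apply_face_mask(f, all_m) == 0))
  some <- matrix(FALSE, 6, 6); some[2:3, 4] <- TRUE
  out <- apply_face_mask(f, some)
  expect_true(all(out[2:3, 4, ] == 0))
  expect_lte(reduce_field(out), reduce_field(f))
  expect_error(apply_face_mask(f, matrix(TRUE, 5, 6)), "shape")
})

test_that("collation builds n-2 stride-1 triples with exact indexing", {
  set.seed(4)
  fields <- lapply(1:5, function(i) encode_field(random_field(4, 4), "auto"))
  ds <- collate_interleaved(fields)
  expect_length(ds, 3)
  expect_identical(ds$y[[1]], fields[[2]]$data)
  expect_identical(ds$x[[1]][, , 1:2], fields[[1]]$data)
  expect_identical(ds$x[[1]][, , 3:4], fields[[3]]$data)
  expect_error(collate_interleaved(fields[1:2]), "at least 3")
  big <- lapply(1:500, function(i) array(0, c(2, 2, 2)))
  expect_length(collate_interleaved(big), 498)
})

test_that("augmentation ops transform grid and vectors together", {
  # single right-pointing vector mirrors to a left-pointing one
  f <- array(0, c(4, 4, 2))
  f[2, 1, 1] <- 1     # vx = +1 at column 1
  ds <- interleaved_dataset(list(array(c(f, f), c(4, 4, 4))), list(f))
  h <- augment(ds, "hflip")
  expect_length(h, 2)
  flipped <- h$y[[2]]
  expect_equal(flipped[2, 4, 1], -1)
  expect_equal(sum(abs(flipped)), 1)
  # involution: hflip twice is the identity
  h2 <- augment(interleaved_dataset(h$x[2], h$y[2]), "hflip")
  expect_identical(h2$y[[2]], f)
  # unknown op errors
  expect_error(augment(ds, "transpose"), "unknown")
})

test_that("augmentation preserves per-field magnitude multisets exactly", {
  set.seed(5)
  f <- random_field(6, 6)
  ds <- interleaved_dataset(list(array(c(f, f), c(6, 6, 4))), list(f))
  aug <- augment(ds, c("hflip", "vflip", "rot90", "rot180", "rot270"))
  expect_length(aug, 6)
  base_mags <- sort(sqrt(f[, , 1]^2 + f[, , 2]^2))
  for (k in 2:6) {
    y <- aug$y[[k]]
    expect_equal(sort(sqrt(y[, , 1]^2 + y[, , 2]^2)), base_mags,
                 tolerance = 1e-14)
    expect_equal(reduce_field(y), reduce_field(f), tolerance = 1e-10)
  }
})

test_that("quarter rotations compose to the identity", {
  set.seed(6)
  f <- random_field(5, 5)
  g <- f
  for (i in 1:4) g <- exhaleflow:::transform_field2(g, "rot90")
  expect_equal(g, f, tolerance = 1e-14)
  r <- exhaleflow:::transform_field2(
    exhaleflow:::transform_field2(f, "rot90"), "rot270")
  expect_equal(r, f, tolerance = 1e-14)
  # rot90 on a non-square field is rejected
  expect_error(exhaleflow:::transform_field2(random_field(4, 6), "rot90"),
               "square")
})

test_that("split_dataset partitions deterministically at the fraction", {
  set.seed(7)
  items <- lapply(1:100, function(i) random_field(2, 2))
  xs <- lapply(items, function(f) array(c(f, f), c(2, 2, 4)))
  ds <- interleaved_dataset(xs, items)
  sp1 <- split_dataset(ds, 0.9, seed = 11)
  sp2 <- split_dataset(ds, 0.9, seed = 11)
  expect_length(sp1$train, 90)
  expect_length(sp1$val, 10)
  expect_identical(sp1$train$y, sp2$train$y)
  # union of splits restores the original multiset of targets
  key <- function(f) paste(signif(as.numeric(f), 12), collapse = ",")
  expect_setequal(c(vapply(sp1$train$y, key, character(1)),
                    vapply(sp1$val$y, key, character(1))),
                  vapply(items, key, character(1)))
})
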