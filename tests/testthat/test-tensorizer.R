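# BSP frame -> image tensors: the two layouts, resizing, replication,
# normalization.

test_that("3-channel layout places panels and zero cells correctly", {
  ones <- rep(1, 64)
  img <- make_3channel(ones)
  expect_equal(dim(img), c(6, 4, 3))
  expect_equal(sum(img == 1), 64)
  expect_equal(sum(img == 0), 8)           # unoccupied side cells
  expect_true(all(img[1:2, , 2] == 0))     # sides occupy the last 4 rows
  fr <- frame64()
  img2 <- make_3channel(fr)
  # channel 1 flattened row-major equals the 24 front values in vest order
  expect_equal(as.numeric(t(img2[, , 1])), fr[1:24])
  expect_equal(as.numeric(t(img2[, , 3])), fr[25:48])
  expect_error(make_3channel(fr[1:63]), "64")
})

test_that("1-channel layout unrolls, fills gaps and mirrors", {
  ones <- rep(1, 64)
  img <- make_1channel(ones)
  expect_equal(dim(img), c(6, 16))
  expect_true(all(img == 1))               # gap means of ones are 1
  fr <- frame64()
  m <- make_1channel(fr)
  expect_equal(m[, 1:2], m[, 13:14])       # mirror identity (left)
  expect_equal(m[, 15:16], m[, 3:4])       # mirror identity (right)
  expect_error(make_1channel(fr[-1]), "64")
})

test_that("gap cells average the 3 nearest electrodes (hand-computed)", {
  # cell (2, 5) of the 12-column cylinder is empty; its Chebyshev-1
  # occupied neighbors sorted by (distance, row, col) start with
  # (1,4), (2,4), (3,4) = front column 4 rows 1..3.  Set those to 1, 2, 3.
  fr <- rep(100, 64)
  # canonical order: front is row-major 6x4 -> (r, c) at index (r-1)*4 + c
  fr[(1 - 1) * 4 + 4] <- 1
  fr[(2 - 1) * 4 + 4] <- 2
  fr[(3 - 1) * 4 + 4] <- 3
  m <- make_1channel(fr)
  # mirrored output shifts base columns by mirror width 2
  expect_equal(m[2, 5 + 2], 2)
})

test_that("every electrode appears exactly once per layout (bijectivity)", {
  fr <- seq_len(64) * 10                      # distinct values
  img3 <- make_3channel(fr)
  cnt3 <- table(factor(as.numeric(img3), levels = fr))
  expect_true(all(cnt3 == 1))
  expect_equal(sum(as.numeric(img3) == 0), 8)
  base <- afdriverloc:::.cylinder12(fr, default_vest_layout())
  cntb <- table(factor(as.numeric(base), levels = fr))
  expect_true(all(cntb == 1))
  expect_equal(sum(is.na(base)), 8)
})

test_that("bilinear resize is align-corners exact and shape-correct", {
  const <- matrix(3.3, 6, 16)
  r <- bilinear_resize(const, 78, 192)
  expect_equal(dim(r), c(78, 192))
  expect_true(all(abs(r - 3.3) < 1e-12))
  arr <- array(1.5, c(6, 4, 3))
  r3 <- bilinear_resize(arr, 150, 152)
  expect_equal(dim(r3), c(150, 152, 3))
  expect_true(all(abs(r3 - 1.5) < 1e-12))
  # corner reproduction on a column-linear ramp
  ramp <- matrix(rep(seq(0, 1, length.out = 10), each = 5), 5, 10)
  rr <- bilinear_resize(ramp, 37, 91)
  expect_equal(rr[1, 1], ramp[1, 1])
  expect_equal(rr[37, 91], ramp[5, 10])
  expect_equal(rr[1, 91], ramp[1, 10])
  # idempotence at identical shape
  set.seed(8)
  im <- matrix(rnorm(6 * 16), 6)
  expect_equal(bilinear_resize(im, 6, 16), im)
  expect_error(bilinear_resize(im, 1, 5), "at least 2")
})

test_that("replicate_channels produces identical channels", {
  im <- matrix(rnorm(78 * 19), 78)
  r <- replicate_channels(im, 3)
  expect_equal(dim(r), c(78, 19, 3))
  expect_equal(r[, , 1], im)
  expect_equal(r[, , 2], im)
  expect_equal(r[, , 3], im)
  expect_equal(replicate_channels(im, 1)[, , 1], im)
  expect_error(replicate_channels(array(1, c(4, 4, 2))), "single-channel")
})

test_that("normalize_tensor modes behave", {
  set.seed(3)
  im <- array(rnorm(120, 5, 2), c(6, 4, 5))
  z <- normalize_tensor(im, "zscore")
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(as.numeric(z)) - 1), 1e-9)
  expect_equal(as.numeric(normalize_tensor(im, "none")), as.numeric(im))
  cz <- normalize_tensor(array(7, c(2, 2)), "zscore")
  expect_true(all(cz == 0))
  expect_true(isTRUE(attr(cz, "degenerate")))
})

test_that("tensorize_frames stacks frames with the right shapes", {
  set.seed(5)
  x <- matrix(rnorm(64 * 10), 64)
  t1 <- tensorize_frames(x, "1ch", resize = c(39, 96))
  expect_equal(dim(t1), c(10, 39, 96, 1))
  t3 <- tensorize_frames(x, "3ch", resize = c(30, 30), frames = c(2, 5))
  expect_equal(dim(t3), c(2, 30, 30, 3))
  # default resizes follow the two published tensor shapes
  expect_equal(dim(tensorize_frames(x, "1ch", frames = 1))[2:4],
               c(78, 192, 1))
  expect_equal(dim(tensorize_frames(x, "3ch", frames = 1))[2:4],
               c(150, 152, 3))
})
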