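# Labels, phase-singularity cross-check, splits, class weights.

test_that("driver-free episodes are labeled 0 throughout", {
  m <- small_mesh()
  vs <- simulate_propagation(m, protocol = stimulus_protocol("planar_wave"),
                             duration_s = 0.6, fs = 500)
  expect_true(all(vs$labels == 0))
  for (f in c(10, 200))
    expect_equal(detect_driver_label(vs, m, f), 0L)
})

test_that("phase detector confirms the protocol label on a rotor episode", {
  m <- medium_mesh()
  vs <- rotor_episode()            # rotor in region 3
  expect_true(all(vs$labels[vs$labels > 0] == 3L))
  agree <- verify_driver_labels(vs, m)
  expect_gte(agree, 0.9)
})

test_that("quiescent tail after the wave exits is labeled 0", {
  m <- small_mesh()
  vs <- simulate_propagation(m, protocol = stimulus_protocol("planar_wave"),
                             duration_s = 1.0, fs = 500)
  tail_frames <- 400:501
  expect_true(all(vs$labels[tail_frames] == 0))
  phase_lab <- detect_driver_label(vs, m, 480, mode = "phase")
  expect_equal(phase_lab, 0L)
})

test_that("time-independent split has the stated sizes and is seeded", {
  sp <- split_time_independent(1000, seed = 4)
  expect_equal(length(sp$train), 640)
  expect_equal(length(sp$val), 160)
  expect_equal(length(sp$test), 200)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, 1:1000)
  expect_equal(length(all_idx), 1000)      # pairwise disjoint
  expect_identical(sp, split_time_independent(1000, seed = 4))
  expect_false(identical(sp, split_time_independent(1000, seed = 5)))
  expect_error(split_time_independent(5), "at least 10")
})

test_that("stratified split preserves class proportions", {
  ds <- structure(list(labels = rep(0:3, c(400, 200, 100, 100)),
                       episode = rep(1L, 800), frame_idx = 1:800),
                  class = "labeled_dataset")
  sp <- split_time_independent(ds, seed = 3, stratify = TRUE)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:800)
  h <- function(idx) tabulate(ds$labels[idx] + 1L, 4)
  expect_equal(h(sp$test), round(0.2 * c(400, 200, 100, 100)))
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), 800)
})

test_that("block split keeps temporal order and leaks nothing", {
  ds <- structure(list(labels = rep(0L, 250),
                       episode = rep(1:2, c(100, 150)),
                       frame_idx = c(1:100, 1:150)),
                  class = "labeled_dataset")
  sp <- split_blocks(ds)
  # 100-frame episode: train 1..64, val 65..80, test 81..100
  e1 <- function(v) v[v <= 100]
  expect_equal(e1(sp$train), 1:64)
  expect_equal(e1(sp$val), 65:80)
  expect_equal(e1(sp$test), 81:100)
  for (e in 1:2) {
    tr <- intersect(sp$train, which(ds$episode == e))
    te <- intersect(sp$test, which(ds$episode == e))
    expect_lt(max(tr), min(te))
  }
  expect_identical(sp, split_blocks(ds))
  short <- structure(list(labels = rep(0L, 4), episode = rep(1L, 4),
                          frame_idx = 1:4), class = "labeled_dataset")
  expect_error(split_blocks(short), "episode")
})

test_that("class weights follow inverse frequency with mean one", {
  lab8 <- rep(0:7, each = 25)
  expect_equal(unname(class_weights(lab8)), rep(1, 8))
  lab2 <- rep(c(0L, 1L), c(200, 100))
  w <- class_weights(lab2)
  expect_equal(unname(w[c("0", "1")]), c(0.75, 1.5))
  expect_equal(unname(w[as.character(2:7)]), rep(0, 6))
  w1 <- class_weights(rep(3L, 40))
  expect_equal(unname(w1["3"]), 1)
  expect_equal(sum(w1), 1)
  # weighted mean over samples is 1 for any label mix
  set.seed(6)
  labs <- sample(0:7, 500, TRUE, prob = c(8, 4, 2, 1, 1, 1, 1, 1))
  wc <- class_weights(labs)
  expect_equal(mean(wc[as.character(labs)]), 1)
})

test_that("dataset assembly conserves the label histogram across splits", {
  set.seed(7)
  eps <- lapply(1:2, function(e) list(
    bsp = afdriverloc:::new_bsp_recording(matrix(rnorm(64 * 40), 64), 500),
    labels = sample(0:3, 40, TRUE)))
  ds <- build_labeled_dataset(eps, "1ch", resize = c(12, 24),
                              frame_stride = 2L)
  expect_equal(length(ds$labels), 40)
  expect_equal(dim(ds$images), c(40, 12, 24, 1))
  expect_true(all(diff(ds$frame_idx[ds$episode == 1]) > 0))
  sp <- split_time_independent(ds, seed = 2)
  h <- function(lab) table(factor(lab, 0:7))
  expect_equal(h(ds$labels[sp$train]) + h(ds$labels[sp$val]) +
                 h(ds$labels[sp$test]), h(ds$labels))
})
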