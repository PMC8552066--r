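# Accuracy, Cohen's kappa, per-class rates, sweep mechanics.

test_that("accuracy is trace over total", {
  cm <- diag(c(10, 20, 5, 1, 1, 1, 1, 1))
  expect_equal(accuracy(cm), 1)
  cm2 <- matrix(1, 2, 2) * c(91, 5, 4, 0)   # trace 91 of 100
  cm2 <- matrix(c(91, 4, 5, 0), 2, 2)
  expect_equal(accuracy(cm2), 0.91)
  zd <- matrix(c(0, 3, 7, 0), 2, 2)
  expect_equal(accuracy(zd), 0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("kappa matches the closed form and its landmarks", {
  # perfect agreement over 1,000 8-class samples
  set.seed(1)
  lab <- sample(0:7, 1000, TRUE)
  cm <- confusion_matrix(lab, lab)
  expect_equal(cohens_kappa(cm), 1)
  # frozen worked example: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  cm2 <- matrix(c(40, 20, 10, 30), 2, 2)
  expect_equal(accuracy(cm2), 0.7)
  expect_equal(cohens_kappa(cm2), 0.4)
  # independent raters with matched marginals -> kappa near 0
  set.seed(2)
  p <- c(0.3, 0.2, 0.15, 0.1, 0.1, 0.05, 0.05, 0.05)
  t1 <- sample(0:7, 1e5, TRUE, p)
  t2 <- sample(0:7, 1e5, TRUE, p)
  expect_lt(abs(cohens_kappa(confusion_matrix(t1, t2))), 0.01)
  # p_e = 1 is signaled, not silently returned
  const <- confusion_matrix(rep(2L, 50), rep(2L, 50))
  expect_error(cohens_kappa(const), "undefined")
})

test_that("sensitivity and specificity use the one-vs-rest collapse", {
  cm <- matrix(0, 8, 8, dimnames = list(as.character(0:7),
                                        as.character(0:7)))
  cm["1", "1"] <- 8; cm["1", "2"] <- 2          # TP 8, FN 2
  cm["0", "0"] <- 90; cm["0", "1"] <- 10        # class 1: FP 10, TN 90
  expect_equal(sensitivity(cm, 1), 0.8)
  expect_equal(specificity(cm, 1), 0.9)
  expect_warning(v <- sensitivity(cm, 5), "undefined")
  expect_true(is.na(v))
  # perfect classifier: TPR = TNR = 1 for every non-empty class
  set.seed(3)
  lab <- sample(0:7, 400, TRUE)
  pcm <- confusion_matrix(lab, lab)
  for (c in unique(lab)) {
    expect_equal(sensitivity(pcm, c), 1)
    expect_equal(specificity(pcm, c), 1)
  }
})

test_that("kappa never exceeds accuracy (property over random matrices)", {
  set.seed(10)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    cm <- matrix(rpois(k * k, sample(1:20, 1)), k)
    if (sum(cm) == 0) next
    pe <- sum((rowSums(cm) / sum(cm)) * (colSums(cm) / sum(cm)))
    if (pe >= 1 - 1e-12) next
    expect_lte(cohens_kappa(cm), accuracy(cm) + 1e-12)
  }
})

test_that("metrics_report is consistent micro and per class", {
  set.seed(4)
  truth <- sample(0:7, 600, TRUE)
  pred <- ifelse(runif(600) < 0.7, truth, sample(0:7, 600, TRUE))
  rep <- metrics_report(truth, pred)
  cm <- rep$confusion
  expect_equal(sum(diag(cm)), round(rep$accuracy * rep$n))
  # per-class accuracy equals recall under one-vs-rest
  for (c in 0:7) {
    row <- rep$per_class[rep$per_class$class == c, ]
    expect_equal(row$accuracy, row$tpr)
  }
  micro_tp <- sum(vapply(0:7, function(c) cm[c + 1, c + 1], numeric(1)))
  expect_equal(micro_tp, sum(diag(cm)))
})

test_that("noise sweep has the right mechanics", {
  # toy model + episodes: constant-image classes so prediction is cheap
  set.seed(5)
  model <- build_custom_cnn(c(8, 8, 1), n_classes = 8, filters = c(2, 2, 2),
                            dense_units = c(8, 8), dropout = 0, seed = 1)
  eps <- list(list(
    bsp = afdriverloc:::new_bsp_recording(matrix(rnorm(64 * 120), 64), 500),
    labels = sample(0:7, 120, TRUE), frames = seq(10, 110, by = 10)))
  sw <- noise_robustness_sweep(model, eps, snrs = c(5, 20), n_reps = 3,
                               seed = 3, resize = c(8, 8))
  expect_equal(nrow(sw$summary), 2)
  expect_equal(nrow(sw$raw), 6)
  expect_true(all(sw$summary$accuracy_sd >= 0))
  sw2 <- noise_robustness_sweep(model, eps, snrs = c(5, 20), n_reps = 3,
                                seed = 3, resize = c(8, 8))
  expect_identical(sw$raw, sw2$raw)
  # infinite SNR reproduces the clean metrics exactly
  swc <- noise_robustness_sweep(model, eps, snrs = Inf, n_reps = 2,
                                seed = 3, resize = c(8, 8))
  expect_equal(swc$raw$accuracy[1], swc$raw$accuracy[2])
  expect_error(noise_robustness_sweep(model, eps, snrs = numeric(0)),
               "empty")
})
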