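# Epoch container, Z-score normalization, split planning, fixture I/O.

make_epochs <- function(data, labels, fs = 250, ...) {
  eeg_epochs(data, labels, fs, ...)
}

test_that("the epoch container validates its invariants", {
  ok <- array(rnorm(2 * 3 * 64), c(2, 3, 64))
  expect_s3_class(make_epochs(ok, c(0, 1)), "eeg_epochs")
  bad <- ok; bad[1, 1, 1] <- NaN
  expect_error(make_epochs(bad, c(0, 1)), "non-finite")
  expect_error(make_epochs(ok, c(0, 1, 2)), "trials")
  expect_error(make_epochs(ok, c(0, 5), n_classes = 2), "out of range")
  expect_error(make_epochs(array(rnorm(2 * 3 * 32), c(2, 3, 32)), c(0, 1)),
               ">= 64 samples")
})

test_that("normalization statistics match hand computation", {
  # channel 0: alternating -1, 1 -> mean 0, population variance 1
  x <- array(0, c(1, 2, 64))
  x[1, 1, ] <- rep(c(-1, 1), 32)
  x[1, 2, ] <- rnorm(64)
  st <- zscore_fit(make_epochs(x, 0))
  expect_equal(st$mean[1], 0)
  expect_equal(st$variance[1], 1)

  # 2-channel, 2-trial toy set against brute-force mean/variance
  y <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  st2 <- zscore_fit(make_epochs(y, c(0, 1)))
  for (ch in 1:2) {
    vals <- as.vector(y[, ch, ])
    expect_equal(st2$mean[ch], mean(vals))
    expect_equal(st2$variance[ch], mean((vals - mean(vals))^2))
  }

  # constant channel -> degenerate-channel error naming the channel
  z <- y; z[, 2, ] <- 3
  expect_error(zscore_fit(make_epochs(z, c(0, 1))), "channel 2")
})

test_that("normalization applies train statistics unchanged and supports both denominators", {
  y <- array(rnorm(3 * 2 * 64, sd = 2), c(3, 2, 64))
  ep <- make_epochs(y, c(0, 1, 0))
  st <- zscore_fit(ep)
  z <- zscore_apply(ep, st)
  for (ch in 1:2) {
    vals <- as.vector(z$data[, ch, ])
    expect_lt(abs(mean(vals)), 1e-6)
    expect_lt(abs(sqrt(mean((vals - mean(vals))^2)) - 1), 1e-6)
  }
  # centering: data equal to the stored mean maps to zero
  cst <- ep
  for (ch in 1:2) cst$data[, ch, ] <- st$mean[ch]
  expect_true(all(abs(zscore_apply(cst, st)$data) < 1e-12))
  # mean 2, variance 4, x = 6: sd convention gives 2, variance convention 1
  st1 <- structure(list(mean = 2, variance = 4, n_channels = 1L),
                   class = "norm_stats")
  one <- make_epochs(array(6, c(1, 1, 64)), 0)
  expect_equal(zscore_apply(one, st1)$data[1, 1, 1], 2.0)
  expect_equal(zscore_apply(one, st1, denominator = "variance")$data[1, 1, 1],
               1.0)
  # channel-count mismatch
  expect_error(zscore_apply(ep, st1), "mismatch")
})

test_that("stratified k-fold plans partition trials with balanced labels", {
  ep <- make_epochs(array(rnorm(72 * 2 * 64), c(72, 2, 64)),
                    rep(0:3, each = 18))
  plan <- make_within_subject_folds(ep, k = 5, seed = 11)
  sizes <- sort(vapply(plan$folds, function(f) length(f$test), integer(1)))
  expect_equal(sizes, c(14L, 14L, 14L, 15L, 15L))
  expect_identical(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:72)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    hist <- table(factor(ep$labels[f$test], levels = 0:3))
    expect_true(all(abs(hist - length(f$test) / 4) <= 1))
  }
  # determinism
  plan2 <- make_within_subject_folds(ep, k = 5, seed = 11)
  expect_identical(plan, plan2)
  # two trials per class cannot be dealt over five folds
  few <- epochs_subset(ep, c(1, 2, 19, 20, 37, 38, 55, 56))
  expect_error(make_within_subject_folds(few, k = 5), "insufficient")
})

test_that("LOSO plans hold out each subject exactly once", {
  cohort <- lapply(1:9, function(s)
    make_epochs(array(rnorm(4 * 2 * 64), c(4, 2, 64)), c(0, 1, 0, 1),
                subject_id = sprintf("S%02d", s)))
  plan <- make_loso_folds(cohort)
  expect_length(plan$folds, 9)
  for (f in plan$folds) expect_length(f$train, 8)
  expect_identical(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:9)

  two <- make_loso_folds(cohort[1:2])
  expect_length(two$folds, 2)
  expect_length(two$folds[[1]]$train, 1)

  dup <- cohort[c(1, 1)]
  expect_error(make_loso_folds(dup), "duplicate")
  expect_error(make_loso_folds(cohort[1]), "2 subjects")
})

test_that("fixture files round-trip losslessly and validate on read", {
  ep <- generate_epochs(desk_spec(trials_per_class = 3), 1)
  path <- withr::local_tempfile(fileext = ".rds")
  write_fixture(ep, path)
  back <- read_fixture(path)
  expect_identical(back$data, ep$data)
  expect_identical(back$labels, ep$labels)
  expect_identical(back$channel_names, ep$channel_names)
  expect_identical(back$fs, ep$fs)

  # missing field
  obj <- readRDS(path); obj$labels <- NULL
  saveRDS(obj, path)
  expect_error(read_fixture(path), "labels")
  # labels exceeding the declared class count
  obj2 <- readRDS(path); obj2$labels <- rep(9L, dim(obj2$data)[1])
  saveRDS(obj2, path)
  expect_error(read_fixture(path), "n_classes")
  expect_error(read_fixture("no/such/file.rds"), "not found")
})

test_that("GDF loading fails cleanly without a file", {
  expect_error(load_gdf_epochs("missing.gdf"), "cannot read")
})
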