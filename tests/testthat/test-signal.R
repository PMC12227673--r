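test_that("baseline subtraction removes the per-channel 3rd percentile", {
  # constant column collapses to zero
  m <- cbind(rep(5, 50), rep(-2, 50))
  expect_equal(unname(subtract_baseline(m)), matrix(0, 50, 2))

  # idempotent once the 3rd percentile is zero
  set.seed(3)
  x <- cbind(rnorm(200, 10), rnorm(200, 3))
  once <- subtract_baseline(x)
  expect_equal(subtract_baseline(once), once)

  # linear-interpolation percentile definition: 3rd percentile of 0..99
  col <- matrix(0:99, ncol = 1)
  expect_equal(subtract_baseline(col)[, 1], (0:99) - 2.97)

  expect_error(subtract_baseline(matrix(numeric(), 0, 2)), "empty")
})

test_that("crosstalk compensation inverts spectral mixing", {
  # identity matrix is a no-op
  m <- matrix(rnorm(40), ncol = 4)
  expect_equal(compensate_crosstalk(m, diag(4)), m, ignore_attr = TRUE)

  # hand-computed 2x2 case: obs = xt %*% true
  xt <- rbind(c(1, 0.2), c(0, 1))
  expect_equal(unname(compensate_crosstalk(rbind(c(1.4, 2.0)), xt)),
               rbind(c(1.0, 2.0)))

  # mix-then-compensate round trip on a random near-diagonal matrix
  set.seed(11)
  xt4 <- matrix(runif(16, 0, 0.3), 4); diag(xt4) <- 1
  true <- matrix(rnorm(400, 1), ncol = 4)
  mixed <- t(xt4 %*% t(true))
  expect_lt(max(abs(compensate_crosstalk(mixed, xt4) - true)), 1e-9)

  singular <- matrix(1, 3, 3)
  expect_error(compensate_crosstalk(matrix(rnorm(9), 3), singular), "singular")
})

test_that("1i calibration rescales each channel to a unit reference", {
  m <- cbind(c(9.32, 18.64), c(18.9, 37.8))
  cal <- calibrate(m, reference = c(9.32, 18.9))
  expect_equal(unname(cal), cbind(c(1, 2), c(1, 2)))
  expect_equal(calibrate(m, c(1, 1)), m, ignore_attr = TRUE)
  # idempotent once the reference is 1
  expect_equal(calibrate(cal, c(1, 1)), cal)
  expect_error(calibrate(m, c(0, 1)), "positive")

  # reference centers recovered from single-positive 1i partitions
  set.seed(5)
  raw <- cbind(c(rnorm(60, 0.2, 0.05), rnorm(20, 9.3, 0.2)), rnorm(80, 0.2, 0.05))
  ref <- level1_reference(raw, c(4, 14, 24))
  expect_equal(ref[1], 9.3, tolerance = 0.05)
  expect_true(is.na(ref[2]))
})

test_that("threshold classification assigns the four amplitude levels", {
  cl <- classify_partitions(rbind(
    c(0.15, 2.10, 0.20, 0.04),
    c(0, 0, 0, 0),
    c(0.6, 1.6, 2.6, 3.6)
  ))
  expect_equal(cl$labels, c("0200", "0000", "1233"))
  expect_equal(cl$counts$n_partitions, 3)
  expect_equal(cl$counts$counts[["0000"]], 1)

  # classification is monotone in each channel value
  set.seed(13)
  for (i in 1:20) {
    v <- runif(4, -0.5, 3.5)
    base <- label_digits(classify_partitions(rbind(v))$labels)
    c <- sample(4, 1)
    v2 <- v; v2[c] <- v2[c] + runif(1, 0, 2)
    up <- label_digits(classify_partitions(rbind(v2))$labels)
    expect_gte(up[c], base[c])
    expect_equal(up[-c], base[-c])
  }

  expect_error(threshold_set(4, c(1, 1, 2)), "increasing")
})

test_that("tag presence calls respect the partition-count threshold", {
  cb <- codebook(c("1000", "0100", "0010"))
  labels <- c(rep("1000", 4), "0100", rep("0000", 10))
  counts <- label_counts(labels)
  expect_setequal(call_tags(counts, cb, min_partitions = 1), c("1000", "0100"))
  expect_setequal(call_tags(counts, cb, min_partitions = 5), character())
  expect_equal(call_tags(label_counts(rep("0000", 5)), cb), character())
})

test_that("Euclidean QC masks undetected channels before measuring distance", {
  cb <- enumerate_codebook(4, 2, 2)
  m <- rbind(c(0.15, 2.10, 0.20, 0.04),
             c(0, 2, 0, 0),
             c(1.1, 0, 0, 1.9),
             c(5, 5, 5, 5))
  asg <- c("0200", "0200", "1002", NA)
  d <- euclidean_qc(m, asg, cb)
  expect_equal(d[1], 0.10)
  expect_equal(d[2], 0)
  expect_equal(d[3], sqrt(0.1^2 + 0.1^2))
  expect_true(is.na(d[4]))
  expect_error(euclidean_qc(m, c("9999", NA, NA, NA), cb), "unknown tag")
})

test_that("label tallies validate and account for every partition", {
  lc <- label_counts(c("0100", "0100", "0000", "3000"))
  expect_equal(lc$n_partitions, 4)
  expect_equal(lc$counts[["0100"]], 2)
  expect_equal(lc$null_label, "0000")
  # named-count construction keeps a missing null label at zero
  lc2 <- label_counts(c("0100" = 5))
  expect_equal(lc2$counts[["0000"]], 0)
  expect_error(label_counts(c("01A0")), "digits")
  expect_error(label_counts(c("0100" = -1)), "non-negative")
})
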