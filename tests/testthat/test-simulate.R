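test_that("Poisson loading reproduces occupancy statistics", {
  cb <- codebook("1")
  N <- 20000
  # no template -> every partition empty
  occ0 <- load_partitions(cb, copies = 0, n_partitions = N, seed = 1)
  expect_false(any(occ0))

  # occupancy rate converges to 1 - exp(-copies/N) for both placement methods
  for (method in c("molecules", "bernoulli")) {
    lam <- 0.5
    occ <- load_partitions(cb, copies = N * lam, n_partitions = N,
                           method = method, seed = 2)
    p <- -expm1(-lam)
    se <- sqrt(p * (1 - p) / N)
    expect_lt(abs(mean(occ) - p), 4 * se)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cb <- enumerate_codebook(4, 2, 2)
  a <- simulate_run(cb, copies = 50, n_partitions = 3000, seed = 123)
  b <- simulate_run(cb, copies = 50, n_partitions = 3000, seed = 123)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$true_labels, b$true_labels)
})

test_that("noiseless rendering produces the ideal level intensities", {
  cb <- enumerate_codebook(4, 2, 2)
  quiet <- noise_model(cluster_sd = 0)
  occ <- matrix(FALSE, 3, 32, dimnames = list(NULL, cb$tags$name))
  occ[2, match("0200", cb$tags$signature)] <- TRUE
  occ[3, match("1000", cb$tags$signature)] <- TRUE
  occ[3, match("2000", cb$tags$signature)] <- TRUE

  r <- render_signal(occ, cb, quiet)
  expect_equal(unname(r$amplitudes[1, ]), c(0, 0, 0, 0))   # empty partition
  expect_equal(unname(r$amplitudes[2, ]), c(0, 2, 0, 0))
  expect_equal(unname(r$amplitudes[3, ]), c(3, 0, 0, 0))   # 1i + 2i additive
  expect_equal(r$true_labels, c("0000", "0200", "3000"))
})

test_that("incomplete hydrolysis attenuates the 2i contribution", {
  cb <- enumerate_codebook(4, 2, 2)
  occ <- matrix(FALSE, 1, 32, dimnames = list(NULL, cb$tags$name))
  occ[1, match("0012", cb$tags$signature)] <- TRUE
  nm <- noise_model(cluster_sd = 0, incomplete_hydrolysis_prob = 1,
                    incomplete_hydrolysis_factor = 0.75)
  r <- render_signal(occ, cb, nm)
  expect_equal(unname(r$amplitudes[1, ]), c(0, 0, 1, 1.5))
})

test_that("rain draws positive channels between adjacent level means", {
  cb <- codebook("2")
  occ <- matrix(TRUE, 500, 1, dimnames = list(NULL, cb$tags$name))
  nm <- noise_model(cluster_sd = 0, rain_fraction = 1)
  r <- render_signal(occ, cb, nm, seed = 9)
  expect_true(all(r$amplitudes[, 1] >= 1 & r$amplitudes[, 1] < 2))
})

test_that("crosstalk mixes rendered channels linearly", {
  cb <- enumerate_codebook(4, 2, 2)
  occ <- matrix(FALSE, 1, 32, dimnames = list(NULL, cb$tags$name))
  occ[1, match("0200", cb$tags$signature)] <- TRUE
  xt <- uniform_crosstalk(4, 0.3)
  r <- render_signal(occ, cb, noise_model(cluster_sd = 0), crosstalk = xt)
  expect_equal(unname(r$amplitudes[1, ]), as.vector(xt %*% c(0, 2, 0, 0)))
})

test_that("classification inverts noiseless rendering (loop-back)", {
  set.seed(7)
  cb <- enumerate_codebook(4, 2, 2)
  run <- simulate_run(cb, copies = 80, n_partitions = 4000,
                      noise = noise_model(cluster_sd = 0), seed = 17)
  cl <- classify_partitions(run$amplitudes)
  expect_identical(cl$labels, run$true_labels)
})

test_that("default-noise simulations classify almost perfectly end to end", {
  cb <- enumerate_codebook(4, 2, 2)
  run <- simulate_run(cb, copies = 60, n_partitions = 26000, seed = 29)
  cl <- classify_partitions(run$amplitudes)
  occupied <- run$true_labels != "0000"
  agree <- mean(cl$labels[occupied] == run$true_labels[occupied])
  expect_gte(agree, 0.99)
})

test_that("noise model validates its parameters", {
  expect_error(noise_model(level_means = c(0, 2, 1, 3)), "increasing")
  expect_error(noise_model(cluster_sd = -1))
  expect_error(noise_model(rain_fraction = 1.5))
})
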