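test_that("single-channel estimation inverts Poisson occupancy", {
  counts <- label_counts(c("0000" = 10000, "1000" = 1000, "0100" = 0))
  expect_equal(estimate_single_channel(counts, "1000"), log(1.1))
  expect_equal(estimate_single_channel(counts, "0100"), 0)
  expect_error(estimate_single_channel(counts, "1100"), "single-channel")
  expect_error(estimate_single_channel(label_counts(c("1000" = 5)), "1000"),
               "saturated")

  # one-tag codebook reduces to the textbook dPCR estimator -ln(1 - P/N)
  N <- 26000; pos <- 3123
  counts1 <- label_counts(c("0" = N - pos, "1" = pos))
  expect_equal(estimate_single_channel(counts1, "1"), -log(1 - pos / N))
  fit1 <- decode_dpcr(counts1, codebook("1"))
  expect_equal(unname(coef(fit1, "lambda")), -log(1 - pos / N))
})

test_that("label probabilities match the brute-force presence enumeration", {
  # single tag: closed form
  cb1 <- codebook("10")
  p <- label_probabilities(cb1, 0.3)
  expect_equal(p[["10"]], -expm1(-0.3))
  expect_equal(p[["00"]], exp(-0.3))

  # two tags in different channels: independence product
  cb2 <- codebook(c("10", "01"))
  p2 <- label_probabilities(cb2, c(0.2, 0.4))
  expect_equal(p2[["11"]], (-expm1(-0.2)) * (-expm1(-0.4)))

  # random codebooks against exhaustive subset enumeration
  set.seed(21)
  for (i in 1:8) {
    cb <- random_codebook(channels = sample(2:4, 1), n_tags = 10)
    lam <- runif(nrow(cb$tags), 0, 0.3)
    got <- label_probabilities(cb, lam)
    want <- oracle_label_probs(cb, lam)
    expect_equal(sum(got), 1)
    expect_equal(got[sort(names(got), method = "radix")], want,
                 tolerance = 1e-12)
  }
})

test_that("the hierarchy recovers generating occupancies from exact counts", {
  # three-tag worked case with label expectations written out longhand
  la <- 0.09; lb <- 0.05; lc <- 0.02
  N <- 26000
  Lam <- la + lb + lc
  P0 <- N * exp(-Lam)
  P1000 <- P0 * (exp(la) - 1)
  P0100 <- P0 * (exp(lb) - 1)
  P1100 <- N * exp(-(Lam - la - lb - lc)) *
    ((1 - exp(-lc)) + exp(-lc) * (1 - exp(-la)) * (1 - exp(-lb)))
  cb <- codebook(c("1000", "0100", "1100"))
  counts <- label_counts(c("0000" = P0, "1000" = P1000,
                           "0100" = P0100, "1100" = P1100))
  fit <- decode_dpcr(counts, cb)
  expect_equal(unname(coef(fit, "lambda")[c("1000", "0100", "1100")]),
               c(la, lb, lc), tolerance = 1e-12)
  # the intermediate ladder matches the printed special case
  row <- fit$table[fit$table$signature == "1100", ]
  expect_equal(row$E_L, P0 * (P1000 / P0) * (P0100 / P0))
  expect_equal(row$P_star, row$P_prime * exp(-la - lb))

  # all-null counts give zero everywhere
  z <- decode_dpcr(label_counts(c("0000" = 1000)), cb)
  expect_equal(unname(coef(z)), c(0, 0, 0))
})

test_that("estimation excludes ambiguous non-signature labels but reports them", {
  cb <- enumerate_codebook(4, 2, 2)
  counts <- label_counts(c("0000" = 9000, "1000" = 500, "3000" = 40,
                           "1110" = 7))
  fit <- decode_dpcr(counts, cb)
  expect_setequal(fit$excluded$label, c("3000", "1110"))
  expect_equal(sum(fit$excluded$count), 47)
  # excluded labels contribute nothing to the occupancy estimates (they do
  # still count toward N, hence toward copies = N * lambda)
  drop <- decode_dpcr(label_counts(c("0000" = 9000, "1000" = 500)), cb)
  expect_equal(coef(fit, "lambda"), coef(drop, "lambda"))
})

test_that("lambda is monotone in the tag's exact-label count and never negative", {
  cb <- codebook(c("1000", "0100", "1100"))
  base <- c("0000" = 9000, "1000" = 600, "0100" = 400, "1100" = 50)
  prev <- -Inf
  for (extra in c(0, 25, 100, 400)) {
    counts <- base; counts[["1100"]] <- counts[["1100"]] + extra
    lam <- coef(decode_dpcr(label_counts(counts), cb), "lambda")[["1100"]]
    expect_gte(lam, prev)
    prev <- lam
  }
  # sampling noise can push the corrected count negative: clamp at zero
  noisy <- c("0000" = 9000, "1000" = 600, "0100" = 400, "1100" = 10)
  lam <- coef(decode_dpcr(label_counts(noisy), cb), "lambda")
  expect_true(all(lam >= 0))
  expect_equal(lam[["1100"]], 0)
})

test_that("decoding refuses saturated reactions and mismatched labels", {
  cb <- codebook(c("1000", "0100"))
  expect_error(decode_dpcr(label_counts(c("1000" = 100)), cb), "saturated")
  expect_error(decode_dpcr(label_counts(c("10" = 1, "00" = 9)), cb),
               "channel count")
})

test_that("modelling methods are mutually consistent", {
  set.seed(31)
  cb <- enumerate_codebook(4, 2, 2)
  lam <- runif(32, 0.001, 0.01)
  probs <- label_probabilities(cb, lam)
  fit <- decode_dpcr(label_counts(probs * 26000, channels = 4), cb)

  expect_equal(coef(fit), coef(fit, "lambda") * fit$n_partitions)
  # fitted counts reproduce the (exact) observed counts; residuals vanish
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_equal(sum(fitted(fit)), fit$n_partitions)
  pr <- predict(fit, type = "counts")
  expect_equal(sum(pr$value), fit$n_partitions)

  # parametric bootstrap: re-decoding simulated tallies recovers the copies
  sims <- simulate(fit, nsim = 20, seed = 8)
  est <- vapply(sims, function(s) sum(coef(decode_dpcr(s, cb))), numeric(1))
  expect_equal(mean(est), sum(coef(fit)), tolerance = 0.02)

  s <- summary(fit)
  expect_s3_class(s, "summary.dpcr_decode")
  expect_named(s$table, c("name", "signature", "sites", "P_L", "E_L",
                          "P_prime", "P_star", "lambda", "copies"))
  expect_output(print(fit), "deconvolution")

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("decoding accepts raw per-partition labels", {
  cb <- codebook(c("10", "01"))
  labels <- c(rep("00", 900), rep("10", 60), rep("01", 40))
  fit <- decode_dpcr(labels, cb)
  expect_equal(coef(fit, "lambda")[["10"]], log(1 + 60 / 900))
})
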