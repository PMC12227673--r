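test_that("encoding capacity matches the combinatorial closed form", {
  expect_equal(capacity(4, 2, 2), 32)
  expect_equal(capacity(5, 2, 2), 50)
  expect_equal(capacity(6, 2, 2), 72)
  expect_equal(capacity(4, 2, 4), 80)
  expect_equal(capacity(6, 2, 6), 728)
  expect_equal(capacity(1, 2, 1), 2)
  # with sites allowed in every channel the code space is all nonzero
  # ternary strings: (L+1)^C - 1
  for (C in 1:8) expect_equal(capacity(C, 2, C), 3^C - 1)
  expect_error(capacity(4, 2, 5), "max_sites")
  expect_error(capacity(0, 2, 1), ">= 1")
})

test_that("canonical enumeration is exhaustive, distinct and deterministic", {
  cb <- enumerate_codebook(2, 2, 1)
  expect_equal(cb$tags$signature, c("01", "02", "10", "20"))

  cb4 <- enumerate_codebook(4, 2, 2)
  expect_equal(nrow(cb4$tags), 32)
  expect_false(anyDuplicated(cb4$tags$signature) > 0)
  expect_true(all(c("1100", "2020", "0202") %in% cb4$tags$signature))
  expect_identical(cb4$tags, enumerate_codebook(4, 2, 2)$tags)

  for (args in list(c(3, 2, 2), c(4, 2, 3), c(6, 2, 6))) {
    expect_equal(nrow(enumerate_codebook(args[1], args[2], args[3])$tags),
                 capacity(args[1], args[2], args[3]))
  }
})

test_that("codebook construction enforces the signature invariants", {
  expect_error(codebook(c("1100", "1100")), "distinct")
  expect_error(codebook("1300"), "digits")
  expect_error(codebook("0000"), "nonzero")
  expect_error(codebook(c("10", "012")), "same number of channels")
  expect_error(codebook("1110", max_sites = 2), "max_sites")
})

test_that("signature union is the per-channel probe-class set union", {
  expect_equal(signature_union(c("1000", "0100")), "1100")
  expect_equal(signature_union(c("1000", "2000")), "3000")
  expect_equal(signature_union(c("1000", "1000")), "1000")
  expect_equal(signature_union("0210"), "0210")

  # idempotent / commutative / associative over random draws
  set.seed(41)
  full <- enumerate_codebook(4, 2, 4)$tags$signature
  for (i in 1:25) {
    s <- sample(full, 3)
    expect_equal(signature_union(c(s, s)), signature_union(s))
    expect_equal(signature_union(sample(s)), signature_union(s))
    expect_equal(signature_union(c(signature_union(s[1:2]), s[3])),
                 signature_union(s))
  }
})

test_that("labels decompose into exactly the consistent tag combinations", {
  cb <- codebook(c("1000", "0100", "1100"))
  d <- decompositions("1100", cb)
  expect_length(d, 5)
  expected <- list("1100", c("1000", "0100"), c("1100", "1000"),
                   c("1100", "0100"), c("1100", "1000", "0100"))
  canon <- function(sets) sort(vapply(sets, function(s) paste(sort(s), collapse = "+"), ""))
  expect_equal(canon(d), canon(expected))

  # single-channel labels are unambiguous
  expect_equal(decompositions("1000", cb), list("1000"))

  # level 3 in a channel forces both probe classes of that channel
  cb32 <- enumerate_codebook(4, 2, 2)
  expect_equal(decompositions("3000", cb32), list(c("1000", "2000")))

  expect_length(decompositions("2222", cb), 0)
})

test_that("every decomposition unions back to its label", {
  set.seed(99)
  for (i in 1:10) {
    cb <- random_codebook(channels = 3, n_tags = 8)
    subset <- sample(cb$tags$signature, sample(1:3, 1))
    lab <- signature_union(subset)
    d <- decompositions(lab, cb)
    expect_gt(length(d), 0)
    for (s in d) expect_equal(signature_union(s), lab)
    # single-site signatures decompose uniquely
    one_site <- cb$tags$signature[
      rowSums(matrix(as.integer(strsplit(paste(cb$tags$signature, collapse = ""),
                                         "")[[1]]), ncol = 3, byrow = TRUE) > 0) == 1][1]
    if (!is.na(one_site)) expect_length(decompositions(one_site, cb), 1)
  }
})

test_that("decomposition enumeration is capped on pathological labels", {
  cb <- enumerate_codebook(4, 2, 4)  # 80 tags, most contained in 3333
  expect_error(decompositions("3333", cb, max_contained = 20), "capped")
})
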