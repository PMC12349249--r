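test_that("raw recording ingestion enforces the discard rule", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ok.tsv")
  m <- matrix(seq_len(80) / 10, 10, 8)
  writeLines(apply(m, 1, paste, collapse = "\t"), f)
  rec <- read_raw_table(f, label = "x", source = "meta_train")
  expect_s3_class(rec, "raw_recording")
  expect_equal(dim(rec$channels), c(10L, 8L))
  expect_equal(rec$channels, m, ignore_attr = TRUE)

  # one blank cell anywhere discards the whole recording
  bad <- apply(m, 1, paste, collapse = "\t")
  bad[4] <- sub("^([^\t]*)\t[^\t]*", "\\1\t", bad[4])
  fb <- file.path(d, "bad.tsv")
  writeLines(bad, fb)
  expect_error(read_raw_table(fb), "discarded")

  # non-numeric cells likewise
  fc <- file.path(d, "nonnum.tsv")
  writeLines(sub("0.1", "oops", bad[1], fixed = TRUE), fc)
  expect_error(read_raw_table(fc), "discarded")

  expect_error(read_raw_table(file.path(d, "absent.tsv")), "not found")
  expect_error(raw_recording(matrix(c(1, NA), 1, 2), 0.01, "x"), "discarded")
})

test_that("per-second averaging reduces blocks to their means", {
  # constant input stays constant
  const <- matrix(2.5, 400, 3)
  out <- per_second_average(const, 100L)
  expect_equal(dim(out), c(4L, 3L))
  expect_true(all(out == 2.5))

  # ramp oracle: mean of 0..99 is 49.5, of 100..199 is 149.5
  ramp <- matrix(0:199, 200, 1)
  expect_equal(per_second_average(ramp, 100L)[, 1], c(49.5, 149.5))

  # full-size contract: 40,000 points at 100 per second -> 400 rows
  big <- matrix(rnorm(40000 * 8), 40000, 8)
  expect_equal(dim(per_second_average(big, 100L)), c(400L, 8L))

  # trailing remainder dropped with a message
  expect_message(out2 <- per_second_average(matrix(1, 250, 2), 100L),
                 "dropping")
  expect_equal(nrow(out2), 2L)
  expect_error(per_second_average(ramp, 0L), "positive")
})

test_that("per-second averaging commutes with channel permutation", {
  set.seed(3)
  m <- matrix(rnorm(600 * 4), 600, 4)
  perm <- c(3L, 1L, 4L, 2L)
  a <- per_second_average(m[, perm], 100L)
  b <- per_second_average(m, 100L)[, perm]
  expect_equal(a, b)
})

test_that("window truncation keeps the half-open [start, end) rows", {
  m <- matrix(seq_len(400 * 8), 400, 8)
  out <- window_truncate(m)
  expect_equal(dim(out), c(240L, 8L))
  # row i of output equals row 17 + i of the input (0-based)
  for (i in c(1L, 100L, 240L)) expect_equal(out[i, ], m[17L + i, ])
  expect_equal(window_truncate(m, 0L, nrow(m)), m)
  expect_error(window_truncate(m, 17L, 401L), "outside")
  expect_error(window_truncate(m, 100L, 50L), "outside")
})

test_that("equal-interval extraction selects rounded linspace indices", {
  m <- matrix(seq_len(10), 10, 1)
  # n = 10, target = 4: 0-based indices 0, 3, 6, 9
  expect_equal(equal_interval_extract(m, 4L)[, 1], c(1, 4, 7, 10))
  # identity when target equals n
  expect_equal(equal_interval_extract(m, 10L), m)
  # full-size contract
  big <- matrix(rnorm(4000 * 8), 4000, 8)
  expect_equal(dim(equal_interval_extract(big, 240L)), c(240L, 8L))
  # endpoints always included
  got <- equal_interval_extract(big, 240L)
  expect_equal(got[1, ], big[1, ])
  expect_equal(got[240, ], big[4000, ])
  expect_error(equal_interval_extract(m, 11L), "exceeds")
})

test_that("min-max normalisation maps channels to [0, 1] and is idempotent", {
  expect_equal(normalize_sample(matrix(c(1, 3, 5), 3, 1))[, 1], c(0, 0.5, 1))
  expect_equal(normalize_sample(matrix(4, 2, 1))[, 1], c(0, 0))
  set.seed(5)
  m <- matrix(rnorm(240 * 8, sd = 10), 240, 8)
  n1 <- normalize_sample(m)
  expect_equal(unname(apply(n1, 2, min)), rep(0, 8))
  expect_equal(unname(apply(n1, 2, max)), rep(1, 8))
  expect_equal(normalize_sample(n1), n1)
  s <- enose_sample(m, "a", "meta_train")
  expect_s3_class(normalize_sample(s), "enose_sample")
})

test_that("channel shuffle applies one shared permutation to a batch", {
  set.seed(7)
  batch <- lapply(1:3, function(i)
    enose_sample(matrix(rnorm(20 * 4), 20, 4), "a", "meta_test"))
  idp <- channel_shuffle(batch, permutation = 1:4)
  expect_equal(idp[[2]]$matrix, batch[[2]]$matrix)

  sh <- channel_shuffle(batch)
  p <- attr(sh, "permutation")
  # every sample permuted by the same p; inverse restores the original
  inv <- order(p)
  back <- channel_shuffle(sh, permutation = inv)
  for (i in 1:3) expect_equal(back[[i]]$matrix, batch[[i]]$matrix)
  # fixed seed gives a fixed permutation
  set.seed(99); p1 <- attr(channel_shuffle(batch), "permutation")
  set.seed(99); p2 <- attr(channel_shuffle(batch), "permutation")
  expect_identical(p1, p2)
  expect_error(channel_shuffle(batch, permutation = c(1L, 1L, 2L, 3L)),
               "bijection")
})

test_that("preprocessing is shape-deterministic for both dataset styles", {
  set.seed(13)
  long <- raw_recording(matrix(rnorm(40000 * 8), 40000, 8), 0.01,
                        "gas", "meta_train")
  s1 <- preprocess_recording(long)
  expect_equal(dim(s1$matrix), c(240L, 8L))
  breath <- raw_recording(matrix(rnorm(4000 * 8), 4000, 8), 0.002,
                          "copd", "meta_test")
  s2 <- preprocess_recording(breath)
  expect_equal(dim(s2$matrix), c(240L, 8L))
  expect_true(all(s1$matrix >= 0 & s1$matrix <= 1))
})

test_that("bundle construction validates shapes and labels", {
  s <- function(lab) enose_sample(matrix(0, 5, 2), lab, "meta_test")
  b <- dataset_bundle(list(s("a"), s("b")), role = "meta_test")
  expect_equal(b$classes, c("a", "b"))
  expect_equal(bundle_labels(b), c("a", "b"))
  bad <- enose_sample(matrix(0, 6, 2), "a", "meta_test")
  expect_error(dataset_bundle(list(s("a"), bad)), "shape")
  expect_error(dataset_bundle(list(s("a")), classes = "b"), "vocabulary")
})
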