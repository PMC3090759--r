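test_that("build_feature_space is the ordered union of training polymorphisms", {
  d <- profile_dataset(list(
    sample_profile("A", full_hvr(), "16298C", label = "x"),
    sample_profile("B", full_hvr(), c("16298C", "73G"), label = "y")
  ))
  sp <- build_feature_space(d)
  # ordering follows the concatenated HVR axis: HVR1 before HVR2
  expect_identical(sp$tokens, c("16298C", "73G"))
  expect_identical(length(sp$tokens), 2L)

  # all-rCRS training set: n = 0 with a warning
  d0 <- profile_dataset(list(
    sample_profile("A", full_hvr()), sample_profile("B", full_hvr())
  ))
  expect_warning(sp0 <- build_feature_space(d0), "n = 0")
  expect_identical(length(sp0$tokens), 0L)

  # n equals a text-level count of distinct tokens in the written file
  gen <- generate_dataset(synthetic_config(n_samples = 60, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(gen$dataset, path)
  lines <- readLines(path)[-1]
  toks <- unlist(strsplit(vapply(strsplit(lines, "\t"), `[`, "", 5), " "))
  expect_identical(
    length(build_feature_space(gen$dataset)$tokens),
    length(unique(toks[nzchar(toks)]))
  )
})

test_that("same-site features stay contiguous: substitution, insertion, deletion", {
  d <- profile_dataset(list(
    sample_profile("A", full_hvr(), c("16189-", "16189.1C", "16189T", "16190A"))
  ))
  expect_identical(
    build_feature_space(d)$tokens,
    c("16189T", "16189.1C", "16189-", "16190A")
  )
})

test_that("encode_binary sets exactly the harboured in-space features", {
  d <- tiny_dataset()
  sp <- build_feature_space(d)
  X <- encode_binary(d, sp)
  expect_true(all(X$values %in% c(0, 1)))
  # row sums equal per-sample in-space polymorphism counts (brute recount)
  expect_equal(
    rowSums(X$values),
    vapply(d$samples, function(s) sum(s$polymorphisms %in% sp$tokens), 0)
  )
  # rCRS-identical sample encodes as the all-zero row
  expect_true(all(X$values[4, ] == 0))
  # single-feature check against the token order
  s1 <- profile_dataset(d$samples[1])
  X1 <- encode_binary(s1, sp)
  expect_equal(as.numeric(X1$values), as.numeric(sp$tokens %in% d$samples[[1]]$polymorphisms))

  # out-of-space polymorphisms are ignored with a logged count
  d_extra <- profile_dataset(list(
    sample_profile("Z", full_hvr(), c("16298C", "16300A"), label = "x")
  ))
  sp_small <- build_feature_space(profile_dataset(list(
    sample_profile("A", full_hvr(), "16298C", label = "x")
  )))
  expect_message(Xz <- encode_binary(d_extra, sp_small), "1 out-of-space")
  expect_equal(as.numeric(Xz$values), 1)
})

test_that("encode_rcrs equals encode_binary and zeroes untyped features", {
  d <- tiny_dataset()
  sp <- build_feature_space(d)
  expect_identical(encode_rcrs(d, sp)$values, encode_binary(d, sp)$values)
  # a sample typed only in HVR1 gets 0 for every HVR2 feature
  hvr2_only <- vapply(
    sp$positions, function(p) p >= 1 && p <= 576, TRUE
  )
  X <- encode_rcrs(d, sp)
  expect_true(all(X$values[3, hvr2_only] == 0)) # S3 is HVR1-only
})

test_that("position_rates implements the typed-denominator convention", {
  d <- profile_dataset(list(
    sample_profile("A", rs(16024, 16365), "16298C", label = "x"),
    sample_profile("B", rs(16024, 16365), "16298T", label = "x"),
    sample_profile("C", rs(16024, 16365), character(0), label = "x"),
    sample_profile("D", rs(16024, 16365), "16311C", label = "x")
  ))
  rates <- position_rates(d)
  expect_equal(rates$rate[rates$position == 16298], 0.5) # 2 of 4 typed
  expect_equal(rates$rate[rates$position == 16311], 0.25)
  expect_equal(rates$rate[rates$position == 100], 0) # typed in no sample

  # brute-force per-position tally on a synthetic mixed-coverage dataset
  gen <- generate_dataset(
    synthetic_config(n_samples = 50, seed = 9, coverage_model = "published_like")
  )
  rates2 <- position_rates(gen$dataset)
  brute <- vapply(rates2$position, function(p) {
    typed <- vapply(gen$dataset$samples, function(s) {
      any(s$typed$start <= p & s$typed$end >= p)
    }, TRUE)
    if (!any(typed)) {
      return(0)
    }
    poly <- vapply(gen$dataset$samples, function(s) {
      length(s$polymorphisms) > 0 &&
        p %in% parse_polymorphisms(s$polymorphisms)$position
    }, TRUE)
    sum(poly & typed) / sum(typed)
  }, 0)
  expect_equal(rates2$rate, brute)
})

test_that("encode_probability adds the 1122 positional variables", {
  d <- profile_dataset(list(
    sample_profile("A", full_hvr(), c("16298C", "73G"), label = "x"),
    sample_profile("B", rs(16024, 16365), "16298C", label = "y"),
    sample_profile("C", full_hvr(), character(0), label = "x"),
    sample_profile("D", full_hvr(), "73G", label = "y")
  ))
  sp <- build_feature_space(d)
  rates <- position_rates(d)
  X <- encode_probability(d, sp, rates)
  n <- length(sp$tokens)
  expect_identical(ncol(X$values), n + 1122L)
  expect_true(all(X$values >= 0 & X$values <= 1))

  axis <- hvr_axis()
  # fully typed rows carry only 0/1 in the positional block
  expect_true(all(X$values[1, ] %in% c(0, 1)))
  # typed and polymorphic -> 1; typed and reference -> 0
  expect_equal(X$values[1, n + which(axis == 16298)], 1)
  expect_equal(X$values[1, n + which(axis == 16300)], 0)
  # untyped positions hold the training rate (B is HVR1-only; 73 is HVR2)
  rate73 <- rates$rate[rates$position == 73]
  expect_equal(rate73, 2 / 3) # 2 of the 3 samples typed at 73 harbour 73G
  expect_equal(X$values[2, n + which(axis == 73)], rate73)
  # B's binary indicator for the untyped feature 73G is 0
  expect_equal(X$values[2, which(sp$tokens == "73G")], 0)
  # complete coverage reduces to encode_binary plus a deterministic 0/1 block
  full_rows <- c(1, 3, 4)
  Xb <- encode_binary(d, sp)
  expect_identical(X$values[full_rows, seq_len(n)], Xb$values[full_rows, ])
  expect_true(all(X$values[full_rows, ] %in% c(0, 1)))
})

test_that("restrict_to_common_region keeps only features inside the test region", {
  gen <- generate_dataset(separable_config(80))
  train <- gen$dataset

  # a test profile typed over the full training region reproduces the
  # plain pipeline exactly
  test_full <- sample_profile("T1", full_hvr(), character(0))
  r <- restrict_to_common_region(test_full, train)
  sp <- build_feature_space(train)
  expect_identical(r$space$tokens, sp$tokens)
  expect_identical(r$train$values, encode_binary(train, sp)$values)

  # HVR1-only test region excludes every HVR2 feature
  test_h1 <- sample_profile("T2", rs(16024, 16365))
  r1 <- restrict_to_common_region(test_h1, train)
  expect_true(all(r1$space$positions >= 16024))
  expect_true(length(r1$space$tokens) < length(sp$tokens) ||
    all(sp$positions >= 16024 & sp$positions <= 16365))

  # restricted n is monotone under nested test regions
  ends <- c(16365, 16250, 16150, 16100)
  ns <- vapply(ends, function(e) {
    t <- sample_profile("T", rs(16024, e))
    res <- tryCatch(restrict_to_common_region(t, train), error = function(e) NULL)
    if (is.null(res)) 0L else length(res$space$tokens)
  }, 0L)
  expect_true(all(diff(ns) <= 0))

  # no overlap at all advises a fallback strategy
  hvr1_train <- profile_dataset(list(
    sample_profile("A", full_hvr(), c("16298C", "16311C"), label = "x"),
    sample_profile("B", full_hvr(), "16223T", label = "y")
  ))
  narrow <- sample_profile("T3", rs(400, 500))
  expect_error(restrict_to_common_region(narrow, hvr1_train), "strategy")
})

test_that("all encodings agree in the no-missing-data limit", {
  gen <- generate_dataset(separable_config(40, seed = 21))
  d <- gen$dataset
  sp <- build_feature_space(d)
  plain <- encode_binary(d, sp)$values
  expect_identical(encode_rcrs(d, sp)$values, plain)
  r <- restrict_to_common_region(d$samples[[1]], d)
  expect_identical(r$train$values, plain)
  prob <- encode_probability(d, sp, position_rates(d))$values
  expect_identical(prob[, seq_len(ncol(plain))], plain)
  expect_true(all(prob %in% c(0, 1)))
})
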