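test_that("read-share index matches direct ratios in both modes", {
  idx <- compute_reads_index(fixture_counts())
  expect_equal(idx$proportion, c(0.1, 0.2, 0.7))
  expect_equal(compute_reads_index(count_table(letters[1:4], rep(5, 4)))$proportion,
               rep(0.25, 4))
  ctf <- count_table(letters[1:3], c(100, 100, 100),
                     feature_count = c(50, 50, 100))
  expect_equal(compute_reads_index(ctf, mode = "features")$proportion,
               c(0.25, 0.25, 0.5))
  expect_error(compute_reads_index(count_table(letters[1:2], c(0, 0))),
               "degenerate")
  expect_error(compute_reads_index(fixture_counts(), mode = "features"),
               "feature_count")
})

test_that("index proportions sum to one across random tables", {
  set.seed(11)
  for (k in 1:25) {
    ct <- random_count_table(sample(3:50, 1), with_features = TRUE)
    expect_equal(sum(compute_reads_index(ct)$proportion), 1, tolerance = 1e-9)
    if (sum(ct$feature_count) > 0) {
      expect_equal(sum(compute_reads_index(ct, "features")$proportion), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("volume computation reproduces the worked examples", {
  # uniform index: everyone gets the full fill, no flags
  vu <- compute_volumes(index_from_p(rep(1 / 3, 3)))
  expect_equal(vu$volume_nl, rep(1000, 3))
  expect_true(all(vu$flags == ""))

  # 1/p scaling anchored at v_max, quantized half-up to 2.5 nL
  v <- compute_volumes(index_from_p(c(0.1, 0.2, 0.7)))
  expect_equal(v$volume_nl, c(1000, 500, 142.5))
  expect_equal(v$raw_volume_nl, c(1000, 500, 1000 / 7), tolerance = 1e-12)

  # extreme skew clamps at the floor
  v2 <- compute_volumes(index_from_p(c(0.001, 0.999)))
  expect_equal(v2$volume_nl, c(1000, 10))
  expect_identical(has_flag(v2, "clamped_low"), c(FALSE, TRUE))
})

test_that("volumes are monotone in the index and quantized within bounds", {
  set.seed(23)
  cfg <- normalization_config()
  for (k in 1:20) {
    n <- sample(3:30, 1)
    p <- stats::rgamma(n, 1) + 1e-6
    p <- p / sum(p)
    v <- compute_volumes(index_from_p(p), config = cfg)
    # smaller share -> at least as much volume (weak after clamp/quantize)
    ord <- order(p)
    expect_true(all(diff(v$volume_nl[ord]) <= 1e-9))
    # strict monotonicity before clamping/quantization
    expect_true(all(diff(v$raw_volume_nl[order(p, decreasing = TRUE)]) >= 0))
    expect_true(all(v$volume_nl >= cfg$v_min_nl - 1e-9))
    expect_true(all(v$volume_nl <= cfg$v_max_nl + 1e-9))
    q <- v$volume_nl / cfg$quantum_nl
    expect_equal(q, round(q), tolerance = 1e-9)
  }
})

test_that("blank and zero-count policies assign flagged fixed volumes", {
  idx <- index_from_p(c(0.5, 0.45, 0.05, 0),
                      role = c("sample", "sample", "blank", "sample"))
  v <- compute_volumes(idx)
  expect_equal(v$volume_nl[3], 10) # blank pinned to v_min
  expect_true(has_flag(v, "blank_fixed")[3])
  expect_equal(v$volume_nl[4], 1000) # zero count gets v_max, flagged
  expect_true(has_flag(v, "zero_count")[4])

  vex <- compute_volumes(idx, config = normalization_config(
    zero_count_policy = "exclude_flagged"))
  expect_equal(vex$volume_nl[4], 0)
  expect_true(has_flag(vex, "excluded")[4])

  vas <- compute_volumes(idx, config = normalization_config(
    blank_policy = "as_sample"))
  # as_sample: the blank is boosted like a sample and clamps high
  expect_true(vas$volume_nl[3] == 1000 || has_flag(vas, "clamped_high")[3])
})

test_that("feature mode equals reads mode when all reads are on target", {
  set.seed(31)
  reads <- sample.int(1e5, 12)
  ct <- count_table(sprintf("L%02d", 1:12), reads, feature_count = reads)
  vr <- compute_volumes(compute_reads_index(ct, "reads"))
  vf <- compute_volumes(compute_reads_index(ct, "features"))
  expect_equal(vf$volume_nl, vr$volume_nl)
})

test_that("projection matches the frozen examples and conserves mass", {
  idx <- index_from_p(c(0.1, 0.2, 0.7))
  v <- compute_volumes(idx)
  pr <- project_proportions(v, idx)
  expect_equal(pr$projected_proportion,
               c(100, 100, 99.75) / 299.75, tolerance = 1e-9)
  expect_equal(sum(pr$projected_proportion), 1, tolerance = 1e-9)

  idx2 <- index_from_p(c(0.001, 0.999))
  pr2 <- project_proportions(compute_volumes(idx2), idx2)
  expect_equal(pr2$projected_proportion, c(1, 9.99) / 10.99, tolerance = 1e-9)

  # perfectly even input is a fixed point
  idx3 <- index_from_p(rep(0.25, 4))
  pr3 <- project_proportions(compute_volumes(idx3), idx3)
  expect_equal(pr3$projected_proportion, rep(0.25, 4), tolerance = 1e-12)
})

test_that("projection agrees with brute-force mass bookkeeping on small instances", {
  set.seed(47)
  for (k in 1:30) {
    n <- sample(2:6, 1)
    p <- stats::rgamma(n, 1) + 1e-4
    p <- p / sum(p)
    prior <- stats::runif(n, 50, 500)
    idx <- index_from_p(p)
    v <- compute_volumes(idx, prior_volumes = prior)
    pr <- project_proportions(v, idx, prior_volumes = prior)
    expect_equal(pr$projected_proportion,
                 brute_force_projection(v$volume_nl, p, prior),
                 tolerance = 1e-12)
  }
})

test_that("an index within the dispenser's dynamic range is equalized exactly", {
  set.seed(53)
  for (k in 1:10) {
    n <- sample(3:20, 1)
    # shares within ~30-fold of each other: no clamping at 100x range
    p <- stats::runif(n, 1, 30)
    p <- p / sum(p)
    idx <- index_from_p(p)
    v <- compute_volumes(idx)
    expect_false(any(has_flag(v, "clamped_low") | has_flag(v, "clamped_high")))
    # ignoring quantization, projected shares are exactly equal
    w <- v$raw_volume_nl * p
    expect_equal(w / sum(w), rep(1 / n, n), tolerance = 1e-9)
    # with 2.5 nL quantization they are equal to within the droplet-rounding
    # bound: half a quantum relative to the smallest transfer, spread over n
    pr <- project_proportions(v, idx)
    bound <- 3 * (2.5 / 2) / min(v$volume_nl) / n
    expect_lt(max(abs(pr$projected_proportion - 1 / n)), bound)
  }
})

test_that("projected counts scale proportions by depth and on-target fraction", {
  pr <- structure(data.frame(sample_id = c("a", "b"), role = "sample",
                             projected_proportion = c(0.5, 0.5)),
                  class = c("projection", "data.frame"))
  pc <- project_counts(pr, depth = 1000)
  expect_equal(pc$projected_reads, c(500, 500))
  pc2 <- project_counts(pr, depth = 1000, on_target_fraction = c(0.2, 0.8))
  expect_equal(pc2$projected_on_target, c(100, 400))
  expect_error(project_counts(pr, 1000, on_target_fraction = c(1.2, 0.1)),
               "\\[0, 1\\]")

  # 384-way even split of a 5.7M-pair run lands near 14.8k pairs/library
  prN <- structure(data.frame(sample_id = sprintf("L%03d", 1:384),
                              role = "sample",
                              projected_proportion = rep(1 / 384, 384)),
                   class = c("projection", "data.frame"))
  expect_equal(project_counts(prN, 5.7e6)$projected_reads[1], 5.7e6 / 384,
               tolerance = 1e-9)
})
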