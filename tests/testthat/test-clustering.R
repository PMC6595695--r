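test_that("bout splitting groups maximal straight runs", {
  expect_identical(split_into_bouts(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)),
                   c(1L, 1L, NA, NA, 2L, 2L))
  expect_identical(split_into_bouts(rep(FALSE, 4)), rep(1L, 4))
  expect_identical(split_into_bouts(logical(0)), integer(0))
  sched <- generate_schedule(seed = 2)
  expect_identical(max(split_into_bouts(sched$phase == "turning"), na.rm = TRUE), 4L)
})

test_that("bout normalization divides by the bout mean", {
  expect_equal(normalize_bout(c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(normalize_bout(rep(7, 5)), rep(1, 5))
  for (seed in 1:20) {
    set.seed(seed)
    v <- runif(sample(3:30, 1), 0.5, 2)
    expect_equal(mean(normalize_bout(v)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_bout(c(-1, 1)), "zero bout mean")
})

test_that("crop labels use round-half-up counts", {
  lab <- crop_labels(20, 25)
  expect_identical(lab, c(rep("non_constant", 5), rep("constant", 10),
                          rep("non_constant", 5)))
  # 5% of 9 strides rounds to zero cropped strides
  expect_identical(crop_labels(9, 5), rep("constant", 9))
  lab10 <- crop_labels(10, 10)
  expect_identical(which(lab10 == "non_constant"), c(1L, 10L))
  # 25% of 3 strides rounds half-up to one stride per end
  expect_identical(crop_labels(3, 25),
                   c("non_constant", "constant", "non_constant"))
  expect_identical(crop_labels(2, 25), rep("non_constant", 2))  # 2k >= n
  expect_warning(crop_labels(10, 33), "grid")
  expect_error(crop_labels(0, 10), "empty")
})

test_that("median thresholds are 5% around the bout median", {
  r <- threshold_labels(c(1.0, 1.02, 0.90), "median")
  expect_identical(r$labels, c("constant", "constant", "non_constant"))
  expect_equal(c(r$lower, r$upper), c(0.95, 1.05))
})

test_that("distr thresholds are mean +- sd of mean-normalized values", {
  v <- c(0.8, 1.0, 1.0, 1.0, 1.2)
  r <- threshold_labels(v, "distr")
  x <- v / mean(v)
  expect_equal(r$lower, mean(x) - sd(x))
  expect_equal(r$upper, mean(x) + sd(x))
  expect_identical(r$labels,
                   c("non_constant", "constant", "constant", "constant",
                     "non_constant"))
})

test_that("kmeans3 thresholds are the extreme cluster centers", {
  v <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  r <- threshold_labels(v, "kmeans3", seed = 1)
  m <- mean(v)
  expect_equal(r$lower, 1 / m, tolerance = 1e-12)
  expect_equal(r$upper, 3 / m, tolerance = 1e-12)
  # strict inequality: only the middle point-mass is constant
  expect_identical(r$labels, rep(c("non_constant", "constant", "non_constant"),
                                 each = 3))
  expect_identical(threshold_labels(v, "kmeans3", seed = 7)$labels, r$labels)
  expect_error(threshold_labels(c(1, 1, 2), "kmeans3"), "distinct")
})

test_that("percentile thresholds use linear-interpolation quartiles", {
  v <- 1:8
  r <- threshold_labels(v, "percentile")
  expect_equal(r$lower * mean(v), 2.75)
  expect_equal(r$upper * mean(v), 6.25)
  expect_identical(which(r$labels == "constant"), 3:6)
})

test_that("median and percentile thresholds match a sorting oracle exactly", {
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(4:40, 1)
    v <- runif(n, 0.5, 2)
    s <- sort(v)
    # percentile oracle: linear interpolation between order statistics
    pctl <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
    }
    r <- threshold_labels(v, "percentile")
    expect_equal(r$lower, pctl(0.25) / mean(v), tolerance = 1e-12)
    expect_equal(r$upper, pctl(0.75) / mean(v), tolerance = 1e-12)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    rm_ <- threshold_labels(v, "median")
    expect_identical(rm_$labels,
                     ifelse(v / med > 0.95 & v / med < 1.05,
                            "constant", "non_constant"))
  }
})

test_that("kmeans3 recovers well-separated tri-modal centers", {
  for (seed in 1:10) {
    set.seed(seed)
    v <- c(rnorm(10, 1, 0.005), rnorm(10, 2, 0.005), rnorm(10, 3, 0.005))
    centers <- sort(gaitphase:::kmeans3_1d(v, seed = seed))
    expect_lt(max(abs(centers - c(1, 2, 3)) / c(1, 2, 3)), 0.01)
  }
})

test_that("the ordering post-processor applies the 25% band rule", {
  raw <- rep("constant", 12)
  raw[c(1, 3, 10, 12)] <- "non_constant"
  out <- postprocess_labels(raw)
  expect_identical(out, c(rep("acceleration", 3), rep("constant", 6),
                          rep("deceleration", 3)))
  expect_identical(postprocess_labels(rep("constant", 12)), rep("constant", 12))
  mid <- rep("constant", 12); mid[6] <- "non_constant"
  expect_identical(postprocess_labels(mid), rep("constant", 12))
})

test_that("post-processed labels always match acceleration* constant* deceleration*", {
  for (seed in 1:1000) {
    set.seed(seed)
    n <- sample(2:30, 1)   # a 1-stride bout is its own head and tail band
    raw <- sample(c("constant", "non_constant"), n, replace = TRUE)
    out <- postprocess_labels(raw)
    expect_match(paste(substr(out, 1, 1), collapse = ""), "^a*c*d*$")
    band <- ceiling(0.25 * n)
    nc <- which(out != "constant")
    expect_true(all(nc <= band | nc > n - band))
    # reversing the bout swaps acceleration and deceleration
    rev_out <- postprocess_labels(rev(raw))
    swapped <- rev(out)
    swapped[swapped == "acceleration"] <- "tmp"
    swapped[swapped == "deceleration"] <- "acceleration"
    swapped[swapped == "tmp"] <- "deceleration"
    expect_identical(rev_out, swapped)
  }
})

test_that("cluster_bout dispatches all named methods", {
  expect_setequal(clustering_methods(),
                  c("5%crop", "10%crop", "15%crop", "20%crop", "25%crop",
                    "median vel", "median t", "distr vel", "distr t",
                    "3means vel", "3means t", "perc vel", "perc t"))
  v <- runif(20, 1, 1.5); tm <- runif(20, 0.8, 1.2)
  raw <- cluster_bout(v, tm, "25%crop", raw = TRUE)
  expect_identical(sum(raw == "non_constant"), 10L)
  out <- cluster_bout(v, tm, "25%crop")
  expect_identical(out, c(rep("acceleration", 5), rep("constant", 10),
                          rep("deceleration", 5)))
  expect_error(cluster_bout(v, tm, "4means vel"), "unknown method")
  expect_error(cluster_bout(v, tm, "crop"), "unknown method")
  expect_identical(cluster_bout(v, tm, "3means vel", seed = 3),
                   cluster_bout(v, tm, "3means vel", seed = 3))
})

test_that("distr vel marks ramp strides of a bout-shaped velocity profile", {
  # velocity ramps up, holds, ramps down (the shape of a 10 m bout)
  v <- c(0.7, 0.95, 1.2, rep(1.4, 6), 1.2, 0.95, 0.7)
  out <- cluster_bout(v, rep(1, length(v)), "distr vel")
  x <- v / mean(v)
  raw_expect <- ifelse(x > mean(x) - sd(x) & x < mean(x) + sd(x),
                       "constant", "non_constant")
  expect_identical(cluster_bout(v, rep(1, length(v)), "distr vel", raw = TRUE),
                   raw_expect)
  # the slowest ramp strides sit outside mean +- sd, so the bout opens with
  # acceleration and closes with deceleration around a constant core
  expect_identical(out[1], "acceleration")
  expect_identical(out[12], "deceleration")
  expect_identical(out[4:9], rep("constant", 6))
  expect_identical(out, postprocess_labels(raw_expect))
})
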