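# Pearson scoring, the strict validity rule, per-ROI top-n summaries,
# repeat averaging and the two-model scatter categorization.

test_that("pearson matches the covariance formula and flags undefined cases", {
  v <- c(1, 2, 3, 4); vh <- c(1, 2, 3, 5)
  num <- sum((v - mean(v)) * (vh - mean(vh)))
  den <- sqrt(sum((v - mean(v))^2) * sum((vh - mean(vh))^2))
  expect_equal(pearson(v, vh), num / den, tolerance = 1e-12)
  expect_equal(pearson(v, v), 1)
  expect_equal(pearson(v, -v), -1)
  expect_true(is.na(pearson(v, rep(2, 4))))
  expect_error(pearson(v, c(1, 2)), "length mismatch")
  # scale invariance: pearson(a v + c, vh) = sign(a) pearson(v, vh)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10); a <- runif(1, -3, 3)
    if (a == 0) next
    expect_equal(pearson(a * x + 2, y), sign(a) * pearson(x, y),
                 tolerance = 1e-10)
  }
})

test_that("the valid-voxel rule is strict at the threshold", {
  vm <- valid_mask(c(0.40, 0.41, 0.42))
  expect_equal(vm$valid, c(FALSE, FALSE, TRUE))
  expect_equal(vm$n_valid, 1L)
  expect_equal(valid_mask(rep(NA_real_, 5))$n_valid, 0L)
  set.seed(2)
  pcc <- runif(500, -1, 1)
  pcc[sample(500, 20)] <- NA
  vm2 <- valid_mask(pcc, 0.2)
  brute <- 0L
  for (p in pcc) if (!is.na(p) && p > 0.2) brute <- brute + 1L
  expect_equal(vm2$n_valid, brute)
})

test_that("roi_top_n_mean matches sort-and-slice and is monotone", {
  r <- make_result(c(0.1, 0.2, 0.3), roi = "V1")
  expect_equal(roi_top_n_mean(r, "V1", n = 2), 0.25)
  # constant region returns the constant for any n
  rc <- make_result(rep(0.5, 7), roi = "FFA")
  for (n in c(1, 3, 100)) expect_equal(roi_top_n_mean(rc, "FFA", n = n), 0.5)
  expect_error(roi_top_n_mean(r, "LGN"), "unknown ROI")
  set.seed(3)
  pcc <- rnorm(1000, 0.2, 0.3)
  rr <- make_result(pcc, roi = "VC_sim")
  expect_equal(roi_top_n_mean(rr, "VC_sim", n = 100),
               oracle_top_n_mean(pcc, 100), tolerance = 1e-12)
  # adding a voxel above the current n-th largest cannot decrease the mean
  base <- roi_top_n_mean(rr, "VC_sim", n = 100)
  rr2 <- make_result(c(pcc, 0.99), roi = "VC_sim")
  expect_gte(roi_top_n_mean(rr2, "VC_sim", n = 100), base)
})

test_that("derived ROI groups aggregate the base regions", {
  regions <- list(V1 = c("a", "b"), V2 = "c", V3 = "d", V4 = "e",
                  LOC = "f", FFA = "g", PPA = c("h", "i"))
  rm <- roi_map(regions)
  grp <- attr(rm, "groups")
  expect_setequal(grp$LVC, c("a", "b", "c", "d"))
  expect_setequal(grp$HVC, c("f", "g", "h", "i"))
  expect_setequal(grp$VC, letters[1:9])
  expect_error(roi_map(list(V1 = "a", V2 = "a")), "more than one")
  expect_error(roi_map(list(LVC = "a")), "derived")
  pcc <- seq(0.1, 0.9, by = 0.1)
  res <- make_result(pcc, ids = letters[1:9],
                     roi = rm$roi[match(letters[1:9], rm$voxel_id)])
  expect_equal(roi_top_n_mean(res, "LVC", rois = rm, n = 2),
               mean(c(0.4, 0.3)))
  summ <- roi_summary(res, rm, n = 2)
  expect_setequal(summ$roi, c(names(regions), "LVC", "HVC", "VC"))
})

test_that("scatter categorization matches a brute-force loop", {
  a <- make_result(c(0.5, 0.5, 0.1, 0.6), model_id = "A")
  b <- make_result(c(0.5, 0.7, 0.2, 0.3), model_id = "B")
  sc <- scatter_compare(a, b)
  expect_equal(sc$category, c("tie", "red", "black", "blue"))
  # equal everywhere: no red, no blue
  s2 <- scatter_compare(a, a)
  expect_equal(unname(attr(s2, "counts")[c("red", "blue")]), c(0L, 0L))
  # one model dominant and valid everywhere: all red
  lo <- make_result(rep(0, 5)); hi <- make_result(rep(0.9, 5))
  expect_true(all(scatter_compare(lo, hi)$category == "red"))
  set.seed(4)
  pa <- runif(1000, -0.2, 0.9); pb <- runif(1000, -0.2, 0.9)
  pa[sample(1000, 30)] <- NA; pb[sample(1000, 30)] <- NA
  ra <- make_result(pa); rb <- make_result(pb)
  got <- scatter_compare(ra, rb, threshold = 0.41)$category
  for (i in seq_len(1000)) {
    ca <- if (is.na(pa[i])) -Inf else pa[i]
    cb <- if (is.na(pb[i])) -Inf else pb[i]
    want <- if (max(ca, cb) <= 0.41) "black"
      else if (cb > ca) "red" else if (ca > cb) "blue" else "tie"
    expect_identical(got[i], want)
  }
  expect_error(scatter_compare(ra, make_result(pa[1:5])), "same voxel set")
})

test_that("repeat averaging groups trials per image", {
  resp <- matrix(rep(c(1, 2), each = 35), ncol = 2)
  pm <- rep("img1", 35)
  expect_equal(unname(average_repeats(resp, pm)), matrix(c(1, 2), 1))
  # x and -x average to zero
  x <- rnorm(3)
  r2 <- rbind(x, -x)
  expect_equal(unname(average_repeats(r2, c("a", "a"))),
               matrix(0, 1, 3))
  set.seed(5)
  pm3 <- sample(rep(sprintf("im%02d", 1:8), each = 5))
  r3 <- matrix(rnorm(40 * 4), 40)
  got <- average_repeats(r3, pm3)
  for (im in sprintf("im%02d", 1:8))
    expect_equal(got[im, ], colMeans(r3[pm3 == im, , drop = FALSE]))
  expect_error(average_repeats(r3, pm3, image_ids = c("im01", "im99")),
               "zero trials")
})
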