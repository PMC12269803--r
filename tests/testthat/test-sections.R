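test_that("max projection is the per-pixel maximum over focal planes", {
  p1 <- matrix(c(0, 3, 5, 1), 2, 2)
  p2 <- matrix(2, 2, 2)
  expect_equal(max_project(list(p1, p2)), pmax(p1, p2))
  expect_equal(max_project(list(p1)), p1)
  expect_error(max_project(list(p1, matrix(0, 3, 3))), "differ in shape")

  set.seed(31)
  for (rep in 1:5) {
    planes <- replicate(5, matrix(runif(48), 6, 8), simplify = FALSE)
    mp <- max_project(planes)
    brute <- matrix(0, 6, 8)
    for (i in 1:6) for (j in 1:8) {
      brute[i, j] <- max(vapply(planes, function(p) p[i, j], numeric(1)))
    }
    expect_equal(mp, brute)
  }
})

test_that("gamma plan clamps the anterior and posterior quarters", {
  # uniform means: every ratio is 1, both clamps leave gamma at 1
  stk <- section_stack(lapply(1:8, const_section, value = 0.4), 80)
  plan <- plan_gamma(stk)
  expect_true(all(plan$gamma == 1))
  expect_equal(attr(plan, "dataset_mean"), 0.4)

  # n = 4: one anterior, one posterior; means (2, 1, 0.5, 0.5) with M = 1
  stk2 <- section_stack(list(
    const_section(1, 0.8), const_section(2, 0.4),
    const_section(3, 0.2), const_section(4, 0.2)
  ), 80)
  plan2 <- plan_gamma(stk2)
  expect_equal(plan2$gamma[1], 1.5)        # ratio 2 clamped to the upper limit
  expect_equal(plan2$gamma[4], 0.9)        # ratio 0.5 clamped to the lower bound
  expect_equal(plan2$quarter, c("anterior", "middle", "middle", "posterior"))

  expect_error(plan_gamma(section_stack(lapply(1:3, const_section, value = 1), 80)),
               "at least 4 sections")
  expect_error(plan_gamma(section_stack(lapply(1:4, const_section, value = 0), 80)),
               "degenerate")
})

test_that("gamma transfer is a normalized power law with the right limits", {
  img <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(apply_gamma(img, 1), img)
  expect_equal(apply_gamma(matrix(1, 2, 2), 3), matrix(1, 2, 2))
  expect_equal(apply_gamma(matrix(0.25, 1, 1), 2)[1, 1], 0.0625)
  expect_equal(apply_gamma(matrix(64, 1, 1), 2, intensity_max = 256)[1, 1], 16)
  expect_error(apply_gamma(matrix(-1, 1, 1), 1), "negative")

  set.seed(17)
  for (g in c(0.5, 0.9, 1.3, 2)) {
    x <- matrix(runif(100), 10, 10)
    y <- apply_gamma(x, g)
    expect_true(all(diff(as.vector(y)[order(as.vector(x))]) >= -1e-12))
  }
})

test_that("background subtraction removes flat background, keeps small features", {
  expect_true(all(subtract_background(matrix(0.7, 16, 16), 2) == 0))

  img <- matrix(0, 16, 16)
  img[8, 8] <- 0.9
  out <- subtract_background(img, 2)
  expect_gt(out[8, 8], 0.85)              # feature smaller than the ball survives

  # ramp + spots against the independent grey-opening oracle
  set.seed(23)
  ramp <- outer(seq(0, 0.4, length.out = 24), rep(1, 24))
  spots <- matrix(0, 24, 24)
  spots[cbind(sample(5:20, 6), sample(5:20, 6))] <- 0.5
  noisy <- ramp + spots
  out2 <- subtract_background(noisy, 2)
  brush <- EBImage::makeBrush(5, "disc")
  bg_oracle <- brute_opening(noisy, brush)
  interior <- which(!is.na(bg_oracle), arr.ind = TRUE)
  expect_equal(out2[interior], pmax(noisy - bg_oracle, 0)[interior],
               tolerance = 1e-10)
})

test_that("binary threshold segmentation behaves at the extremes and is monotone", {
  set.seed(29)
  img <- matrix(runif(400), 20, 20)
  expect_false(any(segment_axons(img, max(img) + 1)))
  expect_true(all(segment_axons(img, 0) | img <= 0))
  m1 <- segment_axons(img, 0.3)
  m2 <- segment_axons(img, 0.6)
  expect_true(all(m1[m2]))                # mask(t2) subset of mask(t1)
  expect_equal(attr(m1, "threshold_used"), 0.3)
  expect_warning(segment_axons(matrix(0.5, 4, 4), 0.1), "zero dynamic range")
})

test_that("noise-only sections stay below the Gaussian false-positive bound", {
  set.seed(37)
  n <- 128 * 96
  img <- matrix(rnorm(n, mean = 0.3, sd = 0.02), 128, 96)
  thr <- mean(img) + 5 * sd(img)
  fp <- sum(segment_axons(img, thr))
  # exhaustive count vs binomial tail bound at p = P(Z > 5)
  bound <- qbinom(0.999, n, pnorm(-5))
  expect_lte(fp, bound)
})

test_that("a gradient-free dataset passes through the gamma stage untouched", {
  stk <- uniform_mean_stack()
  on <- process_sections(stk, gamma_enabled = TRUE)
  off <- process_sections(stk, gamma_enabled = FALSE)
  expect_true(all(on$provenance$gamma == 1))
  expect_identical(on$masks, off$masks)
})

test_that("gamma correction shrinks the spread of section means on a ramp", {
  atl <- small_atlas(n_leaf = 6, shape = c(24, 32, 24))
  acr <- atl$tree$acronym[match(tree_leaves(atl$tree), atl$tree$id)]
  truth <- ground_truth(prescribe_densities(atl, stats::setNames(rep(0.1, 6), acr)),
                        ap_brightness = c(1, 0.5), seed = 41)
  sim <- simulate_axon_brain(atl, truth, keep_every_other = FALSE)
  prov <- process_sections(sim$stack, atlas = atl)$provenance
  expect_lt(sd(prov$mean_after), sd(prov$mean_before))
  n <- nrow(prov)
  q <- ceiling(n / 4)
  expect_true(all(prov$gamma[1:q] >= 1 & prov$gamma[1:q] <= 1.5))
  expect_true(all(prov$gamma[(n - q + 1):n] >= 0.9 &
                    prov$gamma[(n - q + 1):n] <= 1))
  expect_true(all(prov$gamma[(q + 1):(n - q)] == 1))
})

test_that("per-section threshold overrides and exclusion zones are honoured", {
  stk <- uniform_mean_stack()
  res <- process_sections(stk, overrides = c(`3` = 0.9))
  expect_equal(sum(res$masks[[3]]), 0)     # bright feature is below 0.9
  expect_gt(sum(res$masks[[1]]), 0)
  excl <- process_sections(stk, exclusion = list(row = 5, col = 5,
                                                 radius_px = 20))
  expect_equal(sum(vapply(excl$masks, sum, numeric(1))), 0)
})
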