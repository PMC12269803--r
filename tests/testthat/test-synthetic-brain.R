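test_that("toy atlas tiles bilaterally, deterministically, with live leaves", {
  atl <- build_toy_atlas(4, c(64, 64, 64), seed = 1)
  labs <- atl$annotation[atl$annotation > 0]
  expect_length(unique(labs), 4)                   # 4 leaves, mirrored
  counts <- table(labs, atl$annotation[atl$annotation > 0] > 0)
  # mirror symmetry: label field equals its reflection along the midline
  dims <- dim(atl$annotation)
  expect_identical(atl$annotation, atl$annotation[, , dims[3]:1])
  atl2 <- build_toy_atlas(4, c(64, 64, 64), seed = 1)
  expect_identical(atl$annotation, atl2$annotation)
  expect_error(build_toy_atlas(12, c(4, 4, 4), seed = 1), "too small")
})

test_that("every leaf receives voxels, verified by exhaustive histogram", {
  atl <- build_toy_atlas(12, c(96, 128, 96), seed = 7)
  hist <- table(factor(as.vector(atl$annotation),
                       levels = tree_leaves(atl$tree)))
  expect_true(all(hist > 0))
  expect_length(hist, 12)
})

test_that("an empty prescription yields background only and zero axon pixels", {
  atl <- small_atlas()
  acr <- atl$tree$acronym[match(tree_leaves(atl$tree), atl$tree$id)]
  truth <- ground_truth(prescribe_densities(atl, stats::setNames(rep(0, 4), acr)),
                        seed = 3)
  sim <- simulate_axon_brain(atl, truth, keep_every_other = FALSE)
  expect_false(any(sim$fiber))
  # threshold above the noise ceiling: no pixel survives
  masks <- process_sections(sim$stack, atlas = atl, threshold = 0.2)
  expect_equal(sum(vapply(masks$masks, sum, numeric(1))), 0)
})

test_that("fibers stay inside their prescribed region (exhaustive overlap)", {
  atl <- small_atlas(n_leaf = 4, shape = c(20, 24, 20))
  tr <- atl$tree
  acr <- tr$acronym[match(tree_leaves(tr), tr$id)]
  dens <- stats::setNames(c(1, 0, 0, 0), acr)
  truth <- ground_truth(prescribe_densities(atl, dens, dens), seed = 9)
  sim <- simulate_axon_brain(atl, truth)
  target_id <- tr$id[tr$acronym == acr[1]]
  inside <- sum(sim$fiber & atl$annotation == target_id)
  expect_equal(sum(sim$fiber), inside)             # no fiber voxel elsewhere
  expect_gt(inside, 0)
  vox <- sum(atl$annotation == target_id)
  expect_equal(inside, vox)                        # density 1 fills the region
})

test_that("every-other-section collection halves the series, AP increasing", {
  atl <- build_toy_atlas(4, c(16, 20, 16), seed = 2)  # 16 AP planes
  acr <- atl$tree$acronym[match(tree_leaves(atl$tree), atl$tree$id)]
  truth <- ground_truth(prescribe_densities(atl, stats::setNames(rep(0.05, 4), acr)),
                        seed = 4)
  sim <- simulate_axon_brain(atl, truth, keep_every_other = TRUE)
  ap <- vapply(sim$stack$sections, function(s) s$ap_index, integer(1))
  expect_length(ap, 8)
  expect_true(all(diff(ap) > 0))
  sim_all <- simulate_axon_brain(atl, truth, keep_every_other = FALSE)
  expect_length(sim_all$stack$sections, 16)
})

test_that("achieved fiber fractions track the prescription (>= 500-voxel regions)", {
  atl <- small_atlas(n_leaf = 6, shape = c(24, 32, 24))
  tr <- atl$tree
  acr <- tr$acronym[match(tree_leaves(tr), tr$id)]
  set.seed(11)
  dens <- stats::setNames(runif(6, 0.05, 0.3), acr)
  truth <- ground_truth(prescribe_densities(atl, dens, dens / 2), seed = 12)
  sim <- simulate_axon_brain(atl, truth)
  d <- sim$truth$densities
  vox <- table(factor(as.vector(atl$annotation), levels = tree_leaves(tr)))
  expect_true(all(vox / 2 >= 500))
  expect_true(all(abs(d$achieved / d$density - 1) <= 0.1))
  # recorded by exhaustive counting: achieved equals the fiber/label overlap
  for (r in sample(nrow(d), 4)) {
    id <- d$region_id[r]
    dims <- dim(atl$annotation)
    ml <- slice.index(atl$annotation, 3)
    hemi <- ifelse(ml > (dims[3] + 1) / 2, "ipsi", "contra")
    sel <- atl$annotation == id & hemi == d$hemisphere[r]
    expect_equal(d$achieved[r], sum(sim$fiber & sel) / sum(sel))
  }
})

test_that("simulation is bit-identical for a fixed seed and validates density", {
  atl <- small_atlas()
  acr <- atl$tree$acronym[match(tree_leaves(atl$tree), atl$tree$id)]
  truth <- ground_truth(prescribe_densities(atl, stats::setNames(rep(0.1, 4), acr)),
                        seed = 21)
  s1 <- simulate_axon_brain(atl, truth)
  s2 <- simulate_axon_brain(atl, truth)
  expect_identical(s1$fiber, s2$fiber)
  expect_identical(s1$stack$sections[[3]]$planes, s2$stack$sections[[3]]$planes)
  bad <- truth
  bad$densities$density[1] <- 1.5
  expect_error(simulate_axon_brain(atl, bad), "must not exceed 1|must lie in")
})
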