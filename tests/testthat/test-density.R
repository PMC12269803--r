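make_mask_set <- function(atlas, fill = NULL, predicate = NULL, ap = NULL) {
  dims <- dim(atlas$annotation)
  if (is.null(ap)) ap <- seq_len(dims[1])
  masks <- lapply(ap, function(i) {
    lab <- axonmap:::annotation_plane(atlas, i)
    m <- matrix(FALSE, nrow(lab), ncol(lab))
    if (!is.null(predicate)) m <- predicate(lab, i)
    m
  })
  structure(list(masks = masks, ap_index = as.integer(ap)),
            class = "axon_masks")
}

test_that("overlap counting handles empty and region-filling masks", {
  atl <- small_atlas()
  empty <- make_mask_set(atl)
  tab <- count_overlap(empty, atl)
  expect_true(all(tab$axon_voxels == 0))
  expect_true(all(tab$axon_voxels <= tab$region_voxels))

  id <- tree_leaves(atl$tree)[1]
  full <- make_mask_set(atl, predicate = function(lab, i) lab == id)
  tab2 <- relative_density(count_overlap(full, atl))
  r <- tab2[tab2$region_id == id & tab2$hemisphere == "both", ]
  expect_equal(r$axon_density, 1)
  expect_equal(r$relative_density, 100)
})

test_that("overlap counts match a brute-force per-voxel double loop", {
  atl <- small_atlas(n_leaf = 4, shape = c(8, 10, 9))   # odd midline axis
  set.seed(53)
  for (rep in 1:3) {
    ap <- sort(sample(8, 4))
    masks <- make_mask_set(atl, ap = ap, predicate = function(lab, i) {
      matrix(runif(length(lab)) < 0.3, nrow(lab), ncol(lab))
    })
    tab <- count_overlap(masks, atl)
    oracle <- brute_overlap(masks$masks, ap, atl)
    for (row in seq_len(nrow(tab))) {
      key <- paste(tab$region_id[row], tab$hemisphere[row], sep = "/")
      exp_axon <- if (is.null(oracle[[key]])) 0 else oracle[[key]]["axon"]
      exp_vox <- if (is.null(oracle[[key]])) 0 else oracle[[key]]["vox"]
      expect_equal(tab$axon_voxels[row], unname(exp_axon))
      expect_equal(tab$region_voxels[row], unname(exp_vox))
    }
  }
  bad <- structure(list(masks = list(matrix(FALSE, 10, 9)),
                        ap_index = 99L), class = "axon_masks")
  expect_error(count_overlap(bad, atl), "AP index")
})

test_that("relative densities are conserved and handle the no-signal case", {
  atl <- small_atlas()
  set.seed(59)
  masks <- make_mask_set(atl, predicate = function(lab, i) {
    matrix(runif(length(lab)) < 0.2, nrow(lab), ncol(lab))
  })
  tab <- relative_density(count_overlap(masks, atl))
  leafrows <- tab$hemisphere %in% c("ipsi", "contra")
  expect_equal(sum(tab$relative_density[leafrows]), 100, tolerance = 1e-12)
  # two regions with equal counts split 50/50
  t0 <- count_overlap(make_mask_set(atl), atl)
  t0$axon_voxels[t0$region_id == tree_leaves(atl$tree)[1] &
                   t0$hemisphere == "ipsi"] <- 7
  t0$axon_voxels[t0$region_id == tree_leaves(atl$tree)[2] &
                   t0$hemisphere == "ipsi"] <- 7
  t1 <- relative_density(t0)
  vals <- t1$relative_density[t1$axon_voxels > 0 & t1$hemisphere == "ipsi"]
  expect_equal(vals, c(50, 50))

  expect_message(t2 <- relative_density(count_overlap(make_mask_set(atl), atl)),
                 "no axon signal")
  expect_true(all(is.na(t2$relative_density)))
  expect_true(attr(t2, "no_signal"))
})

test_that("proportional density is a subtree ratio with exact partitioning", {
  atl <- small_atlas()
  tr <- atl$tree
  leaves <- tree_leaves(tr)
  acr <- tr$acronym[match(leaves, tr$id)]
  ctx_leaves <- tree_leaves(tr, "Isocortex")
  tab <- count_overlap(make_mask_set(atl), atl)
  # counts 1 and 3 for the two cortical children
  tab$axon_voxels[tab$region_id == ctx_leaves[1] & tab$hemisphere == "ipsi"] <- 1
  tab$axon_voxels[tab$region_id == ctx_leaves[2] & tab$hemisphere == "ipsi"] <- 3
  tab <- relative_density(tab)
  a1 <- tr$acronym[match(ctx_leaves[1], tr$id)]
  a2 <- tr$acronym[match(ctx_leaves[2], tr$id)]
  expect_equal(proportional_density(tab, a1, "Isocortex")$value, 0.25)
  expect_equal(proportional_density(tab, a2, "Isocortex")$value, 0.75)
  expect_equal(proportional_density(tab, "Isocortex", "Isocortex")$value, 1)
  expect_error(proportional_density(tab, "grey", "Isocortex"), "not within")
  expect_warning(p <- proportional_density(tab, "BS", "grey", hemisphere = "contra"),
                 "zero axon")
  expect_true(is.na(p$value))
})

test_that("proportional densities of partitioning children sum to 1", {
  atl <- small_atlas(n_leaf = 6, shape = c(24, 32, 24))
  tr <- atl$tree
  set.seed(61)
  masks <- make_mask_set(atl, predicate = function(lab, i) {
    matrix(runif(length(lab)) < 0.15, nrow(lab), ncol(lab))
  })
  tab <- relative_density(count_overlap(masks, atl))
  for (h in c("ipsi", "contra", "both")) {
    kids <- tr$acronym[which(tr$parent_structure_id ==
                               axonmap:::resolve_node(tr, "Isocortex"))]
    s <- sum(vapply(kids, function(k) {
      proportional_density(tab, k, "Isocortex", hemisphere = h)$value
    }, numeric(1)))
    expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("network profiles aggregate member subtrees within the scope", {
  atl <- small_atlas(n_leaf = 12, shape = c(32, 48, 32))
  tr <- atl$tree
  nw <- prune_networks(default_networks(), tr)
  mop <- axonmap:::resolve_node(tr, "MOp")
  tab <- count_overlap(make_mask_set(atl), atl)
  tab$axon_voxels[tab$region_id == mop & tab$hemisphere == "ipsi"] <- 50
  tab <- relative_density(tab)
  prof <- network_profile(tab, nw, scope = "Isocortex")
  expect_equal(prof$value[prof$network == "central" & prof$hemisphere == "both"], 1)
  expect_equal(prof$value[prof$network == "medial" & prof$hemisphere == "both"], 0)
  expect_error(network_profile(tab, default_networks()), "absent from tree")

  # equal axon in one member of each network: profile 0.25 each
  tab2 <- count_overlap(make_mask_set(atl), atl)
  pick <- vapply(nw, function(m) m[1], "")
  for (a in pick) {
    tab2$axon_voxels[tab2$region_id == axonmap:::resolve_node(tr, a) &
                       tab2$hemisphere == "ipsi"] <- 10
  }
  prof2 <- network_profile(relative_density(tab2), nw, scope = "Isocortex")
  expect_equal(prof2$value[prof2$hemisphere == "both"], rep(0.25, 4))

  # oracle: brute-force member-wise summation on random counts
  set.seed(67)
  tab3 <- count_overlap(make_mask_set(atl, predicate = function(lab, i) {
    matrix(runif(length(lab)) < 0.1, nrow(lab), ncol(lab))
  }), atl)
  prof3 <- network_profile(relative_density(tab3), nw, scope = "Isocortex")
  ctx <- tree_leaves(tr, "Isocortex")
  den <- sum(tab3$axon_voxels[tab3$region_id %in% ctx])
  for (nm in names(nw)) {
    member_ids <- unlist(lapply(nw[[nm]], function(a) tree_leaves(tr, a)))
    num <- sum(tab3$axon_voxels[tab3$region_id %in% intersect(member_ids, ctx)])
    expect_equal(prof3$value[prof3$network == nm & prof3$hemisphere == "both"],
                 num / den)
  }
})

test_that("hemispheric ratios flag symmetric, dominant and undefined cases", {
  atl <- small_atlas()
  tr <- atl$tree
  leaves <- tree_leaves(tr)
  tab <- count_overlap(make_mask_set(atl), atl)
  tab$axon_voxels[tab$region_id == leaves[1]] <- 12   # both hemispheres
  tab <- relative_density(tab)
  a1 <- tr$acronym[match(leaves[1], tr$id)]
  expect_equal(hemispheric_ratio(tab, a1)$ratio, 1)

  tab2 <- count_overlap(make_mask_set(atl), atl)
  tab2$axon_voxels[tab2$region_id == leaves[1] & tab2$hemisphere == "ipsi"] <- 9
  tab2 <- relative_density(tab2)
  expect_warning(r <- hemispheric_ratio(tab2, a1), "zero")
  expect_identical(r$ratio, Inf)
})

test_that("all ratio metrics are invariant to labeling efficiency", {
  atl <- small_atlas(n_leaf = 6, shape = c(24, 32, 24))
  set.seed(71)
  masks <- make_mask_set(atl, predicate = function(lab, i) {
    matrix(runif(length(lab)) < 0.2, nrow(lab), ncol(lab))
  })
  tab <- count_overlap(masks, atl)
  scaled <- tab
  scaled$axon_voxels <- scaled$axon_voxels * 7    # uniform efficiency change
  class(scaled) <- class(tab)
  attr(scaled, "tree") <- attr(tab, "tree")
  t1 <- relative_density(tab)
  t2 <- relative_density(scaled)
  expect_equal(t1$relative_density, t2$relative_density)
  acr <- atl$tree$acronym[match(tree_leaves(atl$tree)[1], atl$tree$id)]
  expect_equal(proportional_density(t1, acr, "Isocortex")$value,
               proportional_density(t2, acr, "Isocortex")$value)
  expect_equal(hemispheric_ratio(t1, "Isocortex")$ratio,
               hemispheric_ratio(t2, "Isocortex")$ratio)
})
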