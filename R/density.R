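#' Count axon-mask / annotation overlap per region and hemisphere
#'
#' Overlays each section's binary axon mask on the annotation plane it
#' registers to (`ap_index`) and accumulates, for every leaf region and
#' hemisphere, the number of axon-positive pixels and the number of region
#' pixels over the kept sections. Counts are over kept sections only:
#' every-other-section sampling is a property of the data, not corrected
#' for. Mask pixels falling on label 0 (outside the brain) accumulate in an
#' explicit `unassigned` row per hemisphere so that pixel conservation is
#' auditable.
#'
#' @param masks an `axon_masks` object from [process_sections()], or a list
#'   of logical matrices plus an `ap_index` attribute-style list.
#' @param atlas a [toy_atlas()].
#' @return A `density_table`: data frame `(region_id, acronym, hemisphere,
#'   axon_voxels, region_voxels)` with one row per leaf region x
#'   {ipsi, contra} plus two `unassigned` rows; the structure tree is
#'   attached as attribute `tree`.
#' @export
count_overlap <- function(masks, atlas) {
  stopifnot(inherits(atlas, "toy_atlas"))
  if (inherits(masks, "axon_masks")) {
    mask_list <- masks$masks
    ap <- masks$ap_index
  } else {
    mask_list <- masks$masks
    ap <- masks$ap_index
    stopifnot(!is.null(mask_list), !is.null(ap))
  }
  n_ap <- dim(atlas$annotation)[atlas$ap_axis]
  if (any(ap < 1L | ap > n_ap)) {
    stop("AP index not found in atlas: ",
         paste(ap[ap < 1L | ap > n_ap], collapse = ", "))
  }
  hemi <- hemisphere_plane(atlas)
  tree <- atlas$tree
  leaves <- tree_leaves(tree)
  ids <- c(leaves, 0L)                  # 0 = unassigned (outside brain)
  key_levels <- as.vector(outer(ids, c("ipsi", "contra"), paste, sep = "/"))
  axon <- stats::setNames(numeric(length(key_levels)), key_levels)
  vox <- stats::setNames(numeric(length(key_levels)), key_levels)
  for (i in seq_along(mask_list)) {
    lab <- annotation_plane(atlas, ap[i])
    m <- mask_list[[i]]
    if (!identical(dim(lab), dim(m))) {
      stop("mask/annotation shape mismatch at ap_index ", ap[i])
    }
    key <- factor(paste(lab, hemi, sep = "/"), levels = key_levels)
    vox <- vox + table(key)
    axon <- axon + table(key[m])
  }
  parts <- strsplit(key_levels, "/", fixed = TRUE)
  out <- data.frame(
    region_id = as.integer(vapply(parts, `[`, "", 1L)),
    hemisphere = vapply(parts, `[`, "", 2L),
    axon_voxels = as.numeric(axon),
    region_voxels = as.numeric(vox)
  )
  out$acronym <- ifelse(out$region_id == 0L, "unassigned",
                        tree$acronym[match(out$region_id, tree$id)])
  out <- out[, c("region_id", "acronym", "hemisphere", "axon_voxels",
                 "region_voxels")]
  rownames(out) <- NULL
  attr(out, "tree") <- tree
  class(out) <- c("density_table", "data.frame")
  out
}

#' Add density metrics to an overlap-count table
#'
#' Computes axon density (axon pixels / region pixels, a fraction) and
#' relative density (a region's axon pixels as a percentage of all axon
#' pixels detected brain-wide, including the unassigned pool — the metric
#' that cancels labeling efficiency) and appends `both`-hemisphere rows as
#' the sum of ipsi + contra. Regions with zero pixels in the kept sections
#' get `NA` axon density (undefined, not zero). A table with zero total
#' axon gets `NA` relative densities and attribute `no_signal = TRUE`
#' rather than a division error.
#'
#' @param table a `density_table` from [count_overlap()].
#' @return The table with `axon_density` and `relative_density` columns and
#'   `both` rows appended.
#' @export
relative_density <- function(table) {
  stopifnot(inherits(table, "density_table"))
  tree <- attr(table, "tree")
  tab <- as.data.frame(table)
  tab <- tab[tab$hemisphere %in% c("ipsi", "contra"), ]
  total <- sum(tab$axon_voxels)
  both <- stats::aggregate(tab[, c("axon_voxels", "region_voxels")],
                           by = tab[, c("region_id", "acronym"), drop = FALSE],
                           FUN = sum)
  both$hemisphere <- "both"
  out <- rbind(tab, both[, names(tab)])
  out$axon_density <- ifelse(out$region_voxels > 0,
                             out$axon_voxels / out$region_voxels, NA_real_)
  out$axon_density[out$region_id == 0L] <- NA_real_   # no meaningful denominator
  if (total == 0) {
    message("no axon signal detected; relative densities undefined")
    out$relative_density <- NA_real_
    attr(out, "no_signal") <- TRUE
  } else {
    out$relative_density <- 100 * out$axon_voxels / total
    attr(out, "no_signal") <- FALSE
  }
  rownames(out) <- NULL
  attr(out, "tree") <- tree
  attr(out, "total_axon_voxels") <- total
  class(out) <- c("density_table", "data.frame")
  out
}

# rolled-up axon count over a node's descendant leaves for one hemisphere
# ("both" = ipsi + contra); `node` is an id or acronym
rollup_axon <- function(table, tree, node, hemisphere = "both") {
  leaves <- tree_leaves(tree, node)
  rows <- table$region_id %in% leaves &
    table$hemisphere %in% (if (hemisphere == "both") c("ipsi", "contra")
                           else hemisphere)
  sum(table$axon_voxels[rows])
}

#' Proportional density of a region within an enclosing region
#'
#' The relative density of the numerator region (rolled up over its subtree)
#' divided by that of the enclosing denominator region — a comparison of
#' regional axon distribution that is independent of overall labeling
#' efficiency (the whole-brain normalizer cancels, so this reduces to a
#' ratio of axon pixel counts). The numerator must lie in the denominator's
#' subtree.
#'
#' @param table a `density_table` (counts populated).
#' @param numerator,denominator region acronyms (or ids).
#' @param hemisphere `"both"` (default), `"ipsi"` or `"contra"`.
#' @param tree structure tree; defaults to the one attached to `table`.
#' @return Data frame `(numerator, denominator, hemisphere, value)`; `value`
#'   is `NA` with a warning when the denominator carries no axon.
#' @export
proportional_density <- function(table, numerator, denominator,
                                 hemisphere = "both", tree = attr(table, "tree")) {
  stopifnot(inherits(table, "density_table"), !is.null(tree))
  num_id <- resolve_node(tree, numerator)
  den_id <- resolve_node(tree, denominator)
  if (!(num_id %in% descendants(tree, den_id))) {
    stop("numerator '", numerator, "' is not within the subtree of '",
         denominator, "'")
  }
  num <- rollup_axon(table, tree, num_id, hemisphere)
  den <- rollup_axon(table, tree, den_id, hemisphere)
  value <- if (den == 0) {
    warning("denominator '", denominator, "' has zero axon; proportional ",
            "density undefined")
    NA_real_
  } else {
    num / den
  }
  data.frame(numerator = as.character(numerator),
             denominator = as.character(denominator),
             hemisphere = hemisphere, value = value)
}

#' Per-network proportional density profile
#'
#' For each named network, sums the axon pixels of its member leaves (a leaf
#' belongs to a network if its acronym or any ancestor's acronym is in the
#' member list) restricted to the scope subtree, and divides by the scope's
#' axon pixels — i.e. the sum of the members' proportional densities within
#' the scope. Reported for ipsi, contra and combined hemispheres. A member
#' acronym absent from the tree is a configuration error; prune definitions
#' first with [prune_networks()] when using partial ontologies.
#'
#' @param table a `density_table`.
#' @param networks named list of member acronym vectors
#'   ([default_networks()]).
#' @param scope enclosing region acronym (default `"Isocortex"`).
#' @param tree structure tree; defaults to the one attached to `table`.
#' @return Data frame `(network, hemisphere, value)`.
#' @export
network_profile <- function(table, networks = default_networks(),
                            scope = "Isocortex",
                            tree = attr(table, "tree")) {
  stopifnot(inherits(table, "density_table"), !is.null(tree))
  validate_networks(networks)
  scope_leaves <- tree_leaves(tree, scope)
  out <- do.call(rbind, lapply(names(networks), function(nw) {
    member_lv <- intersect(network_leaves(tree, networks[[nw]]), scope_leaves)
    do.call(rbind, lapply(c("ipsi", "contra", "both"), function(h) {
      hemis <- if (h == "both") c("ipsi", "contra") else h
      num <- sum(table$axon_voxels[table$region_id %in% member_lv &
                                     table$hemisphere %in% hemis])
      den <- sum(table$axon_voxels[table$region_id %in% scope_leaves &
                                     table$hemisphere %in% hemis])
      data.frame(network = nw, hemisphere = h,
                 value = if (den == 0) NA_real_ else num / den)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Ipsilateral / contralateral relative-density ratio
#'
#' Ratio of ipsilateral to contralateral relative density for a region
#' subtree or a named network; values above 1 indicate ipsilateral
#' dominance. Since both relative densities share the whole-brain
#' denominator, the ratio reduces to a ratio of axon pixel counts. A zero
#' contralateral count yields an explicit `Inf` (ipsi > 0) or `NaN` (both
#' zero) with a warning, never a silent value.
#'
#' @param table a `density_table`.
#' @param scope region acronym/id, or a network name present in `networks`.
#' @param networks optional named list of network member vectors; consulted
#'   when `scope` matches a network name.
#' @param tree structure tree; defaults to the one attached to `table`.
#' @return Data frame `(scope, axon_ipsi, axon_contra, ratio)`.
#' @export
hemispheric_ratio <- function(table, scope, networks = NULL,
                              tree = attr(table, "tree")) {
  stopifnot(inherits(table, "density_table"), !is.null(tree))
  if (!is.null(networks) && is.character(scope) && scope %in% names(networks)) {
    leaves <- network_leaves(tree, networks[[scope]])
  } else {
    leaves <- tree_leaves(tree, scope)
  }
  count_h <- function(h) {
    sum(table$axon_voxels[table$region_id %in% leaves & table$hemisphere == h])
  }
  ipsi <- count_h("ipsi")
  contra <- count_h("contra")
  ratio <- if (contra == 0) {
    warning("contralateral axon count is zero for scope '", scope,
            "'; ratio ", if (ipsi > 0) "infinite" else "undefined")
    if (ipsi > 0) Inf else NaN
  } else {
    ipsi / contra
  }
  data.frame(scope = as.character(scope), axon_ipsi = ipsi,
             axon_contra = contra, ratio = ratio)
}

#' Expected relative densities implied by a ground truth
#'
#' Converts a prescription of per-region fiber fractions into the relative
#' densities an ideal pipeline would report: prescribed (or achieved)
#' fraction times region voxel count, normalized to 100% over all regions.
#' Used to validate parameter recovery on simulated brains.
#'
#' @param truth a [ground_truth()] (after simulation, so `achieved` is
#'   populated; falls back to prescribed densities otherwise).
#' @param atlas the [toy_atlas()] the brain was simulated from.
#' @param use_achieved use achieved rather than prescribed fractions
#'   (default TRUE when available).
#' @return Data frame `(region_id, acronym, hemisphere, expected_relative)`.
#' @export
expected_relative_density <- function(truth, atlas, use_achieved = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(atlas, "toy_atlas"))
  dens <- truth$densities
  frac <- if (use_achieved && !is.null(dens$achieved)) dens$achieved
          else dens$density
  lab_vec <- as.vector(atlas$annotation)
  ml_idx <- as.vector(slice.index(atlas$annotation, atlas$midline_axis))
  side <- midline_side(dim(atlas$annotation)[atlas$midline_axis], ml_idx)
  side[side == "mid"] <- atlas$injection_side
  hemi_vec <- ifelse(side == atlas$injection_side, "ipsi", "contra")
  nvox <- mapply(function(id, h) sum(lab_vec == id & hemi_vec == h),
                 dens$region_id, dens$hemisphere)
  expected <- frac * nvox
  total <- sum(expected)
  data.frame(region_id = dens$region_id,
             acronym = if (!is.null(dens$acronym)) dens$acronym else NA,
             hemisphere = dens$hemisphere,
             expected_relative = if (total > 0) 100 * expected / total
                                 else NA_real_)
}
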