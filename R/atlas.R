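#' Construct a toy atlas object
#'
#' A toy atlas bundles a 3D integer annotation volume (voxel label ids,
#' 0 = outside brain), its voxel size, the structure tree the labels refer
#' to, and the axis conventions: `ap_axis` (anterior -> posterior, increasing
#' index) and `midline_axis` (the axis split by the midsagittal plane).
#' `injection_side` names the hemisphere carrying the tracer injection, so
#' sides can be reported as ipsi/contra rather than left/right.
#'
#' @param annotation 3D integer array of voxel labels (0 outside the brain).
#' @param voxel_size_um positive scalar, edge length of a voxel in micrometres.
#' @param tree a [structure_tree()]; every nonzero label must be a leaf id.
#' @param ap_axis axis index (1-3) running anterior -> posterior.
#' @param midline_axis axis index (1-3) split by the midline plane.
#' @param injection_side `"right"` or `"left"`; default right.
#' @return A `toy_atlas` object.
#' @export
toy_atlas <- function(annotation, voxel_size_um, tree,
                      ap_axis = 1L, midline_axis = 3L,
                      injection_side = c("right", "left")) {
  stopifnot(is.array(annotation), length(dim(annotation)) == 3L,
            voxel_size_um > 0, inherits(tree, "structure_tree"))
  injection_side <- match.arg(injection_side)
  ap_axis <- as.integer(ap_axis)
  midline_axis <- as.integer(midline_axis)
  stopifnot(ap_axis %in% 1:3, midline_axis %in% 1:3, ap_axis != midline_axis)
  labels <- setdiff(unique(as.vector(annotation)), 0L)
  bad <- setdiff(labels, tree_leaves(tree))
  if (length(bad) > 0L) {
    stop("annotation labels not leaves of the tree: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(annotation = annotation, voxel_size_um = voxel_size_um, tree = tree,
         ap_axis = ap_axis, midline_axis = midline_axis,
         injection_side = injection_side),
    class = "toy_atlas"
  )
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat("toy_atlas:", paste(dim(x$annotation), collapse = " x "),
      "voxels @", x$voxel_size_um, "um;",
      length(setdiff(unique(as.vector(x$annotation)), 0L)), "labels;",
      "injection side:", x$injection_side, "\n")
  invisible(x)
}

# side of a coordinate along the midline axis: "left", "right" or "mid"
# (mid only possible for odd-sized axes; callers resolve mid -> ipsi)
midline_side <- function(n, k) {
  mid <- (n + 1) / 2
  ifelse(k < mid, "left", ifelse(k > mid, "right", "mid"))
}

#' Hemisphere of a voxel relative to the injection side
#'
#' Assigns `ipsi` or `contra` from the voxel's position relative to the
#' midsagittal plane along `midline_axis`, mapped through the atlas's
#' injection side. Voxels exactly on the midline plane (possible only for an
#' odd-sized midline axis) are assigned to `ipsi` — a deterministic,
#' documented tie rule covering negligible volume. Voxels outside the brain
#' (label 0) are a domain error.
#'
#' @param atlas a [toy_atlas()].
#' @param voxel_index integer vector of length 3, or a 3-column matrix of
#'   voxel indices (1-based).
#' @return Character vector of `"ipsi"` / `"contra"`.
#' @export
hemisphere_of <- function(atlas, voxel_index) {
  stopifnot(inherits(atlas, "toy_atlas"))
  idx <- if (is.matrix(voxel_index)) voxel_index else matrix(voxel_index, nrow = 1L)
  stopifnot(ncol(idx) == 3L)
  labs <- atlas$annotation[idx]
  if (any(labs == 0L)) stop("voxel outside the brain (label 0)")
  n <- dim(atlas$annotation)[atlas$midline_axis]
  side <- midline_side(n, idx[, atlas$midline_axis])
  side[side == "mid"] <- atlas$injection_side
  unname(ifelse(side == atlas$injection_side, "ipsi", "contra"))
}

# per-plane hemisphere matrix for a coronal section (dims = the two non-AP
# axes, in their natural order); used by the overlap counter
hemisphere_plane <- function(atlas) {
  dims <- dim(atlas$annotation)
  other <- setdiff(1:3, atlas$ap_axis)
  ml_pos <- match(atlas$midline_axis, other)
  n_ml <- dims[atlas$midline_axis]
  side <- midline_side(n_ml, seq_len(n_ml))
  side[side == "mid"] <- atlas$injection_side
  hemi <- ifelse(side == atlas$injection_side, "ipsi", "contra")
  if (ml_pos == 1L) {
    matrix(hemi, nrow = n_ml, ncol = dims[other[2L]])
  } else {
    matrix(hemi, nrow = dims[other[1L]], ncol = n_ml, byrow = TRUE)
  }
}

# extract the annotation plane at AP index i (dims = non-AP axes in order)
annotation_plane <- function(atlas, i) {
  a <- atlas$annotation
  switch(atlas$ap_axis,
         `1` = a[i, , ],
         `2` = a[, i, ],
         `3` = a[, , i])
}
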