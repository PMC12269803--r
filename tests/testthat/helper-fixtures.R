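# shared fixtures and brute-force oracles

# 3-level toy tree: root -> {P1, P2} -> leaves A..D under P1, E..F under P2
tiny_tree <- function() {
  structure_tree(data.frame(
    id = 1:9,
    acronym = c("root", "P1", "P2", "A", "B", "C", "D", "E", "F"),
    name = paste("node", 1:9),
    parent_structure_id = c(NA, 1, 1, 2, 2, 2, 2, 3, 3)
  ))
}

small_atlas <- function(n_leaf = 4, shape = c(16, 20, 16), seed = 1) {
  build_toy_atlas(n_leaf, shape, seed = seed)
}

# brute-force per-voxel overlap counts (the oracle for count_overlap)
brute_overlap <- function(mask_list, ap, atlas) {
  tree <- atlas$tree
  dims <- dim(atlas$annotation)
  mid <- (dims[atlas$midline_axis] + 1) / 2
  res <- list()
  for (s in seq_along(mask_list)) {
    lab <- axonmap:::annotation_plane(atlas, ap[s])
    m <- mask_list[[s]]
    for (r in seq_len(nrow(lab))) {
      for (cc in seq_len(ncol(lab))) {
        # axis order of a coronal plane: (dv, ml) for ap_axis = 1
        ml <- cc
        h <- if (ml > mid) "ipsi" else if (ml < mid) "contra" else "ipsi"
        key <- paste(lab[r, cc], h, sep = "/")
        if (is.null(res[[key]])) res[[key]] <- c(axon = 0, vox = 0)
        res[[key]]["vox"] <- res[[key]]["vox"] + 1
        if (m[r, cc]) res[[key]]["axon"] <- res[[key]]["axon"] + 1
      }
    }
  }
  res
}

# brute-force greyscale opening with an arbitrary structuring element;
# valid only where the full neighbourhood fits inside the image
brute_opening <- function(img, brush) {
  r <- (nrow(brush) - 1L) / 2
  n <- nrow(img); m <- ncol(img)
  off <- which(brush == 1, arr.ind = TRUE) - (r + 1L)
  ero <- matrix(NA_real_, n, m)
  for (i in (r + 1):(n - r)) {
    for (j in (r + 1):(m - r)) {
      ero[i, j] <- min(img[cbind(i + off[, 1], j + off[, 2])])
    }
  }
  dil <- matrix(NA_real_, n, m)
  for (i in (2 * r + 1):(n - 2 * r)) {
    for (j in (2 * r + 1):(m - 2 * r)) {
      dil[i, j] <- max(ero[cbind(i + off[, 1], j + off[, 2])])
    }
  }
  dil
}

# constant-intensity section (all focal planes equal) for gamma-plan tests
const_section <- function(ap_index, value, dims = c(8, 8), n_planes = 2) {
  list(ap_index = ap_index,
       planes = replicate(n_planes, matrix(value, dims[1], dims[2]),
                          simplify = FALSE),
       nuclear = matrix(0.2, dims[1], dims[2]),
       pixel_size_um = 80)
}

# stack of identical patterned sections: means are exactly uniform
uniform_mean_stack <- function(n_sections = 8, dims = c(12, 12)) {
  base <- matrix(0.25, dims[1], dims[2])
  base[4:6, 4:6] <- 0.8                     # a bright feature to segment
  sections <- lapply(seq_len(n_sections), function(i) {
    list(ap_index = i, planes = list(base, base * 0.9),
         nuclear = matrix(0.2, dims[1], dims[2]), pixel_size_um = 80)
  })
  section_stack(sections, 80)
}

# textbook one-way ANOVA F from explicit sums of squares
brute_anova_F <- function(value, group) {
  group <- as.factor(group)
  gm <- mean(value)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((value - means[group])^2)
  dfb <- nlevels(group) - 1
  dfw <- length(value) - nlevels(group)
  (ssb / dfb) / (ssw / dfw)
}

# pooled two-sample t statistic from the closed form
brute_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# fixed-position trajectory (e.g. arena midpoint or a corner)
fixed_trajectory <- function(x, y, n = 100, fps = 30, arena = 63.5) {
  trajectory(data.frame(t = (seq_len(n) - 1) / fps, x = rep(x, n),
                        y = rep(y, n)), fps = fps, arena_side_cm = arena)
}
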