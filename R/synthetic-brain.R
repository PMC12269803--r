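#' Build a toy bilateral brain atlas with a hierarchical ontology
#'
#' Generates a small annotation volume whose leaf regions tile an ellipsoidal
#' "brain" bilaterally: one hemisphere is partitioned into `n_leaf_regions`
#' roughly equal blocks (equal-count bins along the anterior-posterior and
#' dorso-ventral axes), then mirrored across the midsagittal plane. The
#' accompanying structure tree has a root (`grey`), an isocortex-like parent
#' and a subcortical parent; leaves carry standard cortical acronyms (MOs,
#' MOp, SS, VIS, RSP, AUD, ACA, ...) so that network definitions resolve.
#'
#' Axis convention: axis 1 = anterior -> posterior, axis 2 = dorso-ventral,
#' axis 3 = medio-lateral (midline axis). Deterministic for a fixed seed.
#'
#' @param n_leaf_regions number of leaf regions per hemisphere (>= 4).
#' @param shape integer vector of 3 positive dims (AP, DV, ML).
#' @param seed integer seed (controls the region-to-block assignment).
#' @param voxel_size_um voxel edge length; default 80 so that one 80-um
#'   section spans exactly one annotation plane.
#' @param injection_side hemisphere carrying the tracer injection.
#' @return A [toy_atlas()].
#' @examples
#' atl <- build_toy_atlas(4, c(32, 32, 32), seed = 1)
#' table(atl$annotation[atl$annotation > 0])
#' @export
build_toy_atlas <- function(n_leaf_regions, shape, seed,
                            voxel_size_um = 80,
                            injection_side = c("right", "left")) {
  injection_side <- match.arg(injection_side)
  n_leaf_regions <- as.integer(n_leaf_regions)
  shape <- as.integer(shape)
  stopifnot(n_leaf_regions >= 4L, length(shape) == 3L, all(shape > 0L))

  centre <- (shape + 1) / 2
  semi <- 0.48 * shape
  i <- slice.index(array(0L, shape), 1L)
  j <- slice.index(array(0L, shape), 2L)
  k <- slice.index(array(0L, shape), 3L)
  in_brain <- ((i - centre[1]) / semi[1])^2 + ((j - centre[2]) / semi[2])^2 +
    ((k - centre[3]) / semi[3])^2 <= 1

  half <- floor(shape[3] / 2)
  left <- which(in_brain & (k <= half))
  g1 <- ceiling(sqrt(n_leaf_regions))
  g2 <- ceiling(n_leaf_regions / g1)
  if (length(left) < 4L * g1 * g2) {
    stop("shape ", paste(shape, collapse = "x"), " too small for ",
         n_leaf_regions, " bilateral leaf regions")
  }
  # equal-count bins: AP first, then DV within each AP bin
  li <- i[left]
  lj <- j[left]
  bin_i <- ceiling(g1 * rank(li, ties.method = "first") / length(li))
  bin_j <- integer(length(left))
  for (b in seq_len(g1)) {
    sel <- bin_i == b
    bin_j[sel] <- ceiling(g2 * rank(lj[sel], ties.method = "first") / sum(sel))
  }
  cell <- (bin_i - 1L) * g2 + bin_j
  region_of_cell <- with_seed(seed, {
    ((sample.int(g1 * g2) - 1L) %% n_leaf_regions) + 1L
  })
  region <- region_of_cell[cell]

  annotation <- array(0L, shape)
  leaf_ids <- 1000L + seq_len(n_leaf_regions)
  annotation[left] <- leaf_ids[region]
  for (kk in seq_len(half)) {               # mirror across the midline plane
    annotation[, , shape[3] + 1L - kk] <- annotation[, , kk]
  }

  tree <- toy_ontology(n_leaf_regions, leaf_ids)
  counts <- table(annotation[annotation > 0L])
  if (length(counts) < n_leaf_regions) {
    stop("shape too small: some regions received no voxels")
  }
  toy_atlas(annotation, voxel_size_um, tree,
            ap_axis = 1L, midline_axis = 3L, injection_side = injection_side)
}

# ontology for the toy atlas: root 'grey' -> {Isocortex, BS} -> leaves.
# Cortical acronym pool is ordered so small atlases still cover all four
# cortical networks.
toy_ontology <- function(n_leaf, leaf_ids) {
  cortical_pool <- c("MOs", "MOp", "SS", "VIS", "RSP", "AUD", "ACA", "TEa",
                     "PL", "ILA", "ORB", "FRP", "AId", "AIv", "AIp", "GU",
                     "VISC", "PERI", "ECT", "ENT", "PTLp")
  subcort_pool <- c("TH", "CP", "HY", "SC", "MB", "P", "MY", "PAL", "HPF",
                    "BLA")
  n_ctx <- min(ceiling(2 * n_leaf / 3), n_leaf - 1L)
  n_sub <- n_leaf - n_ctx
  acr_ctx <- c(cortical_pool, paste0("CTX", seq_len(n_leaf)))[seq_len(n_ctx)]
  acr_sub <- c(subcort_pool, paste0("SUB", seq_len(n_leaf)))[seq_len(n_sub)]
  nodes <- data.frame(
    id = c(997L, 315L, 343L, leaf_ids),
    acronym = c("grey", "Isocortex", "BS", acr_ctx, acr_sub),
    name = c("grey matter", "isocortex", "brain stem",
             paste("region", c(acr_ctx, acr_sub))),
    parent_structure_id = c(NA_integer_, 997L, 997L,
                            rep(315L, n_ctx), rep(343L, n_sub))
  )
  structure_tree(nodes)
}

#' Prescribe per-region, per-hemisphere axon densities
#'
#' Convenience constructor for the density prescription consumed by
#' [simulate_axon_brain()]: named numeric vectors by leaf acronym, one per
#' hemisphere; leaves not named get density 0.
#'
#' @param atlas a [toy_atlas()].
#' @param ipsi named numeric vector (acronym -> density in \[0, 1\]).
#' @param contra named numeric vector; defaults to `ipsi` (symmetric brain).
#' @return Data frame with columns `region_id`, `acronym`, `hemisphere`,
#'   `density`.
#' @export
prescribe_densities <- function(atlas, ipsi, contra = ipsi) {
  stopifnot(inherits(atlas, "toy_atlas"))
  tree <- atlas$tree
  leaves <- tree_leaves(tree)
  acr <- tree$acronym[match(leaves, tree$id)]
  fill <- function(v) {
    unknown <- setdiff(names(v), acr)
    if (length(unknown) > 0L) {
      stop("unknown leaf acronym: ", paste(unknown, collapse = ", "))
    }
    out <- stats::setNames(numeric(length(acr)), acr)
    out[names(v)] <- v
    out
  }
  ip <- fill(ipsi)
  co <- fill(contra)
  out <- data.frame(
    region_id = rep(leaves, 2L),
    acronym = rep(acr, 2L),
    hemisphere = rep(c("ipsi", "contra"), each = length(leaves)),
    density = c(ip, co),
    row.names = NULL
  )
  if (any(out$density < 0 | out$density > 1)) {
    stop("prescribed densities must lie in [0, 1]")
  }
  out
}

#' Ground truth for a simulated axon-labeled brain
#'
#' Bundles the prescribed per-region densities, the anterior -> posterior
#' brightness profile endpoints (a linear ramp, anterior bright -> posterior
#' dim, emulating the acquisition gradient the gamma stage must remove), and
#' the dataset seed. [simulate_axon_brain()] fills in the achieved fiber
#' fractions and the realized per-section brightness factors, so ground truth
#' is always serialized alongside the data it describes.
#'
#' @param densities data frame from [prescribe_densities()] (columns
#'   `region_id`, `hemisphere`, `density`, optionally `acronym`).
#' @param ap_brightness length-2 numeric `c(anterior, posterior)`
#'   multiplicative intensity factors; default `c(1, 0.5)`.
#' @param seed integer seed governing all randomness of the dataset.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(densities, ap_brightness = c(1, 0.5), seed = 1L) {
  stopifnot(is.data.frame(densities),
            all(c("region_id", "hemisphere", "density") %in% names(densities)),
            length(ap_brightness) == 2L, all(ap_brightness > 0))
  if (any(densities$density < 0 | densities$density > 1)) {
    stop("prescribed densities must lie in [0, 1]")
  }
  structure(
    list(densities = densities, ap_brightness = as.numeric(ap_brightness),
         seed = as.integer(seed), achieved = NULL, section_brightness = NULL),
    class = "ground_truth"
  )
}

#' Simulate an axon-labeled serial-section dataset from a toy atlas
#'
#' Places fibers as short straight segments (random position and orientation,
#' clipped to their region) within each leaf region and hemisphere until the
#' prescribed voxel fraction is reached, slices the volume into coronal
#' sections of the given thickness (optionally keeping alternating sections,
#' emulating every-other-section collection), and renders each kept section
#' as `n_focal_planes` noisy axon-channel images plus one nuclear-channel
#' image with region-boundary texture. Each section's intensity is scaled by
#' the linear anterior -> posterior brightness ramp in `truth`, so the gamma
#' normalization stage has a genuine gradient to remove.
#'
#' Noise model: per-pixel Gaussian noise on top of a constant offset
#' (`offset`), fiber pixels at `amplitude` attenuated per focal plane by a
#' uniform factor in `plane_atten`; the maximum projection restores close to
#' the full amplitude.
#'
#' @param atlas a [toy_atlas()].
#' @param truth a [ground_truth()].
#' @param section_thickness_um section thickness; default 80.
#' @param keep_every_other keep alternating sections (default TRUE).
#' @param n_focal_planes focal planes per section (default 5).
#' @param noise_sd Gaussian noise SD on the unit intensity scale (default 0.02).
#' @param fiber_len_vox fiber segment length in voxels (default 10).
#' @param amplitude fiber intensity added above background on the unit scale (default 0.5).
#' @param offset constant background offset (default 0.3, placing section means in the mid-tone range where power-law corrections act gently).
#' @param plane_atten length-2 range of per-plane fiber attenuation factors.
#' @return List with `stack` (a [section_stack()]), `truth` (the input
#'   ground truth with `achieved` densities and `section_brightness` filled
#'   in) and `fiber` (the 3D logical fiber volume, for auditing).
#' @export
simulate_axon_brain <- function(atlas, truth,
                                section_thickness_um = 80,
                                keep_every_other = TRUE,
                                n_focal_planes = 5L,
                                noise_sd = 0.02,
                                fiber_len_vox = 10L,
                                amplitude = 0.5,
                                offset = 0.3,
                                plane_atten = c(0.7, 1)) {
  stopifnot(inherits(atlas, "toy_atlas"), inherits(truth, "ground_truth"),
            section_thickness_um > 0, n_focal_planes >= 1L)
  dens <- truth$densities
  if (any(dens$density > 1)) stop("prescribed densities must not exceed 1")

  shape <- dim(atlas$annotation)
  lab_vec <- as.vector(atlas$annotation)
  ml_idx <- as.vector(slice.index(atlas$annotation, atlas$midline_axis))
  side <- midline_side(shape[atlas$midline_axis], ml_idx)
  side[side == "mid"] <- atlas$injection_side
  hemi_vec <- ifelse(side == atlas$injection_side, "ipsi", "contra")

  result <- with_seed(truth$seed, {
    fiber <- logical(length(lab_vec))
    achieved <- numeric(nrow(dens))
    for (r in seq_len(nrow(dens))) {
      d <- dens$density[r]
      region_idx <- which(lab_vec == dens$region_id[r] &
                            hemi_vec == dens$hemisphere[r])
      n_reg <- length(region_idx)
      target <- round(d * n_reg)
      if (n_reg == 0L || target == 0L) {
        achieved[r] <- 0
        next
      }
      in_region <- logical(length(lab_vec))
      in_region[region_idx] <- TRUE
      placed <- 0L
      iter <- 0L
      while (placed < target && iter < 200L) {
        iter <- iter + 1L
        n_seg <- max(10L, ceiling((target - placed) / (fiber_len_vox * 0.5)))
        starts <- arrayInd(region_idx[sample.int(n_reg, n_seg, replace = TRUE)],
                           shape)
        dirs <- matrix(stats::rnorm(3L * n_seg), ncol = 3L)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        steps <- seq_len(fiber_len_vox) - 1L
        ii <- round(outer(dirs[, 1L], steps) + starts[, 1L])
        jj <- round(outer(dirs[, 2L], steps) + starts[, 2L])
        kk <- round(outer(dirs[, 3L], steps) + starts[, 3L])
        ok <- ii >= 1L & ii <= shape[1L] & jj >= 1L & jj <= shape[2L] &
          kk >= 1L & kk <= shape[3L]
        # commit one segment at a time so the target is not overshot
        for (g in seq_len(n_seg)) {
          o <- ok[g, ]
          lin <- (kk[g, o] - 1L) * shape[1L] * shape[2L] +
            (jj[g, o] - 1L) * shape[1L] + ii[g, o]
          lin <- unique(lin[in_region[lin]])  # clip the segment to the region
          new <- lin[!fiber[lin]]
          if (placed + length(new) > target) {   # trim the last segment
            new <- new[seq_len(target - placed)]
          }
          fiber[new] <- TRUE
          placed <- placed + length(new)
          if (placed >= target) break
        }
      }
      if (placed < target) {            # top up sparse tail coverage
        uncovered <- region_idx[!fiber[region_idx]]
        fill <- sample(uncovered, target - placed)
        fiber[fill] <- TRUE
        placed <- target
      }
      achieved[r] <- placed / n_reg
    }

    fiber3 <- array(fiber, shape)
    n_ap <- shape[atlas$ap_axis]
    pps <- max(1L, round(section_thickness_um / atlas$voxel_size_um))
    n_sec <- floor(n_ap / pps)
    if (n_sec < 1L) stop("volume thinner than one section")
    profile <- seq(truth$ap_brightness[1L], truth$ap_brightness[2L],
                   length.out = n_sec)
    kept <- seq(1L, n_sec, by = if (isTRUE(keep_every_other)) 2L else 1L)

    plane_dims <- dim(ap_slice(atlas$annotation, atlas$ap_axis, 1L))
    npx <- prod(plane_dims)
    sections <- vector("list", length(kept))
    for (si in seq_along(kept)) {
      s <- kept[si]
      planes_of_s <- ((s - 1L) * pps + 1L):(s * pps)
      mid_plane <- planes_of_s[ceiling(pps / 2)]
      f2 <- Reduce(pmax, lapply(planes_of_s, function(p) {
        ap_slice(fiber3, atlas$ap_axis, p) * 1
      }))
      b <- profile[s]
      planes <- lapply(seq_len(n_focal_planes), function(p) {
        atten <- matrix(stats::runif(npx, plane_atten[1L], plane_atten[2L]),
                        plane_dims[1L], plane_dims[2L])
        img <- b * (amplitude * f2 * atten + offset) +
          matrix(stats::rnorm(npx, 0, noise_sd), plane_dims[1L], plane_dims[2L])
        clamp(img, 0, 1)
      })
      lab <- ap_slice(atlas$annotation, atlas$ap_axis, mid_plane)
      boundary <- lab != rbind(lab[-1L, , drop = FALSE], lab[nrow(lab), ]) |
        lab != cbind(lab[, -1L, drop = FALSE], lab[, ncol(lab)])
      nuclear <- clamp(0.1 + 0.35 * (lab > 0L) + 0.35 * boundary +
                         matrix(stats::rnorm(npx, 0, noise_sd),
                                plane_dims[1L], plane_dims[2L]), 0, 1)
      sections[[si]] <- list(ap_index = mid_plane, ap_planes = planes_of_s,
                             planes = planes, nuclear = nuclear,
                             pixel_size_um = atlas$voxel_size_um)
    }
    list(sections = sections, achieved = achieved, fiber = fiber3,
         brightness = data.frame(section = kept,
                                 ap_index = vapply(sections, function(x) x$ap_index, integer(1)),
                                 factor = profile[kept]))
  })

  dens$achieved <- result$achieved
  truth$densities <- dens
  truth$achieved <- dens
  truth$section_brightness <- result$brightness
  list(stack = section_stack(result$sections, atlas$voxel_size_um),
       truth = truth, fiber = result$fiber)
}
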