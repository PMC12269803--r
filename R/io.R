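#' Write a toy atlas to disk
#'
#' Annotation volume as a multi-page 16-bit TIFF (one page per
#' anterior-posterior plane), ontology as an Allen-style JSON node array,
#' and a small metadata JSON (voxel size, axis conventions, injection side).
#'
#' @param atlas a [toy_atlas()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "toy_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_ap <- dim(atlas$annotation)[atlas$ap_axis]
  pages <- lapply(seq_len(n_ap), function(i) {
    annotation_plane(atlas, i) / 65535
  })
  tiff::writeTIFF(pages, file.path(dir, "annotation.tif"),
                  bits.per.sample = 16L)
  write_tree_json(atlas$tree, file.path(dir, "ontology.json"))
  meta <- list(voxel_size_um = atlas$voxel_size_um, ap_axis = atlas$ap_axis,
               midline_axis = atlas$midline_axis,
               injection_side = atlas$injection_side,
               shape = dim(atlas$annotation))
  jsonlite::write_json(meta, file.path(dir, "atlas.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a toy atlas written by [write_atlas()]
#'
#' @param dir directory containing `annotation.tif`, `ontology.json`,
#'   `atlas.json`.
#' @return A [toy_atlas()].
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "atlas.json"))
  pages <- tiff::readTIFF(file.path(dir, "annotation.tif"), all = TRUE,
                          as.is = TRUE)
  shape <- as.integer(meta$shape)
  ann <- array(0L, shape)
  for (i in seq_along(pages)) {
    if (meta$ap_axis == 1L) ann[i, , ] <- pages[[i]]
    else if (meta$ap_axis == 2L) ann[, i, ] <- pages[[i]]
    else ann[, , i] <- pages[[i]]
  }
  toy_atlas(ann, meta$voxel_size_um, load_tree(file.path(dir, "ontology.json")),
            ap_axis = as.integer(meta$ap_axis),
            midline_axis = as.integer(meta$midline_axis),
            injection_side = meta$injection_side)
}

#' Write a section stack to disk
#'
#' One multi-page TIFF per section (pages: axon-channel focal planes in
#' order, then the nuclear channel) plus a JSON manifest documenting the
#' page order, `ap_index` and pixel size of every section.
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_section_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "section_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(stack$sections), function(i) {
    s <- stack$sections[[i]]
    fn <- sprintf("section_%04d.tif", s$ap_index)
    pages <- c(lapply(s$planes, function(p) clamp(p, 0, 1)),
               list(clamp(s$nuclear, 0, 1)))
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 16L)
    list(file = fn, ap_index = s$ap_index, n_focal_planes = length(s$planes),
         page_order = c(paste0("axon_plane_", seq_along(s$planes)), "nuclear"),
         pixel_size_um = s$pixel_size_um)
  })
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            sections = entries),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir directory with section TIFFs and `manifest.json`.
#' @return A [section_stack()].
#' @export
read_section_stack <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyDataFrame = FALSE)
  sections <- lapply(man$sections, function(e) {
    pages <- tiff::readTIFF(file.path(dir, e$file), all = TRUE)
    n_fp <- e$n_focal_planes
    list(ap_index = as.integer(e$ap_index), planes = pages[seq_len(n_fp)],
         nuclear = pages[[n_fp + 1L]], pixel_size_um = e$pixel_size_um)
  })
  section_stack(sections, man$pixel_size_um)
}

#' Write axon masks and their provenance
#'
#' Masks as one TIFF per section, provenance (per-section gamma, threshold,
#' background radius) as JSON.
#'
#' @param masks an `axon_masks` object from [process_sections()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir) {
  stopifnot(inherits(masks, "axon_masks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(masks$masks)) {
    fn <- sprintf("mask_%04d.tif", masks$ap_index[i])
    tiff::writeTIFF(masks$masks[[i]] * 1, file.path(dir, fn),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(masks$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a density table as tidy CSV
#'
#' One row per region x hemisphere with counts and metrics; stable column
#' names (`region_id`, `acronym`, `hemisphere`, `axon_voxels`,
#' `region_voxels`, `axon_density`, `relative_density`).
#'
#' @param table a `density_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write / read open-field trajectories as CSV
#'
#' Columns: `frame`, `t`, `x_cm`, `y_cm` — the documented export format of
#' the upstream tracker.
#'
#' @param traj a [trajectory()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(data.frame(frame = seq_len(nrow(traj)), t = traj$t,
                              x_cm = traj$x, y_cm = traj$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param arena_side_cm arena side length (cm) of the recorded session.
#' @param fps frame rate; inferred from the median time step when `NULL`.
#' @return `read_trajectory_csv`: a [trajectory()].
#' @export
read_trajectory_csv <- function(path, arena_side_cm, fps = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "x_cm", "y_cm") %in% names(d)))
  if (is.null(fps)) fps <- 1 / stats::median(diff(d$t))
  trajectory(data.frame(t = d$t, x = d$x_cm, y = d$y_cm),
             fps = fps, arena_side_cm = arena_side_cm)
}

#' Serialize ground truth alongside a generated dataset
#'
#' Ground truth is never implicit: this writes the prescribed and achieved
#' per-region densities as CSV and the brightness profile / seed as JSON.
#'
#' @param truth a [ground_truth()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$densities, file.path(dir, "ground_truth_densities.csv"),
                   row.names = FALSE)
  if (!is.null(truth$section_brightness)) {
    utils::write.csv(truth$section_brightness,
                     file.path(dir, "section_brightness.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(ap_brightness = truth$ap_brightness,
                            seed = truth$seed),
                       file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
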