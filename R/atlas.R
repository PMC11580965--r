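#' Labeled atlas volume
#'
#' An integer region-label voxel grid with world-coordinate metadata and a
#' label ontology.  Label 0 is background and never becomes a particle.
#'
#' @param labels 3D integer array of region labels.
#' @param voxel_size Length-3 voxel edge lengths (micrometers per axis).
#' @param origin World coordinates of the center of voxel (1,1,1)
#'   (default c(0,0,0)).
#' @param ontology Optional data frame with columns `id` (integer label) and
#'   `name` (region name); defaults to `region_<id>` names.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size, origin = c(0, 0, 0),
                           ontology = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (is.null(ontology))
    ontology <- data.frame(id = ids,
                           name = if (length(ids)) paste0("region_", ids)
                                  else character(0))
  miss <- setdiff(ids, ontology$id)
  if (length(miss))
    stop("ontology is missing labels: ", paste(miss, collapse = ", "))
  structure(list(labels = labels, voxel_size = voxel_size,
                 origin = as.numeric(origin), ontology = ontology),
            class = "labeled_volume")
}

#' Read a labeled NIfTI volume
#'
#' World coordinates are taken from the NIfTI voxel dimensions (pixdim);
#' values in millimeters are converted to micrometers when
#' `units = "mm"`.
#'
#' @param path NIfTI file path.
#' @param ontology Optional ontology data frame (see [labeled_volume()]).
#' @param units Units of the NIfTI pixdim: `"mm"` (default, converted to
#'   micrometers) or `"um"`.
#' @return A `labeled_volume`.
#' @export
read_labeled_volume <- function(path, ontology = NULL, units = c("mm", "um")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  if (units == "mm") vox <- vox * 1000
  labeled_volume(array(as.integer(round(img)), dim = dim(img)[1:3]),
                 voxel_size = vox, ontology = ontology)
}

#' Convert a labeled volume to atlas particles
#'
#' Aggregates foreground voxels into cells of edge `resolution`: one
#' particle per cell containing foreground, positioned at the foreground
#' centroid, weighted by the foreground volume in the cell, with region
#' memberships equal to the per-cell label fractions (one-hot in region
#' interiors, mixed at boundaries).
#'
#' @param vol A [labeled_volume()].
#' @param resolution Cell edge (micrometers, >= the voxel size).
#' @param target_features Target [feature_space()] the latent model will map
#'   onto; defaults to a placeholder single-feature space until set.
#' @return An [atlas_latent_model()] whose atlas particles live over the
#'   region ontology (laws unset).
#' @export
volume_to_particles <- function(vol, resolution, target_features = NULL) {
  if (resolution < max(vol$voxel_size) * (1 - 1e-6))
    stop("'resolution' must be >= the voxel size")
  fg <- which(vol$labels != 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("volume has no foreground voxels")
  world <- sweep(sweep(fg - 1, 2L, vol$voxel_size, `*`), 2L, vol$origin, `+`)
  lab <- vol$labels[fg]
  cell <- floor(sweep(world, 2L, apply(world, 2L, min), `-`) / resolution)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = "_")
  ids <- vol$ontology$id
  vox_vol <- prod(vol$voxel_size)
  groups <- split(seq_len(nrow(fg)), key)
  n <- length(groups)
  pos <- matrix(0, n, 3L); wts <- numeric(n)
  pi_mat <- matrix(0, n, length(ids))
  for (k in seq_len(n)) {
    g <- groups[[k]]
    pos[k, ] <- colMeans(world[g, , drop = FALSE])
    wts[k] <- length(g) * vox_vol
    pi_mat[k, ] <- tabulate(match(lab[g], ids), length(ids)) / length(g)
  }
  region_fs <- feature_space(as.character(vol$ontology$name), "discrete")
  atlas <- particle_measure(pos, wts, pi_mat, region_fs)
  if (is.null(target_features))
    target_features <- feature_space("feature_1")
  atlas_latent_model(atlas, target_features)
}
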