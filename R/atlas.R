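#' Generate a phantom parcellation
#'
#' Partitions the interior of the grid (everything except a one-voxel
#' shell, the phantom "brain mask") into `n_regions` contiguous,
#' mutually exclusive, non-empty parcels labeled 1..n_regions, with 0 as
#' background. The default 116 parcels stand in for the AAL parcellation
#' used for network construction. Parcels are consecutive chunks of a
#' serpentine raster walk over the interior box, so each parcel is a
#' connected lattice path and parcel sizes differ by at most one voxel.
#' The partition is deterministic; `seed` is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_regions number of parcels (<= interior voxel count).
#' @param grid_shape integer length-3 grid dimensions.
#' @param seed unused (deterministic partition).
#' @param min_voxels minimum parcel size; error if the grid cannot give
#'   every parcel at least this many voxels.
#' @param voxel_size_mm voxel size recorded in the atlas volume.
#' @return list with `volume` (a 3D [brain_volume] of integer labels)
#'   and `labels` (data.frame: label, name, size_voxels).
#' @export
generate_phantom_atlas <- function(n_regions, grid_shape, seed = 1L,
                                   min_voxels = 4L,
                                   voxel_size_mm = c(3, 3, 3)) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 3L))
    stop("generate_phantom_atlas: grid too small for an interior mask")
  inner <- grid_shape - 2L
  n_mask <- as.integer(prod(inner))
  if (n_regions > n_mask)
    stop("generate_phantom_atlas: grid too small: ", n_mask,
         " interior voxels for ", n_regions, " regions")
  if (n_mask %/% n_regions < min_voxels)
    stop("generate_phantom_atlas: grid too small: smallest region would ",
         "have ", n_mask %/% n_regions, " < ", min_voxels, " voxels")

  # serpentine raster order over the interior box: consecutive entries
  # are always lattice neighbours, so consecutive chunks are connected
  ord <- matrix(0L, nrow = n_mask, ncol = 3L)
  i <- 1L
  for (z in seq_len(inner[3])) {
    ys <- if (z %% 2L == 1L) seq_len(inner[2]) else rev(seq_len(inner[2]))
    for (y in ys) {
      flip <- xor(z %% 2L == 0L, y %% 2L == 0L)
      xs <- if (!flip) seq_len(inner[1]) else rev(seq_len(inner[1]))
      n <- length(xs)
      ord[i:(i + n - 1L), ] <- cbind(xs, y, z)
      i <- i + n
    }
  }
  # near-equal chunk sizes: n_mask = q*n_regions + r -> r chunks of q+1
  q <- n_mask %/% n_regions
  r <- n_mask %% n_regions
  sizes <- rep(q, n_regions) + c(rep(1L, r), rep(0L, n_regions - r))
  lab_seq <- rep(seq_len(n_regions), times = sizes)

  vol <- array(0L, dim = grid_shape)
  vol[ord + 1L] <- lab_seq  # +1: interior starts at voxel index 2
  list(
    volume = brain_volume(vol, voxel_size_mm = voxel_size_mm),
    labels = data.frame(
      label = seq_len(n_regions),
      name = sprintf("roi_%03d", seq_len(n_regions)),
      size_voxels = sizes))
}

#' Brain mask of a phantom grid
#'
#' The interior of the grid (one-voxel shell removed), matching the
#' support of [generate_phantom_atlas].
#'
#' @param grid_shape integer length-3.
#' @return logical 3D array.
#' @export
phantom_mask <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  m <- array(FALSE, dim = grid_shape)
  m[2:(grid_shape[1] - 1L), 2:(grid_shape[2] - 1L),
    2:(grid_shape[3] - 1L)] <- TRUE
  m
}
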