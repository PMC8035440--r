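#' Grid geometry of a brain volume
#'
#' Describes the voxel lattice of a volume: dimensions, voxel size in mm,
#' and the 4x4 voxel-to-world affine (NIfTI convention: applied to 0-based
#' voxel indices). The default affine is diagonal with the volume centred
#' on the world origin, mimicking a standard-space grid.
#'
#' @param dims integer triple, voxels per axis.
#' @param voxel_size_mm positive real triple, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world transform; must be invertible.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims, voxel_size_mm = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- -(dims - 1) / 2 * voxel_size_mm
  }
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "grid_geometry")
}

#' Voxel indices to world coordinates
#'
#' @param geometry a [grid_geometry()].
#' @param ijk n x 3 matrix of 1-based voxel indices (R convention).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  A <- geometry$affine
  sweep((ijk - 1) %*% t(A[1:3, 1:3]), 2L, A[1:3, 4], "+")
}

# World coordinates (n x 3) of a set of linear voxel indices.
world_coords_of <- function(geometry, lin_idx) {
  voxel_to_world(geometry, arrayInd(lin_idx, geometry$dims))
}

#' Construct concentric-shell tissue masks on a synthetic grid
#'
#' Builds deterministic gray-matter / white-matter / CSF / whole-brain masks
#' as concentric spherical shells around the grid centre: a gray-matter core,
#' a one-voxel white-matter shell, and a one-voxel CSF shell. The three
#' tissue classes are pairwise disjoint and contained in the whole-brain
#' mask. This is deliberately simple anatomy: it exercises mask plumbing,
#' not realism.
#'
#' @param geometry a [grid_geometry()].
#' @return A `tissue_masks` object: list of logical 3D arrays
#'   `gray`, `white`, `csf`, `whole_brain`.
#' @export
make_tissue_masks <- function(geometry) {
  d <- geometry$dims
  vs <- geometry$voxel_size_mm
  ijk <- arrayInd(seq_len(prod(d)), d)
  w <- voxel_to_world(geometry, ijk)
  ctr <- voxel_to_world(geometry, matrix((d + 1) / 2, 1L))
  r <- sqrt(rowSums(sweep(w, 2L, as.numeric(ctr))^2))
  r_brain <- 0.45 * min(d * vs)
  shell <- max(vs)  # one-voxel shells
  as_arr <- function(v) array(v, d)
  masks <- list(
    gray = as_arr(r <= r_brain - 2 * shell),
    white = as_arr(r > r_brain - 2 * shell & r <= r_brain - shell),
    csf = as_arr(r > r_brain - shell & r <= r_brain),
    whole_brain = as_arr(r <= r_brain)
  )
  structure(masks, class = "tissue_masks")
}
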