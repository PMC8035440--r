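#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically fold a stream of small integers into one 31-bit seed.
# All arithmetic stays below 2^53 so it is exact in doubles.
mix_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) * 1234567 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Separable 3D Gaussian convolution via per-axis banded kernel matrices.
# sigma_vox: per-axis standard deviation in voxel units; <= 0 means identity
# along that axis. Boundaries are zero-padded (renormalize with a mask if
# edge dilution matters; see smooth_map).
gauss_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  kmat <- function(n, sigma) {
    if (sigma <= 1e-8) return(NULL)
    h <- max(1L, as.integer(ceiling(4 * sigma)))
    w <- stats::dnorm(seq(-h, h), sd = sigma)
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (off in seq(-h, h)) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- w[off + h + 1L]
    }
    K
  }
  K1 <- kmat(d[1], sigma_vox[1])
  K2 <- kmat(d[2], sigma_vox[2])
  K3 <- kmat(d[3], sigma_vox[3])
  if (!is.null(K1)) arr <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), d)
  if (!is.null(K2)) {
    ap <- aperm(arr, c(2L, 1L, 3L))
    ap <- array(K2 %*% matrix(ap, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(ap, c(2L, 1L, 3L))
  }
  if (!is.null(K3)) {
    ap <- aperm(arr, c(3L, 1L, 2L))
    ap <- array(K3 %*% matrix(ap, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    arr <- aperm(ap, c(2L, 3L, 1L))
  }
  arr
}

# Smooth a stack of volumes (4D array, subject-last) in one pass: the
# per-axis kernel matmuls fold the remaining axes together, so the R-level
# overhead is paid once per stack instead of once per volume.
gauss_smooth_stack <- function(stack, sigma_vox, kmats = NULL) {
  d <- dim(stack)
  if (is.null(kmats)) kmats <- smooth_kernels(d[1:3], sigma_vox)
  if (!is.null(kmats[[1]]))
    stack <- array(kmats[[1]] %*% matrix(stack, d[1]), d)
  if (!is.null(kmats[[2]])) {
    ap <- aperm(stack, c(2L, 1L, 3L, 4L))
    ap <- array(kmats[[2]] %*% matrix(ap, d[2]), c(d[2], d[1], d[3], d[4]))
    stack <- aperm(ap, c(2L, 1L, 3L, 4L))
  }
  if (!is.null(kmats[[3]])) {
    ap <- aperm(stack, c(3L, 1L, 2L, 4L))
    ap <- array(kmats[[3]] %*% matrix(ap, d[3]), c(d[3], d[1], d[2], d[4]))
    stack <- aperm(ap, c(2L, 3L, 1L, 4L))
  }
  stack
}

smooth_kernels <- function(dims, sigma_vox) {
  kmat <- function(n, sigma) {
    if (sigma <= 1e-8) return(NULL)
    h <- max(1L, as.integer(ceiling(4 * sigma)))
    w <- stats::dnorm(seq(-h, h), sd = sigma)
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (off in seq(-h, h)) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- w[off + h + 1L]
    }
    K
  }
  list(kmat(dims[1], sigma_vox[1]), kmat(dims[2], sigma_vox[2]),
       kmat(dims[3], sigma_vox[3]))
}

# FWHM (mm) -> Gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

# Connected components of a logical 3D array under 6/18/26 connectivity.
# Returns a list of integer vectors of linear voxel indices (possibly empty).
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(list())
  lab <- array(0L, d)
  lab[idx] <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(offs))
  offs <- offs[nn > 0 & nn <= switch(as.character(connectivity),
                                     "6" = 1L, "18" = 2L, "26" = 3L), ,
               drop = FALSE]
  # keep one direction per offset pair to avoid duplicate edges
  keep <- offs[, 1] > 0 |
    (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs <- offs[keep, , drop = FALSE]
  ijk <- arrayInd(idx, d)
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- ijk + matrix(offs[r, ], n, 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
      nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nl <- lab[nb_lin]
    hit <- nl > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(which(ok)[hit], nl[hit]))
    }
  }
  memb <- union_find(n, edges)
  unname(split(idx, memb))
}

# Connected-component membership via weighted union-find with path
# compression; edges is a flat vector of vertex-index pairs.
union_find <- function(n, edges) {
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nx <- parent[x]
      parent[x] <<- root
      x <- nx
    }
    root
  }
  if (length(edges)) {
    ne <- length(edges) / 2L
    for (k in seq_len(ne)) {
      a <- find(edges[2L * k - 1L])
      b <- find(edges[2L * k])
      if (a != b) {
        if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
        parent[b] <- a
        size[a] <- size[a] + size[b]
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
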