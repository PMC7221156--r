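# Low-level 3D array utilities shared by the habitat and texture engines.

# Shift a 3D array by an integer offset, filling vacated entries with `fill`.
# shiftArray(a, c(1,0,0))[i,j,k] == a[i-1,j,k].
shiftArray <- function(a, off, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= d[ax] || -o >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- seq.int(1L + o, d[ax])
      src[[ax]] <- seq.int(1L, d[ax] - o)
    } else {
      dst[[ax]] <- seq.int(1L, d[ax] + o)
      src[[ax]] <- seq.int(1L - o, d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D lattice directions (one per antipodal pair) at Chebyshev
# distance 1, optionally restricted by connectivity (6 face, 18 face+edge,
# 26 face+edge+corner).
latticeDirections <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- g[, 3] * 9 + g[, 2] * 3 + g[, 1]
  g <- g[ord > 0, , drop = FALSE]  # one representative per antipodal pair
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  unname(g[keep, , drop = FALSE])
}

# Connected components of a logical 3D mask under 6/18/26-connectivity.
# Returns an integer array of component labels (0 = background). Built on
# the voxel adjacency graph; labels are renumbered so that label order
# follows the smallest linear voxel index in each component (deterministic).
connectedComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(idx)) return(lab)
  compact <- integer(prod(d))
  compact[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  dirs <- latticeDirections(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    nb <- sweep(coords, 2L, dirs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nb_id <- compact[nb_lin]
    hit <- nb_id > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_id[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber by first (smallest linear index) appearance
  first <- match(unique(memb), memb)
  renum <- integer(max(memb))
  renum[memb[sort(first)]] <- seq_along(first)
  lab[idx] <- renum[memb]
  lab
}

# Largest connected component of a logical mask; ties broken in favour of
# the component containing the smallest linear voxel index (which is the
# lowest-numbered label under connectedComponents' ordering).
largestComponent <- function(mask, connectivity = 26) {
  lab <- connectedComponents(mask, connectivity)
  if (!any(lab > 0L)) return(array(FALSE, dim = dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))[1L]
  lab == best
}

# Separable 1D filtering of a 3D array along one axis with symmetric
# (edge-inclusive) boundary padding. For a kernel of length L the output is
# out[i] = sum_j k[j] * a[i + j - 1 - floor((L-1)/2)], i.e. correlation with
# the kernel centred (left-centred for even L).
axisFilter <- function(a, kernel, axis) {
  d <- dim(a)
  L <- length(kernel)
  pl <- (L - 1L) %/% 2L
  pr <- L - 1L - pl
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  dim(ap) <- c(n, m)
  # symmetric padding: ..., a2, a1 | a1, ..., an | an, an-1, ...
  top <- if (pl > 0) ap[pmin(pl:1, n), , drop = FALSE] else NULL
  bot <- if (pr > 0) ap[pmax(n + 1L - (1:pr), 1L), , drop = FALSE] else NULL
  padded <- rbind(top, ap, bot)
  out <- matrix(0, n, m)
  for (j in seq_len(L))
    out <- out + kernel[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Separable 3D filter: kernels kx, ky, kz applied along axes 1..3.
separableFilter3D <- function(a, kx, ky, kz) {
  axisFilter(axisFilter(axisFilter(a, kx, 1L), ky, 2L), kz, 3L)
}

# World coordinates (mm) of voxel centres for given array indices (matrix
# with columns i,j,k; 1-based).
worldCoords <- function(ind, spacing, origin) {
  sweep(sweep(ind - 1, 2L, spacing, "*"), 2L, origin, "+")
}

# Bounding box of a mask with a margin, clipped to the array; returns index
# ranges as a list of three integer vectors.
maskBoundingBox <- function(mask, margin = 0L) {
  d <- dim(mask)
  ind <- which(mask, arr.ind = TRUE)
  lapply(1:3, function(ax) {
    seq.int(max(1L, min(ind[, ax]) - margin), min(d[ax], max(ind[, ax]) + margin))
  })
}
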