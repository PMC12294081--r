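# 3D binary morphology on logical arrays.
#
# Structuring elements are the 6-connected cross (faces) or the full
# 26-connected cube; voxels outside the grid count as background, so
# erosion removes the outermost voxel layer at the image border.

neighbor_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

# shift a logical array by (dx,dy,dz), padding with `fill`
shift_mask <- function(mask, off, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]; n <- d[ax]
    if (abs(o) >= n) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):n; src[[ax]] <- 1:(n - o) }
    else        { dst[[ax]] <- 1:(n + o); src[[ax]] <- (1 - o):n }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary erosion and dilation of 3D masks
#'
#' One iteration erodes (dilates) by the chosen structuring element:
#' 6-connectivity is the face-adjacent cross (the default used for the
#' assumed marrow VOI construction), 26-connectivity the full cube.
#'
#' @param mask logical 3D array.
#' @param iterations number of passes (0 returns the input).
#' @param connectivity 6 or 26.
#' @return logical 3D array.
#' @export
erode_mask <- function(mask, iterations = 1, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, iterations >= 0)
  offs <- neighbor_offsets(connectivity)
  for (it in seq_len(iterations)) {
    out <- mask
    for (k in seq_len(nrow(offs))) out <- out & shift_mask(mask, offs[k, ], fill = FALSE)
    mask <- out
  }
  mask
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iterations = 1, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, iterations >= 0)
  offs <- neighbor_offsets(connectivity)
  for (it in seq_len(iterations)) {
    out <- mask
    for (k in seq_len(nrow(offs))) out <- out | shift_mask(mask, offs[k, ], fill = FALSE)
    mask <- out
  }
  mask
}

#' Surface voxels of a mask
#'
#' A surface voxel is a mask voxel with at least one face-adjacent neighbor
#' outside the mask (grid borders count as outside).
#'
#' @param mask logical 3D array.
#' @return logical 3D array marking the surface shell.
#' @export
surface_voxels <- function(mask) {
  mask & !erode_mask(mask, 1, connectivity = 6)
}

#' Connected components of a 3D mask
#'
#' Labels foreground voxels by connectivity (default 26, appropriate for
#' blob-like blurred lesions) using the voxel adjacency graph.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array: 0 = background, 1..K = component labels ordered
#'   by decreasing size.
#' @export
connected_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    in_mask <- rank[nb_lin] > 0L
    if (!any(in_mask)) next
    edges[[k]] <- cbind(rank[idx[ok]][in_mask], rank[nb_lin][in_mask])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)
  # relabel by decreasing voxel count, deterministically
  ord <- order(-comp$csize, seq_along(comp$csize))
  relab <- integer(length(comp$csize))
  relab[ord] <- seq_along(ord)
  lab[idx] <- relab[comp$membership]
  lab
}

#' Minimum surface-to-surface distance between two masks
#'
#' Minimum Euclidean distance (mm) between surface-voxel centers of the two
#' masks; 0 if the masks overlap.
#'
#' @param mask_a,mask_b nonempty logical 3D arrays on the same grid.
#' @param spacing_mm isotropic voxel spacing in mm.
#' @return scalar distance in mm.
#' @export
surface_distance_mm <- function(mask_a, mask_b, spacing_mm) {
  if (!any(mask_a) || !any(mask_b)) stop("masks must be nonempty")
  stopifnot_same_grid(mask_a, mask_b)
  if (any(mask_a & mask_b)) return(0)
  d <- dim(mask_a)
  pa <- arrayInd(which(surface_voxels(mask_a)), d)
  pb <- arrayInd(which(surface_voxels(mask_b)), d)
  # blockwise min over all pairs to bound memory on large surfaces
  best <- Inf
  step <- 2000L
  for (i0 in seq(1L, nrow(pa), by = step)) {
    ia <- i0:min(i0 + step - 1L, nrow(pa))
    A <- pa[ia, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(pb^2), `+`) - 2 * tcrossprod(A, pb)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0)) * spacing_mm
}
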