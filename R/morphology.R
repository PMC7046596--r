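# Binary raster morphology on logical matrices.
#
# Conventions used throughout the package:
#   * masks are logical matrices, row-major indexed [row, col], 0-based
#     origin top-left when coordinates are reported to the user;
#   * the structuring element is a Euclidean disk of integer radius r
#     (offsets dr^2 + dc^2 <= r^2);
#   * connected components use 8-connectivity (one documented constant).

CONNECTIVITY <- 8L

disk_offsets <- function(radius) {
  stopifnot(radius >= 0)
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  sr <- max(1L, 1L + dr):min(h, h + dr)
  sc <- max(1L, 1L + dc):min(w, w + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

binary_dilate <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(m, off[k, 1L], off[k, 2L])
  }
  out
}

binary_erode <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    out <- out & shift_mask(m, -off[k, 1L], -off[k, 2L])
  }
  out & m
}

# Connected-component labelling via igraph. Labels are assigned in
# first-encounter order of the column-major pixel scan, so the result is
# deterministic and independent of igraph internals.
cc_label <- function(m, connectivity = CONNECTIVITY) {
  stopifnot(is.matrix(m), connectivity %in% c(4L, 8L))
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  fg <- which(m)
  n <- length(fg)
  if (n == 0L) return(lab)
  idx <- matrix(0L, h, w)
  idx[fg] <- seq_len(n)

  neigh <- list(c(1L, 0L), c(0L, 1L))           # S, E
  if (connectivity == 8L) {
    neigh <- c(neigh, list(c(1L, 1L), c(1L, -1L)))  # SE, SW
  }
  edges <- integer(0)
  for (d in neigh) {
    a <- idx
    b <- shift_mask_int(idx, -d[1L], -d[2L])  # neighbour pulled onto a's cell
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }
  if (length(edges) == 0L) {
    membership <- seq_len(n)
  } else {
    g <- igraph::make_graph(edges, n = n, directed = FALSE)
    membership <- igraph::components(g)$membership
  }
  membership <- match(membership, unique(membership))
  lab[fg] <- membership
  lab
}

shift_mask_int <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  sr <- max(1L, 1L + dr):min(h, h + dr)
  sc <- max(1L, 1L + dc):min(w, w + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# Fill background components not connected to the image border.
fill_holes_mat <- function(m) {
  bg <- !m
  lab <- cc_label(bg, connectivity = 4L)  # 4-connected background is the
                                          # topological dual of 8-connected fg
  if (max(lab) == 0L) return(m)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  holes <- lab > 0L & !(lab %in% border)
  m | holes
}

# Assign each TRUE pixel of `fg` to the seed label nearest in Euclidean
# distance; ties go to the lower label id (seeds are scanned in label order).
nearest_seed_assign <- function(fg, seeds, chunk = 1024L) {
  stopifnot(all(dim(fg) == dim(seeds)))
  out <- matrix(0L, nrow(fg), ncol(fg))
  sidx <- which(seeds > 0L)
  if (length(sidx) == 0L) return(out)
  h <- nrow(fg)
  sr <- ((sidx - 1L) %% h) + 1L
  sc <- ((sidx - 1L) %/% h) + 1L
  slab <- seeds[sidx]
  ord <- order(slab, sr, sc)
  sr <- sr[ord]; sc <- sc[ord]; slab <- slab[ord]

  pidx <- which(fg)
  pr <- ((pidx - 1L) %% h) + 1L
  pc <- ((pidx - 1L) %/% h) + 1L
  for (start in seq(1L, length(pidx), by = chunk)) {
    ii <- start:min(start + chunk - 1L, length(pidx))
    d2 <- outer(pr[ii], sr, "-")^2 + outer(pc[ii], sc, "-")^2
    j <- max.col(-d2, ties.method = "first")
    out[pidx[ii]] <- slab[j]
  }
  out
}
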