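# Neighbourhood offsets for 3-D connectivity. "Forward" offsets are the
# lexicographically positive half, enough to enumerate each undirected
# neighbour pair once.
connectivity_offsets <- function(connectivity = 26, forward = TRUE) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))  # 1 = face, 2 = edge, 3 = corner
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  g <- g[keep, , drop = FALSE]
  if (forward) {
    pos <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
    g <- g[pos, , drop = FALSE]
  }
  g
}

#' Label connected components of a 3-D binary mask
#'
#' Components are defined by face (6), face+edge (18) or full face, edge and
#' corner (26) neighbourhood connectivity. Adjacencies are enumerated by
#' vectorized index shifts and resolved with graph components.
#'
#' @param mask Logical 3-D array (or mask-role `voxel_grid`).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the mask's shape; 0 for background, 1..k
#'   component labels.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (inherits(mask, "voxel_grid")) mask <- mask$data
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask & !is.na(mask)
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  if (!length(idx)) return(lab)
  node <- integer(prod(dims))
  node[idx] <- seq_along(idx)
  coord <- arrayInd(idx, dims)
  offs <- connectivity_offsets(connectivity, forward = TRUE)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb1 <- coord[, 1] + offs[k, 1]
    nb2 <- coord[, 2] + offs[k, 2]
    nb3 <- coord[, 3] + offs[k, 3]
    ok <- nb1 >= 1L & nb1 <= dims[1] & nb2 >= 1L & nb2 <= dims[2] &
      nb3 >= 1L & nb3 <= dims[3]
    if (!any(ok)) next
    lin <- nb1[ok] + (nb2[ok] - 1L) * dims[1] + (nb3[ok] - 1L) * dims[1] * dims[2]
    tgt <- node[lin]
    src <- node[idx[ok]]
    hit <- tgt > 0L
    if (any(hit)) edges[[k]] <- cbind(src[hit], tgt[hit])
  }
  edges <- do.call(rbind, edges)
  n <- length(idx)
  if (is.null(edges)) {
    memb <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(memb)
  lab
}

#' Remove small connected components (islanding filter)
#'
#' Drops every connected component of the mask with fewer than `min_size`
#' voxels, the cleanup step that removes spurious isolated points
#' misclassified as trabecular bone. `min_size = 1` is the identity; the
#' output is always a subset of the input, and every surviving component has
#' at least `min_size` voxels.
#'
#' @param mask Logical 3-D array (or mask-role `voxel_grid`).
#' @param min_size Minimum component size P, in voxels (>= 1).
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return Logical array of the mask's shape.
#' @export
island_filter <- function(mask, min_size = 10, connectivity = 26) {
  if (inherits(mask, "voxel_grid")) mask <- mask$data
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1)
    stop("island_filter: min_size must be a single count >= 1")
  if (min_size == 1) return(mask & !is.na(mask))
  lab <- label_components(mask, connectivity)
  k <- max(lab)
  if (k == 0L) return(array(FALSE, dim(lab)))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- c(FALSE, sizes >= min_size)[lab + 1L]
  array(keep, dim(lab))
}

#' Apply the islanding filter to a compartment partition
#'
#' Filters the trabecular mask with [island_filter()] and re-assigns the
#' removed voxels to the cortical compartment, so cortical and trabecular
#' still partition the bone mask.
#'
#' @param masks A `compartment_masks` object from [classify_compartments()].
#' @param min_size,connectivity Passed to [island_filter()].
#' @return A `compartment_masks` object.
#' @export
filter_compartments <- function(masks, min_size = 10, connectivity = 26) {
  stopifnot(inherits(masks, "compartment_masks"))
  trab <- island_filter(masks$trabecular, min_size, connectivity)
  structure(list(bone = masks$bone,
                 cortical = masks$bone & !trab,
                 trabecular = trab),
            class = "compartment_masks")
}
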