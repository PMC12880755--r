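#' Build a hexagonal (honeycomb) lattice
#'
#' Constructs an embedded honeycomb graph with uniform edge length \code{d},
#' optionally rotated by \code{theta} degrees about the origin.  Interior
#' nodes have degree three; the gradient axis used by the chemokine fields is
#' +y, and the rotation is applied to the lattice, not the field.
#'
#' The lattice is generated from the two-site unit cell: sublattice A nodes
#' at \code{i*a1 + j*a2} with \code{a1 = (sqrt(3) d, 0)},
#' \code{a2 = (sqrt(3) d / 2, 3 d / 2)}, and sublattice B displaced by
#' \code{(0, d)}.  At \code{theta = 0} one edge of every A node points along
#' +y, so ideal paths toward +y zig-zag at 30 degrees off the axis
#' (maximal forward migration index \code{sqrt(3)/2}).
#'
#' @param d edge length (grid size, in cell rest lengths).
#' @param theta rotation angle in degrees.
#' @param nx,ny number of unit cells in each lattice direction (the lattice
#'   spans roughly \code{[-nx/2, nx/2] * sqrt(3) d} horizontally).
#' @param center 2-vector; the lattice is translated so that the node
#'   nearest \code{center} (before rotation) sits closest to the origin.
#' @return an object of class \code{"cell_network"}: list with \code{xy}
#'   (node coordinates), \code{adj} (adjacency list, 1-based),
#'   \code{d}, \code{theta}, and \code{kind = "hex"}.
#' @examples
#' net <- hex_lattice(d = 3, theta = 0, nx = 6, ny = 6)
#' nrow(net$xy)
#' @export
hex_lattice <- function(d = 3, theta = 0, nx = 30, ny = 30, center = c(0, 0)) {
  if (d <= 0) stop("grid size d must be positive")
  if (nx < 1 || ny < 1) stop("lattice dimensions must be positive")
  is <- seq.int(-ceiling(nx / 2), ceiling(nx / 2))
  js <- seq.int(-ceiling(ny / 2), ceiling(ny / 2))
  grid <- expand.grid(i = is, j = js)
  a1 <- c(sqrt(3) * d, 0)
  a2 <- c(sqrt(3) * d / 2, 1.5 * d)
  ax <- grid$i * a1[1] + grid$j * a2[1]
  ay <- grid$i * a1[2] + grid$j * a2[2]
  # sublattice A then B
  xy <- rbind(cbind(ax, ay), cbind(ax, ay + d))
  nA <- nrow(grid)
  key <- function(i, j, s) paste(i, j, s, sep = "/")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nA)) {
    assign(key(grid$i[r], grid$j[r], 0L), r, envir = idx)
    assign(key(grid$i[r], grid$j[r], 1L), r + nA, envir = idx)
  }
  get_idx <- function(i, j, s) {
    k <- key(i, j, s)
    if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA_integer_
  }
  adj <- vector("list", 2L * nA)
  for (r in seq_len(nA)) {
    i <- grid$i[r]; j <- grid$j[r]
    # neighbours of A(i, j): B(i, j), B(i, j - 1), B(i + 1, j - 1)
    nb <- c(get_idx(i, j, 1L), get_idx(i, j - 1L, 1L), get_idx(i + 1L, j - 1L, 1L))
    adj[[r]] <- nb[!is.na(nb)]
    # neighbours of B(i, j): A(i, j), A(i, j + 1), A(i - 1, j + 1)
    nb <- c(get_idx(i, j, 0L), get_idx(i, j + 1L, 0L), get_idx(i - 1L, j + 1L, 0L))
    adj[[r + nA]] <- nb[!is.na(nb)]
  }
  # shift so the A node nearest `center` is exactly at `center`'s position,
  # then rotate about the origin
  d2 <- (xy[seq_len(nA), 1] - center[1])^2 + (xy[seq_len(nA), 2] - center[2])^2
  o <- which.min(d2)
  xy[, 1] <- xy[, 1] - xy[o, 1] + center[1]
  xy[, 2] <- xy[, 2] - xy[o, 2] + center[2]
  th <- theta * pi / 180
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  xy <- xy %*% t(rot)
  colnames(xy) <- c("x", "y")
  structure(list(xy = xy, adj = adj, d = d, theta = theta, kind = "hex",
                 origin_node = o),
            class = "cell_network")
}

#' Single-junction (Y) network
#'
#' One degree-three node with three long straight branches, used for the
#' junction decision-making protocol.  Branch 1 points toward -y (the
#' incoming direction), branch 3 toward the upper right (the source side)
#' and branch 2 toward the upper left.
#'
#' @param branch_len length of each branch (long enough that tips never
#'   reach the far ends).
#' @param d nominal grid size carried for metric defaults (the slow-mode
#'   leader threshold); the branches themselves are unbranched.
#' @return a \code{"cell_network"} with nodes 1 (centre), 2, 3, 4 (far ends
#'   of branches 1, 2, 3).
#' @examples
#' yj <- junction_network()
#' yj$adj[[1]]
#' @export
junction_network <- function(branch_len = 1000, d = 3) {
  ang <- c(270, 150, 30) * pi / 180   # branches 1, 2, 3
  xy <- rbind(c(0, 0), t(vapply(ang, function(a) branch_len * c(cos(a), sin(a)),
                                numeric(2))))
  colnames(xy) <- c("x", "y")
  adj <- list(c(2L, 3L, 4L), 1L, 1L, 1L)
  structure(list(xy = xy, adj = adj, d = d, theta = 0, kind = "junction",
                 centre = 1L, branches = c(2L, 3L, 4L)),
            class = "cell_network")
}

#' Infinite-line (1D) network
#'
#' A single long edge along +y.  Cells on it always keep two arms; used for
#' the one-dimensional stick-slip threshold scan and for preparing the
#' polarized incoming state of the junction protocol.
#'
#' @param len total length of the track.
#' @return a \code{"cell_network"}.
#' @export
line_network <- function(len = 4000) {
  xy <- rbind(c(0, -len / 2), c(0, len / 2))
  colnames(xy) <- c("x", "y")
  structure(list(xy = xy, adj = list(2L, 1L), d = len, theta = 0, kind = "line"),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("cell_network (%s): %d nodes, d = %g, theta = %g deg\n",
              x$kind, nrow(x$xy), x$d, x$theta))
  invisible(x)
}

#' Nearest lattice node to a point
#' @param net a \code{cell_network}.
#' @param p numeric length-2 point.
#' @return node index.
#' @export
nearest_node <- function(net, p = c(0, 0)) {
  which.min((net$xy[, 1] - p[1])^2 + (net$xy[, 2] - p[2])^2)
}

#' Export / import a network as JSON
#'
#' Round-trippable plain-text representation (nodes, adjacency, grid size,
#' rotation) for reproducing rotated-grid ensembles.
#'
#' @param net a \code{cell_network}.
#' @param path file path.
#' @return \code{network_to_json} invisibly returns \code{path};
#'   \code{network_from_json} returns the \code{cell_network}.
#' @export
network_to_json <- function(net, path) {
  obj <- list(kind = net$kind, d = net$d, theta = net$theta,
              xy = unname(as.matrix(net$xy)), adj = net$adj)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  xy <- as.matrix(obj$xy)
  colnames(xy) <- c("x", "y")
  adj <- lapply(obj$adj, as.integer)
  structure(list(xy = xy, adj = adj, d = obj$d, theta = obj$theta,
                 kind = obj$kind),
            class = "cell_network")
}

#' Junction-distance table of a branched cell
#'
#' For a cell topology given as arms attached to junctions and segments
#' connecting junctions, returns the symmetric matrix \code{m[i, j]} counting
#' the spanned junctions on the unique path between the tips of arms i and j.
#' The flow-splitting weights \code{2^-m} then satisfy
#' \code{rowSums(2^-m) = 1} (off-diagonal), which
#' \code{\link{net_arm_flow}} relies on.
#'
#' @param topo a cell topology: list with \code{arm_base} (junction label per
#'   arm) and \code{segments} (2-column matrix of junction labels, possibly
#'   zero rows).
#' @return integer matrix \code{m} with \code{NA} on the diagonal.
#' @examples
#' junction_distances(list(arm_base = c(1, 1, 1),
#'                         segments = matrix(numeric(0), ncol = 2)))
#' @export
junction_distances <- function(topo) {
  ab <- topo$arm_base
  segs <- topo$segments
  if (is.null(dim(segs))) segs <- matrix(segs, ncol = 2)
  N <- length(ab)
  if (N < 3) return(matrix(NA_integer_, N, N))
  juncs <- unique(c(ab, as.vector(segs)))
  nj <- length(juncs)
  # junction graph distances (number of edges between junctions)
  jd <- matrix(Inf, nj, nj, dimnames = list(juncs, juncs))
  diag(jd) <- 0
  if (nrow(segs) > 0) {
    for (s in seq_len(nrow(segs))) {
      a <- as.character(segs[s, 1]); b <- as.character(segs[s, 2])
      jd[a, b] <- jd[b, a] <- 1
    }
  }
  for (k in seq_len(nj)) for (i in seq_len(nj)) for (j in seq_len(nj))
    if (jd[i, k] + jd[k, j] < jd[i, j]) jd[i, j] <- jd[i, k] + jd[k, j]
  if (any(!is.finite(jd))) stop("cell topology is disconnected")
  m <- matrix(NA_integer_, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    # junctions on the tip-to-tip path: both endpoints' bases plus all
    # junctions between them
    m[i, j] <- as.integer(jd[as.character(ab[i]), as.character(ab[j])] + 1)
  }
  m
}
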