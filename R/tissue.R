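#' Hexagonal-lattice tissue
#'
#' Builds a tissue of cells on a hexagonal lattice ("odd-r" offset indexing:
#' odd rows are shifted half a cell to the right; the neighbour stencil
#' depends on row parity and is fixed so that snapshots are reproducible).
#' Sites are either fully occupied (`density = 1`), occupied independently
#' with probability `density` from a seeded generator, or set from an
#' explicit occupancy `mask`. The nominal coordination number is 6; empty
#' neighbour sites contribute nothing to neighbour signals but still count
#' in the averaging denominator, so the signal a cell receives scales with
#' its local cell density (see [neighbor_signals()]).
#'
#' @param width,height Lattice dimensions (sites per row, number of rows).
#'   Periodic boundaries require an even `height` so the row-parity stencil
#'   closes consistently.
#' @param density Occupation probability per site in `[0, 1]`.
#' @param seed Integer seed for occupancy sampling (ignored when `mask` is
#'   given or `density` is 0 or 1). Sampling is done with a private RNG
#'   stream so the global `.Random.seed` is untouched.
#' @param mask Optional explicit occupancy: a logical `height x width`
#'   matrix, or a data frame with columns `row`, `col` (1-based) and
#'   optionally `occupied`.
#' @param boundary `"periodic"` (default; bulk behaviour, no edge
#'   artifacts) or `"fixed"` (sites beyond the edge are void).
#' @return A `tissue` object: cell coordinates, neighbour index, sparse
#'   cell-cell adjacency and bookkeeping fields.
#' @seealso [triangle3()], [graph_tissue()], [aggregate_stats()]
#' @examples
#' tis <- hex_lattice(10, 10)
#' aggregate_stats(tis)$mean_neighbors  # 6 on the full periodic lattice
#' @export
hex_lattice <- function(width, height, density = 1, seed = NULL,
                        mask = NULL, boundary = c("periodic", "fixed")) {
  boundary <- match.arg(boundary)
  if (width < 1 || height < 1) stop("width and height must be >= 1",
                                    call. = FALSE)
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 1)
    stop("density must be a single number in [0, 1]", call. = FALSE)
  if (boundary == "periodic" && height %% 2 != 0)
    stop("periodic hexagonal lattices need an even height", call. = FALSE)

  n_sites <- width * height
  # site index = (row - 1) * width + col, 1-based, row-major
  if (!is.null(mask)) {
    occupied <- parse_mask(mask, width, height)
  } else if (density == 1) {
    occupied <- rep(TRUE, n_sites)
  } else if (density == 0) {
    occupied <- rep(FALSE, n_sites)
  } else {
    occupied <- with_private_seed(seed, stats::runif(n_sites) < density)
  }

  site_row <- rep(seq_len(height), each = width)
  site_col <- rep(seq_len(width), times = height)
  nb_sites <- hex_site_neighbors(width, height, boundary)

  build_tissue(topology = "hex_lattice", occupied = occupied,
               nb_sites = nb_sites, coordination = 6L,
               width = width, height = height, boundary = boundary,
               site_row = site_row, site_col = site_col)
}

# List of neighbour site indices per site ("odd-r" stencil).
hex_site_neighbors <- function(width, height, boundary) {
  off_even <- cbind(c(0, 0, -1, -1, 1, 1), c(-1, 1, -1, 0, -1, 0))
  off_odd  <- cbind(c(0, 0, -1, -1, 1, 1), c(-1, 1, 0, 1, 0, 1))
  res <- vector("list", width * height)
  for (r0 in 0:(height - 1)) {
    off <- if (r0 %% 2 == 0) off_even else off_odd
    for (c0 in 0:(width - 1)) {
      rr <- r0 + off[, 1]; cc <- c0 + off[, 2]
      if (boundary == "periodic") {
        rr <- rr %% height; cc <- cc %% width
      } else {
        keep <- rr >= 0 & rr < height & cc >= 0 & cc < width
        rr <- rr[keep]; cc <- cc[keep]
      }
      res[[r0 * width + c0 + 1]] <- rr * width + cc + 1
    }
  }
  res
}

#' Minimal three-cell tissue
#'
#' Three mutually adjacent cells, the smallest tissue in which homogeneous
#' acinar, homogeneous islet and mixed fate configurations can all occur.
#' The coordination number is 2 (each cell averages over its two
#' neighbours).
#'
#' @return A `tissue` object with 3 cells.
#' @examples
#' neighbor_signals(triangle3(), initial_states(3, "adult"))
#' @export
triangle3 <- function() {
  build_tissue(topology = "triangle3", occupied = rep(TRUE, 3),
               nb_sites = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
               coordination = 2L, width = NA_integer_, height = NA_integer_,
               boundary = "none", site_row = rep(1L, 3), site_col = 1:3)
}

#' Tissue from an explicit neighbour graph
#'
#' @param edges Two-column integer matrix or data frame of undirected cell
#'   pairs (1-based ids); duplicate and reversed pairs are merged,
#'   self-loops rejected.
#' @param n_cells Number of cells; defaults to the largest id in `edges`.
#' @param coordination Averaging denominator for neighbour signals;
#'   defaults to the maximum degree of the graph.
#' @return A `tissue` object.
#' @export
graph_tissue <- function(edges, n_cells = NULL, coordination = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed", call. = FALSE)
  if (is.null(n_cells)) n_cells <- max(edges, 0L)
  if (any(edges < 1L) || any(edges > n_cells))
    stop("edge ids out of range", call. = FALSE)
  nb <- vector("list", n_cells)
  for (i in seq_len(n_cells)) nb[[i]] <- integer(0)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nb[[i]] <- union(nb[[i]], j)
    nb[[j]] <- union(nb[[j]], i)
  }
  if (is.null(coordination)) coordination <- max(lengths(nb), 1L)
  build_tissue(topology = "explicit_graph", occupied = rep(TRUE, n_cells),
               nb_sites = nb, coordination = as.integer(coordination),
               width = NA_integer_, height = NA_integer_, boundary = "none",
               site_row = rep(1L, n_cells), site_col = seq_len(n_cells))
}

# Shared constructor: restrict the site-level neighbour relation to occupied
# sites, renumber cells 1..n_cells, verify symmetry/irreflexivity.
build_tissue <- function(topology, occupied, nb_sites, coordination,
                         width, height, boundary, site_row, site_col) {
  cell_of_site <- integer(length(occupied))
  cell_of_site[occupied] <- seq_len(sum(occupied))
  n_cells <- sum(occupied)
  neighbors <- vector("list", n_cells)
  cells <- which(occupied)
  for (i in seq_len(n_cells)) {
    nbs <- nb_sites[[cells[i]]]
    neighbors[[i]] <- sort(cell_of_site[nbs[occupied[nbs]]])
  }
  deg <- lengths(neighbors)
  ii <- rep.int(seq_len(n_cells), deg)
  jj <- unlist(neighbors, use.names = FALSE)
  if (any(ii == jj)) stop("neighbour relation must be irreflexive",
                          call. = FALSE)
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(n_cells, n_cells))
  if (!Matrix::isSymmetric(adj))
    stop("neighbour relation must be symmetric", call. = FALSE)
  structure(list(topology = topology, width = width, height = height,
                 boundary = boundary, coordination = coordination,
                 occupied = occupied, n_cells = n_cells,
                 cell_row = site_row[cells], cell_col = site_col[cells],
                 neighbors = neighbors, adjacency = adj),
            class = "tissue")
}

#' @exportS3Method base::print
print.tissue <- function(x, ...) {
  cat(sprintf("Tissue: %s, %d cells", x$topology, x$n_cells))
  if (x$topology == "hex_lattice")
    cat(sprintf(" on %dx%d lattice (%s boundary, density %.3f)",
                x$width, x$height, x$boundary, mean(x$occupied)))
  cat("\n")
  invisible(x)
}

#' Neighbour signals received by each cell
#'
#' For every cell `i` the signal is the average expression of `X` and of `Y`
#' over the directly adjacent cells, where the average divides by the
#' topology's nominal coordination number (6 on the hexagonal lattice, 2 on
#' the three-cell tissue): empty neighbour sites contribute 0 to the sum
#' but still count in the denominator. An isolated cell therefore receives
#' the signal `(0, 0)` and is neither inhibited nor stabilized.
#'
#' @param tissue A `tissue` object.
#' @param states State matrix, one row per cell (columns `A`, `X`, `Y`,
#'   `Z`).
#' @return An `n_cells x 2` matrix with columns `Xbar`, `Ybar`.
#' @export
neighbor_signals <- function(tissue, states) {
  states <- as_state_matrix(states)
  if (nrow(states) != tissue$n_cells)
    stop("states must have one row per occupied cell", call. = FALSE)
  if (tissue$n_cells == 0L)
    return(matrix(0, 0, 2, dimnames = list(NULL, c("Xbar", "Ybar"))))
  sig <- as.matrix(tissue$adjacency %*% states[, c("X", "Y"), drop = FALSE]) /
    tissue$coordination
  dimnames(sig) <- list(NULL, c("Xbar", "Ybar"))
  sig
}

#' Aggregate occupancy statistics of a tissue
#'
#' @param tissue A `tissue` object.
#' @return A list with `n_cells`, `mean_neighbors` (average number of
#'   occupied neighbours per occupied cell, the compactness measure used in
#'   the aggregate-shape analysis) and `density` (occupied fraction of
#'   lattice sites; 1 for non-lattice topologies).
#' @export
aggregate_stats <- function(tissue) {
  mn <- if (tissue$n_cells == 0L) 0 else mean(lengths(tissue$neighbors))
  list(n_cells = tissue$n_cells, mean_neighbors = mn,
       density = tissue$n_cells / length(tissue$occupied))
}

parse_mask <- function(mask, width, height) {
  if (is.matrix(mask)) {
    if (nrow(mask) != height || ncol(mask) != width)
      stop("mask matrix must be height x width", call. = FALSE)
    return(as.vector(t(mask != 0)))
  }
  if (is.data.frame(mask)) {
    if (!all(c("row", "col") %in% names(mask)))
      stop("mask data frame needs columns 'row' and 'col'", call. = FALSE)
    occ <- rep(FALSE, width * height)
    keep <- if ("occupied" %in% names(mask)) as.logical(mask$occupied)
            else rep(TRUE, nrow(mask))
    r <- mask$row[keep]; c <- mask$col[keep]
    if (any(r < 1 | r > height | c < 1 | c > width))
      stop("mask coordinates out of lattice range", call. = FALSE)
    occ[(r - 1) * width + c] <- TRUE
    return(occ)
  }
  stop("mask must be a logical matrix or a row/col data frame",
       call. = FALSE)
}

#' Read and write occupancy masks
#'
#' Masks are stored as plain CSV with columns `row`, `col`, `occupied`
#' (1-based coordinates, one line per lattice site or per occupied site).
#'
#' @param tissue A hexagonal-lattice `tissue`.
#' @param path File path.
#' @return `read_occupancy()` returns a data frame usable as the `mask`
#'   argument of [hex_lattice()]; `write_occupancy()` invisibly returns
#'   `path`.
#' @export
write_occupancy <- function(tissue, path) {
  if (tissue$topology != "hex_lattice")
    stop("occupancy masks apply to hexagonal lattices", call. = FALSE)
  df <- data.frame(row = rep(seq_len(tissue$height), each = tissue$width),
                   col = rep(seq_len(tissue$width), times = tissue$height),
                   occupied = as.integer(tissue$occupied))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  df <- read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("occupancy file needs columns 'row' and 'col'", call. = FALSE)
  df
}

#' Read an explicit neighbour graph from an edge-list file
#'
#' Plain text, two integer cell ids per line (whitespace separated).
#'
#' @param path File path.
#' @param ... Passed to [graph_tissue()].
#' @return A `tissue` object.
#' @export
read_edge_list <- function(path, ...) {
  e <- utils::read.table(path, col.names = c("from", "to"))
  graph_tissue(e, ...)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_private_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
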