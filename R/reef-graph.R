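#' Construct a reef raster
#'
#' Plain-matrix raster: a logical habitat mask plus a traversal-cost layer
#' (open water 1, land 10,000 per cell). Row 1 is the top of the grid and
#' indices are matrix (row, col).
#'
#' @param habitat logical matrix (TRUE = reef habitat)
#' @param land logical matrix of the same shape (TRUE = land); a habitat
#'   cell cannot be land
#' @param resolution_km cell edge length in km (default 1)
#' @param land_cost cost multiplier of a land cell (default 10000)
#' @param sea_cost cost multiplier of a water cell (default 1)
#' @return a `reef_raster`
#' @export
reef_raster <- function(habitat, land = NULL, resolution_km = 1,
                        land_cost = 10000, sea_cost = 1) {
  habitat <- as.matrix(habitat) > 0
  if (is.null(land)) land <- matrix(FALSE, nrow(habitat), ncol(habitat))
  land <- as.matrix(land) > 0
  stopifnot(identical(dim(habitat), dim(land)), resolution_km > 0,
            land_cost >= 1, sea_cost >= 1)
  if (any(habitat & land)) stop("habitat cells cannot be land")
  cost <- matrix(sea_cost, nrow(habitat), ncol(habitat))
  cost[land] <- land_cost
  structure(list(habitat = habitat, land = land, cost = cost,
                 resolution_km = resolution_km),
            class = "reef_raster")
}

#' Read an Esri ASCII grid as a matrix
#'
#' Minimal reader for the plain-text grid format (ncols/nrows/... header
#' followed by rows of values, top row first).
#' @param path file path
#' @return numeric matrix
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
}

#' Write a matrix as an Esri ASCII grid
#' @param m numeric matrix
#' @param path file path
#' @param cellsize cell size recorded in the header
#' @export
write_ascii_grid <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cellsize), "NODATA_value -9999"), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# linear index helpers for grid cells
cell_id <- function(r, c, nr) (c - 1L) * nr + r

neighbors8 <- function(nr, nc) {
  # returns edge list (from, to, diag flag) over the full grid, each
  # undirected pair once
  r <- rep(seq_len(nr), nc)
  c <- rep(seq_len(nc), each = nr)
  from <- to <- integer(0)
  diagonal <- logical(0)
  shifts <- list(c(1, 0, FALSE), c(0, 1, FALSE), c(1, 1, TRUE), c(-1, 1, TRUE))
  for (s in shifts) {
    rr <- r + s[[1]]; cc <- c + s[[2]]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    from <- c(from, cell_id(r[ok], c[ok], nr))
    to <- c(to, cell_id(rr[ok], cc[ok], nr))
    diagonal <- c(diagonal, rep(s[[3]], sum(ok)))
  }
  list(from = from, to = to, diagonal = diagonal)
}

#' Extract habitat patches from a reef raster
#'
#' Connected components of habitat cells under 8-connectivity; components
#' smaller than `min_area_ha` are dropped (1 km^2 = 100 ha). Patch ids are
#' stable: sorted by the (row, col) of each patch's first cell.
#'
#' @param rr a [reef_raster()]
#' @param min_area_ha minimum patch area in hectares (default 25)
#' @return a `patch_set`: data.frame (patch, n_cells, area_ha,
#'   centroid_row, centroid_col) plus a `cells` attribute (list of cell
#'   index matrices)
#' @export
extract_patches <- function(rr, min_area_ha = 25) {
  nr <- nrow(rr$habitat); nc <- ncol(rr$habitat)
  if (!any(rr$habitat)) {
    warning("empty habitat mask: no patches")
    out <- data.frame(patch = integer(0), n_cells = integer(0),
                      area_ha = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
    attr(out, "cells") <- list()
    class(out) <- c("patch_set", "data.frame")
    return(out)
  }
  ed <- neighbors8(nr, nc)
  hab <- as.vector(rr$habitat)
  keep <- hab[ed$from] & hab[ed$to]
  g <- igraph::graph_from_edgelist(
    cbind(ed$from[keep], ed$to[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comp[!hab] <- NA
  cell_area_ha <- rr$resolution_km^2 * 100
  ids <- unique(comp[!is.na(comp)])
  # order patches by first cell in (row, col) scan order
  first_cell <- vapply(ids, function(id) {
    cells <- which(comp == id)
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    min(rows * 1e6 + cols)
  }, numeric(1))
  ids <- ids[order(first_cell)]
  cells_list <- list()
  rows_out <- list()
  pid <- 0L
  for (id in ids) {
    cells <- which(comp == id)
    area <- length(cells) * cell_area_ha
    if (area < min_area_ha) next
    pid <- pid + 1L
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    cells_list[[pid]] <- cbind(row = rows, col = cols, id = cells)
    rows_out[[pid]] <- data.frame(patch = pid, n_cells = length(cells),
                                  area_ha = area,
                                  centroid_row = mean(rows),
                                  centroid_col = mean(cols))
  }
  out <- if (pid > 0) do.call(rbind, rows_out) else
    data.frame(patch = integer(0), n_cells = integer(0),
               area_ha = numeric(0), centroid_row = numeric(0),
               centroid_col = numeric(0))
  attr(out, "cells") <- cells_list
  class(out) <- c("patch_set", "data.frame")
  out
}

#' Least-cost distances between all patch pairs
#'
#' Exact Dijkstra expansion over the 8-neighbor grid: a step costs its
#' length (resolution, or sqrt(2) x resolution diagonally) times the mean
#' of the two cells' cost values, so open-water distances come out in km.
#' Patch-to-patch distance is the minimum over cell pairs (equivalently
#' boundary-cell pairs).
#'
#' @param ps a [extract_patches()] patch set
#' @param rr the [reef_raster()] the patches came from
#' @return a `link_set`: symmetric matrix of least-cost distances in km
#'   (Inf where unreachable)
#' @export
least_cost_linkset <- function(ps, rr) {
  np <- nrow(ps)
  out <- matrix(0, np, np)
  if (np <= 1) return(structure(out, class = c("link_set", "matrix")))
  nr <- nrow(rr$cost); nc <- ncol(rr$cost)
  ed <- neighbors8(nr, nc)
  costv <- as.vector(rr$cost)
  step <- ifelse(ed$diagonal, sqrt(2), 1) * rr$resolution_km
  w <- step * (costv[ed$from] + costv[ed$to]) / 2
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  igraph::E(g)$weight <- w
  cells <- attr(ps, "cells")
  for (a in seq_len(np - 1)) {
    dmat <- igraph::distances(g, v = cells[[a]][, "id"],
                              mode = "all")
    for (b in (a + 1):np) {
      out[a, b] <- out[b, a] <- min(dmat[, cells[[b]][, "id"]])
    }
  }
  dimnames(out) <- list(ps$patch, ps$patch)
  structure(out, class = c("link_set", "matrix"))
}

#' Build a species' binary dispersal graph
#'
#' D_max = PLD x current speed; an undirected unweighted edge joins two
#' patches whose least-cost distance is positive and at most D_max.
#'
#' @param ls a [least_cost_linkset()] matrix
#' @param pld_days maximum pelagic larval duration in days
#' @param current_speed mean current speed in km/day (default 18.7)
#' @return a `species_graph`: list with the igraph `graph`, `d_max_km`,
#'   `pld_days`, and patch ids
#' @export
build_species_graph <- function(ls, pld_days, current_speed = 18.7) {
  stopifnot(pld_days > 0, current_speed > 0)
  d_max <- pld_days * current_speed
  adj <- is.finite(unclass(ls)) & unclass(ls) <= d_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(ls)
  structure(list(graph = g, d_max_km = d_max, pld_days = pld_days,
                 current_speed = current_speed,
                 patches = rownames(ls)),
            class = "species_graph")
}

#' Betweenness centrality of each patch
#'
#' Unweighted shortest-path betweenness with equal splitting among tied
#' shortest paths, endpoints excluded, normalized by (n-1)(n-2)/2.
#'
#' @param sg a [build_species_graph()] graph
#' @return named numeric vector in [0, 1] (all zeros when n < 3)
#' @export
patch_betweenness <- function(sg) {
  g <- sg$graph
  n <- igraph::vcount(g)
  if (n < 3) return(setNames(rep(0, n), igraph::V(g)$name))
  bc <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(bc), igraph::V(g)$name)
}

#' Graph diameter in dispersal steps
#'
#' Maximum shortest-path step count over connected pairs. Disconnected
#' graphs report the per-component maximum with `disconnected = TRUE`;
#' an edgeless graph reports 0 with the flag.
#'
#' @param sg a [build_species_graph()] graph
#' @return list with `diameter` (integer) and `disconnected` (logical)
#' @export
graph_diameter <- function(sg) {
  g <- sg$graph
  disconnected <- igraph::vcount(g) > 1 && !igraph::is_connected(g)
  if (igraph::ecount(g) == 0) {
    return(list(diameter = 0L, disconnected = igraph::vcount(g) >= 2))
  }
  d <- igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                        weights = NA)
  list(diameter = as.integer(d), disconnected = disconnected)
}

#' Betweenness rank of a focal patch
#'
#' 1-based rank of the focal patch's betweenness among all patches; ties
#' share the best (minimum) rank.
#'
#' @param sg a [build_species_graph()] graph
#' @param focal patch id (name)
#' @return integer rank
#' @export
rank_focal_patch <- function(sg, focal) {
  bc <- patch_betweenness(sg)
  focal <- as.character(focal)
  if (!focal %in% names(bc)) stop("unknown patch id: ", focal)
  as.integer(sum(bc > bc[focal]) + 1L)
}

#' Generate a synthetic seascape raster
#'
#' Places square reef patches at given centers on an open-water grid, with
#' optional rectangular land barriers; the generator is the stand-in for a
#' digitized reef map and records its geometry as ground truth metadata.
#'
#' @param nrow,ncol grid dimensions
#' @param patch_centers 2-column matrix of (row, col) patch centers
#' @param patch_half_width patches are squares of side 2w + 1 (default 1)
#' @param land_rects optional list of c(row1, row2, col1, col2) land blocks
#' @param resolution_km cell size (default 1)
#' @param seed optional seed for jitter-free reproducibility bookkeeping
#' @return a [reef_raster()] with attribute `truth` (patch centers and
#'   pairwise straight-line center distances in km)
#' @export
generate_synthetic_seascape <- function(nrow, ncol, patch_centers,
                                        patch_half_width = 1,
                                        land_rects = NULL,
                                        resolution_km = 1, seed = NULL) {
  patch_centers <- matrix(as.numeric(patch_centers), ncol = 2)
  habitat <- matrix(FALSE, nrow, ncol)
  used <- matrix(FALSE, nrow, ncol)
  w <- patch_half_width
  for (i in seq_len(nrow(patch_centers))) {
    r0 <- patch_centers[i, 1]; c0 <- patch_centers[i, 2]
    rs <- max(1, r0 - w):min(nrow, r0 + w)
    cs <- max(1, c0 - w):min(ncol, c0 + w)
    if (any(used[rs, cs])) stop("placement error: patches overlap")
    habitat[rs, cs] <- TRUE
    used[rs, cs] <- TRUE
  }
  land <- matrix(FALSE, nrow, ncol)
  for (rect in land_rects) {
    rs <- rect[1]:rect[2]; cs <- rect[3]:rect[4]
    if (any(habitat[rs, cs])) stop("placement error: land overlaps habitat")
    land[rs, cs] <- TRUE
  }
  rr <- reef_raster(habitat, land, resolution_km = resolution_km)
  dmat <- as.matrix(dist(patch_centers)) * resolution_km
  attr(rr, "truth") <- list(centers = patch_centers,
                            center_distance_km = dmat)
  rr
}
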