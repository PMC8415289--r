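test_that("patch extraction applies area threshold and 8-connectivity", {
  hab <- matrix(FALSE, 5, 5)
  hab[1, 1] <- TRUE                       # 1 km2 = 100 ha at 1 km cells
  ps <- extract_patches(reef_raster(hab))
  expect_equal(nrow(ps), 1)
  expect_equal(ps$area_ha, 100)

  # diagonal touch joins under 8-connectivity
  hab2 <- matrix(FALSE, 5, 5)
  hab2[2, 2] <- TRUE; hab2[3, 3] <- TRUE
  ps2 <- extract_patches(reef_raster(hab2))
  expect_equal(nrow(ps2), 1)
  expect_equal(ps2$n_cells, 2)

  # a single 0.4 km cell is 16 ha < 25: dropped
  ps3 <- extract_patches(reef_raster(hab, resolution_km = 0.4))
  expect_equal(nrow(ps3), 0)

  expect_warning(extract_patches(reef_raster(matrix(FALSE, 3, 3))), "empty")
})

test_that("least-cost distances follow open corridors and detours", {
  # two single-cell patches 10 cells apart in one row
  hab <- matrix(FALSE, 3, 12)
  hab[2, 1] <- TRUE; hab[2, 12] <- TRUE
  rr <- reef_raster(hab)
  ps <- extract_patches(rr)
  ls <- least_cost_linkset(ps, rr)
  expect_equal(ls[1, 2], 11, tolerance = 1e-9)  # 11 unit steps
  expect_equal(diag(ls), c(0, 0), ignore_attr = TRUE)

  # land wall forces a detour; brute-force oracle over the small grid
  hab2 <- matrix(FALSE, 5, 7)
  hab2[3, 1] <- TRUE; hab2[3, 7] <- TRUE
  land <- matrix(FALSE, 5, 7)
  land[1:4, 4] <- TRUE                     # wall with a gap at the bottom
  rr2 <- reef_raster(hab2, land)
  ps2 <- extract_patches(rr2)
  ls2 <- least_cost_linkset(ps2, rr2)
  straight <- least_cost_linkset(ps2, reef_raster(hab2))
  expect_gt(ls2[1, 2], straight[1, 2])
  # oracle: exhaustive Dijkstra written against plain matrices
  oracle <- local({
    nr <- 5; nc <- 7
    cost <- rr2$cost
    dist <- matrix(Inf, nr, nc); dist[3, 1] <- 0
    frontier <- TRUE
    while (frontier) {
      frontier <- FALSE
      for (r in 1:nr) for (cc in 1:nc) {
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- cc + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          step <- sqrt(dr^2 + dc^2) * (cost[r, cc] + cost[r2, c2]) / 2
          if (dist[r, cc] + step < dist[r2, c2] - 1e-12) {
            dist[r2, c2] <- dist[r, cc] + step
            frontier <- TRUE
          }
        }
      }
    }
    dist[3, 7]
  })
  expect_equal(ls2[1, 2], oracle, tolerance = 1e-9)
})

test_that("grid least-cost distance is bounded by Euclidean and octile", {
  rr <- generate_synthetic_seascape(9, 30, rbind(c(5, 2), c(5, 15), c(5, 28)),
                                    patch_half_width = 0)
  ps <- extract_patches(rr)
  ls <- least_cost_linkset(ps, rr)
  truth <- attr(rr, "truth")$center_distance_km
  for (a in 1:2) for (b in (a + 1):3) {
    expect_gte(ls[a, b], truth[a, b] - 2 * sqrt(2)) # minus patch extent
    expect_lte(ls[a, b], truth[a, b] * 1.09)        # octile overhead <= 8%
  }
})

test_that("species graphs threshold edges by PLD-scaled dispersal", {
  expect_equal(build_species_graph(structure(matrix(0, 1, 1,
    dimnames = list("1", "1")), class = c("link_set", "matrix")),
    pld_days = 26)$d_max_km, 486.2)
  ls <- structure(matrix(c(0, 100, 600, 100, 0, 450, 600, 450, 0), 3,
                         dimnames = list(1:3, 1:3)),
                  class = c("link_set", "matrix"))
  sg_all <- build_species_graph(ls, pld_days = 60)   # D_max = 1122
  expect_equal(igraph::ecount(sg_all$graph), 3)      # complete
  expect_equal(graph_diameter(sg_all)$diameter, 1L)
  sg_none <- build_species_graph(ls, pld_days = 1)   # D_max = 18.7
  expect_equal(igraph::ecount(sg_none$graph), 0)
  di <- graph_diameter(sg_none)
  expect_equal(di$diameter, 0L)
  expect_true(di$disconnected)
})

test_that("betweenness matches brute-force path counting", {
  # path graph A-B-C
  ls <- structure(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
                  class = c("link_set", "matrix"))
  sg <- build_species_graph(ls, pld_days = 1.001 / 18.7)  # D_max ~ 1
  bc <- patch_betweenness(sg)
  expect_equal(unname(bc), c(0, 1, 0))
  # star: center carries everything
  adj <- matrix(c(0, 1, 1, 1, 1, 0, 9, 9, 1, 9, 0, 9, 1, 9, 9, 0), 4)
  dimnames(adj) <- list(1:4, 1:4)
  sgs <- build_species_graph(structure(adj, class = c("link_set", "matrix")),
                             pld_days = 2.001 / 18.7)
  expect_equal(unname(patch_betweenness(sgs)), c(1, 0, 0, 0))
  # 4-cycle: brute-force enumeration gives 0.5/3 per node
  cyc <- matrix(9, 4, 4); diag(cyc) <- 0
  cyc[1, 2] <- cyc[2, 1] <- cyc[2, 3] <- cyc[3, 2] <- 1
  cyc[3, 4] <- cyc[4, 3] <- cyc[4, 1] <- cyc[1, 4] <- 1
  dimnames(cyc) <- list(1:4, 1:4)
  sgc <- build_species_graph(structure(cyc, class = c("link_set", "matrix")),
                             pld_days = 1.001 / 18.7)
  expect_equal(unname(patch_betweenness(sgc)), rep(0.5 / 3, 4),
               tolerance = 1e-12)
  # n < 3: all zero
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(1:2, 1:2))
  expect_equal(unname(patch_betweenness(build_species_graph(
    structure(two, class = c("link_set", "matrix")), 1))), c(0, 0))
})

test_that("diameter counts steps and flags disconnection", {
  n <- 8
  ls <- structure(abs(outer(1:n, 1:n, "-")) * 10,
                  class = c("link_set", "matrix"))
  dimnames(ls) <- list(1:n, 1:n)
  sg <- build_species_graph(ls, pld_days = 10 / 18.7)   # neighbors only
  expect_equal(graph_diameter(sg)$diameter, n - 1L)
  # two components: flag set, per-component maximum reported
  ls2 <- ls
  ls2[1:4, 5:8] <- Inf; ls2[5:8, 1:4] <- Inf
  sg2 <- build_species_graph(ls2, pld_days = 10 / 18.7)
  d2 <- graph_diameter(sg2)
  expect_true(d2$disconnected)
  expect_equal(d2$diameter, 3L)
})

test_that("focal-patch rank handles ties and unique cut vertices", {
  # complete graph: all betweenness zero, all tied at rank 1
  cmpl <- matrix(1, 4, 4); diag(cmpl) <- 0
  dimnames(cmpl) <- list(1:4, 1:4)
  sg <- build_species_graph(structure(cmpl, class = c("link_set", "matrix")),
                            pld_days = 1)
  expect_equal(rank_focal_patch(sg, "2"), 1L)
  expect_error(rank_focal_patch(sg, "99"), "unknown patch")
})

test_that("a unique bridge patch ranks first in betweenness", {
  # 10-patch archipelago: two clusters of 4 + 5 joined only through patch 5
  centers <- rbind(c(2, 2), c(2, 6), c(6, 2), c(6, 6),     # west cluster
                   c(10, 14),                               # bridge
                   c(18, 22), c(18, 26), c(22, 22), c(22, 26), c(18, 30))
  rr <- generate_synthetic_seascape(30, 36, centers, patch_half_width = 0)
  ps <- extract_patches(rr)
  expect_equal(nrow(ps), 10)
  ls <- least_cost_linkset(ps, rr)
  # D_max links within clusters and cluster-to-bridge, not across
  sg <- build_species_graph(ls, pld_days = 12 / 18.7)
  expect_true(igraph::is_connected(sg$graph))
  bridge <- which.min((ps$centroid_row - 10)^2 + (ps$centroid_col - 14)^2)
  expect_equal(rank_focal_patch(sg, as.character(ps$patch[bridge])), 1L)
  # oracle: brute-force betweenness by enumerating shortest paths
  g <- sg$graph
  n <- igraph::vcount(g)
  bc_oracle <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- igraph::all_shortest_paths(g, from = s, to = t)$res
    for (p in paths) {
      inner <- setdiff(as.integer(p), c(s, t))
      bc_oracle[inner] <- bc_oracle[inner] + 1 / length(paths)
    }
  }
  bc_oracle <- bc_oracle / ((n - 1) * (n - 2) / 2)
  expect_equal(unname(patch_betweenness(sg)), bc_oracle, tolerance = 1e-12)
})

test_that("edges grow and diameter shrinks as D_max increases", {
  rr <- generate_synthetic_seascape(9, 40,
                                    rbind(c(5, 3), c(5, 12), c(5, 21),
                                          c(5, 30), c(5, 39)),
                                    patch_half_width = 0)
  ps <- extract_patches(rr)
  ls <- least_cost_linkset(ps, rr)
  plds <- c(0.6, 1, 1.5, 2.5)
  edges <- diams <- numeric(length(plds))
  for (i in seq_along(plds)) {
    sg <- build_species_graph(ls, pld_days = plds[i])
    edges[i] <- igraph::ecount(sg$graph)
    diams[i] <- graph_diameter(sg)$diameter
  }
  expect_true(all(diff(edges) >= 0))
  connected <- diams[edges > 0]
  expect_true(all(diff(connected) <= 0))
})

test_that("synthetic seascapes are reproducible and respect placement", {
  r1 <- generate_synthetic_seascape(10, 10, rbind(c(3, 3), c(8, 8)))
  r2 <- generate_synthetic_seascape(10, 10, rbind(c(3, 3), c(8, 8)))
  expect_identical(r1$habitat, r2$habitat)
  expect_error(generate_synthetic_seascape(10, 10,
                                           rbind(c(3, 3), c(4, 4))),
               "placement error")
  expect_error(generate_synthetic_seascape(10, 10, rbind(c(3, 3)),
                                           land_rects = list(c(2, 4, 2, 4))),
               "placement error")
  # land wall lengthens the route
  open_rr <- generate_synthetic_seascape(11, 11, rbind(c(6, 2), c(6, 10)),
                                         patch_half_width = 0)
  wall_rr <- generate_synthetic_seascape(11, 11, rbind(c(6, 2), c(6, 10)),
                                         patch_half_width = 0,
                                         land_rects = list(c(1, 9, 6, 6)))
  d_open <- least_cost_linkset(extract_patches(open_rr), open_rr)[1, 2]
  d_wall <- least_cost_linkset(extract_patches(wall_rr), wall_rr)[1, 2]
  expect_gt(d_wall, d_open)
})

test_that("ASCII grid round trip preserves the matrix", {
  m <- matrix(runif(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path)
  expect_equal(read_ascii_grid(path), m, tolerance = 1e-12,
               ignore_attr = TRUE)
})
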