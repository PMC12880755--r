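test_that("hex lattice geometry", {
  net <- hex_lattice(d = 3, theta = 0, nx = 14, ny = 14)
  # every edge has length d
  els <- unlist(lapply(seq_along(net$adj), function(i)
    vapply(net$adj[[i]], function(j)
      sqrt(sum((net$xy[i, ] - net$xy[j, ])^2)), 0)))
  expect_true(all(abs(els - 3) < 1e-9))
  # interior nodes have exactly three neighbours
  deg <- lengths(net$adj)
  # honeycomb: no node exceeds degree three, most interior nodes reach it,
  # and the node at the origin certainly does
  expect_lte(max(deg), 3)
  expect_gt(mean(deg == 3), 0.8)
  expect_equal(deg[nearest_node(net, c(0, 0))], 3L)
  expect_error(hex_lattice(d = -1), "positive")
})

test_that("rotating by 120 degrees reproduces the edge geometry", {
  a <- hex_lattice(d = 2, theta = 0, nx = 6, ny = 6)
  b <- hex_lattice(d = 2, theta = 120, nx = 6, ny = 6)
  edge_set <- function(net) {
    es <- do.call(rbind, lapply(seq_along(net$adj), function(i)
      t(vapply(net$adj[[i]], function(j)
        c(sort(c(net$xy[i, 1], net$xy[j, 1])), sort(c(net$xy[i, 2], net$xy[j, 2])),
          (net$xy[i, 1] + net$xy[j, 1]) / 2, (net$xy[i, 2] + net$xy[j, 2]) / 2),
        numeric(6)))))
    round(es[, 5:6], 6)
  }
  ea <- edge_set(a); eb <- edge_set(b)
  # compare midpoints of edges well inside both finite lattices
  r <- 4
  inside <- function(e) e[, 1]^2 + e[, 2]^2 < r^2
  ma <- ea[inside(ea), , drop = FALSE]
  mb <- eb[inside(eb), , drop = FALSE]
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(ma), key(mb))
})

test_that("junction distances count spanned junctions on tip paths", {
  expect_equal(unique(stats::na.omit(as.vector(junction_distances(
    list(arm_base = c(1, 1, 1), segments = matrix(numeric(0), ncol = 2)))))), 1L)
  m <- junction_distances(list(arm_base = c(1, 1, 2, 2), segments = cbind(1, 2)))
  expect_equal(m[1, 2], 1L); expect_equal(m[3, 4], 1L)
  expect_equal(m[1, 3], 2L); expect_equal(m[2, 4], 2L)
  # two-arm cell: no junctions, empty table
  m2 <- junction_distances(list(arm_base = c(1, 1),
                                segments = matrix(numeric(0), ncol = 2)))
  expect_true(all(is.na(m2)))
  expect_error(junction_distances(list(arm_base = c(1, 1, 2),
                                       segments = matrix(numeric(0), ncol = 2))),
               "disconnected")
})

test_that("network JSON round-trip", {
  net <- hex_lattice(d = 2.5, theta = 30, nx = 4, ny = 4)
  fp <- tempfile(fileext = ".json")
  network_to_json(net, fp)
  back <- network_from_json(fp)
  expect_equal(back$d, net$d)
  expect_equal(back$theta, net$theta)
  expect_equal(unname(as.matrix(back$xy)), unname(as.matrix(net$xy)))
  expect_equal(back$adj, lapply(net$adj, as.integer))
  unlink(fp)
})
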