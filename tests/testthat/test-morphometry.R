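# Morphometry checks against analytic fixtures and brute-force oracles.

test_that("a 5-px-wide straight bar skeletonizes to one path of known length", {
  m <- matrix(FALSE, 60, 160)
  m[28:32, 10:150] <- TRUE
  sk <- skeletonize(m, px_per_um = 1)
  deg <- table(igraph::degree(dendromorph:::as_igraph(sk)))
  expect_equal(sum(igraph::degree(dendromorph:::as_igraph(sk)) > 2), 0)
  expect_equal(total_length(sk), 140, tolerance = 0.02 * 140)
})

test_that("a plus sign gives 4 tips and one central branch node", {
  m <- matrix(FALSE, 81, 81)
  m[41, 11:71] <- TRUE
  m[11:71, 41] <- TRUE
  sk <- skeletonize(m, px_per_um = 1)
  expect_equal(count_tips(sk, soma_exclusion_radius_px = 0), 4L)
  deg <- igraph::degree(dendromorph:::as_igraph(sk))
  expect_equal(sum(deg >= 3), 1L)
})

test_that("a ring has no tips and keeps its cycle", {
  m <- matrix(FALSE, 101, 101)
  th <- seq(0, 2 * pi, length.out = 720)
  for (r in c(29.5, 30, 30.5)) {
    m[cbind(round(51 + r * sin(th)), round(51 + r * cos(th)))] <- TRUE
  }
  sk <- skeletonize(m, px_per_um = 1)
  expect_equal(count_tips(sk), 0L)
  g <- dendromorph:::as_igraph(sk)
  expect_gt(igraph::ecount(g), igraph::vcount(g) - 1)  # cycle survives
})

test_that("path lengths follow the orthogonal/diagonal step rule", {
  nodes <- data.frame(id = 1:101, x = seq(10, 110), y = rep(5, 101))
  sk <- skeleton_graph(nodes, edges = cbind(1:100, 2:101), root = 1,
                       px_per_um = 2)
  expect_equal(total_length(sk), 50)
  nodes2 <- data.frame(id = 1:101, x = seq(10, 110), y = seq(10, 110))
  sk2 <- skeleton_graph(nodes2, edges = cbind(1:100, 2:101), root = 1,
                        px_per_um = 2)
  expect_equal(total_length(sk2), 100 * sqrt(2) / 2, tolerance = 1e-9)
})

test_that("tip counting respects the soma exclusion radius", {
  nodes <- data.frame(id = 1:3, x = c(50, 52, 120), y = c(50, 50, 50))
  sk <- skeleton_graph(nodes, edges = rbind(c(1, 2), c(2, 3)), root = 1,
                       px_per_um = 1, soma_radius_px = 5)
  expect_equal(count_tips(sk), 1L)   # far endpoint only
})

test_that("Sholl matches analytic star and circle fixtures", {
  # star of 4 straight branches of length 100 px (50 um at 2 px/um)
  k <- 4; L <- 100
  th <- 2 * pi * (seq_len(k) - 1) / k + 0.3
  nodes <- data.frame(id = 1:(2 * k + 1),
                      x = c(200, 200 + L * cos(th), 200 + 0.5 * L * cos(th)),
                      y = c(200, 200 + L * sin(th), 200 + 0.5 * L * sin(th)))
  edges <- rbind(cbind(1, k + 2:(k + 1)), cbind(k + 2:(k + 1), 2:(k + 1)))
  sk <- skeleton_graph(nodes, edges = edges, root = 1, px_per_um = 2)
  pr <- sholl(sk, step_um = 10, r_max_um = 70)
  expect_equal(pr$crossings[pr$radius_um < 50], rep(4L, 4))
  expect_equal(pr$crossings[pr$radius_um > 50], rep(0L, 2))
  # a circle centred on the soma crosses no sampled radius r != rho
  thc <- seq(0, 2 * pi, length.out = 201)[-201]
  nodes_c <- rbind(
    data.frame(id = 1:200, x = 100 + 25 * cos(thc), y = 100 + 25 * sin(thc)),
    data.frame(id = 201, x = 100, y = 100))
  edges_c <- cbind(1:200, c(2:200, 1))
  skc <- skeleton_graph(nodes_c, edges = edges_c, root = 201, px_per_um = 1)
  prc <- sholl(skc, step_um = 10, r_max_um = 50)
  expect_true(all(prc$crossings == 0L))
})

test_that("Sholl equals a brute-force circle-crossing oracle", {
  for (seed in 1:3) {
    sp <- synthetic_spec(field_size_px = 256L, target_tips = 20L,
                         margin_px = 10, seed = 40 + seed)
    sk <- generate_arbor(sp)
    expect_lte(nrow(sk$nodes), 200)
    pr <- sholl(sk, step_um = 10)
    # oracle: subdivide each edge into 200 pieces and count sign changes of
    # (distance - r) along the dense polyline, per edge
    nd <- sk$nodes
    ri <- match(sk$root, nd$id)
    i <- match(sk$edges[, 1], nd$id); j <- match(sk$edges[, 2], nd$id)
    for (rw in seq_len(nrow(pr))) {
      r <- pr$radius_um[rw]
      n_cross <- 0L
      for (e in seq_along(i)) {
        t <- seq(0, 1, length.out = 201)
        dx <- nd$x[i[e]] + t * (nd$x[j[e]] - nd$x[i[e]]) - nd$x[ri]
        dy <- nd$y[i[e]] + t * (nd$y[j[e]] - nd$y[i[e]]) - nd$y[ri]
        d <- sqrt(dx^2 + dy^2) / sk$px_per_um
        s <- sign(d - r)
        n_cross <- n_cross + sum(s[-1] != s[-length(s)] & s[-1] != 0)
      }
      expect_equal(pr$crossings[rw], n_cross)
    }
  }
})

test_that("territory coverage: full grids and degenerate lines score 100", {
  # dense grid arbor filling its hull
  xs <- as.vector(outer(seq(20, 180, by = 10), rep(1, 17)))
  ys <- as.vector(outer(rep(1, 17), seq(20, 180, by = 10)))
  nodes <- data.frame(id = seq_along(xs), x = xs, y = ys)
  edges <- cbind(seq_len(length(xs) - 1), seq_len(length(xs) - 1) + 1)
  sk <- skeleton_graph(nodes, edges = edges, root = 1, px_per_um = 1)
  expect_equal(territory_coverage(sk, cell_px = 20), 100)
  # straight line (degenerate hull)
  nodes2 <- data.frame(id = 1:50, x = seq(10, 206, by = 4), y = rep(30, 50))
  sk2 <- skeleton_graph(nodes2, edges = cbind(1:49, 2:50), root = 1,
                        px_per_um = 1)
  expect_equal(territory_coverage(sk2, cell_px = 20), 100)
})

test_that("coverage strictly decreases after strong branch elimination", {
  sk <- cached("cov_arbor", generate_arbor(
    synthetic_spec(field_size_px = 512L, target_tips = 80L, margin_px = 12,
                   seed = 77)))
  ev <- evolve_arbor(sk, p_elim = 0.5, p_add = 0, seed = 3)
  expect_lt(territory_coverage(ev$t2), territory_coverage(sk))
})

test_that("morphometry is invariant under translation and 90-degree rotation", {
  ren <- tiny_noiseless(1)
  m <- ren$mask
  sk1 <- skeletonize(m)
  m_shift <- matrix(FALSE, nrow(m), ncol(m))
  m_shift[11:nrow(m), 6:ncol(m)] <- m[1:(nrow(m) - 10), 1:(ncol(m) - 5)]
  sk2 <- skeletonize(m_shift)
  m_rot <- t(m)[ncol(m):1, ]
  sk3 <- skeletonize(m_rot)
  expect_equal(count_tips(sk2), count_tips(sk1))
  expect_equal(count_tips(sk3), count_tips(sk1))
  expect_equal(total_length(sk2), total_length(sk1), tolerance = 1e-9)
  # thinning is not exactly rotation-symmetric; the residual is < 0.1%
  expect_equal(total_length(sk3), total_length(sk1), tolerance = 1e-3)
})

test_that("monotonicity: elimination never increases the measures", {
  sp <- update_spec(tiny_spec(88), noise_sd = 0, debris_rate = 0,
                    psf_sigma_px = 0)
  sk <- generate_arbor(sp)
  ren1 <- render_arbor(sk, sp)
  ev <- evolve_arbor(sk, p_elim = 0.4, p_add = 0, seed = 4)
  ren2 <- render_arbor(ev$t2, sp)
  s1 <- skeletonize(ren1$mask); s2 <- skeletonize(ren2$mask)
  expect_lte(count_tips(s2), count_tips(s1))
  expect_lte(total_length(s2), total_length(s1))
  # hull shrinkage can nudge coverage up by a fraction of a point
  expect_lte(territory_coverage(s2), territory_coverage(s1) + 1)
})

test_that("quantify composes the measures and handles dead neurons", {
  ren <- tiny_noiseless(1)
  rec <- quantify(ren$mask, neuron_id = "nX", timepoint = "t1")
  expect_s3_class(rec, "morphometry_record")
  expect_gt(rec$total_length_um, 0)
  expect_gt(rec$tip_count, 0)
  expect_true(rec$territory_pct > 0 && rec$territory_pct <= 100)
  expect_true(all(diff(rec$sholl$radius_um) > 0))
  rec2 <- quantify(ren$mask, neuron_id = "nX", timepoint = "t1")
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  dead <- quantify(matrix(FALSE, 40, 40))
  expect_true(dead$dead)
  expect_equal(dead$tip_count, 0L)
  expect_equal(dead$total_length_um, 0)
})

test_that("quantify accepts SWC input and matches the skeleton measures", {
  sk <- tiny_arbor(1)
  f <- tempfile(fileext = ".swc")
  write_swc(sk, f)
  rec <- quantify(f, px_per_um = sk$px_per_um)
  expect_equal(rec$total_length_um, total_length(sk), tolerance = 1e-4)
  expect_equal(rec$tip_count, length(tip_ids(sk)))
})
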