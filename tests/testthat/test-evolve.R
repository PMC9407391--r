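mid_arbor <- function(seed = 11, tips = 100L) {
  cached(paste0("mid", seed, "_", tips), generate_arbor(
    synthetic_spec(field_size_px = 512L, target_tips = tips,
                   margin_px = 12, seed = seed)))
}

test_that("identity evolution returns the same arbor, all tips stable", {
  sk <- tiny_arbor(1)
  ev <- evolve_arbor(sk, p_elim = 0, p_add = 0, growth = 1,
                     offset_px = c(0, 0), seed = 5)
  expect_same_skeleton(sk, ev$t2)
  expect_true(all(ev$labels$t1_tip_labels$label == "stable"))
  expect_true(all(ev$labels$t2_tip_labels$label == "stable"))
  expect_equal(ev$labels$counts[["eliminated"]], 0L)
  expect_equal(ev$labels$counts[["added"]], 0L)
})

test_that("elimination bookkeeping is exact", {
  sk <- mid_arbor()
  T1 <- length(tree_leaves(sk))
  ev <- evolve_arbor(sk, p_elim = 0.2, p_add = 0, seed = 7)
  E <- round(0.2 * T1)
  expect_equal(ev$labels$counts[["eliminated"]], E)
  expect_equal(length(tree_leaves(ev$t2)), T1 - E)
  expect_equal(sum(ev$labels$t1_tip_labels$label == "eliminated"), E)
})

test_that("addition fraction added/T2 is honored by construction", {
  sk <- mid_arbor(12, 90L)
  T1 <- length(tree_leaves(sk))
  ev <- evolve_arbor(sk, p_elim = 0, p_add = 0.25, seed = 8)
  A <- ev$labels$counts[["added"]]
  T2 <- length(tree_leaves(ev$t2))
  expect_equal(A, round(0.25 * T1 / 0.75))
  expect_equal(T2, T1 + A)
  expect_equal(ev$labels$counts[["T2"]], T2)
})

test_that("label conservation partitions both tip sets, with offset+growth", {
  sk <- mid_arbor()
  ev <- evolve_arbor(sk, p_elim = 0.3, p_add = 0.15, growth = 1.05,
                     offset_px = c(4, -6), seed = 9, field_size_px = Inf)
  lab1 <- ev$labels$t1_tip_labels
  lab2 <- ev$labels$t2_tip_labels
  expect_setequal(lab1$id, tree_leaves(sk))
  expect_setequal(lab2$id, tree_leaves(ev$t2))
  cnt <- ev$labels$counts
  expect_equal(cnt[["stable"]] + cnt[["eliminated"]], cnt[["T1"]])
  expect_equal(cnt[["stable"]] + cnt[["added"]], cnt[["T2"]])
  # stable tips map to the same geometry shifted/scaled
  map <- ev$labels$node_map
  i1 <- match(map$t1_id, sk$nodes$id)
  i2 <- match(map$t2_id, ev$t2$nodes$id)
  ri <- match(sk$root, sk$nodes$id)
  expect_equal(ev$t2$nodes$x[i2],
               sk$nodes$x[ri] + 1.05 * (sk$nodes$x[i1] - sk$nodes$x[ri]) + 4,
               tolerance = 1e-9)
})

test_that("total elimination is allowed and flagged degenerate", {
  sk <- tiny_arbor(2)
  expect_warning(ev <- evolve_arbor(sk, p_elim = 1, p_add = 0, seed = 3),
                 "degenerate")
  expect_equal(nrow(ev$t2$nodes), 1L)
  expect_true(ev$labels$degenerate)
})

test_that("evolution validates inputs", {
  sk <- tiny_arbor(1)
  expect_error(evolve_arbor(sk, p_elim = -0.1))
  expect_error(evolve_arbor(sk, p_elim = 0.1, growth = 0.5))
  nog <- skeleton_graph(data.frame(id = 1:2, x = c(1, 2), y = c(1, 2)),
                        edges = cbind(1L, 2L))
  expect_error(evolve_arbor(nog), "parent")
})
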