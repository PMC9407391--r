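paired_arbors <- function(seed = 61, tips = 80L, p_elim = 0.2, p_add = 0.15,
                          offset = c(5, -3)) {
  sk <- cached(paste0("dyn", seed, tips), generate_arbor(
    synthetic_spec(field_size_px = 512L, target_tips = tips, margin_px = 14,
                   seed = seed)))
  ev <- evolve_arbor(sk, p_elim = p_elim, p_add = p_add,
                     offset_px = offset, seed = seed + 1)
  list(t1 = sk, t2 = ev$t2, labels = ev$labels)
}

test_that("alignment recovers a known rigid shift (exhaustive oracle)", {
  pa <- paired_arbors(offset = c(5, -3), p_elim = 0.1, p_add = 0.1)
  off <- align_skeletons(pa$t1, pa$t2, search_px = 10)
  expect_equal(c(off$dx, off$dy), c(5, -3))
  # identical skeletons align at the identity
  off0 <- align_skeletons(pa$t1, pa$t1, search_px = 8)
  expect_equal(c(off0$dx, off0$dy), c(0, 0))
})

test_that("disjoint skeletons beyond the window fall back to identity", {
  n1 <- data.frame(id = 1:2, x = c(5, 10), y = c(5, 5))
  n2 <- data.frame(id = 1:2, x = c(200, 205), y = c(200, 200))
  s1 <- skeleton_graph(n1, edges = cbind(1L, 2L), root = 1)
  s2 <- skeleton_graph(n2, edges = cbind(1L, 2L), root = 1)
  expect_warning(off <- align_skeletons(s1, s2, search_px = 5), "overlap")
  expect_equal(c(off$dx, off$dy), c(0, 0))
})

test_that("transition arbor: identity, deletion, and empty cases", {
  pa <- paired_arbors(p_elim = 0.25, p_add = 0, offset = c(0, 0))
  # identity: transition arbor == t1
  tr_id <- transition_arbor(pa$t1, pa$t1, match_tol_px = 2)
  expect_equal(nrow(tr_id$nodes), nrow(pa$t1$nodes))
  # t2 = t1 minus eliminated branches: transition drops those branches
  tr <- transition_arbor(pa$t1, pa$t2, match_tol_px = 2)
  expect_lt(nrow(tr$nodes), nrow(pa$t1$nodes))
  expect_equal(count_tips(tr), pa$labels$counts[["stable"]],
               tolerance = 0.06 * pa$labels$counts[["T1"]])
  # eliminated branch nodes are (mostly) excluded
  gone_ids <- setdiff(pa$t1$nodes$id, pa$labels$node_map$t1_id)
  kept_xy <- paste(round(tr$nodes$x, 3), round(tr$nodes$y, 3))
  gone_xy <- paste(round(pa$t1$nodes$x[match(gone_ids, pa$t1$nodes$id)], 3),
                   round(pa$t1$nodes$y[match(gone_ids, pa$t1$nodes$id)], 3))
  expect_lt(mean(gone_xy %in% kept_xy), 0.25)
  # empty t2
  tr0 <- transition_arbor(pa$t1, dendromorph:::empty_skeleton())
  expect_equal(nrow(tr0$nodes), 0L)
})

test_that("identical time points give all-stable records", {
  pa <- paired_arbors()
  rec <- dynamics_record(pa$t1, pa$t1, align = FALSE)
  expect_equal(rec$S, rec$T1)
  expect_equal(rec$E, 0L)
  expect_equal(rec$A, 0L)
  expect_equal(rec$pct_eliminated, 0)
  expect_equal(rec$ratio_tips, 1)
  expect_equal(rec$delta_length_um, 0)
})

test_that("generator labels are recovered on noiseless skeleton pairs", {
  pa <- paired_arbors(seed = 63, tips = 100L, p_elim = 0.2, p_add = 0.2,
                      offset = c(4, -2))
  cnt <- pa$labels$counts
  rec <- dynamics_record(pa$t1, pa$t2)
  expect_equal(c(rec$offset[["dx"]], rec$offset[["dy"]]), c(4, -2))
  expect_equal(rec$T1, cnt[["T1"]])
  expect_equal(rec$T2, cnt[["T2"]])
  expect_equal(rec$E, cnt[["eliminated"]], tolerance = 0.03 * cnt[["T1"]])
  expect_equal(rec$A, cnt[["added"]], tolerance = 0.03 * cnt[["T2"]])
  expect_equal(rec$pct_eliminated, 100 * cnt[["eliminated"]] / cnt[["T1"]],
               tolerance = 3)
  # conservation identities hold exactly
  expect_identical(rec$S + rec$E, rec$T1)
  expect_identical(rec$S + rec$A, rec$T2)
})

test_that("deltas and ratios follow the arithmetic definitions", {
  pa <- paired_arbors(seed = 64, p_elim = 0.1, p_add = 0.1)
  rec <- dynamics_record(pa$t1, pa$t2)
  L1 <- total_length(pa$t1); L2 <- total_length(pa$t2)
  expect_equal(rec$delta_length_um, L2 - L1)
  expect_equal(rec$ratio_length, L2 / L1)
  expect_equal(rec$delta_tips, rec$T2 - rec$T1)
  expect_equal(rec$ratio_tips, rec$T2 / rec$T1)
})

test_that("swapping time points swaps eliminations and additions", {
  pa <- paired_arbors(seed = 65, p_elim = 0.2, p_add = 0.1, offset = c(0, 0))
  f <- dynamics_record(pa$t1, pa$t2, align = FALSE)
  b <- dynamics_record(pa$t2, pa$t1, align = FALSE)
  expect_equal(b$E, f$A, tolerance = 2)
  expect_equal(b$A, f$E, tolerance = 2)
  expect_equal(b$ratio_length, 1 / f$ratio_length, tolerance = 1e-6)
})

test_that("a neuron dead at t2 yields S=0, E=T1, A=0, flagged", {
  pa <- paired_arbors()
  rec <- dynamics_record(pa$t1, dendromorph:::empty_skeleton())
  expect_true(rec$dead)
  expect_equal(rec$S, 0L)
  expect_equal(rec$E, rec$T1)
  expect_equal(rec$A, 0L)
  expect_equal(rec$pct_eliminated, 100)
})

test_that("survival table arithmetic", {
  tab <- survival_rate(rep(TRUE, 10))
  expect_equal(tab$survival_pct, 100)
  tab2 <- survival_rate(rep(FALSE, 12))
  expect_equal(tab2$survival_pct, 0)
  tab3 <- survival_rate(c(rep(TRUE, 13), rep(FALSE, 2)))
  expect_equal(tab3$survival_pct, 86.67, tolerance = 0.01)
  mixed <- survival_rate(c(TRUE, TRUE, FALSE, TRUE),
                         condition = c("a", "a", "b", "b"))
  expect_equal(mixed$n_alive[mixed$condition == "a"], 2L)
  expect_equal(mixed$survival_pct[mixed$condition == "b"], 50)
})
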