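test_that("SWC roundtrip preserves geometry and topology", {
  sk <- tiny_arbor(1)
  f <- tempfile(fileext = ".swc")
  write_swc(sk, f)
  sk2 <- read_swc(f, px_per_um = sk$px_per_um)
  expect_equal(sk2$nodes$x, sk$nodes$x, tolerance = 1e-4)
  expect_equal(sk2$nodes$y, sk$nodes$y, tolerance = 1e-4)
  expect_equal(sk2$root, sk$root)
  expect_equal(total_length(sk2), total_length(sk), tolerance = 1e-4)
})

test_that("PGM roundtrip (binary and ascii) is lossless at 16 bit", {
  m <- matrix(runif(30 * 20), 30, 20)
  f <- tempfile(fileext = ".pgm")
  write_pgm(m, f, maxval = 65535L)
  expect_equal(read_pgm(f), m, tolerance = 1 / 65535)
  write_pgm(m, f, maxval = 255L, ascii = TRUE)
  expect_equal(read_pgm(f), m, tolerance = 1 / 255)
})

test_that("unpaired dataset writes n image/mask/SWC triples plus manifest", {
  out <- file.path(tempdir(), "ds1")
  man_f <- make_dataset(tiny_spec(21), 3, paired = FALSE, out_dir = out)
  man <- read.csv(man_f)
  expect_equal(nrow(man), 3L)
  for (col in c("image", "mask", "swc")) {
    expect_true(all(file.exists(file.path(out, man[[col]]))))
  }
})

test_that("paired dataset rows carry t1/t2 files, labels and truth counts", {
  out <- file.path(tempdir(), "ds2")
  man_f <- make_dataset(tiny_spec(22), 2, paired = TRUE, out_dir = out,
                        p_elim = 0.2, p_add = 0.1)
  man <- read.csv(man_f)
  expect_equal(nrow(man), 2L)
  need <- c("image_t1", "image_t2", "mask_t1", "mask_t2", "swc_t1", "swc_t2",
            "labels", "offset_dx", "gt_stable", "gt_eliminated", "gt_added")
  expect_true(all(need %in% names(man)))
  expect_true(all(file.exists(file.path(out, man$labels))))
  lab <- read.csv(file.path(out, man$labels[1]))
  expect_setequal(unique(lab$timepoint), c("t1", "t2"))
  # conservation recorded in the manifest
  expect_equal(man$gt_stable + man$gt_eliminated, man$gt_tips_t1)
  expect_equal(man$gt_stable + man$gt_added, man$gt_tips_t2)
})

test_that("manifest ground truth matches an independent SWC re-read", {
  out <- file.path(tempdir(), "ds3")
  man_f <- make_dataset(tiny_spec(23), 3, paired = FALSE, out_dir = out)
  man <- read.csv(man_f)
  for (i in seq_len(nrow(man))) {
    tab <- read.table(file.path(out, man$swc[i]), comment.char = "#")
    names(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
    # oracle: leaves = ids that are nobody's parent, excluding the root
    leaves <- setdiff(tab$id[!tab$id %in% tab$parent], tab$id[tab$parent == -1])
    expect_equal(man$gt_tips[i], length(leaves))
    # oracle: sum of parent-child Euclidean distances (µm)
    ii <- tab$parent != -1
    pi <- match(tab$parent[ii], tab$id)
    len <- sum(sqrt((tab$x[ii] - tab$x[pi])^2 + (tab$y[ii] - tab$y[pi])^2))
    expect_equal(man$gt_length_um[i], len, tolerance = 1e-3)
  }
})
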