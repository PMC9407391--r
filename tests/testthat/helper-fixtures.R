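# Shared fixtures. Everything is generated in code; expensive objects are
# memoized per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small fast spec for unit tests
tiny_spec <- function(seed = 1, ...) {
  synthetic_spec(field_size_px = 256L, target_tips = 30L, margin_px = 10,
                 seed = seed, ...)
}

tiny_arbor <- function(seed = 1) {
  cached(paste0("arbor", seed), generate_arbor(tiny_spec(seed)))
}

# noiseless render of the tiny arbor (support == mask)
tiny_noiseless <- function(seed = 1) {
  cached(paste0("noiseless", seed), {
    sp <- update_spec(tiny_spec(seed), noise_sd = 0, debris_rate = 0,
                      psf_sigma_px = 0)
    render_arbor(generate_arbor(sp), sp)
  })
}

# a trained segmenter shared by model and acceptance tests (small corpus)
shared_model <- function() {
  cached("model", {
    dir <- file.path(tempdir(), "dendromorph_train")
    spec <- synthetic_spec(seed = 7000, field_size_px = 384L,
                           target_tips = 70L, margin_px = 12)
    man <- make_dataset(spec, 10, paired = FALSE, out_dir = dir)
    train_segmenter(man, segmenter_config(hidden = 16L, epochs = 8L, seed = 2))
  })
}

# leaves of a tree-structured skeleton, counted independently of tip_ids
tree_leaves <- function(skel) {
  ids <- skel$nodes$id
  setdiff(ids[!ids %in% skel$nodes$parent], skel$root)
}

expect_same_skeleton <- function(a, b) {
  expect_equal(a$nodes$x, b$nodes$x)
  expect_equal(a$nodes$y, b$nodes$y)
  expect_equal(a$edges, b$edges)
}
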