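test_that("scene generation is deterministic and respects the 60x60/[0,1] contract", {
  a <- generate_scene("mC", scene_params(), seed = 3)
  b <- generate_scene("mC", scene_params(), seed = 3)
  expect_identical(a$image, b$image)
  expect_identical(dim(a$image), c(60L, 60L))
  expect_true(all(a$image >= 0 & a$image <= 1))
  d <- generate_scene("mC", scene_params(), seed = 4)
  expect_false(identical(a$image, d$image))
})

test_that("rendered cell counts match the label contract (brute-force components)", {
  p <- scene_params()
  for (seed in 1:15) {
    expect_equal(cc_count(generate_scene("nC", p, seed)$mask), 0)
    expect_equal(cc_count(generate_scene("mC", p, seed)$mask), 1)
    expect_equal(cc_count(generate_scene("mduC", p, seed)$mask), 2)
    expect_equal(cc_count(generate_scene("mddC", p, seed)$mask), 2)
    expect_gte(cc_count(generate_scene("exC", p, seed)$mask), 3)
  }
  # hard mode keeps the same guarantees
  ph <- scene_params(hard = TRUE)
  for (seed in 1:10) {
    expect_equal(cc_count(generate_scene("mduC", ph, seed)$mask), 2)
    expect_gte(cc_count(generate_scene("exC", ph, seed)$mask), 3)
  }
})

test_that("daughter orientation matches the label in the pre-noise mask", {
  for (p in list(scene_params(), scene_params(hard = TRUE))) {
    for (seed in c(7, 1:12)) {
      s <- generate_scene("mddC", p, seed)
      rows <- cc_centroid_rows(s$mask)
      # mother is the larger component; daughter centroid strictly below
      lab <- cc_label(s$mask)
      sizes <- tabulate(lab[lab > 0])
      mother <- which.max(sizes)
      daughter <- setdiff(seq_along(sizes), mother)
      expect_gt(rows[daughter], rows[mother])

      s2 <- generate_scene("mduC", p, seed)
      lab2 <- cc_label(s2$mask)
      rows2 <- cc_centroid_rows(s2$mask)
      sizes2 <- tabulate(lab2[lab2 > 0])
      mother2 <- which.max(sizes2)
      expect_lt(rows2[setdiff(seq_along(sizes2), mother2)], rows2[mother2])
    }
  }
})

test_that("invalid labels and degenerate parameters are rejected", {
  expect_error(generate_scene("bogus", scene_params(), 1), "unknown")
  expect_error(scene_params(mother_radius_range = c(5, 3)), "low <= high")
  expect_error(scene_params(daughter_radius_range = c(4, 9)), "strictly below")
  expect_error(scene_params(noise_sigma = 2), "out of")
})

test_that("dataset generation stratifies splits within one image per category", {
  ds <- generate_dataset(100, scene_params(), c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(dataset_size(ds), 500)
  tab <- table(ds$labels, ds$split)
  for (cat in category5_levels()) {
    expect_lte(abs(tab[cat, "train"] - 60), 1)
    expect_lte(abs(tab[cat, "val"] - 20), 1)
    expect_lte(abs(tab[cat, "test"] - 20), 1)
  }
  # disjoint and exhaustive by construction: every image has exactly one split
  expect_true(all(ds$split %in% c("train", "val", "test")))
})

test_that("dataset generation honors uneven counts and the trivial split", {
  ds <- generate_dataset(c(nC = 1), scene_params(), c(1, 0, 0), seed = 2)
  expect_equal(dataset_size(ds), 1)
  expect_equal(ds$split, "train")
  expect_equal(ds$labels, "nC")
  expect_error(generate_dataset(10, scene_params(), c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
})

test_that("identical seeds reproduce identical datasets, split assignment included", {
  a <- generate_dataset(20, scene_params(), c(0.6, 0.2, 0.2), seed = 5)
  b <- generate_dataset(20, scene_params(), c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(a$images, b$images)
  expect_identical(a$split, b$split)
  expect_identical(a$provenance, b$provenance)
})

test_that("default dataset scale states the published collection size", {
  # 1,000 per category over 5 categories; checked via split arithmetic only
  sizes <- trapnet:::split_sizes(1000, c(3078, 1026, 896) / 5000)
  expect_equal(sum(sizes), 1000)
  total <- sizes * 5
  expect_equal(sum(total), 5000)
  # stratified rounding lands within 5 images of the published 3078/1026/896
  expect_lte(max(abs(total - c(3078, 1026, 896))), 5)
})
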