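test_that("frame partitioning returns pure crops in anchor order", {
  set.seed(1)
  frame <- matrix(runif(960 * 1280), 960, 1280)
  # 104 anchors laid out as a 13 x 8 grid
  grid <- expand.grid(row = seq(0, 900, length.out = 8),
                      col = seq(0, 1220, length.out = 13))
  spec <- frame_partition_spec(data.frame(row = round(grid$row),
                                          col = round(grid$col)))
  tiles <- partition_frame(frame, spec)
  expect_equal(dim(tiles), c(60, 60, 104))
  # identity crop at (0,0)
  one <- frame_partition_spec(data.frame(row = 0, col = 0))
  t1 <- partition_frame(frame, one)
  expect_identical(t1[, , 1], frame[1:60, 1:60])
  # pure-crop invariant: tile pixel sums equal frame block sums
  for (i in c(1, 50, 104)) {
    r0 <- spec$anchors$row[i]; c0 <- spec$anchors$col[i]
    expect_equal(sum(tiles[, , i]),
                 sum(frame[(r0 + 1):(r0 + 60), (c0 + 1):(c0 + 60)]))
  }
})

test_that("out-of-bounds anchors and wrong frame sizes are rejected", {
  expect_error(frame_partition_spec(data.frame(row = 901, col = 0)),
               "index: 1")
  expect_error(frame_partition_spec(data.frame(row = c(0, 0), col = c(0, 1221))),
               "index: 2")
  spec <- frame_partition_spec(data.frame(row = 0, col = 0))
  expect_error(partition_frame(matrix(0, 100, 100), spec), "expects 960x1280")
})

test_that("PGM round trip preserves 8-bit images (both encodings)", {
  img <- matrix(round(runif(60 * 60) * 255) / 255, 60, 60)
  for (ascii in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".pgm")
    write_pgm(img, f, ascii = ascii)
    back <- read_pgm(f)
    expect_equal(back, img, tolerance = 1e-12)
    unlink(f)
  }
})

test_that("manifest save/load round-trips a dataset", {
  ds <- tiny_dataset()
  dir <- tempfile()
  mp <- save_manifest(ds, dir)
  back <- load_manifest(mp)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$split, ds$split)
  # 8-bit quantization: within half a grey level
  expect_lt(max(abs(back$images - ds$images)), 0.5 / 255 + 1e-9)
  # saving the loaded dataset reproduces the manifest exactly
  dir2 <- tempfile()
  mp2 <- save_manifest(back, dir2)
  expect_identical(readLines(mp), readLines(mp2))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("malformed manifests are rejected with the offending row or path", {
  dir <- tempfile(); dir.create(file.path(dir, "images"), recursive = TRUE)
  write_pgm(matrix(0.5, 60, 60), file.path(dir, "images", "ok.pgm"))
  man <- data.frame(path = "images/ok.pgm", label5 = "xyz", split = "train")
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  expect_error(load_manifest(mp), "row 1")

  # non-60x60 image named by path
  write_pgm(matrix(0.5, 61, 60), file.path(dir, "images", "bad.pgm"))
  man <- data.frame(path = "images/bad.pgm", label5 = "nC", split = "train")
  write.csv(man, mp, row.names = FALSE)
  expect_error(load_manifest(mp), "bad.pgm")
  expect_error(load_manifest(file.path(dir, "missing.csv")), "no such manifest")
  unlink(dir, recursive = TRUE)
})

test_that("dataset directory summaries report split sizes from the manifest", {
  # synthetic stand-in mirroring the published collection's manifest layout
  dir <- tempfile(); dir.create(dir)
  n <- c(train = 3078, val = 1026, test = 896)
  man <- data.frame(
    path = sprintf("images/img%05d.pgm", seq_len(sum(n))),
    label5 = rep(category5_levels(), length.out = sum(n)),
    split = rep(names(n), times = n))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  info <- load_trap_dataset_dir(dir)
  expect_equal(info$n_total, 5000)
  expect_equal(info$n_train, 3078)
  expect_equal(info$n_val, 1026)
  expect_equal(info$n_test, 896)
  unlink(dir, recursive = TRUE)
})
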