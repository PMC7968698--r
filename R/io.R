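#' Read and write portable graymap (PGM) images
#'
#' Single-channel images are stored as PGM, either ASCII (`P2`) or binary
#' (`P5`). Intensities are rescaled to `[0,1]` on read (by the file's
#' maxval, so 8-bit and 16-bit files both normalize correctly); writing
#' quantizes to 8-bit. This is the single intensity-normalization entry
#' point: everything downstream assumes images in `[0,1]`.
#'
#' @param path file path.
#' @param img numeric matrix with values in `[0,1]`.
#' @param ascii write ASCII `P2` (default) or binary `P5`.
#' @return `read_pgm` returns a numeric matrix in `[0,1]`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- ""
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0 || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (ch %in% c("\n", "") || length(ch) == 0) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) {
        tokens <- c(tokens, as.integer(buf))
        buf <- ""
      }
    } else buf <- paste0(buf, ch)
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval < 256) {
      as.integer(readBin(con, "raw", n))
    } else {
      readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
    }
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PGM payload: ", path)
  # PGM is row-major (English reading order); R matrices are column-major
  t(matrix(vals, nrow = w, ncol = h)) / maxval
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, ascii = TRUE) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 1) * 255)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(q), file = con, ncolumns = ncol(img))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", ncol(img), " ", nrow(img), "\n255\n"), con, eos = NULL)
    writeBin(as.raw(as.vector(t(q))), con)
  }
  invisible(path)
}

#' Frame partition specification
#'
#' Describes how a full time-lapse frame (default 1280x960, holding ~104
#' traps) is cut into 60x60 trap sub-images. Anchors are 0-based
#' `(row, col)` top-left coordinates of each tile, row-major convention.
#' Trap anchor positions are supplied (e.g. from a coordinate CSV), not
#' auto-detected.
#'
#' @param anchors data frame or matrix with columns `row`, `col` (0-based).
#' @param frame_width,frame_height frame dimensions in pixels.
#' @param tile_size tile side in pixels, default 60.
#' @return A list of class `frame_partition_spec`.
#' @export
frame_partition_spec <- function(anchors, frame_width = 1280,
                                 frame_height = 960, tile_size = 60) {
  anchors <- as.data.frame(anchors)
  if (!all(c("row", "col") %in% names(anchors))) {
    stop("anchors need 'row' and 'col' columns")
  }
  bad <- which(anchors$row < 0 | anchors$row > frame_height - tile_size |
               anchors$col < 0 | anchors$col > frame_width - tile_size)
  if (length(bad)) {
    stop("anchor(s) out of bounds at index: ", paste(bad, collapse = ", "))
  }
  structure(list(anchors = anchors, frame_width = frame_width,
                 frame_height = frame_height, tile_size = tile_size),
            class = "frame_partition_spec")
}

#' Partition a full frame into trap sub-images
#'
#' Pure crops: tile `i` is exactly the frame block whose top-left corner is
#' anchor `i`, in anchor order.
#'
#' @param frame single-channel numeric matrix matching the spec dimensions.
#' @param spec a [frame_partition_spec()].
#' @return A `tile_size` x `tile_size` x n array of tiles.
#' @export
partition_frame <- function(frame, spec) {
  stopifnot(inherits(spec, "frame_partition_spec"))
  if (nrow(frame) != spec$frame_height || ncol(frame) != spec$frame_width) {
    stop("frame is ", nrow(frame), "x", ncol(frame), " but spec expects ",
         spec$frame_height, "x", spec$frame_width)
  }
  ts <- spec$tile_size
  n <- nrow(spec$anchors)
  tiles <- array(0, c(ts, ts, n))
  for (i in seq_len(n)) {
    r0 <- spec$anchors$row[i]
    c0 <- spec$anchors$col[i]
    tiles[, , i] <- frame[(r0 + 1):(r0 + ts), (c0 + 1):(c0 + ts)]
  }
  tiles
}

#' Read a trap-anchor coordinate CSV
#'
#' Expects columns `row,col`, 0-based top-left tile coordinates.
#' @param path CSV path.
#' @param ... forwarded to [frame_partition_spec()].
#' @export
read_anchors <- function(path, ...) {
  frame_partition_spec(utils::read.csv(path), ...)
}

#' Save / load a labeled dataset as images plus a manifest CSV
#'
#' `save_manifest` writes each image as an 8-bit PGM under `dir/images/`
#' and a `manifest.csv` with columns `path,label5,split`. `load_manifest`
#' reads it back; the round trip is lossless on the manifest and 8-bit
#' lossless on images. Unknown label strings and images that are not
#' 60x60 are rejected with the offending row or path.
#'
#' @param ds a `trap_dataset`.
#' @param dir output directory (created if absent).
#' @param path path to a `manifest.csv` (image paths resolved relative to
#'   its directory).
#' @return `save_manifest` returns the manifest path; `load_manifest`
#'   returns a `trap_dataset`.
#' @export
save_manifest <- function(ds, dir) {
  stopifnot(inherits(ds, "trap_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- dataset_size(ds)
  rel <- sprintf("images/img%05d.pgm", seq_len(n))
  for (i in seq_len(n)) write_pgm(ds$images[, , i], file.path(dir, rel[i]))
  man <- data.frame(path = rel, label5 = ds$labels, split = ds$split)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label5") %in% names(man))) {
    stop("manifest needs 'path' and 'label5' columns")
  }
  bad <- which(!man$label5 %in% category5_levels())
  if (length(bad)) {
    stop("unknown label '", man$label5[bad[1]], "' in manifest row ", bad[1])
  }
  base <- dirname(path)
  n <- nrow(man)
  images <- array(0, c(TILE, TILE, n))
  for (i in seq_len(n)) {
    img <- read_pgm(file.path(base, man$path[i]))
    if (nrow(img) != TILE || ncol(img) != TILE) {
      stop("image is not 60x60: ", man$path[i])
    }
    images[, , i] <- img
  }
  split <- if ("split" %in% names(man)) man$split else rep("train", n)
  new_trap_dataset(images, man$label5, split)
}

#' Summarize a dataset directory's split sizes
#'
#' Reads `manifest.csv` in `dir` (as written by [save_manifest()], or any
#' manifest with `path,label5,split` columns such as one accompanying the
#' published trap-image collection) and reports the number of images per
#' split and per category without loading pixel data.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return A list with `n_total`, `n_train`, `n_val`, `n_test`, and a
#'   `per_category` table.
#' @export
load_trap_dataset_dir <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv under ", dir)
  man <- utils::read.csv(mp, stringsAsFactors = FALSE)
  if (!all(c("path", "label5", "split") %in% names(man))) {
    stop("manifest needs path,label5,split columns")
  }
  bad <- which(!man$label5 %in% category5_levels())
  if (length(bad)) {
    stop("unknown label '", man$label5[bad[1]], "' in manifest row ", bad[1])
  }
  list(n_total = nrow(man),
       n_train = sum(man$split == "train"),
       n_val = sum(man$split == "val"),
       n_test = sum(man$split == "test"),
       per_category = table(label = man$label5, split = man$split))
}
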