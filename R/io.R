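# File formats: the two-header trajectory CSV dialect, landmark/table/pose
# CSVs, raster frame directories, and the pipeline configuration.
#
# All CSVs are comma-separated with '.' decimal separator, locale-independent.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read / write a landmark trajectory file
#'
#' The trajectory dialect stores one landmark track per file: the rotation
#' radius of the landmark on the first line, the landmark's 2D coordinate at
#' the reference position on the second line, and one 2D coordinate per frame
#' (relative to the center of eye rotation) on each following line.
#' `write_trajectory` followed by `read_trajectory` is the identity to full
#' double precision.
#'
#' @param path file path.
#' @param radius rotation radius in pixels (line 1).
#' @param reference length-2 reference coordinate (line 2).
#' @param coords n x 2 matrix of per-frame coordinates.
#' @return `read_trajectory` returns a list with `radius`, `reference`,
#'   `coords`; `write_trajectory` returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop_vog("trajectory file needs a radius line, a reference line and data rows",
             "vog3d_parse_error")
  parse_row <- function(line, nfield, lineno) {
    f <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != nfield || any(!is.finite(v)))
      stop_vog(sprintf("parse error at line %d: expected %d numeric fields",
                       lineno, nfield), "vog3d_parse_error")
    v
  }
  radius <- parse_row(lines[1], 1, 1)
  reference <- parse_row(lines[2], 2, 2)
  dat <- lines[-(1:2)]
  coords <- matrix(NA_real_, length(dat), 2)
  for (i in seq_along(dat)) coords[i, ] <- parse_row(dat[i], 2, i + 2)
  list(radius = radius, reference = reference, coords = coords)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(path, radius, reference, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2)
    stop_vog("coords must have two columns", "vog3d_input_error")
  lines <- c(fmt_num(radius),
             paste(fmt_num(reference), collapse = ","),
             apply(coords, 1, function(r) paste(fmt_num(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Landmark, table and pose CSV files
#'
#' Plain header CSVs for the intermediate pipeline products: the per-frame
#' landmark table (`t, yp, zp, major_len, minor_len, orientation, yi, zi`),
#' the turntable angle series (`t, angle`), and the reconstructed pose series
#' (`t, rx, ry, rz`, one rotation vector per frame).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return read functions return a data.frame; write functions return `path`
#'   invisibly.
#' @export
write_landmarks <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) utils::read.csv(path)

#' @rdname write_landmarks
#' @export
write_table_series <- function(x, path) {
  utils::write.csv(x[, c("t", "angle")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_table_series <- function(path) utils::read.csv(path)

#' @rdname write_landmarks
#' @export
write_poses <- function(x, path) {
  utils::write.csv(x[, c("t", "rx", "ry", "rz")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_poses <- function(path) utils::read.csv(path)

#' Read / write gray-image frames
#'
#' Frames are exchanged as PNG files in a directory, processed in
#' lexicographic order. Raster rows run top-down, while the package works
#' z-up, so images are flipped once here at the IO boundary.
#'
#' @param dir directory of .png frames / target directory.
#' @param frames list of gray image matrices (values 0..255, z-up).
#' @param prefix file-name prefix for written frames.
#' @return `read_frames` returns a list of matrices; `write_frames` the file
#'   paths, invisibly.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    stop_vog(paste("no PNG frames in", dir), "vog3d_input_error")
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a[rev(seq_len(nrow(a))), , drop = FALSE] * 255
  })
}

#' @rdname read_frames
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    img <- frames[[i]] / 255
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    paths[i] <- file.path(dir, sprintf("%s_%06d.png", prefix, i))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}

#' Read a pipeline configuration file
#'
#' The configuration is YAML with blocks for the eye model, the simulated
#' motions, detection thresholds/ROIs, and fit options; every command-line
#' stage takes its parameters from here so a run is reproducible from config
#' plus seed alone.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$frame_rate)) cfg$frame_rate <- 240
  cfg
}
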