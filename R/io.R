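#' Read and write joint-angle series as CSV
#'
#' Comma-separated, '.' decimal, one row per frame, named columns
#' (ankle, knee, hip, LS, C7, AO).  Sampling rate and units are recorded in
#' a leading header comment line `# fs_hz=<fs> units=deg`, which the reader
#' parses back.
#'
#' @param x a `joint_angle_series`.
#' @param path file path.
#' @return `write_angles_csv` returns `path` invisibly; `read_angles_csv`
#'   returns a `joint_angle_series`.
#' @export
write_angles_csv <- function(x, path) {
  stopifnot(inherits(x, "joint_angle_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g units=deg", x$fs), con)
  utils::write.csv(as.data.frame(x$values), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- .parse_fs_header(header, path)
  df <- utils::read.csv(path, comment.char = "#")
  joint_angle_series(as.matrix(df), fs = fs)
}

.parse_fs_header <- function(header, path) {
  m <- regmatches(header, regexec("fs_hz=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) {
    stop("missing '# fs_hz=... units=deg' header line in ", path)
  }
  as.numeric(m[2])
}

#' Read and write sagittal marker frames as CSV
#'
#' One row per frame; columns `<point>_x`, `<point>_y` (mm) for each chain
#' point.  Sampling rate and units go in a `# fs_hz=<fs> units=mm` header
#' comment line.
#'
#' @param frames a `marker_frames`.
#' @param path file path.
#' @export
write_markers_csv <- function(frames, path) {
  stopifnot(inherits(frames, "marker_frames"))
  cols <- do.call(cbind, lapply(names(frames$points), function(nm) {
    p <- frames$points[[nm]]
    colnames(p) <- paste0(nm, c("_x", "_y"))
    p
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g units=mm", frames$fs), con)
  utils::write.csv(as.data.frame(cols), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path) {
  fs <- .parse_fs_header(readLines(path, n = 1L), path)
  df <- utils::read.csv(path, comment.char = "#")
  pts <- lapply(MARKER_POINTS, function(nm) {
    as.matrix(df[, paste0(nm, c("_x", "_y"))])
  })
  names(pts) <- MARKER_POINTS
  marker_frames(pts, fs = fs)
}

#' Read and write marker frames in TRC format
#'
#' Tab-delimited TRC (Track Row Column) motion-capture format with the
#' standard 5-line header (DataRate, marker names, X/Y/Z column labels).
#' The sagittal plane is embedded as X = anterior, Y = vertical, Z = 0; on
#' reading, Z is dropped.  Units are mm.
#'
#' @param frames a `marker_frames`.
#' @param path file path.
#' @export
write_trc <- function(frames, path) {
  stopifnot(inherits(frames, "marker_frames"))
  nm <- names(frames$points)
  n <- frames$n_frames
  fs <- frames$fs
  h1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  h2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
              "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
  h3 <- sprintf("%.10g\t%.10g\t%d\t%d\tmm\t%.10g\t1\t%d", fs, fs, n,
                length(nm), fs, n)
  h4 <- paste(c("Frame#", "Time", as.vector(rbind(nm, "", ""))), collapse = "\t")
  h5 <- paste(c("", "", as.vector(t(outer(seq_along(nm), c("X", "Y", "Z"),
                                          function(i, a) paste0(a, i))))),
              collapse = "\t")
  coords <- do.call(cbind, lapply(frames$points, function(p) {
    cbind(p[, 1], p[, 2], 0)
  }))
  body <- cbind(seq_len(n), (seq_len(n) - 1) / fs, coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(h1, h2, h3, h4, h5), con)
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_trc
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("read_trc: truncated TRC file")
  meta <- strsplit(lines[3], "\t")[[1]]
  fs <- as.numeric(meta[1])
  nm <- strsplit(lines[4], "\t")[[1]]
  nm <- nm[-(1:2)]
  nm <- nm[nzchar(nm)]
  body <- utils::read.table(text = lines[-(1:5)], sep = "\t")
  pts <- lapply(seq_along(nm), function(i) {
    as.matrix(body[, 2 + (i - 1) * 3 + (1:2)])
  })
  names(pts) <- nm
  marker_frames(pts, fs = fs)
}
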