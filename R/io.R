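#' Read a point cloud from LAS, PLY or CSV
#'
#' Coordinates are returned in metres. If an intensity channel is present it
#' is min-max normalised to \[0, 1\] per cloud; the `source` tag is inferred
#' from the channels present (colour implies drone, intensity implies lidar)
#' unless overridden.
#'
#' LAS support covers the uncompressed LAS 1.2 core (point record formats
#' 0--3, the subset this pipeline writes and reads back); PLY support covers
#' ascii and binary little-endian vertex elements.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"las"`, `"ply"` or `"csv"`.
#' @param source optional override for the source tag.
#' @return a [point_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "las", "ply", "csv"),
                       source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", laz = "las", ply = "ply",
                     csv = "csv", txt = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         csv = read_cloud_csv(path, source),
         ply = read_cloud_ply(path, source),
         las = read_cloud_las(path, source))
}

#' Write a point cloud to LAS, PLY or CSV
#'
#' @param pc a [point_cloud()].
#' @param path destination path.
#' @param format `"auto"` (by extension), `"las"`, `"ply"` or `"csv"`.
#' @param binary for PLY: write binary little-endian instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(pc, path, format = c("auto", "las", "ply", "csv"),
                        binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", ply = "ply", csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         csv = write_cloud_csv(pc, path),
         ply = write_cloud_ply(pc, path, binary),
         las = write_cloud_las(pc, path))
  invisible(path)
}

read_cloud_csv <- function(path, source) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("CSV cloud is missing coordinate column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  icol <- intersect(c("i", "intensity"), names(df))[1]
  has_rgb <- all(c("r", "g", "b") %in% names(df))
  point_cloud(as.matrix(df[, need]),
              intensity = if (!is.na(icol)) df[[icol]],
              rgb = if (has_rgb) as.matrix(df[, c("r", "g", "b")]),
              source = source)
}

write_cloud_csv <- function(pc, path) {
  df <- as.data.frame(pc$coords)
  if (!is.null(pc$intensity)) df$i <- pc$intensity
  if (!is.null(pc$rgb)) {
    df$r <- pc$rgb[, 1]; df$g <- pc$rgb[, 2]; df$b <- pc$rgb[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# ---- PLY -------------------------------------------------------------------

read_cloud_ply <- function(path, source) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NULL; props <- character(0); in_vertex <- FALSE
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("PLY header truncated")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, paste(tok[2], tok[3]))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) stop("PLY file has no vertex element")
  pnames <- vapply(strsplit(props, " "), `[`, "", 2)
  ptypes <- vapply(strsplit(props, " "), `[`, "", 1)
  if (identical(fmt, "ascii")) {
    dat <- matrix(scan(con, what = numeric(), n = nvert * length(props),
                       quiet = TRUE), ncol = length(props), byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    rdr <- list(float = function() readBin(con, "double", 1, 4, endian = "little"),
                double = function() readBin(con, "double", 1, 8, endian = "little"),
                uchar = function() readBin(con, "integer", 1, 1, signed = FALSE),
                uint8 = function() readBin(con, "integer", 1, 1, signed = FALSE))
    dat <- matrix(0, nvert, length(props))
    for (i in seq_len(nvert)) for (j in seq_along(props)) {
      f <- rdr[[ptypes[j]]]
      if (is.null(f)) stop("unsupported PLY property type: ", ptypes[j])
      dat[i, j] <- f()
    }
  } else stop("unsupported PLY format: ", fmt)
  colnames(dat) <- pnames
  has_rgb <- all(c("red", "green", "blue") %in% pnames)
  point_cloud(dat[, c("x", "y", "z"), drop = FALSE],
              intensity = if ("intensity" %in% pnames) dat[, "intensity"],
              rgb = if (has_rgb)
                dat[, c("red", "green", "blue"), drop = FALSE],
              source = source)
}

write_cloud_ply <- function(pc, path, binary = FALSE) {
  n <- npoints(pc)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(pc$intensity)) props <- c(props, "property float intensity")
  if (!is.null(pc$rgb))
    props <- c(props, paste("property uchar", c("red", "green", "blue")))
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", n), props, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(pc$coords[i, ]), con, size = 4, endian = "little")
      if (!is.null(pc$intensity))
        writeBin(as.numeric(pc$intensity[i]), con, size = 4,
                 endian = "little")
      if (!is.null(pc$rgb))
        writeBin(as.integer(pc$rgb[i, ]), con, size = 1)
    }
  } else {
    cols <- list(pc$coords[, 1], pc$coords[, 2], pc$coords[, 3])
    fmtv <- c("%.8g", "%.8g", "%.8g")
    if (!is.null(pc$intensity)) { cols <- c(cols, list(pc$intensity)); fmtv <- c(fmtv, "%.8g") }
    if (!is.null(pc$rgb)) {
      cols <- c(cols, list(pc$rgb[, 1], pc$rgb[, 2], pc$rgb[, 3]))
      fmtv <- c(fmtv, "%d", "%d", "%d")
    }
    lines <- do.call(sprintf, c(list(paste(fmtv, collapse = " ")), cols))
    writeLines(lines, con)
  }
}

# ---- LAS 1.2 (uncompressed, point formats 0-3) -----------------------------

read_cloud_las <- function(path, source) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file (bad signature): ", path)
  seek(con, 96)
  off_data <- readBin(con, "integer", 1, 4, endian = "little")
  seek(con, 104)
  pfmt <- readBin(con, "integer", 1, 1, signed = FALSE)
  reclen <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  npts <- readBin(con, "integer", 1, 4, endian = "little")
  seek(con, 131)
  scale <- readBin(con, "double", 3, 8, endian = "little")
  offset <- readBin(con, "double", 3, 8, endian = "little")
  if (!pfmt %in% 0:3) stop("unsupported LAS point format: ", pfmt)
  seek(con, off_data)
  raw <- readBin(con, "raw", npts * reclen)
  if (length(raw) < npts * reclen) stop("LAS point data truncated")
  rec <- matrix(raw, nrow = reclen)
  int32 <- function(rows) {
    b <- rec[rows, , drop = FALSE]
    v <- readBin(as.vector(b), "integer", npts, 4, endian = "little")
    v
  }
  uint16 <- function(rows) {
    b <- rec[rows, , drop = FALSE]
    readBin(as.vector(b), "integer", npts, 2, signed = FALSE,
            endian = "little")
  }
  coords <- cbind(int32(1:4) * scale[1] + offset[1],
                  int32(5:8) * scale[2] + offset[2],
                  int32(9:12) * scale[3] + offset[3])
  intensity <- uint16(13:14)
  rgb <- NULL
  if (pfmt %in% c(2, 3)) {
    base <- if (pfmt == 2) 20 else 28
    rgb <- cbind(uint16(base + 1:2), uint16(base + 3:4), uint16(base + 5:6))
    rgb <- round(rgb / 257)   # LAS stores 16-bit colour
  }
  if (all(intensity == 0)) intensity <- NULL
  point_cloud(coords, intensity = intensity, rgb = rgb, source = source)
}

write_cloud_las <- function(pc, path) {
  n <- npoints(pc)
  has_rgb <- !is.null(pc$rgb)
  pfmt <- if (has_rgb) 2L else 0L
  reclen <- if (has_rgb) 26L else 20L
  scale <- c(0.001, 0.001, 0.001)
  offset <- if (n > 0) floor(apply(pc$coords, 2, min)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("LASF", con, 4, eos = NULL)
  wb(c(0L, 0L), 2)                      # source id, global encoding
  wb(integer(4), 4)                     # GUID (16 bytes)
  writeBin(as.raw(c(1, 2)), con)        # version 1.2
  writeChar(formatC("canopy3d", width = 32), con, 32, eos = NULL)
  writeChar(formatC("canopy3d", width = 32), con, 32, eos = NULL)
  wb(c(1L, 2026L), 2)                   # day, year
  wb(227L, 2)                           # header size
  wb(227L, 4)                           # offset to point data
  wb(0L, 4)                             # number of VLRs
  writeBin(as.raw(pfmt), con)
  wb(reclen, 2)
  wb(n, 4)
  wb(integer(5), 4)                     # points by return
  wb(scale, 8)
  wb(offset, 8)
  bb <- if (n > 0) apply(pc$coords, 2, range) else matrix(0, 2, 3)
  wb(c(bb[2, 1], bb[1, 1], bb[2, 2], bb[1, 2], bb[2, 3], bb[1, 3]), 8)
  ixyz <- round(sweep(sweep(pc$coords, 2, offset), 2, scale, "/"))
  storage.mode(ixyz) <- "integer"
  inten <- if (!is.null(pc$intensity))
    as.integer(round(pc$intensity * 65535)) else integer(n)
  blank <- as.raw(rep(0, 6))            # return info .. point source id
  for (i in seq_len(n)) {
    wb(ixyz[i, ], 4)
    wb(inten[i], 2)
    writeBin(blank, con)
    if (has_rgb) wb(as.integer(pc$rgb[i, ] * 257L), 2)
  }
}
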