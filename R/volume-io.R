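# Volume file I/O: NRRD (raw/gzip), NIfTI-1 (.nii/.nii.gz) and a minimal
# uncompressed explicit-VR little-endian DICOM series reader/writer.
# World convention throughout is LPS in mm (the DICOM patient system);
# NIfTI files, which use RAS, are converted on the fly.

#' Read a volume from disk
#'
#' @param path file (NRRD/NIfTI) or directory (DICOM series).
#' @param format one of \code{"auto"}, \code{"nrrd"}, \code{"nifti"},
#'   \code{"dicom_series"}.
#' @return a \code{\link{volume_image}}.
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti",
                                         "dicom_series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else stop("cannot infer format of ", path, call. = FALSE)
  }
  switch(format,
    nrrd = read_nrrd(path),
    nifti = read_nifti(path),
    dicom_series = read_dicom_series(path))
}

#' Write a volume to disk
#'
#' @param vol a \code{\link{volume_image}}.
#' @param path output path; format inferred from the extension unless given.
#' @param format \code{"auto"}, \code{"nrrd"} or \code{"nifti"}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else stop("cannot infer format of ", path, call. = FALSE)
  }
  switch(format,
    nrrd = write_nrrd(vol, path),
    nifti = write_nifti(vol, path))
  invisible(path)
}

## ---------------------------------------------------------------- NRRD ----

nrrd_types <- data.frame(
  name = c("double", "float", "short", "unsigned short", "int", "uchar",
           "unsigned char", "signed short"),
  what = c("double", "double", "integer", "integer", "integer", "integer",
           "integer", "integer"),
  size = c(8L, 4L, 2L, 2L, 4L, 1L, 1L, 2L),
  signed = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

fmt_vec <- function(v) paste0("(", paste(formatC(v, format = "g", digits = 17),
                                         collapse = ","), ")")

#' @rdname read_volume
#' @param type storage type for NRRD output (\code{"double"} or
#'   \code{"short"}).
#' @param encoding NRRD encoding, \code{"raw"} or \code{"gzip"}.
#' @export
write_nrrd <- function(vol, path, type = "double", encoding = "raw") {
  stopifnot(is_volume_image(vol), type %in% c("double", "short"),
            encoding %in% c("raw", "gzip"))
  d <- dim(vol$data)
  dirs <- vol$orientation %*% diag(vol$spacing)
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("space directions: ", paste(apply(dirs, 2L, fmt_vec),
                                       collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", encoding),
    paste0("space origin: ", fmt_vec(vol$origin))
  )
  payload <- if (type == "double") {
    writeBin(as.vector(vol$data), raw(), size = 8L, endian = "little")
  } else {
    v <- round(as.vector(vol$data))
    if (any(v < -32768 | v > 32767))
      stop("data out of range for short NRRD output", call. = FALSE)
    writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  }
  if (encoding == "gzip")
    payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(charToRaw("\n"), con)
  writeBin(payload, con)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is the byte stream up to the first blank line
  hdr_lines <- character()
  repeat {
    line_bytes <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L)
        stop("truncated NRRD header in ", path, call. = FALSE)
      if (as.integer(b) == 10L) break
      line_bytes <- c(line_bytes, b)
    }
    ln <- sub("\r$", "", rawToChar(line_bytes))
    if (ln == "") break
    hdr_lines <- c(hdr_lines, ln)
  }
  if (!grepl("^NRRD000", hdr_lines[1L]))
    stop(path, " is not a NRRD file", call. = FALSE)
  fields <- hdr_lines[grepl(":", hdr_lines, fixed = TRUE) &
                      !startsWith(hdr_lines, "#")]
  keys <- tolower(trimws(sub(":.*$", "", fields)))
  vals <- trimws(sub("^[^:]*:=?", "", fields))
  gv <- function(k) if (k %in% keys) vals[[match(k, keys)]] else NULL
  typ <- gv("type")
  trow <- nrrd_types[match(typ, nrrd_types$name), ]
  if (is.na(trow$size))
    stop("unsupported NRRD type: ", typ, call. = FALSE)
  if (!identical(gv("dimension"), "3"))
    stop("only 3-D NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(gv("sizes"), "\\s+")[[1L]])
  enc <- gv("encoding")
  if (!enc %in% c("raw", "gzip", "gz"))
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  endian <- gv("endian")
  if (is.null(endian)) endian <- "little"
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc != "raw") payload <- memDecompress(payload, type = "gzip")
  if (length(payload) < n * trow$size)
    stop("truncated NRRD data in ", path, call. = FALSE)
  v <- readBin(payload, trow$what, n = n, size = trow$size,
               signed = trow$signed, endian = endian)
  spacing <- c(1, 1, 1); orientation <- diag(3); origin <- c(0, 0, 0)
  sd_str <- gv("space directions")
  if (!is.null(sd_str)) {
    m <- regmatches(sd_str, gregexpr("\\(([^)]*)\\)", sd_str))[[1L]]
    dirs <- vapply(m, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1L]]), numeric(3L))
    spacing <- sqrt(colSums(dirs^2))
    orientation <- sweep(dirs, 2L, spacing, "/")
  }
  so_str <- gv("space origin")
  if (!is.null(so_str))
    origin <- as.numeric(strsplit(gsub("[()]", "", so_str), ",")[[1L]])
  space <- gv("space")
  flip <- c(1, 1, 1)
  if (!is.null(space)) {
    if (space %in% c("right-anterior-superior", "RAS")) flip <- c(-1, -1, 1)
    else if (!space %in% c("left-posterior-superior", "LPS")) flip <- c(1, 1, 1)
  }
  orientation <- unname(diag(flip) %*% orientation)
  origin <- unname(flip * origin)
  volume_image(array(as.double(v), dim = sizes), unname(spacing), origin,
               orientation)
}

## --------------------------------------------------------------- NIfTI ----

#' @rdname read_volume
#' @export
write_nifti <- function(vol, path) {
  stopifnot(is_volume_image(vol))
  d <- dim(vol$data)
  # LPS -> RAS: negate the first two world axes
  aff <- diag(c(-1, -1, 1)) %*% (vol$orientation %*% diag(vol$spacing))
  orig <- c(-1, -1, 1) * vol$origin
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wi(348L, 4L)                              # sizeof_hdr
  writeBin(raw(36L), con)                   # data_type, db_name, extents...
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)          # dim
  wf(c(0, 0, 0), 4L); wi(0L, 2L)            # intent_p1..3, intent_code
  wi(64L, 2L); wi(64L, 2L)                  # datatype float64, bitpix
  wi(0L, 2L)                                # slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0), 4L)     # pixdim (qfac = 1)
  wf(352, 4L)                               # vox_offset
  wf(c(1, 0), 4L)                           # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)        # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0), 4L)                        # cal_max, cal_min, slice_duration
  wf(0, 4L); wi(c(0L, 0L), 4L)              # toffset, glmax, glmin
  writeBin(raw(104L), con)                  # descrip + aux_file
  wi(c(0L, 1L), 2L)                         # qform_code 0, sform_code 1
  wf(rep(0, 6), 4L)                         # quatern b,c,d + qoffset x,y,z
  wf(c(aff[1L, ], orig[1L]), 4L)            # srow_x
  wf(c(aff[2L, ], orig[2L]), 4L)            # srow_y
  wf(c(aff[3L, ], orig[3L]), 4L)            # srow_z
  writeBin(raw(16L), con)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  writeBin(raw(4L), con)                    # extension flag
  writeBin(as.double(as.vector(vol$data)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L)
    stop(path, " is not a NIfTI-1 file", call. = FALSE)
  dm <- ri(40L, 2L, 8L)
  if (dm[1L] < 3L) stop("only 3-D NIfTI volumes are supported", call. = FALSE)
  d <- dm[2:4]
  datatype <- ri(70L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  sform_code <- ri(254L, 2L)
  srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
  to_skip <- vox_offset - 348L
  if (to_skip > 0L) readBin(con, "raw", n = to_skip)
  n <- prod(d)
  v <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                  endian = "little"),
    "4" = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    "16" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (identical(scl_slope, 0)) scl_slope <- 1
  v <- as.double(v) * scl_slope + scl_inter
  if (sform_code > 0L) {
    aff <- srow[, 1:3]; orig <- srow[, 4L]
  } else {
    aff <- diag(pixdim[2:4]); orig <- c(0, 0, 0)
  }
  # RAS -> LPS
  aff <- diag(c(-1, -1, 1)) %*% aff
  orig <- c(-1, -1, 1) * orig
  spacing <- sqrt(colSums(aff^2))
  orientation <- sweep(aff, 2L, spacing, "/")
  dat <- array(v, dim = d)
  if (det(orientation) < 0) { # flip first axis to keep a proper rotation
    dat <- dat[rev(seq_len(d[1L])), , , drop = FALSE]
    orig <- orig + orientation[, 1L] * spacing[1L] * (d[1L] - 1L)
    orientation[, 1L] <- -orientation[, 1L]
  }
  volume_image(dat, spacing, orig, orientation)
}

## --------------------------------------------------------------- DICOM ----

dcm_elem <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0L)
                   else charToRaw(" "))
  head <- c(writeBin(c(group, elem), raw(), size = 2L, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, raw(2L),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

dcm_ds <- function(...) charToRaw(paste(
  formatC(c(...), format = "g", digits = 10), collapse = "\\"))

#' Write a volume as a DICOM series (one file per slice)
#'
#' A minimal explicit-VR little-endian secondary-capture writer: enough
#' metadata for geometry-faithful round trips (position, orientation, pixel
#' spacing, rescale slope/intercept), 16-bit signed storage.
#'
#' @param vol a \code{\link{volume_image}}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(vol, dir) {
  stopifnot(is_volume_image(vol))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  rng <- range(vol$data)
  integral <- all(abs(vol$data - round(vol$data)) < 1e-6)
  if (integral && rng[1L] >= -32768 && rng[2L] <= 32767) {
    slope <- 1; inter <- 0
  } else {
    slope <- max((rng[2L] - rng[1L]) / 65000, 1e-12)
    inter <- rng[1L] + 32768 * slope
  }
  series_uid <- "1.2.826.0.1.3680043.9999.1"
  for (k in seq_len(d[3L])) {
    pos <- index_to_world(vol, cbind(0, 0, k - 1))[1L, ]
    stored <- as.integer(round((vol$data[, , k] - inter) / slope))
    # DICOM pixel order is row-major (column index fastest); our first array
    # axis is the fastest, so it plays the role of the column index.
    pix <- writeBin(as.vector(stored), raw(), size = 2L, endian = "little")
    meta <- c(
      dcm_elem(0x0002L, 0x0010L, "UI",
               charToRaw("1.2.840.10008.1.2.1")))
    meta <- c(dcm_elem(0x0002L, 0x0000L, "UL",
                       writeBin(length(meta), raw(), size = 4L,
                                endian = "little")), meta)
    body <- c(
      dcm_elem(0x0008L, 0x0016L, "UI",
               charToRaw("1.2.840.10008.5.1.4.1.1.7")),
      dcm_elem(0x0008L, 0x0018L, "UI",
               charToRaw(paste0(series_uid, ".", k))),
      dcm_elem(0x0020L, 0x000EL, "UI", charToRaw(series_uid)),
      dcm_elem(0x0020L, 0x0013L, "IS", charToRaw(as.character(k))),
      dcm_elem(0x0020L, 0x0032L, "DS", dcm_ds(pos)),
      dcm_elem(0x0020L, 0x0037L, "DS",
               dcm_ds(vol$orientation[, 1L], vol$orientation[, 2L])),
      dcm_elem(0x0028L, 0x0002L, "US",
               writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0010L, "US",
               writeBin(d[2L], raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0011L, "US",
               writeBin(d[1L], raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0030L, "DS",
               dcm_ds(vol$spacing[2L], vol$spacing[1L])),
      dcm_elem(0x0028L, 0x0100L, "US",
               writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0101L, "US",
               writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0102L, "US",
               writeBin(15L, raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x0103L, "US",
               writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_elem(0x0028L, 0x1052L, "DS", dcm_ds(inter)),
      dcm_elem(0x0028L, 0x1053L, "DS", dcm_ds(slope)),
      dcm_elem(0x7FE0L, 0x0010L, "OW", pix))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128L), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

# Parse one explicit-VR little-endian DICOM file into a tag -> value list.
read_dicom_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 132L || rawToChar(buf[129:132]) != "DICM")
    stop(path, " is not a DICOM part-10 file", call. = FALSE)
  p <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (p + 8L <= length(buf) + 1L) {
    grp <- readBin(buf[p:(p + 1L)], "integer", size = 2L, signed = FALSE,
                   endian = "little")
    ele <- readBin(buf[(p + 2L):(p + 3L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(buf[(p + 4L):(p + 5L)])
    if (vr %in% long_vrs) {
      len <- readBin(buf[(p + 8L):(p + 11L)], "integer", size = 4L,
                     endian = "little")
      vstart <- p + 12L
    } else {
      len <- readBin(buf[(p + 6L):(p + 7L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      vstart <- p + 8L
    }
    val <- if (len > 0L) buf[vstart:(vstart + len - 1L)] else raw()
    key <- sprintf("%04x,%04x", grp, ele)
    out[[key]] <- list(vr = vr, value = val)
    p <- vstart + len
  }
  out
}

dcm_str <- function(el) if (is.null(el)) NULL else
  trimws(rawToChar(el$value))
dcm_nums <- function(el) if (is.null(el)) NULL else
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1L]])
dcm_us <- function(el) readBin(el$value, "integer", size = 2L, signed = FALSE,
                               endian = "little")

#' @rdname read_volume
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- setdiff(list.files(path, full.names = TRUE),
                     list.dirs(path, recursive = FALSE))
  if (length(files) == 0L)
    stop("no DICOM files in ", path, call. = FALSE)
  slices <- lapply(files, read_dicom_file)
  pos <- t(vapply(slices, function(s) dcm_nums(s[["0020,0032"]]),
                  numeric(3L)))
  iop <- dcm_nums(slices[[1L]][["0020,0037"]])
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2L] * coldir[3L] - rowdir[3L] * coldir[2L],
              rowdir[3L] * coldir[1L] - rowdir[1L] * coldir[3L],
              rowdir[1L] * coldir[2L] - rowdir[2L] * coldir[1L])
  proj <- drop(pos %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]
  proj <- proj[ord]; files <- files[ord]
  nz <- length(slices)
  ps <- dcm_nums(slices[[1L]][["0028,0030"]])  # (row spacing, col spacing)
  spacing_xy <- c(ps[2L], ps[1L])
  if (nz > 1L) {
    gaps <- diff(proj)
    if (any(gaps <= 0))
      stop("duplicate or unsortable DICOM slice positions", call. = FALSE)
    dz <- stats::median(gaps)
    bad <- which(abs(gaps - dz) > 0.01 * dz)
    if (length(bad) > 0L)
      stop("inconsistent DICOM slice spacing (> 1%) between files: ",
           paste(basename(files[c(bad, bad + 1L)]), collapse = ", "),
           call. = FALSE)
  } else dz <- spacing_xy[1L]
  ncol_px <- dcm_us(slices[[1L]][["0028,0011"]])
  nrow_px <- dcm_us(slices[[1L]][["0028,0010"]])
  dat <- array(0, dim = c(ncol_px, nrow_px, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    signed <- dcm_us(s[["0028,0103"]]) == 1L
    stored <- readBin(s[["7fe0,0010"]]$value, "integer",
                      n = ncol_px * nrow_px, size = 2L, signed = signed,
                      endian = "little")
    slope <- dcm_nums(s[["0028,1053"]]); if (is.null(slope)) slope <- 1
    inter <- dcm_nums(s[["0028,1052"]]); if (is.null(inter)) inter <- 0
    dat[, , k] <- stored * slope + inter
  }
  volume_image(dat, c(spacing_xy, dz), pos[1L, ],
               cbind(rowdir, coldir, normal))
}
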