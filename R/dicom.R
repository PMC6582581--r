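## Minimal DICOM adapter: explicit VR little endian with defined element
## lengths, enough to ingest CT series and RT Dose grids into the package's
## own containers.  There is no DICOM toolkit in the supported R stack, so
## this deliberately small reader covers only what the analysis consumes;
## undefined-length sequences and compressed transfer syntaxes are rejected
## with a format error.  DICOM writing of RT objects is out of scope.

dcm_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_uint32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

## Walk top-level data elements, returning a list keyed "gggg,eeee" with
## raw value fields and VRs for the requested tags.
dcm_parse <- function(path, want) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_uint16(raw, pos)
    elem <- dcm_uint16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_format("implicit VR or corrupt DICOM stream not supported")
    if (vr %in% LONG_VRS) {
      len <- dcm_uint32(raw, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- dcm_uint16(raw, pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 4294967295)
      stop_format("undefined-length DICOM elements not supported")
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% want) {
      out[[key]] <- list(vr = vr, value = raw[vstart:(vstart + len - 1L)])
      if (length(out) == length(want)) return(out)
    }
    pos <- vstart + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dcm_nums <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  dcm_uint16(el$value, 1L)
}

dcm_pixels <- function(el, bits, signed, n) {
  size <- bits %/% 8L
  v <- readBin(el$value, "integer", n = n, size = size,
               signed = if (size < 4L) signed else TRUE, endian = "little")
  if (length(v) != n) stop_format("DICOM pixel data truncated")
  as.numeric(v)
}

read_dicom_slice <- function(path) {
  want <- c("0018,0050", "0020,0032", "0020,0037", "0028,0010", "0028,0011",
            "0028,0030", "0028,0100", "0028,0103", "0028,1052", "0028,1053",
            "7fe0,0010")
  el <- dcm_parse(path, want)
  iop <- dcm_nums(el[["0020,0037"]])
  if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    stop_geometry("oblique DICOM orientation not supported")
  rows <- dcm_us(el[["0028,0010"]])
  cols <- dcm_us(el[["0028,0011"]])
  ps <- dcm_nums(el[["0028,0030"]])          # (row spacing = dy, col = dx)
  ipp <- dcm_nums(el[["0020,0032"]])
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(ipp))
    stop_format(paste("missing CT geometry tags in", path))
  bits <- dcm_us(el[["0028,0100"]])
  signed <- identical(dcm_us(el[["0028,0103"]]), 1L)
  slope <- dcm_nums(el[["0028,1053"]])
  inter <- dcm_nums(el[["0028,1052"]])
  if (is.null(slope)) slope <- 1
  if (is.null(inter)) inter <- 0
  px <- dcm_pixels(el[["7fe0,0010"]], bits, signed, rows * cols)
  st <- dcm_nums(el[["0018,0050"]])
  list(values = px * slope + inter, nx = cols, ny = rows,
       dx = ps[2], dy = ps[1], ipp = ipp, thickness = st)
}

read_dicom_ct_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop_format(paste("no DICOM files in", dir))
  slices <- lapply(files, read_dicom_slice)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  s1 <- slices[[1]]
  for (s in slices) {
    if (s$nx != s1$nx || s$ny != s1$ny ||
        max(abs(c(s$dx - s1$dx, s$dy - s1$dy))) > 1e-6 ||
        max(abs(s$ipp[1:2] - s1$ipp[1:2])) > 1e-3)
      stop_geometry("inconsistent in-plane geometry across CT series")
  }
  if (length(slices) > 1L) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-3 || any(dz <= 0))
      stop_geometry("missing or inconsistent slice spacing in CT series")
    dz <- dz[1]
  } else {
    if (is.null(s1$thickness))
      stop_geometry("single-slice series without SliceThickness")
    dz <- s1$thickness
  }
  vals <- array(unlist(lapply(slices, `[[`, "values")),
                dim = c(s1$nx, s1$ny, length(slices)))
  voxel_grid(vals, spacing = c(s1$dx, s1$dy, dz),
             origin = c(s1$ipp[1], s1$ipp[2], z[1]), unit = "HU")
}

read_dicom_rtdose <- function(path) {
  want <- c("0020,0032", "0028,0008", "0028,0010", "0028,0011", "0028,0030",
            "0028,0100", "0028,0103", "3004,000c", "3004,000e", "7fe0,0010")
  el <- dcm_parse(path, want)
  scaling <- dcm_nums(el[["3004,000e"]])
  if (is.null(scaling))
    stop_format("RT Dose without DoseGridScaling")
  rows <- dcm_us(el[["0028,0010"]])
  cols <- dcm_us(el[["0028,0011"]])
  nframes <- as.integer(dcm_str(el[["0028,0008"]]))
  ps <- dcm_nums(el[["0028,0030"]])
  ipp <- dcm_nums(el[["0020,0032"]])
  gfov <- dcm_nums(el[["3004,000c"]])
  if (is.null(rows) || is.null(cols) || is.null(nframes) || is.null(gfov))
    stop_format("missing RT Dose geometry tags")
  if (length(gfov) != nframes) stop_format("GridFrameOffsetVector length mismatch")
  dz <- if (nframes > 1L) {
    d <- diff(gfov)
    if (max(d) - min(d) > 1e-3) stop_geometry("non-uniform dose frame offsets")
    d[1]
  } else 1
  bits <- dcm_us(el[["0028,0100"]])
  signed <- identical(dcm_us(el[["0028,0103"]]), 1L)
  px <- dcm_pixels(el[["7fe0,0010"]], bits, signed, rows * cols * nframes)
  vals <- array(px * scaling, dim = c(cols, rows, nframes))
  voxel_grid(vals, spacing = c(ps[2], ps[1], dz),
             origin = c(ipp[1], ipp[2], ipp[3] + gfov[1]), unit = "Gy")
}
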