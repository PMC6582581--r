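## MetaImage (.mha, local uncompressed data) reader/writer.  This is the
## package's research interchange format for scalar volumes and 3-component
## deformation fields.  Only axis-aligned (identity TransformMatrix) images
## are supported.

MET_TYPES <- c(MET_DOUBLE = "double", MET_FLOAT = "float", MET_SHORT = "short",
               MET_USHORT = "ushort", MET_UCHAR = "uchar")

write_mha_raw <- function(values, dim4, spacing, origin, path,
                          element_type = "MET_DOUBLE", unit = NULL,
                          channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, scientific = FALSE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = LPS",
    paste("ElementSpacing =", paste(format(spacing, scientific = FALSE), collapse = " ")),
    paste("DimSize =", paste(dim4, collapse = " ")),
    if (channels > 1L) paste("ElementNumberOfChannels =", channels),
    if (!is.null(unit)) paste("Unit =", unit),
    paste("ElementType =", element_type),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  sz <- switch(element_type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_UCHAR = 1L,
               stop_format(paste("unsupported ElementType", element_type)))
  if (element_type %in% c("MET_DOUBLE", "MET_FLOAT")) {
    writeBin(as.numeric(values), con, size = sz, endian = "little")
  } else {
    writeBin(as.integer(round(values)), con, size = sz, endian = "little")
  }
  invisible(path)
}

read_mha_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop_format("truncated MetaImage header")
    kv <- regmatches(line, regexec("^([A-Za-z0-9]+) *= *(.*)$", line))[[1]]
    if (length(kv) != 3L) stop_format(paste("bad MetaImage header line:", line))
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop_format("only 3-D MetaImages supported")
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE")
    stop_format("compressed MetaImage not supported")
  tm <- hdr[["TransformMatrix"]]
  if (!is.null(tm)) {
    m <- as.numeric(strsplit(trimws(tm), "[ \t]+")[[1]])
    if (max(abs(m - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop_geometry("non-axis-aligned MetaImage not supported")
  }
  dims <- as.integer(strsplit(trimws(hdr[["DimSize"]]), "[ \t]+")[[1]])
  spacing <- as.numeric(strsplit(trimws(hdr[["ElementSpacing"]]), "[ \t]+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(trimws(hdr[["Offset"]]), "[ \t]+")[[1]]) else c(0, 0, 0)
  channels <- if (!is.null(hdr[["ElementNumberOfChannels"]]))
    as.integer(hdr[["ElementNumberOfChannels"]]) else 1L
  et <- hdr[["ElementType"]]
  if (!et %in% names(MET_TYPES)) stop_format(paste("unsupported ElementType", et))
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop_format("only ElementDataFile = LOCAL supported")
  n <- prod(dims) * channels
  vals <- switch(et,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                        endian = "little"),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UCHAR = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                        endian = "little"))
  if (length(vals) != n) stop_format("MetaImage pixel data truncated")
  list(values = as.numeric(vals), dim = dims, spacing = spacing,
       origin = origin, channels = channels, unit = hdr[["Unit"]])
}

#' Read a scalar volume
#'
#' Reads a 3-D image either from the research MetaImage format (`.mha`,
#' uncompressed, local data) or from a directory containing a DICOM CT
#' series (explicit VR little endian).
#'
#' @param path file (MetaImage) or directory (DICOM series).
#' @param format_hint `"auto"`, `"mha"` or `"dicom"`.
#' @param unit unit tag to use when the file does not carry one.
#' @return a [voxel_grid].
#' @export
read_volume <- function(path, format_hint = c("auto", "mha", "dicom"),
                        unit = NULL) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    format_hint <- if (dir.exists(path)) "dicom"
      else if (grepl("\\.mha$", path, ignore.case = TRUE)) "mha"
      else stop_format(paste("cannot infer format of", path))
  }
  if (!file.exists(path)) stop_format(paste("no such path:", path))
  if (format_hint == "dicom") return(read_dicom_ct_series(path))
  r <- read_mha_raw(path)
  if (r$channels != 1L) stop_format("expected scalar volume, got multi-channel")
  u <- if (!is.null(unit)) unit else if (!is.null(r$unit)) r$unit else "1"
  voxel_grid(array(r$values, dim = r$dim), spacing = r$spacing,
             origin = r$origin, unit = u)
}

#' Write a scalar volume to the research MetaImage format
#'
#' @param grid a [voxel_grid].
#' @param path output `.mha` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  write_mha_raw(grid$values, dim(grid$values), grid$spacing, grid$origin,
                path, unit = grid$unit)
}

#' Read a dose grid
#'
#' Reads a dose distribution in Gy from the research MetaImage format or a
#' DICOM RT Dose file (the stored DoseGridScaling factor is applied).
#'
#' @inheritParams read_volume
#' @return a [voxel_grid] with unit `"Gy"`.
#' @export
read_dose <- function(path, format_hint = c("auto", "mha", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto")
    format_hint <- if (grepl("\\.mha$", path, ignore.case = TRUE)) "mha" else "dicom"
  if (format_hint == "dicom") return(read_dicom_rtdose(path))
  g <- read_volume(path, "mha")
  if (g$unit != "Gy") stop_format("research dose volume must carry unit Gy")
  g
}

## 3-component deformation field I/O (MetaImage, interleaved channels)
write_dvf_mha <- function(dvf, path) {
  d <- dvf$dim
  disp <- dvf$displacements        # n x 3
  inter <- as.numeric(t(disp))     # channel-interleaved
  write_mha_raw(inter, d, dvf$spacing, dvf$origin, path,
                unit = "mm", channels = 3L)
  invisible(path)
}

read_dvf_mha <- function(path) {
  r <- read_mha_raw(path)
  if (r$channels != 3L) stop_format("expected 3-channel deformation field")
  disp <- matrix(r$values, ncol = 3L, byrow = TRUE)
  deformation_field(disp, dim = r$dim, spacing = r$spacing, origin = r$origin)
}
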