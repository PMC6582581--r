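stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_parse_error", "error")))
}

stop_raster <- function(msg) {
  stop(errorCondition(msg, class = c("dosemass_raster_error", "error")))
}

normalize_contour <- function(m, what = "contour") {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop_parse(paste(what, "must have 3 columns (x, y, z mm)"))
  if (any(!is.finite(m))) stop_parse(paste(what, "contains non-finite points"))
  ## closed polygon: drop explicit closing vertex, close implicitly
  if (nrow(m) > 1L && max(abs(m[1, ] - m[nrow(m), ])) < 1e-9)
    m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop_parse(paste(what, "has fewer than 3 distinct points"))
  if (max(m[, 3]) - min(m[, 3]) > 1e-6)
    stop_parse(paste(what, "is not planar (z varies within the contour)"))
  dimnames(m) <- NULL
  m
}

#' Create a structure set
#'
#' A `structure_set` holds named organ structures, each a list of closed
#' planar contours.  A contour is an ordered matrix of (x, y, z) points in
#' patient mm coordinates with constant z; the closing vertex may be repeated
#' or omitted (it is normalized away and closure is implicit).
#'
#' @param structures named list; each element a list of contour matrices.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop_parse("all structures must be named")
  nms <- names(structures)
  cleaned <- lapply(nms, function(nm) {
    cs <- structures[[nm]]
    if (is.matrix(cs)) cs <- list(cs)
    lapply(seq_along(cs), function(i)
      normalize_contour(cs[[i]], sprintf("structure '%s' contour %d", nm, i)))
  })
  names(cleaned) <- nms
  structure(list(structures = cleaned), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures\n", length(x$structures)))
  for (nm in names(x$structures))
    cat(sprintf("  %-12s %d contours\n", nm, length(x$structures[[nm]])))
  invisible(x)
}

#' Read a structure set from a research JSON contour file
#'
#' The file holds an object `structures` mapping structure names to lists of
#' contours; each contour is a list of `[x, y, z]` mm triplets.
#'
#' @param path JSON file path.
#' @return a [structure_set].
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$structures)) stop_parse("JSON contour file lacks 'structures'")
  structs <- lapply(js$structures, function(cs)
    lapply(cs, function(cont)
      do.call(rbind, lapply(cont, function(pt) as.numeric(unlist(pt))))))
  structure_set(structs)
}

#' Write a structure set to the research JSON contour format
#' @param ss a [structure_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(ss, path) {
  stopifnot(inherits(ss, "structure_set"))
  obj <- list(structures = lapply(ss$structures, function(cs)
    lapply(cs, function(m) unname(m))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Create a voxel mask
#'
#' @param values logical 3-D array aligned to a reference grid.
#' @param spacing,origin geometry of the reference grid (mm).
#' @return an object of class `mask`.
#' @export
mask_grid <- function(values, spacing, origin) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  storage.mode(values) <- "logical"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  cat(sprintf("<mask> %s, %d voxels set, %.1f cm^3\n",
              paste(dim(x$values), collapse = " x "), sum(x$values),
              mask_volume_cm3(x)))
  invisible(x)
}

#' Structure volume of a mask in cm^3
#' @param mask a [mask_grid] object.
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask) sum(mask$values) * voxel_volume_cm3(mask)

mask_centroid <- function(mask) {
  idx <- which(mask$values)
  d <- dim(mask$values)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  mask$origin + c(mean(i), mean(j), mean(k)) * mask$spacing
}

#' Rasterize planar contours onto a reference grid
#'
#' A voxel is included iff its center lies inside the contour polygon on the
#' contour's slice, by the even-odd rule; overlapping contours on one slice
#' toggle (supporting holes), disjoint contours union.  Each contour is
#' assigned to the nearest slice within half a slice spacing.
#'
#' @param structure a list of contour matrices, or a [structure_set] together
#'   with `name`.
#' @param reference a [voxel_grid] providing the target geometry.
#' @param name structure name when `structure` is a `structure_set`.
#' @return a [mask_grid] aligned to `reference`.
#' @export
rasterize <- function(structure, reference, name = NULL) {
  if (inherits(structure, "structure_set")) {
    if (is.null(name)) stop_raster("give `name` to rasterize a structure_set")
    if (!name %in% names(structure$structures))
      stop_raster(paste("no structure named", name))
    structure <- structure$structures[[name]]
  }
  stopifnot(inherits(reference, "voxel_grid"))
  d <- dim(reference$values)
  xs <- axis_coords(reference, 1)
  ys <- axis_coords(reference, 2)
  zs <- axis_coords(reference, 3)
  vals <- array(FALSE, dim = d)
  for (cont in structure) {
    cont <- normalize_contour(cont)
    z <- cont[1, 3]
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > reference$spacing[3] / 2 + 1e-9)
      stop_raster(sprintf("contour at z=%.3f matches no slice within %.3f mm",
                          z, reference$spacing[3] / 2))
    ## restrict the test to the contour bounding box
    ii <- which(xs >= min(cont[, 1]) - 1e-9 & xs <= max(cont[, 1]) + 1e-9)
    jj <- which(ys >= min(cont[, 2]) - 1e-9 & ys <= max(cont[, 2]) + 1e-9)
    if (!length(ii) || !length(jj)) next
    px <- rep(xs[ii], times = length(jj))
    py <- rep(ys[jj], each = length(ii))
    inside <- c_points_in_polygon(px, py, cont[, 1], cont[, 2])
    sl <- vals[ii, jj, k]
    vals[ii, jj, k] <- xor(sl, matrix(inside, nrow = length(ii)))
  }
  mask_grid(vals, reference$spacing, reference$origin)
}
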