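#' Specify an organ as a geometric primitive
#'
#' Organs are placed as ellipsoids, boxes or cylinders (axis along z) in a
#' right-handed patient coordinate system: x towards the patient's left,
#' y anterior, z superior, lengths in cm, with the origin (and the treatment
#' isocenter) at the geometric center of the target volume.
#'
#' @param name organ name (used as the voxel label).
#' @param shape `"ellipsoid"`, `"box"` or `"cylinder"`.
#' @param semi_axes length-3 positive numeric: semi-axes (ellipsoid), box
#'   half-extents, or `c(rx, ry, half_height)` for a z-axis cylinder.
#' @param center_offset length-3 numeric, cm from the target center.
#' @param material a material name from [material_library()].
#' @param is_target `TRUE` for the planning target volume (exactly one per
#'   phantom).
#' @return an `oof_organ_spec`.
#' @export
organ_spec <- function(name, shape = c("ellipsoid", "box", "cylinder"),
                       semi_axes, center_offset = c(0, 0, 0),
                       material = "soft_tissue", is_target = FALSE) {
  shape <- match.arg(shape)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3L, length(center_offset) == 3L)
  if (any(semi_axes <= 0)) stop("organ '", name, "': semi-axes must be > 0")
  structure(list(name = name, shape = shape, semi_axes = semi_axes,
                 center_offset = as.numeric(center_offset),
                 material = material, is_target = isTRUE(is_target)),
            class = "oof_organ_spec")
}

# Mask of voxels inside one primitive, given voxel-center coordinate vectors.
.primitive_mask <- function(spec, xc, yc, zc) {
  cx <- spec$center_offset
  s <- spec$semi_axes
  dx <- (xc - cx[1]) / s[1]
  dy <- (yc - cx[2]) / s[2]
  dz <- (zc - cx[3]) / s[3]
  X <- array(rep(dx, times = length(yc) * length(zc)),
             dim = c(length(xc), length(yc), length(zc)))
  Y <- aperm(array(rep(dy, times = length(xc) * length(zc)),
                   dim = c(length(yc), length(xc), length(zc))), c(2, 1, 3))
  Z <- aperm(array(rep(dz, times = length(xc) * length(yc)),
                   dim = c(length(zc), length(xc), length(yc))), c(2, 3, 1))
  switch(spec$shape,
         ellipsoid = X^2 + Y^2 + Z^2 <= 1,
         box = abs(X) <= 1 & abs(Y) <= 1 & abs(Z) <= 1,
         cylinder = X^2 + Y^2 <= 1 & abs(Z) <= 1)
}

#' Build a voxel phantom from organ primitives
#'
#' Voxelizes a body primitive plus a list of organ primitives onto a regular
#' grid.  Overlaps are resolved in painter's order: later organs overwrite
#' earlier ones voxel-wise.  Voxel centers sit at
#' `origin + (index + 0.5) * voxel_size` (0-based indices).
#'
#' @param organs list of [organ_spec()] objects (painted in order).
#' @param body an [organ_spec()] painted first, defining the patient outline.
#' @param dims integer length-3 grid dimensions.
#' @param voxel_size length-3 voxel edge lengths, cm.
#' @param origin length-3 position of the grid corner, cm; defaults to
#'   centering the grid on the body primitive.
#' @param materials material library (named list), defaults to
#'   [material_library()].
#' @return an `oof_phantom`: list with `dims`, `voxel_size`, `origin`,
#'   `material_index` and `organ_label` (integer arrays), `label_names`,
#'   `material_names`, `materials`.
#' @export
build_phantom <- function(organs, body, dims, voxel_size, origin = NULL,
                          materials = material_library()) {
  dims <- as.integer(dims)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(dims) == 3L, all(dims > 0L), length(voxel_size) == 3L,
            all(voxel_size > 0), inherits(body, "oof_organ_spec"))
  specs <- c(list(body), organs)
  if (sum(vapply(specs, function(s) s$is_target, logical(1))) != 1L)
    stop("exactly one organ spec must have is_target = TRUE")
  if (is.null(origin))
    origin <- body$center_offset - dims * voxel_size / 2
  mat_names <- unique(vapply(specs, function(s) s$material, character(1)))
  missing <- setdiff(mat_names, names(materials))
  if (length(missing))
    stop("undefined materials: ", paste(missing, collapse = ", "))
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]

  material_index <- array(0L, dims)   # 0 = undefined/air outside body
  organ_label <- array(0L, dims)
  label_names <- character(length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    m <- .primitive_mask(s, xc, yc, zc)
    if (!any(m))
      stop("organ '", s$name, "' lies entirely outside the voxel grid")
    material_index[m] <- match(s$material, mat_names)
    organ_label[m] <- k
    label_names[k] <- s$name
  }
  structure(list(dims = dims, voxel_size = voxel_size, origin = origin,
                 material_index = material_index, organ_label = organ_label,
                 label_names = setNames(seq_along(label_names), label_names),
                 material_names = mat_names,
                 materials = materials[mat_names]),
            class = "oof_phantom")
}

#' @export
print.oof_phantom <- function(x, ...) {
  cat(sprintf("<oof_phantom> %d x %d x %d voxels (%.4g x %.4g x %.4g cm), %d labels\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3], length(x$label_names)))
  cat(" organs:", paste(names(x$label_names), collapse = ", "), "\n")
  invisible(x)
}

# voxel-centroid center of an organ label, cm
.organ_centroid <- function(phantom, organ) {
  lab <- phantom$label_names[organ]
  if (is.na(lab)) stop("unknown organ label '", organ, "'")
  idx <- which(phantom$organ_label == lab, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("organ '", organ, "' occupies no voxels")
  phantom$origin + (colMeans(idx) - 0.5) * phantom$voxel_size
}

#' Voxel count and volume of an organ
#' @param phantom an `oof_phantom`.
#' @param organ organ name.
#' @return list with `voxels`, `volume_cm3`, `mass_g`.
#' @export
organ_volume <- function(phantom, organ) {
  lab <- phantom$label_names[organ]
  if (is.na(lab)) stop("unknown organ label '", organ, "'")
  n <- sum(phantom$organ_label == lab)
  v <- n * prod(phantom$voxel_size)
  mat_idx <- phantom$material_index[phantom$organ_label == lab][1]
  rho <- phantom$materials[[phantom$material_names[mat_idx]]]$density
  list(voxels = n, volume_cm3 = v, mass_g = v * rho)
}

#' Center-to-center distance between two organs
#'
#' Euclidean distance between the voxel-centroid centers of two labeled
#' organs, cm.  Symmetric; `organ_distance(p, a, a)` is 0.
#'
#' @param phantom an `oof_phantom`.
#' @param organ_a,organ_b organ names.
#' @return distance in cm.
#' @export
organ_distance <- function(phantom, organ_a, organ_b) {
  ca <- .organ_centroid(phantom, organ_a)
  cb <- .organ_centroid(phantom, organ_b)
  sqrt(sum((ca - cb)^2))
}

# Anatomical unit directions (normalized in code) and center distances (cm)
# for the default pediatric out-of-field organ layout.  Each organ center is
# placed exactly at its clinical center-to-center distance from the target.
.PEDIATRIC_LAYOUT <- list(
  right_eye  = list(dir = c(-0.25, 0.93, -0.27), dist = 6.2,
                    shape = "ellipsoid", semi = c(1.2, 1.2, 1.2),
                    material = "soft_tissue"),
  left_eye   = list(dir = c(0.50, 0.84, -0.21), dist = 8.4,
                    shape = "ellipsoid", semi = c(1.2, 1.2, 1.2),
                    material = "soft_tissue"),
  c_spine    = list(dir = c(0.05, -0.25, -0.97), dist = 11.1,
                    shape = "cylinder", semi = c(1.0, 1.0, 3.0),
                    material = "bone"),
  thyroid    = list(dir = c(0.00, 0.15, -0.99), dist = 13.1,
                    shape = "ellipsoid", semi = c(1.8, 0.9, 1.3),
                    material = "thyroid"),
  right_lung = list(dir = c(-0.22, 0.00, -0.975), dist = 21.7,
                    shape = "ellipsoid", semi = c(2.6, 3.4, 5.2),
                    material = "lung"),
  heart      = list(dir = c(0.06, 0.10, -0.993), dist = 22.2,
                    shape = "ellipsoid", semi = c(2.8, 2.5, 2.6),
                    material = "soft_tissue"),
  left_lung  = list(dir = c(0.22, 0.05, -0.975), dist = 23.3,
                    shape = "ellipsoid", semi = c(2.6, 3.4, 5.2),
                    material = "lung")
)

#' Organ specs for the default pediatric phantom
#'
#' Body, brain, elliptical target volume and seven out-of-field organs, each
#' organ center placed along an anatomical direction at exactly its clinical
#' center-to-center distance from the target center (right eye 6.2 cm through
#' left lung 23.3 cm).  The target is an ellipsoid of the configured volume
#' (default 9.8 cm^3) in the right hemisphere of the brain; its center is the
#' coordinate origin and treatment isocenter.
#'
#' @param ptv_volume_cm3 target volume, cm^3.
#' @return list with elements `body` and `organs` for [build_phantom()].
#' @export
pediatric_organ_specs <- function(ptv_volume_cm3 = 9.8) {
  # semi-axes a : b : c = 1.4 : 1 : 1 scaled to the requested volume
  c3 <- ptv_volume_cm3 / (4 / 3 * pi * 1.4)
  cax <- c3^(1 / 3)
  ptv_semi <- c(1.4 * cax, cax, cax)
  organs <- list(
    organ_spec("brain", "ellipsoid", c(6.0, 6.5, 5.0), c(0.3, 0.0, -0.8),
               material = "brain")
  )
  for (nm in names(.PEDIATRIC_LAYOUT)) {
    o <- .PEDIATRIC_LAYOUT[[nm]]
    u <- o$dir / sqrt(sum(o$dir^2))
    organs[[length(organs) + 1L]] <-
      organ_spec(nm, o$shape, o$semi, u * o$dist, material = o$material)
  }
  organs[[length(organs) + 1L]] <-
    organ_spec("ptv", "ellipsoid", ptv_semi, c(0, 0, 0),
               material = "brain", is_target = TRUE)
  body <- organ_spec("body", "box", c(9.0, 8.5, 17.5), c(0, 0, -10.5),
                     material = "soft_tissue")
  list(body = body, organs = organs)
}

#' Grid dimensions covering the pediatric body at a given voxel size
#' @param voxel_size length-3 voxel edges, cm.
#' @return integer length-3 dims.
#' @export
pediatric_grid_dims <- function(voxel_size = c(0.2, 0.2, 0.3)) {
  extent <- 2 * c(9.0, 8.5, 17.5) + 0.4   # body + small margin
  as.integer(ceiling(extent / voxel_size))
}

#' CT-resolution grid of the source voxel phantom
#'
#' The clinical voxel phantom this package's parametric phantom stands in for
#' was built from CT images on a 704 x 704 x 95 grid of
#' 0.09766 x 0.09766 x 0.3 cm voxels (about 47 million voxels, the CT field
#' of view including surrounding air).
#'
#' @return list with `dims` and `voxel_size`.
#' @export
clinical_grid <- function() {
  list(dims = c(704L, 704L, 95L), voxel_size = c(0.09766, 0.09766, 0.3))
}

#' Build the default pediatric phantom
#'
#' Desk-scale default grid is 2 x 2 x 3 mm; finer grids (down to the
#' CT-resolution 0.9766 x 0.9766 x 3 mm spacing of [clinical_grid()]) are
#' available by passing a smaller voxel size.
#'
#' @param voxel_size length-3 voxel edges, cm.
#' @param ptv_volume_cm3 target volume, cm^3.
#' @return an `oof_phantom`.
#' @export
pediatric_phantom <- function(voxel_size = c(0.2, 0.2, 0.3),
                              ptv_volume_cm3 = 9.8) {
  sp <- pediatric_organ_specs(ptv_volume_cm3)
  dims <- pediatric_grid_dims(voxel_size)
  build_phantom(sp$organs, sp$body, dims, voxel_size)
}

#' Write / read a phantom as a MetaImage-style header + raw pair
#'
#' The header is a plain-text key = value file (dims, spacing, origin, label
#' map, material map); the two integer arrays are stored as little-endian
#' 32-bit integers in companion `.raw` files.
#'
#' @param phantom an `oof_phantom`.
#' @param path header file path; raw arrays go to `<path>.material.raw` and
#'   `<path>.label.raw`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  hdr <- c(
    "ObjectType = oofdose-phantom-v1",
    paste("DimSize =", paste(phantom$dims, collapse = " ")),
    paste("ElementSpacing =", paste(format(phantom$voxel_size, digits = 10),
                                    collapse = " ")),
    paste("Offset =", paste(format(phantom$origin, digits = 10),
                            collapse = " ")),
    paste("Materials =", paste(phantom$material_names, collapse = " ")),
    paste("Labels =", paste(sprintf("%d:%s", phantom$label_names,
                                    names(phantom$label_names)),
                            collapse = " ")),
    "ElementType = int32-le"
  )
  writeLines(hdr, path)
  con <- file(paste0(path, ".material.raw"), "wb")
  writeBin(as.integer(phantom$material_index), con, size = 4L,
           endian = "little")
  close(con)
  con <- file(paste0(path, ".label.raw"), "wb")
  writeBin(as.integer(phantom$organ_label), con, size = 4L, endian = "little")
  close(con)
  invisible(path)
}

#' @rdname write_phantom
#' @param materials material library used to resolve the stored names.
#' @export
read_phantom <- function(path, materials = material_library()) {
  lines <- readLines(path)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, " ="), lines, value = TRUE)
    if (!length(ln)) stop("phantom header missing key '", key, "'")
    trimws(sub(paste0("^", key, " = ?"), "", ln[1]))
  }
  if (get_val("ObjectType") != "oofdose-phantom-v1")
    stop("not an oofdose phantom header")
  dims <- as.integer(strsplit(get_val("DimSize"), "[ \t]+")[[1]])
  vs <- as.numeric(strsplit(get_val("ElementSpacing"), "[ \t]+")[[1]])
  org <- as.numeric(strsplit(get_val("Offset"), "[ \t]+")[[1]])
  mats <- strsplit(get_val("Materials"), " +")[[1]]
  labs <- strsplit(get_val("Labels"), " +")[[1]]
  lab_ids <- as.integer(sub(":.*", "", labs))
  lab_nm <- sub("^[0-9]+:", "", labs)
  n <- prod(dims)
  con <- file(paste0(path, ".material.raw"), "rb")
  mi <- readBin(con, "integer", n, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(path, ".label.raw"), "rb")
  ol <- readBin(con, "integer", n, size = 4L, endian = "little")
  close(con)
  structure(list(dims = dims, voxel_size = vs, origin = org,
                 material_index = array(mi, dims),
                 organ_label = array(ol, dims),
                 label_names = setNames(lab_ids, lab_nm),
                 material_names = mats,
                 materials = materials[mats]),
            class = "oof_phantom")
}
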