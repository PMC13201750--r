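## Label codes: right hemisphere 1..5, left hemisphere +10.
.LABELS <- c(STN_MC_R = 1L, STN_assoc_R = 2L, SNr_R = 3L, SNc_R = 4L, RN_R = 5L,
             STN_MC_L = 11L, STN_assoc_L = 12L, SNr_L = 13L, SNc_L = 14L, RN_L = 15L)

.REGION_PARTS <- list(
  STN = c("STN_MC", "STN_assoc"), SN = c("SNr", "SNc"),
  STN_MC = "STN_MC", STN_assoc = "STN_assoc",
  SNr = "SNr", SNc = "SNc", RN = "RN")

#' Parameters of the synthetic subcortical anatomy
#'
#' The synthetic atlas is built from analytic ellipsoids rasterized on an
#' isotropic grid: an STN split into a posterodorsal motor compartment (MC)
#' and an associative remainder, a substantia nigra (SN) ellipsoid sitting
#' ventral to the STN and split by an oblique plane into a dorsomedial SNc
#' strip and an SNr remainder, and a red nucleus (RN) medial and posterior.
#' The right hemisphere is specified; the left is its mirror image across the
#' midsagittal plane. Defaults place the structures at clinically plausible
#' AC-PC coordinates (mid-commissural point at the origin, AC-PC distance
#' 25 mm) with volumes of roughly 160 (STN), 370 (SN) and 230 (RN) mm^3.
#'
#' @param voxelSize isotropic voxel edge in mm.
#' @param bounds list of `x`, `y`, `z` ranges (mm) of the volume.
#' @param stn,sn,rn lists with `center` and `axes` (mm) of the right-side
#'   ellipsoids.
#' @param mcFraction fraction of STN voxels assigned to the motor
#'   compartment (posterodorsal).
#' @param mcNormal direction (right hemisphere) along which the MC lies;
#'   the split threshold is the `1 - mcFraction` quantile of voxel
#'   projections.
#' @param sncNormal,sncOffset the SNc is the part of the SN with
#'   `(v - center) . unit(sncNormal) >= sncOffset` (dorsomedial strip).
#' @param ac,pc,midlineVertex frame landmarks (mm).
#' @param seed integer; recorded for provenance (rasterization itself is
#'   deterministic).
#' @return A list of class `anatomyParams`.
#' @export
anatomyParams <- function(voxelSize = 0.25,
                          bounds = list(x = c(-20, 20), y = c(-18, 8), z = c(-14, 4)),
                          stn = list(center = c(11.5, -1.5, -3.5), axes = c(3, 5, 2.5)),
                          mcFraction = 0.35,
                          mcNormal = c(0, -1, 1),
                          sn = list(center = c(10.5, -5, -8.5), axes = c(4.5, 6.5, 3)),
                          sncNormal = c(-1, 0, 1),
                          sncOffset = 1.2,
                          rn = list(center = c(5.5, -8.5, -4.5), axes = c(3.5, 3.5, 4.5)),
                          ac = c(0, 12.5, 0), pc = c(0, -12.5, 0),
                          midlineVertex = c(0, 0, 40),
                          seed = 1L) {
  p <- list(voxelSize = voxelSize, bounds = bounds, stn = stn,
            mcFraction = mcFraction, mcNormal = mcNormal, sn = sn,
            sncNormal = sncNormal, sncOffset = sncOffset, rn = rn,
            ac = ac, pc = pc, midlineVertex = midlineVertex,
            seed = as.integer(seed))
  class(p) <- "anatomyParams"
  validate_anatomy(p)
  p
}

validate_anatomy <- function(p) {
  stopifnot(p$voxelSize > 0, p$mcFraction > 0, p$mcFraction < 1)
  for (s in c("stn", "sn", "rn")) {
    el <- p[[s]]
    stopifnot(length(el$center) == 3L, length(el$axes) == 3L, all(el$axes > 0))
    lo <- el$center - el$axes; hi <- el$center + el$axes
    bl <- c(p$bounds$x[1], p$bounds$y[1], p$bounds$z[1])
    bh <- c(p$bounds$x[2], p$bounds$y[2], p$bounds$z[2])
    if (any(lo < bl) || any(hi > bh))
      stop(sprintf("structure '%s' extends outside the volume bounds", s))
  }
  if (abs(p$rn$center[1]) >= abs(p$stn$center[1]))
    stop("RN must be strictly medial to the STN center")
  if (p$sn$center[3] >= p$stn$center[3])
    stop("SN centroid must be strictly ventral to the STN centroid")
  ## the SNc split plane must leave both SN compartments non-empty
  ext <- sqrt(sum((p$sn$axes * unitize(p$sncNormal))^2))
  if (p$sncOffset <= -ext || p$sncOffset >= ext)
    stop("sncOffset leaves the SNr or SNc empty; SNr and SNc must partition the SN")
  invisible(p)
}

## voxel-center coordinates along each grid axis
grid_axes <- function(p) {
  h <- p$voxelSize / 2
  lapply(p$bounds, function(b) seq(b[1] + h, b[2] - h, by = p$voxelSize))
}

## mask (logical array over the crop box) plus index ranges of an ellipsoid
rasterize_ellipsoid <- function(axes, center, semi) {
  ix <- which(abs(axes$x - center[1]) <= semi[1])
  iy <- which(abs(axes$y - center[2]) <= semi[2])
  iz <- which(abs(axes$z - center[3]) <= semi[3])
  if (!length(ix) || !length(iy) || !length(iz))
    return(NULL)
  dx2 <- ((axes$x[ix] - center[1]) / semi[1])^2
  dy2 <- ((axes$y[iy] - center[2]) / semi[2])^2
  dz2 <- ((axes$z[iz] - center[3]) / semi[3])^2
  m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  list(ix = ix, iy = iy, iz = iz, mask = m)
}

assign_label <- function(data, ras, code) {
  if (is.null(ras)) return(data)
  sub <- data[ras$ix, ras$iy, ras$iz, drop = FALSE]
  sub[ras$mask] <- code
  data[ras$ix, ras$iy, ras$iz] <- sub
  data
}

mirror_spec <- function(el) { el$center[1] <- -el$center[1]; el }

#' Rasterize the synthetic label atlas
#'
#' Builds a [LabelAtlas-class] from [anatomyParams()]: both hemispheres,
#' labels STN_MC, STN_assoc, SNr, SNc and RN per side. SNr and SNc partition
#' the SN ellipsoid and are therefore disjoint by construction; where
#' ellipsoids overlap, priority is RN over STN over SN. The voxel grid is
#' symmetric about the midsagittal plane so the left hemisphere is an exact
#' mirror image. Deterministic for given parameters.
#'
#' @param params an [anatomyParams()] list.
#' @return A [LabelAtlas-class].
#' @examples
#' atl <- makeAtlas(anatomyParams(voxelSize = 0.5))
#' atl
#' @export
makeAtlas <- function(params = anatomyParams()) {
  validate_anatomy(params)
  axes <- grid_axes(params)
  dims <- unname(lengths(axes))
  data <- array(0L, dim = dims)

  for (hemi in c("right", "left")) {
    off <- if (hemi == "right") 0L else 10L
    stn <- params$stn; sn <- params$sn; rn <- params$rn
    mcN <- unitize(params$mcNormal); sncN <- unitize(params$sncNormal)
    if (hemi == "left") {
      stn <- mirror_spec(stn); sn <- mirror_spec(sn); rn <- mirror_spec(rn)
      mcN[1] <- -mcN[1]; sncN[1] <- -sncN[1]
    }
    ## SN first (lowest priority), then STN, then RN
    ras <- rasterize_ellipsoid(axes, sn$center, sn$axes)
    if (is.null(ras)) stop("SN ellipsoid does not intersect the voxel grid")
    pts <- as.matrix(expand.grid(x = axes$x[ras$ix], y = axes$y[ras$iy],
                                 z = axes$z[ras$iz]))[as.vector(ras$mask), , drop = FALSE]
    proj <- drop(sweep(pts, 2L, sn$center) %*% sncN)
    sub <- data[ras$ix, ras$iy, ras$iz, drop = FALSE]
    sub[ras$mask] <- ifelse(proj >= params$sncOffset, .LABELS["SNc_R"],
                            .LABELS["SNr_R"]) + off
    data[ras$ix, ras$iy, ras$iz] <- sub

    ras <- rasterize_ellipsoid(axes, stn$center, stn$axes)
    if (is.null(ras)) stop("STN ellipsoid does not intersect the voxel grid")
    pts <- as.matrix(expand.grid(x = axes$x[ras$ix], y = axes$y[ras$iy],
                                 z = axes$z[ras$iz]))[as.vector(ras$mask), , drop = FALSE]
    proj <- drop(pts %*% mcN)
    thr <- stats::quantile(proj, 1 - params$mcFraction, names = FALSE, type = 1L)
    sub <- data[ras$ix, ras$iy, ras$iz, drop = FALSE]
    sub[ras$mask] <- ifelse(proj >= thr, .LABELS["STN_MC_R"],
                            .LABELS["STN_assoc_R"]) + off
    data[ras$ix, ras$iy, ras$iz] <- sub

    data <- assign_label(data, rasterize_ellipsoid(axes, rn$center, rn$axes),
                         .LABELS["RN_R"] + off)
  }

  affine <- diag(4)
  diag(affine)[1:3] <- params$voxelSize
  affine[1:3, 4L] <- c(axes$x[1], axes$y[1], axes$z[1])
  new("LabelAtlas", data = data, affine = affine, labelTable = .LABELS,
      masks = list(), cache = new.env(parent = emptyenv()))
}

hemi_suffix <- function(hemisphere) if (hemisphere == "left") "L" else "R"

## label codes of a (possibly composite) region in one hemisphere
region_codes <- function(atlas, region, hemisphere) {
  if (region == "CT") stop("CT is an overlay mask; use region_index()")
  parts <- .REGION_PARTS[[region]]
  if (is.null(parts)) stop(sprintf("unknown region '%s'", region))
  nms <- paste0(parts, "_", hemi_suffix(hemisphere))
  missing <- setdiff(nms, names(atlas@labelTable))
  if (length(missing))
    stop(sprintf("atlas label table lacks %s", paste(missing, collapse = ", ")))
  unname(atlas@labelTable[nms])
}

## linear voxel indices of a region (CT comes from the overlay masks)
region_index <- function(atlas, region, hemisphere) {
  if (region == "CT") {
    nm <- paste0("CT_", hemi_suffix(hemisphere))
    idx <- atlas@masks[[nm]]
    if (is.null(idx))
      stop("atlas has no central-target mask; run buildCentralTarget() first")
    return(idx)
  }
  which(atlas@data %in% region_codes(atlas, region, hemisphere))
}

## mm coordinates of region voxel centers, cached; optionally restricted to
## one axial slice index
region_coords <- function(atlas, region, hemisphere, slice = NULL) {
  key <- paste(region, hemisphere, sep = "|")
  coords <- atlas@cache[[key]]
  if (is.null(coords)) {
    idx <- region_index(atlas, region, hemisphere)
    coords <- voxel_to_world(atlas, idx)
    attr(coords, "slice") <- slice_of_index(atlas, idx)
    atlas@cache[[key]] <- coords
  }
  if (!is.null(slice))
    coords <- coords[attr(coords, "slice") == slice, , drop = FALSE]
  coords
}

slice_of_index <- function(atlas, idx) {
  dims <- dim(atlas@data)
  ((idx - 1L) %/% (dims[1L] * dims[2L])) + 1L
}

## linear voxel indices -> mm voxel-center coordinates (n x 3)
voxel_to_world <- function(atlas, idx) {
  dims <- dim(atlas@data)
  idx <- idx - 1L
  i <- idx %% dims[1L]
  j <- (idx %/% dims[1L]) %% dims[2L]
  k <- idx %/% (dims[1L] * dims[2L])
  vox <- cbind(i, j, k, 1)
  (vox %*% t(atlas@affine))[, 1:3, drop = FALSE]
}

## mm point(s) -> nearest voxel 1-based ijk indices (n x 3); may fall outside
world_to_voxel <- function(atlas, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  inv <- solve(atlas@affine)
  vox <- cbind(pts, 1) %*% t(inv)
  round(vox[, 1:3, drop = FALSE]) + 1L
}

#' Label name at a point
#'
#' Returns the anatomical label of the voxel containing a mm point, e.g.
#' `"STN_MC_R"`, or `NA` outside any structure or outside the volume.
#'
#' @param atlas a [LabelAtlas-class].
#' @param point numeric length-3 (mm).
#' @return Character label name or `NA`.
#' @export
atlasLabel <- function(atlas, point) {
  v <- world_to_voxel(atlas, point)
  dims <- dim(atlas@data)
  if (any(v < 1L) || any(v > dims)) return(NA_character_)
  code <- atlas@data[v[1L], v[2L], v[3L]]
  if (code == 0L) return(NA_character_)
  names(atlas@labelTable)[match(code, atlas@labelTable)]
}

#' Volume of one voxel in mm^3
#' @param atlas a [LabelAtlas-class].
#' @return Scalar mm^3, from the affine determinant (supports anisotropic
#'   voxels).
#' @export
voxelVolume <- function(atlas) abs(det(atlas@affine[1:3, 1:3]))
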