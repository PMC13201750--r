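#' Unit trajectory direction of a lead
#'
#' The implantation trajectory norm is the unit vector from the ventralmost
#' toward the dorsalmost contact (a 3D slope). Intermediate contacts do not
#' enter the computation.
#'
#' @param lead a [Lead-class].
#' @return Unit numeric length-3 vector pointing ventral to dorsal.
#' @examples
#' m <- getLeadModel("Medtronic 3389")
#' ld <- new("Lead", leadId = "L", hemisphere = "right", model = m,
#'           contacts = rbind(c(0, 0, 0), c(0, 0, 10)), extension = c(0, 0))
#' trajectoryNorm(ld)
#' @export
trajectoryNorm <- function(lead) {
  cc <- lead@contacts
  d <- cc[nrow(cc), ] - cc[1L, ]
  if (vnorm(d) < 1e-9) stop("ventralmost and dorsalmost contacts coincide")
  unitize(d)
}

#' Angle between a line and a plane
#'
#' Computes the unsigned angle between a direction vector and a plane, in
#' degrees within \[0, 90\]. The angle between the line and the plane normal
#' is `theta = acos(|l . n| / ||l||)`; the line-to-plane angle reported here
#' is `90 - theta`, which matches how implantation angles to the midsagittal
#' and AC-PC planes are quoted clinically. Symmetric under flipping either
#' the direction or the normal.
#'
#' @param l numeric length-3 direction (need not be unit length).
#' @param plane a [planeSpec()].
#' @return Angle in degrees in \[0, 90\].
#' @examples
#' angleToPlane(c(1, 0, 1), planeSpec(c(0, 0, 0), c(0, 0, 1)))  # 45
#' @export
angleToPlane <- function(l, plane) {
  stopifnot(is.numeric(l), length(l) == 3L, all(is.finite(l)))
  nl <- vnorm(l)
  if (nl < .Machine$double.eps * 10) stop("direction vector has zero length")
  ct <- abs(sum(l * plane$normal)) / nl
  ct <- min(max(ct, 0), 1)
  90 - acos(ct) * 180 / pi
}

#' Extend a lead with virtual contacts
#'
#' Simulates deeper implantation or larger array spans by adding virtual
#' contacts along the trajectory beyond the implanted ventralmost contact,
#' one per requested extension (arc-length mm). The default extensions of
#' 2, 4 and 6 mm generate three additional virtual contacts per lead.
#'
#' @param lead a [Lead-class] with implanted contacts only.
#' @param extensions positive, strictly increasing arc lengths in mm.
#' @return A [Lead-class] whose first `length(extensions)` contacts are
#'   virtual (most ventral first); the `extension` slot records each virtual
#'   contact's arc length.
#' @examples
#' m <- getLeadModel("Medtronic 3389")
#' ld <- new("Lead", leadId = "L", hemisphere = "right", model = m,
#'           contacts = rbind(c(0, 0, 10), c(0, 0, 16)), extension = c(0, 0))
#' contacts(extendVirtual(ld, 2))[1, ]  # (0, 0, 8)
#' @export
extendVirtual <- function(lead, extensions = c(2, 4, 6)) {
  if (!is.numeric(extensions) || !length(extensions) || any(extensions <= 0) ||
      any(diff(extensions) <= 0))
    stop("extensions must be positive and strictly increasing")
  if (any(lead@extension > 0))
    stop("lead already carries virtual contacts")
  u <- trajectoryNorm(lead)
  c0 <- lead@contacts[1L, ]
  virt <- t(vapply(rev(extensions), function(e) c0 - e * u, numeric(3L)))
  new("Lead", leadId = lead@leadId, hemisphere = lead@hemisphere,
      model = lead@model,
      contacts = rbind(virt, lead@contacts),
      extension = c(rev(extensions), lead@extension))
}

## internal: max-RN slice index and world z for one hemisphere
max_rn_slice <- function(atlas, hemisphere) {
  code <- region_codes(atlas, "RN", hemisphere)
  idx <- which(atlas@data %in% code)
  if (!length(idx)) stop(sprintf("atlas has no RN voxels for hemisphere '%s'", hemisphere))
  dims <- dim(atlas@data)
  k <- ((idx - 1L) %/% (dims[1L] * dims[2L])) + 1L
  counts <- tabulate(k, nbins = dims[3L])
  best <- which(counts == max(counts))
  ## world z of candidate slices; tie goes to the more ventral slice
  zs <- vapply(best, function(kk)
    (atlas@affine %*% c(0, 0, kk - 1, 1))[3L], numeric(1L))
  best[which.min(zs)]
}

#' Locate the plane of maximal red nucleus cross-section
#'
#' Scans axial atlas slices and returns the plane of the slice where the
#' ipsilateral red nucleus has the largest cross-sectional voxel count (the
#' max-RN plane, the reference slice for targeting). Ties are broken toward
#' the more ventral slice.
#'
#' @param atlas a [LabelAtlas-class] containing RN voxels for the hemisphere.
#' @param hemisphere "left" or "right".
#' @param frame optional [NativeFrame-class]; if supplied, the atlas grid z
#'   axis must be parallel to the frame dorsal axis (within 1e-6) and the
#'   returned normal is the frame dorsal axis.
#' @return A [planeSpec()] with normal along the axial (dorsal) axis.
#' @export
findMaxRnPlane <- function(atlas, hemisphere = c("right", "left"), frame = NULL) {
  hemisphere <- match.arg(hemisphere)
  k <- max_rn_slice(atlas, hemisphere)
  pt <- drop(atlas@affine %*% c(0, 0, k - 1, 1))[1:3]
  nrm <- unitize(atlas@affine[1:3, 3L])
  if (!is.null(frame)) {
    ez <- frame@basis[, 3L]
    if (abs(abs(sum(nrm * ez)) - 1) > 1e-6)
      stop("atlas grid z axis is not aligned with the frame dorsal axis")
    nrm <- ez
  }
  planeSpec(pt, nrm)
}

#' Bejjani origin of the targeting coordinate system
#'
#' In the max-RN axial slice, Bejjani's line runs mediolaterally through the
#' anterior border of the ipsilateral red nucleus. Its intersection with the
#' medial border of the STN defines the (0, 0) origin for the X/Y trajectory
#' features. The anterior RN border is taken as the anterior-most RN voxel
#' center in the slice; the medial STN border as the STN voxel center closest
#' to the midsagittal plane among voxels within +/- 0.5 mm of the line's
#' anterior-posterior coordinate.
#'
#' @param atlas a [LabelAtlas-class].
#' @param frame a [NativeFrame-class].
#' @param hemisphere "left" or "right".
#' @return Numeric length-3 point (mm) on the max-RN plane.
#' @export
bejjaniOrigin <- function(atlas, frame, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  k <- max_rn_slice(atlas, hemisphere)
  rn <- region_coords(atlas, "RN", hemisphere, slice = k)
  stn <- region_coords(atlas, "STN", hemisphere, slice = k)
  if (!nrow(stn))
    stop(sprintf("no STN voxels in the max-RN slice for hemisphere '%s'", hemisphere))
  rnF <- frame_coords(rn, frame)
  stnF <- frame_coords(stn, frame)
  y0 <- max(rnF[, 2L])                       # anterior RN tangent
  band <- abs(stnF[, 2L] - y0) <= 0.5
  if (!any(band))
    stop(sprintf(
      "Bejjani's line misses the STN in the max-RN slice (closest STN voxel %.2f mm from the line)",
      min(abs(stnF[, 2L] - y0))))
  cand <- stnF[band, , drop = FALSE]
  ## medial border: minimal unsigned distance from the midsagittal plane
  x0 <- cand[which.min(abs(cand[, 1L])), 1L]
  z0 <- frame_coords(drop(atlas@affine %*% c(0, 0, k - 1, 1))[1:3], frame)[1, 3L]
  drop(frame@basis %*% c(x0, y0, z0))
}

## internal: intersection of a lead's trajectory line with a plane
trajectory_plane_point <- function(lead, plane) {
  u <- trajectoryNorm(lead)
  denom <- sum(u * plane$normal)
  if (abs(denom) < 1e-9) stop("trajectory is parallel to the plane")
  p0 <- lead@contacts[1L, ]
  t <- sum((plane$point - p0) * plane$normal) / denom
  p0 + t * u
}

#' Extract targeting features of a trajectory
#'
#' Computes the four features fed to the engagement classifiers: the X
#' (lateral, positive) and Y (anterior, positive) offsets of the point where
#' the trajectory crosses the max-RN plane, measured from the Bejjani origin,
#' and the angles of the trajectory to the midsagittal and AC-PC planes.
#' Left-hemisphere X is reflected so lateral is positive in both hemispheres,
#' allowing bilateral pooling.
#'
#' @param lead a [Lead-class].
#' @param atlas a [LabelAtlas-class].
#' @param frame a [NativeFrame-class].
#' @return One-row `data.frame` with columns `lead_id`, `hemisphere`, `x_mm`,
#'   `y_mm`, `ms_angle`, `acpc_angle`.
#' @seealso [trajectoryFeatures()] for whole cohorts.
#' @export
extractFeatures <- function(lead, atlas, frame) {
  hemi <- lead@hemisphere
  plane <- findMaxRnPlane(atlas, hemi, frame)
  origin <- bejjaniOrigin(atlas, frame, hemi)
  extract_features_at(lead, plane, origin, frame)
}

## internal worker reusing a precomputed plane and origin
extract_features_at <- function(lead, plane, origin, frame) {
  u <- trajectoryNorm(lead)
  q <- trajectory_plane_point(lead, plane)
  rel <- frame_coords(q - origin, frame)
  lat <- if (lead@hemisphere == "left") -rel[1L, 1L] else rel[1L, 1L]
  data.frame(lead_id = lead@leadId, hemisphere = lead@hemisphere,
             x_mm = lat, y_mm = rel[1L, 2L],
             ms_angle = angleToPlane(u, frame@midsagittal),
             acpc_angle = angleToPlane(u, frame@acpc),
             stringsAsFactors = FALSE)
}

#' Feature table for a cohort of leads
#'
#' Vectorized wrapper around [extractFeatures()] that computes the max-RN
#' plane and Bejjani origin once per hemisphere.
#'
#' @param leads list of [Lead-class] objects.
#' @param atlas a [LabelAtlas-class].
#' @param frame a [NativeFrame-class].
#' @return `data.frame` with one row per lead.
#' @export
trajectoryFeatures <- function(leads, atlas, frame) {
  hemis <- unique(vapply(leads, function(l) l@hemisphere, character(1L)))
  planes <- lapply(stats::setNames(hemis, hemis), function(h)
    findMaxRnPlane(atlas, h, frame))
  origins <- lapply(stats::setNames(hemis, hemis), function(h)
    bejjaniOrigin(atlas, frame, h))
  do.call(rbind, lapply(leads, function(l)
    extract_features_at(l, planes[[l@hemisphere]], origins[[l@hemisphere]], frame)))
}

#' Arc-length depth of a contact below a plane
#'
#' Signed distance measured along the electrode trajectory (not along the z
#' axis) from the point where the trajectory crosses the plane to the
#' contact; positive below (ventral to) the plane. For a trajectory at angle
#' `a` to the plane, a contact `dz` mm below the plane has depth
#' `dz / sin(a)`.
#'
#' @param contact numeric length-3 contact center (mm), assumed on the
#'   trajectory line.
#' @param lead the [Lead-class] defining the trajectory.
#' @param plane a [planeSpec()], typically the max-RN plane.
#' @return Depth in mm, ventral-positive.
#' @export
depthAlongTrajectory <- function(contact, lead, plane) {
  u <- trajectoryNorm(lead)
  dn <- sum(u * plane$normal)
  if (abs(dn) < 1e-9) stop("trajectory is parallel to the plane")
  q <- trajectory_plane_point(lead, plane)
  s <- sum((as.numeric(contact) - q) * u)
  -s * sign(dn)
}

#' Depths of all contacts of a lead
#'
#' @param lead a [Lead-class].
#' @param plane a [planeSpec()].
#' @return Numeric vector of ventral-positive arc-length depths, one per
#'   contact (same order as `contacts(lead)`).
#' @export
contactDepths <- function(lead, plane) {
  apply(lead@contacts, 1L, depthAlongTrajectory, lead = lead, plane = plane)
}
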