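#' Volume of overlap between a sphere and an atlas region
#'
#' Estimates the volume of the intersection of a sphere with a labeled
#' region by voxel-center inclusion: the count of region voxel centers
#' within the radius times the voxel volume. Deterministic; converges to the
#' analytic volume as the voxel size shrinks.
#'
#' @param center numeric length-3 sphere center (mm).
#' @param radius sphere radius in mm (> 0).
#' @param atlas a [LabelAtlas-class].
#' @param region one of "STN", "STN_MC", "STN_assoc", "SN", "SNr", "SNc",
#'   "RN", "CT".
#' @param hemisphere "left" or "right".
#' @return Overlap volume in mm^3.
#' @export
sphereRegionOverlap <- function(center, radius, atlas, region,
                                hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(radius > 0)
  coords <- region_coords(atlas, region, hemisphere)
  if (!nrow(coords)) return(0)
  center <- as.numeric(center)
  d2 <- (coords[, 1L] - center[1L])^2 + (coords[, 2L] - center[2L])^2 +
    (coords[, 3L] - center[3L])^2
  sum(d2 <= radius^2) * voxelVolume(atlas)
}

#' Classify a contact's substantia nigra engagement
#'
#' A contact engages a region if a sphere of `radius` (default 1 mm) around
#' it intersects the region. A contact overlapping both SN compartments is
#' assigned to the one with the greater overlap volume; an exact non-zero
#' tie is assigned to SNr with a warning (ties are measure-zero at fine
#' voxel sizes but must resolve deterministically). Contacts touching
#' neither compartment are class "none".
#'
#' @param contact numeric length-3 contact center (mm).
#' @param atlas a [LabelAtlas-class].
#' @param hemisphere "left" or "right".
#' @param radius contact engagement radius in mm.
#' @param regions additional regions whose overlap volumes to report.
#' @return A list with `snClass` ("SNr", "SNc" or "none") and `overlaps`, a
#'   named numeric vector of overlap volumes in mm^3.
#' @export
classifyContact <- function(contact, atlas, hemisphere = c("right", "left"),
                            radius = 1, regions = c("STN_MC", "CT")) {
  hemisphere <- match.arg(hemisphere)
  regions <- setdiff(regions, c("SNr", "SNc"))
  if ("CT" %in% regions && is.null(atlas@masks[[paste0("CT_", hemi_suffix(hemisphere))]]))
    regions <- setdiff(regions, "CT")
  all_regions <- c("SNr", "SNc", regions)
  ov <- vapply(all_regions, function(r)
    sphereRegionOverlap(contact, radius, atlas, r, hemisphere), numeric(1L))
  snr <- ov[["SNr"]]; snc <- ov[["SNc"]]
  snClass <- if (snr == 0 && snc == 0) "none"
    else if (snr > snc) "SNr"
    else if (snc > snr) "SNc"
    else {
      warning("exact SNr/SNc overlap tie; assigning SNr")
      "SNr"
    }
  list(snClass = snClass, overlaps = ov)
}

.SCENARIOS <- c(implanted_only = 0, plus2mm = 2, plus4mm = 4, plus6mm = 6)

#' Trajectory-level engagement under an extension scenario
#'
#' A trajectory engages a region if any of its eligible contacts does. The
#' scenario restricts which virtual contacts count: `implanted_only` uses
#' implanted contacts, `plus2mm`/`plus4mm`/`plus6mm` additionally admit
#' virtual contacts up to that extension. While a single contact is SNr or
#' SNc but never both, a trajectory can engage both compartments through
#' different contacts.
#'
#' @param lead a [Lead-class] (extend first with [extendVirtual()] if virtual
#'   scenarios are wanted).
#' @param atlas a [LabelAtlas-class].
#' @param scenario one of `names(nigratarget:::.SCENARIOS)`.
#' @param radius contact engagement radius in mm.
#' @return List with `lead_id`, `scenario` and `engaged`, a character vector
#'   drawn from SNr, SNc, MC, CT.
#' @export
classifyTrajectory <- function(lead, atlas,
                               scenario = c("implanted_only", "plus2mm",
                                            "plus4mm", "plus6mm"),
                               radius = 1) {
  scenario <- match.arg(scenario)
  tab <- contact_engagements(lead, atlas, radius)
  aggregate_scenario(tab, lead@leadId, scenario)
}

## per-contact engagement records for one lead (data.frame)
contact_engagements <- function(lead, atlas, radius = 1) {
  cc <- lead@contacts
  rows <- lapply(seq_len(nrow(cc)), function(i) {
    ce <- classifyContact(cc[i, ], atlas, lead@hemisphere, radius)
    data.frame(contact_index = i - 1L, extension = lead@extension[i],
               is_virtual = lead@extension[i] > 0,
               sn_class = ce$snClass,
               overlap_snr = ce$overlaps[["SNr"]],
               overlap_snc = ce$overlaps[["SNc"]],
               overlap_mc = ce$overlaps[["STN_MC"]] %||% NA_real_,
               overlap_ct = if ("CT" %in% names(ce$overlaps))
                 ce$overlaps[["CT"]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

aggregate_scenario <- function(tab, lead_id, scenario) {
  maxExt <- .SCENARIOS[[scenario]]
  el <- tab[tab$extension <= maxExt, , drop = FALSE]
  engaged <- character()
  if (any(el$sn_class == "SNr")) engaged <- c(engaged, "SNr")
  if (any(el$sn_class == "SNc")) engaged <- c(engaged, "SNc")
  if (any(!is.na(el$overlap_mc) & el$overlap_mc > 0)) engaged <- c(engaged, "MC")
  if (any(!is.na(el$overlap_ct) & el$overlap_ct > 0)) engaged <- c(engaged, "CT")
  list(lead_id = lead_id, scenario = scenario, engaged = engaged)
}

#' Engagement table for a cohort
#'
#' Classifies every contact of every lead once and aggregates to
#' trajectory-level engagement flags per extension scenario.
#'
#' @param leads list of [Lead-class] objects.
#' @param atlas a [LabelAtlas-class].
#' @param scenarios subset of the four extension scenarios.
#' @param radius contact engagement radius in mm.
#' @return `data.frame` with columns `lead_id`, `scenario`, logical `snr`,
#'   `snc`, `both`, `none` (no SN engagement), `mc`, `ct`.
#' @export
engagementTable <- function(leads, atlas,
                            scenarios = names(.SCENARIOS), radius = 1) {
  scenarios <- match.arg(scenarios, names(.SCENARIOS), several.ok = TRUE)
  rows <- lapply(leads, function(ld) {
    tab <- contact_engagements(ld, atlas, radius)
    do.call(rbind, lapply(scenarios, function(sc) {
      e <- aggregate_scenario(tab, ld@leadId, sc)$engaged
      data.frame(lead_id = ld@leadId, scenario = sc,
                 snr = "SNr" %in% e, snc = "SNc" %in% e,
                 both = all(c("SNr", "SNc") %in% e),
                 none = !any(c("SNr", "SNc") %in% e),
                 mc = "MC" %in% e, ct = "CT" %in% e,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Construct the central target (CT) inside the STN
#'
#' The CT approximates reported STN stimulation sweet spots: STN voxels
#' whose centers lie within 0.75 mm of the boundary between the motor and
#' associative compartments (boundary taken as the shared faces of
#' 6-adjacent MC/associative voxel pairs), with the most ventral 50% of that
#' band excluded. The retained (dorsal) set has exactly
#' `ceiling(0.5 * band size)` voxels; voxels tied at the cut z are admitted
#' in deterministic (linear index) order.
#'
#' @param atlas a [LabelAtlas-class] with STN_MC and STN_assoc labels.
#' @param bandWidth distance to the MC-associative boundary in mm.
#' @return The atlas with `CT_R` and `CT_L` overlay masks added.
#' @export
buildCentralTarget <- function(atlas, bandWidth = 0.75) {
  masks <- atlas@masks
  for (hemi in c("right", "left")) {
    suf <- hemi_suffix(hemi)
    mcCode <- atlas@labelTable[[paste0("STN_MC_", suf)]]
    asCode <- atlas@labelTable[[paste0("STN_assoc_", suf)]]
    faces <- boundary_faces(atlas@data, mcCode, asCode, atlas)
    if (!nrow(faces))
      stop(sprintf("no MC/associative boundary in hemisphere '%s'", hemi))
    stnIdx <- region_index(atlas, "STN", hemi)
    stnXYZ <- voxel_to_world(atlas, stnIdx)
    near <- points_within(stnXYZ, faces, bandWidth)
    bandIdx <- stnIdx[near]
    if (!length(bandIdx))
      stop(sprintf("boundary band is empty in hemisphere '%s'", hemi))
    z <- voxel_to_world(atlas, bandIdx)[, 3L]
    keep <- ceiling(length(bandIdx) / 2)
    ord <- order(-z, bandIdx)
    masks[[paste0("CT_", suf)]] <- sort(bandIdx[ord[seq_len(keep)]])
  }
  out <- new("LabelAtlas", data = atlas@data, affine = atlas@affine,
             labelTable = atlas@labelTable, masks = masks,
             cache = new.env(parent = emptyenv()))
  out
}

## face midpoints between 6-adjacent voxels of codes a and b
boundary_faces <- function(arr, a, b, atlas) {
  dims <- dim(arr)
  faces <- list()
  for (ax in 1:3) {
    n <- dims[ax]
    lo <- slice_array(arr, ax, 1:(n - 1))
    hi <- slice_array(arr, ax, 2:n)
    hit <- (lo == a & hi == b) | (lo == b & hi == a)
    if (!any(hit)) next
    idx <- which(hit)
    ijk <- arrayInd(idx, dim(hit))
    ## midpoint between voxel (i,...) and its +1 neighbor along ax
    lowv <- ijk
    highv <- ijk; highv[, ax] <- highv[, ax] + 1L
    p1 <- ijk_to_world(atlas, lowv)
    p2 <- ijk_to_world(atlas, highv)
    faces[[length(faces) + 1L]] <- (p1 + p2) / 2
  }
  if (!length(faces)) return(matrix(numeric(), 0L, 3L))
  do.call(rbind, faces)
}

slice_array <- function(arr, ax, idx) {
  switch(ax,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

ijk_to_world <- function(atlas, ijk) {
  (cbind(ijk - 1L, 1) %*% t(atlas@affine))[, 1:3, drop = FALSE]
}

## which rows of pts lie within dist of any row of ref (chunked for memory)
points_within <- function(pts, ref, dist) {
  n <- nrow(pts)
  out <- logical(n)
  d2 <- dist^2
  chunk <- max(1L, floor(2e7 / max(1L, nrow(ref))))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- pts[s:e, , drop = FALSE]
    dd <- outer(rowSums(block^2), rowSums(ref^2), `+`) -
      2 * tcrossprod(block, ref)
    rowMin <- dd[cbind(seq_len(nrow(dd)), max.col(-dd, ties.method = "first"))]
    out[s:e] <- rowMin <= d2 + 1e-9
  }
  out
}

#' Percent VAT overlap with a region
#'
#' The volume of activated tissue (VAT) for 1 mA stimulation is modeled as a
#' 2 mm radius sphere around the contact. Overlap is reported as the
#' percentage of the VAT volume inside the region, a graded engagement
#' measure complementing the binary sphere rule.
#'
#' @param contact numeric length-3 contact center (mm).
#' @param atlas a [LabelAtlas-class].
#' @param region region name as in [sphereRegionOverlap()].
#' @param hemisphere "left" or "right".
#' @param radius VAT radius in mm (default 2, the 1 mA approximation).
#' @return Percent in \[0, 100\].
#' @export
vatOverlap <- function(contact, atlas, region, hemisphere = c("right", "left"),
                       radius = 2) {
  hemisphere <- match.arg(hemisphere)
  vol <- sphereRegionOverlap(contact, radius, atlas, region, hemisphere)
  min(100, max(0, 100 * vol / (4 / 3 * pi * radius^3)))
}

#' Depth-binned VAT overlap profile
#'
#' For every contact of every lead (virtual contacts included by default),
#' measures arc-length depth below the ipsilateral max-RN plane and the VAT
#' percent overlap with the region, then aggregates into 2 mm-wide bins
#' `[center - 1, center + 1)`. Empty bins are absent from the result, not
#' reported as zero.
#'
#' @param leads list of [Lead-class] objects.
#' @param atlas a [LabelAtlas-class].
#' @param frame a [NativeFrame-class].
#' @param region region name, typically "SNr" or "SNc".
#' @param binCenters bin centers in mm.
#' @param radius VAT radius in mm.
#' @param includeVirtual include virtual contacts.
#' @return `data.frame` with `region`, `bin_center`, `n`, `mean_percent`,
#'   `sem`.
#' @export
depthProfile <- function(leads, atlas, frame, region = "SNr",
                         binCenters = seq(-6, 12, by = 2), radius = 2,
                         includeVirtual = TRUE) {
  hemis <- unique(vapply(leads, function(l) l@hemisphere, character(1L)))
  planes <- lapply(stats::setNames(hemis, hemis), function(h)
    findMaxRnPlane(atlas, h, frame))
  depth <- numeric(); pct <- numeric()
  for (ld in leads) {
    keep <- if (includeVirtual) rep(TRUE, nrow(ld@contacts)) else ld@extension == 0
    cc <- ld@contacts[keep, , drop = FALSE]
    dd <- contactDepths(ld, planes[[ld@hemisphere]])[keep]
    pp <- apply(cc, 1L, vatOverlap, atlas = atlas, region = region,
                hemisphere = ld@hemisphere, radius = radius)
    depth <- c(depth, dd); pct <- c(pct, pp)
  }
  rows <- lapply(binCenters, function(ctr) {
    inbin <- depth >= ctr - 1 & depth < ctr + 1
    n <- sum(inbin)
    if (n == 0L) return(NULL)
    m <- mean(pct[inbin])
    sem <- if (n > 1L) stats::sd(pct[inbin]) / sqrt(n) else 0
    data.frame(region = region, bin_center = ctr, n = n,
               mean_percent = m, sem = sem, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort engagement rate summary
#'
#' Fractions of trajectories engaging SNr, SNc, both, none (no SN), MC and
#' CT, stratified by scenario and lead design class (plus an "all" stratum).
#' Each fraction is count/total and counts are reported alongside.
#'
#' @param engagements output of [engagementTable()].
#' @param designs `data.frame` with `lead_id` and `design_class`
#'   ("standard"/"extended"); optional.
#' @return `data.frame` of rates and counts per scenario and stratum.
#' @export
cohortSummary <- function(engagements, designs = NULL) {
  stopifnot(nrow(engagements) >= 1L)
  e <- engagements
  if (!is.null(designs)) {
    e <- merge(e, designs[, c("lead_id", "design_class")], by = "lead_id")
  } else {
    e$design_class <- NA_character_
  }
  strata <- c("all", unique(stats::na.omit(e$design_class)))
  out <- list()
  for (sc in unique(e$scenario)) {
    for (st in strata) {
      sub <- e[e$scenario == sc & (st == "all" | (!is.na(e$design_class) &
                                                    e$design_class == st)), ]
      if (!nrow(sub)) next
      n <- nrow(sub)
      cnt <- vapply(c("snr", "snc", "both", "none", "mc", "ct"),
                    function(cl) sum(sub[[cl]]), numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, stratum = st, n = n,
        n_snr = cnt[["snr"]], snr_rate = cnt[["snr"]] / n,
        n_snc = cnt[["snc"]], snc_rate = cnt[["snc"]] / n,
        n_both = cnt[["both"]], both_rate = cnt[["both"]] / n,
        n_none = cnt[["none"]], none_rate = cnt[["none"]] / n,
        n_mc = cnt[["mc"]], mc_rate = cnt[["mc"]] / n,
        n_ct = cnt[["ct"]], ct_rate = cnt[["ct"]] / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
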