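## Electrode models in the dataset the analysis emulates. Spacing is the
## center-to-center distance between returned contact levels (levels are
## modeled as points; contact height is not modeled). A model is "extended"
## if it has more than four levels or spacing above 0.5 mm.
.LEAD_MODELS <- data.frame(
  name = c("Boston Scientific Vercise Cartesia X",
           "Boston Scientific Vercise Directed",
           "Medtronic 3387", "Medtronic 3389",
           "Medtronic B33005", "Medtronic B33015",
           "Abbott/St. Jude Directed 6172", "Abbott/St. Jude Directed 6173"),
  n_levels = c(6L, 4L, 4L, 4L, 4L, 4L, 4L, 4L),
  spacing = c(0.5, 0.5, 1.5, 0.5, 0.5, 1.5, 0.5, 1.5),
  stringsAsFactors = FALSE)
.LEAD_MODELS$design_class <-
  ifelse(.LEAD_MODELS$n_levels > 4L | .LEAD_MODELS$spacing > 0.5,
         "extended", "standard")

#' Registry of supported electrode models
#'
#' @return `data.frame` with `name`, `n_levels`, `spacing` (mm) and
#'   `design_class` for the eight supported lead models.
#' @examples
#' leadModelRegistry()
#' @export
leadModelRegistry <- function() .LEAD_MODELS

#' Look up a lead model by name
#'
#' @param name model name as listed by [leadModelRegistry()].
#' @return A [LeadModel-class].
#' @export
getLeadModel <- function(name) {
  i <- match(name, .LEAD_MODELS$name)
  if (is.na(i)) stop(sprintf("unknown lead model '%s'", name))
  new("LeadModel", name = .LEAD_MODELS$name[i],
      nLevels = .LEAD_MODELS$n_levels[i],
      spacing = .LEAD_MODELS$spacing[i],
      designClass = .LEAD_MODELS$design_class[i])
}

## trajectory direction (ventral->dorsal, world coords) for requested angles
trajectory_direction <- function(msAngle, acpcAngle, hemisphere, frame) {
  if (msAngle <= 0 || msAngle >= 90 || acpcAngle <= 0 || acpcAngle >= 90)
    stop("angles must lie strictly inside (0, 90) degrees")
  sx <- sin(msAngle * pi / 180)
  sz <- sin(acpcAngle * pi / 180)
  rest <- 1 - sx^2 - sz^2
  if (rest <= 1e-12)
    stop("incompatible angles: sin^2(MS) + sin^2(AC-PC) must be < 1")
  dx <- if (hemisphere == "left") -sx else sx
  drop(frame@basis %*% c(dx, sqrt(rest), sz))
}

#' Construct a lead with requested trajectory features
#'
#' Builds a lead whose trajectory crosses `targetPoint` (a mm point on the
#' max-RN plane) at the requested midsagittal and AC-PC angles, with the
#' deepest contact `depthMm` of arc length below that plane. Contact centers
#' are collinear and spaced by the model's inter-level spacing. The
#' direction is oriented dorsal, anterior, and lateral for the given
#' hemisphere, the standard frontal approach. Recomputing features of the
#' returned lead reproduces the request to within numerical round-off.
#'
#' @param model a [LeadModel-class] or model name.
#' @param targetPoint numeric length-3, the intended crossing point (mm) on
#'   the max-RN plane.
#' @param msAngle,acpcAngle trajectory angles in degrees, each in (0, 90),
#'   jointly satisfying `sin^2(MS) + sin^2(AC-PC) < 1`.
#' @param depthMm arc length (mm) of the deepest contact below the plane;
#'   0 places it exactly on the plane, negative values above it.
#' @param frame a [NativeFrame-class].
#' @param hemisphere "left" or "right".
#' @param leadId identifier.
#' @param atlas optional [LabelAtlas-class]; if given, contacts outside the
#'   volume bounds raise an error naming the offending contact.
#' @return A [Lead-class].
#' @export
makeLead <- function(model, targetPoint, msAngle, acpcAngle, depthMm, frame,
                     hemisphere = c("right", "left"), leadId = "lead",
                     atlas = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (is.character(model)) model <- getLeadModel(model)
  d <- trajectory_direction(msAngle, acpcAngle, hemisphere, frame)
  c0 <- as.numeric(targetPoint) - depthMm * d
  cc <- t(vapply(seq_len(model@nLevels) - 1L,
                 function(k) c0 + k * model@spacing * d, numeric(3L)))
  if (!is.null(atlas)) {
    dims <- dim(atlas@data)
    v <- world_to_voxel(atlas, cc)
    bad <- which(apply(v, 1L, function(r) any(r < 1L) || any(r > dims)))
    if (length(bad))
      stop(sprintf("contact %d of lead '%s' falls outside the atlas volume",
                   bad[1L] - 1L, leadId))
  }
  new("Lead", leadId = leadId, hemisphere = hemisphere, model = model,
      contacts = cc, extension = rep(0, model@nLevels))
}

#' Parameters of a synthetic electrode cohort
#'
#' Defines the generating distribution of a cohort of STN-targeted leads.
#' Leads belong to one of three intent classes: SNr-aimed, SNc-aimed or
#' off-target. Per-class feature means default to the reported cohort means
#' for SNr- and SNc-engaging trajectories (X 2.0 / 0.97 mm lateral, Y 0.45
#' anterior / 0.66 posterior mm, MS 22.3 / 22.5 deg, AC-PC 50.1 / 49.2 deg);
#' spreads are those SEMs scaled back to population SDs using the class
#' sizes implied by a 612-trajectory cohort. The off-target class is
#' displaced anteriorly and, chiefly, implanted shallow (deepest contact
#' above the max-RN plane), so it misses the SN at implanted depth while
#' often remaining anatomically on track. Class intent labels are
#' generating metadata only; ground-truth engagement always comes from the
#' engagement module.
#'
#' @param nLeads number of leads.
#' @param classMix named proportions over `snr`, `snc`, `off` (sum to 1).
#' @param featureMeans 3 x 4 matrix (rows snr, snc, off; columns x_mm, y_mm,
#'   ms_angle, acpc_angle).
#' @param featureSds 3 x 4 matrix of per-class SDs (>= 0).
#' @param leadModelMix named proportions over registry model names
#'   (default uniform).
#' @param depthMean,depthSd per-class implantation depth (mm of arc below
#'   the max-RN plane for the deepest contact); recycled if scalar.
#' @param seed integer RNG seed.
#' @return A list of class `cohortParams`.
#' @export
cohortParams <- function(nLeads = 100L,
                         classMix = c(snr = 0.55, snc = 0.32, off = 0.13),
                         featureMeans = rbind(
                           snr = c(2.0, 0.45, 22.3, 50.1),
                           snc = c(0.97, -0.66, 22.5, 49.2),
                           off = c(2.0, 3.5, 22.4, 50.0)),
                         featureSds = rbind(
                           snr = c(1.35, 1.35, 4.4, 6.4),
                           snc = c(1.04, 1.04, 3.8, 5.5),
                           off = c(1.5, 1.5, 4.0, 6.0)),
                         leadModelMix = NULL,
                         depthMean = c(snr = 3.5, snc = 3.5, off = -3),
                         depthSd = c(snr = 1.5, snc = 1.5, off = 1.5),
                         seed = 1L) {
  if (is.null(leadModelMix)) {
    nm <- leadModelRegistry()$name
    leadModelMix <- stats::setNames(rep(1 / length(nm), length(nm)), nm)
  }
  cls <- c("snr", "snc", "off")
  if (length(depthMean) == 1L) depthMean <- stats::setNames(rep(depthMean, 3L), cls)
  if (length(depthSd) == 1L) depthSd <- stats::setNames(rep(depthSd, 3L), cls)
  p <- list(nLeads = as.integer(nLeads), classMix = classMix,
            featureMeans = featureMeans, featureSds = featureSds,
            leadModelMix = leadModelMix,
            depthMean = depthMean, depthSd = depthSd, seed = as.integer(seed))
  class(p) <- "cohortParams"
  stopifnot(p$nLeads >= 1L,
            abs(sum(p$classMix) - 1) < 1e-8,
            abs(sum(p$leadModelMix) - 1) < 1e-8,
            all(p$featureSds >= 0), all(p$depthSd >= 0),
            identical(rownames(p$featureMeans), cls),
            identical(rownames(p$featureSds), cls))
  p
}

#' Sample a synthetic lead cohort
#'
#' Draws leads from the generating distribution in [cohortParams()]:
#' per-lead intent class, trajectory features (truncated-normal per feature;
#' draws with geometrically impossible angle pairs are rejected and
#' resampled), lead model, hemisphere (balanced Bernoulli) and implantation
#' depth. Each lead is constructed with [makeLead()] so that its trajectory
#' crosses the sampled (X, Y) point on the ipsilateral max-RN plane at the
#' sampled angles. Deterministic given the seed.
#'
#' @param atlas a [LabelAtlas-class].
#' @param params a [cohortParams()] list.
#' @param frame the [NativeFrame-class] the atlas was built with.
#' @return List with `leads` (list of [Lead-class]) and `truth`, a
#'   `data.frame` of the generating class and sampled features per lead.
#' @export
sampleCohort <- function(atlas, params, frame) {
  set.seed(params$seed)
  hemis <- c("right", "left")
  origins <- lapply(stats::setNames(hemis, hemis), function(h)
    bejjaniOrigin(atlas, frame, h))
  planes <- lapply(stats::setNames(hemis, hemis), function(h)
    findMaxRnPlane(atlas, h, frame))
  classes <- sample(names(params$classMix), params$nLeads, replace = TRUE,
                    prob = params$classMix)
  models <- sample(names(params$leadModelMix), params$nLeads, replace = TRUE,
                   prob = params$leadModelMix)
  hemi <- sample(hemis, params$nLeads, replace = TRUE)
  leads <- vector("list", params$nLeads)
  truth <- vector("list", params$nLeads)
  for (i in seq_len(params$nLeads)) {
    cl <- classes[i]
    mu <- params$featureMeans[cl, ]; sdv <- params$featureSds[cl, ]
    feat <- NULL
    for (attempt in 1:100) {
      f <- stats::rnorm(4L, mu, sdv)
      ok <- f[3] > 2 && f[3] < 88 && f[4] > 2 && f[4] < 88 &&
        sin(f[3] * pi / 180)^2 + sin(f[4] * pi / 180)^2 < 0.98
      if (ok) { feat <- f; break }
      if (attempt == 100L)
        stop("could not sample a geometrically valid trajectory in 100 attempts")
      message(sprintf("lead %d: resampled degenerate angle draw (attempt %d)",
                      i, attempt))
    }
    depth <- stats::rnorm(1L, params$depthMean[[cl]], params$depthSd[[cl]])
    h <- hemi[i]
    lat <- if (h == "left") -1 else 1
    target <- origins[[h]] + lat * feat[1] * frame@basis[, 1L] +
      feat[2] * frame@basis[, 2L]
    ## keep the crossing point exactly on the max-RN plane (origins are)
    id <- sprintf("lead_%04d", i)
    leads[[i]] <- makeLead(models[i], target, feat[3], feat[4], depth, frame,
                           hemisphere = h, leadId = id)
    truth[[i]] <- data.frame(
      lead_id = id, class = cl, hemisphere = h, model = models[i],
      design_class = leadModelRegistry()$design_class[
        match(models[i], leadModelRegistry()$name)],
      x_mm = feat[1], y_mm = feat[2], ms_angle = feat[3], acpc_angle = feat[4],
      depth_mm = depth, stringsAsFactors = FALSE)
  }
  list(leads = leads, truth = do.call(rbind, truth))
}
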