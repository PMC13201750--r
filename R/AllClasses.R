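#' @import methods
NULL

setOldClass("planeSpec")

#' Labeled subcortical atlas volume
#'
#' A voxel grid of integer anatomical labels with a mm-to-voxel affine. The
#' atlas is the geometric ground truth that all engagement scoring runs
#' against. Label codes are listed in `labelTable` (named integer vector,
#' e.g. `STN_MC_R`, `SNr_L`); 0 is background. Because each voxel carries a
#' single label, SNr and SNc voxel sets are disjoint by construction. Overlay
#' regions that are subsets of labeled structures (the central target, CT)
#' live in `masks` as vectors of linear voxel indices so they can coexist
#' with the compartment labels.
#'
#' @slot data integer 3D array of label codes.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to mm (RAS).
#' @slot labelTable named integer vector, label name to code.
#' @slot masks list of integer vectors of linear voxel indices (overlays).
#' @slot cache environment used to memoize per-region voxel coordinates.
#' @export
setClass("LabelAtlas",
  representation(data = "array", affine = "matrix",
                 labelTable = "integer", masks = "list",
                 cache = "environment"))

setValidity("LabelAtlas", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
  d <- try(det(object@affine[1:3, 1:3]), silent = TRUE)
  if (inherits(d, "try-error") || !is.finite(d) || abs(d) < 1e-12)
    msg <- c(msg, "affine is singular")
  if (is.null(names(object@labelTable)) || anyDuplicated(object@labelTable))
    msg <- c(msg, "labelTable must be a named integer vector with unique codes")
  codes <- unique(as.vector(object@data))
  codes <- codes[codes != 0L]
  if (!all(codes %in% object@labelTable))
    msg <- c(msg, "data contains label codes absent from labelTable")
  if (length(msg)) msg else TRUE
})

#' Electrode lead model
#'
#' Metadata for a DBS lead design: number of contact levels, inter-level
#' spacing in mm, and its design class. A model is `extended` if and only if
#' it has more than four contact levels or spacing greater than 0.5 mm;
#' otherwise it is `standard`.
#'
#' @slot name model name, e.g. "Medtronic 3389".
#' @slot nLevels integer count of contact levels.
#' @slot spacing inter-level spacing (mm) between contact levels.
#' @slot designClass "standard" or "extended".
#' @export
setClass("LeadModel",
  representation(name = "character", nLevels = "integer",
                 spacing = "numeric", designClass = "character"))

setValidity("LeadModel", function(object) {
  msg <- character()
  if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  expected <- if (object@nLevels > 4L || object@spacing > 0.5) "extended" else "standard"
  if (!identical(object@designClass, expected))
    msg <- c(msg, sprintf("designClass must be '%s' for %d levels at %.2f mm spacing",
                          expected, object@nLevels, object@spacing))
  if (length(msg)) msg else TRUE
})

#' An implanted (or simulated) DBS lead
#'
#' Ordered contact centers in mm, from the ventralmost contact (row 1,
#' "contact 0" in clinical numbering) to the dorsalmost. Virtual contacts
#' produced by [extendVirtual()] carry a positive `extension` (mm of
#' arc length beyond the implanted ventralmost contact); implanted contacts
#' have extension 0.
#'
#' @slot leadId character identifier.
#' @slot hemisphere "left" or "right".
#' @slot model a [LeadModel-class].
#' @slot contacts numeric n x 3 matrix of contact centers (mm), ventral to
#'   dorsal.
#' @slot extension numeric vector, per-contact virtual extension in mm
#'   (0 for implanted contacts).
#' @export
setClass("Lead",
  representation(leadId = "character", hemisphere = "character",
                 model = "LeadModel", contacts = "matrix",
                 extension = "numeric"))

setValidity("Lead", function(object) {
  msg <- character()
  cc <- object@contacts
  if (!is.numeric(cc) || ncol(cc) != 3L || nrow(cc) < 2L)
    msg <- c(msg, "contacts must be a numeric matrix with >= 2 rows and 3 columns")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(object@extension) != nrow(cc))
    msg <- c(msg, "extension must have one entry per contact")
  if (nrow(cc) >= 2L && is.numeric(cc)) {
    if (cc[1L, 3L] > min(cc[, 3L]) + 1e-9)
      msg <- c(msg, "contact 1 must be the ventralmost (minimal z)")
    ## collinearity: perpendicular deviation from the line through the
    ## ventralmost and dorsalmost contacts must stay below 0.1 mm
    d <- cc[nrow(cc), ] - cc[1L, ]
    if (vnorm(d) < 1e-9) {
      msg <- c(msg, "ventralmost and dorsalmost contacts coincide")
    } else {
      u <- d / vnorm(d)
      rel <- sweep(cc, 2L, cc[1L, ])
      perp <- rel - outer(drop(rel %*% u), u)
      if (max(sqrt(rowSums(perp^2))) > 0.1)
        msg <- c(msg, "contacts deviate from collinearity by more than 0.1 mm")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Native stereotactic frame
#'
#' The patient-native coordinate frame derived from the anterior commissure
#' (AC), posterior commissure (PC) and a midline vertex point. The derived
#' orthonormal basis has x lateral-right, y anterior (along PC->AC), z dorsal.
#' The midsagittal plane contains AC, PC and the vertex; the AC-PC (axial)
#' plane contains the AC-PC line with normal along frame z.
#'
#' @slot ac,pc,midlineVertex numeric length-3 landmark points (mm).
#' @slot basis 3x3 matrix whose columns are the unit frame axes (ex, ey, ez).
#' @slot midsagittal,acpc plane specifications (see [planeSpec()]).
#' @export
setClass("NativeFrame",
  representation(ac = "numeric", pc = "numeric", midlineVertex = "numeric",
                 basis = "matrix", midsagittal = "planeSpec", acpc = "planeSpec"))

setValidity("NativeFrame", function(object) {
  msg <- character()
  if (vnorm(object@ac - object@pc) < 1e-6) msg <- c(msg, "ac and pc coincide")
  if (!all(dim(object@basis) == c(3L, 3L)) ||
      max(abs(crossprod(object@basis) - diag(3))) > 1e-6)
    msg <- c(msg, "basis must be a 3x3 orthonormal matrix")
  for (nm in c("midsagittal", "acpc"))
    if (!is_plane(slot(object, nm))) msg <- c(msg, paste(nm, "is not a unit-normal plane"))
  ## vertex must not sit on the AC-PC line, else the midsagittal plane is
  ## undefined
  u <- unitize(object@ac - object@pc)
  rel <- object@midlineVertex - object@pc
  if (vnorm(rel - sum(rel * u) * u) < 1e-6)
    msg <- c(msg, "midlineVertex lies on the AC-PC line")
  if (length(msg)) msg else TRUE
})

#' Gaussian process engagement classifier
#'
#' A binary GP classifier with an anisotropic squared-exponential kernel over
#' the four standardized trajectory features and a probit likelihood, fitted
#' by expectation propagation. Predictions revert to the prior probability
#' 0.5 far from the training data.
#'
#' @slot X standardized training feature matrix (n x 4).
#' @slot y numeric labels in {-1, +1}.
#' @slot center,scaleSd feature standardization parameters.
#' @slot hyper list with `loglen` (log lengthscales per feature, standardized
#'   units) and `logsf` (log signal sd).
#' @slot site list of EP site natural parameters `ttau`, `tnu`.
#' @slot post list of cached posterior quantities used for prediction.
#' @slot target region the classifier predicts engagement of ("SNr" or "SNc").
#' @slot logZ EP approximation to the log marginal likelihood.
#' @slot config fitting configuration (see [gpcConfig()]).
#' @export
setClass("GpcModel",
  representation(X = "matrix", y = "numeric", center = "numeric",
                 scaleSd = "numeric", hyper = "list", site = "list",
                 post = "list", target = "character", logZ = "numeric",
                 config = "list"))

setValidity("GpcModel", function(object) {
  msg <- character()
  if (!all(object@y %in% c(-1, 1))) msg <- c(msg, "y must be in {-1, +1}")
  if (length(object@center) != ncol(object@X) ||
      length(object@scaleSd) != ncol(object@X))
    msg <- c(msg, "scaling parameters must match feature dimension")
  if (length(msg)) msg else TRUE
})

#' Gridded engagement probability map with high-confidence regions
#'
#' Predicted engagement probabilities on a 4D grid over (X, Y, MS angle,
#' AC-PC angle) with the boolean region tensor marking grid nodes whose
#' probability meets the confidence threshold (default 0.95). These regions
#' are the machine-learned "rules of thumb".
#'
#' @slot axes list of numeric grid axes `x`, `y`, `ms`, `acpc` (mm, mm, deg,
#'   deg).
#' @slot prob 4D probability array indexed \[x, y, ms, acpc\].
#' @slot threshold confidence threshold in (0, 1).
#' @slot region logical 4D array, `prob >= threshold`.
#' @slot target region name ("SNr" or "SNc").
#' @export
setClass("RuleMap",
  representation(axes = "list", prob = "array", threshold = "numeric",
                 region = "array", target = "character"))

setValidity("RuleMap", function(object) {
  msg <- character()
  dims <- vapply(object@axes[c("x", "y", "ms", "acpc")], length, 1L)
  if (!all(dim(object@prob) == dims)) msg <- c(msg, "prob dims must match axes")
  if (any(object@prob < -1e-12 | object@prob > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0, 1)")
  if (!identical(dim(object@region), dim(object@prob)) ||
      !identical(as.vector(object@region), as.vector(object@prob >= object@threshold)))
    msg <- c(msg, "region must equal prob >= threshold elementwise")
  if (length(msg)) msg else TRUE
})
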