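#' Stratified k-fold cross-validation of a GPC
#'
#' Folds are stratified by class and assigned deterministically from the
#' seed. Overall accuracy is the pooled out-of-fold correct fraction; the
#' confident subset comprises out-of-fold predictions whose max-class
#' probability meets the confidence threshold. Kernel hyperparameters are
#' optimized once on the full data set (when `config$optimize` is `TRUE`)
#' and held fixed across folds, which keeps the report deterministic and
#' the refits cheap; only the EP posterior is recomputed per fold.
#'
#' @param features feature `data.frame` or matrix.
#' @param labels logical engagement labels.
#' @param k number of folds.
#' @param confidenceThreshold max-class probability defining the confident
#'   subset.
#' @param seed fold-assignment seed.
#' @param target region name.
#' @param config a [gpcConfig()].
#' @return List of class `cvReport`: `k`, `n`, `accuracy`,
#'   `confidentAccuracy`, `confidentFraction`, `hyper`, `seed` and a
#'   `predictions` data.frame (row, fold, truth, prob).
#' @export
crossValidate <- function(features, labels, k = 5L, confidenceThreshold = 0.95,
                          seed = 1L, target = "SNr", config = gpcConfig()) {
  X <- feature_matrix(features)
  yl <- as.logical(labels)
  n <- nrow(X)
  stopifnot(n >= k, length(yl) == n)
  if (length(unique(yl)) < 2L) stop("labels contain a single class")

  hyper <- NULL
  if (config$optimize) {
    full <- trainGpc(X, yl, target = target, config = config)
    hyper <- full@hyper
  }
  foldCfg <- config
  foldCfg$optimize <- FALSE
  if (!is.null(hyper)) {
    foldCfg$loglen <- hyper$loglen
    foldCfg$logsf <- hyper$logsf
  }

  set.seed(seed)
  fold <- integer(n)
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(yl == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  prob <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(yl[tr])) < 2L)
      stop(sprintf("fold %d leaves a single-class training set", f))
    m <- trainGpc(X[tr, , drop = FALSE], yl[tr], target = target,
                  config = foldCfg)
    prob[!tr] <- predictGpc(m, X[!tr, , drop = FALSE])
  }
  pred <- prob >= 0.5
  conf <- pmax(prob, 1 - prob) >= confidenceThreshold
  res <- list(k = k, n = n,
              accuracy = mean(pred == yl),
              confidentAccuracy = if (any(conf)) mean(pred[conf] == yl[conf])
                else NA_real_,
              confidentFraction = mean(conf),
              confidenceThreshold = confidenceThreshold,
              hyper = hyper %||% list(loglen = foldCfg$loglen,
                                      logsf = foldCfg$logsf),
              seed = seed, target = target,
              predictions = data.frame(row = seq_len(n), fold = fold,
                                       truth = yl, prob = prob))
  class(res) <- "cvReport"
  res
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): accuracy %.3f; confident subset (p >= %.2f): %.1f%% of cases, accuracy %s\n",
              x$k, x$target, x$accuracy, x$confidenceThreshold,
              100 * x$confidentFraction,
              ifelse(is.na(x$confidentAccuracy), "n/a",
                     sprintf("%.3f", x$confidentAccuracy))))
  invisible(x)
}

#' Default probability-map grid
#'
#' @param x,y lateral and anterior offsets from the Bejjani origin (mm).
#' @param ms,acpc trajectory angles (degrees).
#' @return Named list of grid axes.
#' @export
ruleGrid <- function(x = seq(-1, 3, by = 0.5), y = seq(-2, 2, by = 0.5),
                     ms = seq(10, 35, by = 1), acpc = seq(35, 65, by = 1)) {
  list(x = x, y = y, ms = ms, acpc = acpc)
}

#' Engagement probability map over trajectory space
#'
#' Evaluates a trained classifier at every node of a 4D grid over (X, Y, MS
#' angle, AC-PC angle) and thresholds at the confidence level to obtain the
#' high-confidence targeting regions.
#'
#' @param model a [GpcModel-class].
#' @param grid a [ruleGrid()] list.
#' @param threshold confidence threshold (default 0.95).
#' @return A [RuleMap-class].
#' @export
probabilityMap <- function(model, grid = ruleGrid(), threshold = 0.95) {
  stopifnot(all(c("x", "y", "ms", "acpc") %in% names(grid)))
  nodes <- as.matrix(expand.grid(x_mm = grid$x, y_mm = grid$y,
                                 ms_angle = grid$ms, acpc_angle = grid$acpc,
                                 KEEP.OUT.ATTRS = FALSE))
  p <- predictGpc(model, nodes)
  dims <- lengths(grid[c("x", "y", "ms", "acpc")])
  prob <- array(p, dim = dims)
  new("RuleMap", axes = grid[c("x", "y", "ms", "acpc")], prob = prob,
      threshold = threshold, region = prob >= threshold,
      target = model@target)
}

## largest all-true axis-aligned rectangle in a logical matrix, by brute
## force over row spans with a summed-area table
largest_true_rect <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cum <- apply(apply(m * 1L, 2L, cumsum), 1L, cumsum)  # cum[j, i] = sum to (i, j)
  sat <- function(i1, i2, j1, j2) {
    tot <- cum[j2, i2]
    if (i1 > 1L) tot <- tot - cum[j2, i1 - 1L]
    if (j1 > 1L) tot <- tot - cum[j1 - 1L, i2]
    if (i1 > 1L && j1 > 1L) tot <- tot + cum[j1 - 1L, i1 - 1L]
    tot
  }
  best <- NULL; bestArea <- 0L
  for (i1 in seq_len(nr)) for (i2 in i1:nr) {
    w <- i2 - i1 + 1L
    if (w * nc <= bestArea) next
    for (j1 in seq_len(nc)) for (j2 in j1:nc) {
      a <- w * (j2 - j1 + 1L)
      if (a <= bestArea) next
      if (sat(i1, i2, j1, j2) == a) { best <- c(i1, i2, j1, j2); bestArea <- a }
    }
  }
  list(idx = best, area = bestArea)
}

#' Extract angle rules from a probability-map panel
#'
#' For a fixed (X, Y) target point, returns the admissible (MS, AC-PC)
#' angle cells whose predicted probability meets the map threshold, together
#' with conservative threshold-style bounds: the largest axis-aligned angle
#' box lying entirely inside the high-confidence region. Every angle pair
#' satisfying the emitted bounds is guaranteed to be in the region. Bounds
#' coinciding with the grid edge are dropped from the human-readable
#' summary (the grid does not constrain there).
#'
#' @param map a [RuleMap-class].
#' @param x,y panel coordinates; must be grid nodes.
#' @return List with `cells` (data.frame of admissible `ms`, `acpc`),
#'   `bounds` (named list with optional `ms_min`, `ms_max`, `acpc_min`,
#'   `acpc_max`) and `summary` (character). An empty region yields zero
#'   cells, `NULL` bounds and an explanatory summary, not an error.
#' @export
extractRules <- function(map, x, y) {
  ix <- match(TRUE, abs(map@axes$x - x) < 1e-9)
  iy <- match(TRUE, abs(map@axes$y - y) < 1e-9)
  if (is.na(ix) || is.na(iy)) stop("(x, y) is not a grid node of the map")
  panel <- map@region[ix, iy, , ]
  cells <- which(panel, arr.ind = TRUE)
  if (!nrow(cells)) {
    return(list(cells = data.frame(ms = numeric(), acpc = numeric()),
                bounds = NULL,
                summary = sprintf("no angle combination reaches p >= %.2f at (X=%g, Y=%g)",
                                  map@threshold, x, y)))
  }
  cellDf <- data.frame(ms = map@axes$ms[cells[, 1L]],
                       acpc = map@axes$acpc[cells[, 2L]])
  rect <- largest_true_rect(panel)
  b <- rect$idx
  bounds <- list()
  txt <- character()
  if (b[1L] > 1L) { bounds$ms_min <- map@axes$ms[b[1L]] }
  if (b[2L] < length(map@axes$ms)) { bounds$ms_max <- map@axes$ms[b[2L]] }
  if (b[3L] > 1L) { bounds$acpc_min <- map@axes$acpc[b[3L]] }
  if (b[4L] < length(map@axes$acpc)) { bounds$acpc_max <- map@axes$acpc[b[4L]] }
  fmt <- function(nm, lo, hi) {
    if (!is.null(lo) && !is.null(hi)) sprintf("%s in [%g, %g] deg", nm, lo, hi)
    else if (!is.null(lo)) sprintf("%s >= %g deg", nm, lo)
    else if (!is.null(hi)) sprintf("%s <= %g deg", nm, hi)
    else NULL
  }
  txt <- c(fmt("MS", bounds$ms_min, bounds$ms_max),
           fmt("AC-PC", bounds$acpc_min, bounds$acpc_max))
  if (is.null(txt)) txt <- "all grid angles admissible"
  list(cells = cellDf, bounds = bounds,
       summary = paste(txt, collapse = "; "),
       rect = list(ms = map@axes$ms[b[1L]:b[2L]],
                   acpc = map@axes$acpc[b[3L]:b[4L]]))
}

#' Precision of the high-confidence rule on held-out trajectories
#'
#' Precision is the proportion of held-out trajectories with predicted
#' engagement probability at or above the threshold that truly engaged the
#' intended SN subregion. With no trajectory selected the precision is
#' undefined and reported as `NA` with `selected = 0`.
#'
#' @param model a [GpcModel-class].
#' @param features held-out features.
#' @param labels held-out engagement labels (logical).
#' @param threshold selection threshold on the predicted probability.
#' @return List with `precision`, `selected`, `n`, `threshold`.
#' @export
rulePrecision <- function(model, features, labels, threshold = 0.95) {
  stopifnot(nrow(feature_matrix(features)) >= 1L)
  p <- predictGpc(model, features)
  sel <- p >= threshold
  list(precision = if (any(sel)) mean(as.logical(labels)[sel]) else NA_real_,
       selected = sum(sel), n = length(p), threshold = threshold)
}

#' Logistic depth rule for SN engagement
#'
#' Fits a logistic regression of in-SN status on arc-length depth below the
#' max-RN plane and reports the minimum depth at which the predicted
#' probability reaches the confidence level:
#' `min_depth = (logit(level) - intercept) / slope` (for a positive slope).
#' Under perfect separation the fit is ridge-penalized on the slope
#' (penalty 1e-4) and flagged. Two depth referents are reported: the
#' contact-center depth and the contact lower border, 0.75 mm (half a
#' standard 1.5 mm contact height) deeper.
#'
#' @param depths numeric depths (mm, ventral-positive) of the evaluated
#'   contacts; trajectories not anatomically on track to the SN should be
#'   excluded upstream (see [onTrack()]).
#' @param inSn logical, whether each contact lies in the SN (1 mm sphere
#'   rule).
#' @param level probability level for the depth rule (default 0.95).
#' @return List of class `depthRule`: `intercept`, `slope`, `minDepth95`,
#'   `minDepth95LowerBorder`, `level`, `separation`, `n`.
#' @examples
#' ## closed form: intercept -8, slope 2 -> (log(19) + 8) / 2
#' @export
fitDepthRule <- function(depths, inSn, level = 0.95) {
  depths <- as.numeric(depths)
  y <- as.logical(inSn)
  stopifnot(length(depths) == length(y), all(is.finite(depths)))
  if (all(y)) stop("degenerate labels: every contact is 'in SN'")
  if (!any(y)) stop("degenerate labels: no contact is 'in SN'")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ depths, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (sep || !fit$converged || abs(coefs[2L]) > 50) {
    sep <- TRUE
    coefs <- ridge_logistic(depths, y, penalty = 1e-4)
  }
  b0 <- unname(coefs[1L]); b1 <- unname(coefs[2L])
  md <- if (b1 > 0) (stats::qlogis(level) - b0) / b1 else NA_real_
  if (is.na(md))
    warning("non-positive depth slope: deeper contacts are not more likely in SN")
  structure(list(intercept = b0, slope = b1, minDepth95 = md,
                 minDepth95LowerBorder = if (is.na(md)) NA_real_ else md + 0.75,
                 level = level, separation = sep, n = length(y)),
            class = "depthRule")
}

#' @export
print.depthRule <- function(x, ...) {
  cat(sprintf("Depth rule: logit P(in SN) = %.3f + %.3f * depth_mm%s\n",
              x$intercept, x$slope,
              if (x$separation) " (ridge-penalized, separated data)" else ""))
  if (!is.na(x$minDepth95))
    cat(sprintf("  P >= %.0f%% from depth %.2f mm (contact center); %.2f mm (lower border)\n",
                100 * x$level, x$minDepth95, x$minDepth95LowerBorder))
  invisible(x)
}

## logistic regression with an L2 penalty on the slope only (IRLS)
ridge_logistic <- function(x, y, penalty = 1e-4, maxit = 100L) {
  X <- cbind(1, x)
  b <- c(0, 0)
  P <- diag(c(0, penalty))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    bNew <- solve(crossprod(X, w * X) + P, crossprod(X, w * z))
    if (max(abs(bNew - b)) < 1e-10) { b <- drop(bNew); break }
    b <- drop(bNew)
  }
  stats::setNames(b, c("(Intercept)", "depths"))
}

#' Is a trajectory anatomically on track to the SN?
#'
#' Tests whether the infinite extension of the trajectory line intersects
#' the ipsilateral SN (SNr or SNc voxels), by sampling the line at `step`
#' mm through the atlas bounding box. Trajectories that miss the SN at
#' every depth are excluded from the depth-rule analysis.
#'
#' @param lead a [Lead-class].
#' @param atlas a [LabelAtlas-class].
#' @param step sampling step along the line in mm.
#' @return Logical.
#' @export
onTrack <- function(lead, atlas, step = 0.1) {
  u <- trajectoryNorm(lead)
  p0 <- lead@contacts[1L, ]
  ## mm bounding box of the voxel grid
  dims <- dim(atlas@data)
  corners <- as.matrix(expand.grid(c(0, dims[1L] - 1L), c(0, dims[2L] - 1L),
                                   c(0, dims[3L] - 1L)))
  cw <- (cbind(corners, 1) %*% t(atlas@affine))[, 1:3]
  lo <- apply(cw, 2L, min); hi <- apply(cw, 2L, max)
  ## slab intersection of the line with the box
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:3) {
    if (abs(u[ax]) < 1e-12) {
      if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) return(FALSE)
    } else {
      t1 <- (lo[ax] - p0[ax]) / u[ax]; t2 <- (hi[ax] - p0[ax]) / u[ax]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) return(FALSE)
  ts <- seq(tmin, tmax, by = step)
  pts <- cbind(p0[1L] + ts * u[1L], p0[2L] + ts * u[2L], p0[3L] + ts * u[3L])
  v <- world_to_voxel(atlas, pts)
  ok <- v[, 1L] >= 1L & v[, 1L] <= dims[1L] & v[, 2L] >= 1L &
    v[, 2L] <= dims[2L] & v[, 3L] >= 1L & v[, 3L] <= dims[3L]
  if (!any(ok)) return(FALSE)
  v <- v[ok, , drop = FALSE]
  codes <- atlas@data[cbind(v[, 1L], v[, 2L], v[, 3L])]
  any(codes %in% region_codes(atlas, "SN", lead@hemisphere))
}

#' Depth/in-SN observations for the depth rule
#'
#' Collects (depth, in-SN) pairs from leads that are anatomically on track
#' to the SN. By default each trajectory contributes its deepest implanted
#' contact ("contact 0"), whose implantation depth is the quantity the depth
#' rule is meant to prescribe; alternatively every (optionally also virtual)
#' contact can contribute. In-SN status uses the 1 mm sphere rule against
#' SNr or SNc. Note that contacts extended far beyond the ventral SN border
#' leave the nucleus again, so all-contact observations can violate the
#' monotone dose-response the logistic rule assumes.
#'
#' @param leads list of [Lead-class] objects.
#' @param atlas a [LabelAtlas-class].
#' @param frame a [NativeFrame-class].
#' @param deepestOnly one observation per lead, its deepest implanted
#'   contact (default); otherwise all contacts contribute.
#' @param includeVirtual with `deepestOnly = FALSE`, also include virtual
#'   contacts.
#' @param radius contact engagement radius in mm.
#' @return `data.frame` with `lead_id`, `depth_mm`, `in_sn`.
#' @export
depthRuleData <- function(leads, atlas, frame, deepestOnly = TRUE,
                          includeVirtual = FALSE, radius = 1) {
  hemis <- unique(vapply(leads, function(l) l@hemisphere, character(1L)))
  planes <- lapply(stats::setNames(hemis, hemis), function(h)
    findMaxRnPlane(atlas, h, frame))
  rows <- lapply(leads, function(ld) {
    if (!onTrack(ld, atlas)) return(NULL)
    keep <- if (deepestOnly) {
      which(ld@extension == 0)[1L]      # ventralmost implanted contact
    } else if (includeVirtual) {
      seq_len(nrow(ld@contacts))
    } else {
      which(ld@extension == 0)
    }
    cc <- ld@contacts[keep, , drop = FALSE]
    dd <- contactDepths(ld, planes[[ld@hemisphere]])[keep]
    insn <- apply(cc, 1L, function(p)
      sphereRegionOverlap(p, radius, atlas, "SN", ld@hemisphere) > 0)
    data.frame(lead_id = ld@leadId, depth_mm = dd, in_sn = insn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
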