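test_that("trajectory norm matches axis-aligned and Pythagorean cases", {
  ld <- simple_lead(c(0, 0, 0), c(0, 0, 1), 10)
  expect_equal(trajectoryNorm(ld), c(0, 0, 1))
  ld2 <- new("Lead", leadId = "p", hemisphere = "right",
             model = getLeadModel("Medtronic 3389"),
             contacts = rbind(c(0, 0, 0), c(3, 0, 4)), extension = c(0, 0))
  expect_equal(trajectoryNorm(ld2), c(0.6, 0, 0.8))
  ## coincident ventral/dorsal contacts are rejected at construction
  expect_error(new("Lead", leadId = "c", hemisphere = "right",
                   model = getLeadModel("Medtronic 3389"),
                   contacts = rbind(c(0, 0, 0), c(0, 0, 0) + 1e-12),
                   extension = c(0, 0)), "coincide")
})

test_that("trajectory norm agrees with an SVD line-fit oracle and is translation invariant", {
  set.seed(101)
  for (i in 1:100) {
    u <- c(rnorm(2), abs(rnorm(1)) + 0.3)
    u <- u / sqrt(sum(u^2))
    p0 <- rnorm(3, sd = 5)
    ts <- sort(runif(4, 0, 8))
    cc <- t(sapply(ts, function(t) p0 + t * u))
    cc <- cc[order(cc[, 3]), ]
    ld <- new("Lead", leadId = "r", hemisphere = "right",
              model = getLeadModel("Medtronic 3389"),
              contacts = cc, extension = rep(0, 4))
    got <- trajectoryNorm(ld)
    sv <- svd(sweep(cc, 2, colMeans(cc)))$v[, 1]   # least-squares direction
    if (sum(sv * got) < 0) sv <- -sv
    expect_close(got, sv, 1e-9)
    shift <- rnorm(3, sd = 20)
    ld2 <- new("Lead", leadId = "r2", hemisphere = "right",
               model = getLeadModel("Medtronic 3389"),
               contacts = sweep(cc, 2, -shift), extension = rep(0, 4))
    expect_close(trajectoryNorm(ld2), got, 1e-12)
  }
})

test_that("line-to-plane angle handles canonical cases and symmetries", {
  pz <- planeSpec(c(0, 0, 0), c(0, 0, 1))
  expect_equal(angleToPlane(c(0, 0, 1), pz), 90)
  expect_equal(angleToPlane(c(1, 0, 0), pz), 0)
  expect_equal(angleToPlane(c(1, 0, 1), pz), 45)
  expect_error(angleToPlane(c(0, 0, 0), pz), "zero length")
  set.seed(7)
  for (i in 1:100) {
    l <- rnorm(3); n <- rnorm(3)
    p <- planeSpec(rnorm(3), n)
    a <- angleToPlane(l, p)
    expect_true(a >= 0 && a <= 90)
    expect_equal(angleToPlane(-l, p), a, tolerance = 1e-12)
    expect_equal(angleToPlane(l, planeSpec(p$point, -n)), a, tolerance = 1e-12)
    ## complement: line-plane angle + line-normal angle = 90
    toNormal <- acos(min(1, abs(sum(l * p$normal)) / sqrt(sum(l^2)))) * 180 / pi
    expect_equal(a + toNormal, 90, tolerance = 1e-9)
  }
})

test_that("virtual extension adds collinear contacts at the requested arc lengths", {
  ld <- simple_lead(c(0, 0, 10), c(0, 0, 1), 6)
  ext <- extendVirtual(ld, 2)
  expect_equal(contacts(ext)[1, ], c(0, 0, 8))
  ld3 <- extendVirtual(ld)
  expect_identical(sum(isVirtual(ld3)), 3L)
  vc <- contacts(ld3)[isVirtual(ld3), ]
  expect_close(as.vector(dist(vc)), c(2, 4, 2), 1e-12)
  ## distance from implanted ventralmost to k-th virtual equals the extension
  v0 <- contacts(ld)[1, ]
  d <- sqrt(rowSums(sweep(vc, 2, v0)^2))
  expect_close(sort(d), c(2, 4, 6), 1e-9)
  ## oblique trajectory keeps collinearity (validity enforces < 0.1 mm)
  ldo <- simple_lead(c(1, 2, 3), c(0.3, 0.4, 0.86), 7)
  expect_s4_class(extendVirtual(ldo), "Lead")
  expect_error(extendVirtual(ld, c(4, 2)), "increasing")
  expect_error(extendVirtual(ld3), "already")
})

test_that("max-RN plane matches an exhaustive per-slice voxel count", {
  atl <- coarse_atlas()
  fr <- default_frame()
  for (hemi in c("right", "left")) {
    pl <- findMaxRnPlane(atl, hemi, fr)
    ## brute force: count RN voxels per k slice
    code <- if (hemi == "right") 5L else 15L
    dims <- dim(atl@data)
    counts <- vapply(seq_len(dims[3]), function(k)
      sum(atl@data[, , k] == code), integer(1))
    kmax <- which(counts == max(counts))
    zs <- atl@affine[3, 4] + (kmax - 1) * atl@affine[3, 3]
    expect_equal(pl$point[3], min(zs))   # tie broken ventral
    expect_equal(abs(pl$normal), c(0, 0, 1))
  }
})

test_that("max-RN tie-break picks the more ventral slice on a constructed tie", {
  ## two identical RN slabs separated by a gap
  vox <- 0.5
  ax <- seq(-4.75, 4.75, by = vox)
  lab <- array(0L, dim = rep(length(ax), 3))
  kA <- 5L; kB <- 12L
  lab[4:8, 4:8, kA] <- 5L
  lab[4:8, 4:8, kB] <- 5L
  lab[10, 10, kB + 1L] <- 1L; lab[10, 10, kB + 1L] <- 1L
  aff <- diag(4); diag(aff)[1:3] <- vox; aff[1:3, 4] <- ax[1]
  atl <- new("LabelAtlas", data = lab, affine = aff,
             labelTable = c(STN_MC_R = 1L, RN_R = 5L),
             masks = list(), cache = new.env(parent = emptyenv()))
  pl <- findMaxRnPlane(atl, "right")
  expect_equal(pl$point[3], ax[kA])
})

test_that("Bejjani origin matches a brute-force voxel scan and mirrors across hemispheres", {
  atl <- coarse_atlas()
  fr <- default_frame()
  bo <- bejjaniOrigin(atl, fr, "right")
  ## brute force in world coordinates (frame axes are identity here)
  dims <- dim(atl@data)
  kmax <- nigratarget:::max_rn_slice(atl, "right")
  vox <- which(atl@data[, , kmax] == 5L, arr.ind = TRUE)
  xs <- atl@affine[1, 4] + (vox[, 1] - 1) * atl@affine[1, 1]
  ys <- atl@affine[2, 4] + (vox[, 2] - 1) * atl@affine[2, 2]
  y0 <- max(ys)
  sl <- atl@data[, , kmax]
  stn <- which(matrix(sl %in% c(1L, 2L), nrow(sl)), arr.ind = TRUE)
  sx <- atl@affine[1, 4] + (stn[, 1] - 1) * atl@affine[1, 1]
  sy <- atl@affine[2, 4] + (stn[, 2] - 1) * atl@affine[2, 2]
  band <- abs(sy - y0) <= 0.5
  x0 <- sx[band][which.min(abs(sx[band]))]
  expect_equal(bo[1], x0)
  expect_equal(bo[2], y0)
  ## mirror-symmetric atlas: left origin is the reflection of the right
  bol <- bejjaniOrigin(atl, fr, "left")
  expect_close(bol, c(-bo[1], bo[2], bo[3]), 1e-9)
  ## construction: the origin sits on the medial STN border near the
  ## anterior RN tangent, within one voxel of the analytic prediction
  p <- coarse_params()
  yTangent <- p$rn$center[2] + p$rn$axes[2]  # anterior RN border (full slice)
  expect_lt(abs(bo[2] - yTangent), 2 * p$voxelSize + 0.35)
})

test_that("features round-trip through lead construction and mirror across hemispheres", {
  atl <- coarse_atlas()
  fr <- default_frame()
  bo <- bejjaniOrigin(atl, fr, "right")
  target <- bo + 1.5 * fr@basis[, 1] + 0 * fr@basis[, 2]
  ld <- makeLead("Medtronic 3389", target, 22, 55, 3, fr, "right", "rt")
  f <- extractFeatures(ld, atl, fr)
  expect_close(c(f$x_mm, f$y_mm, f$ms_angle, f$acpc_angle),
               c(1.5, 0, 22, 55), 1e-6)
  ## crossing exactly at the origin gives (0, 0)
  ld0 <- makeLead("Medtronic 3389", bo, 25, 50, 3, fr, "right", "o")
  f0 <- extractFeatures(ld0, atl, fr)
  expect_close(c(f0$x_mm, f0$y_mm), c(0, 0), 1e-9)
  ## left-hemisphere mirror of the same request yields identical features
  bol <- bejjaniOrigin(atl, fr, "left")
  targetL <- bol - 1.5 * fr@basis[, 1] + 0 * fr@basis[, 2]
  ldl <- makeLead("Medtronic 3389", targetL, 22, 55, fr = fr, depthMm = 3,
                  hemisphere = "left", leadId = "lt")
  fl <- extractFeatures(ldl, atl, fr)
  expect_close(c(fl$x_mm, fl$y_mm, fl$ms_angle, fl$acpc_angle),
               c(1.5, 0, 22, 55), 1e-6)
})

test_that("arc-length depth follows trigonometry and dominates vertical offset", {
  pz <- planeSpec(c(0, 0, -4), c(0, 0, 1))
  ld <- simple_lead(c(1, 1, -20), c(0, 0, 1), 30)
  expect_equal(depthAlongTrajectory(c(1, 1, -8), ld, pz), 4)
  expect_equal(depthAlongTrajectory(c(1, 1, -4), ld, pz), 0)
  ## 60 degrees to the plane: depth = dz / sin(60)
  u <- c(cos(60 * pi / 180), 0, sin(60 * pi / 180))
  ld60 <- simple_lead(c(0, 0, -20), u, 30)
  con <- nigratarget:::trajectory_plane_point(ld60, pz) - (2 / sin(60 * pi / 180)) * u
  expect_equal(depthAlongTrajectory(con, ld60, pz), 2 / sin(60 * pi / 180),
               tolerance = 1e-9)
  expect_equal(con[3], -6)   # dz really is 2 mm below the plane
  ## property: arc length >= |dz|, equality iff perpendicular
  set.seed(21)
  for (i in 1:50) {
    u <- c(rnorm(2, sd = 0.4), 1); u <- u / sqrt(sum(u^2))
    ld <- simple_lead(rnorm(3), u, 20)
    contact <- contacts(ld)[1, ] + runif(1, -5, 5) * u
    d <- depthAlongTrajectory(contact, ld, pz)
    dz <- -(contact[3] - (-4))
    expect_gte(abs(d) + 1e-12, abs(dz))
  }
  ldflat <- simple_lead(c(0, 0, 0), c(1, 0, 1e-12), 10)
  expect_error(depthAlongTrajectory(c(5, 0, 0), ldflat, pz), "parallel")
})
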