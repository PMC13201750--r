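test_that("sphere overlap matches analytic volumes and vanishes under separation", {
  ## generic (non-lattice-aligned) sphere centers, as real contacts are
  set.seed(101)
  centers <- matrix(runif(30, -0.3, 0.3), ncol = 3)
  solid <- predicate_atlas(function(x, y, z) rep(TRUE, length(x)), voxel = 0.25)
  ## half-space bounded by a voxel face (the rasterized boundary)
  half <- predicate_atlas(function(x, y, z) x >= 0, voxel = 0.25)
  errS <- apply(centers, 1, function(ctr)
    abs(sphereRegionOverlap(ctr, 1, solid, "SNr", "right") - 4 / 3 * pi) /
      (4 / 3 * pi))
  expect_lt(mean(errS), 0.02)
  ## half-space through the center: half the sphere volume
  hctr <- cbind(0, centers[, 2:3])
  errH <- apply(hctr, 1, function(ctr)
    abs(sphereRegionOverlap(ctr, 1, half, "SNr", "right") - 2 / 3 * pi) /
      (2 / 3 * pi))
  expect_lt(mean(errH), 0.02)
  ## far from any region voxel: exactly zero
  ball <- predicate_atlas(function(x, y, z) x^2 + y^2 + z^2 <= 4, voxel = 0.25)
  expect_identical(sphereRegionOverlap(c(5.5, 0, 0), 1, ball, "SNr", "right"), 0)
  expect_error(sphereRegionOverlap(c(0, 0, 0), 1, solid, "THAL", "right"),
               "unknown region")
})

test_that("overlap error decreases monotonically with voxel refinement", {
  truth_sphere <- 4 / 3 * pi
  set.seed(102)
  centers <- matrix(runif(24, -0.3, 0.3), ncol = 3)
  errs <- vapply(c(0.5, 0.25, 0.125), function(vx) {
    solid <- predicate_atlas(function(x, y, z) rep(TRUE, length(x)),
                             voxel = vx, lim = 2)
    half <- predicate_atlas(function(x, y, z) x >= 0, voxel = vx, lim = 2)
    e1 <- mean(apply(centers, 1, function(ctr)
      abs(sphereRegionOverlap(ctr, 1, solid, "SNr", "right") - truth_sphere) /
        truth_sphere))
    e2 <- mean(apply(cbind(0, centers[, 2:3]), 1, function(ctr)
      abs(sphereRegionOverlap(ctr, 1, half, "SNr", "right") - truth_sphere / 2) /
        (truth_sphere / 2)))
    max(e1, e2)
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("contact classification follows the greater-overlap rule", {
  atl <- coarse_atlas()
  p <- coarse_params()
  ## deep inside SNr: far lateral-ventral part of the SN
  snr <- nigratarget:::region_coords(atl, "SNr", "right")
  ce <- classifyContact(colMeans(snr), atl, "right")
  expect_identical(ce$snClass, "SNr")
  ce2 <- classifyContact(colMeans(nigratarget:::region_coords(atl, "SNc", "right")),
                         atl, "right")
  expect_identical(ce2$snClass, "SNc")
  ce3 <- classifyContact(c(0, 10, 2), atl, "right")
  expect_identical(ce3$snClass, "none")
  expect_true(all(ce3$overlaps[c("SNr", "SNc")] == 0))
  ## an exact overlap tie resolves to SNr and is flagged
  ax <- seq(-2.75, 2.75, by = 0.5)
  lab <- array(0L, dim = rep(length(ax), 3))
  g <- expand.grid(x = ax, y = ax, z = ax)
  lab[g$x > 0] <- 3L; lab[g$x < 0] <- 4L
  aff <- diag(4); diag(aff)[1:3] <- 0.5; aff[1:3, 4] <- ax[1]
  sym <- new("LabelAtlas", data = lab, affine = aff,
             labelTable = c(SNr_R = 3L, SNc_R = 4L), masks = list(),
             cache = new.env(parent = emptyenv()))
  expect_warning(tie <- classifyContact(c(0, 0, 0), sym, "right",
                                        regions = character(0)), "tie")
  expect_identical(tie$snClass, "SNr")
  expect_identical(unname(tie$overlaps["SNr"]), unname(tie$overlaps["SNc"]))
})

test_that("contact classification agrees with exhaustive voxel enumeration", {
  atl <- coarse_atlas()
  snr <- nigratarget:::region_coords(atl, "SNr", "right")
  snc <- nigratarget:::region_coords(atl, "SNc", "right")
  vol <- voxelVolume(atl)
  set.seed(31)
  ctr <- colMeans(rbind(snr, snc))
  for (i in 1:100) {
    pt <- ctr + rnorm(3, sd = 3)
    ce <- classifyContact(pt, atl, "right")
    ## oracle: direct enumeration over region voxel centers
    oSnr <- sum(colSums((t(snr) - pt)^2) <= 1) * vol
    oSnc <- sum(colSums((t(snc) - pt)^2) <= 1) * vol
    expect_equal(unname(ce$overlaps["SNr"]), oSnr)
    expect_equal(unname(ce$overlaps["SNc"]), oSnc)
    want <- if (oSnr == 0 && oSnc == 0) "none" else if (oSnr >= oSnc) "SNr" else "SNc"
    expect_identical(ce$snClass, want)
  }
})

test_that("a trajectory can engage both SN compartments though contacts cannot", {
  atl <- coarse_atlas()
  snr <- colMeans(nigratarget:::region_coords(atl, "SNr", "right"))
  snc <- colMeans(nigratarget:::region_coords(atl, "SNc", "right"))
  lo <- if (snr[3] < snc[3]) snr else snc
  hi <- if (snr[3] < snc[3]) snc else snr
  ld <- new("Lead", leadId = "both", hemisphere = "right",
            model = getLeadModel("Medtronic 3389"),
            contacts = rbind(lo, hi), extension = c(0, 0))
  tr <- classifyTrajectory(ld, atl, "implanted_only")
  expect_true(all(c("SNr", "SNc") %in% tr$engaged))
  ## per-contact exclusivity
  tab <- nigratarget:::contact_engagements(ld, atl)
  expect_true(all(tab$sn_class %in% c("SNr", "SNc", "none")))
  expect_identical(sort(tab$sn_class), c("SNc", "SNr"))
  ## a lead far from the SN engages nothing
  ldfar <- simple_lead(c(0, 10, -5), c(0, 0.05, 1), 10)
  expect_length(classifyTrajectory(ldfar, atl, "implanted_only")$engaged, 0)
})

test_that("engagement grows monotonically with virtual extension", {
  co <- coarse_cohort(n = 30, seed = 11)
  atl <- coarse_atlas_ct()
  eng <- suppressWarnings(engagementTable(co$extended, atl))
  sc <- c("implanted_only", "plus2mm", "plus4mm", "plus6mm")
  for (ld in unique(eng$lead_id)) {
    sets <- lapply(sc, function(s) {
      r <- eng[eng$lead_id == ld & eng$scenario == s, ]
      c("SNr", "SNc", "MC", "CT")[c(r$snr, r$snc, r$mc, r$ct)]
    })
    for (i in 1:3)
      expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  ## rates are non-decreasing, none-rate non-increasing
  summ <- cohortSummary(eng)
  summ <- summ[match(sc, summ$scenario), ]
  expect_true(all(diff(summ$snr_rate) >= 0))
  expect_true(all(diff(summ$snc_rate) >= 0))
  expect_true(all(diff(summ$none_rate) <= 0))
})

test_that("central target is the dorsal half of the compartment boundary band", {
  ## STN split by a pure-anteroposterior plane gives a simple boundary slab
  p <- anatomyParams(voxelSize = 0.5, mcNormal = c(0, -1, 0), mcFraction = 0.4)
  atl <- buildCentralTarget(makeAtlas(p))
  ct <- atl@masks$CT_R
  expect_gt(length(ct), 0)
  ## oracle: recompute the band by enumerating adjacent MC/assoc pairs
  stnIdx <- nigratarget:::region_index(atl, "STN", "right")
  stnXYZ <- nigratarget:::voxel_to_world(atl, stnIdx)
  mcXYZ <- nigratarget:::voxel_to_world(
    atl, nigratarget:::region_index(atl, "STN_MC", "right"))
  asXYZ <- nigratarget:::voxel_to_world(
    atl, nigratarget:::region_index(atl, "STN_assoc", "right"))
  ## all MC/assoc voxel pairs at exactly one voxel spacing share a face
  faces <- list()
  for (i in seq_len(nrow(mcXYZ))) {
    d2 <- colSums((t(asXYZ) - mcXYZ[i, ])^2)
    hit <- which(abs(d2 - 0.25) < 1e-9)   # (0.5 mm)^2
    if (length(hit))
      faces[[length(faces) + 1L]] <- sweep(asXYZ[hit, , drop = FALSE], 2,
                                           -mcXYZ[i, ]) / 2
  }
  faces <- do.call(rbind, faces)
  dmin <- apply(stnXYZ, 1, function(v) min(colSums((t(faces) - v)^2)))
  band <- stnIdx[dmin <= 0.75^2 + 1e-9]
  expect_identical(length(ct), as.integer(ceiling(length(band) / 2)))
  ## oracle ventral cut: dorsal half by z with deterministic tie order
  z <- nigratarget:::voxel_to_world(atl, band)[, 3]
  ord <- order(-z, band)
  want <- sort(band[ord[seq_len(ceiling(length(band) / 2))]])
  expect_identical(ct, want)
  ## CT is strictly inside the STN
  expect_true(all(ct %in% stnIdx))
})

test_that("VAT overlap percentages are exact at the extremes and half-space", {
  solid <- predicate_atlas(function(x, y, z) rep(TRUE, length(x)), voxel = 0.25)
  expect_close(vatOverlap(c(0.07, -0.11, 0.03), solid, "SNr", "right"), 100, 2)
  half <- predicate_atlas(function(x, y, z) x >= 0, voxel = 0.25)
  expect_close(vatOverlap(c(0, -0.11, 0.03), half, "SNr", "right"), 50, 2)
  ball <- predicate_atlas(function(x, y, z) x^2 + y^2 + z^2 <= 1, voxel = 0.25)
  expect_identical(vatOverlap(c(0, 0, 5.5), ball, "SNr", "right"), 0)
})

test_that("depth profile bins contacts correctly and peaks at the slab center", {
  ## SN slab 4 mm thick centered 4 mm below an RN whose max slice is at z = -4
  vox <- 0.5
  ax <- seq(-15.75, 15.75, by = vox)
  lab <- array(0L, dim = rep(length(ax), 3))
  grid <- expand.grid(x = ax, y = ax, z = ax)
  lab[grid$x^2 + grid$y^2 + (grid$z + 4)^2 <= 9] <- 5L          # RN ball
  lab[abs(grid$x) <= 6 & abs(grid$y) <= 6 &
        grid$z >= -10 & grid$z < -6] <- 3L                       # SNr slab
  aff <- diag(4); diag(aff)[1:3] <- vox; aff[1:3, 4] <- ax[1]
  atl <- new("LabelAtlas", data = lab, affine = aff,
             labelTable = c(SNr_R = 3L, SNc_R = 4L, RN_R = 5L),
             masks = list(), cache = new.env(parent = emptyenv()))
  fr <- buildNativeFrame(c(0, 10, 0), c(0, -10, 0), c(0, 0, 30))
  ## vertical lead with contacts from depth -1 to 7 below the max-RN plane
  ld <- new("Lead", leadId = "v", hemisphere = "right",
            model = getLeadModel("Boston Scientific Vercise Cartesia X"),
            contacts = cbind(0, 0, seq(-11, -3, by = 1)),
            extension = rep(0, 9))
  prof <- depthProfile(list(ld), atl, fr, "SNr", binCenters = seq(-2, 8, 2))
  expect_identical(prof$bin_center[which.max(prof$mean_percent)], 4)
  ## singleton bin: mean equals the value, SEM 0
  ld1 <- new("Lead", leadId = "s", hemisphere = "right",
             model = getLeadModel("Medtronic 3389"),
             contacts = rbind(c(0, 0, -8), c(0, 0, -2)), extension = c(0, 0))
  p1 <- depthProfile(list(ld1), atl, fr, "SNr", binCenters = 4)
  expect_identical(p1$n, 1L)
  expect_identical(p1$sem, 0)
  expect_equal(p1$mean_percent, vatOverlap(c(0, 0, -8), atl, "SNr", "right"))
  ## 3.9 and 4.1 fall in the same [3, 5) bin
  ld2 <- new("Lead", leadId = "d", hemisphere = "right",
             model = getLeadModel("Medtronic 3389"),
             contacts = rbind(c(0, 0, -8.1), c(0, 0, -7.9), c(0, 0, -2)),
             extension = c(0, 0, 0))
  p2 <- depthProfile(list(ld2), atl, fr, "SNr", binCenters = c(2, 4, 6))
  expect_identical(p2$n[p2$bin_center == 4], 2L)
  ## empty bins are absent
  expect_false(any(p2$bin_center == 6 & p2$n == 0))
})

test_that("cohort summary arithmetic and both-rate bound hold", {
  mk <- function(snr, snc) data.frame(
    lead_id = sprintf("l%02d", seq_along(snr)), scenario = "implanted_only",
    snr = snr, snc = snc, both = snr & snc, none = !(snr | snc),
    mc = FALSE, ct = FALSE)
  e <- mk(c(rep(TRUE, 6), rep(FALSE, 4)), rep(FALSE, 10))
  s <- cohortSummary(e)
  expect_equal(s$snr_rate, 0.6)
  expect_equal(s$n_snr, 6)
  e0 <- mk(rep(FALSE, 5), rep(FALSE, 5))
  s0 <- cohortSummary(e0)
  expect_equal(s0$none_rate, 1)
  expect_equal(s0$snr_rate + s0$snc_rate + s0$both_rate, 0)
  set.seed(3)
  for (i in 1:20) {
    e <- mk(runif(30) < 0.5, runif(30) < 0.4)
    s <- cohortSummary(e)
    expect_lte(s$both_rate, min(s$snr_rate, s$snc_rate))
    expect_equal(s$none_rate, 1 - s$snr_rate - s$snc_rate + s$both_rate)
  }
  ## stratification by design class keeps counts additive
  co <- coarse_cohort(n = 30, seed = 11)
  eng <- suppressWarnings(engagementTable(co$extended, coarse_atlas_ct(),
                                          scenarios = "implanted_only"))
  s <- cohortSummary(eng, co$truth)
  tot <- s[s$stratum == "all", "n"]
  expect_equal(sum(s[s$stratum != "all", "n"]), tot)
})
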