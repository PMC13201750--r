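## Shared fixtures, memoized so expensive atlases are built once per session.
.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

coarse_params <- function(...) anatomyParams(voxelSize = 0.5, ...)

coarse_atlas <- function() memo("atlas05", function() makeAtlas(coarse_params()))

coarse_atlas_ct <- function() memo("atlas05ct", function()
  buildCentralTarget(coarse_atlas()))

default_frame <- function() memo("frame", function() {
  p <- coarse_params()
  buildNativeFrame(p$ac, p$pc, p$midlineVertex)
})

## single-region synthetic atlas whose region voxels are defined by a
## predicate on voxel-center mm coordinates (for analytic overlap checks)
predicate_atlas <- function(predicate, voxel = 0.25, lim = 6) {
  ax <- seq(-lim + voxel / 2, lim - voxel / 2, by = voxel)
  grid <- expand.grid(x = ax, y = ax, z = ax)
  lab <- array(0L, dim = c(length(ax), length(ax), length(ax)))
  lab[predicate(grid$x, grid$y, grid$z)] <- 3L  # SNr_R
  aff <- diag(4); diag(aff)[1:3] <- voxel; aff[1:3, 4] <- ax[1]
  new("LabelAtlas", data = lab, affine = aff,
      labelTable = c(SNr_R = 3L, SNc_R = 4L),
      masks = list(), cache = new.env(parent = emptyenv()))
}

## straight two-contact lead through p0 with direction u (unit not required)
simple_lead <- function(p0, u, length_mm = 10, model = "Medtronic 3389",
                        hemisphere = "right", id = "L1") {
  u <- u / sqrt(sum(u^2))
  if (u[3] < 0) u <- -u
  new("Lead", leadId = id, hemisphere = hemisphere,
      model = getLeadModel(model),
      contacts = rbind(p0, p0 + length_mm * u), extension = c(0, 0))
}

## small simulated cohort on the coarse atlas, extended with virtual contacts
coarse_cohort <- function(n = 30, seed = 11) {
  key <- sprintf("cohort_%d_%d", n, seed)
  memo(key, function() {
    co <- sampleCohort(coarse_atlas_ct(),
                       cohortParams(nLeads = n, seed = seed), default_frame())
    co$extended <- lapply(co$leads, extendVirtual)
    co
  })
}

unitize_test <- function(v) v / sqrt(sum(v^2))

## orthonormal basis of the plane perpendicular to n (3 x 2 matrix)
plane_basis <- function(n) {
  q <- qr.Q(qr(cbind(n, diag(3))))
  q[, 2:3]
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 6), collapse = ","), tol,
                              paste(signif(expected, 6), collapse = ",")))
}
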