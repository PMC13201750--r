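cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a native stereotactic frame from AC, PC and a midline vertex
#'
#' Derives the orthonormal frame basis and the two reference planes used for
#' trajectory angle measurement. The y axis runs from PC to AC (anterior
#' positive); the midsagittal plane contains AC, PC and the midline vertex,
#' with its normal oriented toward the right (positive x); z = x cross y
#' points dorsal. The AC-PC plane contains the AC-PC line and has normal
#' along frame z, so axial planes are constant-z in frame coordinates.
#'
#' @param ac,pc,midlineVertex numeric length-3 landmark coordinates (mm).
#' @return A [NativeFrame-class] object.
#' @examples
#' fr <- buildNativeFrame(c(0, 12.5, 0), c(0, -12.5, 0), c(0, 0, 40))
#' fr@basis
#' @export
buildNativeFrame <- function(ac, pc, midlineVertex) {
  ac <- as.numeric(ac); pc <- as.numeric(pc); midlineVertex <- as.numeric(midlineVertex)
  stopifnot(length(ac) == 3L, length(pc) == 3L, length(midlineVertex) == 3L,
            all(is.finite(c(ac, pc, midlineVertex))))
  if (vnorm(ac - pc) < 1e-6) stop("ac and pc coincide")
  ey <- unitize(ac - pc)
  msNormal <- cross3(pc - ac, midlineVertex - ac)
  if (vnorm(msNormal) < 1e-9) stop("midlineVertex lies on the AC-PC line")
  ex <- unitize(msNormal)
  if (ex[1] < 0) ex <- -ex          # orient midsagittal normal to the right
  ez <- cross3(ex, ey)              # dorsal
  basis <- cbind(ex, ey, ez)
  dimnames(basis) <- NULL
  new("NativeFrame", ac = ac, pc = pc, midlineVertex = midlineVertex,
      basis = basis,
      midsagittal = planeSpec(ac, ex),
      acpc = planeSpec(ac, ez))
}

## project world points (n x 3 or length 3) onto the frame basis
frame_coords <- function(pts, frame) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  pts %*% frame@basis
}
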