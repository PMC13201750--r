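## Small vector helpers shared across the geometry and simulation code.
## All coordinates are millimetres in a right-handed RAS frame:
## x right(+), y anterior(+), z dorsal(+).

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < .Machine$double.eps * 10)
    stop("cannot normalize a zero-length vector")
  v / n
}

#' Construct a plane specification
#'
#' A plane is stored as a point on the plane and a unit normal. This is the
#' lightweight value type used for the midsagittal plane, the AC-PC plane and
#' the per-hemisphere max-RN plane.
#'
#' @param point numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3, the plane normal; normalized internally.
#' @return A list of class `planeSpec` with elements `point` and `normal`
#'   (`normal` has unit length).
#' @examples
#' p <- planeSpec(c(0, 0, 0), c(0, 0, 2))
#' vapply(p, length, 1L)
#' @export
planeSpec <- function(point, normal) {
  stopifnot(is.numeric(point), length(point) == 3L, all(is.finite(point)),
            is.numeric(normal), length(normal) == 3L, all(is.finite(normal)))
  structure(list(point = as.numeric(point), normal = unitize(as.numeric(normal))),
            class = "planeSpec")
}

is_plane <- function(x) inherits(x, "planeSpec") &&
  abs(vnorm(x$normal) - 1) < 1e-9

## signed distance of points (n x 3 matrix or length-3 vector) from plane
plane_distance <- function(pts, plane) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  drop((pts - matrix(plane$point, nrow(pts), 3L, byrow = TRUE)) %*% plane$normal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic child seed derived from a base seed and a stage tag,
## kept inside 32-bit integer range
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 101 + h) %% 2147480000L)
}
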