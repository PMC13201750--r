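#' @rdname accessors
#' @export
setGeneric("contacts", function(x, ...) standardGeneric("contacts"))

#' @rdname accessors
#' @export
setGeneric("isVirtual", function(x) standardGeneric("isVirtual"))

#' @rdname accessors
#' @export
setGeneric("leadModel", function(x) standardGeneric("leadModel"))

#' @rdname accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setGeneric("atlasAffine", function(x) standardGeneric("atlasAffine"))

#' Accessors for nigratarget S4 objects
#'
#' `contacts()` returns the contact-center matrix of a lead (optionally only
#' implanted contacts), `isVirtual()` the per-contact virtual flag,
#' `leadModel()` and `hemisphere()` the lead metadata, `voxelSize()`,
#' `labelTable()` and `atlasAffine()` the atlas grid metadata.
#'
#' @param x a [Lead-class] or [LabelAtlas-class] object.
#' @param implantedOnly logical; drop virtual contacts.
#' @param ... passed on between methods.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases contacts,Lead-method isVirtual,Lead-method leadModel,Lead-method
#'   hemisphere,Lead-method voxelSize,LabelAtlas-method
#'   labelTable,LabelAtlas-method atlasAffine,LabelAtlas-method
NULL

#' @rdname accessors
setMethod("contacts", "Lead", function(x, implantedOnly = FALSE, ...) {
  cc <- x@contacts
  if (implantedOnly) cc <- cc[x@extension == 0, , drop = FALSE]
  cc
})

#' @rdname accessors
setMethod("isVirtual", "Lead", function(x) x@extension > 0)

#' @rdname accessors
setMethod("leadModel", "Lead", function(x) x@model)

#' @rdname accessors
setMethod("hemisphere", "Lead", function(x) x@hemisphere)

#' @rdname accessors
setMethod("voxelSize", "LabelAtlas", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname accessors
setMethod("labelTable", "LabelAtlas", function(x) x@labelTable)

#' @rdname accessors
setMethod("atlasAffine", "LabelAtlas", function(x) x@affine)

setMethod("show", "LabelAtlas", function(object) {
  vs <- voxelSize(object)
  cat(sprintf("LabelAtlas: %s voxels at %.3g x %.3g x %.3g mm\n",
              paste(dim(object@data), collapse = " x "), vs[1], vs[2], vs[3]))
  cat("  labels:", paste(names(object@labelTable), collapse = ", "), "\n")
  if (length(object@masks))
    cat("  overlay masks:", paste(names(object@masks), collapse = ", "), "\n")
})

setMethod("show", "LeadModel", function(object) {
  cat(sprintf("LeadModel '%s': %d levels, %.1f mm spacing (%s)\n",
              object@name, object@nLevels, object@spacing, object@designClass))
})

setMethod("show", "Lead", function(object) {
  nv <- sum(object@extension > 0)
  cat(sprintf("Lead '%s' (%s hemisphere), model '%s': %d contacts (%d virtual)\n",
              object@leadId, object@hemisphere, object@model@name,
              nrow(object@contacts), nv))
})

setMethod("show", "NativeFrame", function(object) {
  cat("NativeFrame: AC", sprintf("(%.1f, %.1f, %.1f)", object@ac[1], object@ac[2],
      object@ac[3]), "PC", sprintf("(%.1f, %.1f, %.1f)", object@pc[1],
      object@pc[2], object@pc[3]), "\n")
})

setMethod("show", "GpcModel", function(object) {
  cat(sprintf("GpcModel (%s engagement): n = %d, EP logZ = %.2f\n",
              object@target, nrow(object@X), object@logZ))
  cat("  lengthscales (standardized):",
      paste(sprintf("%.2f", exp(object@hyper$loglen)), collapse = ", "),
      " signal sd:", sprintf("%.2f", exp(object@hyper$logsf)), "\n")
})

setMethod("show", "RuleMap", function(object) {
  cat(sprintf("RuleMap (%s, threshold %.2f): grid %s, %.1f%% of cells confident\n",
              object@target, object@threshold,
              paste(dim(object@prob), collapse = " x "),
              100 * mean(object@region)))
})
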