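#' Write a label atlas as NIfTI with a JSON label sidecar
#'
#' The label volume is written as an integer NIfTI with the atlas affine in
#' both sform and qform; the label table (and any overlay masks, as linear
#' voxel indices) goes to `<path>.labels.json`.
#'
#' @param atlas a [LabelAtlas-class].
#' @param path output NIfTI path (".nii").
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas@data)
  RNifti::pixdim(img) <- voxelSize(atlas)
  aff <- structure(atlas@affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  side <- list(labels = as.list(atlas@labelTable),
               masks = lapply(atlas@masks, as.integer))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")

#' Read a label atlas written by [writeAtlas()]
#'
#' Validates that the volume holds integer labels, that the affine is
#' invertible and that the sidecar lists every required structure for both
#' hemispheres; each failure raises a distinct error naming the problem.
#'
#' @param path NIfTI path; `<path>.labels.json` must exist.
#' @return A [LabelAtlas-class].
#' @export
readAtlas <- function(path) {
  img <- RNifti::readNifti(path)
  data <- structure(as.vector(as.array(img)), dim = dim(img))
  if (!is.integer(data)) {
    if (max(abs(data - round(data))) > 1e-6)
      stop("atlas volume contains non-integer label values")
    storage.mode(data) <- "integer"
  }
  affine <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("atlas affine is singular")
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop(sprintf("label sidecar '%s' not found", sc))
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  labels <- stats::setNames(as.integer(side$labels), names(side$labels))
  required <- names(.LABELS)
  missing <- setdiff(required, names(labels))
  if (length(missing))
    stop(sprintf("label sidecar is missing required entries: %s",
                 paste(missing, collapse = ", ")))
  masks <- lapply(side$masks %||% list(), as.integer)
  new("LabelAtlas", data = data, affine = affine, labelTable = labels,
      masks = masks, cache = new.env(parent = emptyenv()))
}

fixed6 <- function(x) formatC(x, format = "f", digits = 6)

#' Write a lead table
#'
#' CSV columns: `lead_id`, `hemisphere`, `model`, `contact_index` (0 is the
#' ventralmost), `extension` (mm; 0 for implanted contacts), `x_mm`, `y_mm`,
#' `z_mm` with 6-decimal fixed formatting. JSON output mirrors the same
#' records.
#'
#' @param leads list of [Lead-class] objects.
#' @param path output path ending in ".csv" or ".json".
#' @return `path`, invisibly.
#' @export
writeLeadTable <- function(leads, path) {
  rows <- do.call(rbind, lapply(leads, function(ld) {
    cc <- ld@contacts
    data.frame(lead_id = ld@leadId, hemisphere = ld@hemisphere,
               model = ld@model@name,
               contact_index = seq_len(nrow(cc)) - 1L,
               extension = ld@extension,
               x_mm = cc[, 1L], y_mm = cc[, 2L], z_mm = cc[, 3L],
               stringsAsFactors = FALSE)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rows, path, digits = NA, dataframe = "rows")
  } else {
    out <- rows
    for (cl in c("x_mm", "y_mm", "z_mm", "extension")) out[[cl]] <- fixed6(out[[cl]])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read a lead table written by [writeLeadTable()]
#'
#' @param path ".csv" or ".json" path.
#' @return List of [Lead-class] objects.
#' @export
readLeadTable <- function(path) {
  rows <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("lead_id", "hemisphere", "model", "contact_index",
            "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    stop(sprintf("lead table lacks columns: %s", paste(missing, collapse = ", ")))
  if (is.null(rows$extension)) rows$extension <- 0
  lapply(split(rows, rows$lead_id), function(r) {
    r <- r[order(r$contact_index), , drop = FALSE]
    new("Lead", leadId = as.character(r$lead_id[1L]),
        hemisphere = as.character(r$hemisphere[1L]),
        model = getLeadModel(as.character(r$model[1L])),
        contacts = cbind(r$x_mm, r$y_mm, r$z_mm),
        extension = as.numeric(r$extension))
  })
}

#' Write frame landmarks to JSON
#' @param frame a [NativeFrame-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeFrame <- function(frame, path) {
  jsonlite::write_json(list(ac = frame@ac, pc = frame@pc,
                            midline_vertex = frame@midlineVertex),
                       path, digits = NA)
  invisible(path)
}

#' Read frame landmarks from JSON
#' @param path JSON path with `ac`, `pc`, `midline_vertex`.
#' @return A [NativeFrame-class].
#' @export
readFrame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("ac", "pc", "midline_vertex"))
    if (is.null(j[[f]])) stop(sprintf("frame file lacks field '%s'", f))
  buildNativeFrame(j$ac, j$pc, j$midline_vertex)
}
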