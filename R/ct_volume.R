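#' Voxel volume container
#'
#' A 3D voxel grid (grey 8-bit or binary pore = 1 / matrix = 0) with its
#' physical voxel edge length and a cylindrical analysis domain. The first
#' array index is depth (pointing downwards); voxel centres sit at
#' `(index - 0.5) * voxel_edge` in physical units.
#'
#' @param values 3D array. Binary volumes contain only 0/1; grey volumes
#'   any numeric values.
#' @param voxel_edge_um Voxel edge length in micrometres (> 0).
#' @param radius_vox Radius of the cylindrical analysis domain in voxels;
#'   default: the largest inscribed cylinder in the array cross-section.
#' @param binary Logical; if `NULL`, inferred from the values.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_edge_um, radius_vox = NULL,
                         binary = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            is.numeric(voxel_edge_um), voxel_edge_um > 0)
  d <- dim(values)
  if (is.null(binary)) binary <- all(values %in% c(0, 1))
  if (binary && !all(values %in% c(0, 1)))
    stop("binary volume must contain only 0 and 1")
  if (is.null(radius_vox)) radius_vox <- min(d[2], d[3]) / 2
  stopifnot(radius_vox > 0)
  structure(
    list(values = values, voxel_edge_um = voxel_edge_um,
         radius_vox = radius_vox, binary = binary),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "voxel_volume: %d x %d x %d voxels at %.3g um (%s), domain radius %.1f voxels\n",
    d[1], d[2], d[3], x$voxel_edge_um,
    if (x$binary) "binary" else "grey", x$radius_vox))
  invisible(x)
}

#' Cylindrical analysis-domain mask of a volume
#' @param vol A [voxel_volume()].
#' @return Logical array: voxels inside the cylinder.
#' @export
domain_mask <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$values)
  cy <- (d[2] + 1) / 2
  cz <- (d[3] + 1) / 2
  r2 <- outer((seq_len(d[2]) - cy)^2, (seq_len(d[3]) - cz)^2, `+`)
  inside <- r2 <= vol$radius_vox^2
  array(rep(inside, each = d[1]), dim = d)
}

#' Shrink the analysis domain radially
#'
#' Excludes an outer annulus of the cylindrical domain (e.g. to avoid
#' sampling artefacts near the sampler wall). The rim width is converted to
#' voxels via the voxel edge and rounded to the nearest integer.
#'
#' @param vol A [voxel_volume()].
#' @param rim_mm Rim width in mm (>= 0).
#' @return The volume with a reduced `radius_vox`.
#' @export
exclude_rim <- function(vol, rim_mm) {
  stopifnot(inherits(vol, "voxel_volume"), is.numeric(rim_mm), rim_mm >= 0)
  rim_vox <- round(rim_mm * 1000 / vol$voxel_edge_um)
  if (rim_vox >= vol$radius_vox)
    stop("rim larger than the domain radius")
  vol$radius_vox <- vol$radius_vox - rim_vox
  vol
}

#' Segment a grey volume into pores and matrix
#'
#' One global threshold is applied to the whole volume. With polarity
#' `"dark_pore"` (the usual CT convention: air attenuates less than soil)
#' voxels strictly below the threshold become pore; with `"bright_pore"`
#' voxels at or above the threshold become pore.
#'
#' @param vol A grey [voxel_volume()].
#' @param threshold Global grey threshold.
#' @param polarity `"dark_pore"` or `"bright_pore"`.
#' @return A binary [voxel_volume()] (pore = 1).
#' @export
segment_pores <- function(vol, threshold, polarity = c("dark_pore",
                                                       "bright_pore")) {
  stopifnot(inherits(vol, "voxel_volume"))
  polarity <- match.arg(polarity)
  bin <- if (polarity == "dark_pore") vol$values < threshold
         else vol$values >= threshold
  bin <- array(as.integer(bin), dim = dim(vol$values))
  dm <- domain_mask(vol)
  frac <- sum(bin[dm]) / sum(dm)
  if (frac == 0) warning("segmentation yielded no pore voxels")
  if (frac == 1) warning("segmentation yielded no matrix voxels")
  voxel_volume(bin, vol$voxel_edge_um, radius_vox = vol$radius_vox,
               binary = TRUE)
}

#' Visible porosity of a binary volume within a region
#'
#' @param vol Binary [voxel_volume()] or 0/1 array.
#' @param region Logical array delimiting the region; defaults to the
#'   analysis domain.
#' @return Pore voxels / region voxels (m^3 m^-3).
#' @export
visible_porosity <- function(vol, region = NULL) {
  v <- if (inherits(vol, "voxel_volume")) vol$values else vol
  if (is.null(region)) {
    stopifnot(inherits(vol, "voxel_volume"))
    region <- domain_mask(vol)
  }
  if (sum(region) == 0) stop("empty region")
  sum(v[region]) / sum(region)
}

#' Label connected pore clusters
#'
#' Deterministic connected-component labelling (labels assigned in
#' raster-scan discovery order) with 6- or 26-connectivity.
#'
#' @param mask Logical/0-1 3D array or binary [voxel_volume()].
#' @param connectivity 6 or 26 (default 26).
#' @return Integer array of labels; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26) {
  v <- if (inherits(mask, "voxel_volume")) mask$values else mask
  stopifnot(is.array(v), length(dim(v)) == 3)
  lab <- cpp_label3d(as.integer(v != 0), dim(v), as.integer(connectivity))
  array(lab, dim = dim(v))
}

#' Read a voxel volume from a multi-page TIFF plus YAML sidecar
#'
#' The sidecar must provide `voxel_edge_um` and may provide `polarity`
#' (stored as an attribute) and `radius_vox`. Pages are stacked along the
#' depth (first) axis. 8-bit grey data are returned on the 0-255 scale;
#' binary data as 0/1.
#'
#' @param tif_path Path to the TIFF stack.
#' @param meta_path Path to the YAML sidecar; defaults to the TIFF path
#'   with a `.yml` extension.
#' @return A [voxel_volume()].
#' @export
read_voxel_volume <- function(tif_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".yml", tif_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$voxel_edge_um)) stop("sidecar must give voxel_edge_um")
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d23 <- dim(pages[[1]])
  values <- array(0, dim = c(length(pages), d23[1], d23[2]))
  for (i in seq_along(pages)) values[i, , ] <- pages[[i]]
  values <- round(values * 255)
  if (all(values %in% c(0, 255))) values <- values / 255
  vol <- voxel_volume(values, meta$voxel_edge_um,
                      radius_vox = meta$radius_vox)
  attr(vol, "polarity") <- meta$polarity
  vol
}

#' Write a voxel volume to a multi-page TIFF plus YAML sidecar
#'
#' Binary volumes are written as 0/255 8-bit pages, grey volumes on their
#' 0-255 scale.
#'
#' @param vol A [voxel_volume()].
#' @param tif_path Output TIFF path.
#' @param meta_path Output YAML path; defaults to the TIFF path with `.yml`.
#' @return Invisibly, the TIFF path.
#' @export
write_voxel_volume <- function(vol, tif_path, meta_path = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".yml", tif_path)
  v <- vol$values
  v <- if (vol$binary) v else pmin(pmax(v, 0), 255) / 255
  storage.mode(v) <- "double"
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ])
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 8)
  yaml::write_yaml(list(voxel_edge_um = vol$voxel_edge_um,
                        radius_vox = vol$radius_vox,
                        polarity = if (vol$binary) "binary" else "dark_pore"),
                   meta_path)
  invisible(tif_path)
}
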