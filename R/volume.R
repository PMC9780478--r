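#' Tissue label volume
#'
#' A 3-D integer grid of tissue codes on a regular voxel lattice. Index
#' (i, j, k) is 0-based in the mapping to world coordinates: a voxel centre
#' sits at `origin + index * spacing` (cell-centred samples).
#'
#' @param codes 3-D integer array of tissue codes (0 = background).
#' @param spacing voxel spacing (mm), length 3, strictly positive.
#' @param origin world coordinate of voxel (0, 0, 0) centre (mm).
#' @param tissue_map named integer vector mapping tissue name to code.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(codes, spacing, origin = c(0, 0, 0),
                         tissue_map = default_tissue_map()) {
  codes <- as.array(codes)
  storage.mode(codes) <- "integer"
  stopifnot(length(dim(codes)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  if (any(codes < 0)) stop("tissue codes must be non-negative")
  structure(list(codes = codes, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), tissue_map = tissue_map),
            class = "label_volume")
}

#' Default tissue code mapping
#'
#' The source imaging protocol does not prescribe a label-code scheme, so the
#' package uses this documented default throughout: bones 1-3, cartilage 4-8
#' (tibial cartilage carries independent medial/lateral codes, mirroring
#' knee segmentation practice).
#' @return named integer vector.
#' @export
default_tissue_map <- function() {
  c(femur = 1L, tibia = 2L, patella = 3L,
    femoral_cartilage = 4L, tibial_cartilage_medial = 5L,
    tibial_cartilage_lateral = 6L, patellar_cartilage = 7L,
    meniscus = 8L)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume: %s voxels @ %s mm, codes %s>\n",
              paste(dim(x$codes), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(sort(unique(as.vector(x$codes))), collapse = ",")))
  invisible(x)
}

#' World coordinates of voxel indices
#' @param volume a [label_volume()].
#' @param index N x 3 matrix of 0-based voxel indices.
#' @export
voxel_to_world <- function(volume, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(index %*% diag(volume$spacing), 2, volume$origin, "+")
}

#' Look up the code for a tissue name
#' @keywords internal
tissue_code <- function(volume, tissue) {
  if (is.numeric(tissue)) return(as.integer(tissue))
  code <- volume$tissue_map[[tissue]]
  if (is.null(code)) stop("unknown tissue: ", tissue)
  as.integer(code)
}

#' Binary mask for one tissue
#' @param volume a [label_volume()].
#' @param tissue tissue name or integer code.
#' @export
tissue_mask <- function(volume, tissue) {
  volume$codes == tissue_code(volume, tissue)
}

# shift a 3-D logical array by (di, dj, dk), padding with `fill`
shift_array <- function(a, di, dj, dk, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) max(1, 1 - s):min(n, n - s)
  i <- src(d[1], di); j <- src(d[2], dj); k <- src(d[3], dk)
  out[i + di, j + dj, k + dk] <- a[i, j, k]
  out
}

# morphological dilation / erosion with a cubic kernel of odd width
binary_dilate <- function(mask, width) {
  r <- (width - 1) %/% 2
  out <- mask
  # separable along each axis: three 1-D passes
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(r)) {
      off <- c(0, 0, 0); off[axis] <- s
      acc <- acc | shift_array(out, off[1], off[2], off[3]) |
        shift_array(out, -off[1], -off[2], -off[3])
    }
    out <- acc
  }
  out
}

binary_erode <- function(mask, width) {
  !binary_dilate(!mask, width)
}

#' Morphological closing of one tissue mask
#'
#' Removes small segmentation artifacts (slits, interior voids) before
#' surface reconstruction. Cartilage masks are closed with a five-voxel
#' uniform cubic kernel, bone masks with a three-voxel kernel.
#'
#' @param volume a [label_volume()].
#' @param tissue tissue name or code (selects the binary mask to close).
#' @param tissue_class `"cartilage"` (5-voxel kernel) or `"bone"` (3-voxel).
#' @return a [label_volume()] holding the closed binary mask (code 1).
#' @export
close_labels <- function(volume, tissue,
                         tissue_class = c("cartilage", "bone")) {
  tissue_class <- match.arg(tissue_class)
  width <- if (tissue_class == "cartilage") 5L else 3L
  mask <- tissue_mask(volume, tissue)
  if (!any(mask))
    stop("empty mask for tissue ", if (is.numeric(tissue)) tissue else tissue,
         call. = FALSE)
  # pad by the kernel width so dilation never clips at the array boundary
  d <- dim(mask)
  p <- width
  big <- array(FALSE, d + 2L * p)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask
  closed <- binary_erode(binary_dilate(big, width), width)
  closed <- closed[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
  label_volume(array(as.integer(closed), d), volume$spacing,
               volume$origin, volume$tissue_map)
}
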