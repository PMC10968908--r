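#' ROI signal sets: padded per-region voxel vectors
#'
#' An `roi_signal_set` holds one activation vector per region of interest
#' (ROI), all zero-padded at the tail to a common length `D =
#' max(voxel_counts)` so that the set can be stacked as an `R x D` matrix.
#' Binary masks record which entries are real voxels (1) and which are
#' padding (0); padded entries are exactly 0 so that dot products between
#' regions are unaffected by the alignment.
#'
#' @param vectors `R x D` numeric matrix, one ROI per row.
#' @param masks `R x D` binary matrix marking real (1) vs padded (0) entries.
#' @param voxel_counts integer vector of original (unpadded) ROI lengths.
#' @param roi_names character vector of ROI identifiers.
#' @return An object of class `roi_signal_set` with fields `vectors`,
#'   `masks`, `voxel_counts`, `roi_names`, `D`, `R`.
#' @seealso [align_rois()] to build one from ragged vectors.
#' @export
roi_signal_set <- function(vectors, masks, voxel_counts, roi_names) {
  vectors <- as.matrix(vectors)
  masks <- as.matrix(masks)
  voxel_counts <- as.integer(voxel_counts)
  x <- structure(
    list(vectors = vectors, masks = masks, voxel_counts = voxel_counts,
         roi_names = as.character(roi_names),
         D = ncol(vectors), R = nrow(vectors)),
    class = "roi_signal_set")
  validate_roi_signal_set(x)
  x
}

#' @rdname roi_signal_set
#' @param x object to validate / test.
#' @export
validate_roi_signal_set <- function(x) {
  if (!inherits(x, "roi_signal_set")) stop_input("not an roi_signal_set")
  R <- x$R; D <- x$D
  if (R < 2) stop_input("an roi_signal_set needs at least 2 ROIs, got %d", R)
  if (!all(dim(x$masks) == c(R, D)))
    stop_input("mask matrix shape differs from vector matrix shape")
  if (length(x$voxel_counts) != R || length(x$roi_names) != R)
    stop_input("voxel_counts/roi_names length must equal the number of ROIs")
  if (any(x$voxel_counts < 1)) stop_input("all voxel counts must be >= 1")
  if (max(x$voxel_counts) != D)
    stop_input("padded length D (%d) must equal max(voxel_counts) (%d)",
               D, max(x$voxel_counts))
  if (!all(x$masks %in% c(0, 1))) stop_input("masks must be binary")
  if (!all(rowSums(x$masks) == x$voxel_counts))
    stop_input("mask row sums disagree with voxel_counts")
  if (any(x$vectors[x$masks == 0] != 0))
    stop_input("padded positions must hold exactly 0")
  invisible(x)
}

#' @rdname roi_signal_set
#' @export
is_roi_signal_set <- function(x) inherits(x, "roi_signal_set")

#' Align ragged ROI vectors by tail zero-padding
#'
#' Pads each region's voxel vector with zeros at the tail to the maximum
#' region length, recording validity masks. Zero padding keeps dot products
#' between regions identical to those of the unpadded overlap, so downstream
#' cosine connectivity is exact; later normalizations guard their norms with
#' a small epsilon rather than relying on non-zero padding.
#'
#' Idempotent: aligning an already-aligned set returns it unchanged.
#'
#' @param raw_vectors list of numeric vectors, one per ROI (>= 2, all
#'   non-empty), or an existing `roi_signal_set`.
#' @param roi_names optional ROI identifiers (defaults to `ROI1..ROIR`).
#' @return An [roi_signal_set()].
#' @examples
#' s <- align_rois(list(V1 = rnorm(3), V2 = rnorm(5)))
#' s$D            # 5
#' s$vectors[1, 4:5]  # exactly 0
#' @export
align_rois <- function(raw_vectors, roi_names = NULL) {
  if (is_roi_signal_set(raw_vectors)) return(raw_vectors)
  if (!is.list(raw_vectors) || length(raw_vectors) == 0)
    stop_input("align_rois expects a non-empty list of ROI vectors")
  if (length(raw_vectors) < 2) stop_input("need at least 2 ROI vectors")
  lens <- vapply(raw_vectors, length, integer(1))
  if (any(lens == 0)) stop_input("empty ROI vector at position %d",
                                 which(lens == 0)[1])
  if (is.null(roi_names)) {
    roi_names <- names(raw_vectors) %||% paste0("ROI", seq_along(raw_vectors))
    if (any(roi_names == "")) roi_names <- paste0("ROI", seq_along(raw_vectors))
  }
  D <- max(lens)
  R <- length(raw_vectors)
  vec <- matrix(0, R, D)
  msk <- matrix(0, R, D)
  for (r in seq_len(R)) {
    vec[r, seq_len(lens[r])] <- raw_vectors[[r]]
    msk[r, seq_len(lens[r])] <- 1
  }
  roi_signal_set(vec, msk, lens, roi_names)
}

#' Average repeated fMRI recordings of the same stimulus
#'
#' Element-wise mean over a list of `roi_signal_set`s sharing shapes; masks
#' and metadata are taken from the first element. Averaging repeats before
#' decoding is the conventional way to boost the effective signal-to-noise
#' ratio of test-set recordings.
#'
#' @param repeats non-empty list of [roi_signal_set()]s with identical
#'   `roi_names`, `voxel_counts` and `D`.
#' @return A single [roi_signal_set()].
#' @export
average_repeats <- function(repeats) {
  if (!is.list(repeats) || length(repeats) == 0)
    stop_input("average_repeats expects a non-empty list of recordings")
  ref <- repeats[[1]]
  validate_roi_signal_set(ref)
  for (s in repeats[-1]) {
    validate_roi_signal_set(s)
    if (!identical(s$roi_names, ref$roi_names) ||
        !identical(s$voxel_counts, ref$voxel_counts))
      stop_input("repeats disagree in roi_names or voxel_counts")
  }
  acc <- Reduce(`+`, lapply(repeats, `[[`, "vectors"))
  roi_signal_set(acc / length(repeats), ref$masks, ref$voxel_counts,
                 ref$roi_names)
}

# Stack as R x D matrix (already is one); flatten ROI-major to length R*D.
flatten_nodes <- function(nodes) {
  if (is_roi_signal_set(nodes)) nodes <- nodes$vectors
  as.vector(t(nodes))
}

unflatten_nodes <- function(v, R, D) matrix(v, R, D, byrow = TRUE)
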