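#' Cubic image resampling
#'
#' Separable cubic-kernel (Catmull-Rom, a = -0.5) resampling in the
#' align-corners = FALSE convention: output pixel centre `u` maps to input
#' coordinate `(u + 0.5) * s - 0.5` with `s = in/out`. When downsampling the
#' kernel support is widened by the scale factor (anti-aliasing), which is
#' the standard choice for image pyramids. Border samples are clamped
#' (edge replication) and each output weight row is renormalized to sum to 1.
#'
#' @param img `H x W x C` numeric array (or `H x W` matrix).
#' @param out_h,out_w output spatial size.
#' @return resampled array, same channel count, values unclipped.
#' @export
resize_cubic <- function(img, out_h, out_w = out_h) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  Wh <- cubic_weight_matrix(d[1], out_h)
  Ww <- cubic_weight_matrix(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Wh %*% img[, , c] %*% t(Ww)
  out
}

# Dense (out x in) resampling operator for one axis.
cubic_weight_matrix <- function(n_in, n_out) {
  s <- n_in / n_out
  support <- if (s > 1) s else 1   # widen kernel when downsampling
  W <- matrix(0, n_out, n_in)
  for (u in seq_len(n_out)) {
    x <- (u - 0.5) * s - 0.5       # 0-based input coordinate
    lo <- floor(x - 2 * support) + 1
    hi <- ceiling(x + 2 * support) - 1
    ks <- lo:hi
    w <- cubic_kernel((x - ks) / support)
    ks <- pmin(pmax(ks, 0), n_in - 1)  # clamp to border (replication)
    for (t in seq_along(ks)) W[u, ks[t] + 1] <- W[u, ks[t] + 1] + w[t]
    W[u, ] <- W[u, ] / sum(W[u, ])
  }
  W
}

# Keys cubic kernel with a = -0.5 (Catmull-Rom).
cubic_kernel <- function(x) {
  a <- -0.5
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

#' Build the four-level image pyramid
#'
#' Downsamples a 112 x 112 RGB image (values in \[0, 1\]) to 56, 28 and 14
#' pixels with anti-aliased cubic interpolation, clipping interpolated
#' values back to \[0, 1\]. The native 112 level is the input itself,
#' untouched.
#'
#' @param image_112 `112 x 112 x 3` array with values in \[0, 1\].
#' @return An `image_pyramid`: a list with elements `"14"`, `"28"`, `"56"`,
#'   `"112"`, each an `s x s x 3` array in \[0, 1\].
#' @export
build_pyramid <- function(image_112) {
  if (!is.array(image_112) || length(dim(image_112)) != 3 ||
      !all(dim(image_112) == c(112, 112, 3)))
    stop_input("build_pyramid expects a 112 x 112 x 3 array")
  if (min(image_112) < 0 || max(image_112) > 1)
    stop_input("pixel values must lie in [0, 1]")
  levels <- list(`14` = pmin(pmax(resize_cubic(image_112, 14), 0), 1),
                 `28` = pmin(pmax(resize_cubic(image_112, 28), 0), 1),
                 `56` = pmin(pmax(resize_cubic(image_112, 56), 0), 1),
                 `112` = image_112)
  structure(levels, class = "image_pyramid")
}

#' @rdname build_pyramid
#' @param pyramid an `image_pyramid`.
#' @export
validate_pyramid <- function(pyramid) {
  if (!inherits(pyramid, "image_pyramid")) stop_input("not an image_pyramid")
  sizes <- c(14, 28, 56, 112)
  for (s in sizes) {
    lv <- pyramid[[as.character(s)]]
    if (is.null(lv) || !all(dim(lv) == c(s, s, 3)))
      stop_input("pyramid level %d missing or mis-shaped", s)
    if (min(lv) < 0 || max(lv) > 1)
      stop_input("pyramid level %d has values outside [0, 1]", s)
  }
  invisible(pyramid)
}

#' Final reconstruction: the native-resolution pyramid level
#'
#' The multi-stage decoder emits four scales; the 112 x 112 output is the
#' reconstruction proper, the coarser levels exist to constrain training.
#'
#' @param pyramid an `image_pyramid`.
#' @return `112 x 112 x 3` array.
#' @export
final_reconstruction <- function(pyramid) {
  validate_pyramid(pyramid)
  pyramid[["112"]]
}
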