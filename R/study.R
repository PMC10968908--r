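#' Study containers
#'
#' A `study_container` bundles everything one subject's reconstruction
#' experiment needs: training pairs (stimulus image + single fMRI
#' recording), test stimuli with repeated fMRI recordings, an unlabeled
#' image pool for the self-supervised branch, and metadata.
#'
#' @param train_pairs list of `list(image = 112x112x3 array, fmri =
#'   roi_signal_set)`.
#' @param test_stimuli list of `112 x 112 x 3` arrays.
#' @param test_repeats list (one per test stimulus) of lists of
#'   [roi_signal_set()] recordings (>= 1 each).
#' @param unlabeled_images list of `112 x 112 x 3` arrays (possibly empty).
#' @param metadata list with at least `subject`, `roi_names`,
#'   `voxel_counts`, `seed`.
#' @return An object of class `study_container`.
#' @export
study_container <- function(train_pairs, test_stimuli, test_repeats,
                            unlabeled_images = list(), metadata = list()) {
  x <- structure(
    list(train_pairs = train_pairs, test_stimuli = test_stimuli,
         test_repeats = test_repeats, unlabeled_images = unlabeled_images,
         metadata = metadata),
    class = "study_container")
  validate_study(x)
  x
}

#' @rdname study_container
#' @param x object to validate.
#' @export
validate_study <- function(x) {
  if (!inherits(x, "study_container")) stop_input("not a study_container")
  md <- x$metadata
  for (f in c("roi_names", "voxel_counts"))
    if (is.null(md[[f]])) stop_input("metadata field '%s' is missing", f)
  if (length(x$test_stimuli) != length(x$test_repeats))
    stop_input("test_stimuli and test_repeats lengths differ")
  all_sets <- c(lapply(x$train_pairs, `[[`, "fmri"),
                unlist(x$test_repeats, recursive = FALSE))
  for (s in all_sets) {
    validate_roi_signal_set(s)
    if (!identical(s$roi_names, as.character(md$roi_names)))
      stop_input("recording roi_names disagree with metadata roi_names")
    if (!identical(s$voxel_counts, as.integer(md$voxel_counts)))
      stop_input("recording voxel_counts disagree with metadata voxel_counts")
  }
  nrep <- vapply(x$test_repeats, length, integer(1))
  if (length(nrep) && any(nrep < 1))
    stop_input("test stimulus %d has 0 repeats", which(nrep < 1)[1])
  for (im in c(lapply(x$train_pairs, `[[`, "image"), x$test_stimuli,
               x$unlabeled_images)) {
    if (!all(dim(im) == c(112, 112, 3)))
      stop_input("all stimulus images must be 112 x 112 x 3")
    if (min(im) < 0 || max(im) > 1)
      stop_input("image values must lie in [0, 1]")
  }
  # train and test stimuli must be disjoint
  if (length(x$train_pairs) && length(x$test_stimuli)) {
    tr <- vapply(x$train_pairs, function(p) image_digest(p$image), "")
    te <- vapply(x$test_stimuli, image_digest, "")
    if (any(te %in% tr)) stop_input("train and test stimuli overlap")
  }
  invisible(x)
}

# cheap content fingerprint for disjointness checks
image_digest <- function(im) paste(format(sum(im * seq_along(im)), digits = 17),
                                   format(sum(im^2), digits = 17))

#' @export
print.study_container <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "study_container: %d train pairs, %d test stimuli (repeats: %s), %d unlabeled\n",
    length(x$train_pairs), length(x$test_stimuli),
    paste(range(vapply(x$test_repeats, length, integer(1))), collapse = "-"),
    length(x$unlabeled_images)))
  cat(sprintf("  subject: %s | ROIs: %s | D = %d\n",
              md$subject %||% "?", paste(md$roi_names, collapse = ", "),
              max(as.integer(md$voxel_counts))))
  invisible(x)
}

#' Read / write study containers
#'
#' Serializes a [study_container()] to a single versioned RDS file and reads
#' it back with full validation; a write-then-read round trip reproduces all
#' arrays exactly. Read errors name the offending field.
#'
#' @param container a [study_container()].
#' @param path file path (conventionally `.rds`).
#' @return `write_study` returns `path` invisibly; `read_study` returns the
#'   container.
#' @export
write_study <- function(container, path) {
  validate_study(container)
  obj <- unclass(container)
  obj$.format <- "neirecon-study"
  obj$.version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  if (!file.exists(path)) stop_input("study file not found: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$.format, "neirecon-study"))
    stop_input("file is not a neirecon study container: %s", path)
  for (f in c("train_pairs", "test_stimuli", "test_repeats", "metadata"))
    if (is.null(obj[[f]])) stop_input("study container missing field '%s'", f)
  study_container(obj$train_pairs, obj$test_stimuli, obj$test_repeats,
                  obj$unlabeled_images %||% list(), obj$metadata)
}

#' Export / import stimulus images as a PNG directory
#'
#' Writes every image of a study split as PNG files plus an `index.csv`
#' (columns `split`, `stimulus_id`, `filename`). Requires the `png` package.
#'
#' @param images list of `112 x 112 x 3` arrays in \[0, 1\].
#' @param dir output directory (created if needed).
#' @param split split label written to the index.
#' @return invisibly, the index data frame.
#' @export
write_images_png <- function(images, dir, split = "train") {
  if (!requireNamespace("png", quietly = TRUE))
    stop_input("the 'png' package is required for PNG export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(split = character(0), stimulus_id = integer(0),
                    filename = character(0))
  for (i in seq_along(images)) {
    fn <- sprintf("%s_%04d.png", split, i)
    png::writePNG(images[[i]], file.path(dir, fn))
    idx <- rbind(idx, data.frame(split = split, stimulus_id = i,
                                 filename = fn))
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' @rdname write_images_png
#' @export
read_images_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_input("the 'png' package is required for PNG import")
  idx <- read.csv(file.path(dir, "index.csv"))
  lapply(idx$filename, function(fn) {
    im <- png::readPNG(file.path(dir, fn))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    im[, , 1:3, drop = FALSE]
  })
}

#' Restrict a study to a subset of ROIs
#'
#' Drops all other regions from every recording and re-aligns (the padded
#' length D shrinks to the subset's maximum voxel count). Used for
#' lower/higher visual cortex ablations; see [roi_sets].
#'
#' @param study a [study_container()].
#' @param rois character vector of ROI names to keep (>= 2).
#' @return A new [study_container()].
#' @export
subset_rois <- function(study, rois) {
  validate_study(study)
  md <- study$metadata
  keep <- match(rois, md$roi_names)
  if (anyNA(keep)) stop_input("unknown ROI: %s", rois[which(is.na(keep))[1]])
  if (length(keep) < 2) stop_input("need at least 2 ROIs after subsetting")
  cut <- function(s) {
    raw <- lapply(keep, function(r) s$vectors[r, seq_len(s$voxel_counts[r])])
    align_rois(raw, s$roi_names[keep])
  }
  md$roi_names <- md$roi_names[keep]
  md$voxel_counts <- as.integer(md$voxel_counts)[keep]
  study_container(
    lapply(study$train_pairs, function(p) list(image = p$image,
                                               fmri = cut(p$fmri))),
    study$test_stimuli,
    lapply(study$test_repeats, function(rep_list) lapply(rep_list, cut)),
    study$unlabeled_images, md)
}
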