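#' Dataset layout configuration
#'
#' Filename patterns for a BAGLS-style flat dataset directory: one 8-bit
#' grayscale PNG per frame, one mask PNG per frame (values 0/255) and a single
#' CSV of point annotations with header
#' `id,video_id,frame_idx,ap_x,ap_y,pp_x,pp_y`.
#'
#' @param image,mask filename patterns; `{id}` is replaced by the record id.
#' @param annotations annotation CSV filename.
#' @return a layout list.
#' @export
default_layout <- function(image = "{id}.png", mask = "{id}_seg.png",
                           annotations = "annotations.csv") {
  list(image = image, mask = mask, annotations = annotations)
}

fill_pattern <- function(pattern, id) {
  vapply(id, function(i) gsub("{id}", i, pattern, fixed = TRUE),
         character(1), USE.NAMES = FALSE)
}

#' Write videos to a BAGLS-style dataset directory
#'
#' Images and masks are written as 8-bit PNG (mask values 0/255; in-memory
#' masks use 0/1), annotations as one CSV for the whole dataset. Point
#' coordinates are stored as text at full double precision, so they
#' round-trip exactly; image intensities round-trip within 1/255.
#'
#' @param samples list of `video_sample`s (see [generate_video()]); names are
#'   used as video ids (default `video_001`, ...). An empty list writes
#'   nothing and returns an empty manifest.
#' @param root_path output directory (created if needed).
#' @param layout a [default_layout()].
#' @return manifest data frame listing every file written.
#' @export
write_dataset <- function(samples, root_path, layout = default_layout()) {
  if (length(samples) == 0)
    return(data.frame(file = character(), type = character()))
  ok <- dir.exists(root_path) || dir.create(root_path, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(root_path, 2) != 0)
    ml_io_error(sprintf("cannot write to '%s'", root_path))
  if (is.null(names(samples)))
    names(samples) <- sprintf("video_%03d", seq_along(samples))
  rows <- list()
  files <- character()
  types <- character()
  for (vid in names(samples)) {
    video <- samples[[vid]]
    for (i in seq_along(video$frames)) {
      f <- video$frames[[i]]
      id <- sprintf("%s_%04d", vid, i - 1L)
      ip <- file.path(root_path, fill_pattern(layout$image, id))
      mp <- file.path(root_path, fill_pattern(layout$mask, id))
      png::writePNG(pmin(pmax(f$image, 0), 1), ip)
      png::writePNG(f$mask, mp)
      files <- c(files, ip, mp)
      types <- c(types, "image", "mask")
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, video_id = vid, frame_idx = i - 1L,
        ap_x = f$ap[1], ap_y = f$ap[2], pp_x = f$pp[1], pp_y = f$pp[2])
    }
  }
  ann <- do.call(rbind, rows)
  ap <- file.path(root_path, layout$annotations)
  utils::write.csv(ann, ap, row.names = FALSE, quote = FALSE)
  rbind(data.frame(file = files, type = types),
        data.frame(file = ap, type = "annotations"))
}

#' Read and index a BAGLS-style dataset directory
#'
#' Parses the annotation CSV, verifies that every image has a mask of
#' identical dimensions, that points lie inside the image and that frame
#' indices are contiguous within each video.
#'
#' @param root_path dataset directory.
#' @param layout a [default_layout()].
#' @return a `dataset_index` data frame with columns `id`, `video_id`,
#'   `frame_idx`, `image_path`, `mask_path`, `ap_x`, `ap_y`, `pp_x`, `pp_y`,
#'   `height`, `width`.
#' @export
read_dataset <- function(root_path, layout = default_layout()) {
  if (!dir.exists(root_path))
    ml_io_error(sprintf("dataset root '%s' does not exist", root_path))
  ap <- file.path(root_path, layout$annotations)
  if (!file.exists(ap))
    ml_io_error(sprintf("annotation file '%s' not found", ap))
  ann <- utils::read.csv(ap, stringsAsFactors = FALSE)
  need <- c("id", "ap_x", "ap_y", "pp_x", "pp_y")
  if (!all(need %in% names(ann)))
    ml_io_error(sprintf("annotation file misses columns: %s",
                        paste(setdiff(need, names(ann)), collapse = ", ")))
  if (is.null(ann$video_id)) ann$video_id <- ann$id
  if (is.null(ann$frame_idx)) ann$frame_idx <- 0L
  ann$image_path <- file.path(root_path, fill_pattern(layout$image, ann$id))
  ann$mask_path <- file.path(root_path, fill_pattern(layout$mask, ann$id))
  missing_img <- !file.exists(ann$image_path)
  missing_msk <- !file.exists(ann$mask_path)
  if (any(missing_img | missing_msk))
    ml_io_error(sprintf("missing image/mask files for ids: %s",
                        paste(ann$id[missing_img | missing_msk], collapse = ", ")))
  ann$height <- NA_integer_
  ann$width <- NA_integer_
  for (i in seq_len(nrow(ann))) {
    di <- dim(png::readPNG(ann$image_path[i]))[1:2]
    dm <- dim(png::readPNG(ann$mask_path[i]))[1:2]
    if (!all(di == dm))
      ml_validation_error(sprintf("image/mask dimension mismatch for id '%s'",
                                  ann$id[i]))
    ann$height[i] <- di[1]; ann$width[i] <- di[2]
    pts <- c(ann$ap_x[i], ann$pp_x[i], ann$ap_y[i], ann$pp_y[i])
    if (any(pts < 0) || any(c(ann$ap_x[i], ann$pp_x[i]) > di[2] - 1) ||
        any(c(ann$ap_y[i], ann$pp_y[i]) > di[1] - 1))
      ml_validation_error(sprintf("point outside image bounds for id '%s'",
                                  ann$id[i]))
  }
  for (vid in unique(ann$video_id)) {
    fi <- sort(ann$frame_idx[ann$video_id == vid])
    if (!identical(as.integer(fi), seq_along(fi) - 1L))
      ml_validation_error(sprintf("frame indices not contiguous from 0 for video '%s'",
                                  vid))
  }
  ann <- ann[order(ann$video_id, ann$frame_idx), ]
  rownames(ann) <- NULL
  class(ann) <- c("dataset_index", "data.frame")
  ann
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 127 / 255) * 1
}

read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

#' Load one indexed frame
#'
#' Masks are binarized on read (pixel > 127/255 becomes 1, tolerant to
#' anti-aliased masks).
#'
#' @param index a `dataset_index` from [read_dataset()].
#' @param i row number.
#' @return an `annotated_frame` (`image`, `mask`, `ap`, `pp`).
#' @export
load_frame <- function(index, i) {
  structure(list(image = read_image_png(index$image_path[i]),
                 mask = read_mask_png(index$mask_path[i]),
                 ap = c(index$ap_x[i], index$ap_y[i]),
                 pp = c(index$pp_x[i], index$pp_y[i])),
            class = "annotated_frame")
}

#' Load all frames of one video
#'
#' @param index a `dataset_index`.
#' @param video_id id to load.
#' @return a `video_sample`.
#' @export
load_video <- function(index, video_id) {
  rows <- which(index$video_id == video_id)
  if (length(rows) == 0)
    ml_io_error(sprintf("video '%s' not in index", video_id))
  rows <- rows[order(index$frame_idx[rows])]
  frames <- lapply(rows, function(i) load_frame(index, i))
  structure(list(frames = frames, ap = frames[[1]]$ap, pp = frames[[1]]$pp),
            class = "video_sample")
}
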