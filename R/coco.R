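#' COCO-style annotation I/O
#'
#' Ground truth is stored as a COCO annotations JSON (single "apple"
#' category; boxes as `[x, y, width, height]` in pixels), detections as a
#' COCO results JSON. Internally the package uses corner form
#' `(x1, y1, x2, y2)`; conversion happens at the file boundary.
#'
#' @param samples Annotated samples (lists with `image` and `boxes`).
#' @param path Output JSON path.
#' @param file_names Optional character vector of image file names.
#' @return `path`, invisibly.
#' @export
write_coco_annotations <- function(samples, path, file_names = NULL) {
  images <- list()
  anns <- list()
  ann_id <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- if (!is.null(s$id)) s$id else i
    images[[i]] <- list(
      id = id,
      file_name = if (is.null(file_names)) sprintf("img_%05d.tiff", id)
      else file_names[i],
      width = ncol(s$image$pixels), height = nrow(s$image$pixels))
    if (nrow(s$boxes) > 0) {
      for (b in seq_len(nrow(s$boxes))) {
        ann_id <- ann_id + 1L
        bb <- s$boxes[b, ]
        anns[[ann_id]] <- list(
          id = ann_id, image_id = id, category_id = 1L,
          bbox = c(bb$x1, bb$y1, bb$x2 - bb$x1, bb$y2 - bb$y1),
          area = (bb$x2 - bb$x1) * (bb$y2 - bb$y1), iscrowd = 0L)
      }
    }
  }
  doc <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "apple")))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_coco_annotations
#' @return `read_coco_annotations()` returns a data frame with columns
#'   `image_id, x1, y1, x2, y2`.
#' @export
read_coco_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  anns <- doc$annotations
  if (length(anns) == 0 || NROW(anns) == 0) {
    return(data.frame(image_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0)))
  }
  bb <- do.call(rbind, anns$bbox)
  data.frame(image_id = anns$image_id,
             x1 = bb[, 1], y1 = bb[, 2],
             x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4])
}

#' @rdname write_coco_annotations
#' @param detections Data frame with `image_id, x1, y1, x2, y2, score`.
#' @export
write_coco_results <- function(detections, path) {
  res <- lapply(seq_len(NROW(detections)), function(i) {
    d <- detections[i, ]
    list(image_id = d$image_id, category_id = 1L,
         bbox = c(d$x1, d$y1, d$x2 - d$x1, d$y2 - d$y1),
         score = d$score)
  })
  jsonlite::write_json(res, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_coco_annotations
#' @export
read_coco_results <- function(path) {
  res <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(res) == 0 || NROW(res) == 0) {
    return(data.frame(image_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      score = numeric(0)))
  }
  bb <- do.call(rbind, res$bbox)
  data.frame(image_id = res$image_id,
             x1 = bb[, 1], y1 = bb[, 2],
             x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4],
             score = res$score)
}
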