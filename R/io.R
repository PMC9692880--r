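#' Annotation sets
#'
#' An annotation set is a data frame with box columns
#' `x_min`, `y_min`, `x_max`, `y_max` plus optional `score`, `category`
#' and `iscrowd` columns, carrying the image dimensions and source
#' format as attributes. Reading, writing and re-reading a set is an
#' identity on the boxes.
#'
#' @param df a data frame with at least the four corner columns.
#' @param image_w,image_h image dimensions in pixels (optional).
#' @param source_format identifier of the originating format.
#' @return an `annotation_set` data frame.
#' @export
annotation_set <- function(df, image_w = NA_real_, image_h = NA_real_,
                           source_format = "r") {
  if (nrow(df) > 0L) as_boxes(df)  # validates the box columns; empty sets allowed
  structure(df,
            image_w = image_w, image_h = image_h,
            source_format = source_format,
            class = c("annotation_set", "data.frame"))
}

#' Read COCO-style box annotations
#'
#' Accepts the usual COCO annotation dialect: a JSON object with
#' `images` (id, width, height), `annotations` (id, image_id, bbox as
#' `[x, y, w, h]` top-left + size, optional category_id and iscrowd) and
#' optional `categories`. Boxes are converted to corner form
#' (`x_max = x + w`). Crowd annotations are retained and flagged in the
#' `iscrowd` column. Zero-area bboxes and structurally malformed records
#' are rejected with the offending annotation id in the message.
#'
#' @param path path to the JSON file.
#' @return an [annotation_set()] with one row per annotation; image
#'   dimensions are taken from the first image entry when present.
#' @export
read_coco <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$annotations))
    stop("not a COCO-style annotation file (no 'annotations' field): ", path)
  anns <- doc$annotations
  n <- length(anns)
  rec <- function(i, field, default = NULL) {
    v <- anns[[i]][[field]]
    if (is.null(v)) default else v
  }
  out <- data.frame(x_min = numeric(n), y_min = numeric(n),
                    x_max = numeric(n), y_max = numeric(n),
                    category = integer(n), iscrowd = integer(n))
  for (i in seq_len(n)) {
    id <- rec(i, "id", i)
    bb <- rec(i, "bbox")
    if (is.null(bb) || length(bb) != 4L || !all(vapply(bb, is.numeric, TRUE)))
      stop("malformed bbox in annotation id ", id)
    bb <- as.numeric(bb)
    if (bb[3L] <= 0 || bb[4L] <= 0)
      stop("zero-area bbox rejected in annotation id ", id)
    out[i, 1:4] <- c(bb[1L], bb[2L], bb[1L] + bb[3L], bb[2L] + bb[4L])
    out$category[i] <- as.integer(rec(i, "category_id", NA_integer_))
    out$iscrowd[i] <- as.integer(rec(i, "iscrowd", 0L))
  }
  iw <- ih <- NA_real_
  if (length(doc$images)) {
    iw <- as.numeric(doc$images[[1L]]$width %||% NA_real_)
    ih <- as.numeric(doc$images[[1L]]$height %||% NA_real_)
  }
  if (n == 0L)
    out <- out[0L, , drop = FALSE]
  annotation_set(out, image_w = iw, image_h = ih, source_format = "coco")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write COCO-style box annotations
#'
#' Inverse of [read_coco()]: corner boxes are converted back to the
#' top-left + size convention and serialized at full float precision, so
#' a write/read round trip reproduces the boxes exactly.
#'
#' @param set an [annotation_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(set, path) {
  b <- as_boxes(set)
  n <- nrow(b)
  anns <- lapply(seq_len(n), function(i) {
    list(id = i, image_id = 1L,
         category_id = if (!is.null(set$category) && !is.na(set$category[i]))
           set$category[i] else 1L,
         bbox = c(b[i, "x_min"], b[i, "y_min"],
                  b[i, "x_max"] - b[i, "x_min"],
                  b[i, "y_max"] - b[i, "y_min"]),
         area = unname((b[i, "x_max"] - b[i, "x_min"]) *
                       (b[i, "y_max"] - b[i, "y_min"])),
         iscrowd = if (!is.null(set$iscrowd)) set$iscrowd[i] else 0L)
  })
  doc <- list(
    images = list(list(id = 1L,
                       width = attr(set, "image_w") %||% NA_real_,
                       height = attr(set, "image_h") %||% NA_real_)),
    annotations = anns,
    categories = list(list(id = 1L, name = "object")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read and write CSV box tables
#'
#' CSV schema: header `x_min,y_min,x_max,y_max` with optional `score`
#' and `category` columns, corner-coordinate convention. Floats are
#' written with full precision (17 significant digits), so
#' write/read/write round trips are byte-identical.
#'
#' @param path CSV path.
#' @return `read_csv_boxes()`: an [annotation_set()];
#'   `write_csv_boxes()`: `path`, invisibly.
#' @export
read_csv_boxes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV is missing required columns: ", paste(miss, collapse = ", "))
  annotation_set(df, source_format = "csv")
}

#' @rdname read_csv_boxes
#' @param set an [annotation_set()] or compatible data frame.
#' @export
write_csv_boxes <- function(set, path) {
  df <- as.data.frame(set)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
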