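#' Read and write bounding-box annotations
#'
#' Two interchange dialects are supported and round-trip bit-exactly:
#' a COCO-style JSON array `[{"image": name, "bbox": [x, y, w, h]}, ...]`
#' and a flat CSV with columns `image, x, y, w, h`. Coordinates follow the
#' package convention (upper-left corner, width, height, pixels).
#'
#' @param path File to read or write (`.json` or `.csv` decides the dialect,
#'   or pass `format`).
#' @param format `"json"`, `"csv"`, or `NULL` to infer from the extension.
#' @return `read_annotations()`: a named list of `bbox` objects keyed by
#'   image name, in file order.
#' @export
read_annotations <- function(path, format = NULL) {
  format <- annotation_format(path, format)
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    boxes <- lapply(recs, function(r) as_bbox(unlist(r$bbox)))
    names(boxes) <- vapply(recs, function(r) r$image, character(1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    boxes <- lapply(seq_len(nrow(df)),
                    function(i) bbox(df$x[i], df$y[i], df$w[i], df$h[i]))
    names(boxes) <- df$image
  }
  boxes
}

#' @rdname read_annotations
#' @param boxes Named list of `bbox` objects (names are image identifiers).
#' @export
write_annotations <- function(boxes, path, format = NULL) {
  format <- annotation_format(path, format)
  if (is.null(names(boxes)) || any(names(boxes) == ""))
    stop("boxes must be a named list keyed by image name")
  if (format == "json") {
    recs <- lapply(names(boxes), function(nm) {
      b <- as_bbox(boxes[[nm]])
      list(image = nm, bbox = as.numeric(b))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- annotations_to_df(boxes)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

annotation_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext
  else stop("cannot infer annotation format from extension: ", ext)
}

annotations_to_df <- function(boxes) {
  data.frame(image = names(boxes),
             x = vapply(boxes, function(b) as_bbox(b)[["x"]], numeric(1)),
             y = vapply(boxes, function(b) as_bbox(b)[["y"]], numeric(1)),
             w = vapply(boxes, function(b) as_bbox(b)[["w"]], numeric(1)),
             h = vapply(boxes, function(b) as_bbox(b)[["h"]], numeric(1)),
             row.names = NULL)
}

#' Read and write procedural outcome records
#'
#' Outcomes CSV dialect: `image, cannulation_time_s, additional_technique,
#' success`. A failed cannulation has no time (empty field, read as `NA`).
#'
#' @param path CSV file.
#' @return Data frame with one row per image.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image", "cannulation_time_s", "additional_technique", "success")
  if (!all(needed %in% names(df)))
    stop("outcomes CSV needs columns: ", paste(needed, collapse = ", "))
  df$additional_technique <- as.logical(df$additional_technique)
  df$success <- as.logical(df$success)
  df$cannulation_time_s <- as.numeric(df$cannulation_time_s)
  df
}

#' @rdname read_outcomes
#' @param outcomes Data frame as returned by [read_outcomes()].
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a success curve as CSV
#'
#' @param curve A `success_curve` data frame.
#' @param path Output CSV path (`threshold, rate`).
#' @export
write_success_curve <- function(curve, path) {
  utils::write.csv(curve[, c("threshold", "rate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot success curves to a PNG file
#'
#' @param curves A `success_curve` or named list of them (drawn together).
#' @param path PNG output path.
#' @param main Plot title.
#' @export
plot_success_curves <- function(curves, path, main = "Success plot") {
  if (inherits(curves, "success_curve")) curves <- list(model = curves)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  xlim <- range(unlist(lapply(curves, `[[`, "threshold")))
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1),
                 xlab = sprintf("%s threshold", curves[[1]]$metric[1]),
                 ylab = "success rate", main = main)
  cols <- seq_along(curves)
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$threshold, curves[[i]]$rate,
                    type = "o", pch = 16, col = cols[i])
  }
  graphics::legend("bottomleft", legend = names(curves), col = cols,
                   lty = 1, pch = 16, bty = "n")
  invisible(path)
}
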