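#' AFM topograph container
#'
#' A topograph is a 2D grid of heights in nm. Rows follow the slow (y)
#' scan axis, columns the fast (x) axis; pixel centers sit at
#' `(index - 0.5) * pixel_size`. The per-axis pixel size may differ after
#' drift unwarping.
#'
#' @param heights Numeric matrix of heights (nm), finite values only.
#' @param pixel_size Pixel size in nm/px; a scalar or a named vector
#'   `c(x = , y = )`.
#' @param channel One of `"trace"`, `"retrace"`, `"averaged"`, `"model"`.
#' @param provenance Character vector of free-text processing log lines.
#' @return An object of class `topograph`.
#' @export
topograph <- function(heights, pixel_size, channel = "trace",
                      provenance = character()) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("topograph heights must be finite")
  if (length(pixel_size) == 1) pixel_size <- c(x = pixel_size, y = pixel_size)
  pixel_size <- pixel_size[c("x", "y")]
  if (any(is.na(pixel_size)) || any(pixel_size <= 0))
    stop("pixel_size must be positive for both axes")
  channel <- match.arg(channel, c("trace", "retrace", "averaged", "model"))
  structure(
    list(heights = heights, pixel_size = pixel_size, channel = channel,
         provenance = as.character(provenance)),
    class = "topograph"
  )
}

#' @export
print.topograph <- function(x, ...) {
  h <- x$heights
  cat(sprintf("<topograph> %d x %d px, pixel size %.4g x %.4g nm, channel %s\n",
              nrow(h), ncol(h), x$pixel_size["x"], x$pixel_size["y"],
              x$channel))
  cat(sprintf("  height range [%.3f, %.3f] nm\n", min(h), max(h)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
plot.topograph <- function(x, ...) {
  h <- x$heights
  # transpose so the x (fast) axis runs horizontally
  graphics::image(
    x = (seq_len(ncol(h)) - 0.5) * x$pixel_size["x"],
    y = (seq_len(nrow(h)) - 0.5) * x$pixel_size["y"],
    z = t(h), asp = 1, col = grDevices::gray.colors(256),
    xlab = "x (nm)", ylab = "y (nm)", ...
  )
  invisible(x)
}

topo_heights <- function(t) {
  if (inherits(t, "topograph")) t$heights else as.matrix(t)
}

append_provenance <- function(t, line) {
  t$provenance <- c(t$provenance, line)
  t
}

#' Write / read a topograph as float TIFF plus a JSON sidecar
#'
#' Heights are rescaled into `[0, 1]` for 32-bit float TIFF storage; the
#' affine offset/scale is recorded in the sidecar (`<path>.json`) together
#' with pixel size, channel and provenance, so the round trip is lossless
#' to float precision.
#'
#' @param t A [topograph()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `write_topograph()` returns `path` invisibly; `read_topograph()`
#'   returns a [topograph()].
#' @export
write_topograph <- function(t, path) {
  stopifnot(inherits(t, "topograph"))
  h <- t$heights
  off <- min(h)
  sc <- max(h) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF((h - off) / sc, path, bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  side <- list(
    pixel_size_nm = list(x = unname(t$pixel_size["x"]),
                         y = unname(t$pixel_size["y"])),
    channel = t$channel,
    height_offset_nm = off,
    height_scale_nm = sc,
    provenance = t$provenance
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  h <- m * side$height_scale_nm + side$height_offset_nm
  topograph(h, c(x = side$pixel_size_nm$x, y = side$pixel_size_nm$y),
            channel = side$channel,
            provenance = side$provenance %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a topograph as a plain whitespace-delimited text matrix
#'
#' Intended for tiny fixtures; metadata goes to the same JSON sidecar
#' dialect as [write_topograph()].
#'
#' @inheritParams write_topograph
#' @export
write_topograph_text <- function(t, path) {
  stopifnot(inherits(t, "topograph"))
  utils::write.table(t$heights, path, row.names = FALSE, col.names = FALSE)
  side <- list(
    pixel_size_nm = list(x = unname(t$pixel_size["x"]),
                         y = unname(t$pixel_size["y"])),
    channel = t$channel, height_offset_nm = 0, height_scale_nm = 1,
    provenance = t$provenance
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topograph_text
#' @export
read_topograph_text <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- as.matrix(utils::read.table(path))
  dimnames(h) <- NULL
  topograph(h, c(x = side$pixel_size_nm$x, y = side$pixel_size_nm$y),
            channel = side$channel,
            provenance = side$provenance %||% character())
}
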