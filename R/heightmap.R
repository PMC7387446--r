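#' Height map container
#'
#' A simulated topograph: a matrix of non-negative heights in Angstrom with
#' rows indexed by the grid's x nodes and columns by its y nodes.
#'
#' @param values Numeric matrix of heights (Angstrom), all >= 0.
#' @param grid The [scan_grid()] the map was rasterized on.
#' @param provenance Free-text tag identifying tip and structure.
#' @return A `height_map` object (list with `values`, `grid`, `provenance`).
#' @export
height_map <- function(values, grid, provenance = "") {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (!inherits(grid, "scan_grid")) stop("grid must be a 'scan_grid'",
                                         call. = FALSE)
  if (nrow(values) != length(grid$x) || ncol(values) != length(grid$y))
    stop("height matrix dimensions do not match the grid", call. = FALSE)
  if (any(values < 0)) stop("heights must be >= 0", call. = FALSE)
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d nodes, step %.3g A, heights [%.3g, %.3g] A\n",
              nrow(x$values), ncol(x$values), x$grid$step,
              min(x$values), max(x$values)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
plot.height_map <- function(x, main = "simulated topograph", ...) {
  graphics::image(x$grid$x, x$grid$y, x$values, asp = 1,
                  col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE),
                  xlab = "x (Angstrom)", ylab = "y (Angstrom)",
                  main = main, ...)
  invisible(x)
}

#' Average a periodic topograph over its unit cells
#'
#' Splits the map into complete `cell_x` by `cell_y` blocks (Angstrom,
#' which must be integer multiples of the grid step) and returns their
#' mean: the unit-cell-averaged topograph.
#'
#' @param map A [height_map()].
#' @param cell_x,cell_y Unit-cell dimensions in Angstrom.
#' @return A [height_map()] covering one unit cell.
#' @export
average_topograph <- function(map, cell_x, cell_y) {
  if (!inherits(map, "height_map")) stop("expected a 'height_map'",
                                         call. = FALSE)
  step <- map$grid$step
  cnx <- cell_x / step
  cny <- cell_y / step
  if (abs(cnx - round(cnx)) > 1e-9 || abs(cny - round(cny)) > 1e-9)
    stop("cell dimensions must be integer multiples of the grid step",
         call. = FALSE)
  cnx <- as.integer(round(cnx)); cny <- as.integer(round(cny))
  nbx <- nrow(map$values) %/% cnx
  nby <- ncol(map$values) %/% cny
  if (nbx < 1L || nby < 1L)
    stop("map smaller than one unit cell", call. = FALSE)
  acc <- matrix(0, cnx, cny)
  for (bx in seq_len(nbx)) {
    for (by in seq_len(nby)) {
      acc <- acc + map$values[(bx - 1L) * cnx + seq_len(cnx),
                              (by - 1L) * cny + seq_len(cny)]
    }
  }
  g <- scan_grid(map$grid$x_min, map$grid$x_min + (cnx - 1L) * step,
                 map$grid$y_min, map$grid$y_min + (cny - 1L) * step, step)
  height_map(acc / (nbx * nby), g,
             provenance = paste0(map$provenance, " | cell-averaged"))
}

#' Write a height map to disk
#'
#' Formats:
#' \describe{
#'   \item{`ascii-matrix`}{SPM-importable ASCII matrix: `#`-prefixed header
#'     lines carrying the lateral extents and value unit (all in nm),
#'     followed by the height matrix in nm, one image row (fixed y) per
#'     line.}
#'   \item{`tsv`}{Plain tab-separated height matrix in Angstrom, full
#'     double precision, no header.}
#'   \item{`tiff`}{16-bit grayscale TIFF (requires \pkg{tiff}); heights are
#'     scaled linearly to [0, 1] and the scaling (min/max in nm) is written
#'     to a `<path>.scale.txt` sidecar.}
#' }
#'
#' @param map A [height_map()].
#' @param path Output file path.
#' @param format One of `"ascii-matrix"`, `"tsv"`, `"tiff"`.
#' @return Invisibly, `path`.
#' @export
write_heightmap <- function(map, path,
                            format = c("ascii-matrix", "tsv", "tiff")) {
  if (!inherits(map, "height_map")) stop("expected a 'height_map'",
                                         call. = FALSE)
  format <- match.arg(format)
  # image rows are fixed-y lines: transpose so lines run along x
  m <- t(map$values)
  if (format == "tsv") {
    # full double precision so round trips are bit-identical
    writeLines(apply(m, 1, function(row)
      paste(sprintf("%.17g", row), collapse = "\t")), path)
  } else if (format == "ascii-matrix") {
    g <- map$grid
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "# Channel: simulated height",
      sprintf("# Width: %.6f nm", (max(g$x) - min(g$x)) / 10),
      sprintf("# Height: %.6f nm", (max(g$y) - min(g$y)) / 10),
      "# Value units: nm",
      sprintf("# Provenance: %s", map$provenance)
    ), con)
    utils::write.table(format(m / 10, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF export", call. = FALSE)
    lo <- min(m); hi <- max(m)
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    writeLines(c(sprintf("min_nm: %.9g", lo / 10),
                 sprintf("max_nm: %.9g", hi / 10),
                 "encoding: linear 16-bit, value = min + (max-min)*gray"),
               paste0(path, ".scale.txt"))
  }
  invisible(path)
}

#' Read a height map written by [write_heightmap()]
#'
#' @param path File path.
#' @param format `"ascii-matrix"` or `"tsv"`.
#' @param grid Optional [scan_grid()]; if omitted a unit grid with the
#'   stored step (tsv: 0.5 A) is synthesized.
#' @return A [height_map()].
#' @export
read_heightmap <- function(path, format = c("ascii-matrix", "tsv"),
                           grid = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  m <- as.matrix(utils::read.table(text = lines[!hdr], sep = "\t"))
  dimnames(m) <- NULL
  if (format == "ascii-matrix") m <- m * 10  # nm -> Angstrom
  vals <- t(m)
  if (is.null(grid)) {
    grid <- scan_grid(0, (nrow(vals) - 1) * 0.5, 0, (ncol(vals) - 1) * 0.5,
                      0.5)
  }
  height_map(vals, grid, provenance = sprintf("read:%s", basename(path)))
}
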