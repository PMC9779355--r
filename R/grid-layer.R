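#' Construct a grid layer
#'
#' A `grid_layer` is the package's universal raster currency: one band of
#' square cells in a projected (metric) coordinate system, stored as a
#' numeric matrix whose first row is the northernmost row. Masked (nodata)
#' cells are `NA` in `values`.
#'
#' The centre of cell `(r, c)` (1-based, row 1 = north) lies at
#' `(x_min + (c - 0.5) * cellsize, y_max - (r - 0.5) * cellsize)`.
#'
#' @param values numeric matrix; `NA` marks nodata cells. Row 1 is north.
#' @param cellsize positive cell edge length in metres (square cells).
#' @param origin numeric length-2 `(x_min, y_max)`: the grid's top-left
#'   corner in projected coordinates.
#' @param crs_tag opaque CRS label carried through the pipeline.
#' @param kind `"continuous"` or `"categorical"`. Categorical layers must
#'   hold integer codes outside the mask.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, cellsize, origin = c(0, nrow(values) * cellsize),
                       crs_tag = "local", kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("cellsize must be a single positive number (metres)")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be (x_min, y_max)")
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layer contains non-integer codes")
  }
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag),
         kind = kind),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d x %d cells, cellsize %g m, %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$kind))
  cat(sprintf("  origin (x_min, y_max) = (%g, %g), crs '%s', %d nodata cells\n",
              x$origin[1], x$origin[2], x$crs_tag, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Nodata mask of a layer
#' @param layer a `grid_layer`.
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
grid_mask <- function(layer) is.na(layer$values)

#' Cell-centre coordinates
#'
#' @param layer a `grid_layer`.
#' @return list with vectors `x` (length ncol, west to east) and `y`
#'   (length nrow, north to south), in metres.
#' @export
cell_centers <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  list(x = layer$origin[1] + (seq_len(nc) - 0.5) * layer$cellsize,
       y = layer$origin[2] - (seq_len(nr) - 0.5) * layer$cellsize)
}

#' Do two layers share the same grid geometry?
#' @param a,b `grid_layer` objects.
#' @param tol relative tolerance on cellsize and origin.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) <= tol * max(1, a$cellsize) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

valid_cells <- function(layer) which(!is.na(layer$values))

#' Read a raster grid
#'
#' Reads an ESRI ASCII grid (`.asc`/`.txt`). The header must declare
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` and
#' `nodata_value`; a missing nodata declaration is an error (silent fill
#' values are never invented). GeoTIFF is not supported in this build:
#' plain-text grids are the interchange format.
#'
#' @param path file path.
#' @param kind `"continuous"` or `"categorical"`.
#' @param crs_tag CRS label to attach.
#' @return a `grid_layer`.
#' @export
read_grid <- function(path, kind = c("continuous", "categorical"),
                      crs_tag = "local") {
  kind <- match.arg(kind)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop(sprintf("cannot read grid '%s': GeoTIFF is not supported; use ESRI ASCII (.asc)", path))
  if (!file.exists(path)) stop(sprintf("cannot read grid '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("grid '%s': missing header field(s) %s", path,
                 paste(miss, collapse = ", ")))
  if (!("nodata_value" %in% names(hdr)))
    stop(sprintf("grid '%s': missing nodata_value declaration", path))
  if (any(c("xllcenter", "yllcenter") %in% names(hdr)))
    stop(sprintf("grid '%s': xllcenter/yllcenter headers are not supported; use corner registration", path))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("grid '%s': expected %d values, found %d", path, nr * nc,
                 length(body)))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_layer(m, cellsize = hdr$cellsize,
             origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
             crs_tag = crs_tag, kind = kind)
}

#' Write a raster grid as ESRI ASCII
#'
#' Values are written with 6 significant digits; nodata cells as `-9999`
#' (or the next more negative power of ten if `-9999` collides with data).
#'
#' @param layer a `grid_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(layer, path) {
  v <- layer$values
  nodata <- -9999
  while (any(!is.na(v) & v == nodata)) nodata <- nodata * 10
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", layer$origin[1]),
           sprintf("yllcorner %.10g", layer$origin[2] - nr * layer$cellsize),
           sprintf("cellsize %.10g", layer$cellsize),
           sprintf("nodata_value %d", as.integer(nodata)))
  vv <- signif(v, 6)
  vv[is.na(vv)] <- nodata
  rows <- apply(vv, 1L, function(r) paste(format(r, trim = TRUE,
                                                 scientific = FALSE,
                                                 digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
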