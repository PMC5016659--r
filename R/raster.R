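#' Gridded covariate layer
#'
#' A minimal single-band raster in a projected coordinate system. Values are
#' stored as a matrix with row 1 at the *bottom* of the extent, so cell
#' \code{(r, c)} covers the half-open square
#' \eqn{[x_0 + (c-1)w, x_0 + cw) \times [y_0 + (r-1)w, y_0 + rw)} where
#' \eqn{w} is the cell size. The half-open convention means every point
#' inside the extent belongs to exactly one cell.
#'
#' @slot name covariate name (e.g. "ELEV").
#' @slot values numeric matrix of cell values; \code{NA} marks no-data.
#' @slot origin numeric(2), (x, y) of the lower-left corner in meters.
#' @slot cellSize cell edge length in meters.
#' @export
setClass("CovariateRaster",
  representation(name = "character", values = "matrix",
                 origin = "numeric", cellSize = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
    if (length(object@origin) != 2L) msgs <- c(msgs, "origin must be (x, y)")
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      msgs <- c(msgs, "cellSize must be a single positive number")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a CovariateRaster
#'
#' @param name layer name.
#' @param values numeric matrix, row 1 at the bottom edge.
#' @param origin numeric(2) lower-left corner (meters).
#' @param cellSize cell edge length (meters).
#' @return a \linkS4class{CovariateRaster}.
#' @export
covariateRaster <- function(name, values, origin = c(0, 0), cellSize = 1000) {
  new("CovariateRaster", name = name, values = values,
      origin = as.numeric(origin), cellSize = as.numeric(cellSize))
}

#' @describeIn covariateRaster layer name accessor.
#' @param x a \code{CovariateRaster}.
#' @export
rasterName <- function(x) x@name

#' @describeIn covariateRaster value matrix accessor (row 1 = bottom).
#' @export
rasterValues <- function(x) x@values

#' @describeIn covariateRaster extent as c(xmin, xmax, ymin, ymax).
#' @export
rasterExtent <- function(x) {
  c(x@origin[1], x@origin[1] + ncol(x@values) * x@cellSize,
    x@origin[2], x@origin[2] + nrow(x@values) * x@cellSize)
}

setMethod("show", "CovariateRaster", function(object) {
  e <- rasterExtent(object)
  cat(sprintf("CovariateRaster \"%s\": %d x %d cells of %g m, extent [%g, %g] x [%g, %g]\n",
              object@name, nrow(object@values), ncol(object@values),
              object@cellSize, e[1], e[2], e[3], e[4]))
})

#' Regular analysis grid
#'
#' Defines the spatial grid used to segment roads and index raster cells.
#' Cells are half-open \eqn{[x, x+w) \times [y, y+w)}; cell ids run row-major
#' from the lower-left cell (id 1).
#'
#' @slot origin numeric(2), lower-left corner (meters).
#' @slot cellSize cell edge (meters).
#' @slot nCols,nRows grid dimensions.
#' @export
setClass("GridSpec",
  representation(origin = "numeric", cellSize = "numeric",
                 nCols = "integer", nRows = "integer"),
  validity = function(object) {
    if (object@cellSize <= 0) return("cellSize must be positive")
    if (object@nCols < 1L || object@nRows < 1L) return("grid must have cells")
    TRUE
  })

#' @rdname GridSpec-class
#' @param origin numeric(2) lower-left corner.
#' @param cellSize cell edge length in meters (1000 for a 1 km^2 grid).
#' @param nCols,nRows number of columns and rows.
#' @export
gridSpec <- function(origin, cellSize, nCols, nRows) {
  new("GridSpec", origin = as.numeric(origin), cellSize = as.numeric(cellSize),
      nCols = as.integer(nCols), nRows = as.integer(nRows))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m from (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@origin[1], object@origin[2]))
})

#' @rdname GridSpec-class
#' @param grid a \code{GridSpec}.
#' @export
gridExtent <- function(grid) {
  c(grid@origin[1], grid@origin[1] + grid@nCols * grid@cellSize,
    grid@origin[2], grid@origin[2] + grid@nRows * grid@cellSize)
}

# Row/column indices of the cells containing points (half-open cells).
# Returns a list(col, row); points outside the grid get NA.
gridIndex <- function(origin, cellSize, nCols, nRows, x, y) {
  col <- floor((x - origin[1]) / cellSize) + 1
  row <- floor((y - origin[2]) / cellSize) + 1
  out <- col < 1 | col > nCols | row < 1 | row > nRows
  col[out] <- NA_real_
  row[out] <- NA_real_
  list(col = as.integer(col), row = as.integer(row))
}

#' Row-major cell id of the cells containing points
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y point coordinates in meters.
#' @return integer cell ids (1 = lower-left cell); \code{NA} outside the grid.
#' @export
cellIdAt <- function(grid, x, y) {
  idx <- gridIndex(grid@origin, grid@cellSize, grid@nCols, grid@nRows, x, y)
  as.integer((idx$row - 1L) * grid@nCols + idx$col)
}

#' Sample a raster at points (nearest cell, no interpolation)
#'
#' Returns the stored value of the cell containing each point. Cells are
#' half-open so points on interior cell boundaries belong to exactly one
#' cell. No-data cells yield \code{NA}.
#'
#' @param raster a \linkS4class{CovariateRaster}.
#' @param x,y point coordinates (meters); recycled to a common length.
#' @return numeric vector of cell values.
#' @export
sampleRasterAtPoints <- function(raster, x, y) {
  v <- raster@values
  idx <- gridIndex(raster@origin, raster@cellSize, ncol(v), nrow(v), x, y)
  if (anyNA(idx$col)) {
    bad <- which(is.na(idx$col))
    stop(sprintf("point(s) outside raster extent: index %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  v[cbind(idx$row, idx$col)]
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format; the file stores rows top-down, which is
#' converted to/from the package's bottom-up matrix orientation.
#'
#' @param raster a \linkS4class{CovariateRaster}.
#' @param path file path (conventionally \code{.asc}).
#' @return \code{writeAsciiGrid} returns \code{path} invisibly;
#'   \code{readAsciiGrid} returns a \linkS4class{CovariateRaster}.
#' @export
writeAsciiGrid <- function(raster, path) {
  v <- raster@values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster@origin[1]),
           sprintf("yllcorner %.10g", raster@origin[2]),
           sprintf("cellsize %.10g", raster@cellSize),
           "NODATA_value -9999")
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L, function(r) {
    r[is.na(r)] <- -9999
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @param name layer name to assign on read.
#' @export
readAsciiGrid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  covariateRaster(name, m[rev(seq_len(nr)), , drop = FALSE],
                  origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                  cellSize = vals[["cellsize"]])
}
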