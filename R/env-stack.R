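#' Construct an environmental stack
#'
#' A named, grid-aligned collection of [grid_layer()]s used as model
#' predictors. All layers must share shape, cellsize, origin and CRS tag.
#' At most the `"LUCC"` layer (if present) plus any layer flagged
#' categorical is treated as categorical; model operations use the joint
#' valid mask (intersection of per-layer valid cells).
#'
#' @param layers named list of `grid_layer` objects. Conventional names:
#'   `"Bio1"`..`"Bio19"`, `"DEM"`, `"SLO"`, `"ASP"`, `"NPP"`, `"NDVI"`,
#'   `"LUCC"`, `"DW"`, `"DH"`, `"DR"`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a non-empty named list")
  if (anyDuplicated(names(layers)))
    stop("duplicate layer names")
  for (nm in names(layers))
    if (!inherits(layers[[nm]], "grid_layer"))
      stop(sprintf("layer '%s' is not a grid_layer", nm))
  ref <- layers[[1]]
  for (nm in names(layers))
    if (!same_geometry(layers[[nm]], ref))
      stop(sprintf("layer '%s' is not aligned with '%s'", nm, names(layers)[1]))
  if ("LUCC" %in% names(layers) && layers[["LUCC"]]$kind != "categorical")
    stop("the LUCC layer must be categorical")
  structure(list(layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<env_stack> %d layers, %d x %d cells, cellsize %g m\n",
              length(x$layers), nrow(ref$values), ncol(ref$values),
              ref$cellsize))
  kinds <- vapply(x$layers, function(l) l$kind, "")
  cat("  ", paste(sprintf("%s(%s)", names(x$layers), substr(kinds, 1, 3)),
                  collapse = " "), "\n")
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Joint valid mask of a stack
#' @param stack an `env_stack`.
#' @return logical matrix, `TRUE` where every layer is valid.
#' @export
joint_valid_mask <- function(stack) {
  ok <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) ok <- ok & !is.na(l$values)
  ok
}

stack_ref <- function(stack) stack$layers[[1]]

#' Extract a sub-stack by layer name
#' @param stack an `env_stack`.
#' @param vars character vector of layer names to keep.
#' @return an `env_stack`.
#' @export
stack_subset <- function(stack, vars) {
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop(sprintf("stack has no layer(s): %s", paste(miss, collapse = ", ")))
  env_stack(stack$layers[vars])
}

# layer values at the joint-valid cells, as an n x p matrix (raw scale)
stack_matrix <- function(stack, cells = NULL) {
  if (is.null(cells)) cells <- which(joint_valid_mask(stack))
  m <- vapply(stack$layers, function(l) l$values[cells],
              numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, names(stack$layers)))
  m
}

# map projected points to (row, col); NA outside the grid
points_to_cells <- function(layer, x, y) {
  cs <- layer$cellsize
  col <- floor((x - layer$origin[1]) / cs) + 1L
  row <- floor((layer$origin[2] - y) / cs) + 1L
  bad <- col < 1L | col > ncol(layer$values) | row < 1L | row > nrow(layer$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}
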