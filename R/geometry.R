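#' Frustum (truncated cone) microneedle
#'
#' Hydrogel-type microneedles are approximately conical frustums: a top
#' circle of radius `r_top` (the blunt tip), a bottom circle of radius
#' `r_base` attached to the patch backing, slant height `slant` and axial
#' length `length`. All dimensions share one length unit (micrometres by
#' convention inside the simulator, millimetres for reported areas).
#'
#' When all four dimensions are supplied, `slant^2 = (r_base - r_top)^2 +
#' length^2` must hold to within 1e-6 relative; `slant` may be omitted and
#' is then derived from the other three.
#'
#' @param r_top Radius of the top circle (tip side), >= 0.
#' @param r_base Radius of the bottom circle (patch side), >= 0.
#' @param length Axial needle length, >= 0; derived from `slant` if omitted.
#' @param slant Slant height; derived from the other dimensions if omitted.
#' @return An object of class `frustum_needle`.
#' @examples
#' frustum_needle(r_top = 100, r_base = 150, length = 700)
#' @export
frustum_needle <- function(r_top, r_base, length = NULL, slant = NULL) {
  check_nonneg(r_top = r_top, r_base = r_base)
  if (is.null(length) && is.null(slant)) {
    stop("supply at least one of `length` and `slant`", call. = FALSE)
  }
  if (is.null(length)) {
    check_nonneg(slant = slant)
    if (slant < abs(r_base - r_top)) {
      stop("slant height shorter than the radius difference", call. = FALSE)
    }
    length <- sqrt(slant^2 - (r_base - r_top)^2)
  }
  check_nonneg(length = length)
  derived <- sqrt((r_base - r_top)^2 + length^2)
  if (is.null(slant)) {
    slant <- derived
  } else {
    check_nonneg(slant = slant)
    if (slant < length) {
      stop("slant height must be at least the axial length", call. = FALSE)
    }
    if (derived > 0 && abs(slant - derived) > 1e-6 * derived) {
      stop("inconsistent frustum: slant^2 != (r_base - r_top)^2 + length^2",
           call. = FALSE)
    }
  }
  structure(
    list(r_top = r_top, r_base = r_base, slant = slant, length = length),
    class = c("frustum_needle", "mn_needle")
  )
}

#' Regular square-pyramid microneedle
#'
#' Plastic (solid) microneedles are regular square pyramids with bottom
#' square edge `base_edge` and apex-to-base height `height`.
#'
#' @param base_edge Length of the bottom square edge, >= 0.
#' @param height Apex-to-base height, >= 0.
#' @return An object of class `pyramid_needle`.
#' @examples
#' pyramid_needle(base_edge = 0.075, height = 0.7)  # mm
#' @export
pyramid_needle <- function(base_edge, height) {
  check_nonneg(base_edge = base_edge, height = height)
  structure(
    list(base_edge = base_edge, height = height),
    class = c("pyramid_needle", "mn_needle")
  )
}

#' Microneedle patch layout
#'
#' A patch is `n_needles` identical needles plus a type label:
#' `"hydrogel"` needles carry the drug inside the polymer and stay in the
#' skin; `"plastic"` needles only pre-treat the skin, the drug being applied
#' afterwards as a solution.
#'
#' @param needle A [frustum_needle()] or [pyramid_needle()].
#' @param n_needles Number of needles on the patch, non-negative integer.
#' @param needle_type_label `"hydrogel"` or `"plastic"`.
#' @return An object of class `patch_layout`.
#' @export
patch_layout <- function(needle, n_needles,
                         needle_type_label = c("hydrogel", "plastic")) {
  if (!inherits(needle, "mn_needle")) {
    stop("`needle` must be a frustum_needle or pyramid_needle", call. = FALSE)
  }
  needle_type_label <- match.arg(needle_type_label)
  if (length(n_needles) != 1L || is.na(n_needles) || n_needles < 0 ||
      n_needles != round(n_needles)) {
    stop("`n_needles` must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(needle = needle, n_needles = as.integer(n_needles),
         needle_type_label = needle_type_label),
    class = "patch_layout"
  )
}

#' @export
print.frustum_needle <- function(x, ...) {
  cat(sprintf("frustum needle: r_top=%g, r_base=%g, slant=%g, length=%g\n",
              x$r_top, x$r_base, x$slant, x$length))
  invisible(x)
}

#' @export
print.pyramid_needle <- function(x, ...) {
  cat(sprintf("square-pyramid needle: base_edge=%g, height=%g\n",
              x$base_edge, x$height))
  invisible(x)
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("%s patch: %d needles\n", x$needle_type_label, x$n_needles))
  print(x$needle)
  invisible(x)
}

#' Surface area of a single frustum microneedle
#'
#' Area of the top (tip) circle plus the lateral frustum wall,
#' `pi*r^2 + pi*l*(R + r)`. The base circle is excluded: it is attached to
#' the patch backing and never contacts skin.
#'
#' @param needle A [frustum_needle()]. Units are the needle's length unit
#'   squared (mm^2 when dimensions are in mm).
#' @return Single numeric area.
#' @examples
#' frustum_surface_area(frustum_needle(0.1, 0.2, length = NULL, slant = 0.5))
#' @export
frustum_surface_area <- function(needle) {
  stopifnot(inherits(needle, "frustum_needle"))
  pi * needle$r_top^2 + pi * needle$slant * (needle$r_base + needle$r_top)
}

#' Surface area of a single square-pyramid microneedle
#'
#' Sum of the four triangular lateral faces,
#' `4 * (a/2) * sqrt((a/2)^2 + h^2)`; the base square is excluded.
#' With `a = 0.075` mm and `h = 0.7` mm this gives 0.105 mm^2 (3 d.p.).
#'
#' @param needle A [pyramid_needle()].
#' @return Single numeric area.
#' @export
pyramid_surface_area <- function(needle) {
  stopifnot(inherits(needle, "pyramid_needle"))
  a2 <- needle$base_edge / 2
  4 * a2 * sqrt(a2^2 + needle$height^2)
}

#' Total needle surface area of a patch
#'
#' `S_total = S * n`: the single-needle area times the needle count.
#'
#' @param layout A [patch_layout()].
#' @return Single numeric area in the needle's unit squared.
#' @examples
#' p <- patch_layout(pyramid_needle(0.075, 0.7), 351, "plastic")
#' patch_surface_area(p)  # 36.855 mm^2
#' @export
patch_surface_area <- function(layout) {
  stopifnot(inherits(layout, "patch_layout"))
  needle_surface_area(layout$needle) * layout$n_needles
}

#' Surface area of a single needle (dispatching on shape)
#' @param needle A [frustum_needle()] or [pyramid_needle()].
#' @return Single numeric area.
#' @export
needle_surface_area <- function(needle) {
  if (inherits(needle, "frustum_needle")) {
    frustum_surface_area(needle)
  } else if (inherits(needle, "pyramid_needle")) {
    pyramid_surface_area(needle)
  } else {
    stop("unknown needle shape", call. = FALSE)
  }
}

# half-width of the needle cross-section at depth y below the skin surface;
# widest at the surface (base for a pyramid, r_base for a frustum), narrowing
# towards the tip at depth = needle length. NA outside [0, length].
needle_half_width <- function(needle, y) {
  if (inherits(needle, "pyramid_needle")) {
    len <- needle$height
    w0 <- needle$base_edge / 2
    w1 <- 0
  } else {
    len <- needle$length
    w0 <- needle$r_base
    w1 <- needle$r_top
  }
  if (len == 0) return(ifelse(y == 0, w0, NA_real_))
  ifelse(y >= 0 & y <= len, w0 + (w1 - w0) * y / len, NA_real_)
}

needle_length <- function(needle) {
  if (inherits(needle, "pyramid_needle")) needle$height else needle$length
}

#' Rasterize the half needle cross-section onto the simulation grid
#'
#' The diffusion solver works on the half unit cell (the needle's symmetry
#' axis is the left column edge). This marks the grid cells lying inside the
#' needle's half cross-section. A cell in row i, column j (row 1 at the skin
#' surface) spans depths `[(i-1)*dy, i*dy]` and x in `[(j-1)*dx, j*dx]` from
#' the axis; it is marked when its x-center lies within the needle half-width
#' at the cell's top-edge depth, i.e. the widest profile point over the
#' cell's depth span. Row widths are therefore monotone non-increasing with
#' depth and the mask area converges to the analytic half cross-section as
#' the grid is refined.
#'
#' @param needle A needle object; dimensions in micrometres.
#' @param dx,dy Grid spacing in micrometres, > 0.
#' @param skin_thickness Domain depth in micrometres; the needle must not
#'   exceed it.
#' @param ncols Number of grid columns (defaults to just covering the
#'   needle's maximum half-width).
#' @return Logical matrix with `skin_thickness/dy` rows; `TRUE` marks cells
#'   inside the needle.
#' @export
rasterize_half_needle <- function(needle, dx, dy, skin_thickness,
                                  ncols = NULL) {
  stopifnot(inherits(needle, "mn_needle"), dx > 0, dy > 0, skin_thickness > 0)
  len <- needle_length(needle)
  if (len > skin_thickness) {
    stop("needle length exceeds the skin domain depth", call. = FALSE)
  }
  nrows <- max(1L, as.integer(round(skin_thickness / dy)))
  w0 <- needle_half_width(needle, 0)
  if (is.null(ncols)) {
    ncols <- max(1L, as.integer(ceiling(ifelse(is.na(w0), 0, w0) / dx)))
  }
  mask <- matrix(FALSE, nrows, ncols)
  if (len == 0 || is.na(w0) || w0 == 0) return(mask)
  n_need_rows <- min(nrows, as.integer(ceiling(len / dy)))
  for (i in seq_len(n_need_rows)) {
    y_top <- (i - 1) * dy
    hw <- needle_half_width(needle, min(y_top, len))
    if (is.na(hw) || hw <= 0) break
    xc <- (seq_len(ncols) - 0.5) * dx
    mask[i, xc <= hw] <- TRUE
  }
  mask
}

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || is.na(v) || !is.numeric(v)) {
      stop(sprintf("`%s` must be a single number", nm), call. = FALSE)
    }
    if (v < 0) {
      stop(sprintf("`%s` must be non-negative (got %g)", nm, v),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
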