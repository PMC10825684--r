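#' Voxel masks and dose grids
#'
#' `voxel_mask()` wraps a 3-D binary array with its physical geometry;
#' `dose_grid()` does the same for a scalar dose array in Gy.  Metrics
#' require identical geometry (dimensions, spacing, origin) between their
#' inputs and raise an error on mismatch rather than resampling.
#'
#' @param grid 3-D array; logical/0-1 for a mask, non-negative finite
#'   numeric for a dose grid.
#' @param spacing positive length-3 physical voxel size in mm.
#' @param origin physical coordinate (mm) of the first voxel center.
#' @return An object of class `voxel_mask` or `dose_grid`.
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("'grid' must be a 3-D array")
  if (!all(grid %in% c(0, 1, TRUE, FALSE)) || any(is.na(grid)))
    stop("mask grid must be binary")
  check_geometry_args(spacing, origin)
  structure(list(grid = array(as.logical(grid), dim(grid)),
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @rdname voxel_mask
#' @export
dose_grid <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("'grid' must be a 3-D array")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("dose grid must be non-negative and finite")
  check_geometry_args(spacing, origin)
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

check_geometry_args <- function(spacing, origin) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  invisible(TRUE)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("Voxel mask %s, spacing (%s) mm, %d foreground voxel(s)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(x$spacing, collapse = ", "), sum(x$grid)))
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid %s, spacing (%s) mm, range [%.3g, %.3g] Gy\n",
              paste(dim(x$grid), collapse = "x"),
              paste(x$spacing, collapse = ", "),
              min(x$grid), max(x$grid)))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grid geometry mismatch (dimensions, spacing or origin); ",
         "resampling is not performed")
  invisible(TRUE)
}

#' Dice overlap coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)` over foreground voxel counts.
#'
#' @param a,b [voxel_mask()] objects on identical geometry, not both empty.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  check_same_geometry(a, b)
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0L) stop("both masks are empty; Dice is undefined")
  2 * sum(a$grid & b$grid) / (na + nb)
}

# Boundary faces of a mask: centers (physical mm) and areas (mm^2) of the
# voxel faces separating foreground from background (grid edges count as
# background).  x runs fastest, matching R's column-major array layout.
boundary_faces <- function(mask) {
  g <- mask$grid; dm <- dim(g); sp <- mask$spacing
  centers <- matrix(numeric(0), 0L, 3L)
  areas <- numeric(0)
  shift_bg <- function(axis, dir) {
    # background neighbour of each voxel, one step along axis*dir
    out <- array(FALSE, dm)
    n <- dm[axis]
    idx_to <- lapply(dm, seq_len); idx_from <- idx_to
    if (dir > 0) { idx_to[[axis]] <- 1:(n - 1); idx_from[[axis]] <- 2:n }
    else         { idx_to[[axis]] <- 2:n;       idx_from[[axis]] <- 1:(n - 1) }
    if (n > 1) {
      bg <- !g
      out <- do.call(`[<-`, c(list(out), idx_to,
                              list(do.call(`[`, c(list(bg), idx_from)))))
    }
    # faces on the grid boundary
    idx_edge <- lapply(dm, seq_len)
    idx_edge[[axis]] <- if (dir > 0) n else 1L
    out <- do.call(`[<-`, c(list(out), idx_edge, list(TRUE)))
    out
  }
  for (axis in 1:3) {
    for (dir in c(-1, 1)) {
      face_here <- g & shift_bg(axis, dir)
      if (!any(face_here)) next
      w <- which(face_here, arr.ind = TRUE)
      ctr <- sweep(sweep(w - 1, 2, sp, `*`), 2, mask$origin, `+`)
      ctr[, axis] <- ctr[, axis] + dir * sp[axis] / 2
      centers <- rbind(centers, ctr)
      areas <- c(areas, rep(prod(sp[-axis]), nrow(ctr)))
    }
  }
  list(centers = centers, areas = areas)
}

# min Euclidean distance from each row of p to the point set q, chunked so
# the cross-distance matrix stays small
min_dist_to_set <- function(p, q, chunk_cells = 2e7) {
  np <- nrow(p); nq <- nrow(q)
  out <- numeric(np)
  q2 <- rowSums(q^2)
  step <- max(1L, floor(chunk_cells / nq))
  i <- 1L
  while (i <= np) {
    j <- min(np, i + step - 1L)
    pc <- p[i:j, , drop = FALSE]
    d2 <- outer(rowSums(pc^2), q2, `+`) - 2 * tcrossprod(pc, q)
    out[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

#' Surface Dice at a distance tolerance
#'
#' Fraction of the two masks' boundary surfaces lying within a physical
#' distance tolerance of the other surface:
#' `(|S_A within tau of S_B| + |S_B within tau of S_A|) / (|S_A| + |S_B|)`.
#' Surfaces are represented by the voxel faces separating foreground from
#' background; distances between face centers are Euclidean in physical mm,
#' respecting anisotropic spacing, and surface amounts are face areas (in
#' the isotropic case this reduces to face counts).
#'
#' @param a,b non-empty [voxel_mask()] objects on identical geometry.
#' @param tolerance_mm non-negative tolerance in mm (3 mm is a common
#'   choice for heart contours).
#' @return Fraction in `[0, 1]`; 1 when the masks are identical, and
#'   non-decreasing in the tolerance.
#' @export
surface_dice <- function(a, b, tolerance_mm = 3) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"),
            is.numeric(tolerance_mm), tolerance_mm >= 0)
  check_same_geometry(a, b)
  if (!any(a$grid) || !any(b$grid))
    stop("surface Dice needs non-empty masks")
  fa <- boundary_faces(a)
  fb <- boundary_faces(b)
  tol <- tolerance_mm + 1e-9  # guard exact-coincidence against fp rounding
  da <- min_dist_to_set(fa$centers, fb$centers)
  db <- min_dist_to_set(fb$centers, fa$centers)
  (sum(fa$areas[da <= tol]) + sum(fb$areas[db <= tol])) /
    (sum(fa$areas) + sum(fb$areas))
}

#' Mean dose over a mask
#'
#' Volume-weighted mean of the dose over the foreground voxels; with a
#' uniform voxel volume this is the arithmetic mean (e.g. the mean heart
#' dose when the mask is a heart contour).
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [voxel_mask()] on the same geometry.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "voxel_mask"))
  check_same_geometry(dose, mask)
  if (!any(mask$grid)) stop("mask is empty; mean dose is undefined")
  mean(dose$grid[mask$grid])
}

#' VxGy: percent of masked volume receiving at least x Gy
#'
#' `100 * |{foreground voxels with dose >= x}| / |foreground voxels|`; the
#' threshold is inclusive ("at least x Gy").
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [voxel_mask()] on the same geometry.
#' @param x dose threshold(s) in Gy, `>= 0`; vectorized.
#' @return Percentage(s) in `[0, 100]`, non-increasing in `x`.
#' @examples
#' # V5Gy, V10Gy, V30Gy of a phantom under a dose gradient
#' ph <- generate_phantom_pair(dim = c(20, 20, 20), radius = 8,
#'                             dose_field = "linear",
#'                             dose_params = list(gradient = 2))
#' vxgy(ph$dose, ph$mask_a, c(5, 10, 30))
#' @export
vxgy <- function(dose, mask, x) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "voxel_mask"),
            is.numeric(x), all(x >= 0))
  check_same_geometry(dose, mask)
  if (!any(mask$grid)) stop("mask is empty; VxGy is undefined")
  d <- dose$grid[mask$grid]
  vapply(x, function(xi) 100 * mean(d >= xi), numeric(1))
}

#' Cohort-level metric summary
#'
#' Mean and standard deviation of per-patient metric values, the usual
#' reporting form for contour-agreement tables.
#'
#' @param ... named numeric vectors of per-patient metric values.
#' @return Data frame with columns `metric`, `n`, `mean`, `sd`.
#' @examples
#' summarize_metrics(dice = c(0.91, 0.88, 0.86),
#'                   surface_dice_3mm = c(0.71, 0.66, 0.62))
#' @export
summarize_metrics <- function(...) {
  vals <- list(...)
  stopifnot(length(vals) > 0, !is.null(names(vals)), all(nzchar(names(vals))))
  data.frame(metric = names(vals),
             n = vapply(vals, length, integer(1)),
             mean = vapply(vals, mean, numeric(1)),
             sd = vapply(vals, sd, numeric(1)),
             row.names = NULL)
}
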