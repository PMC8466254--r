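#' Rigid transform in 3-D
#'
#' A rigid (proper orthogonal) transform `x -> R x + t` mapping cast-space
#' coordinates into CBCT space. Rotations must be proper: `t(R) %*% R = I` and
#' `det(R) = +1`, both within `tol`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation in mm.
#' @param tol Tolerance for the orthogonality and determinant checks.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' rigid_transform()  # identity
#' rigid_transform(rotation_axis_angle(c(0, 0, 1), 10), c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    abort_geometry("`rotation` must be a finite 3x3 matrix.")
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    abort_geometry("`translation` must be a finite length-3 vector.")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    abort_geometry("`rotation` is not orthogonal within tolerance.")
  }
  if (abs(det(rotation) - 1) > tol) {
    abort_geometry("`rotation` must be proper (det = +1): reflections are not rigid.")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula for the rotation by `angle_deg` degrees about `axis`
#' (right-hand rule).
#'
#' @param axis Numeric length-3 axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) {
    abort_geometry("`axis` must be a nonzero finite vector.")
  }
  k <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points An n x 3 numeric matrix, a length-3 vector, or a data frame
#'   with columns `x`, `y`, `z`.
#' @return The transformed points, in the same form as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
    out <- m %*% t(transform$rotation) +
      matrix(transform$translation, nrow(m), 3, byrow = TRUE)
    points$x <- out[, 1]; points$y <- out[, 2]; points$z <- out[, 3]
    return(points)
  }
  if (is.null(dim(points))) {
    return(drop(transform$rotation %*% points) + transform$translation)
  }
  points %*% t(transform$rotation) +
    matrix(transform$translation, nrow(points), 3, byrow = TRUE)
}

#' Apply a rigid transform to implant records
#'
#' Maps both the platform (`px`, `py`, `pz`) and apex (`ax`, `ay`, `az`)
#' centers of each implant; all other columns pass through untouched.
#'
#' @param transform A [rigid_transform()].
#' @param implants Implant data frame (see [read_implants()] for the schema).
#' @return A tibble with transformed coordinates.
#' @export
transform_implants <- function(transform, implants) {
  p <- transform_points(transform, as.matrix(implants[, c("px", "py", "pz")]))
  a <- transform_points(transform, as.matrix(implants[, c("ax", "ay", "az")]))
  out <- tibble::as_tibble(implants)
  out$px <- p[, 1]; out$py <- p[, 2]; out$pz <- p[, 3]
  out$ax <- a[, 1]; out$ay <- a[, 2]; out$az <- a[, 3]
  out
}

#' Compose and invert rigid transforms
#'
#' `transform_compose(a, b)` returns the transform applying `b` first and
#' then `a`; `transform_inverse(a)` returns the transform undoing `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' @rdname transform_compose
#' @export
transform_inverse <- function(a) {
  rigid_transform(t(a$rotation), drop(-t(a$rotation) %*% a$translation))
}

#' Read and write rigid transforms as JSON
#'
#' The on-disk format stores the rotation row-major plus the translation, both
#' at full double precision.
#'
#' @param transform A [rigid_transform()].
#' @param path File path.
#' @return `write_transform_json()` returns `path` invisibly;
#'   `read_transform_json()` returns a `rigid_transform`.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  obj <- list(rotation_row_major = as.numeric(t(transform$rotation)),
              translation_mm = as.numeric(transform$translation))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rotation_row_major) || is.null(obj$translation_mm)) {
    abort_parse(paste0("'", path, "' is not a rigid-transform JSON file."))
  }
  rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  obj$translation_mm)
}

# Internal: random proper rotation with angle uniform in [0, max_angle_deg]
# about a uniformly random axis. Uses the ambient RNG stream.
random_small_rotation <- function(max_angle_deg) {
  ax <- rnorm(3)
  rotation_axis_angle(ax, runif(1, 0, max_angle_deg))
}
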