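#' Rigid (6 degrees-of-freedom) spatial transform
#'
#' Represents a rotation about a centre point followed by a translation:
#' `p' = R (p - c) + c + t`, with all lengths in mm and rotation angles in
#' degrees. Angles follow the extrinsic x-y-z convention
#' (`R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`).
#'
#' @param rotation either a length-3 vector of angles in degrees
#'   `(rx, ry, rz)` or a 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @param center length-3 rotation centre in mm.
#' @return an object of class `rigid_transform` with elements `R` (3x3
#'   matrix), `translation` and `center`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  abort_if(length(translation) != 3L || length(center) != 3L,
           "`translation` and `center` must be length-3")
  if (is.matrix(rotation)) {
    R <- rotation
    abort_if(!all(dim(R) == c(3L, 3L)), "rotation matrix must be 3x3")
    abort_if(max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9,
             "rotation matrix must be orthonormal with determinant +1")
  } else {
    ang <- as.numeric(rotation) * pi / 180
    abort_if(length(ang) != 3L, "`rotation` must be 3 angles or a 3x3 matrix")
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
  }
  structure(list(R = R, translation = translation, center = center),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function(center = c(0, 0, 0)) {
  rigid_transform(diag(3), c(0, 0, 0), center)
}

#' Euler angles (degrees) of a rigid transform
#'
#' Inverts the extrinsic x-y-z factorization; `ry` is returned in
#' `[-90, 90]` (gimbal-lock ambiguity resolved toward `rx` and `rz`).
#' @param t a [rigid_transform()].
#' @return length-3 numeric `(rx, ry, rz)` in degrees.
#' @export
transform_angles <- function(t) {
  R <- t$R
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (deg): %s | trans (mm): %s | centre (mm): %s\n",
    paste(sprintf("%.3f", transform_angles(x)), collapse = ", "),
    paste(sprintf("%.3f", x$translation), collapse = ", "),
    paste(sprintf("%.3f", x$center), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param t a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of world points in mm.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts, 2, t$center) %*% t(t$R) +
    matrix(t$center + t$translation, nrow(pts), 3, byrow = TRUE)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @inheritParams apply_transform
#' @export
transform_matrix <- function(t) {
  H <- diag(4)
  H[1:3, 1:3] <- t$R
  H[1:3, 4] <- t$center + t$translation - t$R %*% t$center
  H
}

#' Compose two rigid transforms
#'
#' `compose(first, second)` returns the transform whose action is
#' "apply `first`, then `second`" — so two registration steps can be
#' combined and applied as a single resampling.
#' @param first,second [rigid_transform()] objects.
#' @export
compose <- function(first, second) {
  H <- transform_matrix(second) %*% transform_matrix(first)
  R <- H[1:3, 1:3]
  c0 <- second$center
  rigid_transform(R, translation = H[1:3, 4] - c0 + R %*% c0, center = c0)
}

#' Exact closed-form inverse of a rigid transform
#' @inheritParams apply_transform
#' @export
invert <- function(t) {
  Rt <- t(t$R)
  H <- transform_matrix(t)
  b <- -Rt %*% H[1:3, 4]
  rigid_transform(Rt, translation = b - t$center + Rt %*% t$center,
                  center = t$center)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The JSON stores angles in degrees plus translation and centre in mm.
#' @param t a [rigid_transform()].
#' @param path file path.
#' @export
transform_to_json <- function(t, path) {
  jsonlite::write_json(
    list(rotation_deg = transform_angles(t),
         translation_mm = t$translation,
         center_mm = t$center),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$rotation_deg, j$translation_mm, j$center_mm)
}
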