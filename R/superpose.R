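# Kabsch superposition and RMSD.

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (weighted) RMSD between `R %*% mobile + t` and `reference`.
#'
#' Degenerate (collinear or single-point) coordinate sets cannot determine
#' a rotation; they are handled with a translation-only fit and flagged.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), equal n >= 3.
#' @param weights optional non-negative atom weights.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3,
#'   nm), `rmsd` (nm), and logical `degenerate`.
#' @export
superpose_rmsd <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 atoms for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)

  H <- t(A * w) %*% B
  degenerate <- FALSE
  sv <- tryCatch(svd(H), error = function(e) NULL)
  if (is.null(sv) || sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    # collinear (or worse): rotation underdetermined -> translation only
    degenerate <- TRUE
    R <- diag(3)
    warning("degenerate coordinate set: translation-only fit")
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)
  }
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  translation <- cr - as.numeric(R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd,
       degenerate = degenerate)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' Pairwise RMSD without superposition
#' @param a,b n x 3 matrices.
#' @return plain coordinate RMSD (nm).
#' @export
rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
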