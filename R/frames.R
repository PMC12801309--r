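# Mid-frame (CEHS / 3DNA-style) composition and decomposition of rigid
# base and base-pair transforms.  The same kernel serves base-pair step
# parameters (shift, slide, rise, tilt, roll, twist) and intra-base-pair
# parameters (shear, stretch, stagger, buckle, propeller, opening), which
# are the analogous quantities between a base and its flipped partner.
#
# Angles are degrees, translations nm.  A "frame" is a list(R = 3x3
# orthonormal matrix with columns x, y, z; o = origin 3-vector).

#' Decompose the relative transform of two frames into helical parameters
#'
#' Mid-frame decomposition: the two z-axes are symmetrically rotated onto
#' their bisector about the hinge axis (`z1 x z2`), twist is the angle
#' between the corrected x-axes about the common z, roll/tilt are the
#' projections of the hinge rotation onto the mid-frame y/x axes, and the
#' displacement is expressed in the mid-frame.
#'
#' @param f1,f2 frames, `list(R, o)`; for intra-bp use the flipped
#'   partner frame as `f2`.
#' @return list with `twist`, `roll`, `tilt` (deg), `shift`, `slide`,
#'   `rise` (nm) and the mid-frame `mid = list(R, o)`.
#' @export
frame_params <- function(f1, f2) {
  z1 <- f1$R[, 3]; z2 <- f2$R[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cg)
  hv <- .cross3(z1, z2)
  if (gamma < 1e-9 || .norm3(hv) < 1e-12) {
    gamma <- 0
    h <- f1$R[, 2]  # arbitrary: no hinge rotation to distribute
  } else {
    h <- .unit(hv)
  }
  R1p <- rot_axis(h, gamma / 2) %*% f1$R
  R2p <- rot_axis(h, -gamma / 2) %*% f2$R
  zm <- .unit(R1p[, 3] + R2p[, 3])
  x1 <- R1p[, 1]; x2 <- R2p[, 1]
  twist <- .signed_angle(x1, x2, zm)
  xm <- .unit(.unit(x1) + .unit(x2))
  ym <- .cross3(zm, xm)
  phi <- .signed_angle(h, ym, zm)
  roll <- gamma * cos(phi)
  tilt <- gamma * sin(phi)
  Rm <- cbind(xm, ym, zm)
  om <- (f1$o + f2$o) / 2
  tr <- as.numeric(t(Rm) %*% (f2$o - f1$o))
  list(twist = twist * 180 / pi, roll = roll * 180 / pi,
       tilt = tilt * 180 / pi,
       shift = tr[1], slide = tr[2], rise = tr[3],
       mid = list(R = Rm, o = om))
}

#' Compose a step: generate the next frame from helical parameters
#'
#' Exact inverse of [frame_params()]: given frame `f1` and the six
#' parameters, returns `f2` such that `frame_params(f1, f2)` reproduces
#' them.
#'
#' @param f1 frame `list(R, o)`.
#' @param twist,roll,tilt degrees.
#' @param shift,slide,rise nm.
#' @return frame `f2`.
#' @export
frame_step <- function(f1, twist = 0, roll = 0, tilt = 0,
                       shift = 0, slide = 0, rise = 0) {
  om <- twist * pi / 180
  rl <- roll * pi / 180; tl <- tilt * pi / 180
  gamma <- sqrt(rl^2 + tl^2)
  phi <- atan2(tl, rl)
  h <- c(sin(phi), cos(phi), 0)  # hinge in mid-frame coordinates
  A <- rot_axis_safe(h, -gamma / 2) %*% .rot_z(-om / 2)
  B <- rot_axis_safe(h, gamma / 2) %*% .rot_z(om / 2)
  Rm <- f1$R %*% t(A)
  R2 <- Rm %*% B
  o2 <- f1$o + as.numeric(Rm %*% c(shift, slide, rise))
  list(R = R2, o = o2)
}

# rot_axis that tolerates gamma == 0 (axis irrelevant)
rot_axis_safe <- function(axis, theta) {
  if (abs(theta) < 1e-15) return(diag(3))
  rot_axis(axis, theta)
}

#' Place the two base frames of a pair from intra-bp parameters
#'
#' The base-pair frame is the mid-frame of base I and the flipped
#' (180 deg about x) base II frame; generation distributes the parameters
#' symmetrically about it.
#'
#' @param bp base-pair frame `list(R, o)`.
#' @param shear,stretch,stagger nm.
#' @param buckle,propeller,opening degrees.
#' @return list `base1` and `base2` frames (base II unflipped, i.e. its z
#'   runs antiparallel to the stack).
#' @export
pair_frames <- function(bp, shear = 0, stretch = 0, stagger = 0,
                        buckle = 0, propeller = 0, opening = 0) {
  om <- opening * pi / 180
  rl <- propeller * pi / 180; tl <- buckle * pi / 180
  gamma <- sqrt(rl^2 + tl^2)
  phi <- atan2(tl, rl)
  h <- c(sin(phi), cos(phi), 0)
  A <- rot_axis_safe(h, -gamma / 2) %*% .rot_z(-om / 2)
  B <- rot_axis_safe(h, gamma / 2) %*% .rot_z(om / 2)
  tvec <- c(shear, stretch, stagger)
  Fx <- diag(c(1, -1, -1))  # 180 deg about x: unflip base II
  o1 <- bp$o - as.numeric(bp$R %*% (tvec / 2))
  o2 <- bp$o + as.numeric(bp$R %*% (tvec / 2))
  list(base1 = list(R = bp$R %*% A, o = o1),
       base2 = list(R = bp$R %*% B %*% Fx, o = o2))
}

#' Intra-base-pair parameters from two base frames
#'
#' @param f1 strand-I base frame.
#' @param f2 strand-II base frame (as assigned, z antiparallel to I).
#' @return list with `shear`, `stretch`, `stagger` (nm), `buckle`,
#'   `propeller`, `opening` (deg) and the base-pair frame `bp`.
#' @export
pair_params <- function(f1, f2) {
  Fx <- diag(c(1, -1, -1))
  f2f <- list(R = f2$R %*% Fx, o = f2$o)
  p <- frame_params(f1, f2f)
  list(shear = p$shift, stretch = p$slide, stagger = p$rise,
       buckle = p$tilt, propeller = p$roll, opening = p$twist,
       bp = p$mid)
}
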