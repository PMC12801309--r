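# Rigid placement of a carbon dot in catalogued binding poses on a
# nucleic-acid structure, and synthesis of noisy trajectories with
# scheduled binding events.

.pose_modes <- c("minor_groove", "major_groove", "backbone",
                 "terminal_stack", "unpaired_stack", "tetrad_stack",
                 "unbound")

# centre CD at origin, return structure + useful geometry
.cd_centered <- function(cd) {
  st <- cd$structure
  xyz <- coords(st)
  cen <- colMeans(xyz)
  st <- set_coords(st, sweep(xyz, 2, cen))
  layers <- sort(unique(cd$layer_of_atom))
  zs <- vapply(layers, function(l) {
    mean(st$atoms$z[cd$layer_of_atom[as.character(st$atoms$serial)] == l])
  }, 0)
  # distance from the centroid to the lowest layer plane: the -z face
  # is the one oriented toward a stacking target
  list(st = st, half_height = max(abs(zs)), half_low = -min(zs),
       layers = layers)
}

# orient CD (centered, z = stacking axis) with its z axis along `zdir`,
# then translate to `pos`
.cd_place <- function(cdc, zdir, pos) {
  z0 <- c(0, 0, 1)
  zdir <- .unit(zdir)
  ax <- .cross3(z0, zdir)
  ang <- acos(max(-1, min(1, sum(z0 * zdir))))
  R <- if (.norm3(ax) < 1e-9) {
    if (ang < 1) diag(3) else rot_axis(c(1, 0, 0), pi)
  } else rot_axis(ax, ang)
  set_coords(cdc$st, sweep(coords(cdc$st) %*% t(R), 2, -pos))
}

# smallest t >= t0 along dir (from origin point `from`) with no clash
.slide_out <- function(cd_xyz0, cd_r, na_xyz, na_r, from, dir, t0 = 0) {
  lim <- outer(cd_r, na_r, "+") * 0.8
  t <- t0
  repeat {
    p <- sweep(cd_xyz0, 2, -(from + dir * t))
    d2 <- .cross_min_d2(p, na_xyz)
    if (all(d2 > lim^2)) return(t)
    t <- t + 0.01
    if (t > t0 + 20) stop("unresolvable clash while placing pose")
  }
}

#' Place a carbon dot in a catalogued binding pose
#'
#' Rigid-body placement following the interaction-mode taxonomy: groove
#' poses approach along the base-pair x axis (negative x faces the
#' minor groove) to van der Waals contact; `backbone` approaches a
#' phosphate radially; stacking poses set the outermost flake plane
#' parallel to the target base (or quartet) plane at `separation`;
#' `unbound` parks the dot at least 2 nm from every nucleic-acid atom.
#'
#' @param na a `mol_structure` (duplex, superhelix or quadruplex mock
#'   with the annotations the mode needs: `"terminal"`, `"unpaired"`,
#'   `"quartet"` tags).
#' @param cd a `cd_model`.
#' @param mode one of `r paste(.pose_modes, collapse=", ")`.
#' @param anchor base-pair index (groove/stack modes) or residue
#'   `rindex` (backbone/unpaired); default picks a sensible one.
#' @param separation stacking distance, nm (default 0.34).
#' @return merged `mol_structure` (CD chain `"X"`, atoms tagged
#'   `"cd"`), with attribute `pose` recording mode, approach direction
#'   and CD serial range.
#' @export
place_cd_pose <- function(na, cd, mode, anchor = NULL,
                          separation = 0.34) {
  mode <- match.arg(mode, .pose_modes)
  cdc <- .cd_centered(cd)
  na_xyz <- coords(na)
  na_r <- na$atoms$radius
  heavy <- na$atoms$element != "H"
  pose_dir <- c(0, 0, 1)

  if (mode %in% c("minor_groove", "major_groove")) {
    p <- bp_step_params(na)
    nbp <- length(p$bp_frames)
    if (is.null(anchor)) anchor <- max(1L, nbp %/% 2)
    fb <- p$bp_frames[[anchor]]
    dir <- fb$R[, 1] * if (mode == "minor_groove") -1 else 1
    pose_dir <- dir
    # face-on approach: CD stacking axis along the groove bisector
    placed0 <- .cd_place(cdc, dir, c(0, 0, 0))
    t <- .slide_out(coords(placed0), placed0$atoms$radius,
                    na_xyz, na_r, fb$o, dir, t0 = 0.2)
    cd_st <- set_coords(placed0, sweep(coords(placed0), 2,
                                       -(fb$o + dir * t)))
  } else if (mode == "backbone") {
    p <- bp_step_params(na)
    nbp <- length(p$bp_frames)
    bpidx <- max(1L, nbp %/% 3)
    if (is.null(anchor)) {
      pr <- na$atoms[na$atoms$name == "P" & na$atoms$chain == "A", ]
      anchor <- pr$rindex[which.min(abs(pr$resno - bpidx))]
    }
    prow <- na$atoms[na$atoms$rindex == anchor & na$atoms$name == "P", ]
    if (nrow(prow) == 0) stop("anchor residue has no phosphate")
    ppos <- as.numeric(prow[1, c("x", "y", "z")])
    # nearest bp origin defines the outward radial direction
    oo <- t(vapply(p$bp_frames, function(f) f$o, numeric(3)))
    near <- which.min(rowSums(sweep(oo, 2, ppos)^2))
    dir <- .unit(ppos - p$bp_frames[[near]]$o)
    pose_dir <- dir
    placed0 <- .cd_place(cdc, dir, c(0, 0, 0))  # face-on to the ridge
    t <- .slide_out(coords(placed0), placed0$atoms$radius,
                    na_xyz, na_r, ppos, dir, t0 = 0.1)
    cd_st <- set_coords(placed0, sweep(coords(placed0), 2,
                                       -(ppos + dir * t)))
  } else if (mode %in% c("terminal_stack", "unpaired_stack",
                         "tetrad_stack")) {
    tgt <- .stack_target(na, mode, anchor)
    zdir <- tgt$normal
    pose_dir <- zdir
    pos <- tgt$centroid + zdir * (separation + cdc$half_low)
    cd_st <- .cd_place(cdc, zdir, pos)
  } else {  # unbound
    cen <- colMeans(na_xyz)
    dir <- .unit(c(1, 1, 1))
    pose_dir <- dir
    ext <- max(sqrt(rowSums(sweep(na_xyz, 2, cen)^2)))
    cd_rad <- max(sqrt(rowSums(coords(cdc$st)^2)))
    cd_st <- .cd_place(cdc, c(0, 0, 1),
                       cen + dir * (ext + cd_rad + 2.5))
  }
  cd_st <- add_tag(cd_st, seq_len(nrow(cd_st$atoms)), "cd")
  out <- merge_structures(na, cd_st)
  out$pairing <- na$pairing
  attr(out, "pose") <- list(
    mode = mode, anchor = anchor, direction = pose_dir,
    separation = separation,
    cd_serials = out$atoms$serial[(nrow(na$atoms) + 1):nrow(out$atoms)])
  out
}

# stacking target plane: terminal bp base, unpaired base, or quartet
.stack_target <- function(na, mode, anchor) {
  a <- na$atoms
  if (mode == "tetrad_stack") {
    qt <- has_tag(na, "quartet:1")
    if (!any(qt)) qt <- has_tag(na, "quartet")
    if (!any(qt)) stop("tetrad_stack requires quartet annotation")
    ring <- a[qt & a$element != "H", ]
    pl <- fit_plane(as.matrix(ring[, c("x", "y", "z")]))
    oth <- colMeans(as.matrix(a[!qt, c("x", "y", "z")]))
    nrm <- pl$normal
    if (sum((pl$centroid - oth) * nrm) < 0) nrm <- -nrm
    return(list(centroid = pl$centroid, normal = nrm))
  }
  if (mode == "unpaired_stack") {
    up <- which(has_tag(na, "unpaired"))
    if (length(up) == 0) stop("no unpaired residues annotated")
    ri <- if (is.null(anchor)) a$rindex[up[length(up)]] else anchor
  } else {
    term <- which(has_tag(na, "terminal"))
    if (length(term) == 0) stop("no terminal bp annotated")
    ri <- if (is.null(anchor)) max(a$rindex[term][a$chain[term] == "A"])
      else anchor
  }
  rows <- a[a$rindex == ri, ]
  base <- .base_letter(rows$resname[1])
  ring <- rows[rows$name %in% .base_ring_atoms[[base]], ]
  pl <- fit_plane(as.matrix(ring[, c("x", "y", "z")]))
  # outward: away from the rest of the molecule
  oth <- colMeans(as.matrix(a[a$rindex != ri, c("x", "y", "z")]))
  nrm <- pl$normal
  if (sum((pl$centroid - oth) * nrm) < 0) nrm <- -nrm
  list(centroid = pl$centroid, normal = nrm)
}

#' Synthesize a noisy trajectory with an optional binding event
#'
#' Frame 0 is the input complex (or its unbound variant when an event
#' is scheduled).  Subsequent frames add isotropic per-atom Gaussian
#' noise of width `noise_sigma`.  With `event_frame` set, the carbon
#' dot starts 2.5 nm out along its approach direction and interpolates
#' linearly into the pose over frames `event_frame` to
#' `event_frame + 10`.
#'
#' @param complex output of [place_cd_pose()] (or any structure; the
#'   event schedule needs the `pose` attribute).
#' @param n_frames number of frames (>= 1).
#' @param noise_sigma per-coordinate Gaussian width, nm (>= 0).
#' @param event_frame 0-based frame of binding onset, or `NULL`.
#' @param seed RNG seed; same seed gives a bitwise-identical
#'   trajectory.
#' @return a `trajectory`.
#' @export
synthesize_trajectory <- function(complex, n_frames, noise_sigma = 0,
                                  event_frame = NULL, seed = 1) {
  if (n_frames < 1) stop("need at least one frame")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  base_xyz <- coords(complex)
  pose <- attr(complex, "pose")
  cd_rows <- if (!is.null(pose))
    match(pose$cd_serials, complex$atoms$serial) else integer()
  offset0 <- if (!is.null(pose)) pose$direction * 2.5 else c(0, 0, 0)
  old <- .restore_seed()
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    f <- base_xyz
    if (!is.null(event_frame) && length(cd_rows) > 0) {
      fr <- k - 1
      lam <- if (fr < event_frame) 0 else
        min(1, (fr - event_frame) / 10)
      f[cd_rows, ] <- sweep(f[cd_rows, , drop = FALSE], 2,
                            -(1 - lam) * offset0)
    }
    if (k > 1 && noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sigma),
                      ncol = 3)
    frames[[k]] <- f
  }
  .put_seed(old)
  trajectory(complex, frames)
}
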