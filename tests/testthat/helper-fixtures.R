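# Shared fixtures, built once per test run.

.fx <- new.env()

fx_duplex <- function() {
  if (is.null(.fx$duplex)) .fx$duplex <- build_duplex(strrep("CG", 10))
  .fx$duplex
}

fx_duplex12 <- function() {
  if (is.null(.fx$duplex12))
    .fx$duplex12 <- build_duplex(strrep("AT", 6))
  .fx$duplex12
}

fx_cd0 <- function() {
  if (is.null(.fx$cd0)) .fx$cd0 <- stack_layers(c(2, 3, 3, 3, 2))
  .fx$cd0
}

fx_cd_plus <- function() {
  if (is.null(.fx$cdp))
    .fx$cdp <- functionalize(fx_cd0(), "NH3+", count = 9, seed = 1)
  .fx$cdp
}

fx_overhang <- function() {
  if (is.null(.fx$ovh))
    .fx$ovh <- build_duplex(paste0(strrep("CG", 8), "AA"), overhang3 = 2)
  .fx$ovh
}

fx_g4 <- function() {
  if (is.null(.fx$g4)) .fx$g4 <- build_g4_mock()
  .fx$g4
}

# random proper rotation matrix
random_rotation <- function() {
  rot_axis(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
}

# brute-force rigid-superposition oracle: coarse rotation grid followed
# by Nelder-Mead refinement over the rotation vector; independent of the
# SVD (Kabsch) path it checks
oracle_rmsd <- function(mobile, reference, n_grid = 1500) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  score <- function(v) {
    ang <- sqrt(sum(v^2))
    R <- if (ang < 1e-12) diag(3) else rot_axis(v, ang)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  # Fibonacci-distributed axes x angle grid
  best <- c(0, 0, 0); bestv <- score(best)
  i <- seq_len(n_grid)
  z <- 1 - 2 * (i - 0.5) / n_grid
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  axes <- cbind(r * cos(phi), r * sin(phi), z)
  for (k in seq_len(n_grid)) {
    for (ang in seq(0.25, pi, by = 0.25)) {
      v <- axes[k, ] * ang
      s <- score(v)
      if (s < bestv) { best <- v; bestv <- s }
    }
  }
  o <- stats::optim(best, score, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 2000))
  o$value
}

# planar pentagonal five-ring with a target pseudorotation phase, via
# scan of the out-of-plane displacement phase (inverse construction,
# independent of backbone_state)
ring_from_pucker <- function(P_target, R = 0.124, q = 0.038) {
  deg <- pi / 180
  best <- NULL
  for (phi in seq(0, 359.5, 0.5)) {
    r <- lapply(0:4, function(j)
      c(R * cos((90 - 72 * j) * deg), R * sin((90 - 72 * j) * deg),
        q * cos(4 * pi * j / 5 + phi * deg)))
    names(r) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
    nu <- c(dihedral(r[["C4'"]], r[["O4'"]], r[["C1'"]], r[["C2'"]]),
            dihedral(r[["O4'"]], r[["C1'"]], r[["C2'"]], r[["C3'"]]),
            dihedral(r[["C1'"]], r[["C2'"]], r[["C3'"]], r[["C4'"]]),
            dihedral(r[["C2'"]], r[["C3'"]], r[["C4'"]], r[["O4'"]]),
            dihedral(r[["C3'"]], r[["C4'"]], r[["O4'"]], r[["C1'"]]))
    Pv <- (atan2((nu[5] + nu[2]) - (nu[4] + nu[1]),
                 2 * nu[3] * (sin(36 * deg) + sin(72 * deg))) / deg) %% 360
    e <- abs(((Pv - P_target + 180) %% 360) - 180)
    if (is.null(best) || e < best$e) best <- list(r = r, e = e)
  }
  best$r
}

# wrap ring coordinates into a minimal one-residue structure
ring_structure <- function(r) {
  at <- data.frame(serial = 1:5, name = names(r),
                   element = c("O", "C", "C", "C", "C"),
                   resno = 1L, resname = "DA", chain = "A",
                   x = vapply(r, `[`, 0, 1), y = vapply(r, `[`, 0, 2),
                   z = vapply(r, `[`, 0, 3))
  mol_structure(at)
}

# the seven planted poses on their natural substrates
planted_poses <- function(cd = fx_cd_plus()) {
  list(
    minor_groove = place_cd_pose(fx_duplex(), cd, "minor_groove"),
    major_groove = place_cd_pose(fx_duplex(), cd, "major_groove"),
    backbone = place_cd_pose(fx_duplex(), cd, "backbone"),
    terminal_bp_stack = place_cd_pose(fx_duplex(), cd, "terminal_stack"),
    unpaired_base_stack = place_cd_pose(fx_overhang(), cd,
                                        "unpaired_stack"),
    tetrad_stack = place_cd_pose(fx_g4(), cd, "tetrad_stack"),
    unbound = place_cd_pose(fx_duplex(), cd, "unbound"))
}
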