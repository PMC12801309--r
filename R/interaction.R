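# Contact observables: Shrake-Rupley SASA with deterministic Fibonacci
# sphere points, SASA-difference contact area, geometric hydrogen bonds,
# radial distribution functions and pi-stacking detection.

#' Contact-analysis configuration
#'
#' Bundles the geometric cutoffs used by the interaction and
#' binding-mode functions.
#'
#' @param probe_radius solvent probe radius, nm (default 0.14).
#' @param contact_cutoff heavy-atom contact distance, nm (default 0.40).
#' @param hbond_dist donor-acceptor distance cutoff, nm (default 0.35).
#' @param hbond_angle minimum D-H...A angle, degrees (default 135).
#' @param stack_sep allowed ring-plane separation range, nm.
#' @param stack_angle maximum normal-normal angle, degrees.
#' @param stack_offset maximum lateral centroid offset, nm.
#' @param sasa_points Fibonacci points per atom for SASA (default 960).
#' @param groove_sector half-width (degrees) of the azimuthal sectors
#'   around the base-pair +x / -x axes within which a contact-ambiguous
#'   carbon dot is labelled major / minor groove (default 60).
#' @return list of class `contact_config`.
#' @export
contact_config <- function(probe_radius = 0.14, contact_cutoff = 0.40,
                           hbond_dist = 0.35, hbond_angle = 135,
                           stack_sep = c(0.25, 0.45), stack_angle = 30,
                           stack_offset = 0.20, sasa_points = 960,
                           groove_sector = 60) {
  cfg <- list(probe_radius = probe_radius,
              contact_cutoff = contact_cutoff, hbond_dist = hbond_dist,
              hbond_angle = hbond_angle, stack_sep = stack_sep,
              stack_angle = stack_angle, stack_offset = stack_offset,
              sasa_points = sasa_points, groove_sector = groove_sector)
  if (any(unlist(cfg) <= 0)) stop("all cutoffs must be positive")
  class(cfg) <- "contact_config"
  cfg
}

# deterministic Fibonacci sphere point set (unit sphere)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Shrake-Rupley: each atom's expanded sphere (vdW radius
#' plus probe) is sampled with a Fibonacci point set; points inside any
#' neighbouring expanded sphere are buried.  Per-atom areas sum to the
#' total.
#'
#' @param x a `mol_structure`, or an n x 3 coordinate matrix (then
#'   `radii` is required).
#' @param config a [contact_config()].
#' @param radii per-atom vdW radii, nm (taken from `x` if a structure).
#' @return list with `total` (nm^2) and `per_atom` (numeric vector).
#' @export
sasa <- function(x, config = contact_config(), radii = NULL) {
  if (inherits(x, "mol_structure")) {
    xyz <- coords(x)
    radii <- x$atoms$radius
  } else xyz <- as.matrix(x)
  n <- nrow(xyz)
  if (is.null(radii) || length(radii) != n)
    stop("radii required, one per atom")
  if (any(radii <= 0)) stop("zero/negative radius atom")
  rext <- radii + config$probe_radius
  pts <- .fib_sphere(config$sasa_points)
  # neighbour lists via cutoff on expanded radii
  maxr <- max(rext)
  per_atom <- numeric(n)
  d2 <- as.matrix(dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rext[i] + rext & seq_len(n) != i)
    if (length(nb) == 0) {
      per_atom[i] <- 4 * pi * rext[i]^2
      next
    }
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    dp2 <- .cross_d2(p, xyz[nb, , drop = FALSE])
    buried <- dp2 <= rep(rext[nb]^2, each = nrow(p))
    acc <- rowSums(buried) == 0
    per_atom[i] <- mean(acc) * 4 * pi * rext[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' SASA-difference contact area between two atom groups
#'
#' `SASA(A) + SASA(B) - SASA(A union B)`, i.e. the buried interface
#' area (larger = more contact), clamped at zero.
#'
#' @param x a `mol_structure` containing both groups.
#' @param group_a,group_b disjoint logical or integer atom indices.
#' @param config a [contact_config()].
#' @return contact area, nm^2.
#' @export
contact_area <- function(x, group_a, group_b,
                         config = contact_config()) {
  ia <- if (is.logical(group_a)) which(group_a) else group_a
  ib <- if (is.logical(group_b)) which(group_b) else group_b
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  if (length(intersect(ia, ib)) > 0)
    stop("groups share atoms")
  xyz <- coords(x); r <- x$atoms$radius
  # quick reject: no pair within burial range
  lim <- max(r[ia]) + max(r[ib]) + 2 * config$probe_radius
  da <- xyz[ia, , drop = FALSE]; db <- xyz[ib, , drop = FALSE]
  mind2 <- min(.cross_min_d2(da, db))
  if (mind2 > lim^2) return(0)
  sa <- sasa(da, config, radii = r[ia])$total
  sb <- sasa(db, config, radii = r[ib])$total
  sab <- sasa(rbind(da, db), config, radii = c(r[ia], r[ib]))$total
  max(0, sa + sb - sab)
}

# minimum squared distances between row sets (returns matrix n_a x n_b)
.cross_d2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}
.cross_min_d2 <- function(a, b) {
  m <- .cross_d2(a, b)
  pmax(m, 0)
}

#' Geometric hydrogen bonds between donor and acceptor sets
#'
#' A bond requires donor-acceptor distance at most `hbond_dist` and a
#' D-H...A angle of at least `hbond_angle`.  Donor hydrogens are found
#' via the bond list, or by proximity (< 0.125 nm) when no bonds are
#' recorded; donors without any hydrogen are skipped with a warning.
#'
#' @param x a `mol_structure`.
#' @param donors serials of donor heavy atoms (N/O with attached H).
#' @param acceptors serials of acceptor heavy atoms.
#' @param config a [contact_config()].
#' @return list with `bonds` (data frame donor, hydrogen, acceptor
#'   serials, distance nm, angle deg) and `count`.
#' @export
hydrogen_bonds <- function(x, donors, acceptors,
                           config = contact_config()) {
  a <- x$atoms
  xyz <- coords(x)
  pos <- function(serial) xyz[match(serial, a$serial), ]
  hser <- a$serial[a$element == "H"]
  h_of <- function(d) {
    if (!is.null(x$bonds) && length(x$bonds) > 0) {
      b <- x$bonds
      hs <- c(b[b[, 1] == d & b[, 2] %in% hser, 2],
              b[b[, 2] == d & b[, 1] %in% hser, 1])
      if (length(hs) > 0) return(hs)
    }
    if (length(hser) == 0) return(integer())
    dh <- sqrt(rowSums(sweep(xyz[match(hser, a$serial), , drop = FALSE],
                             2, pos(d))^2))
    hser[dh < 0.125]
  }
  res <- NULL
  for (d in donors) {
    hs <- h_of(d)
    if (length(hs) == 0) {
      warning("donor ", d, " has no attached hydrogen; skipped")
      next
    }
    for (ac in acceptors) {
      if (ac == d) next
      dda <- .norm3(pos(ac) - pos(d))
      if (dda > config$hbond_dist) next
      for (h in hs) {
        ang <- acos(max(-1, min(1, sum(
          .unit(pos(d) - pos(h)) * .unit(pos(ac) - pos(h)))))) * 180 / pi
        if (ang >= config$hbond_angle) {
          res <- rbind(res, data.frame(donor = d, hydrogen = h,
                                       acceptor = ac, distance = dda,
                                       angle = ang))
          break
        }
      }
    }
  }
  list(bonds = res, count = if (is.null(res)) 0L else nrow(res))
}

#' Radial distribution function between two atom groups
#'
#' Count-based g(r) for non-periodic systems: pair counts per shell are
#' normalized by the ideal-gas shell expectation using the mean density
#' of group B inside the analysis sphere of radius `r_max`.
#'
#' @param a,b n x 3 coordinate matrices, or lists of matrices (frames).
#' @param bin_width shell width, nm.
#' @param r_max maximum radius, nm (must exceed `bin_width`).
#' @return data frame with `r` (shell midpoints, nm) and `g`.
#' @export
rdf <- function(a, b, bin_width = 0.02, r_max = 2.0) {
  if (r_max <= bin_width) stop("r_max must exceed bin_width")
  if (!is.list(a)) a <- list(as.matrix(a))
  if (!is.list(b)) b <- list(as.matrix(b))
  if (any(vapply(a, nrow, 0) == 0) || any(vapply(b, nrow, 0) == 0))
    stop("empty group")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1)
  nfr <- length(a)
  nb_tot <- 0
  for (k in seq_len(nfr)) {
    d <- sqrt(.cross_min_d2(a[[k]], b[[k]]))
    d <- d[d > 1e-9 & d <= r_max]
    counts <- counts + hist(d, breaks = breaks, plot = FALSE)$counts
    nb_tot <- nb_tot + nrow(b[[k]])
  }
  na_mean <- mean(vapply(a, nrow, 0))
  rho <- (nb_tot / nfr) / (4 / 3 * pi * r_max^3)
  vshell <- 4 / 3 * pi * diff(breaks^3)
  expected <- na_mean * rho * vshell * nfr
  mid <- (utils::head(breaks, -1) + breaks[-1]) / 2
  data.frame(r = mid, g = counts / expected)
}

#' Detect pi-stacking between two rings
#'
#' Fits a plane to each ring by SVD; stacking requires plane separation
#' inside `stack_sep`, normal-normal angle at most `stack_angle` and
#' lateral centroid offset at most `stack_offset`.
#'
#' @param ring_a,ring_b n x 3 coordinate matrices (>= 5 atoms each,
#'   approximately planar).
#' @param config a [contact_config()].
#' @return list with `stacked` (logical), `separation`, `offset` (nm)
#'   and `angle` (deg).
#' @export
detect_stacking <- function(ring_a, ring_b, config = contact_config()) {
  ring_a <- as.matrix(ring_a); ring_b <- as.matrix(ring_b)
  if (nrow(ring_a) < 5 || nrow(ring_b) < 5)
    stop("rings need at least 5 atoms")
  pa <- fit_plane(ring_a); pb <- fit_plane(ring_b)
  ang <- acos(min(1, abs(sum(pa$normal * pb$normal)))) * 180 / pi
  dv <- pb$centroid - pa$centroid
  nmean <- .unit(pa$normal * sign(sum(pa$normal * pb$normal)) +
                   pb$normal)
  sep <- abs(sum(dv * nmean))
  off <- .norm3(dv - sum(dv * nmean) * nmean)
  stacked <- sep >= config$stack_sep[1] & sep <= config$stack_sep[2] &
    ang <= config$stack_angle & off <= config$stack_offset
  list(stacked = stacked, separation = sep, offset = off, angle = ang)
}
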