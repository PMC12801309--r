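# Nucleic-acid structural observables: base reference frames, intra-bp
# and step helical parameters, backbone dihedrals, sugar pucker, groove
# widths, and per-bp/time tables.

#' Assign base reference frames
#'
#' Fits the embedded standard base (ring atoms) of each residue onto the
#' observed coordinates by Kabsch superposition; the fitted rotation and
#' translation are the base frame (x toward the major groove, y toward
#' the strand-I sugar, z along the stack as generated).
#'
#' @param x a `mol_structure`.
#' @return data-frame-free list of frames: each `list(rindex, chain,
#'   resno, base, R, o, fit_rmsd)`.  Residues without the full ring atom
#'   set are skipped with a warning.
#' @export
assign_base_frames <- function(x) {
  a <- x$atoms
  out <- list()
  skipped <- 0
  for (ri in unique(a$rindex)) {
    rows <- a[a$rindex == ri, , drop = FALSE]
    base <- .base_letter(rows$resname[1])
    if (!(base %in% names(.base_ring_atoms))) next
    ring <- .base_ring_atoms[[base]]
    idx <- match(ring, rows$name)
    if (anyNA(idx)) { skipped <- skipped + 1; next }
    obs <- as.matrix(rows[idx, c("x", "y", "z")])
    tpl <- .base_templates[[base]][ring, ]
    fit <- superpose_rmsd(tpl, obs)
    out[[length(out) + 1]] <- list(
      rindex = ri, chain = rows$chain[1], resno = rows$resno[1],
      base = base, R = fit$rotation, o = fit$translation,
      fit_rmsd = fit$rmsd)
  }
  if (skipped > 0)
    warning(skipped, " residue(s) lacking ring atoms skipped")
  out
}

.frame_of <- function(frames, rindex) {
  for (f in frames) if (f$rindex == rindex) return(f)
  NULL
}

#' Infer Watson-Crick pairing from geometry
#'
#' Fallback when no generator annotation is present: residues are paired
#' when their N1-N3 distance is below `cutoff` and their base frames are
#' anti-aligned (z axes opposed).
#'
#' @param x a `mol_structure`.
#' @param frames output of [assign_base_frames()]; computed if missing.
#' @param cutoff N1-N3 distance cutoff, nm.
#' @return two-column matrix of paired global residue indices.
#' @export
infer_pairing <- function(x, frames = NULL, cutoff = 0.32) {
  if (is.null(frames)) frames <- assign_base_frames(x)
  a <- x$atoms
  wc_atom <- function(base) if (.is_purine(base)) "N1" else "N3"
  pts <- lapply(frames, function(f) {
    nm <- wc_atom(f$base)
    r <- a[a$rindex == f$rindex & a$name == nm, c("x", "y", "z")]
    if (nrow(r) == 0) NULL else as.numeric(r[1, ])
  })
  pairs <- NULL
  used <- logical(length(frames))
  for (i in seq_along(frames)) {
    if (used[i] || is.null(pts[[i]])) next
    best <- 0; bestd <- cutoff
    for (j in seq_along(frames)) {
      if (j == i || used[j] || is.null(pts[[j]])) next
      d <- .norm3(pts[[i]] - pts[[j]])
      anti <- sum(frames[[i]]$R[, 3] * frames[[j]]$R[, 3]) < -0.5
      if (d < bestd && anti) { best <- j; bestd <- d }
    }
    if (best > 0) {
      pairs <- rbind(pairs, c(frames[[i]]$rindex, frames[[best]]$rindex))
      used[i] <- TRUE; used[best] <- TRUE
    }
  }
  pairs
}

#' Intra-base-pair and base-pair-step helical parameters
#'
#' Mid-frame (CEHS, 3DNA-convention) decomposition.  The strand-II base
#' frame is flipped 180 degrees about its x axis; the base-pair frame is
#' the half-rotation average, and step parameters come from consecutive
#' base-pair frames.
#'
#' @param x a `mol_structure`.
#' @param pairing two-column matrix of global residue indices in strand-I
#'   5'->3' order; defaults to the generator annotation, else geometric
#'   inference.
#' @return list with data frames `intra` (bp, shear, stretch, stagger,
#'   buckle, propeller, opening), `step` (step, shift, slide, rise,
#'   tilt, roll, twist), and the list of bp frames `bp_frames`.
#' @export
bp_step_params <- function(x, pairing = NULL) {
  frames <- assign_base_frames(x)
  if (is.null(pairing)) pairing <- x$pairing
  if (is.null(pairing)) pairing <- infer_pairing(x, frames)
  if (is.null(pairing) || nrow(pairing) == 0)
    stop("no base pairing available")
  if (anyDuplicated(c(pairing)))
    stop("pairing uses a residue more than once")
  nbp <- nrow(pairing)
  intra <- data.frame(bp = seq_len(nbp), shear = NA_real_,
                      stretch = NA_real_, stagger = NA_real_,
                      buckle = NA_real_, propeller = NA_real_,
                      opening = NA_real_)
  bp_frames <- vector("list", nbp)
  for (i in seq_len(nbp)) {
    f1 <- .frame_of(frames, pairing[i, 1])
    f2 <- .frame_of(frames, pairing[i, 2])
    if (is.null(f1) || is.null(f2)) next
    p <- pair_params(f1, f2)
    intra[i, -1] <- c(p$shear, p$stretch, p$stagger, p$buckle,
                      p$propeller, p$opening)
    bp_frames[[i]] <- p$bp
  }
  nstep <- max(nbp - 1, 0)
  step <- data.frame(step = seq_len(nstep), shift = NA_real_,
                     slide = NA_real_, rise = NA_real_, tilt = NA_real_,
                     roll = NA_real_, twist = NA_real_)
  for (i in seq_len(nstep)) {
    if (is.null(bp_frames[[i]]) || is.null(bp_frames[[i + 1]])) next
    p <- frame_params(bp_frames[[i]], bp_frames[[i + 1]])
    step[i, -1] <- c(p$shift, p$slide, p$rise, p$tilt, p$roll, p$twist)
  }
  list(intra = intra, step = step, bp_frames = bp_frames)
}

#' Base pairs per helical turn
#'
#' `360 / mean(twist)`; returns `NA` with a warning if the mean twist is
#' zero.
#'
#' @param twists vector of step twists, degrees.
#' @return bp per turn (real).
#' @export
bp_per_turn <- function(twists) {
  m <- mean(twists, na.rm = TRUE)
  if (!is.finite(m) || abs(m) < 1e-12) {
    warning("mean twist is zero; bp/turn undefined")
    return(NA_real_)
  }
  360 / m
}

.torsion_atoms <- function(a, spec) {
  # spec: list of c(rindex, name); returns 4 points or NULL
  pts <- lapply(spec, function(s) {
    r <- a[a$rindex == s[[1]] & a$name == s[[2]], c("x", "y", "z")]
    if (nrow(r) == 0) NULL else as.numeric(r[1, ])
  })
  if (any(vapply(pts, is.null, logical(1)))) return(NULL)
  pts
}

#' Backbone torsions and sugar pucker of one residue
#'
#' Standard four-atom dihedrals alpha..zeta and chi, and the
#' Altona-Sundaralingam pseudorotation phase/amplitude from the five
#' endocyclic torsions nu0..nu4.  Fields whose atoms are missing (chain
#' termini, reduced models) are `NA`.
#'
#' @param x a `mol_structure`.
#' @param rindex global residue index (or use `chain` + `resno`).
#' @param chain,resno alternative residue addressing.
#' @return list with `alpha`, `beta`, `gamma`, `delta`, `epsilon`,
#'   `zeta`, `chi` (degrees, (-180, 180]), `pucker_phase` (degrees,
#'   [0, 360)) and `pucker_amplitude` (degrees).
#' @export
backbone_state <- function(x, rindex = NULL, chain = NULL, resno = NULL) {
  a <- x$atoms
  if (is.null(rindex)) {
    rindex <- a$rindex[a$chain == chain & a$resno == resno][1]
    if (is.na(rindex)) stop("no such residue")
  }
  me <- a[a$rindex == rindex, , drop = FALSE]
  ch <- me$chain[1]; rn <- me$resno[1]
  prev <- a$rindex[a$chain == ch & a$resno == rn - 1][1]
  nxt <- a$rindex[a$chain == ch & a$resno == rn + 1][1]
  tor <- function(spec) {
    pts <- .torsion_atoms(a, spec)
    if (is.null(pts)) NA_real_ else
      dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
  r <- rindex
  res <- list(
    alpha = if (is.na(prev)) NA_real_ else
      tor(list(list(prev, "O3'"), list(r, "P"), list(r, "O5'"),
               list(r, "C5'"))),
    beta = tor(list(list(r, "P"), list(r, "O5'"), list(r, "C5'"),
                    list(r, "C4'"))),
    gamma = tor(list(list(r, "O5'"), list(r, "C5'"), list(r, "C4'"),
                     list(r, "C3'"))),
    delta = tor(list(list(r, "C5'"), list(r, "C4'"), list(r, "C3'"),
                     list(r, "O3'"))),
    epsilon = if (is.na(nxt)) NA_real_ else
      tor(list(list(r, "C4'"), list(r, "C3'"), list(r, "O3'"),
               list(nxt, "P"))),
    zeta = if (is.na(nxt)) NA_real_ else
      tor(list(list(r, "C3'"), list(r, "O3'"), list(nxt, "P"),
               list(nxt, "O5'"))))
  base <- .base_letter(me$resname[1])
  chi_n <- if (.is_purine(base)) c("N9", "C4") else c("N1", "C2")
  res$chi <- tor(list(list(r, "O4'"), list(r, "C1'"),
                      list(r, chi_n[1]), list(r, chi_n[2])))
  nu <- c(tor(list(list(r, "C4'"), list(r, "O4'"), list(r, "C1'"),
                   list(r, "C2'"))),
          tor(list(list(r, "O4'"), list(r, "C1'"), list(r, "C2'"),
                   list(r, "C3'"))),
          tor(list(list(r, "C1'"), list(r, "C2'"), list(r, "C3'"),
                   list(r, "C4'"))),
          tor(list(list(r, "C2'"), list(r, "C3'"), list(r, "C4'"),
                   list(r, "O4'"))),
          tor(list(list(r, "C3'"), list(r, "C4'"), list(r, "O4'"),
                   list(r, "C1'"))))
  if (anyNA(nu)) {
    res$pucker_phase <- NA_real_
    res$pucker_amplitude <- NA_real_
  } else {
    s36 <- sin(36 * pi / 180); s72 <- sin(72 * pi / 180)
    P <- atan2((nu[5] + nu[2]) - (nu[4] + nu[1]),
               2 * nu[3] * (s36 + s72)) * 180 / pi
    res$pucker_phase <- P %% 360
    res$pucker_amplitude <- nu[3] / cos(P * pi / 180)
  }
  res
}

#' Groove widths per base pair
#'
#' Minor and major groove widths as minimal cross-strand P-P distances
#' with a 3-bp register offset, minus a 0.58 nm phosphate vdW
#' correction.  Base pairs whose register partners lack phosphates
#' (termini, short duplexes) get `NA`.
#'
#' @param x a `mol_structure`.
#' @param pairing pairing matrix (defaults to annotation).
#' @param register register offset in bp (default 3).
#' @param correction phosphate diameter subtracted, nm.
#' @return data frame with `bp`, `minor`, `major` (nm).
#' @export
groove_widths <- function(x, pairing = NULL, register = 3,
                          correction = 0.58) {
  if (is.null(pairing)) pairing <- x$pairing
  if (is.null(pairing)) stop("pairing required")
  a <- x$atoms
  nbp <- nrow(pairing)
  p_of <- function(ri) {
    r <- a[a$rindex == ri & a$name == "P", c("x", "y", "z")]
    if (nrow(r) == 0) NULL else as.numeric(r[1, ])
  }
  out <- data.frame(bp = seq_len(nbp), minor = NA_real_,
                    major = NA_real_)
  for (i in seq_len(nbp)) {
    ip <- i + register; im <- i - register
    if (ip <= nbp && im >= 1) {
      # minor: strand-I P downstream vs strand-II P of the upstream bp
      p1 <- p_of(pairing[ip, 1]); p2 <- p_of(pairing[im, 2])
      if (!is.null(p1) && !is.null(p2))
        out$minor[i] <- .norm3(p1 - p2) - correction
      q1 <- p_of(pairing[im, 1]); q2 <- p_of(pairing[ip, 2])
      if (!is.null(q1) && !is.null(q2))
        out$major[i] <- .norm3(q1 - q2) - correction
    }
  }
  out
}

#' Per-base-pair/time table of a helical parameter
#'
#' Long-format table of one intra-bp or step parameter over a
#' trajectory, for heatmap-style reporting.
#'
#' @param traj a `trajectory`.
#' @param parameter one of shear, stretch, stagger, buckle, propeller,
#'   opening (per bp) or shift, slide, rise, tilt, roll, twist (per
#'   step).
#' @param pairing pairing matrix (defaults to topology annotation).
#' @return data frame with `frame` (0-based), `bp` (or step index) and
#'   `value`.
#' @export
heatmap_table <- function(traj, parameter, pairing = NULL) {
  intra_p <- c("shear", "stretch", "stagger", "buckle", "propeller",
               "opening")
  step_p <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  if (!(parameter %in% c(intra_p, step_p)))
    stop("unknown parameter: ", parameter)
  if (is.null(pairing)) pairing <- traj$topology$pairing
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    st <- frame_structure(traj, k - 1)
    p <- bp_step_params(st, pairing)
    tab <- if (parameter %in% intra_p) p$intra else p$step
    idx <- tab[[1]]
    out[[k]] <- data.frame(frame = k - 1, bp = idx,
                           value = tab[[parameter]])
  }
  do.call(rbind, out)
}

#' Windowed per-bp average of a heatmap table
#'
#' @param tab output of [heatmap_table()].
#' @param frames frame range (0-based, inclusive) to average over;
#'   default all.
#' @return data frame `bp`, `mean`.
#' @export
window_average <- function(tab, frames = NULL) {
  if (!is.null(frames))
    tab <- tab[tab$frame >= frames[1] & tab$frame <= frames[2], ]
  agg <- aggregate(value ~ bp, tab, mean)
  names(agg) <- c("bp", "mean")
  agg
}
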