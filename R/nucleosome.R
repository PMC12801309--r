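# Nucleosome-oriented metrics: cross-gyre base-pair distances with a
# sequence exclusion, per-residue RMSF, and event-aligned per-residue
# RMSD around binding events.

.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)

# centre of mass of each base pair (all atoms of both residues)
.bp_coms <- function(x, pairing, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(x)
  a <- x$atoms
  t(apply(pairing, 1, function(pr) {
    rows <- which(a$rindex %in% pr)
    w <- .atomic_mass[a$element[rows]]
    w[is.na(w)] <- 12
    colSums(xyz[rows, , drop = FALSE] * w) / sum(w)
  }))
}

#' Cross-gyre base-pair distances
#'
#' For each base pair, the closest distance between its centre of mass
#' and that of any base pair more than `exclusion` positions away in
#' sequence.  On a nucleosomal superhelix the minimum over base pairs
#' approximates the superhelical pitch.
#'
#' @param x a `mol_structure` or `trajectory`.
#' @param pairing pairing matrix (defaults to annotation).
#' @param exclusion sequence exclusion in bp (default 10).
#' @return data frame with `bp` and `distance` (nm); for trajectories
#'   an additional `frame` column (long format).
#' @export
gyre_distances <- function(x, pairing = NULL, exclusion = 10) {
  if (exclusion < 1) stop("exclusion must be >= 1")
  topo <- if (inherits(x, "trajectory")) x$topology else x
  if (is.null(pairing)) pairing <- topo$pairing
  if (is.null(pairing)) stop("pairing required")
  nbp <- nrow(pairing)
  if (nbp < 2 * exclusion + 2)
    stop("need at least ", 2 * exclusion + 2, " base pairs for ",
         "exclusion ", exclusion)
  one <- function(xyz) {
    com <- .bp_coms(topo, pairing, xyz)
    d <- as.matrix(dist(com))
    seq_sep <- abs(outer(seq_len(nbp), seq_len(nbp), "-"))
    d[seq_sep <= exclusion] <- Inf
    data.frame(bp = seq_len(nbp), distance = apply(d, 1, min))
  }
  if (!inherits(x, "trajectory")) return(one(coords(x)))
  out <- lapply(seq_len(n_frames(x)), function(k) {
    cbind(frame = k - 1, one(x$frames[[k]]))
  })
  do.call(rbind, out)
}

# superpose every frame onto a reference using the alignment selection;
# returns the list of aligned coordinate matrices
.align_frames <- function(traj, align_rows, ref_xyz) {
  lapply(traj$frames, function(f) {
    fit <- superpose_rmsd(f[align_rows, , drop = FALSE],
                          ref_xyz[align_rows, , drop = FALSE])
    apply_transform(f, fit$rotation, fit$translation)
  })
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed (Kabsch) on the alignment selection onto the
#' time-average structure (two-pass); RMSF of a residue is the root
#' mean square displacement of its atoms from their time-average
#' positions.
#'
#' @param traj a `trajectory` (>= 2 frames).
#' @param align logical/integer atom rows used for superposition
#'   (default: all atoms).
#' @return data frame with `rindex`, `chain`, `resno`, `rmsf` (nm).
#' @export
per_residue_rmsf <- function(traj, align = NULL) {
  if (n_frames(traj) < 2) stop("need at least 2 frames for RMSF")
  a <- traj$topology$atoms
  if (is.null(align)) align <- seq_len(nrow(a))
  if (is.logical(align)) align <- which(align)
  al <- .align_frames(traj, align, traj$frames[[1]])
  mean1 <- Reduce(`+`, al) / length(al)
  al <- .align_frames(traj, align, mean1)
  mn <- Reduce(`+`, al) / length(al)
  msd <- Reduce(`+`, lapply(al, function(f) rowSums((f - mn)^2))) /
    length(al)
  out <- aggregate(msd, by = list(rindex = a$rindex), FUN = mean)
  names(out)[2] <- "msd"
  first <- match(out$rindex, a$rindex)
  data.frame(rindex = out$rindex, chain = a$chain[first],
             resno = a$resno[first], rmsf = sqrt(out$msd))
}

#' Event-aligned per-residue RMSD around a binding event
#'
#' The event frame `t0` is the onset of the first bound state that
#' persists for at least `persist` frames in the mode timeline (or is
#' given directly).  Frames in the pre-window `[t0 - delta, t0)` and
#' post-window `[t0, t0 + delta]` are superposed on the alignment
#' selection onto the pre-event window average; each window's
#' per-residue RMSD is computed against that average, and the profile
#' `delta_rmsd = after - before` localizes structural change at the
#' binding site.
#'
#' @param traj a `trajectory`.
#' @param timeline a `mode_timeline` from [classify_trajectory()], or
#'   `NULL` if `t0` is given.
#' @param delta window half-width in frames.
#' @param t0 event frame override (0-based).
#' @param persist minimum persistence defining the event (default 10).
#' @param align atom rows for superposition (default all).
#' @return list with `t0` and `profile` (data frame rindex, chain,
#'   resno, before, after, delta_rmsd); `t0 = NA` and an empty profile
#'   if no qualifying event exists.
#' @export
event_aligned_rmsd <- function(traj, timeline = NULL, delta = 20,
                               t0 = NULL, persist = 10, align = NULL) {
  if (is.null(t0)) {
    if (is.null(timeline)) stop("need a timeline or an explicit t0")
    m <- timeline$modes$mode
    bound <- m != "unbound"
    r <- rle(bound)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= persist)
    if (length(hit) == 0)
      return(list(t0 = NA_integer_,
                  profile = data.frame(rindex = integer(),
                                       chain = character(),
                                       resno = integer(),
                                       before = numeric(),
                                       after = numeric(),
                                       delta_rmsd = numeric())))
    t0 <- timeline$modes$frame[starts[hit[1]]]
  }
  nf <- n_frames(traj)
  if (t0 - delta < 0 || t0 + delta > nf - 1)
    stop("window [t0 - delta, t0 + delta] outside trajectory")
  a <- traj$topology$atoms
  if (is.null(align)) align <- seq_len(nrow(a))
  if (is.logical(align)) align <- which(align)
  pre_idx <- (t0 - delta):(t0 - 1) + 1
  post_idx <- t0:(t0 + delta) + 1
  pre0 <- lapply(traj$frames[pre_idx], identity)
  ref <- Reduce(`+`, pre0) / length(pre0)
  alignw <- function(frames) {
    lapply(frames, function(f) {
      fit <- superpose_rmsd(f[align, , drop = FALSE],
                            ref[align, , drop = FALSE])
      apply_transform(f, fit$rotation, fit$translation)
    })
  }
  pre <- alignw(traj$frames[pre_idx])
  ref <- Reduce(`+`, pre) / length(pre)   # refined pre-event average
  pre <- alignw(traj$frames[pre_idx])
  post <- alignw(traj$frames[post_idx])
  res_rmsd <- function(frames) {
    msd <- Reduce(`+`, lapply(frames, function(f)
      rowSums((f - ref)^2))) / length(frames)
    agg <- aggregate(msd, by = list(rindex = a$rindex), FUN = mean)
    sqrt(agg$x)
  }
  rb <- res_rmsd(pre); ra <- res_rmsd(post)
  ri <- sort(unique(a$rindex))
  first <- match(ri, a$rindex)
  list(t0 = t0,
       profile = data.frame(rindex = ri, chain = a$chain[first],
                            resno = a$resno[first], before = rb,
                            after = ra, delta_rmsd = ra - rb))
}
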