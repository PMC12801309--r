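# Per-frame binding-mode classification of a carbon dot on a nucleic
# acid, following the interaction-mode taxonomy: groove binding (minor/
# major), backbone contact, and stacking on terminal base pairs,
# unpaired bases or G-tetrads, plus unbound.
#
# The assignment is a contact-count decision procedure (the source
# trajectories were labelled by inspection; the operational rules here
# live in contact_config and are documented in the vignette).

.mode_levels <- c("minor_groove", "major_groove", "backbone",
                  "terminal_bp_stack", "unpaired_base_stack",
                  "tetrad_stack", "unbound")

# residue-level groove/backbone atom name sets
.edge_sets <- function(a) {
  base <- .base_letter(a$resname)
  minor <- mapply(function(nm, b) {
    s <- .groove_atom_map$minor[[b]]
    !is.null(s) && nm %in% s
  }, a$name, base)
  major <- mapply(function(nm, b) {
    s <- .groove_atom_map$major[[b]]
    !is.null(s) && nm %in% s
  }, a$name, base)
  backbone <- a$name %in% .groove_atom_map$backbone
  list(minor = minor, major = major, backbone = backbone)
}

#' Classify the binding mode of one frame
#'
#' Decision procedure: (1) if the minimum CD-NA heavy-atom distance
#' exceeds the contact cutoff the frame is `unbound`; (2) stacking of
#' any CD layer on a G-tetrad, annotated unpaired base or terminal base
#' pair is tested geometrically (precedence tetrad > unpaired >
#' terminal); (3) otherwise nucleic-acid atoms in contact with the CD
#' are counted per minor-edge / major-edge / backbone set; `backbone`
#' requires more than twice both groove counts, else the larger groove
#' count wins (ties broken by SASA-difference contact area).
#'
#' @param x a `mol_structure` containing the complex (CD atoms tagged
#'   `"cd"` or on chain `"X"`).
#' @param config a [contact_config()].
#' @return list with `mode` (factor level of the taxonomy) and
#'   `evidence` (contact counts, stacking geometry, min distance).
#' @export
classify_frame <- function(x, config = contact_config()) {
  a <- x$atoms
  is_cd <- has_tag(x, "cd") | a$chain == "X"
  if (!any(is_cd) || all(is_cd)) stop("complex must contain CD and NA atoms")
  heavy <- a$element != "H"
  xyz <- coords(x)
  cdh <- which(is_cd & heavy); nah <- which(!is_cd & heavy)
  d2 <- .cross_d2(xyz[cdh, , drop = FALSE], xyz[nah, , drop = FALSE])
  mind <- sqrt(max(0, min(d2)))
  ev <- list(min_distance = mind)
  if (mind > config$contact_cutoff)
    return(list(mode = "unbound", evidence = ev))

  # stacking candidates, in precedence order
  cand <- list()
  for (t in c("quartet:1", "quartet:0")) {
    idx <- which(has_tag(x, t) & heavy)
    if (length(idx) >= 5)
      cand[[length(cand) + 1]] <- list(mode = "tetrad_stack", idx = idx)
  }
  if (length(cand) == 0 && any(has_tag(x, "quartet"))) {
    idx <- which(has_tag(x, "quartet") & heavy)
    cand[[1]] <- list(mode = "tetrad_stack", idx = idx)
  }
  for (ri in unique(a$rindex[has_tag(x, "unpaired")])) {
    idx <- .ring_rows(x, ri)
    if (length(idx) >= 5)
      cand[[length(cand) + 1]] <- list(mode = "unpaired_base_stack",
                                       idx = idx)
  }
  for (ri in unique(a$rindex[has_tag(x, "terminal") & !is_cd])) {
    idx <- .ring_rows(x, ri)
    if (length(idx) >= 5)
      cand[[length(cand) + 1]] <- list(mode = "terminal_bp_stack",
                                       idx = idx)
  }
  layers <- unique(a$tag[is_cd])
  layer_ids <- unique(stats::na.omit(as.integer(
    sub("^.*layer:(\\d+).*$", "\\1", a$tag[is_cd]))))
  stack_hits <- character()
  stack_geom <- NULL
  for (cnd in cand) {
    ringb <- xyz[cnd$idx, , drop = FALSE]
    cb <- colMeans(ringb)
    for (l in layer_ids) {
      li <- which(is_cd & heavy & has_tag(x, paste0("layer:", l)) &
                    a$element == "C")
      if (length(li) < 5) next
      ringa <- xyz[li, , drop = FALSE]
      # cheap gate before plane fitting
      if (min(.cross_min_d2(matrix(cb, 1), ringa)) > 1.0^2) next
      s <- detect_stacking(ringa, ringb, config)
      if (s$stacked) {
        stack_hits <- c(stack_hits, cnd$mode)
        if (is.null(stack_geom)) stack_geom <- s
      }
    }
    if (length(stack_hits) > 0) break  # candidates are in precedence order
  }
  ev$stacking <- stack_geom
  if (length(stack_hits) > 0) {
    return(list(mode = stack_hits[1], evidence = ev))
  }

  # contact counts per groove-edge / backbone set
  na_a <- a[nah, , drop = FALSE]
  sets <- .edge_sets(na_a)
  in_contact <- apply(d2, 2, min) <= config$contact_cutoff^2
  nmin <- sum(in_contact & sets$minor)
  nmaj <- sum(in_contact & sets$major)
  nbb <- sum(in_contact & sets$backbone)
  ev$contacts <- c(minor = nmin, major = nmaj, backbone = nbb)
  # clear groove dominance by contact counts alone
  if (nmin > nmaj && nbb <= 2 * nmin)
    return(list(mode = "minor_groove", evidence = ev))
  if (nmaj > nmin && nbb <= 2 * nmaj)
    return(list(mode = "major_groove", evidence = ev))
  # backbone-dominated or ambiguous: decide by the azimuth of the CD
  # centroid in the nearest base-pair frame (minor groove opens along
  # -x, major along +x, the strand ridges lie between)
  cen <- colMeans(xyz[cdh, , drop = FALSE])
  fb <- .bp_frame_near(x, cen)
  if (!is.null(fb)) {
    v <- as.numeric(t(fb$R) %*% (cen - fb$o))
    theta <- atan2(v[2], v[1]) * 180 / pi
    ev$azimuth <- theta
    sector <- config$groove_sector
    if (abs(theta) <= sector)
      return(list(mode = "major_groove", evidence = ev))
    if (abs(theta) >= 180 - sector)
      return(list(mode = "minor_groove", evidence = ev))
    return(list(mode = "backbone", evidence = ev))
  }
  # no pairing (e.g. quadruplex mock): fall back to counts
  if (nbb >= nmin && nbb >= nmaj && nbb > 0)
    return(list(mode = "backbone", evidence = ev))
  if (nmin == 0 && nmaj == 0)
    return(list(mode = "unbound", evidence = ev))
  list(mode = if (nmin >= nmaj) "minor_groove" else "major_groove",
       evidence = ev)
}

# base-pair frame nearest to a point (by paired-ring-centroid midpoint);
# NULL when the structure has no pairing annotation
.bp_frame_near <- function(x, point) {
  pairing <- x$pairing
  if (is.null(pairing) || nrow(pairing) == 0) return(NULL)
  xyz <- coords(x)
  mids <- t(apply(pairing, 1, function(pr) {
    r1 <- .ring_rows(x, pr[1]); r2 <- .ring_rows(x, pr[2])
    if (length(r1) == 0 || length(r2) == 0) return(c(NA, NA, NA))
    (colMeans(xyz[r1, , drop = FALSE]) +
       colMeans(xyz[r2, , drop = FALSE])) / 2
  }))
  ok <- !is.na(mids[, 1])
  if (!any(ok)) return(NULL)
  d2 <- rowSums(sweep(mids, 2, point)^2)
  i <- which(ok)[which.min(d2[ok])]
  f1 <- .residue_frame(x, pairing[i, 1])
  f2 <- .residue_frame(x, pairing[i, 2])
  if (is.null(f1) || is.null(f2)) return(NULL)
  pair_params(f1, f2)$bp
}

# Kabsch base frame of one residue (NULL if ring atoms missing)
.residue_frame <- function(x, ri) {
  a <- x$atoms
  rows <- a[a$rindex == ri, , drop = FALSE]
  base <- .base_letter(rows$resname[1])
  if (!(base %in% names(.base_ring_atoms))) return(NULL)
  ring <- .base_ring_atoms[[base]]
  idx <- match(ring, rows$name)
  if (anyNA(idx)) return(NULL)
  fit <- superpose_rmsd(.base_templates[[base]][ring, ],
                        as.matrix(rows[idx, c("x", "y", "z")]))
  list(R = fit$rotation, o = fit$translation)
}

.ring_rows <- function(x, ri) {
  a <- x$atoms
  rows <- which(a$rindex == ri)
  base <- .base_letter(a$resname[rows[1]])
  if (!(base %in% names(.base_ring_atoms))) return(integer())
  rows[a$name[rows] %in% .base_ring_atoms[[base]]]
}

#' Classify every frame of a trajectory
#'
#' @param traj a `trajectory` whose topology contains CD and NA atoms.
#' @param config a [contact_config()].
#' @param dominant_window fraction of trailing frames over which the
#'   dominant (modal) mode is taken (default 0.2).
#' @return a `mode_timeline`: list with `modes` (data frame frame,
#'   mode), `fractions` (named, sums to 1), `dominant` (character; may
#'   have several co-dominant labels).
#' @export
classify_trajectory <- function(traj, config = contact_config(),
                                dominant_window = 0.2) {
  nf <- n_frames(traj)
  modes <- character(nf)
  for (k in seq_len(nf)) {
    modes[k] <- classify_frame(frame_structure(traj, k - 1),
                               config)$mode
  }
  fr <- table(factor(modes, levels = .mode_levels)) / nf
  tail_n <- max(1, ceiling(dominant_window * nf))
  tailm <- modes[(nf - tail_n + 1):nf]
  tt <- table(tailm)
  dom <- names(tt)[tt == max(tt)]
  structure(list(modes = data.frame(frame = seq_len(nf) - 1,
                                    mode = modes),
                 fractions = as.numeric(fr) |> stats::setNames(names(fr)),
                 dominant = dom),
            class = "mode_timeline")
}

#' @export
print.mode_timeline <- function(x, ...) {
  cat("mode_timeline:", nrow(x$modes), "frames; dominant:",
      paste(x$dominant, collapse = "/"), "\n")
  invisible(x)
}

#' Summarize dominant modes over simulations
#'
#' Percentage of simulations whose dominant mode is each taxonomy
#' label; co-dominant timelines contribute fractionally.
#'
#' @param timelines list of `mode_timeline` objects.
#' @return data frame with `mode` and `percent` (sums to 100).
#' @export
summarize_modes <- function(timelines) {
  if (length(timelines) == 0) stop("need at least one timeline")
  acc <- stats::setNames(numeric(length(.mode_levels)), .mode_levels)
  for (tl in timelines) {
    d <- tl$dominant
    acc[d] <- acc[d] + 1 / length(d)
  }
  data.frame(mode = .mode_levels,
             percent = 100 * as.numeric(acc) / length(timelines))
}
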