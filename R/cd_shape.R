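# Per-frame carbon-dot shape descriptors: layer plane fits, interlayer
# distances, undulation, tilt/rotation/lateral offset versus the middle
# reference layer, and layer-detachment detection.

# layer membership (serial -> layer) from a cd_model or from layer tags
.layer_membership <- function(x) {
  if (inherits(x, "cd_model")) return(x$layer_of_atom)
  lay <- suppressWarnings(as.integer(sub("^.*layer:(\\d+).*$", "\\1",
                                         x$atoms$tag)))
  names(lay) <- x$atoms$serial
  lay
}

#' Fit planes to carbon-dot layers
#'
#' Least-squares plane per layer (carbons only) by SVD; the out-of-plane
#' RMS residual is the layer undulation.  Normals are sign-aligned with
#' the middle (reference) layer normal.
#'
#' @param x a `mol_structure` whose atoms carry `"layer:k"` tags (or a
#'   `cd_model`).
#' @param membership optional named vector serial -> layer index.
#' @param reference reference layer index; default the middle layer.
#' @return data frame with `layer`, centroid (`cx`, `cy`, `cz`), normal
#'   (`nx`, `ny`, `nz`) and `undulation` (nm).
#' @export
fit_layers <- function(x, membership = NULL, reference = NULL) {
  if (inherits(x, "cd_model")) { membership <- x$layer_of_atom; x <- x$structure }
  if (is.null(membership)) membership <- .layer_membership(x)
  a <- x$atoms
  lay <- membership[as.character(a$serial)]
  layers <- sort(unique(stats::na.omit(lay)))
  if (length(layers) == 0) stop("no layer membership found")
  if (is.null(reference)) reference <- layers[(length(layers) + 1) %/% 2]
  res <- lapply(layers, function(l) {
    sel <- which(lay == l & a$element == "C")
    if (length(sel) < 3) stop("layer ", l, " has fewer than 3 carbons")
    pl <- fit_plane(as.matrix(a[sel, c("x", "y", "z")]))
    data.frame(layer = l, cx = pl$centroid[1], cy = pl$centroid[2],
               cz = pl$centroid[3], nx = pl$normal[1],
               ny = pl$normal[2], nz = pl$normal[3],
               undulation = pl$rms)
  })
  out <- do.call(rbind, res)
  # sign-align all normals with the reference layer
  rn <- as.numeric(out[out$layer == reference, c("nx", "ny", "nz")])
  flip <- as.matrix(out[, c("nx", "ny", "nz")]) %*% rn < 0
  out[flip, c("nx", "ny", "nz")] <- -out[flip, c("nx", "ny", "nz")]
  attr(out, "reference") <- reference
  out
}

# rotation markers: layer centroid -> the two lowest-serial perimeter
# carbons (the second fixes the normal's sign by internal handedness)
.layer_marker <- function(x, membership, layer) {
  a <- x$atoms
  lay <- membership[as.character(a$serial)]
  sel <- which(lay == layer & has_tag(x, "perimeter"))
  if (length(sel) < 2) sel <- which(lay == layer & a$element == "C")
  sel[order(a$serial[sel])[1:2]]
}

#' Carbon-dot shape descriptors over a trajectory
#'
#' Per frame and per layer: interlayer distance of adjacent layer
#' centroids projected on the reference normal, tilt angle versus the
#' reference layer, in-plane rotation versus frame 0 (measured on the
#' marker direction from the layer centroid to its lowest-serial
#' perimeter carbon), lateral centroid offset perpendicular to the
#' reference normal, and undulation.
#'
#' @param traj a `trajectory` of a carbon dot (layer tags required).
#' @param membership optional serial -> layer map.
#' @param reference reference layer; defaults to the middle layer (an
#'   even layer count requires an explicit choice).
#' @return a `shape_timeline`: list with `layers` (long data frame:
#'   frame, layer, tilt, rotation, offset, undulation, cx, cy, cz),
#'   `interlayer` (frame, pair, distance) and `reference`.
#' @export
shape_descriptors <- function(traj, membership = NULL, reference = NULL) {
  topo <- traj$topology
  if (is.null(membership)) membership <- .layer_membership(topo)
  layers <- sort(unique(stats::na.omit(membership)))
  if (is.null(reference)) {
    if (length(layers) %% 2 == 0)
      stop("even layer count: give an explicit reference layer")
    reference <- layers[(length(layers) + 1) %/% 2]
  }
  marker_idx <- t(vapply(layers, function(l)
    .layer_marker(topo, membership, l), integer(2)))
  iref <- match(reference, layers)
  rot0 <- NULL
  lay_rows <- list(); il_rows <- list()
  for (k in seq_len(n_frames(traj))) {
    st <- frame_structure(traj, k - 1)
    fl <- fit_layers(st, membership, reference)
    nref <- as.numeric(fl[fl$layer == reference, c("nx", "ny", "nz")])
    cref <- as.numeric(fl[fl$layer == reference, c("cx", "cy", "cz")])
    xyz <- coords(st)
    # marker of the reference layer: the internal azimuth origin, so
    # that all rotation angles are invariant to global rigid motion
    mref <- xyz[marker_idx[iref, 1], ] - cref
    if (is.null(rot0)) rot0 <- numeric(length(layers))
    for (i in seq_along(layers)) {
      l <- layers[i]
      row <- fl[fl$layer == l, ]
      nl <- as.numeric(row[c("nx", "ny", "nz")])
      cl <- as.numeric(row[c("cx", "cy", "cz")])
      tilt <- acos(min(1, abs(sum(nl * nref)))) * 180 / pi
      dvec <- cl - cref
      offset <- .norm3(dvec - sum(dvec * nref) * nref)
      # in-plane marker direction, measured against the reference
      # layer's marker projected into this layer's plane; the normal's
      # sign is fixed internally (handedness of the two markers) so
      # the signed angle is invariant to global rigid motion
      m1 <- xyz[marker_idx[i, 1], ] - cl
      m2 <- xyz[marker_idx[i, 2], ] - cl
      if (sum(nl * .cross3(m1, m2)) < 0) nl <- -nl
      m <- .unit(m1 - sum(m1 * nl) * nl)
      mr <- .unit(mref - sum(mref * nl) * nl)
      ang <- .signed_angle(mr, m, nl) * 180 / pi
      if (k == 1) {
        rot0[i] <- ang
        rot <- 0
      } else {
        rot <- .wrap180(ang - rot0[i])
      }
      lay_rows[[length(lay_rows) + 1]] <- data.frame(
        frame = k - 1, layer = l, tilt = tilt, rotation = rot,
        offset = offset, undulation = row$undulation,
        cx = cl[1], cy = cl[2], cz = cl[3])
    }
    cen <- as.matrix(fl[, c("cx", "cy", "cz")])
    for (i in seq_len(length(layers) - 1)) {
      il_rows[[length(il_rows) + 1]] <- data.frame(
        frame = k - 1,
        pair = sprintf("%d-%d", layers[i], layers[i + 1]),
        distance = abs(sum((cen[i + 1, ] - cen[i, ]) * nref)))
    }
  }
  structure(list(layers = do.call(rbind, lay_rows),
                 interlayer = do.call(rbind, il_rows),
                 reference = reference),
            class = "shape_timeline")
}

#' @export
print.shape_timeline <- function(x, ...) {
  cat(sprintf("shape_timeline: %d frames, %d layers (reference %d)\n",
              length(unique(x$layers$frame)),
              length(unique(x$layers$layer)), x$reference))
  invisible(x)
}

#' Detect layer-detachment events
#'
#' An outer layer is detached when its nearest-neighbour centroid
#' distance exceeds `threshold` for at least `persistence` consecutive
#' frames; the event is reported at the first such frame.
#'
#' @param timeline a `shape_timeline`.
#' @param threshold nm (default 0.60; must exceed the built spacing).
#' @param persistence minimum consecutive frames (default 5).
#' @return data frame with `layer` and `frame` (0-based onset), empty
#'   if no event.
#' @export
detect_detachment <- function(timeline, threshold = 0.60,
                              persistence = 5) {
  ly <- timeline$layers
  layers <- sort(unique(ly$layer))
  frames <- sort(unique(ly$frame))
  cen <- array(NA_real_, c(length(frames), length(layers), 3))
  for (i in seq_along(layers)) {
    rows <- ly[ly$layer == layers[i], ]
    rows <- rows[order(rows$frame), ]
    cen[, i, ] <- as.matrix(rows[, c("cx", "cy", "cz")])
  }
  events <- data.frame(layer = integer(), frame = integer())
  for (i in seq_along(layers)) {
    nn <- vapply(seq_along(frames), function(k) {
      d <- vapply(seq_along(layers)[-i], function(j)
        sqrt(sum((cen[k, i, ] - cen[k, j, ])^2)), 0)
      min(d)
    }, 0)
    over <- nn > threshold
    run <- rle(over)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    hit <- which(run$values & run$lengths >= persistence)
    if (length(hit) > 0)
      events <- rbind(events,
                      data.frame(layer = layers[i],
                                 frame = frames[starts[hit[1]]]))
  }
  events
}
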