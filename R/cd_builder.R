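# Layered graphitic carbon-dot construction: hexagonal polyaromatic
# flakes (coronene n = 2, circumcoronene n = 3, ...), vertical stacking,
# and charged edge functionalization.

#' Build a hexagonal polyaromatic flake
#'
#' Generates a D6h-symmetric graphene fragment of ring order `n`: all
#' hexagons within hexagonal (ring) distance `n - 1` of a central hexagon.
#' This gives `6 n^2` carbons and `6 n` perimeter C-H hydrogens (n = 2 is
#' coronene C24H12, n = 3 circumcoronene C54H18).  The flake lies in the
#' z = 0 plane; edge carbons (two carbon neighbours) carry their hydrogen
#' along the in-plane bisector of the missing bond.
#'
#' @param n ring order, integer >= 1.
#' @param cc_bond carbon-carbon bond length, nm (default 0.142).
#' @param ch_bond carbon-hydrogen bond length, nm (default 0.109).
#' @return a `mol_structure` with C-C and C-H bonds; perimeter carbons
#'   are tagged `"perimeter"` and H-bearing carbons `"edge"`.
#' @export
build_flake <- function(n, cc_bond = 0.142, ch_bond = 0.109) {
  if (length(n) != 1 || n < 1 || n != round(n))
    stop("ring order n must be a positive integer")
  a1 <- sqrt(3) * cc_bond * c(1, 0)
  a2 <- sqrt(3) * cc_bond * c(0.5, sqrt(3) / 2)
  k <- n - 1
  centers <- list()
  for (q in -k:k) for (r in -k:k) {
    if ((abs(q) + abs(r) + abs(q + r)) / 2 <= k)
      centers[[length(centers) + 1]] <- q * a1 + r * a2
  }
  # hexagon vertices at angles 30 + 60 j degrees, radius cc_bond
  ang <- (30 + 60 * 0:5) * pi / 180
  verts <- do.call(rbind, lapply(centers, function(cen) {
    cbind(cen[1] + cc_bond * cos(ang), cen[2] + cc_bond * sin(ang))
  }))
  key <- paste(round(verts[, 1] / cc_bond * 1e6),
               round(verts[, 2] / cc_bond * 1e6))
  carbons <- verts[!duplicated(key), , drop = FALSE]
  nc <- nrow(carbons)
  stopifnot(nc == 6 * n^2)

  # C-C bonds by distance
  d2 <- as.matrix(dist(carbons))
  nbr <- d2 < cc_bond * 1.1 & d2 > 1e-9
  deg <- rowSums(nbr)

  atoms <- data.frame(
    serial = seq_len(nc),
    name = paste0("C", seq_len(nc)), element = "C",
    resno = 1L, resname = "CDF", chain = "X",
    x = carbons[, 1], y = carbons[, 2], z = 0,
    stringsAsFactors = FALSE)
  bonds <- which(nbr & upper.tri(nbr), arr.ind = TRUE)
  colnames(bonds) <- NULL

  # hydrogens on 2-coordinate carbons, along the bisector away from the ring
  edge_idx <- which(deg == 2)
  h <- lapply(edge_idx, function(i) {
    nb <- which(nbr[i, ])
    dir <- carbons[i, ] - colMeans(carbons[nb, , drop = FALSE])
    carbons[i, ] + dir / sqrt(sum(dir^2)) * ch_bond
  })
  nh <- length(h)
  stopifnot(nh == 6 * n)
  hmat <- do.call(rbind, h)
  hat <- data.frame(
    serial = nc + seq_len(nh),
    name = paste0("H", seq_len(nh)), element = "H",
    resno = 1L, resname = "CDF", chain = "X",
    x = hmat[, 1], y = hmat[, 2], z = 0,
    stringsAsFactors = FALSE)
  bonds <- rbind(bonds, cbind(edge_idx, nc + seq_len(nh)))

  st <- mol_structure(rbind(atoms, hat), bonds = bonds,
                      title = sprintf("flake n=%d (C%dH%d)", n, nc, nh))
  st <- add_tag(st, edge_idx, "edge")
  # perimeter = H-bearing carbons plus junction carbons between them
  junction <- which(deg == 3 &
                      vapply(seq_len(nc),
                             function(i) sum(deg[which(nbr[i, ])] == 2) >= 2,
                             logical(1)))
  st <- add_tag(st, sort(unique(c(edge_idx, junction))), "perimeter")
  st
}

#' Stack flakes into a layered carbon-dot model
#'
#' Layers are centred on a common z axis, layer `k` (0-based) at
#' `z = k * spacing`.  By default adjacent layers are laterally shifted by
#' half a C-C bond (AB-like registry); `registry = "AA"` stacks eclipsed.
#'
#' @param layer_ring_orders integer vector of flake ring orders, e.g.
#'   `c(2, 3, 3, 3, 2)` for the five-layer dot or
#'   `c(3, 4, 5, 5, 5, 4, 3)` for the seven-layer dot.
#' @param spacing interlayer spacing, nm (graphitic default 0.35; must
#'   exceed 0.30).
#' @param registry `"AB"` (default) or `"AA"`.
#' @param cc_bond,ch_bond bond lengths, nm.
#' @return a `cd_model`: list with `structure` (atoms tagged
#'   `"layer:k"`), `layer_of_atom` (serial -> layer), and an empty
#'   `functional_sites` table.
#' @export
stack_layers <- function(layer_ring_orders, spacing = 0.35,
                         registry = c("AB", "AA"),
                         cc_bond = 0.142, ch_bond = 0.109) {
  registry <- match.arg(registry)
  if (length(layer_ring_orders) == 0) stop("no layers specified")
  if (spacing <= 0.30) stop("interlayer spacing must exceed 0.30 nm")
  st <- NULL
  for (k in seq_along(layer_ring_orders) - 1) {
    fl <- build_flake(layer_ring_orders[k + 1], cc_bond, ch_bond)
    xyz <- coords(fl)
    xyz[, 3] <- xyz[, 3] + k * spacing
    if (registry == "AB" && k %% 2 == 1) xyz[, 1] <- xyz[, 1] + cc_bond / 2
    fl <- set_coords(fl, xyz)
    fl$atoms$resno <- k + 1L
    fl <- add_tag(fl, seq_len(nrow(fl$atoms)), paste0("layer:", k))
    st <- if (is.null(st)) fl else merge_structures(st, fl)
  }
  st$title <- sprintf("CD [%s]", paste(layer_ring_orders, collapse = ","))
  layer_of_atom <- as.integer(sub("^.*layer:(\\d+).*$", "\\1",
                                  st$atoms$tag))
  names(layer_of_atom) <- st$atoms$serial
  structure(list(structure = st, layer_of_atom = layer_of_atom,
                 layer_ring_orders = as.integer(layer_ring_orders),
                 spacing = spacing,
                 functional_sites = data.frame(layer = integer(),
                                               serial = integer(),
                                               group = character())),
            class = "cd_model")
}

#' @export
print.cd_model <- function(x, ...) {
  cat(sprintf("cd_model: %d layers [%s], %d atoms, net charge %+d e\n",
              length(x$layer_ring_orders),
              paste(x$layer_ring_orders, collapse = ","),
              nrow(x$structure$atoms), cd_net_charge(x)))
  invisible(x)
}

#' Net formal charge of a carbon-dot model (e)
#' @param cd a `cd_model`.
#' @return integer net charge.
#' @export
cd_net_charge <- function(cd) sum(cd$structure$atoms$charge)

# geometry constants for the grafted groups (nm)
.func_geom <- list(
  "NH3+" = list(cx = 0.147, charge = +1L),
  "COO-" = list(cx = 0.152, co = 0.126, charge = -1L))

#' Functionalize carbon-dot edge sites
#'
#' Replaces edge C-H hydrogens by charged groups.  Sites are drawn
#' uniformly without replacement with the given seed.  `NH3+`: N along
#' the former C-H vector (C-N 0.147 nm) with three tetrahedral
#' hydrogens, formal charge +1 on N.  `COO-`: carboxyl C along the C-H
#' vector (C-C 0.152 nm), two O at 120 degrees (C-O 0.126 nm), formal
#' charge -1 on one oxygen.
#'
#' The `coverage` alternative requests `round(coverage * n_perimeter)`
#' groups, where the denominator counts all perimeter carbons (H-bearing
#' and junction); printed group counts in build recipes should use
#' `count`, which is authoritative.
#'
#' @param cd a `cd_model`.
#' @param group `"NH3+"` or `"COO-"`.
#' @param count number of groups; exactly one of `count`/`coverage`.
#' @param coverage fraction of perimeter carbons (e.g. 0.10).
#' @param seed integer RNG seed for site selection.
#' @return the functionalized `cd_model` with updated charges and
#'   `functional_sites`.
#' @export
functionalize <- function(cd, group = c("NH3+", "COO-"), count = NULL,
                          coverage = NULL, seed = 1) {
  group <- match.arg(group)
  st <- cd$structure
  if (is.null(count) == is.null(coverage))
    stop("give exactly one of count or coverage")
  if (!is.null(coverage)) {
    n_perim <- sum(has_tag(st, "perimeter"))
    count <- round(coverage * n_perim)
  }
  if (count == 0) return(cd)
  edge_c <- which(has_tag(st, "edge"))
  # edge carbons that still carry an H
  hser <- st$atoms$serial[st$atoms$element == "H"]
  bonded_h <- function(ci) {
    s <- st$atoms$serial[ci]
    b <- st$bonds
    hs <- c(b[b[, 1] == s & b[, 2] %in% hser, 2],
            b[b[, 2] == s & b[, 1] %in% hser, 1])
    hs[1]
  }
  avail <- edge_c[!is.na(vapply(edge_c, bonded_h, numeric(1)))]
  if (count > length(avail))
    stop("requested ", count, " groups but only ", length(avail),
         " edge sites available")
  old <- .restore_seed()
  set.seed(seed)
  sites <- sort(sample(avail, count))
  .put_seed(old)

  geom <- .func_geom[[group]]
  new_atoms <- list(); drop_serials <- integer(); new_bonds <- list()
  ns <- max(st$atoms$serial)
  for (ci in sites) {
    cpos <- as.numeric(st$atoms[ci, c("x", "y", "z")])
    hs <- bonded_h(ci)
    hrow <- which(st$atoms$serial == hs)
    hpos <- as.numeric(st$atoms[hrow, c("x", "y", "z")])
    u <- .unit(hpos - cpos)          # former C-H direction, in plane
    layer <- cd$layer_of_atom[as.character(st$atoms$serial[ci])]
    drop_serials <- c(drop_serials, hs)
    # local axes: u in plane, w out of plane, v completes
    w <- c(0, 0, 1)
    v <- .unit(.cross3(w, u))
    if (group == "NH3+") {
      npos <- cpos + u * geom$cx
      # three H tetrahedral about the C-N axis
      hh <- lapply(0:2, function(j) {
        dir <- u * cos(109.5 * pi / 180) +
          (v * cos(2 * pi * j / 3) + w * sin(2 * pi * j / 3)) *
            sin(109.5 * pi / 180)
        npos + dir * 0.101
      })
      ids <- ns + 1:4
      new_atoms[[length(new_atoms) + 1]] <- data.frame(
        serial = ids,
        name = c("NZ", "HZ1", "HZ2", "HZ3"),
        element = c("N", "H", "H", "H"),
        resno = st$atoms$resno[ci], resname = "CDF", chain = "X",
        x = c(npos[1], hh[[1]][1], hh[[2]][1], hh[[3]][1]),
        y = c(npos[2], hh[[1]][2], hh[[2]][2], hh[[3]][2]),
        z = c(npos[3], hh[[1]][3], hh[[2]][3], hh[[3]][3]),
        charge = c(1L, 0L, 0L, 0L),
        radius = .lookup_vdw(c("N", "H", "H", "H")),
        tag = paste0("layer:", layer, ";func:NH3+"),
        stringsAsFactors = FALSE)
      new_bonds[[length(new_bonds) + 1]] <-
        rbind(c(st$atoms$serial[ci], ids[1]),
              cbind(ids[1], ids[2:4]))
    } else {
      cxpos <- cpos + u * geom$cx
      o1 <- cxpos + (u * cos(120 * pi / 180) + v * sin(120 * pi / 180)) *
        geom$co
      o2 <- cxpos + (u * cos(120 * pi / 180) - v * sin(120 * pi / 180)) *
        geom$co
      ids <- ns + 1:3
      new_atoms[[length(new_atoms) + 1]] <- data.frame(
        serial = ids, name = c("CX", "OX1", "OX2"),
        element = c("C", "O", "O"),
        resno = st$atoms$resno[ci], resname = "CDF", chain = "X",
        x = c(cxpos[1], o1[1], o2[1]),
        y = c(cxpos[2], o1[2], o2[2]),
        z = c(cxpos[3], o1[3], o2[3]),
        charge = c(0L, -1L, 0L),
        radius = .lookup_vdw(c("C", "O", "O")),
        tag = paste0("layer:", layer, ";func:COO-"),
        stringsAsFactors = FALSE)
      new_bonds[[length(new_bonds) + 1]] <-
        rbind(c(st$atoms$serial[ci], ids[1]),
              cbind(ids[1], ids[2:3]))
    }
    ns <- ns + nrow(new_atoms[[length(new_atoms)]])
    cd$functional_sites <- rbind(
      cd$functional_sites,
      data.frame(layer = layer, serial = st$atoms$serial[ci],
                 group = group))
  }
  keep <- !(st$atoms$serial %in% drop_serials)
  atoms <- rbind(st$atoms[keep, setdiff(names(st$atoms), "rindex")],
                 do.call(rbind, new_atoms))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]  # keep layers contiguous
  bonds <- st$bonds[!(st$bonds[, 1] %in% drop_serials |
                        st$bonds[, 2] %in% drop_serials), , drop = FALSE]
  bonds <- rbind(bonds, do.call(rbind, new_bonds))
  st2 <- mol_structure(atoms, bonds = bonds, title = st$title)
  cd$structure <- st2
  loa <- as.integer(sub("^.*layer:(\\d+).*$", "\\1", st2$atoms$tag))
  names(loa) <- st2$atoms$serial
  cd$layer_of_atom <- loa
  cd
}

# save/restore the global RNG state so seeded helpers do not disturb it
.restore_seed <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.put_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Effective dimensions and net charge of a carbon-dot model
#'
#' Height = distance between the mean planes of the outermost layers plus
#' the carbon vdW diameter (0.34 nm).  Diameter = largest in-plane
#' carbon-carbon distance within the widest layer plus 0.34 nm.
#' Atom-centre extents are reported alongside.
#'
#' @param cd a `cd_model`.
#' @return list with `height`, `diameter` (nm, vdW-augmented),
#'   `core_height`, `core_diameter` (atom-centre extents) and
#'   `net_charge` (e).
#' @export
cd_dimensions <- function(cd) {
  st <- cd$structure
  carb <- st$atoms$element == "C" & !has_tag(st, "func:COO-")
  lay <- cd$layer_of_atom[carb]
  z_by_layer <- tapply(st$atoms$z[carb], lay, mean)
  core_h <- max(z_by_layer) - min(z_by_layer)
  diam <- 0
  for (l in unique(lay)) {
    xy <- as.matrix(st$atoms[carb, c("x", "y")])[lay == l, , drop = FALSE]
    d <- max(dist(xy))
    if (d > diam) diam <- d
  }
  list(height = core_h + .carbon_vdw_diameter,
       diameter = diam + .carbon_vdw_diameter,
       core_height = core_h, core_diameter = diam,
       net_charge = cd_net_charge(cd))
}
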