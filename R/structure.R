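# Core containers: mol_structure (ordered atom table + bonds) and
# trajectory (topology + coordinate frames).  Style follows bio3d: plain
# lists with a class attribute and data.frame atom tables.

#' Create a molecular structure
#'
#' The central container of the package: an ordered atom table plus an
#' optional covalent bond list.  Coordinates are in nanometres.
#'
#' @param atoms data.frame with columns `serial` (unique positive integer),
#'   `name` (atom name), `element` (chemical symbol), `resno` (1-based
#'   residue index within its chain), `resname`, `chain` (single
#'   character), `x`, `y`, `z` (nm), and optionally `charge` (integer
#'   formal charge, e), `radius` (vdW radius, nm) and `tag`
#'   (semicolon-separated free-form tags such as `"layer:2"` or
#'   `"func:NH3+"`).  Missing optional columns are filled with defaults;
#'   radii come from [vdw_radii_nm].
#' @param bonds two-column integer matrix of atom serials (unordered
#'   pairs), or `NULL`.
#' @param title character title.
#' @param pairing optional two-column matrix of global residue indices
#'   (`rindex`) giving Watson-Crick pairing; generators annotate this.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = NULL, title = "", pairing = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resno", "resname", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!("charge" %in% names(atoms))) atoms$charge <- 0L
  if (!("radius" %in% names(atoms)))
    atoms$radius <- .lookup_vdw(atoms$element)
  if (!("tag" %in% names(atoms))) atoms$tag <- ""
  atoms$tag[is.na(atoms$tag)] <- ""
  # global residue index in order of appearance (chain + resno)
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  atoms$rindex <- match(key, unique(key))
  rownames(atoms) <- NULL
  x <- structure(list(atoms = atoms, bonds = bonds, title = title,
                      pairing = pairing),
                 class = "mol_structure")
  validate_structure(x)
  x
}

#' Validate a molecular structure
#'
#' Checks the container invariants: unique serials, finite coordinates,
#' positive radii, known elements, bond endpoints present and residue
#' numbering non-decreasing within each chain.
#'
#' @param x a `mol_structure`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_structure <- function(x) {
  a <- x$atoms
  if (nrow(a) == 0) stop("structure has no atoms")
  if (anyDuplicated(a$serial)) stop("atom serials are not unique")
  if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates")
  if (!all(a$radius > 0)) stop("non-positive vdW radius")
  bad <- setdiff(unique(a$element), .known_elements)
  if (length(bad) > 0)
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(r)) stop("residue numbering decreases within chain ", ch)
  }
  if (!is.null(x$bonds) && length(x$bonds) > 0) {
    if (!all(x$bonds %in% a$serial)) stop("bond endpoint not in atom table")
  }
  invisible(x)
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("mol_structure: %d atoms, %d residues, %d chain(s)%s\n",
              nrow(a), max(a$rindex), length(unique(a$chain)),
              if (nzchar(x$title)) paste0("  [", x$title, "]") else ""))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix (nm)
#' @param x a `mol_structure`.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param x a `mol_structure`.
#' @param xyz n x 3 matrix, nm.
#' @return the modified structure.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(nrow(xyz) == nrow(x$atoms), ncol(xyz) == 3)
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Test atoms for a tag
#' @param x a `mol_structure`.
#' @param tag tag string, e.g. `"layer:2"`.
#' @return logical vector over atoms.
#' @export
has_tag <- function(x, tag) {
  vapply(strsplit(x$atoms$tag, ";", fixed = TRUE),
         function(t) tag %in% t, logical(1))
}

#' Add a tag to a subset of atoms
#' @param x a `mol_structure`.
#' @param idx logical or integer atom row index.
#' @param tag tag string to append.
#' @return the modified structure.
#' @export
add_tag <- function(x, idx, tag) {
  cur <- x$atoms$tag[idx]
  x$atoms$tag[idx] <- ifelse(nzchar(cur), paste(cur, tag, sep = ";"), tag)
  x
}

#' Concatenate two structures
#'
#' Atom serials of `b` are shifted above those of `a`; chains are kept as
#' is (callers should ensure chain ids do not collide when that matters).
#'
#' @param a,b `mol_structure` objects.
#' @return combined `mol_structure`; pairing annotation of `a` is kept.
#' @export
merge_structures <- function(a, b) {
  off <- max(a$atoms$serial)
  bb <- b$atoms
  bb$serial <- bb$serial + off
  bonds <- rbind(a$bonds, if (!is.null(b$bonds)) b$bonds + off)
  at <- rbind(a$atoms[setdiff(names(a$atoms), "rindex")],
              bb[setdiff(names(bb), "rindex")])
  mol_structure(at, bonds = bonds,
                title = paste(a$title, b$title, sep = " + "),
                pairing = a$pairing)
}

#' Create a trajectory
#'
#' @param topology a `mol_structure`.
#' @param frames list of n x 3 coordinate matrices (nm), or a 3-d array
#'   `c(n_atoms, 3, n_frames)`.
#' @param times frame times in ns; defaults to `0, 1, 2, ...`.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  n <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) nrow(f) == n && ncol(f) == 3, logical(1))
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames) || is.unsorted(times, strictly = TRUE))
    stop("frame_times must be strictly increasing, one per frame")
  structure(list(topology = topology, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

#' Extract one frame of a trajectory as a structure
#' @param x a `trajectory`.
#' @param i frame index, 0-based (frames are 0-based throughout).
#' @return a `mol_structure` with that frame's coordinates.
#' @export
frame_structure <- function(x, i) {
  stopifnot(i >= 0, i < length(x$frames))
  set_coords(x$topology, x$frames[[i + 1]])
}
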