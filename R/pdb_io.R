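# PDB and XYZ file I/O.  Parsing/writing of PDB records is delegated to
# bio3d; this layer adds validation with line numbers, multi-model
# trajectory handling, formal-charge columns and the A <-> nm conversion
# (file format is in Angstrom, the package works in nm).

.pdb_atom_lines <- function(lines) grepl("^(ATOM  |HETATM)", lines)

#' Read a PDB file
#'
#' Single-model files yield a [mol_structure()]; files with multiple
#' MODEL/ENDMDL blocks yield a [trajectory()].  Coordinates are converted
#' from Angstrom to nm.  Formal charges are taken from PDB columns 79-80
#' when present.  Atoms with an altloc other than blank or `'A'` are
#' dropped with a warning.  ATOM and HETATM records are treated alike.
#'
#' @param path file path.
#' @param vdw named radius table (nm) used to assign `radius`.
#' @return `mol_structure` or `trajectory`.
#' @export
read_pdb <- function(path, vdw = vdw_radii_nm) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_at <- .pdb_atom_lines(lines)
  if (!any(is_at)) stop("no ATOM/HETATM records in ", path)
  # validate coordinate fields, reporting the first bad line number
  for (i in which(is_at)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinates at line ", i)
  }
  # consistent atom counts across MODEL blocks
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(is_at[s:e]), model_starts, ends)
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count across models: ",
           paste(unique(counts), collapse = ", "))
  }

  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  # altloc filtering
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(alt_ok)) {
    warning(sum(!alt_ok), " atom(s) with altloc other than blank/'A' dropped")
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- trimws(elem)
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | !nzchar(elem)] <- guess[is.na(elem) | !nzchar(elem)]
  elem <- paste0(substr(elem, 1, 1),
                 tolower(substr(elem, 2, 2)))
  chg <- rep(0L, nrow(at))
  if (!is.null(at$charge)) {
    cc <- as.character(at$charge)
    m <- regmatches(cc, regexpr("^[0-9]+[+-]$", cc))
    has <- !is.na(cc) & nzchar(cc) & grepl("^[0-9]+[+-]$", cc)
    chg[has] <- as.integer(substr(cc[has], 1, nchar(cc[has]) - 1)) *
      ifelse(substr(cc[has], nchar(cc[has]), nchar(cc[has])) == "-", -1L, 1L)
  }
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    resno = at$resno, resname = trimws(at$resid), chain = chain,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    charge = chg, stringsAsFactors = FALSE)
  atoms <- atoms[alt_ok, , drop = FALSE]
  atoms$radius <- .lookup_vdw(atoms$element, vdw)
  title <- basename(path)
  st <- mol_structure(atoms, title = title)

  nmod <- max(1L, nrow(p$xyz))
  if (length(model_starts) > 1 && nmod > 1) {
    frames <- lapply(seq_len(nmod), function(k) {
      m <- matrix(p$xyz[k, ], ncol = 3, byrow = TRUE) / 10
      m[alt_ok, , drop = FALSE]
    })
    st <- set_coords(st, frames[[1]])
    return(trajectory(st, frames))
  }
  st
}

#' Write a PDB file
#'
#' Accepts a [mol_structure()] (single model) or a [trajectory()]
#' (MODEL/ENDMDL blocks).  nm coordinates are written in Angstrom; formal
#' charges are emitted in columns 79-80.  Round trip through [read_pdb()]
#' preserves coordinates to 1e-4 nm (the PDB precision) and residue/chain
#' metadata exactly.
#'
#' @param x structure or trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "trajectory")) {
    topo <- x$topology
    frames <- x$frames
  } else {
    validate_structure(x)
    topo <- x
    frames <- list(coords(x))
  }
  a <- topo$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  if (nrow(a) > 99999) stop("more than 99999 atoms: serial field overflow")
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f * 10))))
  pdb <- list(
    atom = data.frame(
      type = "ATOM", eleno = a$serial, elety = a$name, alt = NA,
      resid = a$resname, chain = a$chain, resno = a$resno, insert = NA,
      x = frames[[1]][, 1] * 10, y = frames[[1]][, 2] * 10,
      z = frames[[1]][, 3] * 10,
      o = 1, b = 0, segid = NA, elesy = a$element, charge = NA,
      stringsAsFactors = FALSE),
    xyz = bio3d::as.xyz(xyz), calpha = rep(FALSE, nrow(a)))
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, xyz = pdb$xyz, file = path)
  # splice formal charges into columns 79-80 (bio3d leaves them blank)
  if (any(a$charge != 0)) {
    lines <- readLines(path, warn = FALSE)
    ai <- which(.pdb_atom_lines(lines))
    per <- length(ai) / length(frames)
    chgstr <- ifelse(a$charge == 0, "  ",
                     paste0(abs(a$charge),
                            ifelse(a$charge > 0, "+", "-")))
    for (k in seq_along(frames)) {
      idx <- ai[((k - 1) * per + 1):(k * per)]
      ln <- lines[idx]
      ln <- sprintf("%-78s", ln)
      substr(ln, 79, 80) <- chgstr
      lines[idx] <- ln
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an XYZ file (possibly concatenated frames)
#'
#' Plain XYZ: atom count line, comment line, then `element x y z` rows in
#' Angstrom.  Concatenated blocks become a trajectory.
#'
#' @param path file path.
#' @param template optional `mol_structure` supplying residue/chain
#'   metadata (element order must match).
#' @return `mol_structure` or `trajectory`.
#' @export
read_xyz <- function(path, template = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elems <- NULL; i <- 1
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad atom-count line at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, character(1), 1)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
    if (is.null(elems)) elems <- el
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  if (!is.null(template)) {
    st <- set_coords(template, frames[[1]])
  } else {
    st <- mol_structure(data.frame(
      serial = seq_along(elems), name = elems, element = elems,
      resno = 1L, resname = "UNK", chain = "A",
      x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
      stringsAsFactors = FALSE))
  }
  if (length(frames) > 1) return(trajectory(st, frames))
  st
}

#' Write an XYZ file (concatenated frames for trajectories)
#' @param x structure or trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "trajectory")) {
    topo <- x$topology; frames <- x$frames
  } else {
    topo <- x; frames <- list(coords(x))
  }
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]] * 10
    writeLines(c(as.character(nrow(topo$atoms)),
                 sprintf("frame %d", k - 1),
                 sprintf("%-2s %12.6f %12.6f %12.6f",
                         topo$atoms$element, f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}
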