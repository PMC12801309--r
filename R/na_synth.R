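# Synthetic nucleic-acid generator: idealized duplexes built from
# embedded standard-frame templates placed by accumulated helical
# parameters, nucleosomal superhelix DNA, a minimal two-tetrad
# G-quadruplex mock, and noisy trajectories with planted binding events.

.complement <- c(A = "T", T = "A", C = "G", G = "C", U = "A")
.complement_rna <- c(A = "U", U = "A", C = "G", G = "C")

.resname_for <- function(base, form) {
  if (form == "B-DNA") paste0("D", base) else base
}
.base_letter <- function(resname) sub("^D", "", resname)

# atoms of one residue (backbone + base) in the global frame `fr`
.residue_atoms <- function(base, form, fr, with_p = TRUE) {
  bb <- if (form == "B-DNA") .bb_B else .bb_A
  bt <- .base_templates[[base]]
  anchor_shift <- if (.is_purine(base)) c(0, 0, 0) else
    bt[if (base %in% c("C", "T", "U")) "N1" else "N9", ] - .bb_anchor_N
  bbl <- sweep(bb, 2, -anchor_shift)
  if (!with_p) bbl <- bbl[rownames(bbl) != "P", , drop = FALSE]
  tpl <- rbind(bbl, bt)
  xyz <- sweep(tpl %*% t(fr$R), 2, -fr$o)
  elem <- substr(rownames(tpl), 1, 1)
  data.frame(name = rownames(tpl), element = elem,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             is_base = rownames(tpl) %in% rownames(bt),
             stringsAsFactors = FALSE)
}

# Assemble a (possibly bent) duplex from a list of base-pair frames.
# overhang3: that many trailing letters of `letters` are strand-I-only
# (unpaired), continuing the helix without a partner.
.assemble_duplex <- function(bp_frames, letters, form,
                             propeller = 0, buckle = 0, shear = 0,
                             overhang3 = 0, title = "duplex") {
  n <- length(letters)
  npair <- n - overhang3
  comp <- if (form == "B-DNA") .complement else .complement_rna
  prop <- rep(propeller, length.out = n)
  buck <- rep(buckle, length.out = n)
  shr <- rep(shear, length.out = n)
  rows1 <- vector("list", n); rows2 <- vector("list", npair)
  for (i in seq_len(n)) {
    pf <- pair_frames(bp_frames[[i]], shear = shr[i],
                      buckle = buck[i], propeller = prop[i])
    rs1 <- .residue_atoms(letters[i], form, pf$base1, with_p = (i > 1))
    rs1$resno <- i; rs1$chain <- "A"
    rs1$resname <- .resname_for(letters[i], form)
    rows1[[i]] <- rs1
    if (i <= npair) {
      b2 <- comp[letters[i]]
      # strand II residue j runs 5'->3' opposite to strand I
      j <- npair - i + 1
      rs2 <- .residue_atoms(b2, form, pf$base2, with_p = (i < npair))
      rs2$resno <- j; rs2$chain <- "B"
      rs2$resname <- .resname_for(b2, form)
      rows2[[i]] <- rs2
    }
  }
  at1 <- do.call(rbind, rows1)
  at2 <- do.call(rbind, rows2)
  at2 <- at2[order(at2$resno), , drop = FALSE]
  at <- rbind(at1, at2)
  at$serial <- seq_len(nrow(at))
  at$tag <- ifelse(at$is_base, "base", "backbone")
  at$is_base <- NULL
  st <- mol_structure(at, title = title)
  # residue-level tags
  for (i in seq_len(n)) {
    if (i > npair) {
      st <- add_tag(st, st$atoms$chain == "A" & st$atoms$resno == i,
                    "unpaired")
    }
  }
  term <- c(1L, npair)
  for (i in term) {
    st <- add_tag(st, (st$atoms$chain == "A" & st$atoms$resno == i) |
                    (st$atoms$chain == "B" &
                       st$atoms$resno == npair - i + 1), "terminal")
  }
  # pairing on global residue indices
  r1 <- vapply(seq_len(npair), function(i)
    st$atoms$rindex[st$atoms$chain == "A" & st$atoms$resno == i][1], 0)
  r2 <- vapply(seq_len(npair), function(i)
    st$atoms$rindex[st$atoms$chain == "B" &
                      st$atoms$resno == npair - i + 1][1], 0)
  st$pairing <- cbind(strand1 = r1, strand2 = r2)
  st
}

#' Build an idealized nucleic-acid duplex
#'
#' Places embedded standard-frame base and reduced-backbone templates by
#' accumulated twist/rise about the z axis (the helix axis).  Per-base-
#' pair overrides of propeller, buckle and shear (intra-bp) and of the
#' step parameters are applied in the same mid-frame convention that the
#' analysis functions use, so analyzer round trips are exact on
#' noise-free output.
#'
#' @param sequence strand-I sequence 5'->3' over A, C, G, T (B-DNA) or
#'   A, C, G, U (A-RNA).
#' @param form `"B-DNA"` or `"A-RNA"`.
#' @param twist step twist in degrees; scalar or length `n-1` vector
#'   (default 34.3 for B, the 10.5 bp/turn solution value; 32.7 for A).
#' @param rise step rise in nm (default 0.338 B, 0.281 A).
#' @param shift,slide,roll,tilt step overrides, scalar or per-step.
#' @param propeller,buckle,shear intra-bp overrides, scalar or per-bp,
#'   degrees / nm.
#' @param overhang3 number of trailing strand-I bases left unpaired
#'   (tagged `"unpaired"`), continuing the helix without partners.
#' @return a `mol_structure` with chains A and B, pairing annotation and
#'   `"terminal"`/`"unpaired"`/`"base"`/`"backbone"` tags.
#' @export
build_duplex <- function(sequence, form = c("B-DNA", "A-RNA"),
                         twist = NULL, rise = NULL,
                         shift = 0, slide = 0, roll = 0, tilt = 0,
                         propeller = 0, buckle = 0, shear = 0,
                         overhang3 = 0) {
  form <- match.arg(form)
  letters <- strsplit(toupper(sequence), "")[[1]]
  valid <- if (form == "B-DNA") c("A", "C", "G", "T") else
    c("A", "C", "G", "U")
  bad <- setdiff(letters, valid)
  if (length(bad) > 0)
    stop("invalid base letter(s) for ", form, ": ",
         paste(unique(bad), collapse = ", "))
  n <- length(letters)
  if (n < 1) stop("empty sequence")
  if (overhang3 >= n) stop("overhang leaves no paired bases")
  if (is.null(twist)) twist <- if (form == "B-DNA") 34.3 else 32.7
  if (is.null(rise)) rise <- if (form == "B-DNA") 0.338 else 0.281
  tw <- rep(twist, length.out = n - 1)
  rs <- rep(rise, length.out = n - 1)
  sh <- rep(shift, length.out = n - 1)
  sl <- rep(slide, length.out = n - 1)
  ro <- rep(roll, length.out = n - 1)
  ti <- rep(tilt, length.out = n - 1)
  frames <- vector("list", n)
  frames[[1]] <- list(R = diag(3), o = c(0, 0, 0))
  for (i in seq_len(n - 1)) {
    frames[[i + 1]] <- frame_step(frames[[i]], twist = tw[i],
                                  roll = ro[i], tilt = ti[i],
                                  shift = sh[i], slide = sl[i],
                                  rise = rs[i])
  }
  .assemble_duplex(frames, letters, form, propeller = propeller,
                   buckle = buckle, shear = shear, overhang3 = overhang3,
                   title = sprintf("%s duplex %s", form, sequence))
}

#' Build nucleosomal superhelix DNA
#'
#' A B-DNA duplex bent along a left-handed superhelical path of the
#' given radius and pitch; base-pair origins lie exactly on the path.
#' The local twist winds the base-pair x axis about the path tangent.
#'
#' @param n_bp number of base pairs (default 146).
#' @param radius superhelix radius, nm (default 4.18).
#' @param pitch superhelix pitch, nm per turn (default 2.39).
#' @param turns superhelical turns (default 1.7); `turns = 0` gives a
#'   straight duplex.
#' @param local_twist local helical twist, degrees per step (default
#'   35.3).
#' @param sequence optional strand-I sequence (recycled "ACGT" default).
#' @param rise step rise used when `turns = 0`, nm.
#' @return a `mol_structure` with pairing annotation.
#' @export
build_superhelix_dna <- function(n_bp = 146, radius = 4.18, pitch = 2.39,
                                 turns = 1.7, local_twist = 35.3,
                                 sequence = NULL, rise = 0.338) {
  if (pitch <= 0) stop("pitch must be positive")
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"),
                          length.out = n_bp), collapse = "")
  letters <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters) != n_bp) stop("sequence length must equal n_bp")
  if (turns == 0) {
    st <- build_duplex(sequence, "B-DNA", twist = local_twist,
                       rise = rise)
    attr(st, "superhelix") <- list(straight = TRUE)
    return(st)
  }
  theta_tot <- 2 * pi * turns
  th <- seq(0, theta_tot, length.out = n_bp)
  # left-handed superhelix
  pos <- cbind(radius * cos(th), -radius * sin(th),
               pitch * th / (2 * pi))
  tang <- cbind(-radius * sin(th), -radius * cos(th),
                rep(pitch / (2 * pi), n_bp))
  frames <- vector("list", n_bp)
  psi <- (seq_len(n_bp) - 1) * local_twist * pi / 180
  for (i in seq_len(n_bp)) {
    z <- .unit(tang[i, ])
    inward <- -c(cos(th[i]), -sin(th[i]), 0)      # toward superhelix axis
    e1 <- .unit(inward - sum(inward * z) * z)
    e2 <- .cross3(z, e1)
    x <- cos(psi[i]) * e1 + sin(psi[i]) * e2
    frames[[i]] <- list(R = cbind(x, .cross3(z, x), z), o = pos[i, ])
  }
  st <- .assemble_duplex(frames, letters, "B-DNA",
                         title = sprintf("superhelix %d bp", n_bp))
  attr(st, "superhelix") <- list(straight = FALSE, radius = radius,
                                 pitch = pitch, turns = turns,
                                 path = pos)
  st
}

#' Build a minimal two-tetrad G-quadruplex mock
#'
#' Eight guanine bases arranged as two stacked planar quartets (O6
#' carbonyls inward), 0.34 nm apart with a 30 degree inter-tetrad
#' rotation.  Bases only (no backbone); residues are tagged
#' `"quartet"` and `"quartet:<t>"` per tetrad.  Intended as a stacking
#' target for tetrad-binding poses, not as a realistic quadruplex.
#'
#' @param separation inter-tetrad spacing, nm.
#' @param ring_radius distance of each guanine ring centroid from the
#'   quartet axis, nm.
#' @return a `mol_structure`.
#' @export
build_g4_mock <- function(separation = 0.34, ring_radius = 0.35) {
  bt <- .base_templates$G
  ring <- bt[.base_ring_atoms$G, ]
  cen <- colMeans(ring)
  d0 <- .unit((bt["O6", ] - cen)[1:2])
  rows <- list(); rid <- 0
  for (t in 0:1) {
    for (g in 0:3) {
      rid <- rid + 1
      ang <- (90 * g + 30 * t) * pi / 180
      u <- c(cos(ang), sin(ang))
      # rotate template so O6 points inward (-u), centroid at ring_radius*u
      beta <- atan2(-u[2], -u[1]) - atan2(d0[2], d0[1])
      R <- .rot_z(beta)
      tr <- c(ring_radius * u, t * separation) -
        as.numeric(R %*% cen)
      xyz <- sweep(bt %*% t(R), 2, -tr)
      rows[[rid]] <- data.frame(
        name = rownames(bt), element = substr(rownames(bt), 1, 1),
        resno = rid, resname = "G", chain = "G",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        tag = sprintf("base;quartet;quartet:%d", t),
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  mol_structure(at, title = "two-tetrad G-quadruplex mock")
}
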