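# Idealized nucleotide templates in the standard base reference frame
# (base in the xy plane, origin at the bp centre, x toward the major
# groove, y toward strand I sugar, z along the stack).  Coordinates in nm.
# Base heavy-atom geometries follow the standard reference frame
# convention used by 3DNA/cpptraj; the reduced backbone (P, O5', C5',
# C4', O4', C3', O3', C2', C1') is an idealized construction with
# C2'-endo (B) / C3'-endo (A) sugar pucker and canonical torsions,
# anchored on the glycosidic nitrogen.

.base_templates <- local({
  A <- matrix(c(
    -1.291, 4.498, 0.000,   # N9
     0.024, 4.897, 0.000,   # C8
     0.877, 3.902, 0.000,   # N7
     0.071, 2.771, 0.000,   # C5
     0.369, 1.398, 0.000,   # C6
     1.611, 0.909, 0.000,   # N6
    -0.668, 0.532, 0.000,   # N1
    -1.912, 1.023, 0.000,   # C2
    -2.320, 2.290, 0.000,   # N3
    -1.267, 3.124, 0.000),  # C4
    ncol = 3, byrow = TRUE)
  rownames(A) <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3",
                   "C4")
  G <- matrix(c(
    -1.289, 4.551, 0.000,   # N9
     0.023, 4.962, 0.000,   # C8
     0.870, 3.969, 0.000,   # N7
     0.071, 2.833, 0.000,   # C5
     0.424, 1.460, 0.000,   # C6
     1.554, 0.955, 0.000,   # O6
    -0.700, 0.641, 0.000,   # N1
    -1.999, 1.087, 0.000,   # C2
    -2.949, 0.139, 0.000,   # N2
    -2.342, 2.364, 0.000,   # N3
    -1.265, 3.177, 0.000),  # C4
    ncol = 3, byrow = TRUE)
  rownames(G) <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
                   "N3", "C4")
  C <- matrix(c(
    -1.285, 4.542, 0.000,   # N1
    -1.472, 3.158, 0.000,   # C2
    -2.628, 2.709, 0.000,   # O2
    -0.391, 2.344, 0.000,   # N3
     0.837, 2.868, 0.000,   # C4
     1.875, 2.027, 0.000,   # N4
     1.056, 4.275, 0.000,   # C5
    -0.023, 5.068, 0.000),  # C6
    ncol = 3, byrow = TRUE)
  rownames(C) <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
  T <- matrix(c(
    -1.284, 4.500, 0.000,   # N1
    -1.462, 3.135, 0.000,   # C2
    -2.562, 2.608, 0.000,   # O2
    -0.298, 2.407, 0.000,   # N3
     0.994, 2.897, 0.000,   # C4
     1.944, 2.119, 0.000,   # O4
     1.106, 4.338, 0.000,   # C5
     2.466, 4.961, 0.000,   # C7
    -0.024, 5.057, 0.000),  # C6
    ncol = 3, byrow = TRUE)
  rownames(T) <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
  U <- matrix(c(
    -1.284, 4.500, 0.000,   # N1
    -1.462, 3.131, 0.000,   # C2
    -2.563, 2.608, 0.000,   # O2
    -0.302, 2.397, 0.000,   # N3
     0.989, 2.884, 0.000,   # C4
     1.935, 2.094, 0.000,   # O4
     1.089, 4.311, 0.000,   # C5
    -0.024, 5.053, 0.000),  # C6
    ncol = 3, byrow = TRUE)
  rownames(U) <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  # 180-degree rotation about x (y -> -y; bases are planar in z) puts the
  # frame z axis along the strand 5'->3' direction for the backbone
  # templates below
  lapply(list(A = A, G = G, C = C, T = T, U = U),
         function(m) { m <- m / 10; m[, 2] <- -m[, 2]; m })
})

# ring atoms used for base-frame fitting
.base_ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"))

.is_purine <- function(base) base %in% c("A", "G")

# groove-edge and backbone atom name sets per base (GrooveAtomMap)
.groove_atom_map <- list(
  minor = list(A = c("C2", "N3", "O4'"), G = c("N3", "N2", "O4'"),
               C = c("O2", "O4'"), T = c("O2", "O4'"), U = c("O2", "O4'")),
  major = list(A = c("N6", "N7", "C8"), G = c("O6", "N7", "C8"),
               C = c("N4", "C5", "C6"), T = c("O4", "C5", "C7"),
               U = c("O4", "C5")),
  backbone = c("P", "OP1", "OP2", "O5'", "O3'", "C5'", "C4'", "C3'"))

# .backbone_templates is generated by a one-off geometric construction
# (pentagonal sugar ring with target pseudorotation phase, canonical
# gamma/beta/delta torsions, glycosidic attachment at the anchor
# nitrogen with anti chi) and frozen here; see the methods vignette.
# Coordinates nm, standard frame, anchored for a purine N9; pyrimidines
# reuse the template shifted by (N1 - N9_anchor).
.bb_anchor_N <- c(-0.1291, -0.4498, 0)

# Reduced sugar-phosphate backbone templates, standard frame, nm.
# Constructed once from a pentagonal sugar ring at the target
# pseudorotation phase (B: 162 deg C2'-endo, A: 18 deg C3'-endo) with an
# anti glycosidic torsion, O5'/O3' placed at canonical gamma/delta
# torsions, and P placed by helix closure (0.16 nm from the previous
# residue's O3' under the default helical step).
.bb_B <- matrix(c(
   -0.67600,  -0.60460,  -0.15482,  # P
   -0.57420,  -0.71285,  -0.10335,  # O5'
   -0.45532,  -0.75585,  -0.17230,  # C5'
   -0.33374,  -0.74308,  -0.08367,  # C4'
   -0.25539,  -0.62610,  -0.12144,  # O4'
   -0.37551,  -0.72448,   0.06111,  # C3'
   -0.36536,  -0.84779,   0.13081,  # O3'
   -0.24381,  -0.64849,   0.11453,  # C2'
   -0.24875,  -0.53520,   0.00000),  # C1'
  ncol = 3, byrow = TRUE)
rownames(.bb_B) <- c("P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")

.bb_A <- matrix(c(
   -0.53393,  -0.61987,   0.10331,  # P
   -0.46535,  -0.74883,   0.17708,  # O5'
   -0.39586,  -0.80547,   0.06439,  # C5'
   -0.25016,  -0.76583,   0.06517,  # C4'
   -0.21551,  -0.66922,  -0.04673,  # O4'
   -0.21234,  -0.67190,   0.19055,  # C3'
   -0.23898,  -0.74019,   0.31217,  # O3'
   -0.30394,  -0.54898,   0.14078,  # C2'
   -0.24875,  -0.53520,  -0.00000),  # C1'
  ncol = 3, byrow = TRUE)
rownames(.bb_A) <- c("P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")

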