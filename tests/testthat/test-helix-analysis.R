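# Base frames, helical parameters, backbone state, grooves, heatmaps.

test_that("base frames fit ideal bases exactly and are equivariant", {
  d <- fx_duplex12()
  fr <- assign_base_frames(d)
  expect_equal(length(fr), 24)
  expect_true(all(vapply(fr, function(f) f$fit_rmsd, 0) < 1e-6))
  # rigid 30-degree rotation co-rotates the triads
  R <- rot_axis(c(0, 0, 1), 30 * pi / 180)
  d2 <- set_coords(d, coords(d) %*% t(R))
  fr2 <- assign_base_frames(d2)
  expect_equal(fr2[[5]]$R, R %*% fr[[5]]$R, tolerance = 1e-9)
  # paired frames are anti-aligned along the stack before flipping
  pr <- d$pairing[4, ]
  z1 <- Filter(function(f) f$rindex == pr[1], fr)[[1]]$R[, 3]
  z2 <- Filter(function(f) f$rindex == pr[2], fr)[[1]]$R[, 3]
  expect_lt(sum(z1 * z2), -0.99)
})

test_that("generator parameters are recovered through the analyzer", {
  set.seed(21)
  for (k in 1:4) {
    tw <- runif(1, 30, 40); ri <- runif(1, 0.26, 0.36)
    d <- build_duplex("GCATGCAT", twist = tw, rise = ri,
                      propeller = -12, buckle = 4)
    p <- bp_step_params(d)
    expect_equal(mean(p$step$twist), tw, tolerance = 0.3)
    expect_equal(mean(p$step$rise), ri, tolerance = 0.005)
    expect_equal(mean(p$intra$propeller), -12, tolerance = 0.3)
    expect_equal(mean(p$intra$buckle), 4, tolerance = 0.3)
  }
  # local overrides recovered in place
  d <- build_duplex(strrep("AT", 6),
                    propeller = c(rep(0, 4), -12, rep(0, 7)),
                    shift = c(rep(0, 2), 0.05, rep(0, 8)))
  p <- bp_step_params(d)
  expect_equal(p$intra$propeller[5], -12, tolerance = 0.3)
  expect_equal(p$step$shift[3], 0.05, tolerance = 0.002)
  expect_lt(max(abs(p$intra$propeller[-5])), 1e-6)
})

test_that("helical parameters are invariant under global rigid motion", {
  d <- fx_duplex12()
  p0 <- bp_step_params(d)
  set.seed(3)
  R <- random_rotation()
  d2 <- set_coords(d, sweep(coords(d) %*% t(R), 2, -c(1, -2, 3)))
  p1 <- bp_step_params(d2)
  expect_equal(p1$step$twist, p0$step$twist, tolerance = 1e-6)
  expect_equal(p1$intra$propeller, p0$intra$propeller, tolerance = 1e-6)
  expect_equal(p1$step$shift, p0$step$shift, tolerance = 1e-6)
})

test_that("reversing strand direction negates the sign-odd parameters", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  f2 <- frame_step(f1, twist = 33, roll = 4, tilt = 2.5,
                   shift = 0.04, slide = -0.03, rise = 0.34)
  fwd <- frame_params(f1, f2)
  Fx <- diag(c(1, -1, -1))
  rev <- frame_params(list(R = f2$R %*% Fx, o = f2$o),
                      list(R = f1$R %*% Fx, o = f1$o))
  expect_equal(rev$twist, fwd$twist, tolerance = 1e-9)
  expect_equal(rev$rise, fwd$rise, tolerance = 1e-9)
  expect_equal(rev$roll, fwd$roll, tolerance = 1e-9)
  expect_equal(rev$slide, fwd$slide, tolerance = 1e-9)
  expect_equal(rev$tilt, -fwd$tilt, tolerance = 1e-9)
  expect_equal(rev$shift, -fwd$shift, tolerance = 1e-9)
})

test_that("bp_per_turn follows 360/mean(twist)", {
  expect_equal(bp_per_turn(rep(36, 10)), 10)
  expect_equal(round(bp_per_turn(rep(35.3, 5)), 1), 10.2)
  p <- bp_step_params(fx_duplex())
  expect_equal(round(bp_per_turn(p$step$twist), 1), 10.5)
  expect_warning(v <- bp_per_turn(c(-1, 1)), "undefined")
  expect_true(is.na(v))
})

test_that("backbone torsions and pucker follow their definitions", {
  # planar cis four-atom chain has zero torsion
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                        c(1, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(abs(dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                            c(1, 0, 0))), 180, tolerance = 1e-9)
  # ring built from the inverse pseudorotation formula is recovered
  for (P in c(18, 90, 162)) {
    st <- ring_structure(ring_from_pucker(P))
    bs <- backbone_state(st, rindex = 1)
    expect_equal(bs$pucker_phase, P, tolerance = 2)
  }
  # generator B-DNA bases are anti
  d <- fx_duplex()
  for (i in c(3, 10, 17)) {
    bs <- backbone_state(d, chain = "A", resno = i)
    expect_gt(bs$chi, -180); expect_lt(bs$chi, -90)
    expect_equal(bs$pucker_phase, 162, tolerance = 2)
  }
  # missing atoms yield NA fields, not errors
  bs1 <- backbone_state(d, chain = "A", resno = 1)
  expect_true(is.na(bs1$alpha))
})

test_that("groove widths are uniform on an ideal duplex", {
  gw <- groove_widths(fx_duplex())
  ok <- !is.na(gw$minor) & !is.na(gw$major)
  expect_gt(sum(ok), 10)
  expect_lt(diff(range(gw$minor[ok])), 0.02)
  expect_lt(diff(range(gw$major[!is.na(gw$major)])), 0.02)
  expect_true(all(gw$minor[ok] < gw$major[ok]))
  # 4-bp duplex cannot host the +-3 register
  gw4 <- groove_widths(build_duplex("ACGT"))
  expect_true(all(is.na(gw4$minor)))
})

test_that("radial compression narrows the measured minor groove", {
  d <- fx_duplex()
  widths <- vapply(c(1, 0.95, 0.9, 0.85), function(f) {
    xyz <- coords(d)
    xyz[, 1:2] <- xyz[, 1:2] * f
    mean(groove_widths(set_coords(d, xyz))$minor, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("heatmap tables reflect frame-local perturbations", {
  d <- fx_duplex12()
  xyz <- coords(d)
  dpert <- build_duplex(strrep("AT", 6),
                        propeller = c(rep(0, 4), -15, rep(0, 7)))
  frames <- c(rep(list(xyz), 3), rep(list(coords(dpert)), 3),
              rep(list(xyz), 2))
  tr <- trajectory(d, frames)
  tab <- heatmap_table(tr, "propeller")
  expect_error(heatmap_table(tr, "wobble"), "unknown parameter")
  base <- tab$value[tab$frame == 0]
  for (k in c(1, 2, 6, 7))
    expect_equal(tab$value[tab$frame == k], base, tolerance = 1e-9)
  pert <- tab$value[tab$frame == 4]
  expect_equal(pert[5], -15, tolerance = 0.3)
  expect_equal(pert[-5], base[-5], tolerance = 0.3)
  # averaging over the full range equals the mean of per-frame values
  wa <- window_average(tab)
  expect_equal(wa$mean[5], mean(tab$value[tab$bp == 5]), tolerance = 1e-12)
  wa2 <- window_average(tab, frames = c(3, 5))
  expect_equal(wa2$mean[5],
               mean(tab$value[tab$bp == 5 & tab$frame %in% 3:5]),
               tolerance = 1e-12)
})

test_that("pairing inference recovers the generator annotation", {
  d <- fx_duplex12()
  inferred <- infer_pairing(d)
  want <- d$pairing
  expect_equal(nrow(inferred), nrow(want))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  expect_setequal(key(inferred), key(want))
})
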