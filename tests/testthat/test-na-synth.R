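# Synthetic nucleic-acid generator: duplexes, superhelix, poses,
# trajectories.

test_that("duplex construction gives the expected chain layout", {
  d <- fx_duplex()
  expect_equal(nrow(d$pairing), 20)
  expect_equal(max(d$atoms$resno[d$atoms$chain == "A"]), 20)
  expect_equal(max(d$atoms$resno[d$atoms$chain == "B"]), 20)
  # no 5'-terminal phosphates
  expect_equal(nrow(select_atoms(d, element = "P")), 38)
  expect_false("P" %in% select_atoms(d, chain = "A", resno = 1)$name)
  # Watson-Crick complement on strand II
  b1 <- select_atoms(d, chain = "A", resno = 3)$resname[1]
  pr <- d$pairing[3, ]
  b2 <- d$atoms$resname[d$atoms$rindex == pr[2]][1]
  expect_equal(sub("D", "", b2),
               c(A = "T", T = "A", C = "G", G = "C")[[sub("D", "", b1)]])
  # backbone is chemically continuous (O3'-P about a bond length)
  a <- d$atoms
  for (i in 1:5) {
    o3 <- as.numeric(a[a$chain == "A" & a$resno == i &
                         a$name == "O3'", c("x", "y", "z")])
    p <- as.numeric(a[a$chain == "A" & a$resno == i + 1 &
                        a$name == "P", c("x", "y", "z")])
    expect_lt(abs(sqrt(sum((o3 - p)^2)) - 0.16), 0.01)
  }
})

test_that("sequence validation distinguishes DNA and RNA alphabets", {
  expect_error(build_duplex("ACGU", "B-DNA"), "invalid base")
  expect_error(build_duplex("ACGT", "A-RNA"), "invalid base")
  expect_error(build_duplex("ACXT"), "invalid base")
  r <- build_duplex("ACGU", "A-RNA")
  expect_equal(nrow(r$pairing), 4)
})

test_that("generator twist propagates to bp-per-turn downstream", {
  d <- build_duplex(strrep("AT", 6), twist = 36)
  p <- bp_step_params(d)
  expect_equal(bp_per_turn(p$step$twist), 10.0, tolerance = 1e-6)
})

test_that("superhelix base-pair origins lie on the parametric path", {
  ns <- build_superhelix_dna(80, turns = 1.0)
  p <- bp_step_params(ns)
  path <- attr(ns, "superhelix")$path
  dev <- vapply(seq_along(p$bp_frames), function(i)
    sqrt(sum((p$bp_frames[[i]]$o - path[i, ])^2)), 0)
  expect_lt(max(dev), 0.05)
  expect_error(build_superhelix_dna(pitch = -1), "pitch")
  # turns = 0 degenerates to a straight duplex
  st <- build_superhelix_dna(30, turns = 0)
  expect_true(attr(st, "superhelix")$straight)
})

test_that("cross-gyre minimum approximates the superhelical pitch", {
  ns <- build_superhelix_dna(146)
  gd <- gyre_distances(ns)
  # bp centres of mass sit up to ~0.25 nm off the path centreline, so
  # the closest cross-gyre approach undershoots the pitch by up to
  # about twice that
  expect_lt(abs(min(gd$distance) - 2.39), 0.5)
})

test_that("terminal stack pose sits at the requested stacking distance", {
  cx <- place_cd_pose(fx_duplex(), fx_cd_plus(), "terminal_stack",
                      separation = 0.34)
  r <- classify_frame(cx)
  expect_equal(r$mode, "terminal_bp_stack")
  expect_equal(r$evidence$stacking$separation, 0.34, tolerance = 0.005)
})

test_that("unbound pose has zero contact area", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  is_cd <- has_tag(cx, "cd")
  expect_equal(contact_area(cx, which(is_cd), which(!is_cd)), 0)
})

test_that("noise-free trajectories are constant; noise is calibrated", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  tr0 <- synthesize_trajectory(cx, 5, noise_sigma = 0, seed = 1)
  for (k in 2:5) expect_identical(tr0$frames[[k]], tr0$frames[[1]])
  tr <- synthesize_trajectory(cx, 200, noise_sigma = 0.05, seed = 9)
  dev <- unlist(lapply(tr$frames[-1], function(f) f - coords(cx)))
  expect_equal(sd(dev), 0.05, tolerance = 0.05 * 0.05)
})

test_that("trajectories are seed-reproducible bitwise", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "minor_groove")
  a <- synthesize_trajectory(cx, 10, noise_sigma = 0.03, seed = 5)
  b <- synthesize_trajectory(cx, 10, noise_sigma = 0.03, seed = 5)
  expect_identical(a$frames, b$frames)
  cc <- synthesize_trajectory(cx, 10, noise_sigma = 0.03, seed = 6)
  expect_false(identical(a$frames[[2]], cc$frames[[2]]))
})

test_that("a scheduled binding event lands inside its window", {
  cx <- place_cd_pose(fx_duplex(), fx_cd_plus(), "major_groove")
  tr <- synthesize_trajectory(cx, 100, noise_sigma = 0,
                              event_frame = 50, seed = 2)
  tl <- classify_trajectory(tr)
  m <- tl$modes$mode
  expect_true(all(m[1:50] == "unbound"))
  expect_true(all(m[67:100] == "major_groove"))
  sw <- which(m == "major_groove")[1]
  expect_gte(sw, 51); expect_lte(sw, 66)
})

test_that("the quadruplex mock is two planar tagged tetrads", {
  g4 <- fx_g4()
  expect_equal(length(unique(g4$atoms$rindex)), 8)
  for (t in 0:1) {
    idx <- which(has_tag(g4, paste0("quartet:", t)))
    expect_equal(length(unique(g4$atoms$rindex[idx])), 4)
    pl <- fit_plane(coords(g4)[idx, ])
    expect_lt(pl$rms, 0.01)
  }
})
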