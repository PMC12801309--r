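# Gyre distances, per-residue RMSF, event-aligned RMSD.

test_that("gyre distances on a straight helix follow the exclusion", {
  d40 <- build_duplex(paste(rep("ACGT", 10), collapse = ""))
  gd <- gyre_distances(d40, exclusion = 10)
  interior <- gd$distance[15:26]
  expect_equal(interior, rep(11 * 0.338, length(interior)),
               tolerance = 0.01 * 11 * 0.338)
  expect_error(gyre_distances(d40, exclusion = 40), "base pairs")
  # monotone non-increasing as the exclusion shrinks
  g5 <- gyre_distances(d40, exclusion = 5)
  expect_true(all(g5$distance <= gd$distance + 1e-12))
  # rigid-motion invariance
  set.seed(2)
  R <- random_rotation()
  d2 <- set_coords(d40, sweep(coords(d40) %*% t(R), 2, -c(1, 2, 3)))
  g2 <- gyre_distances(d2, exclusion = 10)
  expect_equal(g2$distance, gd$distance, tolerance = 1e-9)
})

test_that("RMSF vanishes for static trajectories and scales with noise", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  xyz <- coords(cx)
  tr0 <- trajectory(cx, list(xyz, xyz, xyz))
  expect_lt(max(per_residue_rmsf(tr0)$rmsf), 1e-12)
  expect_error(per_residue_rmsf(trajectory(cx, list(xyz))), "2 frames")
  # linear scaling across sigma (R^2 > 0.99)
  sig <- c(0.01, 0.04, 0.07, 0.10)
  mrms <- vapply(sig, function(s) {
    tr <- synthesize_trajectory(cx, 150, noise_sigma = s, seed = 17)
    mean(per_residue_rmsf(tr)$rmsf)
  }, 0)
  fit <- summary(lm(mrms ~ sig))
  expect_gt(fit$r.squared, 0.99)
  expect_equal(unname(coef(lm(mrms ~ 0 + sig))), sqrt(3),
               tolerance = 0.05 * sqrt(3))
})

test_that("RMSF is invariant to frame order and localizes noise", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  tr <- synthesize_trajectory(cx, 40, noise_sigma = 0.05, seed = 23)
  r1 <- per_residue_rmsf(tr)
  tr2 <- trajectory(tr$topology, rev(tr$frames))
  r2 <- per_residue_rmsf(tr2)
  expect_equal(r2$rmsf, r1$rmsf, tolerance = 1e-6)
  # noise confined to the terminal residues shows up only there
  d <- fx_duplex12()
  xyz <- coords(d)
  term <- d$atoms$rindex %in% c(1, 12, 13, 24)
  set.seed(31)
  frames <- lapply(1:60, function(k) {
    f <- xyz
    f[term, ] <- f[term, ] + matrix(rnorm(sum(term) * 3, 0, 0.08),
                                    ncol = 3)
    f
  })
  rf <- per_residue_rmsf(trajectory(d, frames),
                         align = !term)
  term_r <- rf$rmsf[rf$rindex %in% c(1, 12, 13, 24)]
  core_r <- rf$rmsf[!(rf$rindex %in% c(1, 12, 13, 24))]
  expect_gt(min(term_r), max(core_r))
})

test_that("event-aligned RMSD localizes post-event displacement", {
  d <- fx_duplex()
  cx <- place_cd_pose(d, fx_cd_plus(), "major_groove")
  n_na <- nrow(d$atoms)
  xyz <- coords(cx)
  # rigid NA, CD flies in at frame 30: no structural change
  tr <- synthesize_trajectory(cx, 60, noise_sigma = 0,
                              event_frame = 30, seed = 1)
  tl <- classify_trajectory(tr)
  ev <- event_aligned_rmsd(tr, tl, delta = 10,
                           align = seq_len(n_na))
  expect_equal(ev$t0, 30, tolerance = 10)
  expect_lt(max(abs(ev$profile$delta_rmsd[seq_len(40)])), 1e-9)
  # imposed 0.1 nm displacement of residues 20-25 after the event
  shift_rows <- cx$atoms$rindex %in% 20:25
  frames <- tr$frames
  for (k in 41:60) frames[[k]][shift_rows, 1] <-
      frames[[k]][shift_rows, 1] + 0.1
  tr2 <- trajectory(cx, frames)
  ev2 <- event_aligned_rmsd(tr2, t0 = 40, delta = 10,
                            align = which(!shift_rows &
                                            seq_len(nrow(cx$atoms)) <=
                                            n_na))
  prof <- ev2$profile
  hot <- prof$delta_rmsd[prof$rindex %in% 20:25]
  cold <- prof$delta_rmsd[prof$rindex %in% c(5:15, 30:40)]
  expect_equal(mean(hot), 0.1, tolerance = 0.02)
  expect_lt(max(abs(cold)), 0.02)
  # windows must fit inside the trajectory
  expect_error(event_aligned_rmsd(tr, t0 = 5, delta = 10), "window")
  # no qualifying event yields an empty flagged result
  trq <- synthesize_trajectory(place_cd_pose(d, fx_cd_plus(),
                                             "unbound"),
                               30, noise_sigma = 0, seed = 1)
  tlq <- classify_trajectory(trq)
  evq <- event_aligned_rmsd(trq, tlq, delta = 5)
  expect_true(is.na(evq$t0))
  expect_equal(nrow(evq$profile), 0)
})
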