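# Carbon-dot layer shape descriptors and detachment detection.

cd_traj <- function(frames) {
  st <- fx_cd0()$structure
  trajectory(st, frames)
}

test_that("freshly built layers are planar with graphitic spacing", {
  fl <- fit_layers(fx_cd0())
  expect_equal(nrow(fl), 5)
  expect_true(all(fl$undulation < 1e-9))
  tl <- shape_descriptors(cd_traj(list(coords(fx_cd0()$structure))))
  expect_equal(unique(round(tl$interlayer$distance, 6)), 0.35)
  expect_true(all(tl$layers$tilt < 1e-6))
  expect_true(all(tl$layers$undulation < 1e-9))
})

test_that("imposed layer deformations are recovered", {
  st <- fx_cd0()$structure
  base <- coords(st)
  lay <- carbodot:::.layer_membership(st)[as.character(st$atoms$serial)]
  # sinusoidal undulation of amplitude 0.05 on layer 2
  und <- base
  sel <- which(lay == 2)
  wave <- 0.05 * sin(2 * pi * und[sel, 1] / 1.2)
  und[sel, 3] <- und[sel, 3] + wave
  tl <- shape_descriptors(cd_traj(list(base, und)))
  got <- tl$layers$undulation[tl$layers$frame == 1 & tl$layers$layer == 2]
  # the plane refit removes any mean/tilt component of the wave; the
  # imposed out-of-plane RMS is the residual of a planar fit
  res <- resid(lm(und[sel, 3] ~ und[sel, 1] + und[sel, 2]))
  expect_equal(got, sqrt(mean(res^2)), tolerance = 0.05)

  # 15-degree rotation of layer 3 about its normal
  rot <- base
  sel3 <- which(lay == 3)
  cen <- colMeans(base[sel3, ])
  R <- rot_axis(c(0, 0, 1), 15 * pi / 180)
  rot[sel3, ] <- sweep(sweep(rot[sel3, ], 2, cen) %*% t(R), 2, -cen)
  tl2 <- shape_descriptors(cd_traj(list(base, rot)))
  expect_equal(abs(tl2$layers$rotation[tl2$layers$frame == 1 &
                                         tl2$layers$layer == 3]),
               15, tolerance = 0.1)

  # 10-degree tilt of layer 4
  tilt <- base
  sel4 <- which(lay == 4)
  cen4 <- colMeans(base[sel4, ])
  R4 <- rot_axis(c(1, 0, 0), 10 * pi / 180)
  tilt[sel4, ] <- sweep(sweep(tilt[sel4, ], 2, cen4) %*% t(R4), 2, -cen4)
  tl3 <- shape_descriptors(cd_traj(list(base, tilt)))
  expect_equal(tl3$layers$tilt[tl3$layers$frame == 1 &
                                 tl3$layers$layer == 4],
               10, tolerance = 0.1)
})

test_that("descriptors are invariant under global rigid motion", {
  base <- coords(fx_cd0()$structure)
  set.seed(12)
  frames <- list(base)
  for (k in 1:3) {
    R <- random_rotation()
    frames[[k + 1]] <- sweep(base %*% t(R), 2, -rnorm(3))
  }
  tl <- shape_descriptors(cd_traj(frames))
  expect_lt(max(tl$layers$tilt), 0.01)
  expect_lt(max(abs(tl$layers$rotation)), 0.01)
  expect_lt(diff(range(tl$interlayer$distance)), 1e-4)
})

test_that("layer normals co-rotate with the dot", {
  st <- fx_cd0()$structure
  R <- rot_axis(c(1, 1, 0), 0.7)
  st2 <- set_coords(st, coords(st) %*% t(R))
  f1 <- fit_layers(fx_cd0())
  f2 <- fit_layers(st2)
  n1 <- as.numeric(f1[3, c("nx", "ny", "nz")])
  n2 <- as.numeric(f2[3, c("nx", "ny", "nz")])
  expect_equal(abs(sum((R %*% n1) * n2)), 1, tolerance = 1e-9)
})

test_that("detachment requires both displacement and persistence", {
  base <- coords(fx_cd0()$structure)
  st <- fx_cd0()$structure
  lay <- carbodot:::.layer_membership(st)[as.character(st$atoms$serial)]
  moved <- base
  moved[lay == 0, 3] <- moved[lay == 0, 3] - 1.5
  # intact: no events
  tl0 <- shape_descriptors(cd_traj(rep(list(base), 12)))
  expect_equal(nrow(detect_detachment(tl0)), 0)
  # layer 0 leaves at frame 8 and stays out
  frames <- c(rep(list(base), 8), rep(list(moved), 8))
  tl1 <- shape_descriptors(cd_traj(frames))
  ev <- detect_detachment(tl1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$layer, 0)
  expect_equal(ev$frame, 8)
  # a 3-frame excursion is below the persistence gate
  frames2 <- c(rep(list(base), 8), rep(list(moved), 3),
               rep(list(base), 5))
  tl2 <- shape_descriptors(cd_traj(frames2))
  expect_equal(nrow(detect_detachment(tl2)), 0)
})
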