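# SASA, contact area, hydrogen bonds, RDF, stacking.

test_that("SASA matches closed forms for isolated and paired spheres", {
  one <- matrix(0, 1, 3)
  s <- sasa(one, radii = 0.17)
  expect_equal(s$total, 4 * pi * 0.31^2, tolerance = 1e-3 * s$total)
  # two identical atoms far apart: strict additivity
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  s2 <- sasa(two, radii = c(0.17, 0.17))
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-12)
  expect_equal(sum(s2$per_atom), s2$total)
  # overlapping pair vs spherical-cap formula
  R <- 0.31; d <- 0.30; h <- R - d / 2
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  s3 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(0.17, 0.17))
  expect_equal(s3$total, analytic, tolerance = 0.02 * analytic)
  expect_error(sasa(one, radii = 0), "radius")
})

test_that("SASA point count is converged at the default", {
  st <- fx_cd0()$structure
  s1 <- sasa(st)
  s2 <- sasa(st, contact_config(sasa_points = 3840))
  expect_lt(abs(s1$total - s2$total) / s2$total, 0.01)
})

test_that("contact area is zero iff the groups cannot bury surface", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  is_cd <- has_tag(cx, "cd")
  expect_equal(contact_area(cx, which(is_cd), which(!is_cd)), 0)
  expect_error(contact_area(cx, c(1, 2), c(2, 3)), "share")
  expect_error(contact_area(cx, integer(), 1:3), "empty")
})

test_that("stacked contact area decreases monotonically with separation", {
  areas <- vapply(c(0.34, 0.5, 0.7, 1.0), function(s) {
    cx <- place_cd_pose(fx_g4(), fx_cd_plus(), "tetrad_stack",
                        separation = s)
    is_cd <- has_tag(cx, "cd")
    contact_area(cx, which(is_cd), which(!is_cd))
  }, 0)
  expect_gt(areas[1], 0)
  expect_true(all(diff(areas) <= 0))
  expect_equal(areas[4], 0)
})

test_that("deep groove binding buries more surface than terminal stacking", {
  area_of <- function(mode) {
    cx <- place_cd_pose(fx_duplex(), fx_cd_plus(), mode)
    is_cd <- has_tag(cx, "cd")
    contact_area(cx, which(is_cd), which(!is_cd))
  }
  expect_gt(area_of("major_groove"), area_of("terminal_stack"))
})

test_that("contact area and SASA are invariant under rigid motion", {
  cx <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "terminal_stack")
  is_cd <- has_tag(cx, "cd")
  a0 <- contact_area(cx, which(is_cd), which(!is_cd))
  set.seed(5)
  R <- random_rotation()
  cx2 <- set_coords(cx, sweep(coords(cx) %*% t(R), 2, -c(2, 1, -1)))
  a1 <- contact_area(cx2, which(is_cd), which(!is_cd))
  # the deterministic point set is fixed in space, so rotational
  # invariance holds only to the quadrature resolution
  expect_equal(a1, a0, tolerance = 0.02)
})

test_that("hydrogen bonds apply the distance and angle gates", {
  mk <- function(d_na, angle) {
    # donor N with H, acceptor O at distance d_na; angle at H set by
    # bending the acceptor
    ang <- angle * pi / 180
    h <- c(0.101, 0, 0)
    a <- h + (d_na - 0.101) * c(cos(pi - ang), sin(pi - ang), 0)
    at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                     element = c("N", "H", "O"), resno = 1,
                     resname = "X", chain = "A",
                     x = c(0, h[1], a[1]), y = c(0, h[2], a[2]),
                     z = 0)
    mol_structure(at, bonds = cbind(1, 2))
  }
  lin <- mk(0.29, 180)
  expect_equal(hydrogen_bonds(lin, donors = 1, acceptors = 3)$count, 1)
  far <- mk(0.40, 180)
  expect_equal(hydrogen_bonds(far, donors = 1, acceptors = 3)$count, 0)
  bent <- mk(0.29, 120)
  expect_equal(hydrogen_bonds(bent, donors = 1, acceptors = 3)$count, 0)
  nohy <- mk(0.29, 180)
  nohy$atoms <- nohy$atoms[-2, ]; nohy$bonds <- NULL
  expect_warning(r <- hydrogen_bonds(nohy, donors = 1, acceptors = 3),
                 "no attached hydrogen")
  expect_equal(r$count, 0)
})

test_that("RDF is flat for uniform points and sharp for a fixed pair", {
  set.seed(8)
  n <- 60000
  # uniform points in a sphere of radius 4; reference group restricted
  # to the centre so mid-range shells are fully inside the sphere
  rad <- 4 * runif(n)^(1 / 3)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * rad
  centre <- pts[rad < 1, , drop = FALSE]
  g <- rdf(centre, pts, bin_width = 0.1, r_max = 4)
  mid <- g$g[g$r > 0.3 & g$r < 2.0]
  expect_true(all(abs(mid - 1) < 0.1))
  # two fixed atoms: one occupied bin at their separation
  g2 <- rdf(matrix(0, 1, 3), matrix(c(0.5, 0, 0), 1), bin_width = 0.1,
            r_max = 1)
  expect_equal(sum(g2$g > 0), 1)
  expect_equal(g2$r[g2$g > 0], 0.45, tolerance = 0.051)
  expect_error(rdf(pts[1:5, ], pts[0, , drop = FALSE]), "empty")
  expect_error(rdf(pts, pts, bin_width = 2, r_max = 1), "exceed")
})

test_that("stacking detection gates on separation, angle and offset", {
  hex <- function(R = 0.14, z = 0, dx = 0, tilt = 0) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(R * cos(th) + dx, R * sin(th), z)
    if (tilt != 0) ring %*% t(rot_axis(c(0, 1, 0), tilt * pi / 180))
    else ring
  }
  a <- hex()
  expect_true(detect_stacking(a, hex(z = 0.34))$stacked)
  expect_equal(detect_stacking(a, hex(z = 0.34))$separation, 0.34,
               tolerance = 1e-9)
  expect_false(detect_stacking(a, hex(z = 0.60))$stacked)
  expect_false(detect_stacking(a, hex(z = 0.34, dx = 0.30))$stacked)
  perp <- sweep(hex() %*% t(rot_axis(c(0, 1, 0), pi / 2)), 2,
                -c(0, 0, 0.34))
  expect_false(detect_stacking(a, perp)$stacked)
  line <- cbind(seq(0, 1, length.out = 6), 0, 0)
  expect_error(detect_stacking(line, a), "collinear")
})
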