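test_that("if_params validates its invariants", {
  p <- vim_params()
  expect_equal(p$bond_min, 8.8)
  expect_equal(p$bond_max, 13.2)
  expect_equal(p$reaction_distance, 13.2)
  expect_equal(p$max_displacement, 1.1)
  expect_error(if_params(bond_min = 15), "bond_min < bond_max")
  expect_error(if_params(max_bond_angle = 0), "max_bond_angle")
  expect_error(if_params(beads_per_ulf = 1), "beads_per_ulf")
  expect_error(if_params(reaction_distance = 20), "reaction_distance")
  expect_error(if_params(max_displacement = -1), "max_displacement")
})

test_that("periodic_box derives volume from edge and vice versa", {
  b <- periodic_box(edge = 3200)
  expect_equal(b$volume_um3, 3.2^3)
  b2 <- periodic_box(volume = 28.0)
  expect_equal(b2$edge_nm, 1000 * 28^(1 / 3))
  expect_error(periodic_box(), "exactly one")
  expect_error(periodic_box(edge = 100, volume = 1), "exactly one")
  expect_error(periodic_box(edge = -5), "positive")
})

test_that("minimum_image wraps into (-edge/2, edge/2]", {
  b <- periodic_box(edge = 100)
  expect_equal(minimum_image(c(0, 0, 0), c(0, 0, 0), b), c(0, 0, 0))
  expect_equal(minimum_image(c(1, 0, 0), c(99, 0, 0), b), c(-2, 0, 0))
  expect_equal(minimum_image(c(0, 0, 0), c(50, -50, 150), b), c(50, 50, 50))
  expect_error(minimum_image(c(0, 0, NaN), c(0, 0, 0), b), "finite")
})

test_that("minimum_image agrees with the 27-image brute force", {
  set.seed(42)
  b <- periodic_box(edge = 37.5)
  for (k in 1:50) {
    p <- runif(3, 0, b$edge_nm)
    q <- runif(3, 0, b$edge_nm)
    expect_equal(minimum_image(p, q, b), min_image_brute(p, q, b$edge_nm),
                 tolerance = 1e-12)
    # shifting either point by whole boxes never changes the result
    shift <- sample(-3:3, 3, replace = TRUE) * b$edge_nm
    expect_equal(minimum_image(p + shift, q, b), minimum_image(p, q, b),
                 tolerance = 1e-9)
  }
})

test_that("bond_angle handles collinear, orthogonal and oblique vectors", {
  expect_equal(bond_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(bond_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_equal(bond_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(bond_angle(c(0, 0, 0), c(1, 0, 0)), "non-zero")
})

test_that("validate_filament reports bond and angle violations by index", {
  p <- vim_params()
  expect_identical(nrow(validate_filament(straight_filament(4), p)), 0L)

  v <- validate_filament(straight_filament(2, bond = 1.3 * 11), p)
  expect_equal(v$index, 1L)
  expect_equal(v$constraint, "bond_length")
  expect_equal(v$value, 14.3)

  kinked <- rbind(c(0, 0, 0), c(11, 0, 0),
                  c(11, 0, 0) + 11 * c(cos(20 * pi / 180),
                                       sin(20 * pi / 180), 0))
  v <- validate_filament(kinked, p)
  expect_equal(v$constraint, "bond_angle")
  expect_equal(v$value, 20, tolerance = 1e-9)
  expect_identical(nrow(validate_filament(kinked, ker_params())), 0L)
})

test_that("contour_length sums consecutive bead distances", {
  expect_equal(contour_length(straight_filament(4)), 33)
  expect_equal(contour_length(straight_filament(2, bond = 13.2)), 13.2)
  set.seed(7)
  chain <- ifsim:::cpp_sample_chain(20L, ifsim:::params_for_cpp(vim_params()))
  oracle <- sum(vapply(2:20, function(i) {
    sqrt(sum((chain[i, ] - chain[i - 1, ])^2))
  }, numeric(1)))
  expect_equal(contour_length(chain), oracle, tolerance = 1e-12)
  expect_error(contour_length(chain[1, , drop = FALSE]), "at least 2")
})

test_that("radius_of_gyration matches its definition", {
  expect_equal(radius_of_gyration(matrix(c(5, 2, 9), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  expect_equal(radius_of_gyration(straight_filament(4, bond = 1)),
               sqrt(1.25))
})

test_that("init_system places n0 valid ULFs deterministically", {
  p <- vim_params()
  sys <- init_system(1, periodic_box(edge = 500), p, seed = 3)
  expect_length(sys$filaments, 1L)
  expect_identical(nrow(validate_filament(filament_coords(sys, 1), p)), 0L)
  expect_equal(contour_length(filament_coords(sys, 1)), 33)  # straight 1.0 d

  sys_a <- init_system(20, periodic_box(edge = 500), p, seed = 11)
  sys_b <- init_system(20, periodic_box(edge = 500), p, seed = 11)
  expect_identical(sys_a, sys_b)

  sys_e <- init_system(20, periodic_box(edge = 500), p, seed = 12,
                       init_shape = "equilibrium")
  for (i in seq_along(sys_e$filaments))
    expect_identical(nrow(validate_filament(filament_coords(sys_e, i), p)),
                     0L)
  expect_error(init_system(0, periodic_box(edge = 500), p), "n0")
})

test_that("the reference box reproduces the 0.10 g/l equivalence", {
  sys <- init_system(1000, periodic_box(volume = 28.0), vim_params(),
                     seed = 1)
  conc <- mass_concentration(sys$n0, sys$box$volume_um3, sys$params)
  expect_equal(conc, 0.10, tolerance = 0.03)
})
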