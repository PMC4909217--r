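two_ulf_system <- function(gap = 11, angle = 0, params = vim_params()) {
  make_reactive_pair(gap, angle, params)
}

test_that("trial_move applies the geometric acceptance rules", {
  sys <- init_system(2, periodic_box(edge = 500), vim_params(), seed = 5)

  # zero displacement never violates anything
  res <- trial_move(sys, 1, 2, displacement = c(0, 0, 0))
  expect_true(res$accepted)
  expect_identical(res$system$coords, sys$coords)

  # end bead of a taut bond pushed straight outward breaks the bond
  taut <- init_system(1, periodic_box(edge = 500), vim_params(), seed = 5)
  taut$coords <- straight_filament(4, bond = 1.19 * 11)
  res <- trial_move(taut, 1, 4, displacement = c(1.1, 0, 0))
  expect_false(res$accepted)
  expect_identical(res$system$coords, taut$coords)

  # same displacement inward shortens the bond and is fine
  res <- trial_move(taut, 1, 4, displacement = c(-1.1, 0, 0))
  expect_true(res$accepted)
})

test_that("a sweep attempts one move per bead and conserves the system", {
  sys <- init_system(1, periodic_box(edge = 500), vim_params(), seed = 2)
  res <- sweep_system(sys)
  # acceptance is a multiple of 1/4: exactly 4 attempts were made
  expect_true((res$acceptance * 4) %% 1 == 0)
  expect_equal(res$system$sweep_count, 1)
  expect_length(res$system$filaments, 1L)

  sys <- init_system(30, periodic_box(edge = 400), vim_params(), seed = 2)
  set.seed(9)
  a <- run_assembly(sys, max_sweeps = 50, record_every = 10, react_every = 0)
  set.seed(9)
  b <- run_assembly(sys, max_sweeps = 50, record_every = 10, react_every = 0)
  expect_identical(a$trajectory, b$trajectory)     # determinism
  expect_identical(a$system$coords, b$system$coords)
  expect_length(a$system$filaments, 30L)           # no annealing disabled run
  expect_identical(nrow(a$system$coords), nrow(sys$coords))
})

test_that("detect_reactive_pairs applies the 1.2 d cutoff", {
  expect_identical(nrow(detect_reactive_pairs(two_ulf_system(gap = 13.0))),
                   1L)
  expect_identical(nrow(detect_reactive_pairs(two_ulf_system(gap = 13.4))),
                   0L)
  pr <- detect_reactive_pairs(two_ulf_system(gap = 13.0))
  expect_equal(pr$distance, 13.0)
  expect_identical(pr$end_a, "last")
  expect_identical(pr$end_b, "first")
})

test_that("cell list and brute force find identical reactive pairs", {
  p <- vim_params()
  for (seed in c(1, 2, 3)) {
    sys <- init_system(100, periodic_box(edge = 250), p, seed = seed)
    a <- detect_reactive_pairs(sys, method = "cell")
    b <- detect_reactive_pairs(sys, method = "brute")
    key <- function(d) {
      o <- order(d$filament_a, d$filament_b, d$end_a, d$end_b)
      d[o, c("filament_a", "end_a", "filament_b", "end_b")]
    }
    expect_equal(key(a), key(b), ignore_attr = TRUE)
    expect_gt(nrow(a), 0)  # dense enough that some pairs exist
  }
})

test_that("anneal joins compatible ends and rejects bad geometry", {
  p <- vim_params()

  sys <- two_ulf_system(gap = 11, angle = 0)
  pr <- detect_reactive_pairs(sys)
  res <- anneal(sys, pr[1, ])
  expect_true(res$merged)
  expect_length(res$system$filaments, 1L)
  expect_identical(length(res$system$filaments[[1]]), 8L)
  expect_identical(nrow(validate_filament(
    filament_coords(res$system, 1), p)), 0L)
  expect_equal(sum(filament_ulfs(res$system)), 2L)  # ULF conservation

  # junction angle 40 deg > 15 deg: detected but not merged
  sys <- two_ulf_system(gap = 11, angle = 40)
  pr <- detect_reactive_pairs(sys)
  expect_identical(nrow(pr), 1L)
  res <- anneal(sys, pr[1, ])
  expect_false(res$merged)
  expect_length(res$system$filaments, 2L)

  # the same geometry is fine for the keratin reaction angle
  sys <- two_ulf_system(gap = 11, angle = 20, params = ker_params())
  res <- anneal(sys, detect_reactive_pairs(sys)[1, ])
  expect_true(res$merged)

  # gap below the minimum bond length: too close to bond
  sys <- two_ulf_system(gap = 5, angle = 0)
  res <- anneal(sys, detect_reactive_pairs(sys)[1, ])
  expect_false(res$merged)

  # stale pair referencing a filament that no longer exists
  sys <- two_ulf_system(gap = 11, angle = 0)
  expect_warning(res <- anneal(sys, list(filament_a = 1, end_a = "last",
                                         filament_b = 7, end_b = "first")),
                 "stale")
  expect_false(res$merged)
  expect_error(anneal(sys, list(filament_a = 1, end_a = "last",
                                filament_b = 1, end_b = "first")),
               "self-annealing")
})

test_that("annealing works across the periodic boundary", {
  p <- vim_params()
  sys <- two_ulf_system(gap = 11, angle = 0)
  # push filament B across the box face: minimum image must still find it
  sys$coords[5:8, 1] <- sys$coords[5:8, 1] + sys$box$edge_nm
  pr <- detect_reactive_pairs(sys)
  expect_identical(nrow(pr), 1L)
  res <- anneal(sys, pr[1, ])
  expect_true(res$merged)
  expect_identical(nrow(validate_filament(
    filament_coords(res$system, 1), p)), 0L)
})

test_that("run_assembly merges two pre-positioned reactive ULFs", {
  sys <- two_ulf_system(gap = 11, angle = 0)
  run <- run_assembly(sys, max_sweeps = 1, record_every = 1, seed = 4)
  expect_length(run$system$filaments, 1L)
  expect_identical(nrow(run$events), 1L)
  expect_equal(mean_ulf_length(run$system), 2)
})

test_that("assembly conserves ULFs, decreases filaments, keeps validity", {
  p <- vim_params()
  sys <- init_system(60, box_for_concentration(60, 50, p), p, seed = 8)
  run <- run_assembly(sys, max_sweeps = 4000, record_every = 500, seed = 9)
  tr <- run$trajectory
  expect_true(all(diff(tr$sweep) > 0))
  expect_true(all(diff(tr$n_filaments) <= 0))
  expect_true(all(diff(tr$mean_ln) >= 0))
  expect_lt(tr$n_filaments[nrow(tr)], 60)  # some annealing happened
  expect_equal(sum(filament_ulfs(run$system)), 60L)
  for (i in seq_along(run$system$filaments))
    expect_identical(nrow(validate_filament(
      filament_coords(run$system, i), p)), 0L)
  # trajectory bookkeeping matches the final state
  expect_equal(tr$n_filaments[nrow(tr)], length(run$system$filaments))
  expect_equal(tr$mean_ln[nrow(tr)], mean_ulf_length(run$system))
})

test_that("mean_ulf_length and stop criteria behave as specified", {
  sys <- init_system(10, periodic_box(edge = 1000), vim_params(), seed = 1)
  expect_equal(mean_ulf_length(sys), 1)
  sys$filaments <- sys$filaments[1:5]  # pretend merges happened
  expect_equal(mean_ulf_length(sys), 2)
  sys <- init_system(10, periodic_box(edge = 1000), vim_params(), seed = 1)
  expect_error(run_assembly(sys, target_mean_ulf = 11), "unreachable")
})

test_that("sweeps_to_seconds applies the 1 ns per sweep scale", {
  expect_equal(sweeps_to_seconds(0), 0)
  expect_equal(sweeps_to_seconds(1), 1e-9)
  expect_equal(sweeps_to_seconds(4.30e6), 0.0043)
})
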