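frame_tbl <- function(frame, coords) {
  tibble::tibble(frame = frame, role = names(coords),
                 x = vapply(coords, `[`, numeric(1), 1),
                 y = vapply(coords, `[`, numeric(1), 2),
                 z = vapply(coords, `[`, numeric(1), 3))
}

arom <- som_definition("4'", "aromatic")
aliph <- som_definition("15b", "aliphatic")

test_that("frame geometry returns textbook distances and angles", {
  # collinear C-H-O with H between -> 180 degrees; |C-O| = 0.30 nm
  f <- frame_tbl(1, list(C_som = c(0, 0, 0), H_som = c(0.11, 0, 0),
                         O_ferryl = c(0.30, 0, 0), Fe = c(0.45, 0, 0)))
  g <- frame_geometry(f, arom)
  expect_equal(g$distance_nm, 0.30, tolerance = 1e-12)
  expect_equal(g$angle_deg, 180, tolerance = 1e-9)

  # right angle at the hydrogen vertex
  f90 <- frame_tbl(1, list(C_som = c(0.1, 0, 0), H_som = c(0, 0, 0),
                           O_ferryl = c(0, 0.2, 0), Fe = c(0, 0.4, 0)))
  expect_equal(frame_geometry(f90, arom)$angle_deg, 90, tolerance = 1e-9)

  # aliphatic geometry measures H-O distance and the H-O-Fe angle at O
  fa <- frame_tbl(1, list(H_som = c(0.25, 0, 0), O_ferryl = c(0, 0, 0),
                          Fe = c(0, 0.16, 0), C_som = c(0.36, 0, 0)))
  ga <- frame_geometry(fa, aliph)
  expect_equal(ga$distance_nm, 0.25, tolerance = 1e-12)
  expect_equal(ga$angle_deg, 90, tolerance = 1e-9)
})

test_that("a missing required atom aborts, naming role and frame", {
  f <- frame_tbl(3, list(C_som = c(0, 0, 0), O_ferryl = c(0.3, 0, 0)))
  expect_error(frame_geometry(f, arom), regexp = "H_som",
               class = "p450thermo_validation_error")
})

test_that("classification follows the distance and angle criteria with stated boundaries", {
  place_arom <- function(theta_deg, d) {
    b <- 0.109
    th <- theta_deg * pi / 180
    s <- b * cos(th) + sqrt(d^2 - (b * sin(th))^2)
    frame_tbl(1, list(H_som = c(s, 0, 0),
                      C_som = c(s - b * cos(th), b * sin(th), 0),
                      O_ferryl = c(0, 0, 0), Fe = c(-0.16, 0, 0)))
  }
  # active aromatic pose: close approach, no hydrogen interposition
  expect_true(classify_poses(place_arom(120, 0.30), arom)$active)
  # hydrogen interposed between carbon and ferryl oxygen: excluded
  expect_false(classify_poses(place_arom(160, 0.30), arom)$active)
  # reflection of the printed 140-220 window: 180 is excluded too
  expect_false(classify_poses(place_arom(179.5, 0.30), arom)$active)
  # distance comparison is strict; the angle exclusion bound is inclusive
  expect_false(classify_poses(place_arom(120, 0.35), arom)$active)
  expect_false(classify_poses(place_arom(140, 0.30), arom)$active)
  expect_true(classify_poses(place_arom(139.9, 0.30), arom)$active)

  place_aliph <- function(phi_deg, d) {
    ph <- phi_deg * pi / 180
    frame_tbl(1, list(H_som = d * c(cos(ph), sin(ph), 0),
                      O_ferryl = c(0, 0, 0), Fe = c(0.162, 0, 0),
                      C_som = c(0, 0.4, 0)))
  }
  expect_true(classify_poses(place_aliph(120, 0.30), aliph)$active)
  expect_false(classify_poses(place_aliph(120, 0.40), aliph)$active)
  expect_false(classify_poses(place_aliph(100, 0.30), aliph)$active)
  # window bounds are closed
  expect_true(classify_poses(place_aliph(110, 0.30), aliph)$active)
  expect_true(classify_poses(place_aliph(130, 0.30), aliph)$active)
  expect_false(classify_poses(place_aliph(130.5, 0.30), aliph)$active)
})

test_that("classification is invariant under rigid rotation and translation", {
  sim <- simulate_poses(n_frames = 60, target_fraction = c(50, 50), seed = 11)
  base <- lapply(sim$soms, function(s) classify_poses(sim$frames, s))

  th <- 0.7; ph <- -1.2
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(ph), 0, -sin(ph), 0, 1, 0, sin(ph), 0, cos(ph)), 3, 3)
  rot <- rz %*% ry
  shift <- c(5.5, -2.1, 0.4)
  xyz <- as.matrix(sim$frames[c("x", "y", "z")]) %*% t(rot)
  moved <- sim$frames
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]

  for (i in seq_along(sim$soms)) {
    after <- classify_poses(moved, sim$soms[[i]])
    expect_identical(after$active, base[[i]]$active)
    expect_equal(after$distance_nm, base[[i]]$distance_nm, tolerance = 1e-9)
    expect_equal(after$angle_deg, base[[i]]$angle_deg, tolerance = 1e-9)
  }
})

test_that("shrinking the distance cutoff never gains active frames", {
  sim <- simulate_poses(n_frames = 200, target_fraction = c(60, 40), seed = 3)
  cuts <- seq(0.5, 0.05, by = -0.05)
  for (som in sim$soms) {
    n_active <- vapply(cuts, function(cut) {
      sum(classify_poses(sim$frames, som,
                         pose_criteria(distance_cutoff = cut))$active)
    }, numeric(1))
    expect_true(all(diff(n_active) <= 0))
  }
})

test_that("active fractions are per-trajectory percentages that aggregate frame-weighted", {
  sim <- simulate_poses(n_frames = 100, target_fraction = 60, seed = 7)
  rep <- active_fraction(sim$frames, sim$soms)
  expect_equal(rep$percent_active[rep$som == "arom"], 60)
  expect_true(all(rep$n_active <= rep$n_frames))

  # two disjoint halves average (frame-weighted) to the whole
  halves <- sim$frames
  halves$trajectory <- ifelse(halves$frame <= 50, "A", "B")
  rep_h <- active_fraction(halves, sim$soms[[1]])
  whole <- active_fraction(sim$frames, sim$soms[[1]])
  expect_equal(sum(rep_h$n_active) / sum(rep_h$n_frames) * 100,
               whole$percent_active)

  one <- frame_tbl(1, list(H_som = c(0.6, 0, 0), O_ferryl = c(0, 0, 0),
                           Fe = c(0.162, 0, 0), C_som = c(0.7, 0, 0)))
  expect_equal(active_fraction(one, aliph)$percent_active, 0)

  expect_error(active_fraction(sim$frames[0, ], sim$soms[[1]]),
               class = "p450thermo_validation_error")
})

test_that("pose readers honour declared units and parse XYZ frames", {
  f <- write_tmp_csv(c("frame,role,x,y,z",
                       "1,C_som,0,0,0", "1,H_som,1.1,0,0",
                       "1,O_ferryl,3.0,0,0", "1,Fe,4.5,0,0"))
  expect_error(read_pose_frames(f), class = "p450thermo_usage_error")
  ang <- read_pose_frames(f, unit = "angstrom")
  expect_equal(ang$x[ang$role == "O_ferryl"], 0.30)

  xyz <- write_tmp_csv(c("4", "frame 1",
                         "Fe  -1.62 0 0", "O 0 0 0", "C 3.0 0 0", "H 1.1 0 0",
                         "4", "frame 2",
                         "Fe  -1.62 0 0", "O 0 0 0", "C 2.0 0 0", "H 1.1 0 0"))
  frames <- read_xyz_frames(xyz, c(Fe = 1, O_ferryl = 2, C_som = 3, H_som = 4),
                            unit = "angstrom")
  expect_equal(length(unique(frames$frame)), 2)
  expect_equal(frames$x[frames$role == "C_som" & frames$frame == 2], 0.20)
  g <- frame_geometry(frames, arom)
  expect_equal(g$distance_nm, c(0.30, 0.20), tolerance = 1e-12)
})
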