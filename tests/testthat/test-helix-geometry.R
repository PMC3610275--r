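test_that("dihedral matches definition and the independent projection oracle", {
  # planar cis / trans
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(1, 1, 0) + c(2, 0, 0)), 0)
  expect_equal(abs(dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, -1, 0))), 180)
  set.seed(42)
  for (k in 1:1000) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    ok <- tryCatch({ d <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ]); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    expect_equal(d, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("phi_psi inverts the builder and handles termini", {
  m <- ideal_helix(25)
  pp <- phi_psi(m, "A")
  expect_true(is.na(pp$phi[1]))
  expect_true(is.na(pp$psi[25]))
  expect_lt(max(abs(pp$phi[-1] - (-57))), 0.1)
  expect_lt(max(abs(pp$psi[-25] - (-47))), 0.1)
})

test_that("missing backbone atoms warn and leave NA, not crash", {
  m <- ideal_helix(10)
  a <- m$atoms
  a <- a[!(a$res_seq == 5 & a$name == "C"), ]
  m2 <- gpcrgeom:::new_structure_model(a)
  expect_warning(pp <- phi_psi(m2, "A"), "missing backbone")
  expect_true(is.na(pp$phi[5]) && is.na(pp$psi[5]))
  expect_false(is.na(pp$phi[3]))
})

test_that("local axis fit recovers the closed-form twist of parametric helices", {
  for (rpt in c(3.0, 3.6, 4.0)) {
    fr <- fit_local_axes(parametric_ca_helix(20, rpt))
    expect_lt(max(abs(fr$twist - 360 / rpt)), 1)
  }
  # straight ideal helix: all windows agree, axes within 1 degree
  fr <- fit_local_axes(parametric_ca_helix(25, 3.6, rise = 1.5))
  ax <- as.matrix(fr[, c("axis_x", "axis_y", "axis_z")])
  angs <- apply(ax, 1, function(v) vec_angle(ax[1, ], c(0, 0, 0), v))
  expect_lt(max(angs), 1)
  expect_lt(max(abs(fr$rise - 1.5)), 0.01)
  # TLS cross-check oracle on the built helix
  run <- gpcrgeom:::ca_run(ideal_helix(25), "A")
  fr2 <- fit_local_axes(run$ca)
  mean_axis <- gpcrgeom:::unit(colMeans(as.matrix(
    fr2[, c("axis_x", "axis_y", "axis_z")])))
  tls <- oracle_tls_axis(run$ca)
  if (sum(tls * mean_axis) < 0) tls <- -tls   # orientation-free comparison
  expect_lt(vec_angle(mean_axis, c(0, 0, 0), tls), 2)
  expect_error(fit_local_axes(matrix(0, 3, 3)), "at least 4")
  line <- cbind(seq_len(6), 0, 0)
  expect_error(fit_local_axes(line), "degenerate|collinear")
})

test_that("unit twist profile is ~100 deg for the ideal helix, 120 for 3.0 res/turn", {
  m <- ideal_helix(25)
  tw <- unit_twist_profile(m, "A")
  expect_true(all(is.na(tw$twist[1:3])))
  vals <- tw$twist[!is.na(tw$twist)]
  expect_lt(max(abs(vals - 100)), 1)
  fr <- fit_local_axes(parametric_ca_helix(15, 3.0))
  expect_lt(max(abs(fr$twist - 120)), 1)
})

test_that("unit bend profile: straight helix flat, constructed kink peaks at apex", {
  m <- ideal_helix(25)
  bd <- unit_bend_profile(m, "A")
  expect_lt(max(bd$bend, na.rm = TRUE), 2)
  for (kang in c(20, 35)) {
    mk <- build_peptide(peptide_spec(POLYA25,
                                     kink = list(apex = 13, angle = kang)))
    bk <- unit_bend_profile(mk, "A")
    expect_equal(bk$res_seq[which.max(bk$bend)], 13)
    expect_lt(abs(max(bk$bend, na.rm = TRUE) - kang), 2)
  }
})

test_that("two-segment kink reproduces the inter-axis angle", {
  mk <- build_peptide(peptide_spec(POLYA25, kink = list(apex = 13, angle = 35)))
  run <- gpcrgeom:::ca_run(mk, "A")
  fr <- fit_local_axes(run$ca)
  ax <- function(rows) gpcrgeom:::unit(colMeans(as.matrix(
    fr[rows, c("axis_x", "axis_y", "axis_z")])))
  a_n <- ax(fr$window_start <= 8)
  a_c <- ax(fr$window_start >= 14)
  expect_lt(abs(vec_angle(a_n, c(0, 0, 0), a_c) - 35), 2)
})

test_that("dihedrals, twist and bend are rigid-motion invariant; mirror flips dihedrals", {
  m <- build_peptide(peptide_spec(POLYA25, kink = list(apex = 13, angle = 20)))
  tr <- random_rigid_transform(7)
  m2 <- transform_model(m, tr$R, tr$t)
  pp1 <- phi_psi(m, "A"); pp2 <- phi_psi(m2, "A")
  expect_equal(pp1$phi, pp2$phi, tolerance = 1e-6)
  expect_equal(pp1$psi, pp2$psi, tolerance = 1e-6)
  b1 <- unit_bend_profile(m, "A"); b2 <- unit_bend_profile(m2, "A")
  expect_equal(b1$bend, b2$bend, tolerance = 1e-6)
  t1 <- unit_twist_profile(m, "A"); t2 <- unit_twist_profile(m2, "A")
  expect_equal(t1$twist, t2$twist, tolerance = 1e-6)
  # mirror antisymmetry
  mr <- reflect_model(m)
  ppr <- phi_psi(mr, "A")
  expect_equal(ppr$phi, -pp1$phi, tolerance = 1e-6)
  expect_equal(ppr$psi, -pp1$psi, tolerance = 1e-6)
  br <- unit_bend_profile(mr, "A")
  expect_equal(br$bend, b1$bend, tolerance = 1e-6)
})

test_that("helix_profile indexes offsets relative to the motif residue", {
  m <- ideal_helix(25)
  hp <- helix_profile(m, "A", motif_i = 12)
  expect_equal(hp$offset, -7:4)
  expect_equal(hp$res_seq, 5:16)
  expect_false(any(is.na(hp$phi)))
  expect_false(any(is.na(hp$unit_twist)))
  # out-of-range offsets carry NA markers
  hp2 <- helix_profile(m, "A", motif_i = 4)
  expect_true(is.na(hp2$phi[1]))     # residue -3 does not exist
  expect_true(all(is.na(hp2$unit_twist[hp2$res_seq < 4])))
})
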