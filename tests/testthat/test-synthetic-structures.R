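test_that("peptide_spec validates input", {
  expect_error(peptide_spec("AXZ"), "invalid amino-acid")
  expect_error(peptide_spec("AGA", chi1_targets = c("2" = -60)), "Gly/Ala")
  expect_error(peptide_spec("ACA", chi1_targets = c("9" = -60)), "indices")
  expect_error(peptide_spec(POLYA25, kink = list(apex = 2, angle = 20)),
               "interior")
})

test_that("construction inverses: phi/psi, chi1 and kink at stated tolerances", {
  phi <- rep(-60, 25); psi <- rep(-45, 25)
  phi[10] <- -80; psi[15] <- -20
  tg <- c("12" = -65)
  sq <- strsplit(POLYA25, "")[[1]]; sq[12] <- "C"
  m <- build_peptide(peptide_spec(paste(sq, collapse = ""), phi = phi,
                                  psi = psi, chi1_targets = tg))
  pp <- phi_psi(m, "A")
  expect_lt(max(abs(pp$phi[-1] - phi[-1])), 0.1)
  expect_lt(max(abs(pp$psi[-25] - psi[-25])), 0.1)
  expect_lt(abs(chi1(m, "A", 12)$chi1 - (-65)), 0.1)
  mk <- build_peptide(peptide_spec(POLYA25, kink = list(apex = 14,
                                                        angle = 27)))
  bk <- unit_bend_profile(mk, "A")
  expect_lt(abs(bk$bend[bk$res_seq == 14] - 27), 2)
  expect_lte(abs(bk$res_seq[which.max(bk$bend)] - 14), 1)
})

test_that("conformer panel: ten systems, labels consistent, XWAP variant", {
  panel <- build_all_conformers()
  expect_length(panel, 10)
  expect_true("AAAP" %in% names(panel))
  for (p in panel) {
    if (p$x_residue == "A") next
    c1 <- chi1(p$model, "A", p$motif_i)
    expect_equal(classify_rotamer(c1$chi1), p$rotamer)
    expect_lt(abs(gpcrgeom:::circular_diff(c1$chi1, p$chi1)), 0.1)
    # motif layout: X at i, Pro at i+3
    rt <- gpcrgeom:::residue_table(p$model, "A")
    expect_equal(rt$res_name[p$motif_i + 3], "PRO")
  }
  wpanel <- build_all_conformers(motif = "XWAP")
  expect_length(wpanel, 10)
  p <- wpanel[["CWAP g+"]]
  rt <- gpcrgeom:::residue_table(p$model, "A")
  expect_equal(rt$res_name[p$motif_i + 1], "TRP")
})

test_that("perturb_ensemble: sigma 0 identity, seeded determinism, noise scale", {
  base <- ideal_helix(10)
  e0 <- perturb_ensemble(ensemble_spec(base, 5, 0, seed = 1))
  for (m in e0$models)
    expect_equal(m$atoms$x, base$atoms$x, tolerance = 1e-12)
  e1 <- perturb_ensemble(ensemble_spec(base, 5, 0.1, seed = 42))
  e2 <- perturb_ensemble(ensemble_spec(base, 5, 0.1, seed = 42))
  expect_identical(e1$models[[4]]$atoms$x, e2$models[[4]]$atoms$x)
  e3 <- perturb_ensemble(ensemble_spec(base, 5, 0.1, seed = 43))
  expect_false(identical(e1$models[[1]]$atoms$x, e3$models[[1]]$atoms$x))
  disp <- e1$models[[1]]$atoms$x - base$atoms$x
  expect_lt(abs(stats::sd(disp) - 0.1), 0.05)
  ei <- perturb_ensemble(ensemble_spec(base, 3, 0.1, seed = 4,
                                       include_unperturbed = TRUE))
  expect_equal(ei$models[[1]]$atoms$x, base$atoms$x, tolerance = 1e-12)
})

test_that("hbond fixtures honor requested geometry exactly, pre-PDB rounding", {
  grid <- expand.grid(d = c(2.4, 3.2, 3.8, 4.4, 8.8),
                      a = c(45, 84.5, 120.2, 180))
  for (k in seq_len(nrow(grid))) {
    fx <- build_hbond_fixture("CYS", "ASN", grid$d[k], grid$a[k])
    D <- gpcrgeom:::atom_xyz(fx, "A", 1, "SG")
    CB <- gpcrgeom:::atom_xyz(fx, "A", 1, "CB")
    A <- gpcrgeom:::atom_xyz(fx, "A", 10, "OD1")
    expect_equal(sqrt(sum((A - D)^2)), grid$d[k], tolerance = 1e-6)
    expect_equal(vec_angle(CB, D, A), grid$a[k], tolerance = 1e-6)
  }
  expect_error(build_hbond_fixture("CYS", "ASN", -1, 90), "unrealizable")
  expect_error(build_hbond_fixture("CYS", "ASN", 3, 200), "unrealizable")
  expect_error(build_hbond_fixture("GLY", "ASN", 3, 90), "unsupported donor")
})

test_that("generated structures survive the PDB round trip", {
  panel <- build_all_conformers()
  m <- panel[["CAAP g+"]]$model
  back <- read_pdb(write_pdb(m), multi_model = FALSE)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_lt(max(abs(back$atoms$z - m$atoms$z)), 5e-4 + 1e-9)
  c1 <- chi1(back, "A", panel[["CAAP g+"]]$motif_i)
  expect_lt(abs(c1$chi1 - (-60)), 0.1)
})

test_that("toy_alignment: determinism, counts vs probabilities, validation", {
  a1 <- toy_alignment(50, list("6.47" = c(C = 0.7, S = 0.2)), seed = 9)
  a2 <- toy_alignment(50, list("6.47" = c(C = 0.7, S = 0.2)), seed = 9)
  expect_identical(a1$sequences, a2$sequences)
  # probability remainder becomes gaps
  a3 <- toy_alignment(2000, list("p" = c(C = 0.5)), seed = 10)
  col <- substr(a3$sequences, a3$column_map[["p"]], a3$column_map[["p"]])
  expect_lt(abs(mean(col == "-") - 0.5), 0.05)
  expect_error(toy_alignment(10, list(p = c(C = 0.9, S = 0.3)), seed = 1),
               "more than 1")
  expect_error(toy_alignment(10, list(p = c(C = -1)), seed = 1), "negative")
})

test_that("parametric helix is the closed-form oracle it claims to be", {
  for (rpt in c(3.0, 3.6, 4.0)) {
    ca <- parametric_ca_helix(16, rpt, radius = 2.3, rise = 1.5)
    fr <- fit_local_axes(ca)
    expect_equal(fr$twist, rep(360 / rpt, nrow(fr)), tolerance = 1e-9)
    expect_equal(fr$rise, rep(1.5, nrow(fr)), tolerance = 1e-9)
  }
})
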