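test_that("single-frame ensemble profile equals the frame profile with zero sd", {
  m <- ideal_helix(25)
  ep <- ensemble_profile(as_ensemble(m), "A", 12)
  hp <- helix_profile(m, "A", 12)
  expect_equal(ep$mean$phi, hp$phi, tolerance = 1e-9)
  expect_equal(ep$mean$unit_twist, hp$unit_twist, tolerance = 1e-9)
  expect_true(all(ep$sd$phi[!is.na(ep$sd$phi)] == 0))
  expect_equal(ep$n_frames, 1)
})

test_that("perturbed ensembles average to the target geometry", {
  sp <- peptide_spec(POLYA25)
  ens <- perturb_ensemble(ensemble_spec(sp, n_frames = 100,
                                        noise_sigma = 0.05, seed = 5))
  ep <- ensemble_profile(ens, "A", 12, peptide_label = "AAAP")
  expect_lt(max(abs(ep$mean$phi - (-57)), na.rm = TRUE), 2)
  expect_lt(max(abs(ep$mean$psi - (-47)), na.rm = TRUE), 2)
  expect_lt(abs(mean(ep$mean$unit_twist, na.rm = TRUE) - 100), 1)
  expect_true(all(ep$sd$phi[!is.na(ep$sd$phi)] > 0))
})

test_that("circular averaging is correct where the naive mean fails", {
  angles <- c(176, -178, 179, -177)
  expect_lt(abs(gpcrgeom:::circular_diff(circular_mean(angles), 180)), 1)
  expect_lt(abs(naive_mean(angles)), 90)   # naive mean collapses to ~0
  # wrap-around ensemble through the profile machinery: psi near 180
  sp <- peptide_spec(paste(rep("A", 10), collapse = ""), phi = -179,
                     psi = 179)
  ens <- perturb_ensemble(ensemble_spec(sp, n_frames = 60,
                                        noise_sigma = 0.03, seed = 8))
  ep <- ensemble_profile(ens, "A", 5, offsets = -2:2)
  wrap_err <- abs(gpcrgeom:::circular_diff(ep$mean$psi, 179))
  expect_lt(max(wrap_err, na.rm = TRUE), 3)
})

test_that("profile_delta: identity, antisymmetry, constructed offsets, NA propagation", {
  sp_ref <- peptide_spec(POLYA25)
  ens_ref <- perturb_ensemble(ensemble_spec(sp_ref, 40, 0.02, seed = 21))
  ref <- ensemble_profile(ens_ref, "A", 12, peptide_label = "ref")
  expect_true(all(abs(as.matrix(profile_delta(ref, ref)[, -1])) < 1e-9,
                  na.rm = TRUE))
  # +10 degree psi offset at a single position
  psi <- rep(-47, 25); psi[12 - 3] <- -37
  sp_t <- peptide_spec(POLYA25, psi = psi)
  ens_t <- perturb_ensemble(ensemble_spec(sp_t, 40, 0.02, seed = 22))
  tst <- ensemble_profile(ens_t, "A", 12, peptide_label = "shifted")
  d <- profile_delta(tst, ref)
  expect_lt(abs(d$delta_psi[d$offset == -3] - 10), 1.5)
  expect_lt(max(abs(d$delta_psi[!d$offset %in% c(-3, -4)]), na.rm = TRUE), 1.5)
  # antisymmetry
  d_rev <- profile_delta(ref, tst)
  expect_equal(as.matrix(d[, -1]), -as.matrix(d_rev[, -1]), tolerance = 1e-9)
  # undefined positions propagate
  short <- ensemble_profile(ens_ref, "A", 12, offsets = -2:4)
  d2 <- profile_delta(ref, short)
  expect_equal(d2$offset, -2:4)
  expect_error(profile_delta(ref, ensemble_profile(ens_ref, "A", 12,
                                                   offsets = 20:22)))
})

test_that("frame order does not change the ensemble profile", {
  sp <- peptide_spec(POLYA25)
  ens <- perturb_ensemble(ensemble_spec(sp, 30, 0.05, seed = 31))
  set.seed(1); perm <- sample(30)
  models <- ens$models[perm]
  for (i in seq_along(models)) models[[i]]$model_id <- i
  ens2 <- gpcrgeom:::new_ensemble(models)
  p1 <- ensemble_profile(ens, "A", 12)
  p2 <- ensemble_profile(ens2, "A", 12)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-9)
})

test_that("ensemble mean converges toward the target as 1/sqrt(n)", {
  sp <- peptide_spec(POLYA25)
  err_at <- function(n, seed) {
    ens <- perturb_ensemble(ensemble_spec(sp, n, 0.08, seed = seed))
    ep <- ensemble_profile(ens, "A", 12)
    mean(abs(ep$mean$phi - (-57)), na.rm = TRUE)
  }
  e25 <- mean(vapply(1:3, function(s) err_at(25, 100 + s), numeric(1)))
  e400 <- mean(vapply(1:3, function(s) err_at(400, 200 + s), numeric(1)))
  expect_lt(e400, e25)
})

test_that("flag_distortion thresholds per channel and position", {
  sp_ref <- peptide_spec(POLYA25)
  ref <- ensemble_profile(as_ensemble(build_peptide(sp_ref)), "A", 12,
                          peptide_label = "ref")
  d0 <- profile_delta(ref, ref)
  fd <- flag_distortion(d0, 2)
  expect_equal(fd$verdict, "unperturbed")
  # a 15 degree phi excursion at i-3 is flagged there
  phi <- rep(-57, 25); phi[12 - 3] <- -72
  tst <- ensemble_profile(as_ensemble(build_peptide(
    peptide_spec(POLYA25, phi = phi))), "A", 12, peptide_label = "tst")
  d <- profile_delta(tst, ref)
  fd2 <- flag_distortion(d, 10)
  expect_equal(fd2$verdict, "perturbed")
  expect_true(any(fd2$flagged$channel == "phi" & fd2$flagged$offset == -3))
  # vacuous threshold never flags
  expect_equal(flag_distortion(d, 180)$verdict, "unperturbed")
})

test_that("plot and TSV exports run without error", {
  ref <- ensemble_profile(as_ensemble(ideal_helix(25)), "A", 12)
  d <- profile_delta(ref, ref)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_profile_tsv(ref$mean, f1)
  write_delta_tsv(d, f2)
  expect_true(file.exists(f1) && file.exists(f2))
  got <- utils::read.delim(f2)
  expect_equal(names(got)[1], "offset")
  pdf(NULL)
  expect_silent(plot_profile_delta(d))
  dev.off()
})
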