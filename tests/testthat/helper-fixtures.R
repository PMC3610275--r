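# Shared fixtures and independent oracles. Oracles deliberately use a
# different construction than the package code paths they check.

POLYA25 <- paste(rep("A", 25), collapse = "")

ideal_helix <- function(n = 25, phi = -57, psi = -47) {
  build_peptide(peptide_spec(paste(rep("A", n), collapse = ""),
                             phi = phi, psi = psi))
}

# Independent dihedral oracle: project the flanking bonds onto the plane
# perpendicular to the central bond and take the signed angle between the
# projections (vs the package's cross-product/atan2 normal-vector route).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  cx <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sum(cx * b), sum(u * w)) * 180 / pi
  # oracle measures from p1-side to p4-side; IUPAC sign has cis = 0
  if (ang <= -180) ang <- ang + 360
  ang
}

# Total-least-squares line direction through a point cloud (PCA), the
# cross-check oracle for the local-axis fit on long ideal helices.
oracle_tls_axis <- function(pts) {
  ctr <- scale(pts, scale = FALSE)
  v <- svd(ctr)$v[, 1]
  if (v[3] < 0) v <- -v
  v
}

# naive arithmetic mean of angles -- the oracle that FAILS on wrap-around,
# used to demonstrate the circular mean handles what it cannot
naive_mean <- function(x) mean(x[is.finite(x)])

random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- gpcrgeom:::rotation_matrix(ax, runif(1, 10, 350))
  list(R = R, t = rnorm(3, sd = 20))
}

transform_model <- function(model, R, t) {
  a <- model$atoms
  xyz <- t(R %*% t(as.matrix(a[, c("x", "y", "z")]))) +
    matrix(t, nrow(a), 3, byrow = TRUE)
  a[, c("x", "y", "z")] <- xyz
  gpcrgeom:::new_structure_model(a, model_id = model$model_id,
                                 source_id = model$source_id)
}

reflect_model <- function(model) {
  a <- model$atoms
  a$x <- -a$x
  gpcrgeom:::new_structure_model(a, model_id = model$model_id,
                                 source_id = model$source_id)
}

# receptor-like helical peptide: CWxP and NPxxY motifs in one continuous
# chain, with a configurable residue at position 6.47 and its chi1
receptor_peptide <- function(x647 = "C", chi1_647 = -60, mid = "W") {
  # layout: 7 leading Ala, then x647 W L P (6.47-6.50), 10 Ala,
  # N P L I Y (7.49-7.53), 3 trailing Ala
  sq <- paste0(paste(rep("A", 7), collapse = ""), x647, mid, "LP",
               paste(rep("A", 10), collapse = ""), "NPLIY", "AAA")
  i647 <- 8L
  tg <- if (x647 %in% c("A", "G")) NULL else
    stats::setNames(chi1_647, as.character(i647))
  model <- build_peptide(peptide_spec(sq, chi1_targets = tg))
  list(model = model, i647 = i647, sequence = sq)
}

# three serine residues whose OG atoms sit on a line with controlled
# spacing -- the engineered chain for network-scan tests
ser_triplet <- function(spacing = 3.0) {
  base <- build_peptide(peptide_spec("S",
                                     chi1_targets = c("1" = -60)))
  og <- gpcrgeom:::atom_xyz(base, "A", 1, "OG")
  shift_copy <- function(res_seq, dx) {
    a <- base$atoms
    a$x <- a$x + dx
    a$res_seq <- res_seq
    a
  }
  atoms <- rbind(shift_copy(1L, 0), shift_copy(20L, spacing),
                 shift_copy(40L, 2 * spacing))
  atoms$serial <- seq_len(nrow(atoms))
  gpcrgeom:::new_structure_model(atoms, source_id = "ser-triplet")
}

add_water <- function(model, xyz, res_seq = 500L, chain = "W") {
  a <- model$atoms
  w <- a[1, , drop = FALSE]
  w$record <- "HETATM"; w$name <- "O"; w$alt_loc <- ""
  w$res_name <- "HOH"; w$chain_id <- chain; w$res_seq <- res_seq
  w$ins_code <- ""; w$x <- xyz[1]; w$y <- xyz[2]; w$z <- xyz[3]
  w$occupancy <- 1; w$b_factor <- 0; w$element <- "O"; w$is_hetero <- TRUE
  a <- rbind(a, w)
  a$serial <- seq_len(nrow(a))
  gpcrgeom:::new_structure_model(a, source_id = model$source_id)
}
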