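# Synthetic structure generators: ideal and Pro-kinked helical peptides with
# controlled phi/psi/chi1, thermally perturbed ensembles, engineered
# hydrogen-bond fixtures and toy alignments. Everything is built from
# internal coordinates (standard bond lengths/angles; NeRF placement), so
# every geometric parameter written into a spec is recoverable by the
# analysis operations -- the construction-inverse property the test suite
# leans on.

# Backbone geometry (Engh & Huber style)
BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8,
  # improper torsion N-C-CA-CB is +122.6 for L-amino acids (IUPAC sign)
  cb_bond = 1.530, cb_angle = 110.1, cb_improper = 122.6
)

# Side-chain gamma-atom geometry per residue (bond from CB, angle CA-CB-G).
# chi1 is imposed through the torsion N-CA-CB-G.
GAMMA_GEOM <- list(
  CYS = list(atom = "SG",  bond = 1.808, angle = 114.0),
  SER = list(atom = "OG",  bond = 1.417, angle = 110.8),
  THR = list(atom = "OG1", bond = 1.433, angle = 109.6),
  TRP = list(atom = "CG",  bond = 1.498, angle = 113.6),
  ASN = list(atom = "CG",  bond = 1.516, angle = 112.6),
  GLN = list(atom = "CG",  bond = 1.520, angle = 114.1),
  ASP = list(atom = "CG",  bond = 1.516, angle = 112.6),
  HIS = list(atom = "CG",  bond = 1.497, angle = 113.8),
  VAL = list(atom = "CG1", bond = 1.521, angle = 110.5),
  ILE = list(atom = "CG1", bond = 1.530, angle = 110.4),
  LEU = list(atom = "CG",  bond = 1.530, angle = 116.3),
  MET = list(atom = "CG",  bond = 1.520, angle = 114.1),
  PHE = list(atom = "CG",  bond = 1.502, angle = 113.8),
  TYR = list(atom = "CG",  bond = 1.512, angle = 113.9),
  LYS = list(atom = "CG",  bond = 1.520, angle = 114.1),
  ARG = list(atom = "CG",  bond = 1.520, angle = 114.1),
  GLU = list(atom = "CG",  bond = 1.520, angle = 114.1)
)

ONE2THREE <- stats::setNames(names(AMINO3), AMINO3)

#' Specification of a synthetic helical peptide
#'
#' @param sequence one-letter amino-acid string, e.g. a 25-mer polyalanine
#'   with a CAAP motif at its center.
#' @param phi,psi target backbone dihedrals in degrees; scalars are recycled
#'   to all residues. Defaults are ideal alpha-helix values (-57, -47).
#' @param chi1_targets named numeric vector, names are residue indices (as
#'   characters) and values target chi1 angles in degrees.
#' @param kink optional `list(apex =, angle =)`: rigid kink of the C-terminal
#'   segment about the apex residue's CA producing the requested angle
#'   between the flanking helix axes.
#' @param omega peptide-bond torsion, fixed at 180 by default.
#' @return A `PeptideSpec` object.
#' @export
peptide_spec <- function(sequence, phi = -57, psi = -47,
                         chi1_targets = NULL, kink = NULL, omega = 180) {
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% names(ONE2THREE)))
    stop("invalid amino-acid letters in sequence: ",
         paste(unique(aa[!aa %in% names(ONE2THREE)]), collapse = " "),
         call. = FALSE)
  n <- length(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (!is.null(chi1_targets)) {
    idx <- as.integer(names(chi1_targets))
    if (anyNA(idx) || any(idx < 1 | idx > n))
      stop("chi1_targets names must be residue indices within the sequence",
           call. = FALSE)
    bad <- aa[idx] %in% c("G", "A")
    if (any(bad))
      stop("chi1 target requested on Gly/Ala at position ",
           paste(idx[bad], collapse = " "), call. = FALSE)
  }
  if (!is.null(kink)) {
    stopifnot(is.list(kink), all(c("apex", "angle") %in% names(kink)))
    if (kink$apex <= 4 || kink$apex >= n - 3)
      stop("kink apex must be interior (>= 5 residues from each terminus)",
           call. = FALSE)
  }
  structure(list(sequence = sequence, phi = phi, psi = psi,
                 chi1_targets = chi1_targets, kink = kink, omega = omega),
            class = "PeptideSpec")
}

build_sidechain <- function(res3, xyz, chi1, chain_id, res_seq) {
  # xyz: named list with N, CA, C already placed. Returns extra atom rows.
  rows <- list()
  add <- function(name, coord, element = substr(name, 1, 1)) {
    rows[[length(rows) + 1]] <<- list(name = name, x = coord[1],
                                      y = coord[2], z = coord[3],
                                      element = element)
  }
  if (res3 == "GLY") return(rows)
  cb_ang <- if (res3 == "PRO") 103.2 else BB$cb_angle
  cb_imp <- if (res3 == "PRO") 115.3 else BB$cb_improper
  cb <- place_atom(xyz$N, xyz$C, xyz$CA, BB$cb_bond, cb_ang, cb_imp)
  add("CB", cb, "C")
  if (res3 == "ALA") return(rows)
  if (res3 == "PRO") {
    # rigid standard pucker; the ring is closed only approximately
    cg <- place_atom(xyz$N, xyz$CA, cb, 1.495, 104.5, -25)
    cd <- place_atom(xyz$CA, cb, cg, 1.507, 105.5, 35)
    add("CG", cg, "C"); add("CD", cd, "C")
    return(rows)
  }
  gg <- GAMMA_GEOM[[res3]]
  if (is.null(gg)) return(rows)
  if (is.null(chi1)) chi1 <- -60
  g <- place_atom(xyz$N, xyz$CA, cb, gg$bond, gg$angle, chi1)
  add(gg$atom, g, substr(gg$atom, 1, 1))
  if (res3 == "THR") {
    cg2 <- place_atom(xyz$N, xyz$CA, cb, 1.521, 110.5, chi1 + 120)
    add("CG2", cg2, "C")
  }
  if (res3 %in% c("ASN", "ASP")) {
    o1 <- place_atom(xyz$CA, cb, g, 1.231, 120.8, -60)
    x2 <- if (res3 == "ASN") list(nm = "ND2", b = 1.328, a = 116.4, e = "N")
          else list(nm = "OD2", b = 1.249, a = 118.4, e = "O")
    n2 <- place_atom(xyz$CA, cb, g, x2$b, x2$a, 120)
    add(if (res3 == "ASN") "OD1" else "OD1", o1, "O")
    add(x2$nm, n2, x2$e)
  }
  if (res3 == "GLN") {
    cd <- place_atom(xyz$CA, cb, g, 1.516, 112.6, 180)
    oe1 <- place_atom(cb, g, cd, 1.231, 120.8, -60)
    ne2 <- place_atom(cb, g, cd, 1.328, 116.4, 120)
    add("CD", cd, "C"); add("OE1", oe1, "O"); add("NE2", ne2, "N")
  }
  if (res3 == "HIS") {
    nd1 <- place_atom(xyz$CA, cb, g, 1.378, 122.7, -60)
    cd2 <- place_atom(xyz$CA, cb, g, 1.356, 131.0, 120)
    ce1 <- place_atom(cb, g, nd1, 1.321, 109.3, 180)
    ne2 <- place_atom(g, nd1, ce1, 1.321, 111.0, 0)
    add("ND1", nd1, "N"); add("CD2", cd2, "C")
    add("CE1", ce1, "C"); add("NE2", ne2, "N")
  }
  rows
}

#' Build a peptide structure from internal coordinates
#'
#' Sequentially places backbone atoms honoring the spec's phi/psi (omega
#' fixed at 180), adds side chains honoring any chi1 targets, then applies
#' the optional rigid Pro-kink: all atoms C-terminal of the apex CA are
#' rotated about an axis through the apex CA perpendicular to the N-terminal
#' helix axis, so the angle between the flanking segment axes equals the
#' requested kink angle.
#'
#' @param spec a [peptide_spec()].
#' @param chain_id chain identifier for the generated model.
#' @param source_id label for the generated model.
#' @return A StructureModel.
#' @export
build_peptide <- function(spec, chain_id = "A", source_id = "synthetic") {
  stopifnot(inherits(spec, "PeptideSpec"))
  aa <- strsplit(spec$sequence, "")[[1]]
  n <- length(aa)
  res3 <- unname(ONE2THREE[aa])

  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BB$n_ca, 0, 0)
  th <- deg2rad(180 - BB$ang_n_ca_c)
  C[[1]] <- CA[[1]] + BB$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                           BB$c_n, BB$ang_ca_c_n, spec$psi[i - 1])
      CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                            BB$n_ca, BB$ang_c_n_ca, spec$omega)
      C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                           BB$ca_c, BB$ang_n_ca_c, spec$phi[i])
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         BB$c_o, BB$ang_ca_c_o, spec$psi[i] + 180)
  }

  rows <- list()
  for (i in seq_len(n)) {
    xyz <- list(N = N[[i]], CA = CA[[i]], C = C[[i]])
    chi <- if (!is.null(spec$chi1_targets) &&
               as.character(i) %in% names(spec$chi1_targets))
      unname(spec$chi1_targets[[as.character(i)]]) else NULL
    bb_rows <- list(
      list(name = "N", x = N[[i]][1], y = N[[i]][2], z = N[[i]][3], element = "N"),
      list(name = "CA", x = CA[[i]][1], y = CA[[i]][2], z = CA[[i]][3], element = "C"),
      list(name = "C", x = C[[i]][1], y = C[[i]][2], z = C[[i]][3], element = "C"),
      list(name = "O", x = O[[i]][1], y = O[[i]][2], z = O[[i]][3], element = "O"))
    sc_rows <- build_sidechain(res3[i], xyz, chi, chain_id, i)
    for (r in c(bb_rows, sc_rows)) {
      rows[[length(rows) + 1]] <- data.frame(
        record = "ATOM", serial = NA_integer_, name = r$name, alt_loc = "",
        res_name = res3[i], chain_id = chain_id, res_seq = i, ins_code = "",
        x = r$x, y = r$y, z = r$z, occupancy = 1, b_factor = 0,
        element = r$element, is_hetero = FALSE, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  model <- new_structure_model(atoms, model_id = 1L, source_id = source_id)

  if (!is.null(spec$kink)) {
    model <- apply_kink(model, chain_id, spec$kink$apex, spec$kink$angle)
  }
  model
}

# Rigid kink: rotate everything C-terminal of the apex CA (apex side chain
# and N/CA stay put) about an axis through the apex CA perpendicular to the
# N-terminal segment's mean helix axis.
apply_kink <- function(model, chain_id, apex, angle) {
  a <- model$atoms
  ca_sel <- a$chain_id == chain_id & a$name == "CA" & a$res_seq <= apex
  ca <- as.matrix(a[ca_sel, c("x", "y", "z")])
  if (nrow(ca) < 5)
    stop("kink apex too close to the N-terminus to define a segment axis",
         call. = FALSE)
  frames <- fit_local_axes(ca)
  axis_n <- unit(colMeans(as.matrix(frames[, c("axis_x", "axis_y", "axis_z")])))
  # rotation axis: perpendicular to the helix axis, through the apex CA
  ref <- if (abs(axis_n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  rot_axis <- unit(cross3(axis_n, ref))
  pivot <- atom_xyz(model, chain_id, apex, "CA")
  R <- rotation_matrix(rot_axis, angle)
  move <- a$chain_id == chain_id &
    (a$res_seq > apex | (a$res_seq == apex & a$name %in% c("C", "O")))
  xyz <- t(as.matrix(a[move, c("x", "y", "z")]))
  xyz <- R %*% (xyz - pivot) + pivot
  a[move, c("x", "y", "z")] <- t(xyz)
  new_structure_model(a, model_id = model$model_id, source_id = model$source_id)
}

#' Build the full conformer panel of X-helix-Pro peptides
#'
#' Generates the polyalanine reference peptide plus one peptide per
#' combination of X in `x_residues` and chi1 rotamer well (g+ = -60, g- =
#' +60, t = 180): ten structures for the default three residues. The motif
#' (XAAP or XWAP) is centered in a 25-residue helix, with X at position i
#' and the proline three residues downstream.
#'
#' @param x_residues one-letter codes tried at the motif's X position.
#' @param motif "XAAP" or "XWAP".
#' @param length peptide length (odd; X sits at (length + 1)/2 - 1).
#' @param phi,psi helix backbone targets, degrees.
#' @return Named list of `list(spec =, model =, label =, chi1 =)`; the
#'   reference peptide carries `chi1 = NA`.
#' @export
build_all_conformers <- function(x_residues = c("C", "S", "T"),
                                 motif = c("XAAP", "XWAP"),
                                 length = 25, phi = -57, psi = -47) {
  motif <- match.arg(motif)
  rot <- c("g+" = -60, "g-" = 60, "t" = 180)
  i_pos <- (length + 1) %/% 2 - 1          # X position
  mid <- if (motif == "XWAP") "W" else "A"
  make_seq <- function(x) {
    s <- rep("A", length)
    s[i_pos] <- x; s[i_pos + 1] <- mid; s[i_pos + 3] <- "P"
    paste(s, collapse = "")
  }
  out <- list()
  ref_spec <- peptide_spec(make_seq("A"), phi = phi, psi = psi)
  ref_label <- sub("X", "A", motif)
  out[[ref_label]] <- list(spec = ref_spec, model = build_peptide(
    ref_spec, source_id = ref_label), label = ref_label, chi1 = NA_real_,
    x_residue = "A", rotamer = NA_character_, motif_i = i_pos)
  for (x in x_residues) {
    for (r in names(rot)) {
      label <- paste0(sub("X", x, motif), " ", r)
      tgt <- stats::setNames(rot[[r]], as.character(i_pos))
      sp <- peptide_spec(make_seq(x), phi = phi, psi = psi,
                         chi1_targets = tgt)
      out[[label]] <- list(spec = sp,
                           model = build_peptide(sp, source_id = label),
                           label = label, chi1 = rot[[r]], x_residue = x,
                           rotamer = r, motif_i = i_pos)
    }
  }
  out
}

#' Specification of a perturbed conformational ensemble
#'
#' @param base a PeptideSpec or a StructureModel used as the reference
#'   conformation.
#' @param n_frames number of models to generate.
#' @param noise_sigma isotropic Gaussian displacement SD per atom
#'   coordinate, Angstrom.
#' @param seed mandatory RNG seed (reproducibility contract).
#' @param include_unperturbed if TRUE the first frame is the base structure.
#' @return An `EnsembleSpec` object.
#' @export
ensemble_spec <- function(base, n_frames, noise_sigma, seed,
                          include_unperturbed = FALSE) {
  stopifnot(n_frames >= 1, noise_sigma >= 0, !missing(seed))
  structure(list(base = base, n_frames = as.integer(n_frames),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 include_unperturbed = include_unperturbed),
            class = "EnsembleSpec")
}

#' Generate a thermally perturbed ensemble
#'
#' Adds i.i.d. Gaussian noise to every atom coordinate of the base structure,
#' one independent draw per frame. Deterministic under the spec's seed. This
#' is a deliberate simplification of thermal motion: it has no covariance
#' structure, so it validates averaging machinery, not physics.
#'
#' @param spec an [ensemble_spec()].
#' @return An Ensemble of `n_frames` models.
#' @export
perturb_ensemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  base <- if (inherits(spec$base, "PeptideSpec")) build_peptide(spec$base)
          else spec$base
  stopifnot(inherits(base, "StructureModel"))
  a0 <- base$atoms
  nat <- nrow(a0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  models <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    a <- a0
    if (!(k == 1 && spec$include_unperturbed) && spec$noise_sigma > 0) {
      a$x <- a$x + stats::rnorm(nat, 0, spec$noise_sigma)
      a$y <- a$y + stats::rnorm(nat, 0, spec$noise_sigma)
      a$z <- a$z + stats::rnorm(nat, 0, spec$noise_sigma)
    }
    models[[k]] <- new_structure_model(a, model_id = k,
                                       source_id = base$source_id)
  }
  new_ensemble(models, source_id = base$source_id)
}

#' Engineer a two-residue hydrogen-bond fixture with exact geometry
#'
#' Places a donor residue (its side-chain terminal heavy atom D) and an
#' acceptor residue so that the D...A distance and the Cbeta-D...A angle
#' equal the requested values exactly. Used to exercise the interaction
#' module against known answers.
#'
#' @param donor_res three-letter code of the donor (CYS, SER, THR, or an
#'   amide donor ASN/GLN donating through ND2/NE2).
#' @param acceptor_res three-letter code of the acceptor (ASN, GLN, SER,
#'   THR, ASP, HIS).
#' @param da_distance donor-acceptor heavy-atom distance, Angstrom.
#' @param approach_angle Cbeta-D...A angle at the donor atom, degrees.
#' @param facing for Asn/Gln acceptors, which amide atom receives the bond:
#'   "CO" (OD1/OE1, the default) or "NH2" (ND2/NE2).
#' @param donor_chi1 chi1 given to the donor side chain, degrees.
#' @return A StructureModel with the donor as residue 1 and the acceptor as
#'   residue 10 of chain A (numbering gap keeps them non-bonded).
#' @export
build_hbond_fixture <- function(donor_res, acceptor_res, da_distance,
                                approach_angle, facing = c("CO", "NH2"),
                                donor_chi1 = -60) {
  facing <- match.arg(facing)
  if (da_distance <= 0)
    stop("unrealizable fixture: nonpositive distance", call. = FALSE)
  if (approach_angle < 0 || approach_angle > 180)
    stop("unrealizable fixture: angle outside [0, 180]", call. = FALSE)
  donor_res <- toupper(donor_res); acceptor_res <- toupper(acceptor_res)
  dterm <- c(CYS = "SG", SER = "OG", THR = "OG1", GLN = "NE2",
             ASN = "ND2")[donor_res]
  if (is.na(dterm))
    stop("unsupported donor residue: ", donor_res, call. = FALSE)
  aat <- switch(acceptor_res,
                ASN = if (facing == "CO") "OD1" else "ND2",
                GLN = if (facing == "CO") "OE1" else "NE2",
                SER = "OG", THR = "OG1", ASP = "OD1", HIS = "ND1",
                stop("unsupported acceptor residue: ", acceptor_res,
                     call. = FALSE))

  donor <- build_peptide(peptide_spec(
    unname(AMINO3[donor_res]),
    chi1_targets = stats::setNames(donor_chi1, "1")), source_id = "hbond-fixture")
  da <- donor$atoms
  D <- unlist(da[da$name == dterm, c("x", "y", "z")], use.names = FALSE)
  CB <- unlist(da[da$name == "CB", c("x", "y", "z")], use.names = FALSE)

  # acceptor direction: rotate the CB->D extension by (180 - approach_angle)
  u <- unit(D - CB)                       # extension direction (angle 180)
  perp <- unit(cross3(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  v <- as.vector(rotation_matrix(perp, 180 - approach_angle) %*% u)
  A <- D + da_distance * v

  acc <- build_peptide(peptide_spec(unname(AMINO3[acceptor_res])),
                       source_id = "hbond-fixture")
  aa <- acc$atoms
  A0 <- unlist(aa[aa$name == aat, c("x", "y", "z")], use.names = FALSE)
  # orient the acceptor residue body away from the donor along v
  body0 <- colMeans(aa[aa$name != aat, c("x", "y", "z")])
  w <- unit(as.numeric(body0) - A0)
  ax <- cross3(w, v)
  Rm <- if (vnorm(ax) < 1e-9) diag(3) else
    rotation_matrix(ax, vec_angle(w + A0, A0 * 0 + A0, v + A0))
  xyz <- t(as.matrix(aa[, c("x", "y", "z")]))
  xyz <- Rm %*% (xyz - A0) + A
  aa[, c("x", "y", "z")] <- t(xyz)
  aa$res_seq <- 10L
  out <- rbind(da, aa)
  out$serial <- seq_len(nrow(out))
  new_structure_model(out, source_id = "hbond-fixture")
}

#' Parametric CA trace of a helix with a given number of residues per turn
#'
#' Places CA atoms on an ideal cylindrical helix: CA(k) = (R cos(k O),
#' R sin(k O), k h) with O = 360/residues_per_turn. The unit twist of this
#' trace is exactly O, which makes it the closed-form oracle for the local
#' axis fit.
#'
#' @param n_res number of CA positions.
#' @param residues_per_turn helical periodicity (3.6 for an ideal
#'   alpha-helix).
#' @param radius helix radius, Angstrom.
#' @param rise axial rise per residue, Angstrom.
#' @return numeric matrix of CA coordinates, one row per residue.
#' @export
parametric_ca_helix <- function(n_res, residues_per_turn = 3.6,
                                radius = 2.3, rise = 1.5) {
  stopifnot(n_res >= 4, residues_per_turn > 2)
  k <- seq_len(n_res) - 1
  om <- deg2rad(360 / residues_per_turn)
  cbind(radius * cos(k * om), radius * sin(k * om), k * rise)
}

#' Generate a toy multiple sequence alignment with controlled columns
#'
#' Columns named in `column_spec` get a controlled residue composition;
#' remaining columns are filled with the background residue. Compositions
#' given as whole counts summing to `n_seqs` are laid down deterministically;
#' compositions given as probabilities (sum <= 1, remainder = gap) are
#' sampled, deterministically under `seed`.
#'
#' @param n_seqs number of sequences.
#' @param column_spec named list: names are generic-position labels (e.g.
#'   "6.47"), each value a named numeric vector over residues (may include
#'   `"-"` for gaps).
#' @param seed RNG seed (mandatory).
#' @param n_cols total alignment width (default: one column per spec entry).
#' @param background filler residue for unspecified columns.
#' @param path optional FASTA destination; written when non-NULL.
#' @return list with `sequences` (named character vector), `column_map`
#'   (named integer vector: generic position -> column), and `path`.
#' @export
toy_alignment <- function(n_seqs, column_spec, seed, n_cols = NULL,
                          background = "A", path = NULL) {
  stopifnot(n_seqs >= 1, length(column_spec) >= 1, !missing(seed))
  if (is.null(n_cols)) n_cols <- length(column_spec)
  if (n_cols < length(column_spec))
    stop("n_cols smaller than the number of specified columns", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  mat <- matrix(background, nrow = n_seqs, ncol = n_cols)
  column_map <- stats::setNames(seq_along(column_spec), names(column_spec))
  for (j in seq_along(column_spec)) {
    comp <- column_spec[[j]]
    if (any(comp < 0)) stop("negative composition values", call. = FALSE)
    if (all(abs(comp - round(comp)) < 1e-9) && sum(comp) == n_seqs) {
      mat[, j] <- rep(names(comp), times = round(comp))
    } else {
      if (sum(comp) > 1 + 1e-9)
        stop("probabilities for column '", names(column_spec)[j],
             "' sum to more than 1", call. = FALSE)
      p <- c(comp, "-" = max(0, 1 - sum(comp)))
      mat[, j] <- sample(names(p), n_seqs, replace = TRUE, prob = p)
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- sprintf("seq%04d", seq_len(n_seqs))
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  list(sequences = seqs, column_map = column_map, path = path)
}
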