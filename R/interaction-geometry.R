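# TM6-TM7 interaction geometry: donor-acceptor distances, Cbeta-D...A
# angles, hydrogen-bond verdicts, Asn/Gln amide-flip assessment and polar
# network scans.
#
# Hydrogen-bond criterion: thiol sulfur is a long-range, weakly directional
# donor (its H-bond has a large dispersion component and a flat potential
# energy surface), so S donors use a distance-only cutoff of 4.3 A. Oxygen
# and nitrogen donors use 3.5 A plus a loose 60 degree floor on the
# Cbeta(antecedent)-D...A angle. All cutoffs are configurable arguments.

# side-chain terminal donor atom per residue type
DONOR_TERMINAL <- c(CYS = "SG", SER = "OG", THR = "OG1", TYR = "OH",
                    ASN = "ND2", GLN = "NE2", LYS = "NZ", TRP = "NE1")

# donor-capable side-chain atoms (can carry a polar hydrogen)
SC_DONOR_ATOMS <- list(
  CYS = "SG", SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
  GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1")

# acceptor-capable side-chain atoms
SC_ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

# heavy-atom antecedent used for the angle at a donor/acceptor atom
ATOM_ANTECEDENT <- c(SG = "CB", OG = "CB", OG1 = "CB", OH = "CZ",
                     OD1 = "CG", OD2 = "CG", ND2 = "CG",
                     OE1 = "CD", OE2 = "CD", NE2 = "CD", ND1 = "CG",
                     NE = "CD", NH1 = "CZ", NH2 = "CZ", NZ = "CE",
                     NE1 = "CD1", O = "C")

res_atom_xyz <- function(res, name) {
  hit <- res[res$name == name, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  unlist(hit[1, c("x", "y", "z")], use.names = FALSE)
}

get_residue <- function(model, chain, res_seq, ins_code = "") {
  a <- model$atoms
  res <- a[a$chain_id == chain & a$res_seq == res_seq &
             a$ins_code == ins_code, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("residue absent: chain %s residue %s", chain, res_seq),
         call. = FALSE)
  res
}

new_hbond_geometry <- function(donor_pos, donor_addr, donor_atom,
                               acceptor_pos, acceptor_addr, acceptor_atom,
                               facing_group, da_distance, cb_d_a_angle,
                               is_hbond = NA) {
  structure(list(donor_pos = donor_pos, donor_addr = donor_addr,
                 donor_atom = donor_atom, acceptor_pos = acceptor_pos,
                 acceptor_addr = acceptor_addr,
                 acceptor_atom = acceptor_atom, facing_group = facing_group,
                 da_distance = da_distance, cb_d_a_angle = cb_d_a_angle,
                 is_hbond = is_hbond),
            class = "HBondGeometry")
}

#' @export
print.HBondGeometry <- function(x, ...) {
  cat(sprintf("<HBond %s %s ... %s %s: %.2f A, %.1f deg, facing %s, %s>\n",
              x$donor_pos, x$donor_atom, x$acceptor_pos, x$acceptor_atom,
              x$da_distance,
              if (is.na(x$cb_d_a_angle)) NA else x$cb_d_a_angle,
              x$facing_group,
              if (isTRUE(x$is_hbond)) "H-bond" else "no H-bond"))
  invisible(x)
}

#' Decide hydrogen-bond presence from measured geometry
#'
#' TRUE iff the donor-acceptor distance is at or below the element class
#' cutoff: `s_cutoff` for sulfur donors (no angular requirement), `o_cutoff`
#' for oxygen/nitrogen donors, which additionally require the antecedent
#' angle (Cbeta-D...A) to be at least `min_angle_o`. An NA angle restricts
#' the verdict to the distance criterion.
#'
#' The sulfur cutoff default (4.3 A) is calibrated on the deposited
#' structure panel: the longest thiol-amide contact still described as a
#' hydrogen bond measures 4.3 A, while the broken agonist-state contact
#' measures 4.4 A.
#'
#' @param geometry an HBondGeometry, or a bare distance in Angstrom.
#' @param donor_element "S", "O" or "N"; inferred from the donor atom name
#'   when a geometry object is given.
#' @param s_cutoff,o_cutoff distance cutoffs, Angstrom.
#' @param min_angle_o angular floor for O/N donors, degrees.
#' @return logical verdict.
#' @export
hbond_verdict <- function(geometry, donor_element = NULL, s_cutoff = 4.3,
                          o_cutoff = 3.5, min_angle_o = 60) {
  if (inherits(geometry, "HBondGeometry")) {
    dist <- geometry$da_distance
    ang <- geometry$cb_d_a_angle
    if (is.null(donor_element))
      donor_element <- substr(geometry$donor_atom, 1, 1)
  } else {
    dist <- geometry
    ang <- NA_real_
    if (is.null(donor_element))
      stop("donor_element required when a bare distance is given",
           call. = FALSE)
  }
  if (is.na(dist)) return(FALSE)
  if (toupper(donor_element) == "S") {
    dist <= s_cutoff
  } else {
    dist <= o_cutoff && (is.na(ang) || ang >= min_angle_o)
  }
}

#' Measure donor-acceptor geometry between two generic positions
#'
#' The donor atom is the side-chain terminal heavy atom of the donor
#' residue (Cys SG, Thr OG1, Ser OG, ...). For Asn/Gln acceptors the
#' acceptor atom is whichever amide heavy atom (OD1/ND2, OE1/NE2) lies
#' nearer the donor atom, recorded in `facing_group` as "CO" or "NH2"; His
#' offers ND1/NE2 (facing "-"); Ser/Thr offer their hydroxyl; Asp/Glu their
#' nearer carboxylate oxygen; other acceptors fall back to the backbone
#' carbonyl O. Returns distance, the Cbeta(donor)-D...A angle, and the
#' H-bond verdict under the default criterion.
#'
#' @param model a StructureModel.
#' @param bw_map a [build_bw_map()] result addressing both positions.
#' @param donor_pos,acceptor_pos generic position strings (e.g. "6.47",
#'   "7.45").
#' @param force_reference_amide if TRUE and the acceptor is an Asn/Gln
#'   whose deposited amide faces the donor with NH2, the amide is flipped
#'   (OD1/ND2 coordinates swapped) before measuring -- the "assume the
#'   reference-structure amide orientation" mode.
#' @param ... cutoffs forwarded to [hbond_verdict()].
#' @return An `HBondGeometry`.
#' @export
measure_pair <- function(model, bw_map, donor_pos, acceptor_pos,
                         force_reference_amide = FALSE, ...) {
  don <- bw_lookup(bw_map, donor_pos)
  acc <- bw_lookup(bw_map, acceptor_pos)
  dres <- get_residue(model, don$chain_id, don$res_seq, don$ins_code)
  ares <- get_residue(model, acc$chain_id, acc$res_seq, acc$ins_code)

  datom <- DONOR_TERMINAL[dres$res_name[1]]
  if (is.na(datom))
    stop(sprintf("no side-chain donor atom defined for %s at %s",
                 dres$res_name[1], donor_pos), call. = FALSE)
  D <- res_atom_xyz(dres, datom)
  if (is.null(D))
    stop(sprintf("donor atom %s missing in %s %s", datom, dres$res_name[1],
                 don$res_seq), call. = FALSE)
  CB <- res_atom_xyz(dres, "CB")

  arn <- ares$res_name[1]
  facing <- "-"
  pick_nearer <- function(n1, n2, lab1, lab2) {
    x1 <- res_atom_xyz(ares, n1); x2 <- res_atom_xyz(ares, n2)
    if (is.null(x1) && is.null(x2))
      stop(sprintf("acceptor atoms %s/%s missing in %s %s", n1, n2, arn,
                   acc$res_seq), call. = FALSE)
    if (is.null(x2) || (!is.null(x1) && vnorm(x1 - D) <= vnorm(x2 - D)))
      list(atom = n1, xyz = x1, facing = lab1)
    else list(atom = n2, xyz = x2, facing = lab2)
  }
  sel <- switch(arn,
    ASN = pick_nearer("OD1", "ND2", "CO", "NH2"),
    GLN = pick_nearer("OE1", "NE2", "CO", "NH2"),
    HIS = pick_nearer("ND1", "NE2", "-", "-"),
    ASP = pick_nearer("OD1", "OD2", "-", "-"),
    GLU = pick_nearer("OE1", "OE2", "-", "-"),
    SER = list(atom = "OG", xyz = res_atom_xyz(ares, "OG"), facing = "-"),
    THR = list(atom = "OG1", xyz = res_atom_xyz(ares, "OG1"), facing = "-"),
    TYR = list(atom = "OH", xyz = res_atom_xyz(ares, "OH"), facing = "-"),
    list(atom = "O", xyz = res_atom_xyz(ares, "O"), facing = "-"))
  if (is.null(sel$xyz))
    stop(sprintf("acceptor atom %s missing in %s %s", sel$atom, arn,
                 acc$res_seq), call. = FALSE)
  facing <- sel$facing

  if (force_reference_amide && arn %in% c("ASN", "GLN") &&
      facing == "NH2") {
    # adopt the flipped amide: the O/N coordinates trade places
    o_name <- if (arn == "ASN") "OD1" else "OE1"
    sel <- list(atom = o_name,
                xyz = res_atom_xyz(ares, if (arn == "ASN") "ND2" else "NE2"),
                facing = "CO")
    facing <- "CO"
  }

  dist <- vnorm(sel$xyz - D)
  ang <- if (is.null(CB)) NA_real_ else vec_angle(CB, D, sel$xyz)
  geo <- new_hbond_geometry(
    donor_pos = donor_pos,
    donor_addr = sprintf("%s:%d%s %s", don$chain_id, don$res_seq,
                         don$ins_code, dres$res_name[1]),
    donor_atom = unname(datom), acceptor_pos = acceptor_pos,
    acceptor_addr = sprintf("%s:%d%s %s", acc$chain_id, acc$res_seq,
                            acc$ins_code, arn),
    acceptor_atom = sel$atom, facing_group = facing,
    da_distance = dist, cb_d_a_angle = ang)
  geo$is_hbond <- hbond_verdict(geo, ...)
  geo
}

amide_atoms <- function(res_name) {
  switch(res_name,
         ASN = list(o = "OD1", n = "ND2", stem = "CG"),
         GLN = list(o = "OE1", n = "NE2", stem = "CD"),
         stop("amide flip only defined for Asn/Gln", call. = FALSE))
}

score_amide_orientation <- function(o_xyz, n_xyz, env, s_cutoff = 4.3,
                                    o_cutoff = 3.5, clash_cutoff = 3.0) {
  fav <- 0L; clash <- 0L
  for (i in seq_len(nrow(env))) {
    e <- env$element[i]
    x <- c(env$x[i], env$y[i], env$z[i])
    d_o <- vnorm(o_xyz - x)
    d_n <- vnorm(n_xyz - x)
    cut_o <- if (e == "S") s_cutoff else o_cutoff
    if (e %in% c("N", "S") && d_o <= cut_o) fav <- fav + 1L
    if (e == "O" && d_n <= o_cutoff) fav <- fav + 1L
    if (e == "O" && d_o < clash_cutoff) clash <- clash + 1L
    if (e == "N" && d_n < clash_cutoff) clash <- clash + 1L
  }
  fav - 2L * clash
}

#' Assess the two amide orientations of an Asn/Gln
#'
#' The crystallographic amide-flip ambiguity: each orientation (deposited
#' and O/N-swapped) is scored as the count of favorable donor-acceptor
#' contacts with surrounding polar atoms minus twice the count of like-atom
#' clashes (O...O or N...N under 3 A). A qualitative contact-score
#' surrogate for knowledge-based flip correction tools, not a reimplementation
#' of one.
#'
#' @param model a StructureModel.
#' @param bw_map a BWMap addressing the position.
#' @param asn_pos generic position of the Asn/Gln.
#' @param environment_radius radius around the amide used to collect polar
#'   atoms, Angstrom.
#' @return A `FlipAssessment`: scores for both orientations and the
#'   preferred one ("deposited", "flipped" or "tie").
#' @export
assess_amide_flip <- function(model, bw_map, asn_pos,
                              environment_radius = 4.5) {
  addr <- bw_lookup(bw_map, asn_pos)
  res <- get_residue(model, addr$chain_id, addr$res_seq, addr$ins_code)
  am <- amide_atoms(res$res_name[1])
  o_xyz <- res_atom_xyz(res, am$o)
  n_xyz <- res_atom_xyz(res, am$n)
  if (is.null(o_xyz) || is.null(n_xyz))
    stop(sprintf("incomplete amide in %s %s: need %s and %s",
                 res$res_name[1], addr$res_seq, am$o, am$n), call. = FALSE)
  a <- model$atoms
  own <- a$chain_id == addr$chain_id & a$res_seq == addr$res_seq &
    a$ins_code == addr$ins_code
  polar <- a[!own & a$element %in% c("N", "O", "S"), , drop = FALSE]
  if (nrow(polar)) {
    d2o <- (polar$x - o_xyz[1])^2 + (polar$y - o_xyz[2])^2 +
      (polar$z - o_xyz[3])^2
    d2n <- (polar$x - n_xyz[1])^2 + (polar$y - n_xyz[2])^2 +
      (polar$z - n_xyz[3])^2
    polar <- polar[pmin(d2o, d2n) <= environment_radius^2, , drop = FALSE]
  }
  s_dep <- score_amide_orientation(o_xyz, n_xyz, polar)
  s_flip <- score_amide_orientation(n_xyz, o_xyz, polar)
  structure(list(residue_pos = asn_pos,
                 residue_addr = sprintf("%s:%d %s", addr$chain_id,
                                        addr$res_seq, res$res_name[1]),
                 score_deposited = s_dep, score_flipped = s_flip,
                 preferred = if (s_dep > s_flip) "deposited"
                             else if (s_flip > s_dep) "flipped" else "tie",
                 n_environment = nrow(polar)),
            class = "FlipAssessment")
}

#' @export
print.FlipAssessment <- function(x, ...) {
  cat(sprintf("<FlipAssessment %s (%s): deposited %d vs flipped %d -> %s>\n",
              x$residue_pos, x$residue_addr, x$score_deposited,
              x$score_flipped, x$preferred))
  invisible(x)
}

# all donor (atom, antecedent) pairs a residue offers
donor_atoms_of <- function(res) {
  nm <- SC_DONOR_ATOMS[[res$res_name[1]]]
  nm[nm %in% res$name]
}

acceptor_atoms_of <- function(res, include_backbone = FALSE) {
  nm <- SC_ACCEPTOR_ATOMS[[res$res_name[1]]]
  nm <- nm[nm %in% res$name]
  if (include_backbone && "O" %in% res$name) nm <- c(nm, "O")
  nm
}

#' Scan a set of generic positions for hydrogen-bond edges
#'
#' Measures every ordered donor-atom/acceptor-atom combination among the
#' mapped residues of `position_set` and reports, per unordered pair, the
#' best (shortest-distance) geometry that passes [hbond_verdict()], or the
#' closest contact when none passes. Backbone carbonyl oxygens are offered
#' as acceptors when `include_backbone = TRUE`. With `water_bridges = TRUE`
#' crystallographic waters within `water_cutoff` of polar atoms of two set
#' members are reported as bridges.
#'
#' @param model a StructureModel.
#' @param bw_map a BWMap covering the positions.
#' @param position_set character vector of generic positions.
#' @param include_backbone offer backbone C=O acceptors.
#' @param water_bridges detect water-mediated contacts.
#' @param water_cutoff protein-water distance cutoff, Angstrom.
#' @param ... cutoffs forwarded to [hbond_verdict()].
#' @return A `NetworkReport` with `edges` (list of HBondGeometry),
#'   `present_pairs`, `absent_pairs` and `water_bridges` (data.frame).
#' @export
network_scan <- function(model, bw_map, position_set,
                         include_backbone = FALSE, water_bridges = FALSE,
                         water_cutoff = 3.5, ...) {
  stopifnot(length(position_set) >= 2)
  residues <- lapply(position_set, function(p) {
    addr <- bw_lookup(bw_map, p)
    get_residue(model, addr$chain_id, addr$res_seq, addr$ins_code)
  })
  names(residues) <- position_set

  edges <- list()
  present <- character(0)
  absent <- character(0)
  pairs <- utils::combn(position_set, 2, simplify = FALSE)
  for (pr in pairs) {
    label <- paste(pr, collapse = "-")
    best <- NULL
    for (ord in list(pr, rev(pr))) {
      dres <- residues[[ord[1]]]
      ares <- residues[[ord[2]]]
      for (datom in donor_atoms_of(dres)) {
        D <- res_atom_xyz(dres, datom)
        ante <- res_atom_xyz(dres, ATOM_ANTECEDENT[datom])
        for (aatom in acceptor_atoms_of(ares, include_backbone)) {
          A <- res_atom_xyz(ares, aatom)
          dist <- vnorm(A - D)
          ang <- if (is.null(ante)) NA_real_ else vec_angle(ante, D, A)
          facing <- if (ares$res_name[1] %in% c("ASN", "GLN")) {
            if (aatom %in% c("OD1", "OE1")) "CO"
            else if (aatom %in% c("ND2", "NE2")) "NH2" else "-"
          } else "-"
          g <- new_hbond_geometry(
            donor_pos = ord[1],
            donor_addr = sprintf("%s:%d %s", dres$chain_id[1],
                                 dres$res_seq[1], dres$res_name[1]),
            donor_atom = datom, acceptor_pos = ord[2],
            acceptor_addr = sprintf("%s:%d %s", ares$chain_id[1],
                                    ares$res_seq[1], ares$res_name[1]),
            acceptor_atom = aatom, facing_group = facing,
            da_distance = dist, cb_d_a_angle = ang)
          g$is_hbond <- hbond_verdict(g, ...)
          if (is.null(best) ||
              (g$is_hbond && !best$is_hbond) ||
              (g$is_hbond == best$is_hbond &&
                 g$da_distance < best$da_distance))
            best <- g
        }
      }
    }
    if (!is.null(best)) {
      edges[[label]] <- best
      if (best$is_hbond) present <- c(present, label)
      else absent <- c(absent, label)
    } else {
      absent <- c(absent, label)
    }
  }

  wb <- data.frame(water = character(0), pos1 = character(0),
                   pos2 = character(0), d1 = numeric(0), d2 = numeric(0))
  if (water_bridges) {
    a <- model$atoms
    wat <- a[a$res_name %in% c("HOH", "WAT", "DOD") & a$element == "O", ,
             drop = FALSE]
    polar_of <- function(res) {
      res[res$element %in% c("N", "O", "S") &
            (res$name %in% c(unlist(SC_DONOR_ATOMS), unlist(SC_ACCEPTOR_ATOMS),
                             "O", "N")), , drop = FALSE]
    }
    for (w in seq_len(nrow(wat))) {
      wx <- c(wat$x[w], wat$y[w], wat$z[w])
      dmin <- vapply(residues, function(res) {
        p <- polar_of(res)
        if (!nrow(p)) return(Inf)
        min(sqrt((p$x - wx[1])^2 + (p$y - wx[2])^2 + (p$z - wx[3])^2))
      }, numeric(1))
      near <- which(dmin <= water_cutoff)
      if (length(near) >= 2) {
        cmb <- utils::combn(near, 2)
        for (k in seq_len(ncol(cmb))) {
          i <- cmb[1, k]; j <- cmb[2, k]
          wb <- rbind(wb, data.frame(
            water = sprintf("%s:%d", wat$chain_id[w], wat$res_seq[w]),
            pos1 = position_set[i], pos2 = position_set[j],
            d1 = dmin[i], d2 = dmin[j], stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(edges = edges, present_pairs = present,
                 absent_pairs = absent, water_bridges = wb,
                 position_set = position_set),
            class = "NetworkReport")
}

#' @export
print.NetworkReport <- function(x, ...) {
  cat(sprintf("<NetworkReport over {%s}>\n",
              paste(x$position_set, collapse = ", ")))
  cat("  present:", if (length(x$present_pairs))
    paste(x$present_pairs, collapse = ", ") else "(none)", "\n")
  cat("  absent: ", if (length(x$absent_pairs))
    paste(x$absent_pairs, collapse = ", ") else "(none)", "\n")
  if (nrow(x$water_bridges))
    cat(sprintf("  water bridges: %d\n", nrow(x$water_bridges)))
  invisible(x)
}

#' Tabulate donor-acceptor geometry across a structure panel
#'
#' One row per entry: the measured pair geometry formatted to one decimal,
#' with the facing amide group and H-bond verdict. Per-entry errors are
#' collected into the `error` column instead of aborting the whole report.
#'
#' @param entries list; each element a list with `structure` (StructureModel
#'   or PDB path), `donor_pos`, `acceptor_pos`, optional `anchors` (passed
#'   to [build_bw_map()], default "auto"), optional `name` label, optional
#'   `force_reference_amide` flag.
#' @param ... cutoffs forwarded to [hbond_verdict()].
#' @return data.frame with name, pair, facing, da_distance, cb_d_a_angle,
#'   is_hbond, error.
#' @export
table_report <- function(entries, ...) {
  if (!length(entries))
    return(data.frame(name = character(0), pair = character(0),
                      facing = character(0), da_distance = numeric(0),
                      cb_d_a_angle = numeric(0), is_hbond = logical(0),
                      error = character(0)))
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    nm <- if (!is.null(e$name)) e$name else sprintf("entry%02d", i)
    out <- data.frame(name = nm,
                      pair = paste(e$donor_pos, e$acceptor_pos, sep = "-"),
                      facing = "-", da_distance = NA_real_,
                      cb_d_a_angle = NA_real_, is_hbond = NA,
                      error = "", stringsAsFactors = FALSE)
    tryCatch({
      model <- if (inherits(e$structure, "StructureModel")) e$structure
               else read_pdb(e$structure, multi_model = FALSE)
      anchors <- if (!is.null(e$anchors)) e$anchors else "auto"
      map <- build_bw_map(model, anchors = anchors)
      g <- measure_pair(model, map, e$donor_pos, e$acceptor_pos,
                        force_reference_amide =
                          isTRUE(e$force_reference_amide), ...)
      out$facing <- g$facing_group
      out$da_distance <- round(g$da_distance, 1)
      out$cb_d_a_angle <- round(g$cb_d_a_angle, 1)
      out$is_hbond <- g$is_hbond
    }, error = function(err) out$error <<- conditionMessage(err))
    out
  })
  do.call(rbind, rows)
}
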