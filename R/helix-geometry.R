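# Backbone dihedrals and local helix-axis analysis.
#
# Local axes follow the Sugeta-Miyazawa construction used by HELANAL: for a
# sliding window of four consecutive CA atoms with bond vectors
# v(k) = CA(k+1) - CA(k), the difference vectors d1 = v1 - v2 and
# d2 = v2 - v3 are radial (they point outward from the helix axis at the two
# interior CAs), the axis is their normalized cross product, the unit twist
# is the angle between d1 and d2, and the rise is the projection of v2 onto
# the axis. For an ideal alpha-helix (3.6 residues/turn) the unit twist is
# 360/3.6 = 100 degrees. No smoothing of per-window axes is applied.

#' Phi/psi backbone dihedrals for one chain
#'
#' Phi(i) is C(i-1)-N-CA-C, Psi(i) is N-CA-C-N(i+1). Values are undefined
#' (NA) at chain termini, across breaks in the peptide bond (C...N distance
#' above `break_cutoff`), and where backbone atoms are missing (with a
#' warning).
#'
#' @param model a StructureModel.
#' @param chain chain identifier.
#' @param break_cutoff maximum C(i-1)-N(i) distance treated as bonded, in
#'   Angstrom.
#' @return data.frame with res_seq, ins_code, res_name, phi, psi.
#' @export
phi_psi <- function(model, chain, break_cutoff = 2.5) {
  rt <- residue_table(model, chain)
  n <- nrow(rt)
  if (!n) stop("no protein residues in chain ", chain, call. = FALSE)
  bb <- function(i, name) {
    tryCatch(atom_xyz(model, chain, rt$res_seq[i], name, rt$ins_code[i]),
             error = function(e) NULL)
  }
  Ns <- lapply(seq_len(n), bb, "N")
  CAs <- lapply(seq_len(n), bb, "CA")
  Cs <- lapply(seq_len(n), bb, "C")
  missing_bb <- vapply(seq_len(n), function(i)
    is.null(Ns[[i]]) || is.null(CAs[[i]]) || is.null(Cs[[i]]), logical(1))
  if (any(missing_bb))
    warning("missing backbone atoms at ",
            paste(rt$res_seq[missing_bb], collapse = " "),
            "; phi/psi undefined there", call. = FALSE)
  bonded <- function(i, j) {
    # residue i's C bonded to residue j's N
    !is.null(Cs[[i]]) && !is.null(Ns[[j]]) &&
      vnorm(Ns[[j]] - Cs[[i]]) <= break_cutoff
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (missing_bb[i]) next
    if (i > 1 && !missing_bb[i - 1] && bonded(i - 1, i))
      phi[i] <- dihedral(Cs[[i - 1]], Ns[[i]], CAs[[i]], Cs[[i]])
    if (i < n && !missing_bb[i + 1] && bonded(i, i + 1))
      psi[i] <- dihedral(Ns[[i]], CAs[[i]], Cs[[i]], Ns[[i + 1]])
  }
  data.frame(res_seq = rt$res_seq, ins_code = rt$ins_code,
             res_name = rt$res_name, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Fit local helix axes to a run of CA atoms
#'
#' One frame per window of four consecutive CA positions (Sugeta-Miyazawa
#' construction, as in HELANAL). `window_start` indexes the first CA of each
#' window within the input matrix.
#'
#' @param ca_coords numeric matrix, one CA position per row (>= 4 rows).
#' @return data.frame with window_start, axis_x/y/z (unit vector),
#'   origin_x/y/z (point on the axis at the level of the window's second
#'   CA), twist (degrees, the per-window unit twist) and rise
#'   (Angstrom/residue).
#' @export
fit_local_axes <- function(ca_coords) {
  ca <- as.matrix(ca_coords)
  dimnames(ca) <- NULL
  if (nrow(ca) < 4)
    stop("need at least 4 CA positions to fit a local axis", call. = FALSE)
  nw <- nrow(ca) - 3
  out <- vector("list", nw)
  for (w in seq_len(nw)) {
    p <- ca[w:(w + 3), , drop = FALSE]
    v1 <- p[2, ] - p[1, ]
    v2 <- p[3, ] - p[2, ]
    v3 <- p[4, ] - p[3, ]
    d1 <- v1 - v2
    d2 <- v2 - v3
    cp <- cross3(d1, d2)
    if (vnorm(d1) < 1e-6 || vnorm(d2) < 1e-6 || vnorm(cp) < 1e-8)
      stop(sprintf("degenerate axis at window %d: collinear CA run", w),
           call. = FALSE)
    h <- unit(cp)
    if (sum(h * v2) < 0) h <- -h          # orient along the chain direction
    twist <- vec_angle(d1 + p[2, ], p[2, ], d2 + p[2, ])
    rise <- sum(v2 * h)
    radius <- vnorm(d1) / (2 * (1 - cos(deg2rad(twist))))
    origin <- p[2, ] - radius * unit(d1)
    out[[w]] <- c(window_start = w, axis_x = h[1], axis_y = h[2],
                  axis_z = h[3], origin_x = origin[1], origin_y = origin[2],
                  origin_z = origin[3], twist = twist, rise = rise)
  }
  as.data.frame(do.call(rbind, out))
}

# CA coordinate matrix for a residue-number range of a chain, with the
# corresponding res_seq vector; errors if a CA is missing inside the range.
ca_run <- function(model, chain, residue_range = NULL) {
  rt <- residue_table(model, chain)
  if (!is.null(residue_range))
    rt <- rt[rt$res_seq >= min(residue_range) &
               rt$res_seq <= max(residue_range), , drop = FALSE]
  if (!nrow(rt)) stop("no residues in requested range", call. = FALSE)
  ca <- t(vapply(seq_len(nrow(rt)), function(i)
    atom_xyz(model, chain, rt$res_seq[i], "CA", rt$ins_code[i]),
    numeric(3)))
  list(ca = ca, res_seq = rt$res_seq)
}

axis_of <- function(frames, w) {
  unlist(frames[frames$window_start == w,
                c("axis_x", "axis_y", "axis_z")], use.names = FALSE)
}

#' Per-position unit twist profile
#'
#' The twist at residue position p is the per-window twist of the
#' four-CA window ending at p, i.e. window (p-3 ... p). Positions without a
#' complete window are NA.
#'
#' @param model a StructureModel.
#' @param chain chain identifier.
#' @param residue_range optional res_seq range to profile (default: whole
#'   chain).
#' @return data.frame with res_seq and twist (degrees).
#' @export
unit_twist_profile <- function(model, chain, residue_range = NULL) {
  run <- ca_run(model, chain, residue_range)
  n <- nrow(run$ca)
  twist <- rep(NA_real_, n)
  if (n >= 4) {
    frames <- fit_local_axes(run$ca)
    twist[frames$window_start + 3] <- frames$twist
  }
  data.frame(res_seq = run$res_seq, twist = twist)
}

#' Per-position unit bend profile
#'
#' The bend at residue position p is the angle between the axis of the
#' window ending at p (p-3 ... p) and the axis of the window starting at p
#' (p ... p+3). Positions lacking a full window on either side are NA.
#'
#' @inheritParams unit_twist_profile
#' @return data.frame with res_seq and bend (degrees).
#' @export
unit_bend_profile <- function(model, chain, residue_range = NULL) {
  run <- ca_run(model, chain, residue_range)
  n <- nrow(run$ca)
  bend <- rep(NA_real_, n)
  if (n >= 7) {
    frames <- fit_local_axes(run$ca)
    for (p in 4:(n - 3)) {
      a1 <- axis_of(frames, p - 3)        # window (p-3 .. p)
      a2 <- axis_of(frames, p)            # window (p .. p+3)
      if (length(a1) && length(a2))
        bend[p] <- vec_angle(a1, c(0, 0, 0), a2)
    }
  }
  data.frame(res_seq = run$res_seq, bend = bend)
}

#' Full helix-distortion profile around a motif residue
#'
#' Computes phi, psi, unit bend and unit twist at integer offsets relative
#' to the motif residue i (the X of an XAAP/XWAP motif), by default the
#' window i-7 ... i+4. Offsets whose residues are absent, or that lack the
#' CA windows needed for bend/twist, carry NA.
#'
#' @param model a StructureModel.
#' @param chain chain identifier.
#' @param motif_i res_seq of the motif residue i.
#' @param offsets integer offsets relative to i.
#' @return A `HelixProfile` data.frame with offset, res_seq, phi, psi,
#'   unit_bend, unit_twist.
#' @export
helix_profile <- function(model, chain, motif_i, offsets = -7:4) {
  pp <- phi_psi(model, chain)
  tw <- unit_twist_profile(model, chain)
  bd <- unit_bend_profile(model, chain)
  res <- motif_i + offsets
  idx <- match(res, pp$res_seq)
  out <- data.frame(
    offset = offsets, res_seq = res,
    phi = pp$phi[idx], psi = pp$psi[idx],
    unit_bend = bd$bend[match(res, bd$res_seq)],
    unit_twist = tw$twist[match(res, tw$res_seq)])
  class(out) <- c("HelixProfile", "data.frame")
  out
}

#' Export a helix profile as TSV
#'
#' @param profile a HelixProfile (or the mean table of an EnsembleProfile).
#' @param path destination file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
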