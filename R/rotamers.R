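# chi1 dihedrals and rotamer classification.
#
# Nomenclature note: the g+ label here denotes the chi1 ~ -60 degree well
# (the "minus"/m well of the Lovell rotamer-library nomenclature). This
# convention is anchored empirically on deposited class A GPCR structures:
# it reproduces the g+ call for the beta2-adrenergic receptor's Cys 6.47 and
# the g- call for the M2 muscarinic receptor's Thr 6.47. Class boundaries
# are the standard thirds of the circle: g+ = [-120, 0), g- = [0, 120),
# t otherwise.

# gamma heavy atom used for chi1, by residue type
GAMMA_ATOM <- c(SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1",
                ILE = "CG1", ARG = "CG", ASN = "CG", ASP = "CG",
                GLN = "CG", GLU = "CG", HIS = "CG", LEU = "CG",
                LYS = "CG", MET = "CG", PHE = "CG", PRO = "CG",
                TRP = "CG", TYR = "CG", MSE = "CG")

#' chi1 side-chain dihedral of a residue
#'
#' N-CA-CB-gamma by the standard convention; the gamma heavy atom is SG for
#' Cys, OG for Ser, OG1 for Thr, CG1 for Val/Ile and CG otherwise.
#'
#' @param model a StructureModel.
#' @param chain chain identifier.
#' @param res_seq author residue number.
#' @param ins_code insertion code, default none.
#' @return list with `chi1` (degrees in (-180, 180]), `gamma_atom`,
#'   `res_name`.
#' @export
chi1 <- function(model, chain, res_seq, ins_code = "") {
  at <- model$atoms
  res <- at[at$chain_id == chain & at$res_seq == res_seq &
              at$ins_code == ins_code, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("residue absent: chain %s residue %s", chain, res_seq),
         call. = FALSE)
  rn <- res$res_name[1]
  if (rn %in% c("GLY", "ALA"))
    stop(sprintf("chi1 not applicable to %s %s (no gamma heavy atom)",
                 rn, res_seq), call. = FALSE)
  gname <- GAMMA_ATOM[rn]
  if (is.na(gname))
    stop(sprintf("no gamma-atom rule for residue type %s", rn),
         call. = FALSE)
  need <- c("N", "CA", "CB", unname(gname))
  have <- need %in% res$name
  if (!all(have))
    stop(sprintf("chi1 undefined for %s %s: missing atom(s) %s", rn, res_seq,
                 paste(need[!have], collapse = " ")), call. = FALSE)
  coords <- lapply(need, function(nm)
    unlist(res[res$name == nm, c("x", "y", "z")][1, ], use.names = FALSE))
  list(chi1 = dihedral(coords[[1]], coords[[2]], coords[[3]], coords[[4]]),
       gamma_atom = unname(gname), res_name = rn)
}

#' Classify a chi1 angle into the g+/g-/t rotamer wells
#'
#' g+ for chi1 in \[-120, 0) (the ~ -60 degree well), g- for \[0, 120)
#' (~ +60), t otherwise (~180). A total function: every defined chi1 maps
#' to exactly one label, and each boundary value belongs to exactly one
#' class.
#'
#' @param chi1 chi1 angle(s) in degrees.
#' @return character vector of labels "g+", "g-" or "t".
#' @export
classify_rotamer <- function(chi1) {
  x <- wrap180(chi1)
  ifelse(is.na(x), NA_character_,
         ifelse(x >= -120 & x < 0, "g+",
                ifelse(x >= 0 & x < 120, "g-", "t")))
}

#' Per-residue rotamer report for a structure
#'
#' chi1 and rotamer label for every residue of the requested types, with
#' the generic position attached when a BWMap is supplied.
#'
#' @param model a StructureModel.
#' @param residue_filter three-letter codes to include.
#' @param bw_map optional [build_bw_map()] result for generic-position
#'   annotation.
#' @param chains chains to scan (default: all).
#' @return data.frame with chain, res_seq, ins_code, res_name, bw, chi1,
#'   label, gamma_atom.
#' @export
rotamer_report <- function(model, residue_filter = c("CYS", "SER", "THR"),
                           bw_map = NULL, chains = NULL) {
  at <- model$atoms
  if (is.null(chains)) chains <- unique(at$chain_id)
  rows <- list()
  for (ch in chains) {
    rt <- residue_table(model, ch)
    rt <- rt[rt$res_name %in% residue_filter, , drop = FALSE]
    for (i in seq_len(nrow(rt))) {
      c1 <- tryCatch(chi1(model, ch, rt$res_seq[i], rt$ins_code[i]),
                     error = function(e) NULL)
      if (is.null(c1)) next
      bw <- if (!is.null(bw_map)) {
        e <- bw_map$entries
        hit <- e$bw[e$chain_id == ch & e$res_seq == rt$res_seq[i] &
                      e$ins_code == rt$ins_code[i]]
        if (length(hit)) hit[1] else NA_character_
      } else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, res_seq = rt$res_seq[i], ins_code = rt$ins_code[i],
        res_name = rt$res_name[i], bw = bw, chi1 = c1$chi1,
        label = classify_rotamer(c1$chi1), gamma_atom = c1$gamma_atom,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chain = character(0), res_seq = integer(0),
                      ins_code = character(0), res_name = character(0),
                      bw = character(0), chi1 = numeric(0),
                      label = character(0), gamma_atom = character(0)))
  do.call(rbind, rows)
}

#' Tabulate rotamer populations over a set of structures
#'
#' Classifies every qualifying residue in the supplied structures
#' (optionally restricted to annotated helical regions) and tabulates
#' counts and percentages per rotamer well and residue type.
#'
#' @param structures list of StructureModels.
#' @param residue_filter three-letter codes to tabulate.
#' @param region_filter optional data.frame with columns chain, from, to
#'   (author numbering): only residues inside these ranges are counted.
#' @return data.frame with res_name, label counts (`n_gminus`, `n_gplus`,
#'   `n_t`), percentages (`pct_gminus`, `pct_gplus`, `pct_t`) and
#'   n_observations. Zero qualifying residues yields an empty table with a
#'   warning.
#' @export
rotamer_population <- function(structures,
                               residue_filter = c("CYS", "SER", "THR"),
                               region_filter = NULL) {
  if (inherits(structures, "StructureModel")) structures <- list(structures)
  reports <- lapply(structures, rotamer_report,
                    residue_filter = residue_filter)
  rep_all <- do.call(rbind, reports)
  if (!is.null(region_filter) && nrow(rep_all)) {
    keep <- vapply(seq_len(nrow(rep_all)), function(i) {
      rf <- region_filter[region_filter$chain == rep_all$chain[i], ,
                          drop = FALSE]
      any(rep_all$res_seq[i] >= rf$from & rep_all$res_seq[i] <= rf$to)
    }, logical(1))
    rep_all <- rep_all[keep, , drop = FALSE]
  }
  if (!nrow(rep_all)) {
    warning("no qualifying residues: empty rotamer population table",
            call. = FALSE)
    return(data.frame(res_name = character(0), n_gminus = integer(0),
                      n_gplus = integer(0), n_t = integer(0),
                      pct_gminus = numeric(0), pct_gplus = numeric(0),
                      pct_t = numeric(0), n_observations = integer(0)))
  }
  out <- lapply(split(rep_all, rep_all$res_name), function(d) {
    n <- nrow(d)
    cnt <- c(`g-` = sum(d$label == "g-"), `g+` = sum(d$label == "g+"),
             t = sum(d$label == "t"))
    data.frame(res_name = d$res_name[1],
               n_gminus = cnt[["g-"]], n_gplus = cnt[["g+"]], n_t = cnt[["t"]],
               pct_gminus = 100 * cnt[["g-"]] / n,
               pct_gplus = 100 * cnt[["g+"]] / n,
               pct_t = 100 * cnt[["t"]] / n,
               n_observations = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
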