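# Bundled reference tables for the class A GPCR structure panel.

#' Reference TM6-TM7 interaction geometry for the crystal-structure panel
#'
#' Published crystallographic measurements of the 6.47 -> 7.45 (or, for the
#' rhodopsins, 6.47 -> 7.44 and 6.43 -> 7.45) donor-acceptor geometry
#' across deposited class A GPCR structures: donor-acceptor distance,
#' Cbeta-D...A angle, the amide group of N7.45 facing the donor, and
#' whether the printed geometry was called compatible with a hydrogen bond.
#' Rows printed without a measurable interaction carry NA. These are
#' inputs for regression fixtures, not values computed by this package.
#'
#' Note the squid-rhodopsin row is printed with pair label "Q6.43-S7.54"
#' in the source; 7.54 is a probable typo for 7.45 (the bridging
#' interaction described for that receptor), and the row is stored here
#' under pair "6.43-7.54" as printed. Do not silently correct it in
#' user-facing output.
#'
#' @return data.frame with receptor, structure, pdb_id, resolution, pair,
#'   donor_res, acceptor_res, facing, da_distance, cb_d_a_angle,
#'   hbond_printed.
#' @export
reference_tm67_geometry <- function() {
  path <- system.file("extdata", "tm67_reference_geometry.tsv",
                      package = "gpcrgeom", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference rotamer labels at position 6.47 for the structure panel
#'
#' Published per-receptor residue identities and chi1 rotamer labels at
#' generic position 6.47 (and, where labelled, 7.44), plus the residue at
#' 7.45. The 6.47 tally is Cys g+ for eleven receptors, Thr g- for the two
#' muscarinic receptors, Cys t for bovine rhodopsin and Ser g+ for squid
#' rhodopsin. "g+/t" marks positions reported with both conformers across
#' the inactive/active structure pair without a per-structure assignment.
#'
#' @return data.frame with receptor, pdb_id, res_647, rotamer_647,
#'   res_744, rotamer_744, res_745.
#' @export
reference_647_rotamers <- function() {
  path <- system.file("extdata", "position_647_rotamers.tsv",
                      package = "gpcrgeom", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
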