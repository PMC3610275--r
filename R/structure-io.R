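# PDB reading/writing and the coordinate model used by every other module.
#
# A StructureModel stores one conformer as a flat atom table; an Ensemble is
# an ordered list of StructureModels sharing identical topology (the stand-in
# for a trajectory). Hydrogens are dropped on input: all downstream geometry
# (D...A distances, Cbeta-D...A angles, dihedrals) is heavy-atom based, as in
# crystal-structure work where hydrogens are not observed.

AMINO3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# common modified residues kept as protein (flagged hetero)
MODIFIED3 <- c(MSE = "M", CSO = "C", SEP = "S", TPO = "T", PTR = "Y")

is_amino <- function(res_name) res_name %in% c(names(AMINO3), names(MODIFIED3))

one_letter <- function(res_name) {
  out <- AMINO3[res_name]
  miss <- is.na(out)
  out[miss] <- MODIFIED3[res_name[miss]]
  out[is.na(out)] <- "X"
  unname(out)
}

new_structure_model <- function(atoms, model_id = 1L, source_id = "") {
  stopifnot(is.data.frame(atoms))
  atoms <- atoms[order(atoms$chain_id, atoms$res_seq, atoms$ins_code), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 source_id = source_id),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  prot <- x$atoms[is_amino(x$atoms$res_name), , drop = FALSE]
  nres <- nrow(unique(prot[c("chain_id", "res_seq", "ins_code")]))
  cat(sprintf("<StructureModel %s model %d: %d atoms, %d residues, chains %s>\n",
              x$source_id, x$model_id, nrow(x$atoms), nres,
              paste(sort(unique(x$atoms$chain_id)), collapse = "")))
  invisible(x)
}

topology_key <- function(model) {
  a <- model$atoms
  paste(a$chain_id, a$res_seq, a$ins_code, a$res_name, a$name, sep = "|")
}

new_ensemble <- function(models, source_id = "") {
  stopifnot(length(models) >= 1)
  ids <- vapply(models, function(m) m$model_id, integer(1))
  if (anyDuplicated(ids))
    stop("ensemble model_ids must be unique", call. = FALSE)
  key0 <- topology_key(models[[1]])
  for (m in models[-1]) {
    if (!identical(topology_key(m), key0))
      stop(sprintf(
        "ensemble topology mismatch: model %d differs from model %d in atom count or naming",
        m$model_id, models[[1]]$model_id), call. = FALSE)
  }
  structure(list(models = models, source_id = source_id), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("<Ensemble %s: %d models x %d atoms>\n", x$source_id,
              length(x$models), nrow(x$models[[1]]$atoms)))
  invisible(x)
}

#' Number of models in an Ensemble
#' @param x an Ensemble.
#' @export
n_models <- function(x) {
  stopifnot(inherits(x, "Ensemble"))
  length(x$models)
}

#' Wrap a single StructureModel as a one-model Ensemble
#' @param model a StructureModel.
#' @export
as_ensemble <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  new_ensemble(list(model), source_id = model$source_id)
}

parse_pdb_lines <- function(lines, source_id) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM records found in PDB input", call. = FALSE)

  # model id per line: increments at MODEL records
  model_idx <- cumsum(is_model)
  model_ids_raw <- if (any(is_model)) model_idx else rep(1L, length(lines))

  keep <- which(is_atom)
  ln <- lines[keep]
  num <- function(s, what, idx) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    bad <- bad | (is.na(v) & what %in% c("x", "y", "z"))
    if (any(bad))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, keep[idx][which(bad)[1]],
                   trimws(ln[which(bad)[1]])), call. = FALSE)
    v
  }
  fld <- function(a, b) substr(ln, a, b)
  x <- num(fld(31, 38), "x", seq_along(ln))
  y <- num(fld(39, 46), "y", seq_along(ln))
  z <- num(fld(47, 54), "z", seq_along(ln))
  occ <- suppressWarnings(as.numeric(fld(55, 60)))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(fld(61, 66)))
  bf[is.na(bf)] <- 0
  elem <- trimws(fld(77, 78))
  name <- trimws(fld(13, 16))
  # derive element from the atom name when the element column is blank
  guess <- sub("^[0-9]*", "", name)
  guess <- ifelse(substr(guess, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
                  substr(guess, 1, 2), substr(guess, 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]

  atoms <- data.frame(
    record = trimws(rec[keep]),
    serial = suppressWarnings(as.integer(fld(7, 11))),
    name = name,
    alt_loc = trimws(fld(17, 17)),
    res_name = trimws(fld(18, 20)),
    chain_id = substr(ln, 22, 22),
    res_seq = suppressWarnings(as.integer(fld(23, 26))),
    ins_code = trimws(fld(27, 27)),
    x = x, y = y, z = z,
    occupancy = occ, b_factor = bf, element = toupper(elem),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$res_seq))
    stop(sprintf("malformed residue number at line %d",
                 keep[which(is.na(atoms$res_seq))[1]]), call. = FALSE)
  atoms$is_hetero <- atoms$record == "HETATM"
  atoms$model <- pmax(1L, model_ids_raw[keep])

  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (!any(is_amino(atoms$res_name)))
    stop("no protein atoms found in PDB input", call. = FALSE)

  # alt-loc resolution: highest occupancy wins, alphabetical tie-break
  atoms$idx0 <- seq_len(nrow(atoms))
  ord <- order(atoms$model, atoms$chain_id, atoms$res_seq, atoms$ins_code,
               atoms$name, -atoms$occupancy, atoms$alt_loc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$model, atoms$chain_id, atoms$res_seq, atoms$ins_code,
               atoms$res_name, atoms$name, sep = "|")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[order(atoms$model, atoms$idx0), , drop = FALSE]
  atoms$idx0 <- NULL
  atoms$occupancy[atoms$occupancy > 1] <- 1

  models <- lapply(sort(unique(atoms$model)), function(mid) {
    a <- atoms[atoms$model == mid, , drop = FALSE]
    a$model <- NULL
    new_structure_model(a, model_id = mid, source_id = source_id)
  })
  models
}

#' Read a PDB file or string into an Ensemble
#'
#' Accepts a path (optionally gzip-compressed) or a character string holding
#' PDB-format text. One StructureModel is produced per MODEL record (a single
#' model if the file has none). Hydrogens are discarded; alternate locations
#' are resolved to the highest-occupancy conformer with alphabetical alt_loc
#' as tie-break; HETATM amino acids (e.g. selenomethionine) are retained and
#' flagged via the `is_hetero` column.
#'
#' @param path_or_text file path or PDB text (anything containing a newline
#'   is treated as text).
#' @param source_id label stored on the models; defaults to the file name.
#' @param multi_model if FALSE, return only the first StructureModel instead
#'   of an Ensemble.
#' @return An Ensemble (or StructureModel when `multi_model = FALSE`).
#' @export
read_pdb <- function(path_or_text, source_id = NULL, multi_model = TRUE) {
  if (length(path_or_text) == 1 && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    con <- gzfile(path_or_text, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent)(\\.gz)?$", "",
                       basename(path_or_text), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(paste(path_or_text, collapse = "\n"), "\n",
                             fixed = TRUE))
    if (is.null(source_id)) source_id <- "pdb-text"
  }
  models <- parse_pdb_lines(lines, source_id)
  ens <- new_ensemble(models, source_id = source_id)
  if (multi_model) ens else ens$models[[1]]
}

format_pdb_atoms <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
                  ifelse(nchar(atoms$element) == 2,
                         sprintf("%-4s", atoms$name),
                         sprintf(" %-3s", atoms$name)))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_hetero, "HETATM", "ATOM"),
          seq_len(nrow(atoms)) %% 100000,
          name4, substr(paste0(atoms$alt_loc, " "), 1, 1),
          atoms$res_name, atoms$chain_id, atoms$res_seq,
          substr(paste0(atoms$ins_code, " "), 1, 1),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
          atoms$element)
}

#' Write an Ensemble (or StructureModel) to a PDB file
#'
#' Multi-model ensembles are written as MODEL/ENDMDL blocks; chains are
#' terminated with TER records. Coordinates round-trip through [read_pdb()]
#' at PDB fixed-width precision (3 decimals).
#'
#' @param x an Ensemble or StructureModel.
#' @param path destination file; `""` returns the text invisibly instead.
#' @return Invisibly, the PDB text.
#' @export
write_pdb <- function(x, path = "") {
  if (inherits(x, "StructureModel")) x <- as_ensemble(x)
  stopifnot(inherits(x, "Ensemble"))
  if (!length(x$models)) stop("cannot write an empty ensemble", call. = FALSE)
  multi <- length(x$models) > 1
  out <- character(0)
  for (m in x$models) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m$model_id))
    a <- m$atoms
    for (ch in unique(a$chain_id)) {
      out <- c(out, format_pdb_atoms(a[a$chain_id == ch, , drop = FALSE]),
               "TER")
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (nzchar(path)) {
    ok <- tryCatch({ writeLines(out, path); TRUE },
                   error = function(e) stop(sprintf(
                     "cannot write PDB to '%s': %s", path, conditionMessage(e)),
                     call. = FALSE))
  }
  invisible(txt)
}

#' Look up a single atom by address
#'
#' @param model a StructureModel.
#' @param chain chain identifier.
#' @param res_seq author residue number.
#' @param atom_name PDB atom name (e.g. "SG").
#' @param ins_code insertion code, default none.
#' @return One-row data.frame with the atom record.
#' @export
get_atom <- function(model, chain, res_seq, atom_name, ins_code = "") {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  res <- a[a$chain_id == chain & a$res_seq == res_seq &
             a$ins_code == ins_code, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("residue absent: chain %s residue %s%s", chain, res_seq,
                 ins_code), call. = FALSE)
  hit <- res[res$name == atom_name, , drop = FALSE]
  if (!nrow(hit))
    stop(sprintf("atom '%s' absent in %s %s%s (chain %s); present: %s",
                 atom_name, res$res_name[1], res_seq, ins_code, chain,
                 paste(res$name, collapse = " ")), call. = FALSE)
  hit[1, , drop = FALSE]
}

# coordinates of one atom as a plain 3-vector
atom_xyz <- function(model, chain, res_seq, atom_name, ins_code = "") {
  at <- get_atom(model, chain, res_seq, atom_name, ins_code)
  c(at$x, at$y, at$z)
}

# residue-level table for a chain: one row per residue in chain order
residue_table <- function(model, chain, protein_only = TRUE) {
  a <- model$atoms[model$atoms$chain_id == chain, , drop = FALSE]
  if (protein_only) a <- a[is_amino(a$res_name), , drop = FALSE]
  if (!nrow(a)) return(data.frame(res_seq = integer(0), ins_code = character(0),
                                  res_name = character(0)))
  key <- paste(a$res_seq, a$ins_code, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(res_seq = a$res_seq[first], ins_code = a$ins_code[first],
                    res_name = a$res_name[first], stringsAsFactors = FALSE)
  out[order(out$res_seq, out$ins_code), , drop = FALSE]
}

# observed one-letter sequence of a chain plus the residue numbering
chain_sequence <- function(model, chain) {
  rt <- residue_table(model, chain)
  list(sequence = paste(one_letter(rt$res_name), collapse = ""),
       res_seq = rt$res_seq, ins_code = rt$ins_code)
}

# all chains present in a model (protein chains first)
model_chains <- function(model) unique(model$atoms$chain_id)
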