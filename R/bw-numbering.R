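# Ballesteros-Weinstein generic numbering.
#
# Position T.NN of transmembrane helix T is the residue (NN - 50) sequence
# positions away from the helix's most conserved residue T.50. TM6 and TM7
# anchors are located from sequence alone via the conserved CWxP (6.47-6.50,
# anchor P6.50) and NPxxY (anchor P7.50) motifs; anchors for other helices
# (2.50, 3.39, ...) lack a uniquely identifying local motif and must be
# supplied explicitly. Numbering extends by residue-count offset only
# through contiguous stretches of author numbering; a gap raises an error
# on lookup instead of silently misnumbering.

#' Locate the CWxP and NPxxY anchor positions in a sequence
#'
#' TM6: the Pro of a `[CSTAV]WxP` match (fallback `WxP`); TM7: the Pro of an
#' `NPxxY` match (fallback `NP`) C-terminal to the TM6 match. When several
#' candidate pairings are consistent an ambiguity error lists them.
#'
#' @param sequence one-letter amino-acid string (length >= 20).
#' @return list with `tm6_p50` and `tm7_p50` (1-based index of P6.50 and
#'   P7.50 within `sequence`) and the matched motif strings.
#' @export
find_motif_anchors <- function(sequence) {
  sequence <- toupper(gsub("[^A-Z]", "", sequence))
  if (nchar(sequence) < 20)
    stop("sequence too short for motif anchoring (need >= 20 residues)",
         call. = FALSE)
  find_all <- function(pattern) {
    m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  cw <- find_all("(?=[CSTAV]W.P)")
  cw_off <- 3L                                 # P is 4th residue of the match
  if (!length(cw)) { cw <- find_all("(?=W.P)"); cw_off <- 2L }
  if (!length(cw))
    stop("anchor not found: no CWxP (nor WxP) motif in sequence",
         call. = FALSE)
  np <- find_all("(?=NP..Y)")
  np_fallback <- FALSE
  if (!length(np)) { np <- find_all("(?=NP)"); np_fallback <- TRUE }
  if (!length(np))
    stop("anchor not found: no NPxxY (nor NP) motif in sequence",
         call. = FALSE)

  # pair each CWxP with the nearest NPxxY C-terminal to it
  pairs <- list()
  for (c0 in cw) {
    p6 <- c0 + cw_off
    cand <- np[np > p6]
    if (length(cand)) pairs[[length(pairs) + 1]] <-
        c(tm6 = p6, tm7 = min(cand) + 1L)    # P is 2nd residue of NPxxY
  }
  if (!length(pairs))
    stop("anchor not found: no NPxxY motif C-terminal to the CWxP match",
         call. = FALSE)
  if (length(pairs) > 1) {
    desc <- vapply(pairs, function(p)
      sprintf("6.50@%d/7.50@%d", p["tm6"], p["tm7"]), character(1))
    stop("ambiguous motif anchoring; candidates: ",
         paste(desc, collapse = ", "), call. = FALSE)
  }
  p <- pairs[[1]]
  list(tm6_p50 = unname(p["tm6"]), tm7_p50 = unname(p["tm7"]),
       tm6_motif = substr(sequence, p["tm6"] - cw_off, p["tm6"]),
       tm7_motif = substr(sequence, p["tm7"] - 1,
                          min(p["tm7"] + 3, nchar(sequence))),
       np_fallback = np_fallback)
}

# parse one anchor value: "A:288", c("A", 288), or list(chain=, res_seq=)
parse_anchor <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl(":", x)) {
    parts <- strsplit(x, ":")[[1]]
    return(list(chain = parts[1], res_seq = as.integer(parts[2])))
  }
  if (is.list(x)) return(list(chain = x$chain, res_seq = as.integer(x$res_seq)))
  if (length(x) == 2) return(list(chain = as.character(x[1]),
                                  res_seq = as.integer(x[2])))
  stop("cannot parse anchor specification", call. = FALSE)
}

#' Build a Ballesteros-Weinstein map for a structure
#'
#' With `anchors = "auto"`, the 6.50 and 7.50 anchors are located by motif
#' search on the chain's observed sequence. Explicit anchors are given as a
#' named list of generic positions (normally the x.50 reference residues,
#' but any "T.NN" works), e.g. `list("2.50" = "A:79", "6.50" = "A:288")`.
#' Generic numbers are assigned by residue-count offset from the
#' anchor, spanning at most +/-`span` positions and only across contiguous
#' author numbering; residues beyond a numbering gap stay unmapped and
#' raise a gap error on lookup.
#'
#' @param model a StructureModel.
#' @param anchors "auto" or a named list of x.50 anchor addresses.
#' @param chain chain used for auto-anchoring (default: first protein
#'   chain).
#' @param span maximum offset from the anchor, in residues.
#' @return A `BWMap` object.
#' @export
build_bw_map <- function(model, anchors = "auto", chain = NULL, span = 15L) {
  stopifnot(inherits(model, "StructureModel"))
  if (identical(anchors, "auto")) {
    if (is.null(chain)) {
      chains <- unique(model$atoms$chain_id[is_amino(model$atoms$res_name)])
      chain <- chains[1]
    }
    cs <- chain_sequence(model, chain)
    hit <- find_motif_anchors(cs$sequence)
    anchors <- list(
      "6.50" = list(chain = chain, res_seq = cs$res_seq[hit$tm6_p50]),
      "7.50" = list(chain = chain, res_seq = cs$res_seq[hit$tm7_p50]))
    source <- "motif"
  } else {
    stopifnot(is.list(anchors), !is.null(names(anchors)))
    source <- "config"
  }

  entries <- list()
  anchor_df <- list()
  breaks <- list()
  for (pos in names(anchors)) {
    m <- regmatches(pos, regexec("^([0-9]+)\\.([0-9]+)$", pos))[[1]]
    if (length(m) != 3)
      stop("anchor names must be generic positions like '6.50', got '",
           pos, "'", call. = FALSE)
    helix <- m[2]
    nn_anchor <- as.integer(m[3])
    aaddr <- parse_anchor(anchors[[pos]])
    rt <- residue_table(model, aaddr$chain)
    k <- which(rt$res_seq == aaddr$res_seq & rt$ins_code == "")
    if (!length(k))
      stop(sprintf("anchor residue %s:%d not found in structure",
                   aaddr$chain, aaddr$res_seq), call. = FALSE)
    k <- k[1]
    # walk outward while author numbering stays contiguous
    lo <- k; hi <- k
    lo_gap <- hi_gap <- FALSE
    while (lo > 1 && (k - lo) < span) {
      if (rt$res_seq[lo - 1] == rt$res_seq[lo] - 1 &&
          rt$ins_code[lo - 1] == "") lo <- lo - 1
      else { lo_gap <- TRUE; break }
    }
    while (hi < nrow(rt) && (hi - k) < span) {
      if (rt$res_seq[hi + 1] == rt$res_seq[hi] + 1 &&
          rt$ins_code[hi + 1] == "") hi <- hi + 1
      else { hi_gap <- TRUE; break }
    }
    idx <- lo:hi
    off <- idx - k
    entries[[pos]] <- data.frame(
      chain_id = aaddr$chain, res_seq = rt$res_seq[idx],
      ins_code = rt$ins_code[idx], res_name = rt$res_name[idx],
      helix = helix, offset = off,
      bw = sprintf("%s.%d", helix, nn_anchor + off), stringsAsFactors = FALSE)
    anchor_df[[pos]] <- data.frame(position = pos, chain_id = aaddr$chain,
                                   res_seq = aaddr$res_seq,
                                   stringsAsFactors = FALSE)
    breaks[[helix]] <- list(min_off = min(off), max_off = max(off),
                            nn_anchor = nn_anchor,
                            lo_gap = lo_gap, hi_gap = hi_gap, span = span)
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  dup <- duplicated(entries$bw)
  if (any(dup))
    stop("generic position(s) mapped twice: ",
         paste(unique(entries$bw[dup]), collapse = " "), call. = FALSE)
  structure(list(entries = entries, anchors = do.call(rbind, anchor_df),
                 breaks = breaks, source = source),
            class = "BWMap")
}

#' @export
print.BWMap <- function(x, ...) {
  cat(sprintf("<BWMap (%s): %d positions, anchors %s>\n", x$source,
              nrow(x$entries),
              paste(x$anchors$position, collapse = " ")))
  invisible(x)
}

#' Resolve a generic position to a residue address
#'
#' @param bw_map a [build_bw_map()] result.
#' @param position generic position string, e.g. "6.47".
#' @return One-row data.frame (chain_id, res_seq, ins_code, res_name, bw).
#' @export
bw_lookup <- function(bw_map, position) {
  stopifnot(inherits(bw_map, "BWMap"))
  e <- bw_map$entries
  hit <- e[e$bw == position, , drop = FALSE]
  if (nrow(hit)) return(hit[1, , drop = FALSE])
  m <- regmatches(position, regexec("^([0-9]+)\\.([0-9]+)$", position))[[1]]
  if (length(m) == 3 && m[2] %in% names(bw_map$breaks)) {
    b <- bw_map$breaks[[m[2]]]
    off <- as.integer(m[3]) - b$nn_anchor
    if (off >= -b$span && off <= b$span &&
        ((off < b$min_off && b$lo_gap) || (off > b$max_off && b$hi_gap)))
      stop(sprintf(
        "gap in author numbering between anchor %s.50 and position %s: cannot number across missing residues",
        m[2], position), call. = FALSE)
    stop(sprintf("position %s not covered by the map for helix %s (offsets %d..%d)",
                 position, m[2], b$min_off, b$max_off), call. = FALSE)
  }
  stop(sprintf("position %s is not mapped (no anchor for its helix)",
               position), call. = FALSE)
}

#' Read an anchor configuration file
#'
#' Anchor configs map generic positions to residue addresses. Two plain-text
#' formats are accepted: JSON (an object like
#' `{"6.50": "A:288", "7.50": "A:329"}`) and two-column TSV
#' (`position<TAB>chain:res_seq`, no header). The result feeds
#' [build_bw_map()]'s `anchors` argument.
#'
#' @param path config file; format chosen by extension (".json" vs
#'   anything else = TSV).
#' @return named list of "chain:res_seq" strings.
#' @export
read_anchor_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    as.list(cfg)
  } else {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (ncol(d) < 2)
      stop("anchor TSV needs two columns: position, chain:res_seq",
           call. = FALSE)
    stats::setNames(as.list(d[[2]]), d[[1]])
  }
}

#' Export a BWMap as TSV
#' @param bw_map a BWMap.
#' @param path destination file.
#' @export
write_bw_map_tsv <- function(bw_map, path) {
  utils::write.table(bw_map$entries[, c("chain_id", "res_seq", "res_name",
                                        "bw")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-position residue frequencies from a multiple sequence alignment
#'
#' Counts residues in the mapped columns; frequencies are percentages over
#' all sequences, with gaps counted separately (so residue frequencies sum
#' to 100 minus the gap percentage). Percentages are not rounded.
#'
#' @param alignment FASTA path, named character vector of aligned
#'   sequences, or a Biostrings XStringSet.
#' @param column_map named integer vector: generic position -> column
#'   index (1-based).
#' @return Named list of `ConservationTable` entries, one per position:
#'   each has position, counts, frequency, n_sequences, n_gaps,
#'   gap_fraction.
#' @export
conservation_frequencies <- function(alignment, column_map) {
  seqs <- if (inherits(alignment, "XStringSet")) {
    as.character(alignment)
  } else if (is.character(alignment) && length(alignment) == 1 &&
             file.exists(alignment)) {
    as.character(Biostrings::readAAStringSet(alignment))
  } else if (is.character(alignment)) {
    alignment
  } else stop("unsupported alignment input", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequences have differing aligned lengths",
         call. = FALSE)
  width <- widths[1]
  n <- length(seqs)
  if (any(column_map < 1 | column_map > width))
    stop("column index out of range for alignment of width ", width,
         call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- lapply(seq_along(column_map), function(j) {
    col <- mat[, column_map[j]]
    gap <- col %in% c("-", ".")
    counts <- table(col[!gap])
    counts <- stats::setNames(as.integer(counts), names(counts))
    structure(list(position = names(column_map)[j],
                   counts = counts,
                   frequency = 100 * counts / n,
                   n_sequences = n,
                   n_gaps = sum(gap),
                   gap_fraction = 100 * sum(gap) / n),
              class = "ConservationTable")
  })
  stats::setNames(out, names(column_map))
}

#' @export
print.ConservationTable <- function(x, ...) {
  cat(sprintf("<ConservationTable %s: n = %d, gap %.1f%%>\n", x$position,
              x$n_sequences, x$gap_fraction))
  if (length(x$counts)) {
    ord <- order(-x$counts)
    for (i in ord)
      cat(sprintf("  %s  %4d  %6.2f%%\n", names(x$counts)[i], x$counts[i],
                  x$frequency[i]))
  }
  invisible(x)
}
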