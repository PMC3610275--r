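# Ensemble-averaged helix-distortion profiles and profile differencing.
#
# Backbone dihedrals are averaged circularly (as unit vectors), since a
# naive arithmetic mean corrupts angles straddling the +/-180 boundary.
# Unit bend and unit twist are bounded magnitudes in (0, 180) and are
# averaged arithmetically.

#' Average helix-distortion profiles over a conformational ensemble
#'
#' Computes a [helix_profile()] for every model and aggregates per position:
#' circular mean/SD for phi and psi, arithmetic mean/SD for unit bend and
#' unit twist.
#'
#' @param ensemble an Ensemble (models sharing topology).
#' @param chain chain identifier.
#' @param motif_i res_seq of the motif residue i (the X of XAAP).
#' @param offsets integer offsets relative to i.
#' @param peptide_label free-text label carried on the result.
#' @return An `EnsembleProfile`: list with `mean` and `sd` data.frames
#'   (offset, phi, psi, unit_bend, unit_twist), `n_frames`,
#'   `peptide_label`.
#' @export
ensemble_profile <- function(ensemble, chain, motif_i, offsets = -7:4,
                             peptide_label = "") {
  if (inherits(ensemble, "StructureModel")) ensemble <- as_ensemble(ensemble)
  stopifnot(inherits(ensemble, "Ensemble"))
  profs <- lapply(ensemble$models, helix_profile, chain = chain,
                  motif_i = motif_i, offsets = offsets)
  stack <- function(col) do.call(rbind, lapply(profs, `[[`, col))
  agg <- function(col, circular) {
    m <- stack(col)
    if (circular) {
      list(mean = apply(m, 2, circular_mean), sd = apply(m, 2, circular_sd))
    } else {
      list(mean = colMeans(m),
           sd = apply(m, 2, function(x) {
             x <- x[is.finite(x)]
             if (length(x) <= 1) if (length(x)) 0 else NA_real_
             else stats::sd(x)
           }))
    }
  }
  phi <- agg("phi", TRUE); psi <- agg("psi", TRUE)
  bend <- agg("unit_bend", FALSE); twist <- agg("unit_twist", FALSE)
  # a position is defined only if defined in every frame
  defined <- function(col) apply(stack(col), 2, function(x) all(is.finite(x)))
  mk <- function(field) {
    d <- data.frame(offset = offsets,
                    phi = phi[[field]], psi = psi[[field]],
                    unit_bend = bend[[field]], unit_twist = twist[[field]])
    d$phi[!defined("phi")] <- NA_real_
    d$psi[!defined("psi")] <- NA_real_
    d$unit_bend[!defined("unit_bend")] <- NA_real_
    d$unit_twist[!defined("unit_twist")] <- NA_real_
    rownames(d) <- NULL
    d
  }
  structure(list(mean = mk("mean"), sd = mk("sd"),
                 n_frames = length(ensemble$models),
                 peptide_label = peptide_label, offsets = offsets),
            class = "EnsembleProfile")
}

#' @export
print.EnsembleProfile <- function(x, ...) {
  cat(sprintf("<EnsembleProfile '%s': %d frames, offsets %d..%d>\n",
              x$peptide_label, x$n_frames, min(x$offsets), max(x$offsets)))
  print(round(x$mean, 2))
  invisible(x)
}

#' Difference two ensemble profiles (test minus reference)
#'
#' Elementwise circular difference in (-180, 180], defined exactly where
#' both inputs are defined. Position ranges must overlap.
#'
#' @param test,reference EnsembleProfile objects.
#' @return A `ProfileDelta` data.frame with offset, delta_phi, delta_psi,
#'   delta_bend, delta_twist.
#' @export
profile_delta <- function(test, reference) {
  stopifnot(inherits(test, "EnsembleProfile"),
            inherits(reference, "EnsembleProfile"))
  common <- intersect(test$offsets, reference$offsets)
  if (!length(common))
    stop("disjoint position ranges: profiles share no offsets",
         call. = FALSE)
  ti <- match(common, test$offsets)
  ri <- match(common, reference$offsets)
  out <- data.frame(
    offset = common,
    delta_phi = circular_diff(test$mean$phi[ti], reference$mean$phi[ri]),
    delta_psi = circular_diff(test$mean$psi[ti], reference$mean$psi[ri]),
    delta_bend = circular_diff(test$mean$unit_bend[ti],
                               reference$mean$unit_bend[ri]),
    delta_twist = circular_diff(test$mean$unit_twist[ti],
                                reference$mean$unit_twist[ri]))
  attr(out, "test_label") <- test$peptide_label
  attr(out, "reference_label") <- reference$peptide_label
  class(out) <- c("ProfileDelta", "data.frame")
  out
}

#' Flag profile positions whose deviation exceeds a threshold
#'
#' Per position and channel, flags |delta| > threshold; the summary verdict
#' is "unperturbed" iff nothing is flagged in any channel -- the criterion
#' for calling a peptide's Pro-kink profile unaltered relative to the
#' reference.
#'
#' @param delta a [profile_delta()] result.
#' @param threshold flag threshold, degrees.
#' @return list with `flags` (data.frame of logicals per channel),
#'   `flagged` (data.frame of offset/channel/delta rows exceeding the
#'   threshold) and `verdict` ("unperturbed" or "perturbed").
#' @export
flag_distortion <- function(delta, threshold = 2) {
  stopifnot(inherits(delta, "ProfileDelta"))
  ch <- c("delta_phi", "delta_psi", "delta_bend", "delta_twist")
  flags <- as.data.frame(lapply(delta[ch], function(x)
    !is.na(x) & abs(x) > threshold))
  flags <- cbind(offset = delta$offset, flags)
  rows <- list()
  for (cc in ch) {
    hit <- which(flags[[cc]])
    for (i in hit)
      rows[[length(rows) + 1]] <- data.frame(
        offset = delta$offset[i], channel = sub("delta_", "", cc),
        delta = delta[[cc]][i], stringsAsFactors = FALSE)
  }
  flagged <- if (length(rows)) do.call(rbind, rows)
  else data.frame(offset = integer(0), channel = character(0),
                  delta = numeric(0))
  list(flags = flags, flagged = flagged,
       verdict = if (nrow(flagged)) "perturbed" else "unperturbed",
       threshold = threshold)
}

#' Four-panel plot of a profile delta
#'
#' Delta phi, delta psi, delta bend and delta twist against position offset,
#' mirroring the usual presentation of Pro-kink distortion profiles.
#'
#' @param delta a ProfileDelta.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot_profile_delta <- function(delta, ...) {
  stopifnot(inherits(delta, "ProfileDelta"))
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  panels <- c(delta_phi = "delta Phi (deg)", delta_psi = "delta Psi (deg)",
              delta_bend = "delta unit bend (deg)",
              delta_twist = "delta unit twist (deg)")
  for (cc in names(panels)) {
    graphics::plot(delta$offset, delta[[cc]], type = "b", pch = 16,
                   xlab = "position relative to motif residue i",
                   ylab = panels[[cc]], ...)
    graphics::abline(h = 0, lty = 2, col = "grey50")
  }
  invisible(delta)
}

#' Export a profile delta as TSV
#' @param delta a ProfileDelta.
#' @param path destination file.
#' @export
write_delta_tsv <- function(delta, path) {
  utils::write.table(as.data.frame(delta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
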