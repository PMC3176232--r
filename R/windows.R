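# Sliding-window engine: fixed-width windows stepped along the alignment
# coordinates of the full sequenced region (introns included). Class-aware
# statistics use only the coding columns falling inside each window, via
# the same `cols` restriction the gene-level functions accept. Defaults
# follow the study design: 75/8 for synonymous diversity, 250/25 for
# Tajima's D, Fay & Wu's H and the KA/KS tracks.

#' Enumerate sliding windows
#'
#' Windows start at 0, step, 2*step, ... and only full-width windows are
#' produced: the count is \code{floor((L - width)/step) + 1}. No truncated
#' trailing window is created; an alignment shorter than one window is an
#' error.
#'
#' @param L Alignment length.
#' @param width,step Window width and increment in bp (0 < step <= width).
#' @return Integer matrix with columns \code{start}, \code{end} (0-based
#'   half-open).
#' @export
make_windows <- function(L, width, step) {
  if (step <= 0 || step > width) stop("need 0 < step <= width")
  if (L < width)
    stop("alignment length ", L, " shorter than window width ", width)
  starts <- seq.int(0L, L - width, by = step)
  cbind(start = as.integer(starts), end = as.integer(starts + width))
}

window_value <- function(aln, mask, statistic, cols) {
  tryCatch(switch(
    statistic,
    pi_syn = pairwise_pi(aln, mask, "syn", cols = cols),
    D = {
      S <- segregating_sites(aln, mask, cols)
      if (S < 1L) NA_real_
      else tajimas_D(S, mean_pairwise_differences(aln, mask, cols), aln$n)
    },
    H_norm = {
      sfs <- unfolded_sfs(aln, mask, cols)
      if (sum(sfs$xi) < 1L) NA_real_ else fay_wu_H_normalized(sfs)
    },
    KA_KS_div = {
      ks <- divergence_by_class(aln, mask, "syn", cols)
      ka <- divergence_by_class(aln, mask, "rep", cols)
      if (!is.finite(ks) || ks <= 0) NA_real_ else ka / ks
    },
    KA_KS_poly = {
      ps <- pairwise_pi(aln, mask, "syn", cols = cols)
      pr <- pairwise_pi(aln, mask, "rep", cols = cols)
      if (!is.finite(ps) || ps <= 0) NA_real_ else pr / ps
    },
    stop("unknown statistic '", statistic, "'")
  ), error = function(e) NA_real_)
}

#' Sliding-window track of a statistic
#'
#' Computes one statistic per window, using only the window's columns
#' (coding-class denominators restricted to codons entirely inside the
#' window). Windows in which the statistic is undefined (no segregating
#' or polarizable site, no class sites, zero synonymous denominator for a
#' KA/KS ratio) carry NA rather than infinities.
#'
#' @param aln A [coding_alignment()].
#' @param mask Masks from [build_site_masks()].
#' @param statistic One of \code{"pi_syn"}, \code{"D"}, \code{"H_norm"},
#'   \code{"KA_KS_div"} (divergence ratio) or \code{"KA_KS_poly"}
#'   (polymorphism ratio pi_rep/pi_syn).
#' @param width,step Window geometry; defaults are per statistic: 75/8 for
#'   \code{pi_syn}, 250/25 otherwise.
#' @return \code{data.frame} with 1-based inclusive output coordinates:
#'   \code{gene_id}, \code{stat}, \code{start}, \code{end}, \code{mid},
#'   \code{value}, \code{ci_low}, \code{ci_high} (NA until filled by
#'   [window_confidence_bands()]) and \code{S_window}.
#' @export
window_statistic_track <- function(aln, mask, statistic,
                                   width = if (statistic == "pi_syn") 75L else 250L,
                                   step = if (statistic == "pi_syn") 8L else 25L) {
  win <- make_windows(aln$L, width, step)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    cols <- (win[i, "start"] + 1L):win[i, "end"]
    data.frame(
      gene_id = aln$gene_id, stat = statistic,
      start = win[i, "start"] + 1L, end = win[i, "end"],
      mid = (win[i, "start"] + 1L + win[i, "end"]) / 2,
      value = window_value(aln, mask, statistic, cols),
      ci_low = NA_real_, ci_high = NA_real_,
      S_window = segregating_sites(aln, mask, cols),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' KA/KS outlier cutoff from a reference-locus panel
#'
#' Empirical 95th percentile (linear interpolation between order
#' statistics) of per-locus KA/KS values from a panel of control loci.
#' With no panel the conventional default cutoff of 1.14 is returned.
#'
#' @param panel Numeric vector of per-locus KA/KS values, or NULL.
#' @param probs Percentile, default 0.95.
#' @return The cutoff value.
#' @export
kaks_cutoff_from_reference <- function(panel = NULL, probs = 0.95) {
  if (is.null(panel)) return(1.14)
  panel <- panel[is.finite(panel)]
  if (length(panel) == 0L) stop("empty reference panel")
  unname(stats::quantile(panel, probs = probs, type = 7))
}

#' Flag outlier windows against a cutoff
#'
#' @param track A track from [window_statistic_track()].
#' @param cutoff Threshold, e.g. from [kaks_cutoff_from_reference()].
#' @return The track with a logical \code{outlier} column (NA values are
#'   never outliers).
#' @export
flag_outliers <- function(track, cutoff) {
  track$outlier <- !is.na(track$value) & track$value > cutoff
  track
}
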