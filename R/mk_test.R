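# McDonald-Kreitman machinery: 2x2 fixed/polymorphic x synonymous/
# replacement tables from a coding alignment with outgroup, the neutrality
# index NI = (Pn/Ps)/(Dn/Ds), the uncorrected likelihood-ratio G statistic
# with its chi-square (df = 1) p-value, and Fisher's exact p.
#
# Counts from sequence data are pathway-averaged and therefore can be
# fractional for multi-hit codons; they are kept exact internally and
# rounded only in table-styled display.

#' Build a McDonald-Kreitman count table from an alignment
#'
#' Walks the usable coding codons (complete deletion including the
#' outgroup). Within each codon, a position at which the ingroup segregates
#' contributes one polymorphism per derived state, classified synonymous or
#' replacement in codon context against the ingroup consensus; positions at
#' which the ingroup is monomorphic but differs from the outgroup
#' contribute fixed differences, classified by the pathway method with
#' polymorphic positions held at the ingroup consensus. A site that is both
#' polymorphic and divergent counts as polymorphism only.
#'
#' @param aln A [coding_alignment()].
#' @param mask Masks from [build_site_masks()].
#' @param cols Optional restriction to a set of 1-based alignment columns.
#' @return List with fractional counts \code{Ds}, \code{Ps}, \code{Dn},
#'   \code{Pn} and bookkeeping: \code{multiallelic_sites} (sites where more
#'   than two ingroup states were seen, each derived state counted as one
#'   polymorphism) and \code{stop_codons_excluded}.
#' @export
build_mk_table <- function(aln, mask, cols = NULL) {
  cm <- usable_codons(aln, mask, cols, polarized = TRUE)
  out <- list(Ds = 0, Ps = 0, Dn = 0, Pn = 0,
              multiallelic_sites = 0L, stop_codons_excluded = 0L)
  if (nrow(cm) == 0L) return(out)
  lk <- syn_sites_lookup()
  cs_in <- codon_strings(aln$mat, cm)
  for (j in seq_len(nrow(cm))) {
    codons <- cs_in[, j]
    outg <- paste(aln$outgroup[cm[j, ]], collapse = "")
    if (all(codons == codons[1L]) && codons[1L] == outg) next
    if (any(!codons %in% names(lk)) || !outg %in% names(lk)) {
      out$stop_codons_excluded <- out$stop_codons_excluded + 1L
      next
    }
    cols3 <- t(aln$mat[, cm[j, ], drop = FALSE])   # 3 x n base matrix
    cons <- apply(cols3, 1L, function(x) names(which.max(table(x))))
    poly_pos <- which(apply(cols3, 1L, function(x) length(unique(x)) > 1L))
    # polymorphisms: one per derived (non-consensus) state, codon context
    for (p in poly_pos) {
      states <- unique(cols3[p, ])
      if (length(states) > 2L)
        out$multiallelic_sites <- out$multiallelic_sites + 1L
      for (b in setdiff(states, cons[p])) {
        ref <- cons; ref[p] <- b
        variant <- paste(ref, collapse = "")
        if (!variant %in% names(lk)) {       # stop variant: replacement
          out$Pn <- out$Pn + 1
          next
        }
        d <- classify_codon_differences(paste(cons, collapse = ""), variant)
        out$Ps <- out$Ps + d[["syn"]]
        out$Pn <- out$Pn + d[["rep"]]
      }
    }
    # fixed differences: positions monomorphic in the ingroup yet
    # different from the outgroup; polymorphic positions are masked to the
    # ingroup consensus so only fixed changes enter the pathway
    outg3 <- strsplit(outg, "", fixed = TRUE)[[1L]]
    fixed_target <- cons
    mono <- setdiff(1:3, poly_pos)
    fixed_target[mono] <- outg3[mono]
    tgt <- paste(fixed_target, collapse = "")
    if (tgt != paste(cons, collapse = "") && tgt %in% names(lk)) {
      d <- classify_codon_differences(paste(cons, collapse = ""), tgt)
      out$Ds <- out$Ds + d[["syn"]]
      out$Dn <- out$Dn + d[["rep"]]
    }
  }
  out
}

#' Neutrality index of a McDonald-Kreitman table
#'
#' \code{NI = (Pn/Ps) / (Dn/Ds)}; values below 1 indicate an excess of
#' replacement fixations (adaptive protein evolution), above 1 an excess of
#' replacement polymorphism. Reported together with \code{-log10(NI)}.
#'
#' @param Ds,Ps,Dn,Pn Fixed/polymorphic synonymous/replacement counts.
#' @return List with \code{NI}, \code{neg_log10_NI} and \code{defined}
#'   (FALSE with NA values when any count is zero; no continuity
#'   correction is applied).
#' @export
neutrality_index <- function(Ds, Ps, Dn, Pn) {
  if (min(Ds, Ps, Dn, Pn) <= 0)
    return(list(NI = NA_real_, neg_log10_NI = NA_real_, defined = FALSE))
  ni <- (Pn / Ps) / (Dn / Ds)
  list(NI = ni, neg_log10_NI = -log10(ni), defined = TRUE)
}

#' Likelihood-ratio G statistic of a 2x2 table
#'
#' \code{G = 2 sum O log(O/E)} with expectations from the row/column
#' marginals; no Williams or Yates correction; empty cells contribute 0.
#'
#' @inheritParams neutrality_index
#' @return Numeric G; errors when a marginal is zero.
#' @export
g_statistic <- function(Ds, Ps, Dn, Pn) {
  O <- matrix(c(Ds, Ps, Dn, Pn), nrow = 2L, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("G statistic undefined: zero marginal")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(ifelse(O > 0, O * log(O / E), 0))
}

#' Two-tailed Fisher's exact p of a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables (with the observed
#' marginals) whose probability does not exceed that of the observed table.
#' Counts are rounded to integers for the exact test.
#'
#' @inheritParams neutrality_index
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(Ds, Ps, Dn, Pn) {
  m <- matrix(round(c(Ds, Ps, Dn, Pn)), nrow = 2L, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Full McDonald-Kreitman test from counts
#'
#' Convenience wrapper producing one table row: the four counts, NI,
#' \code{-log10(NI)}, the G statistic with its chi-square (df = 1)
#' p-value, and Fisher's exact p.
#'
#' @param gene_id Locus label.
#' @inheritParams neutrality_index
#' @return One-row \code{data.frame} of class \code{mk_table}.
#' @export
mk_from_counts <- function(gene_id, Ds, Ps, Dn, Pn) {
  ni <- neutrality_index(Ds, Ps, Dn, Pn)
  marg_ok <- min(Ds + Ps, Dn + Pn, Ds + Dn, Ps + Pn) > 0
  G <- if (marg_ok) g_statistic(Ds, Ps, Dn, Pn) else NA_real_
  res <- data.frame(
    gene_id = gene_id, Ds = Ds, Ps = Ps, Dn = Dn, Pn = Pn,
    NI = ni$NI, neg_log10_NI = ni$neg_log10_NI,
    G = G,
    g_p = if (marg_ok) stats::pchisq(G, df = 1L, lower.tail = FALSE) else NA_real_,
    fisher_p = fisher_exact_p(Ds, Ps, Dn, Pn),
    stringsAsFactors = FALSE
  )
  class(res) <- c("mk_table", class(res))
  res
}

#' McDonald-Kreitman test of a coding alignment
#'
#' Builds the count table with [build_mk_table()] and evaluates NI, G and
#' Fisher's exact test on it.
#'
#' @inheritParams build_mk_table
#' @return One-row \code{data.frame} as in [mk_from_counts()], with the
#'   fractional counts kept exact and bookkeeping columns
#'   \code{multiallelic_sites}, \code{stop_codons_excluded} appended.
#' @export
mk_test <- function(aln, mask = build_site_masks(aln), cols = NULL) {
  cnt <- build_mk_table(aln, mask, cols)
  res <- mk_from_counts(aln$gene_id, cnt$Ds, cnt$Ps, cnt$Dn, cnt$Pn)
  res$multiallelic_sites <- cnt$multiallelic_sites
  res$stop_codons_excluded <- cnt$stop_codons_excluded
  res
}
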