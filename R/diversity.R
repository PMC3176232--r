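# Core per-gene statistics: segregating sites, pairwise diversity (total
# and by Nei-Gojobori site class), the unfolded SFS, Tajima's D, normalized
# Fay & Wu's H, and Jukes-Cantor corrected divergence from the outgroup.
#
# All functions share the complete-deletion masks from build_site_masks();
# window restrictions are expressed through the `cols` argument (1-based
# alignment columns) so a window track and the gene-level value go through
# identical code.

base_counts <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  rbind(A = colSums(sub == "A"), C = colSums(sub == "C"),
        G = colSums(sub == "G"), T = colSums(sub == "T"))
}

restrict_cols <- function(maskvec, cols = NULL) {
  idx <- which(maskvec)
  if (!is.null(cols)) idx <- intersect(idx, cols)
  idx
}

#' Number of segregating sites
#'
#' Counts usable columns (complete deletion over the ingroup) at which the
#' ingroup carries two or more distinct states. Variation present only in
#' the outgroup does not count.
#'
#' @param aln A [coding_alignment()].
#' @param mask Masks from [build_site_masks()].
#' @param cols Optional restriction to a set of 1-based alignment columns
#'   (used by the window engine).
#' @return Integer count.
#' @export
segregating_sites <- function(aln, mask, cols = NULL) {
  idx <- restrict_cols(mask$usable_total, cols)
  if (length(idx) == 0L) return(0L)
  bc <- base_counts(aln$mat, idx)
  sum(apply(bc, 2L, max) < aln$n)
}

pairwise_diff_counts <- function(aln, idx) {
  # per-column number of differing ingroup pairs
  if (length(idx) == 0L) return(numeric(0))
  bc <- base_counts(aln$mat, idx)
  choose(aln$n, 2L) - colSums(choose(bc, 2L))
}

#' Mean number of pairwise differences (count form)
#'
#' Average over all ingroup pairs of the number of differing usable
#' columns; this is the absolute (not per-site) quantity that enters
#' Tajima's D.
#'
#' @inheritParams segregating_sites
#' @return Numeric scalar.
#' @export
mean_pairwise_differences <- function(aln, mask, cols = NULL) {
  idx <- restrict_cols(mask$usable_total, cols)
  sum(pairwise_diff_counts(aln, idx)) / choose(aln$n, 2L)
}

#' Per-site pairwise nucleotide diversity
#'
#' For \code{class = "all"}, the mean over all ingroup pairs of the
#' proportion of differing usable columns. For \code{"syn"}/\code{"rep"},
#' differences within complete usable codons are partitioned by the
#' Nei-Gojobori pathway method and divided by the fractional synonymous /
#' replacement site totals averaged over the ingroup sample. Within-species
#' diversity is uncorrected (no multiple-hit correction).
#'
#' @inheritParams segregating_sites
#' @param class One of \code{"all"}, \code{"syn"}, \code{"rep"}.
#' @return Per-site diversity (numeric scalar); errors when no usable site
#'   (or no class site) exists.
#' @export
pairwise_pi <- function(aln, mask, class = c("all", "syn", "rep"),
                        cols = NULL) {
  class <- match.arg(class)
  if (class == "all") {
    idx <- restrict_cols(mask$usable_total, cols)
    if (length(idx) == 0L) stop("no usable sites: pi undefined")
    return(sum(pairwise_diff_counts(aln, idx)) /
             (choose(aln$n, 2L) * length(idx)))
  }
  cc <- class_counts(aln, mask, cols)
  sites <- if (class == "syn") cc$syn_sites else cc$rep_sites
  diffs <- if (class == "syn") cc$syn_pair_diffs else cc$rep_pair_diffs
  if (!is.finite(sites) || sites <= 0)
    stop("no usable ", class, " sites: pi undefined")
  diffs / (choose(aln$n, 2L) * sites)
}

usable_codons <- function(aln, mask, cols = NULL, polarized = FALSE) {
  cm <- codon_map(aln)
  m <- if (polarized) mask$usable_polarized else mask$usable_total
  ok <- m[cm[, 1L]] & m[cm[, 2L]] & m[cm[, 3L]]
  if (!is.null(cols)) {
    inwin <- matrix(cm %in% cols, ncol = 3L)
    ok <- ok & inwin[, 1L] & inwin[, 2L] & inwin[, 3L]
  }
  cm[ok, , drop = FALSE]
}

codon_strings <- function(seqmat, cm) {
  # rows = sequences, cols = codons
  matrix(paste0(seqmat[, cm[, 1L]], seqmat[, cm[, 2L]], seqmat[, cm[, 3L]]),
         nrow = nrow(seqmat))
}

syn_sites_lookup <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      gc <- genetic_code()
      sense <- names(gc)[gc != "*"]
      tbl <<- vapply(sense, nei_gojobori_sites, numeric(1))
    }
    tbl
  }
})

# Nei-Gojobori bookkeeping over usable complete codons: fractional
# synonymous/replacement site totals (averaged over the ingroup sample)
# and pathway-partitioned pairwise difference totals. Codons in which any
# ingroup haplotype carries a stop are excluded and counted.
class_counts <- function(aln, mask, cols = NULL) {
  cm <- usable_codons(aln, mask, cols)
  empty <- list(syn_sites = 0, rep_sites = 0, syn_pair_diffs = 0,
                rep_pair_diffs = 0, n_codons = 0L, stop_codons_excluded = 0L)
  if (nrow(cm) == 0L) return(empty)
  cs <- codon_strings(aln$mat, cm)
  lk <- syn_sites_lookup()
  has_stop <- colSums(matrix(!(cs %in% names(lk)), nrow = aln$n)) > 0L
  cs <- cs[, !has_stop, drop = FALSE]
  if (ncol(cs) == 0L) {
    empty$stop_codons_excluded <- sum(has_stop)
    return(empty)
  }
  syn_sites <- mean(rowSums(matrix(lk[cs], nrow = aln$n)))
  n_codons <- ncol(cs)
  syn_d <- 0; rep_d <- 0
  poly <- which(apply(cs, 2L, function(x) length(unique(x)) > 1L))
  for (j in poly) {
    tab <- table(cs[, j])
    u <- names(tab)
    for (a in seq_len(length(u) - 1L)) for (b in (a + 1L):length(u)) {
      d <- classify_codon_differences(u[a], u[b])
      w <- tab[[a]] * tab[[b]]
      syn_d <- syn_d + w * d[["syn"]]
      rep_d <- rep_d + w * d[["rep"]]
    }
  }
  list(syn_sites = syn_sites, rep_sites = 3 * n_codons - syn_sites,
       syn_pair_diffs = syn_d, rep_pair_diffs = rep_d,
       n_codons = n_codons, stop_codons_excluded = sum(has_stop))
}

#' Unfolded site frequency spectrum
#'
#' Polarizes biallelic ingroup sites with the outgroup: at each usable
#' polarized column where the ingroup carries exactly two states and the
#' outgroup matches one of them, the other state is derived and its count
#' increments the spectrum. Columns with more than two ingroup states or a
#' third-state outgroup are excluded (counted in \code{excluded}).
#'
#' @inheritParams segregating_sites
#' @return Object of class \code{unfolded_sfs}: list with \code{n},
#'   \code{xi} (counts at derived frequency 1..n-1), \code{sites_polarized}
#'   and \code{excluded}.
#' @export
unfolded_sfs <- function(aln, mask, cols = NULL) {
  idx <- restrict_cols(mask$usable_polarized, cols)
  n <- aln$n
  xi <- integer(n - 1L)
  excluded <- 0L
  if (length(idx)) {
    bc <- base_counts(aln$mat, idx)
    nstates <- colSums(bc > 0L)
    og <- aln$outgroup[idx]
    for (k in which(nstates == 2L)) {
      states <- rownames(bc)[bc[, k] > 0L]
      if (!og[k] %in% states) { excluded <- excluded + 1L; next }
      derived <- setdiff(states, og[k])
      cnt <- bc[derived, k]
      xi[cnt] <- xi[cnt] + 1L
    }
    excluded <- excluded + sum(nstates > 2L)
  }
  structure(list(n = n, xi = xi, sites_polarized = length(idx),
                 excluded = excluded),
            class = "unfolded_sfs")
}

#' Tajima's neutrality-test coefficients and SFS estimators
#'
#' Standard constants for a sample of n haplotypes: harmonic numbers
#' \code{a_n}, \code{b_n} and the Tajima (1989) variance coefficients
#' \code{b1, b2, c1, c2, e1, e2}.
#'
#' @param n Haplotype count, n >= 2.
#' @return Named list of constants.
#' @export
neutrality_constants <- function(n) {
  if (n < 2L) stop("n must be >= 2")
  i <- seq_len(n - 1L)
  a_n <- sum(1 / i)
  b_n <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a_n
  c2 <- b2 - (n + 2) / (a_n * n) + b_n / a_n^2
  list(a_n = a_n, b_n = b_n, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a_n, e2 = c2 / (a_n^2 + b_n))
}

#' Tajima's D
#'
#' Normalized difference between the mean pairwise difference count and
#' Watterson's estimator \code{S / a_n}.
#'
#' @param S Number of segregating sites (>= 1).
#' @param pi_count Mean pairwise differences in absolute (count) form, see
#'   [mean_pairwise_differences()].
#' @param n Haplotype count (>= 4 for a defined variance).
#' @return Numeric scalar.
#' @export
tajimas_D <- function(S, pi_count, n) {
  if (S < 1L) stop("Tajima's D undefined at S = 0")
  if (n < 4L) stop("Tajima's D needs n >= 4")
  k <- neutrality_constants(n)
  (pi_count - S / k$a_n) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

sfs_theta_pi <- function(xi, n) {
  i <- seq_along(xi)
  sum(xi * 2 * i * (n - i)) / (n * (n - 1))
}

sfs_theta_L <- function(xi, n) {
  i <- seq_along(xi)
  sum(i * xi) / (n - 1)
}

#' Normalized Fay & Wu's H
#'
#' \code{H = (theta_pi - theta_L) / sqrt(Var)}, where \code{theta_L} weights
#' the unfolded SFS by derived-allele frequency; the variance uses
#' Watterson's estimator and \code{theta^2 = S(S-1)/(a_n^2 + b_n)} with the
#' Zeng, Fu, Shi & Wu (2006) coefficients. Strongly negative under an
#' excess of high-frequency derived variants, the footprint of a sweep.
#'
#' @param sfs An [unfolded_sfs()] (or list with \code{n} and \code{xi}).
#' @return Numeric scalar; errors when no polarized segregating site.
#' @export
fay_wu_H_normalized <- function(sfs) {
  n <- sfs$n
  xi <- sfs$xi
  S <- sum(xi)
  if (S < 1L) stop("Fay & Wu's H undefined with no polarized variant")
  if (n < 3L) stop("Fay & Wu's H needs n >= 3")
  k <- neutrality_constants(n)
  theta_w <- S / k$a_n
  theta_sq <- S * (S - 1) / (k$a_n^2 + k$b_n)
  b_n1 <- k$b_n + 1 / n^2   # sum_{i=1}^{n} 1/i^2
  v <- theta_w * (n - 2) / (6 * (n - 1)) +
    theta_sq * (18 * n^2 * (3 * n + 2) * b_n1 -
                  (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (sfs_theta_pi(xi, n) - sfs_theta_L(xi, n)) / sqrt(v)
}

#' Jukes-Cantor distance correction
#'
#' @param p Observed proportion of differing sites, p < 0.75.
#' @return Corrected per-site divergence \code{-(3/4) log(1 - 4p/3)}.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction undefined at p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Per-site synonymous or replacement divergence from the outgroup
#'
#' Mean over all ingroup-versus-outgroup comparisons of the class-weighted
#' codon differences divided by class site totals (sites averaged over the
#' two sequences of each pair), Jukes-Cantor corrected. Uses codons whose
#' three columns are usable in both ingroup and outgroup; codons with a
#' stop in any compared sequence are excluded.
#'
#' @inheritParams segregating_sites
#' @param class \code{"syn"} or \code{"rep"}.
#' @return Corrected per-site divergence K.
#' @export
divergence_by_class <- function(aln, mask, class = c("syn", "rep"),
                                cols = NULL) {
  class <- match.arg(class)
  cm <- usable_codons(aln, mask, cols, polarized = TRUE)
  if (nrow(cm) == 0L) stop("no usable codons for divergence")
  lk <- syn_sites_lookup()
  cs_in <- codon_strings(aln$mat, cm)
  cs_out <- codon_strings(matrix(aln$outgroup, nrow = 1L), cm)[1L, ]
  ok <- cs_out %in% names(lk) &
    colSums(matrix(!(cs_in %in% names(lk)), nrow = aln$n)) == 0L
  cs_in <- cs_in[, ok, drop = FALSE]
  cs_out <- cs_out[ok]
  ncod <- length(cs_out)
  if (ncod == 0L) stop("no stop-free usable codons for divergence")
  syn_out <- sum(lk[cs_out])
  p <- vapply(seq_len(aln$n), function(i) {
    syn_i <- sum(lk[cs_in[i, ]])
    d <- c(syn = 0, rep = 0)
    for (j in which(cs_in[i, ] != cs_out))
      d <- d + classify_codon_differences(cs_in[i, j], cs_out[j])[c("syn", "rep")]
    syn_sites <- (syn_i + syn_out) / 2
    sites <- if (class == "syn") syn_sites else 3 * ncod - syn_sites
    d[[class]] / sites
  }, numeric(1))
  jukes_cantor(mean(p))
}

#' Screen haplotypes carrying unexpected stop codons
#'
#' A haplotype with an internal stop codon at a usable codon where the
#' ingroup consensus is a sense codon most likely reflects a frame or
#' annotation error; silently keeping it would corrupt the
#' synonymous/replacement partition. Such haplotypes are dropped with a
#' warning naming the sequence. Codons at which every sequence carries a
#' stop (a conserved terminal stop) are left for the class machinery to
#' exclude.
#'
#' @param aln A [coding_alignment()].
#' @return A (possibly reduced) \code{coding_alignment}.
#' @export
screen_stop_haplotypes <- function(aln) {
  mask <- build_site_masks(aln)
  cm <- usable_codons(aln, mask)
  if (nrow(cm) == 0L) return(aln)
  lk <- syn_sites_lookup()
  cs <- codon_strings(aln$mat, cm)
  gc <- genetic_code()
  is_stop_m <- matrix(!is.na(gc[cs]) & gc[cs] == "*", nrow = aln$n)
  all_stop <- colSums(is_stop_m) == aln$n
  offending <- rowSums(is_stop_m[, !all_stop, drop = FALSE]) > 0L
  if (!any(offending)) return(aln)
  ids <- rownames(aln$mat)
  if (is.null(ids)) ids <- sprintf("hap%02d", seq_len(aln$n))
  for (i in which(offending))
    warning("dropping haplotype '", ids[i],
            "': internal stop codon at a sense-consensus position",
            call. = FALSE)
  keep <- !offending
  if (sum(keep) < 2L)
    stop("fewer than 2 haplotypes remain after stop-codon screening")
  coding_alignment(aln$gene_id,
                   stats::setNames(apply(aln$mat[keep, , drop = FALSE], 1L,
                                         paste, collapse = ""),
                                   ids[keep]),
                   paste(aln$outgroup, collapse = ""), aln$exons)
}

#' One-row summary of a gene
#'
#' Assembles the per-gene summary: haplotype count, usable site counts,
#' segregating sites, the per-site diversity triplet (total, synonymous,
#' replacement), Jukes-Cantor corrected synonymous and replacement
#' divergence from the outgroup, Tajima's D and normalized Fay & Wu's H.
#' Empirical p-value columns are NA until filled by the coalescent null
#' machinery.
#'
#' @inheritParams segregating_sites
#' @return One-row \code{data.frame}.
#' @export
gene_summary <- function(aln, mask = build_site_masks(aln)) {
  S <- segregating_sites(aln, mask)
  sfs <- unfolded_sfs(aln, mask)
  D <- if (S >= 1L && aln$n >= 4L)
    tajimas_D(S, mean_pairwise_differences(aln, mask), aln$n) else NA_real_
  H <- if (sum(sfs$xi) >= 1L && aln$n >= 3L)
    fay_wu_H_normalized(sfs) else NA_real_
  data.frame(
    gene_id = aln$gene_id,
    n = aln$n,
    sites = sum(mask$usable_total),
    coding_sites = sum(mask$usable_total & mask$coding),
    S = S,
    pi_tot = pairwise_pi(aln, mask, "all"),
    pi_syn = pairwise_pi(aln, mask, "syn"),
    pi_rep = pairwise_pi(aln, mask, "rep"),
    K_syn = divergence_by_class(aln, mask, "syn"),
    K_rep = divergence_by_class(aln, mask, "rep"),
    D = D,
    H_norm = H,
    p_D = NA_real_,
    p_H = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.unfolded_sfs <- function(x, ...) {
  cat("unfolded SFS: n =", x$n, ", S_polarized =", sum(x$xi),
      "(", x$excluded, "excluded )\n")
  print(stats::setNames(x$xi, seq_along(x$xi)))
  invisible(x)
}
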