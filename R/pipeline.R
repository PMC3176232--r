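# Per-gene orchestration: one shared mask build feeding the summary row,
# the MK table, the four window tracks (with simulated confidence bands
# for D and H) and the gene-level null distributions. One RNG stream per
# gene is derived from (master seed, gene id) so per-gene results do not
# depend on cohort composition.

#' Derive a per-gene seed from a master seed and gene id
#'
#' @param master_seed Integer master seed.
#' @param gene_id Character gene label.
#' @return Integer below 2^31, deterministic in both arguments.
#' @export
gene_seed <- function(master_seed, gene_id) {
  h <- sum(utf8ToInt(gene_id) * seq_along(utf8ToInt(gene_id)))
  as.integer((as.double(master_seed) * 48271 + h * 16807) %% 2147483647)
}

#' Run the full per-gene analysis
#'
#' From one coding alignment: screens stop-codon haplotypes, builds the
#' shared site masks, computes the gene summary row, the MK test, the
#' gene-level null distributions for D and H (fixed-S at the observed S,
#' under the supplied demography), the four window tracks (75/8
#' synonymous diversity; 250/25 D, H and both KA/KS ratios) with
#' simulated confidence bands on D and H, and the KA/KS outlier flags.
#'
#' @param aln A [coding_alignment()].
#' @param seed Master seed; the gene's own stream is derived via
#'   [gene_seed()].
#' @param R Simulation replicates for null distributions and window bands.
#' @param demography,posterior_draws Demographic null, as in
#'   [simulate_null_statistics()].
#' @param panel Optional numeric vector of reference-locus KA/KS values;
#'   when NULL the default cutoff 1.14 is used.
#' @param window_R Replicates per distinct window S (defaults to R).
#' @param with_windows Set FALSE to skip the window tracks.
#' @return List of class \code{gene_run}: \code{summary} (with empirical
#'   p-values filled), \code{mk}, \code{tracks} (named list), \code{nulls}
#'   (D and H [null_distribution()]s), \code{kaks_cutoff}, \code{log}.
#' @export
run_gene <- function(aln, seed = 1L, R = 10000L, demography = NULL,
                     posterior_draws = NULL, panel = NULL,
                     window_R = R, with_windows = TRUE) {
  aln <- screen_stop_haplotypes(aln)
  mask <- build_site_masks(aln)
  gseed <- gene_seed(seed, aln$gene_id)
  summary <- gene_summary(aln, mask)
  mk <- mk_test(aln, mask)
  nulls <- list()
  if (!is.na(summary$D))
    nulls$D <- null_distribution(summary$D, aln$n, R, "D", "fixed_S",
                                 S = summary$S, demography = demography,
                                 posterior_draws = posterior_draws,
                                 seed = gseed)
  sfs <- unfolded_sfs(aln, mask)
  if (!is.na(summary$H_norm))
    nulls$H <- null_distribution(summary$H_norm, aln$n, R, "H_norm",
                                 "fixed_S", S = sum(sfs$xi),
                                 demography = demography,
                                 posterior_draws = posterior_draws,
                                 seed = gseed + 1L)
  if (!is.null(nulls$D)) summary$p_D <- nulls$D$p_one_tailed
  if (!is.null(nulls$H)) summary$p_H <- nulls$H$p_one_tailed
  cutoff <- kaks_cutoff_from_reference(panel)
  tracks <- list()
  if (with_windows && aln$L >= 250L) {
    tracks$pi_syn <- window_statistic_track(aln, mask, "pi_syn")
    tracks$D <- window_confidence_bands(
      window_statistic_track(aln, mask, "D"), aln$n, window_R,
      demography = demography, posterior_draws = posterior_draws,
      seed = gseed + 2L)
    tracks$H_norm <- window_confidence_bands(
      window_statistic_track(aln, mask, "H_norm"), aln$n, window_R,
      demography = demography, posterior_draws = posterior_draws,
      seed = gseed + 3L)
    tracks$KA_KS_div <- flag_outliers(
      window_statistic_track(aln, mask, "KA_KS_div"), cutoff)
    tracks$KA_KS_poly <- flag_outliers(
      window_statistic_track(aln, mask, "KA_KS_poly"), cutoff)
  }
  log <- list(
    gene_id = aln$gene_id, n = aln$n, seed = gseed,
    masked_columns = sum(!mask$usable_total),
    unpolarizable_columns = sum(mask$usable_total & !mask$usable_polarized),
    sfs_excluded_sites = sfs$excluded,
    kaks_cutoff = cutoff)
  structure(list(summary = summary, mk = mk, tracks = tracks,
                 nulls = nulls, kaks_cutoff = cutoff, log = log),
            class = "gene_run")
}

#' Run a cohort of genes, tolerating per-gene failures
#'
#' @param alns Named list of [coding_alignment()]s.
#' @param ... Passed to [run_gene()].
#' @return Named list of \code{gene_run}s; failed genes carry a
#'   \code{gene_error} condition object instead, with the error message
#'   and stage preserved.
#' @export
run_cohort <- function(alns, ...) {
  lapply(alns, function(a)
    tryCatch(run_gene(a, ...), error = function(e)
      structure(list(gene_id = a$gene_id, message = conditionMessage(e)),
                class = "gene_error")))
}

#' Summarize a cohort run into tables
#'
#' Binds the per-gene summary and MK rows and appends cross-gene
#' averages: the unweighted arithmetic mean over genes and the
#' site-weighted mean (each gene weighted by its usable site count), both
#' labeled.
#'
#' @param runs List of \code{gene_run}s (errors are skipped).
#' @return List with \code{summary} (gene rows plus two average rows) and
#'   \code{mk}.
#' @export
summarize_run <- function(runs) {
  ok <- runs[vapply(runs, inherits, logical(1), "gene_run")]
  if (length(ok) == 0L) stop("no gene completed")
  summ <- do.call(rbind, lapply(ok, `[[`, "summary"))
  mk <- do.call(rbind, lapply(ok, `[[`, "mk"))
  num_cols <- c("pi_tot", "pi_syn", "pi_rep", "K_syn", "K_rep", "D", "H_norm")
  unw <- summ[1, ]
  unw[] <- NA
  unw$gene_id <- "average_unweighted"
  unw[num_cols] <- lapply(summ[num_cols], mean, na.rm = TRUE)
  wts <- summ$sites
  sw <- unw
  sw$gene_id <- "average_site_weighted"
  sw[num_cols] <- lapply(summ[num_cols], function(x)
    sum(x * wts, na.rm = TRUE) / sum(wts[!is.na(x)]))
  rownames(summ) <- NULL
  list(summary = rbind(summ, unw, sw), mk = mk)
}

#' Write the outputs of a gene run to a directory
#'
#' Emits the summary and MK rows as TSV (1-based inclusive coordinates,
#' values at display precision), each window track as TSV, the null
#' replicate values optionally, and a JSON sidecar with full precision
#' plus the run log (including the window coordinate convention and the
#' no-multiple-testing-correction note).
#'
#' @param run A \code{gene_run}.
#' @param dir Output directory.
#' @param dump_null_values Also write the simulated null statistic values.
#' @return Invisibly, the directory.
#' @export
write_gene_outputs <- function(run, dir, dump_null_values = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- run$summary$gene_id
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$summary, paste0(id, "_summary.tsv"))
  wt(run$mk, paste0(id, "_mk.tsv"))
  for (nm in names(run$tracks))
    wt(run$tracks[[nm]], paste0(id, "_track_", nm, ".tsv"))
  meta <- c(run$log,
            list(coordinates = "1-based inclusive in emitted tables",
                 window_convention = "windows index the provided alignment",
                 multiple_testing = "no correction across windows"))
  jsonlite::write_json(
    list(summary = run$summary, mk = run$mk, log = meta),
    file.path(dir, paste0(id, "_run.json")),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)
  if (dump_null_values && length(run$nulls))
    wt(data.frame(statistic = rep(names(run$nulls),
                                  vapply(run$nulls, function(x)
                                    length(x$values), integer(1))),
                  value = unlist(lapply(run$nulls, `[[`, "values"),
                                 use.names = FALSE)),
       paste0(id, "_null_values.tsv"))
  invisible(dir)
}
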