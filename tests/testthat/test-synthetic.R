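test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_gene_config(gene_id = "det", n = 10, L = 600, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_gene(generate_gene(cfg), d1)
  write_synthetic_gene(generate_gene(cfg), d2)
  for (f in c("det.fasta", "det.bed", "det_truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("omega = 0 yields no replacement variation at all", {
  g <- generate_gene(synthetic_gene_config(gene_id = "pur", n = 12, L = 900,
                                           omega = 0, theta = 0.015,
                                           seed = 8))
  expect_false(any(g$truth$class == "rep"))
  mask <- build_site_masks(g$aln)
  expect_equal(pairwise_pi(g$aln, mask, "rep"), 0)
  mk <- build_mk_table(g$aln, mask)
  expect_equal(mk$Pn + mk$Dn, 0)
})

test_that("the SFS computed from sequences equals the truth bookkeeping", {
  for (seed in c(2, 13, 29)) {
    g <- generate_gene(synthetic_gene_config(gene_id = "sfs", n = 9, L = 600,
                                             seed = seed))
    sfs <- unfolded_sfs(g$aln, build_site_masks(g$aln))
    tr <- g$truth[g$truth$side == "ingroup", ]
    expect_equal(sfs$xi, tabulate(tr$count, nbins = g$aln$n - 1L))
  }
})

test_that("generated polymorphism classes agree with post-hoc classification", {
  g <- generate_gene(synthetic_gene_config(gene_id = "cls", n = 8, L = 1200,
                                           coding_frac = 1, omega = 0.6,
                                           seed = 41))
  cm <- codon_map(g$aln)
  # ingroup rows only: the generator puts at most one ingroup change per
  # codon, so haplotype 1 with this position reverted IS the ancestral
  # codon context the label was assigned in
  tr <- g$truth[g$truth$class != "noncoding" & g$truth$side == "ingroup", ]
  for (i in seq_len(nrow(tr))) {
    ci <- (tr$pos[i] - 1L) %/% 3L + 1L
    anc_codon <- g$aln$mat[1, cm[ci, ]]
    a <- anc_codon; a[cm[ci, ] == tr$pos[i]] <- tr$anc[i]
    b <- a; b[cm[ci, ] == tr$pos[i]] <- tr$der[i]
    d <- classify_codon_differences(paste(a, collapse = ""),
                                    paste(b, collapse = ""))
    expect_equal(unname(d[[tr$class[i]]]), 1, info = paste("row", i))
  }
})

test_that("Watterson's estimator recovers the configured theta", {
  reps <- 150L
  n <- 12L; L <- 900L; theta <- 0.01
  a_n <- sum(1 / (1:(n - 1)))
  est <- vapply(seq_len(reps), function(r) {
    g <- generate_gene(synthetic_gene_config(gene_id = "tw", n = n, L = L,
                                             theta = theta, seed = 5000 + r))
    segregating_sites(g$aln, build_site_masks(g$aln)) / (a_n * L)
  }, numeric(1))
  expect_lt(abs(mean(est) - theta), 3 * sd(est) / sqrt(reps))
})

test_that("the reference panel behaves at the edges and reproduces", {
  p1 <- generate_reference_panel(k = 1, n = 8, L = 300, seed = 3)
  expect_equal(kaks_cutoff_from_reference(p1$ka_ks), p1$ka_ks)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  generate_reference_panel(k = 5, n = 8, L = 300, seed = 7, path = f1)
  generate_reference_panel(k = 5, n = 8, L = 300, seed = 7, path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("study-shaped configs carry the intended sample sizes and lengths", {
  cfgs <- table1_like_configs()
  expect_length(cfgs, 8L)
  expect_equal(cfgs$PPO1syn$n, 54L)
  expect_equal(cfgs$PPO1syn$L, 1798L)
  expect_equal(nrow(cfgs$CathLsyn$exons), 4L)
  g <- generate_gene(cfgs$GHf10syn)
  expect_equal(g$aln$L, 1035L)
  expect_equal(g$aln$n, 24L)
})

test_that("sweep and balancing genealogies keep coalescent bookkeeping intact", {
  set.seed(15)
  for (i in 1:10) {
    tw <- aspenselect:::sweep_genealogy(12L, 0.05, 0.8)
    tb <- aspenselect:::balanced_genealogy(12L, 3, 0.5)
    for (tr in list(tw, tb)) {
      expect_equal(sum(tr$parent == 0L), 1L)         # single root
      expect_equal(tr$nleaves[which(tr$parent == 0L)], 12L)
      expect_true(all(tr$blen >= 0))
      nonroot <- which(tr$parent > 0L)
      expect_true(all(tr$nleaves[nonroot] < 12L) ||
                    max(tr$nleaves[nonroot]) <= 11L)
    }
    expect_gt(tb$tmrca, 3)
  }
})

test_that("study-shaped configs realize synonymous divergence in the target band", {
  cfgs <- table1_like_configs(77)
  ks <- vapply(cfgs, function(cfg) {
    g <- generate_gene(cfg)
    divergence_by_class(g$aln, build_site_masks(g$aln), "syn")
  }, numeric(1))
  # configured targets span 0.033-0.079; single replicates are noisy, so
  # assert a generous envelope around the band
  expect_true(all(ks > 0.015 & ks < 0.13))
})
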