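toy_aln <- function(ing, outg, cod_len = NULL) {
  L <- nchar(ing[[1]])
  if (is.null(cod_len)) cod_len <- L %/% 3 * 3
  coding_alignment("toy", setNames(ing, sprintf("h%d", seq_along(ing))),
                   outg, cbind(0, cod_len))
}

test_that("segregating sites and pi behave on constructed cases", {
  a <- toy_aln(c("ATGAAATTT", "ATGAAATTT", "ATGAAATTT"), "ATGAAGTTT")
  m <- build_site_masks(a)
  expect_equal(segregating_sites(a, m), 0L)       # outgroup-only variation
  expect_equal(pairwise_pi(a, m, "all"), 0)
  b <- toy_aln(c("ATGAAATTT", "ATGAAATTT", "ATGAAATTT", "ATGAAATTA"),
               "ATGAAATTT")
  mb <- build_site_masks(b)
  expect_equal(segregating_sites(b, mb), 1L)
  # n = 2: 3 differences over 100 usable sites -> 0.03
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  d <- coding_alignment("p", c(h1 = s1, h2 = s2), s1, cbind(0, 99))
  expect_equal(pairwise_pi(d, build_site_masks(d), "all"), 0.03)
})

test_that("the unfolded SFS polarizes by the outgroup and excludes third states", {
  a <- toy_aln(c("ATGAAATTT", "ATGAAATTT", "ATGAAATTT", "TTGAAATTT"),
               "ATGAAATTT")
  sfs <- unfolded_sfs(a, build_site_masks(a))
  expect_equal(sfs$xi[1], 1L)           # A/A/A/T with outgroup A
  expect_equal(sum(sfs$xi), 1L)
  # outgroup carries a third state: excluded
  b <- toy_aln(c("ATGAAATTT", "ATGAAATTT", "TTGAAATTT", "TTGAAATTT"),
               "GTGAAATTT")
  sfsb <- unfolded_sfs(b, build_site_masks(b))
  expect_equal(sum(sfsb$xi), 0L)
  expect_equal(sfsb$excluded, 1L)
})

test_that("Tajima's D reproduces sign and identity cases", {
  expect_error(tajimas_D(0, 0, 10), "undefined")
  # all singletons: excess rare variation, D < 0
  n <- 10; S <- 20
  pi_singletons <- S * 2 * (n - 1) / (n * (n - 1))
  D <- tajimas_D(S, pi_singletons, n)
  expect_lt(D, 0)
  expect_equal(D, oracle_tajD(S, pi_singletons, n), tolerance = 1e-12)
  # pi at exactly Watterson's expectation: D = 0 identically
  k <- neutrality_constants(54)
  expect_equal(tajimas_D(77, 77 / k$a_n, 54), 0, tolerance = 1e-12)
})

test_that("normalized Fay & Wu's H flags high-frequency derived excess", {
  n <- 10; S <- 5
  near_fix <- list(n = n, xi = c(rep(0L, n - 2L), S))  # all at freq n-1
  H_fix <- fay_wu_H_normalized(near_fix)
  expect_lt(H_fix, -2)
  expect_equal(H_fix, oracle_faywuH(near_fix$xi, n), tolerance = 1e-12)
  singles <- list(n = n, xi = c(S, rep(0L, n - 2L)))
  H_single <- fay_wu_H_normalized(singles)
  expect_gt(H_single, 0)
  expect_equal(H_single, oracle_faywuH(singles$xi, n), tolerance = 1e-12)
  expect_error(fay_wu_H_normalized(list(n = 10, xi = rep(0L, 9))),
               "undefined")
})

test_that("Jukes-Cantor correction and divergence edge cases", {
  expect_equal(jukes_cantor(0.05), 0.05174465, tolerance = 1e-6)
  expect_error(jukes_cantor(0.75), "undefined")
  expect_error(jukes_cantor(0.9), "undefined")
  a <- toy_aln(c("ATGAAATTT", "ATGAAATTT"), "ATGAAATTT")
  m <- build_site_masks(a)
  expect_equal(divergence_by_class(a, m, "syn"), 0)
  expect_equal(divergence_by_class(a, m, "rep"), 0)
})

test_that("pi, S, D and H match brute-force oracles on random alignments", {
  set.seed(1234)
  for (i in 1:50) {
    aln <- random_alignment(n = sample(4:8, 1), L = sample(c(60, 90, 120), 1))
    mask <- build_site_masks(aln)
    S <- segregating_sites(aln, mask)
    expect_equal(S, oracle_S(aln))
    expect_equal(pairwise_pi(aln, mask, "all"), oracle_pi_per_site(aln),
                 tolerance = 1e-9)
    pc <- mean_pairwise_differences(aln, mask)
    expect_equal(pc, oracle_pi_count(aln), tolerance = 1e-9)
    if (S >= 1) {
      expect_equal(tajimas_D(S, pc, aln$n), oracle_tajD(S, pc, aln$n),
                   tolerance = 1e-9)
    }
    xi <- oracle_sfs(aln)
    sfs <- unfolded_sfs(aln, mask)
    expect_equal(sfs$xi, xi)
    if (sum(xi) >= 1) {
      expect_equal(fay_wu_H_normalized(sfs), oracle_faywuH(xi, aln$n),
                   tolerance = 1e-9)
    }
  }
})

test_that("haplotypes with rogue internal stops are screened with a warning", {
  # h3 carries TAA where the consensus is sense
  a <- toy_aln(c("ATGAAATTT", "ATGAAATTT", "ATGTAATTT", "ATGAAATTC"),
               "ATGAAGTTT")
  expect_warning(scr <- screen_stop_haplotypes(a), "h3")
  expect_equal(scr$n, 3L)
  clean <- toy_aln(c("ATGAAATTT", "ATGAAATTC"), "ATGAAGTTT")
  expect_identical(screen_stop_haplotypes(clean), clean)
})

test_that("gene_summary assembles a coherent row", {
  g <- generate_gene(synthetic_gene_config(gene_id = "gs", n = 12, L = 600,
                                           seed = 5))
  row <- gene_summary(g$aln)
  expect_equal(row$n, 12L)
  expect_true(all(c(row$pi_tot, row$pi_syn, row$pi_rep,
                    row$K_syn, row$K_rep) >= 0))
  expect_equal(row$S, segregating_sites(g$aln, build_site_masks(g$aln)))
})
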