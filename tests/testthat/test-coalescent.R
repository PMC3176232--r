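test_that("analytic coalescent expectations hold within Monte-Carlo error", {
  set.seed(101)
  R <- 20000L
  tm <- replicate(R, simulate_genealogy(2L)$tmrca)
  # E[T_MRCA] for a pair: 1 in native 2N0 units, i.e. 0.5 in 4N0 units
  expect_lt(abs(mean(tm) / 2 - 0.5), 3 * sd(tm / 2) / sqrt(R))
  tt <- replicate(5000L, simulate_genealogy(10L)$total_length)
  expect_lt(abs(mean(tt) - 2 * sum(1 / (1:9))), 3 * sd(tt) / sqrt(5000))
})

test_that("theta-mode mutation counts follow Watterson's expectation", {
  set.seed(55)
  n <- 12L; theta <- 8; R <- 5000L
  S <- replicate(R, sum(drop_mutations(simulate_genealogy(n), "theta",
                                       theta = theta)$xi))
  a_n <- sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(S) - theta * a_n), 3 * sd(S) / sqrt(R))
})

test_that("fixed-S mode conditions exactly and maps branches to frequencies", {
  set.seed(66)
  for (i in 1:50) {
    sfs <- drop_mutations(simulate_genealogy(8L), "fixed_S", S = 7L)
    expect_equal(sum(sfs$xi), 7L)
  }
  # a mutation on a branch subtending i leaves contributes to xi_i
  tree <- simulate_genealogy(6L)
  sfs <- drop_mutations(tree, "fixed_S", S = 40L)
  br <- attr(sfs, "branch")
  expect_equal(tabulate(tree$nleaves[br], 5L), sfs$xi)
})

test_that("a severe bottleneck shortens genealogies at matched N0", {
  set.seed(77)
  dem <- demography_model(c(0, 0.2, 0.4), c(1, 0.02, 1))
  tb <- replicate(3000L, simulate_genealogy(10L, dem)$tmrca)
  tc <- replicate(3000L, simulate_genealogy(10L)$tmrca)
  expect_lt(mean(tb), mean(tc) - 3 * sqrt(var(tb) / 3000 + var(tc) / 3000))
})

test_that("replicates are reproducible under a fixed seed", {
  v1 <- simulate_null_statistics(10L, 200L, "D", "fixed_S", S = 9L,
                                 seed = 1234L)
  v2 <- simulate_null_statistics(10L, 200L, "D", "fixed_S", S = 9L,
                                 seed = 1234L)
  expect_identical(v1, v2)
})

test_that("empirical p-values follow the add-one rank formula", {
  vals <- seq(-2, 2, length.out = 9999)
  p <- empirical_p(vals, observed = -5)
  expect_equal(p$p_low, 1 / 10000)
  expect_equal(p$p_one_tailed, 1 / 10000)
  pm <- empirical_p(vals, observed = 0)
  expect_gt(pm$p_two_tailed, 0.95)
  expect_equal(empirical_p(c(vals, rep(NA, 10)), -5)$n_excluded, 10L)
  expect_error(empirical_p(rep(NA_real_, 5), 0), "undefined")
})

test_that("posterior-draw rows convert to demography models", {
  draws <- data.frame(start_1 = c(0, 0), size_1 = c(1, 1),
                      start_2 = c(0.3, 0.5), size_2 = c(0.1, 0.2),
                      start_3 = c(0.6, NA), size_3 = c(1, NA))
  d1 <- demography_from_row(draws[1, ])
  expect_equal(nrow(d1), 3L)
  d2 <- demography_from_row(draws[2, ])
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$relative_size, c(1, 0.2))
  f <- tempfile(fileext = ".tsv")
  write.table(draws, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_demography_draws(f), draws)
  v <- simulate_null_statistics(8L, 50L, "D", "fixed_S", S = 5L,
                                posterior_draws = draws, seed = 3L)
  expect_equal(sum(is.na(v)), 0L)
})

test_that("window bands share values at equal S and widen as S drops", {
  tr <- data.frame(gene_id = "g", stat = "D",
                   start = c(1, 26, 51), end = c(250, 275, 300),
                   mid = c(125.5, 150.5, 175.5), value = c(0.1, 0.2, 0.3),
                   ci_low = NA_real_, ci_high = NA_real_,
                   S_window = c(8L, 8L, 0L))
  out <- window_confidence_bands(tr, n = 12L, R = 500L, seed = 9L)
  expect_equal(out$ci_low[1], out$ci_low[2])
  expect_true(is.na(out$ci_low[3]))
  # with S = 2 the conditional null is supported on far fewer points than
  # with S = 20 (band width itself is not monotone in S: the studentized
  # statistics are variance-normalized, so low-S windows mainly lose
  # resolution, not spread)
  v2 <- simulate_null_statistics(12L, 2000L, "D", "fixed_S", S = 2L,
                                 seed = 21L)
  v20 <- simulate_null_statistics(12L, 2000L, "D", "fixed_S", S = 20L,
                                  seed = 22L)
  expect_lt(length(unique(round(v2, 10))),
            length(unique(round(v20, 10))) / 5)
  expect_true(all(is.finite(c(v2, v20))))
})

test_that("D and H distributions match an independent reference coalescent", {
  oracle_py <- c(
    "import msprime, numpy as np, sys",
    "mode, n, arg, R, seed, out = sys.argv[1], int(sys.argv[2]), float(sys.argv[3]), int(sys.argv[4]), int(sys.argv[5]), sys.argv[6]",
    "rng = np.random.default_rng(seed)",
    "res = []",
    "for ts in msprime.sim_ancestry(samples=n, ploidy=1, sequence_length=1, num_replicates=R, random_seed=seed):",
    "    tr = ts.first()",
    "    if mode == 'fixed':",
    "        nodes = [u for u in tr.nodes() if tr.parent(u) != -1]",
    "        bl = np.array([tr.branch_length(u) for u in nodes])",
    "        nl = np.array([tr.num_samples(u) for u in nodes])",
    "        picks = rng.choice(len(nodes), int(arg), p=bl/bl.sum())",
    "        counts = nl[picks]",
    "    else:",
    "        mts = msprime.sim_mutations(ts, rate=arg/2, discrete_genome=False, random_seed=int(rng.integers(1, 2**31)), model=msprime.BinaryMutationModel())",
    "        counts = np.array([int((v.genotypes != 0).sum()) for v in mts.variants()])",
    "        counts = counts[(counts > 0) & (counts < n)]",
    "    S = len(counts)",
    "    if S < 1:",
    "        res.append((np.nan, np.nan)); continue",
    "    i = np.arange(1, n)",
    "    a1 = (1/i).sum(); a2 = (1/i**2).sum()",
    "    b1 = (n+1)/(3*(n-1)); b2 = 2*(n*n+n+3)/(9*n*(n-1))",
    "    c1 = b1 - 1/a1; c2 = b2 - (n+2)/(a1*n) + a2/a1**2",
    "    pi = (2*counts*(n-counts)).sum()/(n*(n-1))",
    "    D = (pi - S/a1)/np.sqrt(c1/a1*S + c2/(a1**2+a2)*S*(S-1))",
    "    tL = counts.sum()/(n-1)",
    "    tw = S/a1; tsq = S*(S-1)/(a1**2+a2); bn1 = a2 + 1/n**2",
    "    v = tw*(n-2)/(6*(n-1)) + tsq*(18*n*n*(3*n+2)*bn1 - (88*n**3+9*n*n-13*n+6))/(9*n*(n-1)**2)",
    "    res.append((D, (pi - tL)/np.sqrt(v)))",
    "np.savetxt(out, np.array(res))")
  py <- tempfile(fileext = ".py")
  writeLines(oracle_py, py)
  run_oracle <- function(mode, n, arg, R, seed) {
    out <- tempfile(fileext = ".txt")
    status <- system2("python", c(py, mode, n, arg, R, seed, out))
    expect_equal(status, 0L)
    as.matrix(read.table(out))
  }
  # theta mode, n = 24
  ms <- run_oracle("theta", 24, 15, 2000, 424242)
  myD <- simulate_null_statistics(24L, 2000L, "D", "theta", theta = 15,
                                  seed = 11L)
  myH <- simulate_null_statistics(24L, 2000L, "H_norm", "theta", theta = 15,
                                  seed = 12L)
  ksD <- suppressWarnings(ks.test(myD[!is.na(myD)], ms[!is.na(ms[, 1]), 1]))
  ksH <- suppressWarnings(ks.test(myH[!is.na(myH)], ms[!is.na(ms[, 2]), 2]))
  expect_gt(ksD$p.value, 0.01)
  expect_gt(ksH$p.value, 0.01)
  # the means of the normalized statistics (which are slightly non-zero
  # under neutrality) must agree with the reference within combined SE
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  expect_lt(abs(mean(myD, na.rm = TRUE) - mean(ms[, 1], na.rm = TRUE)),
            3 * sqrt(se(myD)^2 + se(ms[, 1])^2))
  # fixed-S mode at two study-shaped configurations
  for (cfg in list(c(n = 10, S = 12), c(n = 54, S = 87))) {
    ms_f <- run_oracle("fixed", cfg[["n"]], cfg[["S"]], 1500, cfg[["n"]] * 7L)
    my_f <- simulate_null_statistics(cfg[["n"]], 1500L, "D", "fixed_S",
                                     S = cfg[["S"]], seed = cfg[["n"]])
    ks_f <- suppressWarnings(ks.test(my_f, ms_f[, 1]))
    expect_gt(ks_f$p.value, 0.01)
  }
})
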