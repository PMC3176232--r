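# Hudson-style coalescent without recombination, with piecewise-constant
# demography (bottlenecks) and two mutation modes: fixed-S (exactly S
# mutations placed on the realized genealogy in proportion to branch
# length, Hudson's "-s" semantics) and theta (Poisson(theta * T_total / 2)
# mutations). Time is measured in coalescent units of 2N0 generations
# throughout (so E[T_MRCA] = 1 for a pair, E[T_total] = 2*a_n, and with
# theta = 4*N0*mu the Watterson expectation E[S] = theta*a_n holds); in
# units of 4N0 generations, halve the times.
#
# The simulator feeds three consumers: gene-level null distributions and
# empirical p-values for D and H, per-window 95% confidence bands
# conditioned on the window's segregating sites, and the synthetic-data
# generator (which needs the full labeled genealogy).

#' Piecewise-constant demographic model
#'
#' Epochs of relative population size N/N0, switching at fixed times in
#' the past (coalescent units of 2N0 generations). The first epoch must
#' start at 0.
#'
#' @param start_time Numeric vector of epoch start times, strictly
#'   increasing from 0.
#' @param relative_size Positive relative sizes, one per epoch.
#' @return \code{data.frame} of class \code{demography_model}.
#' @export
demography_model <- function(start_time = 0, relative_size = 1) {
  if (length(start_time) != length(relative_size))
    stop("start_time and relative_size must have equal length")
  if (start_time[1L] != 0) stop("first epoch must start at time 0")
  if (any(diff(start_time) <= 0)) stop("epoch start times must increase")
  if (any(relative_size <= 0)) stop("relative sizes must be positive")
  structure(data.frame(start_time = start_time,
                       relative_size = relative_size),
            class = c("demography_model", "data.frame"))
}

# Waiting time to the next coalescence among k lineages starting at time t:
# exponential with rate k(k-1)/(2*lambda) within an epoch of relative size
# lambda, integrated piecewise across epoch boundaries.
coal_waiting_time <- function(t, k, demography = NULL) {
  pair_rate <- k * (k - 1) / 2
  if (is.null(demography)) return(stats::rexp(1L) / pair_rate)
  e_units <- stats::rexp(1L)   # exponential "hazard units" to consume
  starts <- demography$start_time
  sizes <- demography$relative_size
  i <- findInterval(t, starts)
  t0 <- t
  repeat {
    rate <- pair_rate / sizes[i]
    epoch_end <- if (i < length(starts)) starts[i + 1L] else Inf
    dt_needed <- e_units / rate
    if (t0 + dt_needed <= epoch_end) return(t0 + dt_needed - t)
    e_units <- e_units - (epoch_end - t0) * rate
    t0 <- epoch_end
    i <- i + 1L
  }
}

#' Simulate a coalescent genealogy
#'
#' Standard n-coalescent: with k lineages extant, the waiting time to the
#' next (random pair) coalescence is exponential with rate
#' \code{k(k-1)/(2 lambda)} in an epoch of relative size lambda.
#'
#' @param n Sample size (>= 2).
#' @param demography A [demography_model()] or NULL for constant size.
#' @return List describing the labeled history: \code{n}; \code{parent},
#'   \code{time}, \code{nleaves}, \code{blen} over nodes 1..2n-1 (leaves
#'   1..n at time 0, root \code{2n-1} with \code{parent = 0} and
#'   \code{blen = 0}); and \code{tmrca}, \code{total_length}.
#' @export
simulate_genealogy <- function(n, demography = NULL) {
  if (n < 2L) stop("n must be >= 2")
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  nleaves <- c(rep(1L, n), integer(n - 1L))
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in seq.int(n, 2L)) {
    t <- t + coal_waiting_time(t, k, demography)
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[a] <- nxt; parent[b] <- nxt
    time[nxt] <- t
    nleaves[nxt] <- nleaves[a] + nleaves[b]
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  blen <- numeric(n_nodes)
  nonroot <- seq_len(n_nodes - 1L)
  blen[nonroot] <- time[parent[nonroot]] - time[nonroot]
  list(n = n, parent = parent, time = time, nleaves = nleaves,
       blen = blen, tmrca = t, total_length = sum(blen))
}

#' Drop mutations on a genealogy (infinite sites)
#'
#' Fixed-S mode places exactly S mutations, each on a branch chosen with
#' probability proportional to branch length; theta mode draws
#' \code{Poisson(theta * T_total / 2)} mutations first. Each mutation is a
#' new column whose derived-allele count is the number of leaves under the
#' mutated branch, yielding the unfolded SFS directly.
#'
#' @param tree From [simulate_genealogy()].
#' @param mode \code{"fixed_S"} or \code{"theta"}.
#' @param S Number of mutations (fixed-S mode).
#' @param theta Per-locus population mutation rate 4N0*mu (theta mode).
#' @return An \code{unfolded_sfs}; attribute \code{branch} holds the node
#'   index carrying each mutation (in placement order) for consumers that
#'   need the lineage subsets.
#' @export
drop_mutations <- function(tree, mode = c("fixed_S", "theta"),
                           S = NULL, theta = NULL) {
  mode <- match.arg(mode)
  m <- switch(mode,
    fixed_S = {
      if (is.null(S) || S < 0) stop("fixed_S mode needs S >= 0")
      as.integer(S)
    },
    theta = {
      if (is.null(theta) || theta < 0) stop("theta mode needs theta >= 0")
      stats::rpois(1L, theta * tree$total_length / 2)
    })
  n <- tree$n
  xi <- integer(n - 1L)
  branch <- integer(0)
  if (m > 0L) {
    nonroot <- seq_len(2L * n - 2L)
    branch <- nonroot[sample.int(length(nonroot), m, replace = TRUE,
                                 prob = tree$blen[nonroot])]
    xi <- tabulate(tree$nleaves[branch], nbins = n - 1L)
  }
  res <- structure(list(n = n, xi = xi, sites_polarized = sum(xi),
                        excluded = 0L),
                   class = "unfolded_sfs")
  attr(res, "branch") <- branch
  res
}

# Statistic from an SFS given precomputed constants; NA when undefined.
sfs_statistic <- function(xi, n, statistic, k = neutrality_constants(n)) {
  S <- sum(xi)
  if (S < 1L) return(NA_real_)
  if (statistic == "D") {
    i <- seq_along(xi)
    pi_count <- sum(xi * i * (n - i)) / choose(n, 2L)
    return((pi_count - S / k$a_n) / sqrt(k$e1 * S + k$e2 * S * (S - 1)))
  }
  if (statistic == "H_norm") {
    theta_w <- S / k$a_n
    theta_sq <- S * (S - 1) / (k$a_n^2 + k$b_n)
    b_n1 <- k$b_n + 1 / n^2
    v <- theta_w * (n - 2) / (6 * (n - 1)) +
      theta_sq * (18 * n^2 * (3 * n + 2) * b_n1 -
                    (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
    return((sfs_theta_pi(xi, n) - sfs_theta_L(xi, n)) / sqrt(v))
  }
  stop("unknown statistic '", statistic, "'")
}

#' Simulate null replicates of an SFS statistic
#'
#' Runs R independent genealogy + mutation replicates and evaluates
#' Tajima's D or normalized Fay & Wu's H on each simulated unfolded SFS.
#' With a table of posterior demography draws, one row is sampled with
#' replacement per replicate.
#'
#' @param n Sample size.
#' @param R Number of replicates.
#' @param statistic \code{"D"} or \code{"H_norm"}.
#' @param mode,S,theta Mutation model, as in [drop_mutations()].
#' @param demography A [demography_model()], or NULL for constant size.
#' @param posterior_draws Optional \code{data.frame} of epoch parameters
#'   (columns \code{start_1, size_1, start_2, size_2, ...}); overrides
#'   \code{demography}.
#' @param seed Optional integer seed.
#' @return Numeric vector of length R (NA where the statistic is
#'   undefined, e.g. S = 0 in theta mode).
#' @export
simulate_null_statistics <- function(n, R, statistic = c("D", "H_norm"),
                                     mode = c("fixed_S", "theta"),
                                     S = NULL, theta = NULL,
                                     demography = NULL,
                                     posterior_draws = NULL,
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k <- neutrality_constants(n)
  draw_idx <- if (!is.null(posterior_draws))
    sample.int(nrow(posterior_draws), R, replace = TRUE)
  vapply(seq_len(R), function(r) {
    dem <- if (!is.null(posterior_draws))
      demography_from_row(posterior_draws[draw_idx[r], ]) else demography
    tree <- simulate_genealogy(n, dem)
    sfs <- drop_mutations(tree, mode, S = S, theta = theta)
    sfs_statistic(sfs$xi, n, statistic, k)
  }, numeric(1))
}

#' Convert one posterior-draw row to a demography model
#'
#' Rows pair columns \code{start_i}/\code{size_i} for epoch i; NA pairs are
#' dropped, so draws may differ in epoch count.
#'
#' @param row One-row \code{data.frame} or named vector/list.
#' @return A [demography_model()].
#' @export
demography_from_row <- function(row) {
  row <- as.list(row)
  ks <- sort(as.integer(sub("^start_", "", grep("^start_", names(row),
                                                value = TRUE))))
  st <- unlist(row[paste0("start_", ks)], use.names = FALSE)
  sz <- unlist(row[paste0("size_", ks)], use.names = FALSE)
  keep <- !is.na(st) & !is.na(sz)
  demography_model(st[keep], sz[keep])
}

#' Read a table of demography posterior draws
#'
#' @param path TSV with header columns \code{start_1, size_1, ...}.
#' @return \code{data.frame} of draws.
#' @export
read_demography_draws <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Empirical p-values against a simulated null
#'
#' Rank-based tail probabilities \code{p = (1 + #{at least as extreme}) /
#' (R_valid + 1)}; undefined replicates are excluded from ranking and
#' counted.
#'
#' @param values Simulated statistic values (NA allowed).
#' @param observed Observed value.
#' @return List with \code{p_low}, \code{p_high}, \code{p_one_tailed}
#'   (smaller tail, i.e. in the direction of the observed deviation),
#'   \code{p_two_tailed} (twice the smaller tail, capped at 1),
#'   \code{R_valid} and \code{n_excluded}.
#' @export
empirical_p <- function(values, observed) {
  valid <- values[!is.na(values)]
  R <- length(valid)
  if (R == 0L) stop("all null replicates undefined")
  p_low <- (1 + sum(valid <= observed)) / (R + 1)
  p_high <- (1 + sum(valid >= observed)) / (R + 1)
  p_one <- min(p_low, p_high)
  list(p_low = p_low, p_high = p_high, p_one_tailed = p_one,
       p_two_tailed = min(1, 2 * p_one),
       R_valid = R, n_excluded = length(values) - R)
}

#' Null distribution of a statistic with empirical p-values
#'
#' @inheritParams simulate_null_statistics
#' @param observed Observed statistic value.
#' @return List of class \code{null_distribution}: replicate
#'   \code{values}, the \code{observed} value, the elements of
#'   [empirical_p()], and a \code{quantile} function over valid values.
#' @export
null_distribution <- function(observed, n, R = 10000L,
                              statistic = c("D", "H_norm"),
                              mode = c("fixed_S", "theta"),
                              S = NULL, theta = NULL, demography = NULL,
                              posterior_draws = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  vals <- simulate_null_statistics(n, R, statistic, mode, S = S,
                                   theta = theta, demography = demography,
                                   posterior_draws = posterior_draws,
                                   seed = seed)
  p <- empirical_p(vals, observed)
  valid <- vals[!is.na(vals)]
  structure(c(list(statistic = statistic, values = vals,
                   observed = observed,
                   quantile = function(q) stats::quantile(valid, q,
                                                          names = FALSE)),
              p),
            class = "null_distribution")
}

#' Simulated per-window confidence bands
#'
#' For each window, runs fixed-S coalescent replicates at the window's
#' observed segregating-site count and the gene's sample size, and fills
#' the track's \code{ci_low}/\code{ci_high} with the 2.5% and 97.5%
#' empirical quantiles of the statistic. Windows with S = 0 keep NA bands.
#' Simulations are cached per distinct S, so windows sharing S share
#' bands.
#'
#' @param track A track from [window_statistic_track()] with statistic
#'   \code{"D"} or \code{"H_norm"}.
#' @param n Sample size of the gene.
#' @param R Replicates per distinct S.
#' @param demography,posterior_draws As in [simulate_null_statistics()].
#' @param seed Optional integer seed (re-seeded per distinct S so bands
#'   for equal S are identical).
#' @return The track with bands filled.
#' @export
window_confidence_bands <- function(track, n, R = 10000L,
                                    demography = NULL,
                                    posterior_draws = NULL, seed = NULL) {
  statistic <- unique(track$stat)
  if (length(statistic) != 1L || !statistic %in% c("D", "H_norm"))
    stop("confidence bands are defined for single-statistic D/H tracks")
  svals <- sort(unique(track$S_window[track$S_window > 0L]))
  for (S in svals) {
    vals <- simulate_null_statistics(n, R, statistic, "fixed_S", S = S,
                                     demography = demography,
                                     posterior_draws = posterior_draws,
                                     seed = if (is.null(seed)) NULL
                                            else seed + S)
    q <- stats::quantile(vals[!is.na(vals)], c(0.025, 0.975), names = FALSE)
    sel <- track$S_window == S
    track$ci_low[sel] <- q[1L]
    track$ci_high[sel] <- q[2L]
  }
  track
}
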