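# Independent brute-force oracles, coded directly from first principles so
# they share no internals with the package: plain double loops over pairs
# and columns, permutation enumeration for codon pathways, hypergeometric
# enumeration for Fisher's exact test. Deliberately slow and literal.

GC_TABLE <- Biostrings::GENETIC_CODE

# random small alignment with optional gaps/Ns, coding region a centered
# multiple of 3
random_alignment <- function(n = 6L, L = 90L, gap_rate = 0.02,
                             div = 0.08, poly = 0.05) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  for (j in seq_len(L)) {
    if (runif(1) < poly) {
      who <- sample(n, sample(n - 1L, 1L))
      mat[who, j] <- sample(setdiff(bases, anc[j]), 1L)
    }
    if (runif(1) < gap_rate) mat[sample(n, 1L), j] <- sample(c("-", "N"), 1L)
  }
  outg <- anc
  flip <- runif(L) < div
  outg[flip] <- vapply(which(flip), function(j)
    sample(setdiff(bases, anc[j]), 1L), character(1))
  outg[runif(L) < gap_rate] <- "N"
  cod_len <- (L %/% 2) %/% 3 * 3
  start <- (L - cod_len) %/% 2
  coding_alignment("rnd",
                   setNames(apply(mat, 1L, paste, collapse = ""),
                            sprintf("h%02d", seq_len(n))),
                   paste(outg, collapse = ""),
                   cbind(start, start + cod_len))
}

oracle_usable <- function(aln) {
  vapply(seq_len(aln$L), function(j)
    all(!aln$mat[, j] %in% c("-", "N")), logical(1))
}

oracle_S <- function(aln) {
  us <- oracle_usable(aln)
  s <- 0L
  for (j in which(us)) if (length(unique(aln$mat[, j])) > 1L) s <- s + 1L
  s
}

oracle_pi_count <- function(aln) {
  us <- which(oracle_usable(aln))
  n <- nrow(aln$mat)
  tot <- 0
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    tot <- tot + sum(aln$mat[a, us] != aln$mat[b, us])
  tot / (n * (n - 1L) / 2)
}

oracle_pi_per_site <- function(aln) {
  oracle_pi_count(aln) / sum(oracle_usable(aln))
}

oracle_sfs <- function(aln) {
  us <- oracle_usable(aln) & !(aln$outgroup %in% c("-", "N"))
  n <- nrow(aln$mat)
  xi <- integer(n - 1L)
  for (j in which(us)) {
    st <- unique(aln$mat[, j])
    if (length(st) != 2L) next
    if (!aln$outgroup[j] %in% st) next
    der <- setdiff(st, aln$outgroup[j])
    xi[sum(aln$mat[, j] == der)] <- xi[sum(aln$mat[, j] == der)] + 1L
  }
  xi
}

oracle_tajD <- function(S, pi_count, n) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_count - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

oracle_faywuH <- function(xi, n) {
  S <- sum(xi)
  i <- seq_along(xi)
  tpi <- sum(xi * 2 * i * (n - i)) / (n * (n - 1))
  tL <- sum(i * xi) / (n - 1)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  bn1 <- sum(1 / (1:n)^2)
  tw <- S / a1
  tsq <- S * (S - 1) / (a1^2 + a2)
  v <- tw * (n - 2) / (6 * (n - 1)) +
    tsq * (18 * n^2 * (3 * n + 2) * bn1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (tpi - tL) / sqrt(v)
}

oracle_ng_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    x <- ch; x[p] <- b
    if (GC_TABLE[paste(x, collapse = "")] == GC_TABLE[codon]) syn <- syn + 1
  }
  syn / 3
}

oracle_pathway <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dp <- which(ca != cb)
  k <- length(dp)
  if (k == 0L) return(c(0, 0))
  perms <- if (k == 1L) list(dp) else if (k == 2L)
    list(dp, rev(dp)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) dp[o])
  res <- list()
  for (ord in perms) {
    cur <- ca; syn <- 0; repl <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      if (GC_TABLE[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      if (GC_TABLE[paste(cur, collapse = "")] ==
            GC_TABLE[paste(nxt, collapse = "")]) syn <- syn + 1
      else repl <- repl + 1
      cur <- nxt
    }
    if (ok) res[[length(res) + 1]] <- c(syn, repl)
  }
  if (length(res) == 0L) return(NULL)   # all pathways hit stops
  colMeans(do.call(rbind, res))
}

oracle_fisher2x2 <- function(Ds, Ps, Dn, Pn) {
  # fixed marginals; enumerate the hypergeometric support of cell (1,1)
  r1 <- Ds + Ps; r2 <- Dn + Pn; c1 <- Ds + Dn
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(supp, r1, r2, c1)
  p_obs <- dhyper(Ds, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
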