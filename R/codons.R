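# Nei-Gojobori site counting and pathway classification of codon
# differences, on the standard genetic code. Fractional synonymous site
# counts and pathway-averaged difference counts are cached per codon (pair)
# in a package-local environment; the full pair table is only 61 x 61.

.codon_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  # cached: GENETIC_CODE is a lazy-load object, repeated fetches add up
  gc <- .codon_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE   # codons -> amino acids, "*" for stops
    .codon_cache$genetic_code <- gc
  }
  gc
}

is_stop <- function(codon) {
  aa <- genetic_code()[codon]
  !is.na(aa) && aa == "*"
}

codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (p in 1:3) for (b in setdiff(bases, ch[p])) {
    x <- ch; x[p] <- b
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

#' Fractional synonymous site count of a codon (Nei-Gojobori)
#'
#' For each codon position, the fraction of the three possible single-base
#' changes that leave the amino acid unchanged contributes to the
#' synonymous site count; changes creating a stop codon count as
#' replacement. Every codon contributes 3 sites in total, so the
#' replacement site count is \code{3 - nei_gojobori_sites(codon)}.
#'
#' @param codon A 3-character string over A/C/G/T, not a stop codon.
#' @return Fractional synonymous site count in \code{[0, 3]}.
#' @export
#' @examples
#' nei_gojobori_sites("TTT") # 1/3: only TTT->TTC is synonymous
#' nei_gojobori_sites("GGG") # 1: fourfold-degenerate third position
#' nei_gojobori_sites("ATG") # 0: every neighbor changes Met
nei_gojobori_sites <- function(codon) {
  gc <- genetic_code()
  if (is.na(gc[codon])) stop("invalid codon '", codon, "'")
  if (gc[codon] == "*") stop("stop codon '", codon, "' has no site count")
  key <- paste0("s_", codon)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  aa <- gc[[codon]]
  nb <- codon_neighbors(codon)
  syn <- sum(gc[nb] == aa) / 3  # stop neighbors ("*") are replacement
  .codon_cache[[key]] <- syn
  syn
}

all_orderings <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
}

#' Classify the differences between two codons (pathway method)
#'
#' Enumerates every ordering of the differing positions as a stepwise
#' mutational pathway, drops pathways that pass through a stop codon, and
#' averages the synonymous and replacement step counts over the remaining
#' pathways. When every pathway passes through a stop, the average is taken
#' over all pathways with stop-creating steps counted as replacement, and
#' the result is flagged.
#'
#' @param codon_a,codon_b Sense codons over A/C/G/T.
#' @return Named numeric vector \code{c(syn, rep)}; attribute
#'   \code{all_stop} is TRUE when the stop-pathway fallback was used. The
#'   two components always sum to the Hamming distance of the codons.
#' @export
#' @examples
#' classify_codon_differences("TTT", "TTC") # 1 synonymous
#' classify_codon_differences("TTT", "TTA") # 1 replacement (Phe -> Leu)
classify_codon_differences <- function(codon_a, codon_b) {
  gc <- genetic_code()
  for (cd in c(codon_a, codon_b)) {
    if (is.na(gc[cd])) stop("invalid codon '", cd, "'")
    if (gc[cd] == "*") stop("stop codon '", cd, "' not classifiable")
  }
  key <- paste0("d_", codon_a, codon_b)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  a <- strsplit(codon_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(codon_b, "", fixed = TRUE)[[1L]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) {
    res <- c(syn = 0, rep = 0)
    attr(res, "all_stop") <- FALSE
    .codon_cache[[key]] <- res
    return(res)
  }
  paths <- all_orderings(k)
  tally <- function(ord, count_stop_steps) {
    cur <- a; syn <- 0; repl <- 0
    for (p in diff_pos[ord]) {
      nxt <- cur; nxt[p] <- b[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (gc[to] == "*") {
        if (!count_stop_steps) return(NULL)
        repl <- repl + 1           # stop-creating step counted replacement
      } else if (gc[from] == gc[to]) syn <- syn + 1
      else repl <- repl + 1
      cur <- nxt
    }
    c(syn, repl)
  }
  res_list <- lapply(paths, tally, count_stop_steps = FALSE)
  res_list <- res_list[!vapply(res_list, is.null, logical(1))]
  all_stop <- length(res_list) == 0L
  if (all_stop)
    res_list <- lapply(paths, tally, count_stop_steps = TRUE)
  m <- do.call(rbind, res_list)
  res <- c(syn = mean(m[, 1L]), rep = mean(m[, 2L]))
  attr(res, "all_stop") <- all_stop
  .codon_cache[[key]] <- res
  res
}
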