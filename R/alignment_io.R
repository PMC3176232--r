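#' Construct a coding alignment object
#'
#' A \code{coding_alignment} bundles an aligned set of ingroup haplotypes,
#' a single outgroup sequence on the same coordinates, and an exon map whose
#' concatenation defines the reading frame. It is the unit every statistic
#' in the package consumes.
#'
#' @param gene_id Character scalar naming the locus.
#' @param ingroup Character vector of aligned haplotype sequences
#'   (characters A/C/G/T/N/-, all the same length). Needs at least two.
#' @param outgroup Single aligned sequence of the same length, used for
#'   polarization and divergence.
#' @param exons Two-column integer matrix of exon intervals in 0-based
#'   half-open alignment coordinates \code{[start, end)}, sorted and
#'   non-overlapping; the summed exon length must be divisible by 3.
#'
#' @return An object of class \code{coding_alignment}: a list with elements
#'   \code{gene_id}, \code{mat} (ingroup character matrix, one row per
#'   haplotype), \code{outgroup} (character vector of length L),
#'   \code{exons}, \code{L} and \code{n}.
#' @export
coding_alignment <- function(gene_id, ingroup, outgroup, exons) {
  if (length(ingroup) < 2L)
    stop("need at least 2 ingroup haplotypes, got ", length(ingroup))
  seqs <- toupper(c(ingroup, outgroup))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  L <- lens[[1L]]
  chars <- strsplit(seqs, "", fixed = TRUE)
  bad <- !vapply(chars, function(x) all(x %in% c("A", "C", "G", "T", "N", "-")), logical(1))
  if (any(bad))
    stop("sequences contain characters outside A/C/G/T/N/-; ",
         "IUPAC ambiguity codes other than N are not accepted")
  exons <- validate_exons(exons, L)
  mat <- do.call(rbind, chars[seq_along(ingroup)])
  rownames(mat) <- names(ingroup)
  out <- chars[[length(chars)]]
  structure(
    list(gene_id = gene_id, mat = mat, outgroup = out,
         exons = exons, L = L, n = nrow(mat)),
    class = "coding_alignment"
  )
}

validate_exons <- function(exons, L) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(is.na(exons))) stop("exon intervals contain NA")
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] > L))
    stop("exon intervals fall outside the alignment [0, ", L, ")")
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty or reversed exon interval")
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exon intervals overlap")
  cds_len <- sum(exons[, 2L] - exons[, 1L])
  if (cds_len %% 3L != 0L)
    stop("frame error: concatenated exon length ", cds_len,
         " is not divisible by 3")
  exons
}

#' Read a coding alignment from FASTA plus an exon annotation
#'
#' Reads a multi-record aligned FASTA containing the ingroup haplotypes and
#' one outgroup record, together with an exon annotation in BED (0-based
#' half-open) or GFF3 (1-based inclusive, converted on read); the dialect is
#' selected by file extension. Sequences are upper-cased; only A/C/G/T/N/-
#' are accepted.
#'
#' @param fasta_path Path to the aligned FASTA (>= 3 records).
#' @param annotation_path Path to a \code{.bed}, \code{.gff} or \code{.gff3}
#'   file with the exon intervals on alignment coordinates.
#' @param outgroup_id Record name of the outgroup sequence in the FASTA.
#' @param gene_id Locus name; defaults to the annotation file stem.
#'
#' @return A validated [coding_alignment()].
#' @export
read_coding_alignment <- function(fasta_path, annotation_path, outgroup_id,
                                  gene_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)
  # readDNAStringSet keeps the full header line; match on the first token
  nm <- vapply(strsplit(nm, "[ \t]"), `[[`, character(1), 1L)
  names(seqs) <- nm
  if (length(seqs) < 3L)
    stop("FASTA must contain at least 3 records (>= 2 ingroup + outgroup)")
  if (!outgroup_id %in% nm)
    stop("outgroup id '", outgroup_id, "' not found in FASTA records")
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("ragged alignment: records differ in length")
  gr <- rtracklayer::import(annotation_path)
  # rtracklayer returns 1-based inclusive ranges for both dialects
  exons <- cbind(start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr))
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]+$", "", basename(annotation_path))
  ing <- as.character(seqs[setdiff(nm, outgroup_id)])
  outg <- as.character(seqs[[outgroup_id]])
  coding_alignment(gene_id, ing, outg, exons)
}

#' Write a coding alignment back to FASTA + BED
#'
#' Inverse of [read_coding_alignment()]: emits the ingroup haplotypes and
#' the outgroup (named \code{outgroup} unless rownames carry ids) as aligned
#' FASTA and the exon map as 3-column BED (0-based half-open).
#'
#' @param aln A [coding_alignment()].
#' @param fasta_path,bed_path Output paths.
#' @param outgroup_id Name to give the outgroup record.
#' @export
write_coding_alignment <- function(aln, fasta_path, bed_path,
                                   outgroup_id = "outgroup") {
  ids <- rownames(aln$mat)
  if (is.null(ids)) ids <- sprintf("hap%02d", seq_len(aln$n))
  seqs <- c(apply(aln$mat, 1L, paste, collapse = ""),
            paste(aln$outgroup, collapse = ""))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- c(ids, outgroup_id)
  Biostrings::writeXStringSet(dss, fasta_path)
  bed <- data.frame(chrom = aln$gene_id,
                    start = aln$exons[, "start"],
                    end = aln$exons[, "end"])
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' Build the shared site masks for an alignment
#'
#' Complete-deletion semantics: a column containing any gap or N in any
#' ingroup haplotype is unusable for every statistic; a gap/N in the
#' outgroup additionally removes the column from polarized analyses
#' (unfolded SFS, divergence, MK) but not from ingroup-only statistics.
#'
#' @param aln A [coding_alignment()].
#' @return A list of three logical vectors of length L:
#'   \code{usable_total}, \code{usable_polarized} (implies usable_total) and
#'   \code{coding}.
#' @export
build_site_masks <- function(aln) {
  ing_bad <- colSums(aln$mat == "-" | aln$mat == "N") > 0L
  out_bad <- aln$outgroup == "-" | aln$outgroup == "N"
  coding <- rep(FALSE, aln$L)
  for (i in seq_len(nrow(aln$exons)))
    coding[(aln$exons[i, 1L] + 1L):aln$exons[i, 2L]] <- TRUE
  list(usable_total = !ing_bad,
       usable_polarized = !ing_bad & !out_bad,
       coding = coding)
}

#' Map coding columns to codons
#'
#' Concatenates the exon columns in order and groups them in triplets.
#'
#' @param aln A [coding_alignment()].
#' @return Integer matrix with one row per codon and three columns holding
#'   the 1-based alignment column indices of each codon position.
#' @export
codon_map <- function(aln) {
  cols <- unlist(lapply(seq_len(nrow(aln$exons)), function(i)
    (aln$exons[i, 1L] + 1L):aln$exons[i, 2L]))
  matrix(cols, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("p1", "p2", "p3")))
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("coding_alignment '", x$gene_id, "': ", x$n, " haplotypes + outgroup, ",
      x$L, " aligned columns, ", nrow(x$exons), " exon(s), ",
      sum(x$exons[, 2] - x$exons[, 1]), " coding bp\n", sep = "")
  invisible(x)
}
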