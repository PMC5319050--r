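#' Phased haplotype matrix
#'
#' The substrate of every scan in the package: a binary matrix of 2N phased
#' haplotypes by S biallelic sites, together with site coordinates, alleles
#' and a sample-to-population assignment.  Haplotype rows `2k - 1` and `2k`
#' belong to sample `k`.
#'
#' @param H integer matrix, 2N x S, entries 0 (reference) or 1 (alternate).
#' @param chrom chromosome identifier(s); length 1 or one per site.
#' @param positions integer vector of 1-based bp positions, strictly
#'   increasing within each chromosome.
#' @param ref,alt per-site allele symbols (defaults `"A"`/`"C"`).
#' @param sample_ids character vector of N sample identifiers.
#' @param pops named character vector mapping sample id to population label.
#' @return An object of class `haplo_matrix`.
#' @examples
#' H <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L), nrow = 4)
#' hm <- haplo_matrix(H, chrom = "1", positions = c(100L, 200L),
#'                    sample_ids = c("s1", "s2"),
#'                    pops = c(s1 = "A", s2 = "B"))
#' @export
haplo_matrix <- function(H, chrom, positions, ref = NULL, alt = NULL,
                         sample_ids = NULL, pops = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  n_hap <- nrow(H)
  n_site <- ncol(H)
  if (n_hap %% 2L != 0L) stop("haplotype count must be even (2 per sample)")
  if (!all(H %in% c(0L, 1L))) stop("H entries must be 0 or 1")
  if (length(positions) != n_site) stop("positions length must equal ncol(H)")
  positions <- as.integer(positions)
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, n_site)
  if (length(chrom) != n_site) stop("chrom must be length 1 or one per site")
  for (ch in unique(chrom)) {
    p <- positions[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  n <- n_hap %/% 2L
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (length(sample_ids) != n) stop("need one sample id per individual")
  if (is.null(pops)) pops <- stats::setNames(rep("pop1", n), sample_ids)
  if (!all(sample_ids %in% names(pops)))
    stop("samples missing from population assignment: ",
         paste(setdiff(sample_ids, names(pops)), collapse = ", "))
  pops <- pops[sample_ids]
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("C", n_site)
  structure(
    list(H = H, chrom = chrom, positions = positions,
         ref = as.character(ref), alt = as.character(alt),
         sample_ids = as.character(sample_ids),
         pops = stats::setNames(as.character(pops), sample_ids)),
    class = "haplo_matrix")
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat(sprintf("<haplo_matrix> %d haplotypes (%d samples) x %d sites, %d chromosome(s)\n",
              nrow(x$H), length(x$sample_ids), ncol(x$H), length(unique(x$chrom))))
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$pops)),
                                    table(x$pops)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.haplo_matrix <- function(x) dim(x$H)

#' Per-haplotype population labels
#'
#' Expands the sample-level assignment to one label per haplotype row.
#' @param hm a [haplo_matrix()].
#' @return character vector of length 2N.
#' @export
hap_pops <- function(hm) rep(unname(hm$pops), each = 2L)

#' Extract the haplotype rows of one or more populations
#'
#' @param hm a [haplo_matrix()].
#' @param pop population label(s); several labels are pooled (used for the
#'   one-vs-rest reference panels of the cross-population scans).
#' @return integer matrix of the selected haplotype rows.
#' @export
pop_haplotypes <- function(hm, pop) {
  hp <- hap_pops(hm)
  if (!all(pop %in% hp)) stop("unknown population label: ",
                              paste(setdiff(pop, hp), collapse = ", "))
  hm$H[hp %in% pop, , drop = FALSE]
}

#' Subset a haplotype matrix by site index
#'
#' @param hm a [haplo_matrix()].
#' @param idx logical or integer site index.
#' @return a [haplo_matrix()] restricted to the selected sites.
#' @export
subset_sites <- function(hm, idx) {
  haplo_matrix(hm$H[, idx, drop = FALSE], hm$chrom[idx], hm$positions[idx],
               hm$ref[idx], hm$alt[idx], hm$sample_ids, hm$pops)
}

#' Collapse haplotypes to genotype dosages
#'
#' Sums each sample's two haplotype bits per site, yielding the N x S
#' alt-allele dosage matrix used by FST, IBS, PCA and the enrichment tests.
#'
#' @param hm a [haplo_matrix()].
#' @return An object of class `geno_matrix`: list with `G` (N x S dosage
#'   matrix in 0/1/2), `chrom`, `positions`, `sample_ids`, `pops`.
#' @export
to_genotypes <- function(hm) {
  n <- length(hm$sample_ids)
  G <- hm$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hm$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(G) <- hm$sample_ids
  structure(list(G = G, chrom = hm$chrom, positions = hm$positions,
                 sample_ids = hm$sample_ids, pops = hm$pops),
            class = "geno_matrix")
}

#' Construct a genotype matrix directly
#'
#' @param G N x S matrix of alt-allele dosages in \{0, 1, 2\} (NA allowed for
#'   missing calls, e.g. from external chip data).
#' @inheritParams haplo_matrix
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(G, chrom, positions, sample_ids = NULL, pops = NULL) {
  G <- as.matrix(G)
  if (!all(G %in% c(0, 1, 2) | is.na(G))) stop("dosages must be 0, 1, 2 or NA")
  n <- nrow(G)
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, ncol(G))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(pops)) pops <- stats::setNames(rep("pop1", n), sample_ids)
  rownames(G) <- sample_ids
  structure(list(G = G, chrom = chrom, positions = as.integer(positions),
                 sample_ids = as.character(sample_ids),
                 pops = stats::setNames(as.character(pops[sample_ids]), sample_ids)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites\n",
              nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Alternate-allele frequency at one site in one population
#'
#' @param hm a [haplo_matrix()].
#' @param site site index (column of the matrix).
#' @param pop population label.
#' @return frequency in `[0, 1]` (mean of the haplotype bits).
#' @export
allele_frequency <- function(hm, site, pop) {
  mean(pop_haplotypes(hm, pop)[, site])
}

#' Per-site alternate-allele frequencies for a population
#'
#' @inheritParams allele_frequency
#' @return numeric vector, one frequency per site.
#' @export
allele_frequencies <- function(hm, pop) {
  colMeans(pop_haplotypes(hm, pop))
}

# derive a child RNG seed from a master seed and a fixed stream offset;
# kept strictly below 2^31 - 1
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}
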