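#' Write a phased VCF 4.2 subset
#'
#' Emits the narrow dialect the package consumes: columns CHROM POS ID REF
#' ALT QUAL FILTER INFO FORMAT plus one GT column per sample, genotypes
#' phased with `|`, INFO keys MQ0/QD/FS when quality annotations are given.
#' Formatting is canonical (fixed two-decimal floats) so that
#' `read_vcf()` followed by `write_vcf()` is a byte-level fixed point.
#'
#' @param hm a [haplo_matrix()].
#' @param quality optional tibble (chrom, pos, qual, mq0, qd, fs) as produced
#'   by the simulator or parsed by [read_vcf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hm, path, quality = NULL) {
  n <- length(hm$sample_ids)
  S <- ncol(hm$H)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Count of mapping-quality-zero reads\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand-bias P\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hm$sample_ids), collapse = "\t"))
  if (!is.null(quality)) {
    key <- paste(hm$chrom, hm$positions)
    qkey <- paste(quality$chrom, quality$pos)
    m <- match(key, qkey)
    qualcol <- ifelse(is.na(quality$qual[m]), ".",
                      sprintf("%.2f", quality$qual[m]))
    info <- ifelse(is.na(m), ".",
                   sprintf("MQ0=%d;QD=%.2f;FS=%.2f",
                           quality$mq0[m], quality$qd[m], quality$fs[m]))
    info[is.na(quality$mq0[m])] <- "."
  } else {
    qualcol <- rep(".", S)
    info <- rep(".", S)
  }
  a1 <- hm$H[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- hm$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), n, S)  # n x S
  body <- paste(hm$chrom, hm$positions, ".", hm$ref, hm$alt, qualcol, ".",
                info, "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the sample-to-population assignment table
#'
#' Two whitespace-separated columns (sample id, population label); lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @return tibble with columns `sample`, `pop`.
#' @export
read_pop_table <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("sample", "pop"),
                          colClasses = "character")
  tibble::as_tibble(tb)
}

#' Read a phased VCF
#'
#' Parses a VCF 4.2 subset into the package's haplotype/genotype containers.
#' Only biallelic, phased SNP records are loaded; multiallelic, indel or
#' unphased records are rejected and counted.  Missing INFO annotations
#' (MQ0/QD/FS) or missing QUAL become NA sentinels that the hard filter
#' treats as passing.
#'
#' @param path VCF file (plain text).
#' @param pop_table tibble as from [read_pop_table()], or a path to one; if
#'   omitted all samples are assigned population `"pop1"`.
#' @return list with `haplotypes` ([haplo_matrix()]), `quality` (tibble),
#'   `genotypes` ([to_genotypes()] of the haplotypes) and `rejected` (named
#'   counts of skipped records).
#' @export
read_vcf <- function(path, pop_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gts <- gt[, -1L, drop = FALSE]
  multi <- grepl(",", alt) | is.na(alt)
  indel <- nchar(ref) != 1L | (nchar(alt) != 1L & !multi)
  gt_core <- sub(":.*", "", gts)
  unphased <- apply(gt_core, 1L, function(r) any(grepl("/", r) | !grepl("\\|", r)))
  bad <- multi | indel | unphased
  rejected <- c(multiallelic = sum(multi),
                indel = sum(indel & !multi),
                unphased = sum(unphased & !multi & !indel))
  if (any(bad))
    message(sum(bad), " record(s) rejected (",
            paste(names(rejected), rejected, sep = "=", collapse = ", "), ")")
  keep <- which(!bad)
  if (length(keep) == 0L) stop("no usable biallelic phased records in ", path)
  a1 <- apply(gt_core[keep, , drop = FALSE], c(1, 2),
              function(g) as.integer(substr(g, 1L, 1L)))
  a2 <- apply(gt_core[keep, , drop = FALSE], c(1, 2),
              function(g) as.integer(substr(g, 3L, 3L)))
  if (any(is.na(a1)) || any(is.na(a2)) || any(c(a1, a2) > 1L))
    stop("malformed GT field in ", path)
  H <- matrix(0L, 2L * length(samples), length(keep))
  H[seq(1L, nrow(H), by = 2L), ] <- t(a1)
  H[seq(2L, nrow(H), by = 2L), ] <- t(a2)
  if (is.character(pop_table) && length(pop_table) == 1L)
    pop_table <- read_pop_table(pop_table)
  if (is.null(pop_table)) {
    pops <- stats::setNames(rep("pop1", length(samples)), samples)
  } else {
    missing <- setdiff(samples, pop_table$sample)
    if (length(missing))
      stop("sample(s) in VCF absent from population table: ",
           paste(missing, collapse = ", "))
    pops <- stats::setNames(pop_table$pop, pop_table$sample)[samples]
  }
  info <- fix[keep, "INFO"]
  info[is.na(info)] <- ""
  info_num <- function(key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]+"), info)
    out <- rep(NA_real_, length(info))
    hit <- !is.na(m) & m > 0
    out[hit] <- as.numeric(sub(paste0("^;?", key, "="), "",
                               regmatches(info, m)))
    out
  }
  qualv <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  quality <- tibble::tibble(chrom = fix[keep, "CHROM"],
                            pos = as.integer(fix[keep, "POS"]),
                            qual = qualv,
                            mq0 = as.integer(info_num("MQ0")),
                            qd = info_num("QD"),
                            fs = info_num("FS"))
  hm <- haplo_matrix(H, chrom = fix[keep, "CHROM"],
                     positions = as.integer(fix[keep, "POS"]),
                     ref = ref[keep], alt = alt[keep],
                     sample_ids = samples, pops = pops)
  list(haplotypes = hm, quality = quality,
       genotypes = to_genotypes(hm), rejected = rejected)
}

#' Apply the hard site filter
#'
#' A site is removed iff `qual < qual_min` OR (`mq0 > mq0_max` AND
#' `qd < qd_min`) OR `fs > fs_max`; the defaults are the conventional GATK
#' hard-filter thresholds (30 / 4 / 5 / 200).  The MQ0/QD rule is a
#' conjunction by default; `mq0_qd_conjunction = FALSE` switches it to a
#' disjunction for sensitivity analysis.  Missing (NA) annotations pass.
#'
#' @param hm a [haplo_matrix()].
#' @param quality quality tibble (chrom, pos, qual, mq0, qd, fs) aligned with
#'   the sites of `hm`.
#' @param qual_min,mq0_max,qd_min,fs_max filter thresholds.
#' @param mq0_qd_conjunction logical; see above.
#' @return list with `haplotypes` (filtered), `quality` (filtered), and
#'   `report`: tibble of per-rule removal counts and the total retained.
#' @export
filter_sites <- function(hm, quality, qual_min = 30, mq0_max = 4,
                         qd_min = 5, fs_max = 200,
                         mq0_qd_conjunction = TRUE) {
  stopifnot(nrow(quality) == ncol(hm$H))
  na_false <- function(x) !is.na(x) & x
  r1 <- na_false(quality$qual < qual_min)
  if (mq0_qd_conjunction) {
    r2 <- na_false(quality$mq0 > mq0_max) & na_false(quality$qd < qd_min)
  } else {
    r2 <- na_false(quality$mq0 > mq0_max) | na_false(quality$qd < qd_min)
  }
  r3 <- na_false(quality$fs > fs_max)
  drop <- r1 | r2 | r3
  report <- tibble::tibble(
    rule = c("qual_lt_min", "mq0_and_qd", "fs_gt_max", "removed_total",
             "retained"),
    n = c(sum(r1), sum(r2), sum(r3), sum(drop), sum(!drop)))
  list(haplotypes = subset_sites(hm, !drop),
       quality = quality[!drop, , drop = FALSE],
       report = report)
}

#' Genotype concordance between two call sets
#'
#' Over the intersection of (chrom, position) pairs and sample ids, the
#' fraction of genotype calls that agree; missing calls are excluded from
#' the denominator.  This is the chip-versus-resequencing concordance check.
#'
#' @param gm_a,gm_b `geno_matrix` objects.
#' @return list with `overall` (fraction concordant) and `per_sample`
#'   (tibble: sample, n_compared, n_concordant, concordance).
#' @export
genotype_concordance <- function(gm_a, gm_b) {
  key_a <- paste(gm_a$chrom, gm_a$positions)
  key_b <- paste(gm_b$chrom, gm_b$positions)
  sites <- intersect(key_a, key_b)
  samples <- intersect(gm_a$sample_ids, gm_b$sample_ids)
  if (length(sites) == 0L || length(samples) == 0L)
    stop("call sets share no sites or no samples")
  A <- gm_a$G[match(samples, gm_a$sample_ids),
              match(sites, key_a), drop = FALSE]
  B <- gm_b$G[match(samples, gm_b$sample_ids),
              match(sites, key_b), drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  eq <- ok & (A == B)
  per_sample <- tibble::tibble(sample = samples,
                               n_compared = unname(rowSums(ok)),
                               n_concordant = unname(rowSums(eq)))
  per_sample$concordance <- ifelse(per_sample$n_compared > 0,
                                   per_sample$n_concordant / per_sample$n_compared,
                                   NA_real_)
  list(overall = sum(eq) / sum(ok), per_sample = per_sample)
}

#' Read gene intervals from BED or GFF3
#'
#' BED is 0-based half-open and converted to the package's 1-based inclusive
#' coordinates; GFF3 is 1-based inclusive, with only `gene` features kept and
#' the id taken from the `ID=` or `gene_id=` attribute.
#'
#' @param path file path ending in `.bed`, `.gff`, `.gff3` (or pass
#'   `format`).
#' @param format `"bed"` or `"gff3"`; inferred from the extension by default.
#' @return tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  if (format == "bed") {
    tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                            sep = "\t", colClasses = "character")
    tibble::tibble(gene_id = if (ncol(tb) >= 4) tb[[4]] else
                     paste0("bed", seq_len(nrow(tb))),
                   chrom = tb[[1]],
                   start = as.integer(tb[[2]]) + 1L,
                   end = as.integer(tb[[3]]),
                   strand = if (ncol(tb) >= 6) tb[[6]] else "*")
  } else {
    tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                            sep = "\t", colClasses = "character")
    tb <- tb[tb[[3]] == "gene", , drop = FALSE]
    attr_id <- function(a) {
      m <- regmatches(a, regexpr("(ID|gene_id)=[^;]+", a))
      ifelse(lengths(regmatches(a, gregexpr("(ID|gene_id)=[^;]+", a))) > 0,
             sub("^(ID|gene_id)=", "", m), NA_character_)
    }
    tibble::tibble(gene_id = attr_id(tb[[9]]),
                   chrom = tb[[1]],
                   start = as.integer(tb[[4]]),
                   end = as.integer(tb[[5]]),
                   strand = tb[[7]])
  }
}
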