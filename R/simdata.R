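#' Configuration for the founder-mosaic haplotype simulator
#'
#' The simulator emulates the data structure the scans consume: phased
#' multi-population haplotypes with distance-decaying LD (each haplotype is a
#' recombinant mosaic of a founder pool), drift-divergent allele frequencies
#' between populations (independent logit-scale perturbation of shared
#' ancestral frequencies), an optional implanted selective sweep, and
#' per-site quality annotations with a controllable failing fraction.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop integer vector (recycled to `n_pops`) of diploid
#'   individuals per population.
#' @param seq_length contig length in bp.
#' @param n_sites target count of segregating sites.
#' @param n_founders founder haplotypes per population pool.
#' @param theta_sfs shape of the neutral site-frequency spectrum: the derived
#'   founder count i is drawn with weight 1 / i^theta_sfs.
#' @param switch_rate founder-mosaic recombination switches per bp; mean
#'   copied segment length is `1 / switch_rate`.
#' @param drift_sigma sd of the per-population logit-scale perturbation of the
#'   ancestral frequencies (0 = identical populations).
#' @param sweep optional [sweep_spec()] describing an implanted sweep.
#' @param qual_fail_fraction fraction of sites assigned filter-failing quality
#'   annotations.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_pops = 2L, samples_per_pop = 10L,
                             seq_length = 5e6, n_sites = 5000L,
                             n_founders = 20L, theta_sfs = 1,
                             switch_rate = 1e-5, drift_sigma = 0.5,
                             sweep = NULL, qual_fail_fraction = 0.1,
                             seed = 1L) {
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  chk <- function(ok, field)
    if (!isTRUE(ok)) stop("invalid configuration field: ", field, call. = FALSE)
  chk(is.numeric(n_pops) && n_pops >= 1, "n_pops")
  chk(all(samples_per_pop >= 1), "samples_per_pop")
  chk(seq_length > 0, "seq_length")
  chk(n_sites >= 2, "n_sites")
  chk(n_founders >= 2, "n_founders")
  chk(theta_sfs > 0, "theta_sfs")
  chk(switch_rate > 0, "switch_rate")
  chk(drift_sigma >= 0, "drift_sigma")
  chk(qual_fail_fraction >= 0 && qual_fail_fraction <= 1, "qual_fail_fraction")
  if (!is.null(sweep) && !inherits(sweep, "sweep_spec"))
    stop("invalid configuration field: sweep")
  if (!is.null(sweep))
    chk(sweep$position >= 1 && sweep$position <= seq_length, "sweep$position")
  structure(list(n_pops = as.integer(n_pops),
                 samples_per_pop = samples_per_pop,
                 seq_length = as.numeric(seq_length),
                 n_sites = as.integer(n_sites),
                 n_founders = as.integer(n_founders),
                 theta_sfs = theta_sfs, switch_rate = switch_rate,
                 drift_sigma = drift_sigma, sweep = sweep,
                 qual_fail_fraction = qual_fail_fraction,
                 seed = as.integer(seed)),
            class = "sweep_sim_config")
}

#' Specification of an implanted selective sweep
#'
#' @param target_pop population label carrying the sweep.
#' @param position focal site position in bp.
#' @param final_frequency fraction of target-population haplotypes carrying
#'   the sweep haplotype at the focal site (0 < f <= 1).
#' @param decay_scale bp distance at which hitchhiked identity to the carrier
#'   decays by a factor e.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_pop, position, final_frequency = 0.95,
                       decay_scale = 1e5) {
  if (!(final_frequency > 0 && final_frequency <= 1))
    stop("invalid configuration field: final_frequency")
  if (decay_scale <= 0) stop("invalid configuration field: decay_scale")
  structure(list(target_pop = as.character(target_pop),
                 position = as.numeric(position),
                 final_frequency = final_frequency,
                 decay_scale = decay_scale),
            class = "sweep_spec")
}

#' Simulate neutral multi-population phased haplotypes
#'
#' Positions are sampled uniformly without replacement over the contig.
#' Ancestral derived-allele frequencies follow the configured neutral SFS
#' over founder counts; each population's founder frequencies are the
#' ancestral ones perturbed on the logit scale with sd `drift_sigma`
#' (creating nonzero FST), and founder pools are drawn with common uniform
#' variates across populations so that `drift_sigma = 0` yields literally
#' identical pools.  Haplotypes are founder mosaics with geometric switch
#' distances (rate `switch_rate`), which produces distance-decaying LD.
#' Exactly `round(qual_fail_fraction * n_sites)` sites receive
#' filter-failing quality annotations.
#'
#' @param config a [sweep_sim_config()] with `sweep = NULL`.
#' @param chrom chromosome name for the emitted contig.
#' @return list with `haplotypes` ([haplo_matrix()]), `quality` (tibble:
#'   chrom, pos, qual, mq0, qd, fs), `truth` (tibble truth ledger with
#'   per-site `qual_fail` flags and sweep columns, all NA here).
#' @export
simulate_neutral <- function(config, chrom = "1") {
  if (!inherits(config, "sweep_sim_config")) stop("config must be a sweep_sim_config")
  if (!is.null(config$sweep)) stop("config must not contain a sweep; use simulate_sweep()")
  sim_core(config, chrom)
}

# shared generator (neutral core; sweep implanted by the caller)
sim_core <- function(config, chrom) {
  set.seed(child_seed(config$seed, 1L))
  S <- config$n_sites
  positions <- sort(sample.int(config$seq_length, S))
  Fn <- config$n_founders
  # ancestral SFS: derived count i in 1..Fn-1 with weight 1/i^theta
  i <- sample.int(Fn - 1L, S, replace = TRUE,
                  prob = (seq_len(Fn - 1L))^(-config$theta_sfs))
  q_anc <- i / Fn
  U <- matrix(stats::runif(Fn * S), Fn, S)  # common founder draws across pops
  pop_names <- paste0("pop", seq_len(config$n_pops))
  H_list <- vector("list", config$n_pops)
  for (p in seq_len(config$n_pops)) {
    set.seed(child_seed(config$seed, 10L + p))
    if (config$drift_sigma > 0) {
      lg <- stats::qlogis(q_anc) + stats::rnorm(S, 0, config$drift_sigma)
      q_p <- stats::plogis(lg)
    } else q_p <- q_anc
    founders <- (U < rep(q_p, each = Fn)) * 1L  # Fn x S
    n_hap <- 2L * config$samples_per_pop[p]
    Hp <- matrix(0L, n_hap, S)
    for (h in seq_len(n_hap)) {
      n_sw <- stats::rpois(1L, config$switch_rate * config$seq_length)
      breaks <- sort(stats::runif(n_sw, 0, config$seq_length))
      seg <- findInterval(positions, breaks) + 1L
      fid <- sample.int(Fn, n_sw + 1L, replace = TRUE)
      Hp[h, ] <- founders[cbind(fid[seg], seq_len(S))]
    }
    H_list[[p]] <- Hp
  }
  H <- do.call(rbind, H_list)
  n_tot <- sum(config$samples_per_pop)
  sample_ids <- sprintf("s%03d", seq_len(n_tot))
  pops <- stats::setNames(rep(pop_names, config$samples_per_pop), sample_ids)
  hm <- haplo_matrix(H, chrom = chrom, positions = positions,
                     sample_ids = sample_ids, pops = pops)
  sq <- sim_site_quality(config, chrom, positions)
  truth <- tibble::tibble(chrom = chrom, pos = positions,
                          qual_fail = sq$qual_fail,
                          sweep_pop = NA_character_,
                          sweep_pos = NA_real_,
                          sweep_start = NA_real_, sweep_end = NA_real_,
                          carrier_hap = NA_integer_)
  list(haplotypes = hm,
       quality = sq$quality,
       truth = truth)
}

# per-site quality annotations; failing sites violate one hard-filter rule
sim_site_quality <- function(config, chrom, positions) {
  S <- length(positions)
  set.seed(child_seed(config$seed, 2L))
  n_fail <- round(config$qual_fail_fraction * S)
  fail <- rep(FALSE, S)
  if (n_fail > 0) fail[sample.int(S, n_fail)] <- TRUE
  # passing sites clear every threshold with margin
  qual <- round(stats::runif(S, 50, 90), 2)
  mq0 <- rep(0L, S)
  qd <- round(stats::runif(S, 10, 30), 2)
  fs <- round(stats::runif(S, 0, 20), 2)
  if (n_fail > 0) {
    rule <- sample.int(3L, n_fail, replace = TRUE)
    idx <- which(fail)
    qual[idx[rule == 1L]] <- round(stats::runif(sum(rule == 1L), 2, 25), 2)
    mq0[idx[rule == 2L]] <- 6L
    qd[idx[rule == 2L]] <- round(stats::runif(sum(rule == 2L), 0.5, 4), 2)
    fs[idx[rule == 3L]] <- round(stats::runif(sum(rule == 3L), 220, 400), 2)
  }
  list(quality = tibble::tibble(chrom = chrom, pos = positions,
                                qual = qual, mq0 = mq0, qd = qd, fs = fs),
       qual_fail = fail)
}

#' Implant a selective sweep into an existing haplotype matrix
#'
#' One carrier haplotype is chosen in the target population; a fraction
#' `final_frequency` of that population's haplotypes is overwritten, site by
#' site, with the carrier's alleles with probability
#' `exp(-distance_to_position / decay_scale)` (independent per site and
#' haplotype).  Other populations are untouched; positions and alleles are
#' preserved.  This creates the locally elevated haplotype homozygosity and
#' allele-frequency differentiation that XP-EHH and XP-CLR detect.
#'
#' @param hm a [haplo_matrix()] (single contig).
#' @param spec a [sweep_spec()].
#' @param seed integer seed.
#' @param window_size window size used to report the sweep-containing window
#'   in the truth ledger (bp).
#' @return list with `haplotypes` (modified [haplo_matrix()]) and `truth`
#'   (one-row tibble: sweep population, focal position, window coordinates,
#'   carrier haplotype index within the full matrix).
#' @export
implant_sweep <- function(hm, spec, seed = 1L, window_size = 50000) {
  if (!inherits(spec, "sweep_spec")) stop("spec must be a sweep_spec")
  hp <- hap_pops(hm)
  if (!spec$target_pop %in% hp)
    stop("unknown population label: ", spec$target_pop)
  set.seed(child_seed(seed, 3L))
  tgt <- which(hp == spec$target_pop)
  carrier <- tgt[sample.int(length(tgt), 1L)]
  n_rec <- round(spec$final_frequency * length(tgt))
  truth_row <- function() {
    ws <- floor((spec$position - 1) / window_size) * window_size + 1
    tibble::tibble(sweep_pop = spec$target_pop, sweep_pos = spec$position,
                   sweep_start = ws, sweep_end = ws + window_size - 1,
                   carrier_hap = carrier)
  }
  if (n_rec == 0L) return(list(haplotypes = hm, truth = truth_row()))
  recip <- tgt[sample.int(length(tgt), n_rec)]
  d <- abs(hm$positions - spec$position)
  p_copy <- exp(-d / spec$decay_scale)
  S <- ncol(hm$H)
  carrier_row <- hm$H[carrier, ]
  for (h in recip) {
    copy <- stats::runif(S) < p_copy
    hm$H[h, copy] <- carrier_row[copy]
  }
  list(haplotypes = hm, truth = truth_row())
}

#' Simulate a sweep-bearing contig
#'
#' Convenience wrapper: [simulate_neutral()] on the neutral part of the
#' config, then [implant_sweep()] per `config$sweep`.
#'
#' @inheritParams simulate_neutral
#' @return as [simulate_neutral()], with the sweep columns of the truth
#'   ledger filled in.
#' @export
simulate_sweep <- function(config, chrom = "1") {
  if (is.null(config$sweep)) stop("config carries no sweep spec")
  out <- sim_core(config, chrom)
  sw <- implant_sweep(out$haplotypes, config$sweep, seed = config$seed)
  out$haplotypes <- sw$haplotypes
  out$truth$sweep_pop <- sw$truth$sweep_pop
  out$truth$sweep_pos <- sw$truth$sweep_pos
  out$truth$sweep_start <- sw$truth$sweep_start
  out$truth$sweep_end <- sw$truth$sweep_end
  out$truth$carrier_hap <- sw$truth$carrier_hap
  out
}

#' Simulate a multi-contig genome
#'
#' Runs the single-contig simulator once per contig with child seeds derived
#' from the master seed, concatenating the results.  If the config carries a
#' sweep it is implanted on `sweep_contig` only.
#'
#' @param config a [sweep_sim_config()].
#' @param n_contigs number of contigs.
#' @param sweep_contig index of the contig receiving the sweep (if any).
#' @return list with `haplotypes`, `quality`, `truth` spanning all contigs,
#'   and `contig_lengths` (named vector).
#' @export
simulate_genome <- function(config, n_contigs = 20L, sweep_contig = 1L) {
  pieces <- vector("list", n_contigs)
  for (k in seq_len(n_contigs)) {
    cfg_k <- config
    cfg_k$seed <- child_seed(config$seed, 100L + k)
    if (!is.null(config$sweep) && k == sweep_contig) {
      pieces[[k]] <- simulate_sweep(cfg_k, chrom = as.character(k))
    } else {
      cfg_k$sweep <- NULL
      pieces[[k]] <- simulate_neutral(cfg_k, chrom = as.character(k))
    }
  }
  hm1 <- pieces[[1L]]$haplotypes
  H <- do.call(cbind, lapply(pieces, function(p) p$haplotypes$H))
  hm <- haplo_matrix(H,
                     chrom = unlist(lapply(pieces, function(p) p$haplotypes$chrom)),
                     positions = unlist(lapply(pieces, function(p) p$haplotypes$positions)),
                     ref = unlist(lapply(pieces, function(p) p$haplotypes$ref)),
                     alt = unlist(lapply(pieces, function(p) p$haplotypes$alt)),
                     sample_ids = hm1$sample_ids, pops = hm1$pops)
  list(haplotypes = hm,
       quality = dplyr::bind_rows(lapply(pieces, function(p) p$quality)),
       truth = dplyr::bind_rows(lapply(pieces, function(p) p$truth)),
       contig_lengths = stats::setNames(rep(config$seq_length, n_contigs),
                                        as.character(seq_len(n_contigs))))
}

#' Write the truth ledger as tab-separated text
#'
#' @param truth truth tibble from the simulator.
#' @param path output file.
#' @export
write_truth_ledger <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write the sample-to-population table
#'
#' Two whitespace-separated columns (sample, population), the format
#' [read_pop_table()] reads.
#' @param hm a [haplo_matrix()].
#' @param path output file.
#' @export
write_pop_table <- function(hm, path) {
  writeLines(paste(hm$sample_ids, unname(hm$pops)), path)
  invisible(path)
}
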