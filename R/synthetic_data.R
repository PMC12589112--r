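#' Configuration for the synthetic repertoire generator
#'
#' Fixes every distributional choice of the simulator so all generators are
#' bit-reproducible from `seed`. Defaults emulate the structure the
#' pipeline assumes in real data: CDR3-beta lengths peaked at 14-15 over
#' the range 8-20 (junction convention `C...F`), a uniform interior
#' amino-acid composition (the simplest null; a composition table can be
#' supplied), a small pool of common TRBV genes with decreasing weights, a
#' shared 4-residue motif fully penetrant among epitope-specific sequences,
#' Zipf (discrete power-law) clone sizes producing heavy-tailed clonal
#' expansion, and a phenotype-cluster vocabulary with specificity biased
#' toward an effector cluster.
#'
#' @param seed integer seed (mandatory).
#' @param n_sequences default number of sequences per generator call.
#' @param length_distribution named probability vector over CDR3 lengths
#'   (names = lengths); default: discretized bell over 8..20 peaked at
#'   14-15.
#' @param aa_composition named probability vector over the 20 residues for
#'   interior positions; default uniform.
#' @param v_gene_pool,v_gene_weights TRBV names and sampling weights.
#' @param motif pattern implanted into epitope-specific sequences
#'   (wildcards `.` allowed; resolved to random residues at implantation).
#' @param implant_fraction fraction of "specific" sequences carrying the
#'   motif (default 1).
#' @param clone_size_alpha power-law exponent of clone sizes (default 2.5;
#'   smaller = heavier tail = more clonal dominance).
#' @param clone_size_max truncation of the clone-size law (default 1000).
#' @param spike_frequency target epitope-specific read (or cell) fraction
#'   per sample (default 0.05).
#' @param cluster_props named phenotype-cluster probabilities for
#'   non-specific cells; default over Tn, Tem/rm, Teff, Temra,
#'   NK-like Temra, IFN CTL.
#' @param enrichment_target cluster receiving specific cells (default
#'   "Teff").
#' @param enrichment_prob probability a specific cell lands in the target
#'   cluster (default 0.7).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_sequences = 1000L,
                       length_distribution = NULL,
                       aa_composition = NULL,
                       v_gene_pool = NULL,
                       v_gene_weights = NULL,
                       motif = "LGQG",
                       implant_fraction = 1,
                       clone_size_alpha = 2.5,
                       clone_size_max = 1000L,
                       spike_frequency = 0.05,
                       cluster_props = NULL,
                       enrichment_target = "Teff",
                       enrichment_prob = 0.7) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(length_distribution)) {
    lens <- 8:20
    w <- exp(-((lens - 14.5)^2) / (2 * 2^2))
    length_distribution <- stats::setNames(w / sum(w), lens)
  }
  if (is.null(aa_composition)) {
    aa_composition <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  if (is.null(v_gene_pool)) {
    v_gene_pool <- c("TRBV19", "TRBV5-1", "TRBV20-1", "TRBV12-3", "TRBV28",
                     "TRBV9", "TRBV6-5", "TRBV27", "TRBV7-9", "TRBV2")
  }
  if (is.null(v_gene_weights)) {
    v_gene_weights <- (seq_along(v_gene_pool))^-0.7
  }
  v_gene_weights <- v_gene_weights / sum(v_gene_weights)
  if (is.null(cluster_props)) {
    cluster_props <- c("Tn" = 0.25, "Tem/rm" = 0.25, "Teff" = 0.20,
                       "Temra" = 0.15, "NK-like Temra" = 0.10,
                       "IFN CTL" = 0.05)
  }
  stopifnot(abs(sum(length_distribution) - 1) < 1e-8,
            abs(sum(cluster_props) - 1) < 1e-8,
            implant_fraction >= 0, implant_fraction <= 1,
            spike_frequency >= 0, spike_frequency < 1,
            enrichment_prob >= 0, enrichment_prob <= 1,
            enrichment_target %in% names(cluster_props))
  bad <- setdiff(strsplit(gsub("\\.", "", motif), "")[[1]], AA20)
  if (length(bad)) {
    stop("motif contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ""))
  }
  structure(list(seed = as.integer(seed),
                 n_sequences = as.integer(n_sequences),
                 length_distribution = length_distribution,
                 aa_composition = aa_composition,
                 v_gene_pool = v_gene_pool,
                 v_gene_weights = v_gene_weights,
                 motif = motif,
                 implant_fraction = implant_fraction,
                 clone_size_alpha = clone_size_alpha,
                 clone_size_max = as.integer(clone_size_max),
                 spike_frequency = spike_frequency,
                 cluster_props = cluster_props,
                 enrichment_target = enrichment_target,
                 enrichment_prob = enrichment_prob,
                 generator_version = "1"),
            class = "sim_config")
}

# -- internal generators; callers are responsible for seeding the RNG --

r_cdr3 <- function(cfg, n) {
  lens <- as.integer(sample(names(cfg$length_distribution), n, replace = TRUE,
                            prob = cfg$length_distribution))
  n_interior <- lens - 2L
  chars <- sample(names(cfg$aa_composition), sum(n_interior), replace = TRUE,
                  prob = cfg$aa_composition)
  ends <- cumsum(n_interior)
  interiors <- substring(paste(chars, collapse = ""),
                         c(1L, utils::head(ends, -1) + 1L), ends)
  paste0("C", interiors, "F")
}

r_background <- function(cfg, n, sample_id, source_label) {
  data.frame(cdr3b = r_cdr3(cfg, n),
             v_gene = sample(cfg$v_gene_pool, n, replace = TRUE,
                             prob = cfg$v_gene_weights),
             count = 1L,
             sample_id = sample_id,
             source_label = source_label,
             stringsAsFactors = FALSE)
}

r_implant <- function(cfg, df) {
  n <- nrow(df)
  carrier <- stats::runif(n) < cfg$implant_fraction
  m <- nchar(cfg$motif)
  for (i in which(carrier)) {
    L <- nchar(df$cdr3b[i])
    if (L < m + 2L) stop("CDR3 too short to implant motif of length ", m)
    concrete <- strsplit(cfg$motif, "")[[1]]
    wild <- concrete == "."
    if (any(wild)) {
      concrete[wild] <- sample(names(cfg$aa_composition), sum(wild),
                               replace = TRUE, prob = cfg$aa_composition)
    }
    # place the motif in the central antigen-contact region (clear of the
    # conserved junction ends) whenever the sequence is long enough
    lo <- 4L; hi <- L - m - 1L
    if (hi < lo) { lo <- 2L; hi <- L - m }
    start <- if (lo == hi) lo else sample(lo:hi, 1L)
    substr(df$cdr3b[i], start, start + m - 1L) <- paste(concrete,
                                                        collapse = "")
  }
  df$carrier <- carrier
  df
}

r_zipf <- function(cfg, n) {
  s <- seq_len(cfg$clone_size_max)
  sample(s, n, replace = TRUE, prob = s^(-cfg$clone_size_alpha))
}

#' Generate background CDR3-beta clonotypes
#'
#' Unselected naive-like sequences: `C` + interior residues drawn from the
#' configured composition + `F`, lengths from the configured distribution,
#' V genes from the pool. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param n number of sequences (default `cfg$n_sequences`).
#' @param sample_id,source_label annotations for the output table.
#' @return Clonotype data frame with `count = 1` per row.
#' @export
generate_background_cdr3s <- function(cfg, n = cfg$n_sequences,
                                      sample_id = "sim",
                                      source_label = "background") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, r_background(cfg, n, sample_id, source_label))
}

#' Generate motif-implanted epitope-specific TCRs
#'
#' Background sequences where a fraction `cfg$implant_fraction` carry the
#' configured motif as a contiguous interior substring at a random offset
#' (never touching the terminal C/F). The ground-truth `carrier` flag is
#' returned alongside.
#'
#' @inheritParams generate_background_cdr3s
#' @return Clonotype data frame with a logical `carrier` column.
#' @export
implant_motif_positives <- function(cfg, n = cfg$n_sequences,
                                    sample_id = "sim",
                                    source_label = "specific") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    df <- r_background(cfg, n, sample_id, source_label)
    r_implant(cfg, df)
  })
}

#' Generate a clonally expanded bulk cohort with spiked specific reads
#'
#' Per sample: background clonotypes with Zipf-distributed clone sizes
#' (heavy-tailed clonal expansion), plus reads from a few epitope-specific
#' clonotypes spiked so the expected specific-read fraction equals
#' `cfg$spike_frequency`, concentrated in `n_spike_clones` expanded clones.
#' With the default `clones_per_sample` every sample exceeds 40000 reads so
#' downstream downsampling is exercised.
#'
#' @param cfg a [sim_config()].
#' @param n_samples number of samples.
#' @param specific_tcrs clonotype data frame of epitope-specific TCRs to
#'   spike (required when `spike_frequency > 0`).
#' @param clones_per_sample background clonotypes per sample.
#' @param n_spike_clones specific clones carrying the spiked mass.
#' @param cohort cohort name; `tissue` `"PB"` or `"BM"`.
#' @return List of class `"cohort_spec"`: `name`, `tissue`,
#'   `downsample_n` (40000), `samples` (list of [new_repertoire()]).
#' @export
generate_bulk_cohort <- function(cfg, n_samples, specific_tcrs = NULL,
                                 clones_per_sample = 25000L,
                                 n_spike_clones = 3L,
                                 cohort = "sim-cohort", tissue = "BM") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$spike_frequency > 0 &&
      (is.null(specific_tcrs) || !nrow(specific_tcrs))) {
    stop("specific_tcrs required when spike_frequency > 0")
  }
  samples <- withr::with_seed(cfg$seed, lapply(seq_len(n_samples), function(s) {
    sid <- sprintf("%s-%d", cohort, s)
    bg <- r_background(cfg, clones_per_sample, sid, "background")
    bg$count <- r_zipf(cfg, clones_per_sample)
    if (cfg$spike_frequency > 0) {
      k <- min(n_spike_clones, nrow(specific_tcrs))
      pick <- sample.int(nrow(specific_tcrs), k)
      total_bg <- sum(bg$count)
      s_total <- round(total_bg * cfg$spike_frequency /
                         (1 - cfg$spike_frequency))
      w <- seq_len(k)^-1
      s_counts <- floor(s_total * w / sum(w))
      s_counts[1] <- s_counts[1] + (s_total - sum(s_counts))
      sp <- data.frame(cdr3b = specific_tcrs$cdr3b[pick],
                       v_gene = specific_tcrs$v_gene[pick],
                       count = as.integer(s_counts),
                       sample_id = sid, source_label = "specific",
                       stringsAsFactors = FALSE)
      sp <- sp[sp$count > 0L, , drop = FALSE]
      bg <- rbind(bg, sp)
    }
    new_repertoire(bg, sample_id = sid, cohort = cohort)
  }))
  structure(list(name = cohort, tissue = tissue, downsample_n = 40000L,
                 samples = samples),
            class = "cohort_spec")
}

#' Generate a clustered single-cell cohort with phenotype-biased specificity
#'
#' Each cell draws a clonotype — epitope-specific with probability
#' `cfg$spike_frequency` (from a small expanded pool of `specific_tcrs`),
#' otherwise from a Zipf-weighted background pool — a phenotype-cluster
#' label (specific cells land in `cfg$enrichment_target` with probability
#' `cfg$enrichment_prob`; other assignments follow `cfg$cluster_props`),
#' and QC fields of which a configurable fraction violates each QC rule.
#' Cells of one clonotype always share the same ground-truth specificity.
#'
#' @param cfg a [sim_config()].
#' @param n_cells number of cells.
#' @param specific_tcrs epitope-specific clonotype pool.
#' @param patient_id patient identifier for all cells.
#' @param n_background_clones size of the background clonotype pool.
#' @param n_specific_clones expanded specific clonotypes to use.
#' @param qc_fail named violation fractions for `pct_mito`, `umi_low`,
#'   `umi_high`, `genes_low`, `genes_high`, `multi_trb`, `no_trb`
#'   (defaults 0).
#' @param alpha_chain_prob probability a clonotype has a paired CDR3-alpha.
#' @return Data frame of cells: `barcode`, `patient_id`, `cdr3b`, `v_gene`,
#'   `cdr3a`, `cluster_label`, QC fields, and logical `truth_specific`.
#' @export
generate_sc_cohort <- function(cfg, n_cells, specific_tcrs,
                               patient_id = "P1",
                               n_background_clones = max(50L, n_cells %/% 4L),
                               n_specific_clones = 5L,
                               qc_fail = c(pct_mito = 0, umi_low = 0,
                                           umi_high = 0, genes_low = 0,
                                           genes_high = 0, multi_trb = 0,
                                           no_trb = 0),
                               alpha_chain_prob = 0.8) {
  stopifnot(inherits(cfg, "sim_config"))
  vocab <- names(cfg$cluster_props)
  if (!length(vocab)) stop("empty cluster vocabulary")
  if (cfg$spike_frequency > 0 &&
      (is.null(specific_tcrs) || !nrow(specific_tcrs))) {
    stop("specific_tcrs required when spike_frequency > 0")
  }
  fail <- function(nm) if (nm %in% names(qc_fail)) qc_fail[[nm]] else 0
  withr::with_seed(cfg$seed, {
    bg_pool <- r_background(cfg, n_background_clones, patient_id, "background")
    bg_pool$cdr3a <- ifelse(stats::runif(n_background_clones) < alpha_chain_prob,
                            r_cdr3(cfg, n_background_clones), NA_character_)
    k <- min(n_specific_clones, nrow(specific_tcrs))
    sp_idx <- if (k > 0) sample.int(nrow(specific_tcrs), k) else integer(0)
    sp_pool <- specific_tcrs[sp_idx, , drop = FALSE]
    if (k > 0 && is.null(sp_pool$cdr3a)) {
      sp_pool$cdr3a <- ifelse(stats::runif(k) < alpha_chain_prob,
                              r_cdr3(cfg, k), NA_character_)
    }
    is_spec <- stats::runif(n_cells) < cfg$spike_frequency & k > 0
    zipf_w <- function(n) seq_len(n)^(-cfg$clone_size_alpha / 2)
    clone_bg <- sample.int(n_background_clones, n_cells, replace = TRUE,
                           prob = zipf_w(n_background_clones))
    clone_sp <- if (k > 0) {
      sample.int(k, n_cells, replace = TRUE, prob = zipf_w(k))
    } else rep(1L, n_cells)
    cdr3b <- ifelse(is_spec, sp_pool$cdr3b[clone_sp], bg_pool$cdr3b[clone_bg])
    v_gene <- ifelse(is_spec, sp_pool$v_gene[clone_sp],
                     bg_pool$v_gene[clone_bg])
    cdr3a <- ifelse(is_spec, sp_pool$cdr3a[clone_sp], bg_pool$cdr3a[clone_bg])
    # cluster labels
    other <- setdiff(vocab, cfg$enrichment_target)
    other_p <- cfg$cluster_props[other] / sum(cfg$cluster_props[other])
    cluster <- sample(vocab, n_cells, replace = TRUE,
                      prob = cfg$cluster_props)
    n_sp <- sum(is_spec)
    if (n_sp > 0) {
      to_target <- stats::runif(n_sp) < cfg$enrichment_prob
      cl_sp <- character(n_sp)
      cl_sp[to_target] <- cfg$enrichment_target
      cl_sp[!to_target] <- sample(other, sum(!to_target), replace = TRUE,
                                  prob = other_p)
      cluster[is_spec] <- cl_sp
    }
    # QC fields: passing baseline, then rule-specific violations
    pct_mito <- stats::runif(n_cells, 0, 9.5)
    umi <- as.integer(round(stats::runif(n_cells, 2000, 60000)))
    genes <- as.integer(round(stats::runif(n_cells, 900, 6500)))
    n_trb <- rep(1L, n_cells)
    n_tra <- as.integer(!is.na(cdr3a))
    viol <- function(p) stats::runif(n_cells) < p
    v1 <- viol(fail("pct_mito")); pct_mito[v1] <- stats::runif(sum(v1), 10.5, 40)
    v2 <- viol(fail("umi_low")); umi[v2] <- as.integer(stats::runif(sum(v2), 0, 1499))
    v3 <- viol(fail("umi_high")); umi[v3] <- as.integer(stats::runif(sum(v3), 70001, 120000))
    v4 <- viol(fail("genes_low")); genes[v4] <- as.integer(stats::runif(sum(v4), 0, 799))
    v5 <- viol(fail("genes_high")); genes[v5] <- as.integer(stats::runif(sum(v5), 7001, 12000))
    v6 <- viol(fail("multi_trb")); n_trb[v6] <- 2L
    v7 <- viol(fail("no_trb")); n_trb[v7] <- 0L
    data.frame(barcode = sprintf("%s-cell%05d", patient_id, seq_len(n_cells)),
               patient_id = patient_id,
               cdr3b = cdr3b, v_gene = v_gene, cdr3a = cdr3a,
               cluster_label = cluster,
               pct_mito = pct_mito, umi_count = umi, gene_count = genes,
               n_trb = n_trb, n_tra = n_tra,
               truth_specific = is_spec,
               stringsAsFactors = FALSE)
  })
}
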