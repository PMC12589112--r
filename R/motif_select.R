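#' Parameters for motif-based training-repertoire selection
#'
#' Controls the GLIPH2-style selection of epitope-specific TCRs: local
#' CDR3-beta motif enrichment against a reference repertoire plus global
#' Hamming-distance similarity. A motif is reported when it occurs in at
#' least `kmer_min_depth` query sequences, its one-sided Fisher p-value
#' against the reference is at most `local_min_pvalue`, and its
#' observed-vs-expected fold enrichment is at least `local_min_ove`.
#' Motif extraction and Hamming comparison operate on the CDR3 interior,
#' excluding the first `trim_left` and last `trim_right` residues (the
#' conserved junction ends contribute little specificity information).
#'
#' @param k_min,k_max inclusive k-mer length range (within 2..8; default 3-5).
#' @param local_min_pvalue maximum one-sided Fisher p (default 1e-4).
#' @param kmer_min_depth minimum number of query sequences containing the
#'   motif (default 5).
#' @param local_min_ove minimum fold enrichment (default 1000).
#' @param trim_left,trim_right residues excluded from each CDR3 end
#'   (default 3 and 2).
#' @param max_global_hamming maximum interior Hamming distance for a global
#'   similarity edge (default 1).
#' @return A list of class `"motif_params"`.
#' @export
motif_params <- function(k_min = 3L, k_max = 5L, local_min_pvalue = 1e-4,
                         kmer_min_depth = 5L, local_min_ove = 1000,
                         trim_left = 3L, trim_right = 2L,
                         max_global_hamming = 1L) {
  stopifnot(k_min >= 2, k_max <= 8, k_min <= k_max,
            local_min_pvalue > 0, kmer_min_depth >= 1, local_min_ove > 0,
            trim_left >= 0, trim_right >= 0, max_global_hamming >= 0)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 local_min_pvalue = local_min_pvalue,
                 kmer_min_depth = as.integer(kmer_min_depth),
                 local_min_ove = local_min_ove,
                 trim_left = as.integer(trim_left),
                 trim_right = as.integer(trim_right),
                 max_global_hamming = as.integer(max_global_hamming)),
            class = "motif_params")
}

# CDR3 interior after end-trimming; "" when the sequence is too short
trim_interior <- function(x, params) {
  out <- substr(x, params$trim_left + 1L, nchar(x) - params$trim_right)
  out[nchar(x) <= params$trim_left + params$trim_right] <- ""
  out
}

#' Extract local motifs from one CDR3-beta
#'
#' Enumerates all contiguous k-mers (k in the configured range) of the
#' trimmed CDR3 interior, plus discontinuous patterns: each contiguous
#' k-mer with exactly one non-terminal position replaced by the wildcard
#' `.`. Sequences whose interior is shorter than `k_min` yield an empty
#' set.
#'
#' @param cdr3b a CDR3-beta amino-acid string.
#' @param params a [motif_params()] object.
#' @return Character vector (multiset) of pattern strings.
#' @export
extract_local_motifs <- function(cdr3b, params = motif_params()) {
  interior <- trim_interior(cdr3b, params)
  n <- nchar(interior)
  if (n < params$k_min) return(character(0))
  out <- character(0)
  for (k in params$k_min:params$k_max) {
    if (n < k) break
    starts <- seq_len(n - k + 1L)
    kmers <- substring(interior, starts, starts + k - 1L)
    out <- c(out, kmers)
    if (k < 3L) next
    for (j in 2:(k - 1L)) {
      out <- c(out, paste0(substr(kmers, 1L, j - 1L), ".",
                           substring(kmers, j + 1L)))
    }
  }
  out
}

# number of sequences containing each pattern at least once
# (sequence-level counting: one sequence contributes one count per pattern)
motif_seq_counts <- function(seqs, params) {
  interiors <- trim_interior(seqs, params)
  len <- nchar(interiors)
  idx_l <- list(); pat_l <- list()
  for (k in params$k_min:params$k_max) {
    max_start <- max(len) - k + 1L
    if (max_start < 1L) next
    for (i in seq_len(max_start)) {
      ok <- which(len >= i + k - 1L)
      if (!length(ok)) next
      km <- substr(interiors[ok], i, i + k - 1L)
      idx_l[[length(idx_l) + 1L]] <- ok
      pat_l[[length(pat_l) + 1L]] <- km
      if (k < 3L) next
      for (j in 2:(k - 1L)) {
        idx_l[[length(idx_l) + 1L]] <- ok
        pat_l[[length(pat_l) + 1L]] <- paste0(substr(km, 1L, j - 1L), ".",
                                              substring(km, j + 1L))
      }
    }
  }
  if (!length(pat_l)) return(integer(0))
  dt <- unique(data.table::data.table(seq = unlist(idx_l),
                                      pat = unlist(pat_l)))
  cnt <- dt[, list(n = .N), by = "pat"]
  stats::setNames(cnt$n, cnt$pat)
}

#' Precompute reference motif counts
#'
#' Tabulates, once, how many reference sequences contain each local
#' pattern. Reuse the returned object across [motif_enrichment()] calls
#' against the same reference; large naive reference repertoires are the
#' expensive part of enrichment screening.
#'
#' @param reference character vector of reference CDR3-beta sequences.
#' @param params a [motif_params()] object (must match the one used for the
#'   query).
#' @return An object of class `"motif_reference"`.
#' @export
reference_motif_counts <- function(reference, params = motif_params()) {
  if (!length(reference)) stop("reference must be nonempty")
  structure(list(counts = motif_seq_counts(reference, params),
                 n = length(reference),
                 params = params),
            class = "motif_reference")
}

# vectorized one-sided (enrichment) Fisher exact p for the 2x2 table
# [[q, Q-q], [r, R-r]]: hypergeometric upper tail P(X >= q)
fisher_p_enrichment <- function(q, Q, r, R) {
  stats::phyper(q - 1, q + r, Q + R - q - r, Q, lower.tail = FALSE)
}

#' Motif enrichment of a query set against a reference repertoire
#'
#' Counts, for every local pattern of the query set, the number of query
#' and reference sequences containing it, and reports patterns passing the
#' depth, one-sided Fisher exact p-value, and fold-enrichment thresholds of
#' `params`. Fold enrichment is the ratio of containment rates,
#' `(q/Q) / (max(r, 0.5)/R)`; the 0.5 pseudocount only applies to patterns
#' absent from the reference so their fold stays finite.
#'
#' @param query character vector of query CDR3-beta sequences.
#' @param reference character vector of reference sequences, or a
#'   precomputed [reference_motif_counts()] object.
#' @param params a [motif_params()] object.
#' @return Data frame (motif, query_count, ref_count, fold, p) sorted by
#'   p then decreasing fold, with attributes `query_size` and `ref_size`.
#' @export
motif_enrichment <- function(query, reference, params = motif_params()) {
  if (!length(query)) stop("query must be nonempty")
  if (inherits(reference, "motif_reference")) {
    ref <- reference
  } else {
    ref <- reference_motif_counts(reference, params)
  }
  Q <- length(query); R <- ref$n
  if (R < 10 * Q) {
    warning("reference is less than 10x the query size; ",
            "enrichment estimates may be unstable")
  }
  qc <- motif_seq_counts(query, params)
  qc <- qc[qc >= params$kmer_min_depth]
  if (!length(qc)) {
    out <- data.frame(motif = character(0), query_count = integer(0),
                      ref_count = integer(0), fold = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  } else {
    rc <- ref$counts[names(qc)]
    rc[is.na(rc)] <- 0L
    # product form keeps exact-boundary folds (e.g. 1000) free of
    # floating-point drift
    fold <- (qc * R) / (pmax(rc, 0.5) * Q)
    p <- fisher_p_enrichment(qc, Q, rc, R)
    keep <- p <= params$local_min_pvalue & fold >= params$local_min_ove
    out <- data.frame(motif = names(qc)[keep],
                      query_count = as.integer(qc[keep]),
                      ref_count = as.integer(rc[keep]),
                      fold = unname(fold[keep]), p = unname(p[keep]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$p, -out$fold, out$motif), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "query_size") <- Q
  attr(out, "ref_size") <- R
  out
}

#' Global similarity edges between TCRs
#'
#' An undirected edge joins two TCRs iff their CDR3-beta sequences have the
#' same length, they use the same V-beta gene, and the Hamming distance over
#' the trimmed CDR3 interior is at most `max_global_hamming`.
#'
#' @param tcrs clonotype data frame with `cdr3b` and `v_gene`.
#' @param params a [motif_params()] object.
#' @return Data frame of edges (`i`, `j`) as row indices into `tcrs`, i < j.
#' @export
global_similarity_pairs <- function(tcrs, params = motif_params()) {
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  empty <- data.frame(i = integer(0), j = integer(0))
  if (nrow(tcrs) < 2) return(empty)
  interiors <- trim_interior(tcrs$cdr3b, params)
  grp <- split(seq_len(nrow(tcrs)),
               paste(tcrs$v_gene, nchar(tcrs$cdr3b), sep = "\r"))
  res_i <- integer(0); res_j <- integer(0)
  for (g in grp) {
    if (length(g) < 2 || nchar(interiors[g[1]]) < 1L) next
    chars <- do.call(rbind, strsplit(interiors[g], ""))
    m <- length(g)
    for (a in seq_len(m - 1L)) {
      rest <- (a + 1L):m
      d <- rowSums(chars[rest, , drop = FALSE] !=
                     matrix(chars[a, ], length(rest), ncol(chars), byrow = TRUE))
      hit <- rest[d <= params$max_global_hamming]
      if (length(hit)) {
        res_i <- c(res_i, rep.int(g[a], length(hit)))
        res_j <- c(res_j, g[hit])
      }
    }
  }
  out <- data.frame(i = pmin(res_i, res_j), j = pmax(res_i, res_j))
  out[order(out$i, out$j), , drop = FALSE]
}

# union-find connected components over edges on n nodes
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

#' Build motif and similarity clusters
#'
#' Local clusters: for each enriched motif, all TCRs whose trimmed CDR3
#' interior matches the pattern. Global clusters: connected components of
#' the global-similarity edge set. A TCR may belong to several clusters;
#' singleton clusters are dropped.
#'
#' @param tcrs clonotype data frame.
#' @param enriched_motifs output of [motif_enrichment()].
#' @param edges output of [global_similarity_pairs()].
#' @param params a [motif_params()] object.
#' @return Membership data frame (`cluster_id`, `kind`, `motif`, `idx`,
#'   `cdr3b`, `v_gene`, `source_label`), one row per (cluster, member).
#' @export
build_clusters <- function(tcrs, enriched_motifs, edges,
                           params = motif_params()) {
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  interiors <- trim_interior(tcrs$cdr3b, params)
  src <- tcrs$source_label %||% rep(NA_character_, nrow(tcrs))
  rows <- list()
  for (m in enriched_motifs$motif) {
    members <- which(grepl(m, interiors, fixed = !grepl(".", m, fixed = TRUE)))
    if (length(members) < 2) next
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = paste0("local:", m), kind = "local", motif = m,
      idx = members, stringsAsFactors = FALSE)
  }
  if (nrow(edges)) {
    comp <- connected_components(nrow(tcrs), edges)
    touched <- unique(c(edges$i, edges$j))
    for (cid in unique(comp[touched])) {
      members <- which(comp == cid)
      if (length(members) < 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = paste0("global:", cid), kind = "global",
        motif = NA_character_, idx = members, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), kind = character(0),
                      motif = character(0), idx = integer(0),
                      cdr3b = character(0), v_gene = character(0),
                      source_label = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$cdr3b <- tcrs$cdr3b[out$idx]
  out$v_gene <- tcrs$v_gene[out$idx]
  out$source_label <- src[out$idx]
  rownames(out) <- NULL
  out
}

#' Select a training repertoire from clusters
#'
#' Takes the union of members over all clusters of size at least
#' `min_cluster_size`. Each selected TCR appears once, annotated with its
#' source label so the composition of the selected repertoire (e.g.
#' healthy / patient / published) can be reported.
#'
#' @param clusters membership table from [build_clusters()].
#' @param tcrs the clonotype data frame the clusters index into.
#' @param min_cluster_size minimum cluster size (default 2).
#' @return Data frame of selected TCRs (rows of `tcrs`, original order).
#' @export
select_training_repertoire <- function(clusters, tcrs, min_cluster_size = 2L) {
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  sizes <- table(clusters$cluster_id)
  good <- names(sizes)[sizes >= min_cluster_size]
  idx <- sort(unique(clusters$idx[clusters$cluster_id %in% good]))
  if (!length(idx)) {
    warning("no cluster reaches min_cluster_size = ", min_cluster_size,
            "; selection is empty")
    return(tcrs[integer(0), , drop = FALSE])
  }
  out <- tcrs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end training-repertoire selection
#'
#' Convenience wrapper chaining [motif_enrichment()],
#' [global_similarity_pairs()], [build_clusters()] and
#' [select_training_repertoire()].
#'
#' @param tcrs query clonotype data frame (the candidate epitope-specific
#'   TCRs).
#' @param reference reference sequences or [reference_motif_counts()].
#' @param params a [motif_params()] object.
#' @param min_cluster_size minimum cluster size for selection.
#' @return List with `selected` (data frame), `motifs` (enrichment table)
#'   and `clusters` (membership table).
#' @export
select_epitope_repertoire <- function(tcrs, reference,
                                      params = motif_params(),
                                      min_cluster_size = 2L) {
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  motifs <- motif_enrichment(tcrs$cdr3b, reference, params)
  edges <- global_similarity_pairs(tcrs, params)
  clusters <- build_clusters(tcrs, motifs, edges, params)
  selected <- if (nrow(clusters)) {
    select_training_repertoire(clusters, tcrs, min_cluster_size)
  } else {
    tcrs[integer(0), , drop = FALSE]
  }
  list(selected = selected, motifs = motifs, clusters = clusters)
}
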