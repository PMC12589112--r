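#' Construct a TCR repertoire
#'
#' A repertoire is one sample's multiset of TCR clonotypes together with its
#' total read mass. It is the unit of downsampling and of frequency
#' computation. Clonotype tables are plain data frames with columns `cdr3b`,
#' `v_gene`, `count` and optionally `cdr3a`, `va_gene`, `sample_id`,
#' `source_label`; missing optional columns are filled with `NA`.
#'
#' @param clonotypes data frame of clonotypes (one row per clonotype).
#' @param sample_id sample identifier.
#' @param cohort optional cohort name.
#' @return An object of class `"repertoire"`: a list with elements
#'   `sample_id`, `cohort`, `clonotypes` and `total_reads` (sum of counts).
#' @export
new_repertoire <- function(clonotypes, sample_id, cohort = NA_character_) {
  clonotypes <- as_clonotypes(clonotypes)
  if (nrow(clonotypes) && any(clonotypes$count < 0)) {
    stop("clonotype counts must be non-negative")
  }
  structure(
    list(sample_id = as.character(sample_id),
         cohort = as.character(cohort),
         clonotypes = clonotypes,
         total_reads = as.integer(sum(clonotypes$count))),
    class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> sample %s%s: %d clonotypes, %d reads\n",
              x$sample_id,
              if (is.na(x$cohort)) "" else paste0(" (", x$cohort, ")"),
              nrow(x$clonotypes), x$total_reads))
  invisible(x)
}

# normalize a clonotype data frame to the canonical column set
as_clonotypes <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(cdr3b = character(0), v_gene = character(0),
                      cdr3a = character(0), va_gene = character(0),
                      count = integer(0), sample_id = character(0),
                      source_label = character(0),
                      stringsAsFactors = FALSE))
  }
  need <- c("cdr3b", "v_gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clonotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$count)) df$count <- 1L
  for (opt in c("cdr3a", "va_gene", "sample_id", "source_label")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  }
  df$cdr3b <- as.character(df$cdr3b)
  df$v_gene <- as.character(df$v_gene)
  df$count <- as.integer(round(df$count))
  rownames(df) <- NULL
  df[, c("cdr3b", "v_gene", "cdr3a", "va_gene", "count", "sample_id",
         "source_label")]
}

#' Read a bulk TCR-beta repertoire
#'
#' Reads an AIRR Rearrangement TSV (columns `junction_aa`, `v_call`,
#' `duplicate_count`) or an immunoSEQ-style TSV (`aminoAcid`/
#' `cdr3_amino_acid`, `vGeneName`/`v_gene`, and a count-like column).
#' Nonproductive rows are dropped: explicit `productive`/`sequenceStatus`
#' flags when present, plus any CDR3 containing a stop codon `*`, a frame
#' marker `_`, or characters outside the 20-letter amino-acid alphabet.
#'
#' @param path path to a tab-separated file.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param sample_id sample identifier; defaults to the file name.
#' @param cohort,source_label optional annotations carried onto the
#'   clonotype table.
#' @return A [new_repertoire()] object.
#' @export
read_bulk_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                                 sample_id = NULL, cohort = NA_character_,
                                 source_label = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!nrow(tab)) stop("empty repertoire file: ", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  if (dialect == "airr") {
    miss <- setdiff(c("junction_aa", "v_call", "duplicate_count"), names(tab))
    if (length(miss)) {
      stop("missing required AIRR column(s): ", paste(miss, collapse = ", "))
    }
    cdr3 <- as.character(tab$junction_aa)
    v <- as.character(tab$v_call)
    cnt <- tab$duplicate_count
    flagged <- if ("productive" %in% names(tab)) {
      tolower(as.character(tab$productive)) %in% c("f", "false")
    } else FALSE
  } else {
    aa_col <- intersect(c("aminoAcid", "cdr3_amino_acid"), names(tab))[1]
    v_col <- intersect(c("vGeneName", "v_gene"), names(tab))[1]
    cnt_col <- intersect(c("count (templates/reads)", "templates", "count",
                           "reads"), names(tab))[1]
    if (is.na(aa_col)) stop("missing required immunoSEQ column: aminoAcid/cdr3_amino_acid")
    if (is.na(v_col)) stop("missing required immunoSEQ column: vGeneName/v_gene")
    if (is.na(cnt_col)) stop("missing required immunoSEQ count column (templates/count/reads)")
    cdr3 <- as.character(tab[[aa_col]])
    v <- as.character(tab[[v_col]])
    cnt <- tab[[cnt_col]]
    flagged <- if ("sequenceStatus" %in% names(tab)) {
      tab$sequenceStatus != "In"
    } else FALSE
  }

  keep <- !flagged & is_valid_aa(cdr3)
  df <- data.frame(cdr3b = cdr3[keep], v_gene = v[keep],
                   count = as.integer(round(cnt[keep])),
                   sample_id = sample_id, source_label = source_label,
                   stringsAsFactors = FALSE)
  new_repertoire(df, sample_id = sample_id, cohort = cohort)
}

#' Write a repertoire as AIRR Rearrangement TSV
#'
#' Inverse of [read_bulk_repertoire()] for the AIRR dialect; writing then
#' re-reading reproduces the clonotype multiset.
#'
#' @param rep a [new_repertoire()] object.
#' @param path output path.
#' @export
write_repertoire_airr <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  out <- data.frame(junction_aa = rep$clonotypes$cdr3b,
                    v_call = rep$clonotypes$v_gene,
                    duplicate_count = rep$clonotypes$count,
                    productive = "T",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-cell V(D)J contigs
#'
#' Reads a 10x `filtered_contig_annotations.csv`-style table and keeps
#' productive TRA/TRB contigs. Contigs on other chains (e.g. IGH) are
#' skipped with a warning.
#'
#' @param path CSV with columns `barcode`, `chain`, `cdr3`, `v_gene`,
#'   `productive`.
#' @return Data frame with columns `barcode`, `chain`, `cdr3_aa`, `v_gene`.
#' @export
read_sc_contigs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("barcode", "chain", "cdr3", "v_gene", "productive"),
                  names(tab))
  if (length(miss)) {
    stop("malformed contig CSV, missing column(s): ",
         paste(miss, collapse = ", "))
  }
  prod <- tolower(as.character(tab$productive)) %in% c("true", "t")
  tab <- tab[prod, , drop = FALSE]
  bad <- !tab$chain %in% c("TRA", "TRB")
  if (any(bad)) {
    warning(sum(bad), " contig(s) on unknown chain(s) skipped: ",
            paste(unique(tab$chain[bad]), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  data.frame(barcode = as.character(tab$barcode),
             chain = as.character(tab$chain),
             cdr3_aa = as.character(tab$cdr3),
             v_gene = as.character(tab$v_gene),
             stringsAsFactors = FALSE)
}

#' Filter cells on quality-control thresholds
#'
#' Removal rules are strict inequalities as printed in standard single-cell
#' QC: a cell is removed iff mitochondrial percentage > 10, UMI count
#' < 1500 or > 70000, detected gene count < 800 or > 7000, or it does not
#' carry exactly one productive TCR-beta chain. Boundary values are kept.
#'
#' @param records data frame with columns `barcode`, `pct_mito`,
#'   `umi_count`, `gene_count`, `n_trb`.
#' @return Character vector of kept barcodes (possibly empty).
#' @export
cell_qc_filter <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records)) return(character(0))
  miss <- setdiff(c("barcode", "pct_mito", "umi_count", "gene_count", "n_trb"),
                  names(records))
  if (length(miss)) {
    stop("QC table is missing column(s): ", paste(miss, collapse = ", "))
  }
  keep <- records$pct_mito <= 10 &
    records$umi_count >= 1500 & records$umi_count <= 70000 &
    records$gene_count >= 800 & records$gene_count <= 7000 &
    records$n_trb == 1
  as.character(records$barcode[keep])
}

#' Aggregate single-cell contigs into clonotypes
#'
#' Groups cells by (CDR3-beta, V-beta, CDR3-alpha-or-absent); the clonotype
#' count is the number of cells. Every barcode must carry exactly one
#' productive TRB (apply [cell_qc_filter()] first); when several TRA contigs
#' exist for a barcode the first is used. The display label uses the
#' `CDR3a_CDR3b` pairing convention with `NA` for a missing alpha chain.
#'
#' @param cells contig records as returned by [read_sc_contigs()].
#' @param sample_id sample identifier.
#' @param cohort optional cohort name.
#' @return A [new_repertoire()] whose clonotype table carries `cdr3a`,
#'   `va_gene` and a `pair_label` column.
#' @export
aggregate_clonotypes <- function(cells, sample_id, cohort = NA_character_) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!nrow(cells)) {
    rep <- new_repertoire(data.frame(cdr3b = character(0),
                                     v_gene = character(0)), sample_id, cohort)
    rep$clonotypes$pair_label <- character(0)
    return(rep)
  }
  trb <- cells[cells$chain == "TRB", , drop = FALSE]
  tra <- cells[cells$chain == "TRA", , drop = FALSE]
  multi <- names(which(table(trb$barcode) > 1L))
  if (length(multi)) {
    stop("barcode(s) with more than one productive TRB: ",
         paste(utils::head(multi, 5), collapse = ", "))
  }
  tra <- tra[!duplicated(tra$barcode), , drop = FALSE]
  m <- merge(trb[, c("barcode", "cdr3_aa", "v_gene")],
             tra[, c("barcode", "cdr3_aa", "v_gene")],
             by = "barcode", all.x = TRUE, suffixes = c("_b", "_a"))
  key <- paste(m$cdr3_aa_b, m$v_gene_b,
               ifelse(is.na(m$cdr3_aa_a), "<none>", m$cdr3_aa_a), sep = "\r")
  agg <- m[!duplicated(key), , drop = FALSE]
  agg$count <- as.integer(table(key)[key[!duplicated(key)]])
  df <- data.frame(cdr3b = agg$cdr3_aa_b, v_gene = agg$v_gene_b,
                   cdr3a = agg$cdr3_aa_a, va_gene = agg$v_gene_a,
                   count = agg$count, sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  rep <- new_repertoire(df, sample_id = sample_id, cohort = cohort)
  rep$clonotypes$pair_label <- paste0(
    ifelse(is.na(rep$clonotypes$cdr3a), "NA", rep$clonotypes$cdr3a), "_",
    rep$clonotypes$cdr3b)
  rep
}

#' Keep one record per unique CDR3-beta
#'
#' Retains the first occurrence (input order) of each distinct CDR3-beta
#' string; later duplicates are dropped. When dropped duplicates disagree on
#' the V gene a message reports how many conflicts were resolved in favor of
#' the first record. Idempotent.
#'
#' @param tcrs clonotype data frame (needs `cdr3b`; other columns carried).
#' @return The deduplicated data frame, input order preserved.
#' @export
dedup_unique_cdr3b <- function(tcrs) {
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  if (!nrow(tcrs)) return(tcrs)
  dup <- duplicated(tcrs$cdr3b)
  if (any(dup) && !is.null(tcrs$v_gene)) {
    first_v <- tcrs$v_gene[match(tcrs$cdr3b, tcrs$cdr3b)]
    n_conflict <- length(unique(tcrs$cdr3b[dup & tcrs$v_gene != first_v]))
    if (n_conflict > 0) {
      message("dedup_unique_cdr3b: ", n_conflict,
              " CDR3b sequence(s) had conflicting V genes; kept first occurrence")
    }
  }
  out <- tcrs[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove TCRs shared between two epitope repertoires
#'
#' Any key present in both inputs is removed from both, guarding against
#' cross-reactive leakage between training repertoires. The default key is
#' the CDR3-beta string alone (most conservative, matching a downstream
#' unique-CDR3-beta selection); `key = "cdr3b_v"` matches on the full
#' (CDR3-beta, V gene) clonotype.
#'
#' @param tcrs_a,tcrs_b clonotype data frames.
#' @param key `"cdr3b"` (default) or `"cdr3b_v"`.
#' @return List with elements `a`, `b` (filtered data frames) and `removed`
#'   (character vector of shared keys).
#' @export
remove_cross_epitope_overlap <- function(tcrs_a, tcrs_b,
                                         key = c("cdr3b", "cdr3b_v")) {
  key <- match.arg(key)
  tcrs_a <- as.data.frame(tcrs_a, stringsAsFactors = FALSE)
  tcrs_b <- as.data.frame(tcrs_b, stringsAsFactors = FALSE)
  if (!nrow(tcrs_a) || !nrow(tcrs_b)) stop("both inputs must be nonempty")
  mk <- function(df) {
    if (key == "cdr3b") df$cdr3b else paste(df$cdr3b, df$v_gene, sep = "|")
  }
  ka <- mk(tcrs_a); kb <- mk(tcrs_b)
  shared <- intersect(ka, kb)
  a <- tcrs_a[!ka %in% shared, , drop = FALSE]
  b <- tcrs_b[!kb %in% shared, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  list(a = a, b = b, removed = shared)
}

# one multivariate hypergeometric draw: n reads without replacement from
# the read multiset given by counts
rmvhyper_once <- function(counts, n) {
  total <- sum(counts)
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (n <= 0L) break
    total <- total - counts[i]
    out[i] <- stats::rhyper(1L, counts[i], total, n)
    n <- n - out[i]
  }
  out
}

#' Downsample a repertoire to a fixed read count
#'
#' Draws `n` reads without replacement from the repertoire's read multiset
#' (a multivariate hypergeometric draw over clonotypes), so that diversity
#' and clonality statistics are comparable across samples. Clonotypes
#' reduced to zero are dropped. A repertoire already at or below `n` reads
#' is returned unchanged; no upsampling is ever performed.
#'
#' @param rep a [new_repertoire()] object.
#' @param n target read count (default 40000).
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return A downsampled [new_repertoire()].
#' @export
downsample_reads <- function(rep, n = 40000, seed) {
  stopifnot(inherits(rep, "repertoire"))
  if (length(n) != 1 || is.na(n) || n <= 0) stop("n must be a positive integer")
  n <- as.integer(n)
  if (rep$total_reads <= n) return(rep)
  counts <- withr::with_seed(seed, rmvhyper_once(rep$clonotypes$count, n))
  keep <- counts > 0L
  cl <- rep$clonotypes[keep, , drop = FALSE]
  cl$count <- counts[keep]
  rownames(cl) <- NULL
  out <- new_repertoire(cl, sample_id = rep$sample_id, cohort = rep$cohort)
  # carry extra columns such as pair_label through the draw
  for (e in setdiff(names(cl), names(out$clonotypes))) {
    out$clonotypes[[e]] <- cl[[e]]
  }
  out
}
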