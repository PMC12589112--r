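#' Low-dimensional amino-acid embedding from BLOSUM62
#'
#' Classical multidimensional scaling of the BLOSUM62 similarity matrix:
#' the 20x20 score matrix is double-centered and eigendecomposed, and each
#' residue is mapped to its coordinates on the top `d` components scaled by
#' root-eigenvalues. Euclidean distance between embeddings then reflects
#' substitution dissimilarity (e.g. L is closer to I than to D). Signs are
#' fixed deterministically.
#'
#' @param d embedding dimension per residue (1..20, default 4).
#' @return A 20 x `d` matrix with rows named by one-letter residue codes.
#' @export
aa_embedding <- function(d = 4L) {
  stopifnot(d >= 1, d <= 20)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA20, AA20]
  H <- diag(20) - matrix(1 / 20, 20, 20)
  C <- H %*% B %*% H
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  E <- eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(d)], 0)), d)
  for (j in seq_len(d)) {
    lead <- which(abs(E[, j]) > 1e-12)[1]
    if (!is.na(lead) && E[lead, j] < 0) E[, j] <- -E[, j]
  }
  rownames(E) <- AA20
  E
}

# V-beta family from an IMGT-style gene name: "TRBV5-1*01" -> "TRBV5"
v_family <- function(v_gene) {
  sub("^([A-Z]+[0-9]+).*$", "\\1", as.character(v_gene))
}

#' Encoding configuration for TCR feature vectors
#'
#' Fixes how a TCR is turned into a numeric vector: each CDR3-beta residue
#' maps to a `embed_dim`-dimensional [aa_embedding()] row; the CDR3 is
#' center-gap aligned to `max_len` positions (first half anchored at the
#' start, second half at the end, all-zero gap vectors in the middle); and,
#' when `use_v_features` is on, a V-gene feature block is appended. If a
#' germline CDR1/CDR2 lookup is supplied via `v_cdr_table` those loop
#' sequences are embedded like the CDR3; otherwise the V block is a one-hot
#' encoding of the V-beta family over the families seen at configuration
#' time (genes from unseen families encode to zeros with a warning).
#'
#' @param max_len aligned CDR3 length; must cover the longest training CDR3.
#' @param embed_dim embedding dimension per residue (default 4).
#' @param use_v_features include the V-gene block? (default TRUE)
#' @param v_genes V genes observed in training (used to fix the family
#'   vocabulary); required when `use_v_features` and no `v_cdr_table`.
#' @param v_cdr_table optional data frame (`v_gene`, `cdr1`, `cdr2`) of
#'   germline loop sequences.
#' @return A list of class `"encoding_config"`.
#' @export
encoding_config <- function(max_len, embed_dim = 4L, use_v_features = TRUE,
                            v_genes = NULL, v_cdr_table = NULL) {
  stopifnot(max_len >= 1)
  E <- aa_embedding(embed_dim)
  cfg <- list(max_len = as.integer(max_len),
              embed_dim = as.integer(embed_dim),
              use_v_features = isTRUE(use_v_features),
              embedding = E,
              v_families = character(0),
              v_cdr_table = NULL,
              v_cdr_len = 0L)
  if (cfg$use_v_features) {
    if (!is.null(v_cdr_table)) {
      v_cdr_table <- as.data.frame(v_cdr_table, stringsAsFactors = FALSE)
      stopifnot(all(c("v_gene", "cdr1", "cdr2") %in% names(v_cdr_table)))
      cfg$v_cdr_table <- v_cdr_table
      cfg$v_cdr_len <- max(nchar(v_cdr_table$cdr1) + nchar(v_cdr_table$cdr2))
    } else {
      if (is.null(v_genes)) stop("v_genes needed to fix the V-family vocabulary")
      cfg$v_families <- sort(unique(v_family(v_genes)))
    }
  }
  class(cfg) <- "encoding_config"
  cfg
}

# total feature-vector length under a config
encoding_width <- function(cfg) {
  w <- cfg$max_len * cfg$embed_dim
  if (cfg$use_v_features) {
    w <- w + if (!is.null(cfg$v_cdr_table)) {
      cfg$v_cdr_len * cfg$embed_dim
    } else {
      length(cfg$v_families)
    }
  }
  w
}

# write an amino-acid string block, center-gap aligned to block_len slots,
# into columns of X for the given rows; chars is a list of char vectors
fill_aligned_block <- function(X, rows, seqs, block_len, E, d, col_offset,
                               what) {
  len <- nchar(seqs)
  for (L in unique(len)) {
    idx <- rows[len == L]
    if (L == 0L) next
    chars <- do.call(rbind, strsplit(seqs[len == L], ""))
    code <- match(chars, rownames(E))
    if (anyNA(code)) {
      bad <- unique(chars[is.na(code)])
      stop("unknown amino-acid character '", bad[1], "' in ", what)
    }
    code <- matrix(code, nrow = length(idx))
    left <- ceiling(L / 2)
    for (t in seq_len(L)) {
      slot <- if (t <= left) t else block_len - (L - t)
      cols <- col_offset + (slot - 1L) * d + seq_len(d)
      X[idx, cols] <- E[code[, t], , drop = FALSE]
    }
  }
  X
}

#' Encode TCRs as feature vectors
#'
#' Vectorized encoder applying the [encoding_config()] rules. CDR3s longer
#' than `max_len` cannot be encoded; their rows are flagged (all-zero) so
#' callers can assign them a default score instead of aborting a cohort
#' scan.
#'
#' @param cdr3b character vector of CDR3-beta sequences.
#' @param v_gene character vector of V genes (recycled if length 1).
#' @param cfg an [encoding_config()].
#' @return List with `X` (numeric matrix, one row per TCR) and `ok`
#'   (logical; FALSE for unencodable over-length sequences).
#' @export
encode_tcrs <- function(cdr3b, v_gene = NA_character_, cfg) {
  stopifnot(inherits(cfg, "encoding_config"))
  n <- length(cdr3b)
  v_gene <- rep_len(as.character(v_gene), n)
  d <- cfg$embed_dim
  X <- matrix(0, n, encoding_width(cfg))
  len <- nchar(cdr3b)
  ok <- !is.na(cdr3b) & len >= 1L & len <= cfg$max_len
  rows <- which(ok)
  if (length(rows)) {
    X <- fill_aligned_block(X, rows, cdr3b[rows], cfg$max_len,
                            cfg$embedding, d, 0L, "CDR3")
  }
  if (cfg$use_v_features && length(rows)) {
    off <- cfg$max_len * d
    if (!is.null(cfg$v_cdr_table)) {
      loop <- paste0(cfg$v_cdr_table$cdr1, cfg$v_cdr_table$cdr2)
      hit <- match(v_gene[rows], cfg$v_cdr_table$v_gene)
      known <- !is.na(hit)
      if (any(!known)) {
        warning(sum(!known), " TCR(s) with V gene absent from v_cdr_table; ",
                "V block left at zero")
      }
      if (any(known)) {
        X <- fill_aligned_block(X, rows[known], loop[hit[known]],
                                cfg$v_cdr_len, cfg$embedding, d, off,
                                "germline CDR1/CDR2")
      }
    } else {
      fam <- v_family(v_gene[rows])
      j <- match(fam, cfg$v_families)
      if (anyNA(j)) {
        warning(sum(is.na(j)), " TCR(s) from V families outside the ",
                "training vocabulary; V block left at zero")
      }
      hit <- !is.na(j)
      X[cbind(rows[hit], off + j[hit])] <- 1
    }
  }
  list(X = X, ok = ok)
}
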