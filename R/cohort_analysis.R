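#' Scores for a clonotype table under any scorer
#'
#' Generic scoring hook used by the cohort and single-cell layers, so a
#' trained [train_model()] classifier and a plain scoring function (e.g. a
#' ground-truth oracle in simulations) are interchangeable.
#'
#' @param model a `"tcrgp_model"` or a function taking a clonotype data
#'   frame and returning one score per row.
#' @param tcrs clonotype data frame.
#' @return Numeric scores in the same order as `tcrs`.
#' @export
tcr_scores <- function(model, tcrs) {
  if (inherits(model, "tcrgp_model")) {
    predict_scores(model, tcrs)
  } else if (is.function(model)) {
    model(tcrs)
  } else {
    stop("model must be a tcrgp_model or a scoring function")
  }
}

# decision threshold for a scorer: explicit argument wins, else the
# model's calibrated threshold
scorer_threshold <- function(model, threshold) {
  if (!is.null(threshold)) return(threshold)
  if (inherits(model, "tcrgp_model") && !is.na(model$threshold)) {
    return(model$threshold)
  }
  stop("no decision threshold: calibrate the model or pass `threshold`")
}

#' Predicted epitope-specific frequency in a repertoire
#'
#' Scores every clonotype and reports the read-weighted fraction predicted
#' specific: the sum of counts over clonotypes scoring strictly above the
#' threshold, divided by total reads. Clonotype and read tallies are
#' reported alongside. The repertoire should already be downsampled to the
#' cohort's common read depth so frequencies are comparable.
#'
#' @param rep a [new_repertoire()].
#' @param model a `"tcrgp_model"` or scoring function (see [tcr_scores()]).
#' @param epitope epitope label for the output row (defaults to the
#'   model's).
#' @param threshold optional decision threshold overriding the model's.
#' @return One-row data frame: `cohort`, `sample_id`, `epitope`,
#'   `frequency`, `n_specific_reads`, `n_specific_clonotypes`.
#' @export
predicted_frequency <- function(rep, model, epitope = NULL,
                                threshold = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  if (!nrow(rep$clonotypes) || rep$total_reads == 0L) {
    stop("empty repertoire: ", rep$sample_id)
  }
  thr <- scorer_threshold(model, threshold)
  epitope <- epitope %||%
    (if (inherits(model, "tcrgp_model")) model$epitope else NA_character_)
  s <- tcr_scores(model, rep$clonotypes)
  hit <- s > thr
  data.frame(cohort = rep$cohort, sample_id = rep$sample_id,
             epitope = as.character(epitope),
             frequency = sum(rep$clonotypes$count[hit]) / rep$total_reads,
             n_specific_reads = as.integer(sum(rep$clonotypes$count[hit])),
             n_specific_clonotypes = as.integer(sum(hit)),
             stringsAsFactors = FALSE)
}

#' Frequency table across a cohort and several models
#'
#' @param samples list of [new_repertoire()] objects.
#' @param models named list of models/scorers (names used as epitope
#'   labels when the model carries none).
#' @param threshold optional shared threshold (mainly for function
#'   scorers).
#' @return Data frame with one row per sample x epitope.
#' @export
cohort_frequency_table <- function(samples, models, threshold = NULL) {
  if (inherits(samples, "repertoire")) samples <- list(samples)
  rows <- list()
  for (rep in samples) {
    for (nm in names(models)) {
      rows[[length(rows) + 1L]] <-
        predicted_frequency(rep, models[[nm]], epitope = nm,
                            threshold = threshold)
    }
  }
  do.call(rbind, rows)
}

#' Simpson clonality of a clone-frequency vector
#'
#' Dominance statistic of the predicted-specific sub-repertoire
#' (renormalized to sum to one). The default is the square-root convention
#' `sqrt(sum(p_i^2))`, common in repertoire sequencing: 1 for a monoclonal
#' population and `n^(-1/2)` for `n` equal clones. `method = "simpson"`
#' returns the plain Simpson index `sum(p_i^2)`.
#'
#' @param frequencies nonnegative clone frequencies summing to 1 (within
#'   1e-9).
#' @param method `"sqrt"` (default) or `"simpson"`.
#' @return Score in (0, 1], or `NA` for an empty vector.
#' @export
simpson_clonality <- function(frequencies, method = c("sqrt", "simpson")) {
  method <- match.arg(method)
  if (!length(frequencies)) return(NA_real_)
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1; renormalize the sub-repertoire first")
  }
  s <- sum(frequencies^2)
  if (method == "sqrt") sqrt(s) else s
}

#' Clonality of the predicted-specific sub-repertoire
#'
#' Convenience helper: restricts a repertoire to clonotypes scoring above
#' the threshold, renormalizes their counts, and returns
#' [simpson_clonality()].
#'
#' @inheritParams predicted_frequency
#' @param method passed to [simpson_clonality()].
#' @return Clonality score, or `NA` when no clonotype is predicted
#'   specific.
#' @export
specific_clonality <- function(rep, model, threshold = NULL,
                               method = "sqrt") {
  thr <- scorer_threshold(model, threshold)
  s <- tcr_scores(model, rep$clonotypes)
  cnt <- rep$clonotypes$count[s > thr]
  if (!length(cnt) || sum(cnt) == 0) return(NA_real_)
  simpson_clonality(cnt / sum(cnt), method = method)
}

#' Compare epitope-specific frequencies between cohorts
#'
#' One-sided Mann-Whitney U test of each patient cohort against the healthy
#' cohort, per epitope. The exact null distribution is used when both
#' groups have at most 20 samples and there are no ties; otherwise the
#' normal approximation with tie correction. P-values are
#' Benjamini-Hochberg adjusted, by default jointly across all cohort x
#' epitope tests.
#'
#' @param freq frequency table from [cohort_frequency_table()] (columns
#'   `cohort`, `epitope`, `frequency`).
#' @param healthy_cohort name of the reference cohort.
#' @param alternative `"greater"` tests patient > healthy (the default,
#'   biologically motivated direction); `"less"` the reverse.
#' @param family BH family: `"joint"` (default) or `"per_epitope"`.
#' @return Data frame (`cohort`, `epitope`, `n_cohort`, `n_healthy`, `U`,
#'   `p`, `p_adj`).
#' @export
compare_cohorts <- function(freq, healthy_cohort,
                            alternative = c("greater", "less"),
                            family = c("joint", "per_epitope")) {
  alternative <- match.arg(alternative)
  family <- match.arg(family)
  freq <- as.data.frame(freq, stringsAsFactors = FALSE)
  if (!healthy_cohort %in% freq$cohort) {
    stop("healthy cohort not found in table: ", healthy_cohort)
  }
  rows <- list()
  for (ep in unique(freq$epitope)) {
    hx <- freq$frequency[freq$cohort == healthy_cohort & freq$epitope == ep]
    for (co in setdiff(unique(freq$cohort), healthy_cohort)) {
      px <- freq$frequency[freq$cohort == co & freq$epitope == ep]
      if (!length(px)) next
      if (length(px) < 3 || length(hx) < 3) {
        warning("fewer than 3 samples in ", co, " or ", healthy_cohort,
                " for ", ep)
      }
      exact <- length(px) <= 20 && length(hx) <= 20 &&
        !any(duplicated(c(px, hx)))
      wt <- suppressWarnings(
        stats::wilcox.test(px, hx, alternative = alternative, exact = exact,
                           correct = !exact))
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = co, epitope = ep,
        n_cohort = length(px), n_healthy = length(hx),
        U = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "joint") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  } else {
    out$p_adj <- NA_real_
    for (ep in unique(out$epitope)) {
      sel <- out$epitope == ep
      out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    }
  }
  rownames(out) <- NULL
  out
}

#' Fraction of predicted CDR3-beta sequences shared between samples
#'
#' Of all unique CDR3-beta sequences predicted specific anywhere in the
#' cohort, the percentage present in at least two samples. V genes are
#' ignored: sharing is over CDR3-beta strings.
#'
#' @param predicted_sets named list mapping sample id to its set
#'   (character vector) of predicted CDR3-beta sequences.
#' @return Percentage in `[0, 100]`, or `NA` for fewer than two samples.
#' @export
sharing_fraction <- function(predicted_sets) {
  if (length(predicted_sets) < 2) return(NA_real_)
  per_sample <- lapply(predicted_sets, unique)
  all_seqs <- unlist(per_sample, use.names = FALSE)
  if (!length(all_seqs)) return(NA_real_)
  tab <- table(all_seqs)
  100 * sum(tab >= 2) / length(tab)
}

#' Position-frequency matrix of equal-length CDR3s
#'
#' Residue frequencies per position over all sequences of the chosen
#' length (the input to a sequence logo). `length = "modal"` picks the most
#' abundant CDR3 length, resolving ties toward the shorter length;
#' sequences of other lengths are excluded.
#'
#' @param cdr3s character vector of CDR3 sequences.
#' @param length an integer length, or `"modal"`.
#' @return A 20 x L matrix (rows: residues, columns: positions); every
#'   column sums to 1.
#' @export
position_frequency_matrix <- function(cdr3s, length = "modal") {
  lens <- nchar(cdr3s)
  if (identical(length, "modal")) {
    tab <- table(lens)
    cand <- as.integer(names(tab)[tab == max(tab)])
    length <- min(cand)
  }
  sel <- cdr3s[lens == length]
  if (!base::length(sel)) stop("no sequence of length ", length)
  chars <- do.call(rbind, strsplit(sel, ""))
  M <- vapply(seq_len(ncol(chars)), function(j) {
    tabulate(factor(chars[, j], levels = AA20), nbins = 20) / nrow(chars)
  }, numeric(20))
  rownames(M) <- AA20
  colnames(M) <- seq_len(ncol(M))
  M
}
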