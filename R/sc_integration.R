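#' Annotate single cells with predicted epitope specificity
#'
#' Scores each cell's TCR-beta under every model and labels the cell with
#' each epitope whose score exceeds that model's threshold. Cells may carry
#' several labels or none. Scoring is per clonotype key, so all cells of
#' one clonotype receive identical labels.
#'
#' @param cells data frame of QC-passing cells with one TCR-beta each:
#'   columns `barcode`, `patient_id`, `cluster_label`, `cdr3b`, `v_gene`
#'   (optional `cdr3a`).
#' @param models named list of `"tcrgp_model"` objects or scoring
#'   functions; names are the epitope labels.
#' @param thresholds optional named numeric vector of decision thresholds
#'   overriding the models' calibrated ones (required for function
#'   scorers).
#' @return `cells` with one logical column `specific_<epitope>` per model
#'   and a `specificity` column joining the labels with `";"` (empty
#'   string for unlabeled cells).
#' @export
annotate_cells <- function(cells, models, thresholds = NULL) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be a named list (names = epitope labels)")
  }
  if (!nrow(cells)) {
    for (nm in names(models)) cells[[paste0("specific_", nm)]] <- logical(0)
    cells$specificity <- character(0)
    return(cells)
  }
  if (any(is.na(cells$cdr3b) | !nzchar(cells$cdr3b))) {
    stop("cell(s) without a TCR-beta chain; apply cell_qc_filter first")
  }
  key <- paste(cells$cdr3b, cells$v_gene, sep = "|")
  uni <- !duplicated(key)
  utab <- cells[uni, c("cdr3b", "v_gene"), drop = FALSE]
  lab_mat <- matrix(FALSE, nrow(cells), length(models),
                    dimnames = list(NULL, names(models)))
  for (nm in names(models)) {
    thr <- scorer_threshold(models[[nm]],
                            if (!is.null(thresholds)) unname(thresholds[nm]))
    s_u <- tcr_scores(models[[nm]], utab)
    lab_mat[, nm] <- (s_u > thr)[match(key, key[uni])]
  }
  for (nm in names(models)) {
    cells[[paste0("specific_", nm)]] <- lab_mat[, nm]
  }
  cells$specificity <- apply(lab_mat, 1L, function(z) {
    paste(names(models)[z], collapse = ";")
  })
  cells
}

#' Phenotype-cluster enrichment of epitope-specific cells
#'
#' For every epitope x cluster pair, tests whether cells predicted
#' specific to the epitope are over-represented in the cluster relative to
#' all non-specific cells, with a one-sided (enrichment) Fisher exact test
#' on the 2x2 table `[[specific & in-cluster, specific & out],
#' [nonspecific & in-cluster, nonspecific & out]]`. P-values are
#' Benjamini-Hochberg adjusted across all epitope x cluster tests.
#'
#' @param annotations output of [annotate_cells()].
#' @param epitopes epitope labels to test (default: all `specific_*`
#'   columns present).
#' @param clusters cluster vocabulary (default: observed labels).
#' @return Data frame (`epitope`, `cluster`, `n11`, `n12`, `n21`, `n22`,
#'   `odds_ratio`, `p`, `p_adj`) ordered by adjusted p.
#' @export
phenotype_enrichment <- function(annotations, epitopes = NULL,
                                 clusters = NULL) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  cols <- grep("^specific_", names(annotations), value = TRUE)
  epitopes <- epitopes %||% sub("^specific_", "", cols)
  clusters <- clusters %||% sort(unique(annotations$cluster_label))
  if (!length(clusters)) stop("empty cluster vocabulary")
  rows <- list()
  for (ep in epitopes) {
    spec <- annotations[[paste0("specific_", ep)]]
    if (is.null(spec)) stop("no annotation column for epitope ", ep)
    for (cl in clusters) {
      inc <- annotations$cluster_label == cl
      tab <- matrix(c(sum(spec & inc), sum(spec & !inc),
                      sum(!spec & inc), sum(!spec & !inc)),
                    nrow = 2, byrow = TRUE)
      ft <- stats::fisher.test(tab, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        epitope = ep, cluster = cl,
        n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1], n22 = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adj, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-patient epitope-specific cell counts and frequencies
#'
#' Frequency is the number of labeled cells over all QC-passing cells of
#' the patient. Cells with multiple labels count once per label; patients
#' with zero labeled cells are reported with frequency 0, not omitted.
#'
#' @param annotations output of [annotate_cells()].
#' @return Data frame (`patient_id`, `epitope`, `n_cells`, `total_cells`,
#'   `frequency`).
#' @export
per_patient_specificity_table <- function(annotations) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  cols <- grep("^specific_", names(annotations), value = TRUE)
  patients <- unique(annotations$patient_id)
  rows <- list()
  for (pid in patients) {
    sel <- annotations$patient_id == pid
    total <- sum(sel)
    for (col in cols) {
      n <- sum(annotations[[col]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, epitope = sub("^specific_", "", col),
        n_cells = n, total_cells = total,
        frequency = if (total > 0) n / total else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
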