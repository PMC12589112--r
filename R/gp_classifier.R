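#' Assemble a labeled training set at a fixed positive:control ratio
#'
#' Combines all positives (label 1) with `ratio` times as many controls
#' (label 0) sampled without replacement from the control pool. Controls
#' whose (CDR3-beta, V gene) key occurs among the positives are excluded
#' before sampling, so no clonotype key ever appears with both labels.
#'
#' @param positives,control_pool clonotype data frames with `cdr3b`,
#'   `v_gene`.
#' @param ratio controls per positive (default 10).
#' @param seed integer seed for the control draw.
#' @return Data frame: positives then sampled controls, with a `label`
#'   column (1/0).
#' @export
assemble_training_set <- function(positives, control_pool, ratio = 10L,
                                  seed = 1L) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  control_pool <- as.data.frame(control_pool, stringsAsFactors = FALSE)
  stopifnot(nrow(positives) > 0)
  pos_key <- paste(positives$cdr3b, positives$v_gene, sep = "|")
  pool_key <- paste(control_pool$cdr3b, control_pool$v_gene, sep = "|")
  pool <- control_pool[!pool_key %in% pos_key, , drop = FALSE]
  need <- as.integer(ratio) * nrow(positives)
  if (nrow(pool) < need) {
    stop(sprintf("insufficient controls: need %d, available %d after removing clonotypes shared with positives",
                 need, nrow(pool)))
  }
  take <- withr::with_seed(seed, sample.int(nrow(pool), need))
  cols <- intersect(c("cdr3b", "v_gene", "cdr3a", "va_gene", "source_label"),
                    intersect(names(positives), names(pool)))
  out <- rbind(cbind(positives[, cols, drop = FALSE], label = 1L),
               cbind(pool[take, cols, drop = FALSE], label = 0L))
  rownames(out) <- NULL
  out
}

#' Train a Gaussian-process TCR classifier
#'
#' Fits a GP binary classifier over encoded TCR vectors: squared-exponential
#' kernel with one shared lengthscale, Bernoulli likelihood with logistic
#' link, Laplace approximation of the posterior. Kernel hyperparameters are
#' optimized by L-BFGS-B on the approximate marginal likelihood computed on
#' a seeded subsample of at most `hyper_subsample` points (initialization:
#' unit signal variance, lengthscale at the median pairwise embedding
#' distance), followed by one full-data fit.
#'
#' @param data labeled data frame (`cdr3b`, `v_gene`, `label` in 0/1).
#' @param cfg optional [encoding_config()]; by default built from the data
#'   (max_len = longest training CDR3, V families observed in training).
#' @param kernel optional fixed hyperparameters `list(sigma_f, lengthscale)`
#'   skipping optimization.
#' @param seed integer seed (subsampling).
#' @param epitope epitope label stored with the model.
#' @param hyper_subsample subsample size for hyperparameter optimization.
#' @return An object of class `"tcrgp_model"` with a decision `threshold`
#'   slot (`NA` until [calibrate_threshold()] is applied; see
#'   [train_epitope_model()] for the full pipeline).
#' @export
train_model <- function(data, cfg = NULL, kernel = NULL, seed = 1L,
                        epitope = NA_character_, hyper_subsample = 1000L) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (length(unique(data$label)) < 2) {
    stop("training data must contain both classes")
  }
  if (nrow(data) < 20) stop("need at least 20 training examples")
  if (is.null(cfg)) {
    cfg <- encoding_config(max_len = max(nchar(data$cdr3b)),
                           v_genes = data$v_gene)
  }
  enc <- encode_tcrs(data$cdr3b, data$v_gene, cfg)
  if (any(!enc$ok)) stop("training CDR3 longer than max_len")
  y <- ifelse(data$label > 0, 1, -1)
  if (is.null(kernel)) {
    kernel <- gp_optimize_hypers(enc$X, y, subsample = hyper_subsample,
                                 seed = seed)
  }
  K <- se_kernel(sq_dists(enc$X), kernel$sigma_f, kernel$lengthscale) +
    diag(1e-6, nrow(enc$X))
  fit <- gp_laplace(K, y)
  structure(list(encoding = cfg,
                 kernel = list(sigma_f = kernel$sigma_f,
                               lengthscale = kernel$lengthscale),
                 X = enc$X, y = y,
                 grad = fit$grad, sW = fit$sW, L = fit$L, f = fit$f,
                 threshold = NA_real_, cv = NULL,
                 epitope = as.character(epitope),
                 version = "1"),
            class = "tcrgp_model")
}

#' @export
print.tcrgp_model <- function(x, ...) {
  cat(sprintf("<tcrgp_model>%s n_train=%d (pos=%d)  sigma_f=%.3f  lengthscale=%.3f  threshold=%s\n",
              if (is.na(x$epitope)) "" else paste0(" [", x$epitope, "]"),
              length(x$y), sum(x$y > 0), x$kernel$sigma_f,
              x$kernel$lengthscale,
              if (is.na(x$threshold)) "uncalibrated" else
                formatC(x$threshold, digits = 4, format = "f")))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV: mean AUROC %.3f, mean AUPR %.3f over %d folds\n",
                x$cv$mean_auroc, x$cv$mean_aupr, length(x$cv$fold_auroc)))
  }
  invisible(x)
}

#' Score TCRs with a trained classifier
#'
#' Deterministic predictive probabilities in (0, 1). CDR3s longer than the
#' model's `max_len` cannot be encoded and receive score 0 with a warning,
#' so cohort scans never abort. Identical (CDR3-beta, V gene) pairs are
#' scored once and broadcast.
#'
#' @param model a `"tcrgp_model"`.
#' @param tcrs clonotype data frame (`cdr3b`, `v_gene`) or character vector
#'   of CDR3-beta sequences.
#' @param v_gene V genes when `tcrs` is a character vector.
#' @return Numeric vector of scores, one per input TCR.
#' @export
predict_scores <- function(model, tcrs, v_gene = NA_character_) {
  stopifnot(inherits(model, "tcrgp_model"))
  if (is.character(tcrs)) {
    tcrs <- data.frame(cdr3b = tcrs, v_gene = rep_len(v_gene, length(tcrs)),
                       stringsAsFactors = FALSE)
  }
  tcrs <- as.data.frame(tcrs, stringsAsFactors = FALSE)
  key <- paste(tcrs$cdr3b, tcrs$v_gene, sep = "|")
  uni <- !duplicated(key)
  enc <- encode_tcrs(tcrs$cdr3b[uni], tcrs$v_gene[uni], model$encoding)
  scores_u <- numeric(sum(uni))
  if (any(!enc$ok)) {
    warning(sum(!enc$ok), " TCR(s) longer than max_len scored 0 (unencodable)")
  }
  if (any(enc$ok)) {
    scores_u[enc$ok] <- gp_predict(model, model$X,
                                   enc$X[enc$ok, , drop = FALSE],
                                   model$kernel$sigma_f,
                                   model$kernel$lengthscale)
  }
  scores_u[match(key, key[uni])]
}

#' Calibrate a decision threshold to a target false positive rate
#'
#' The threshold is the `ceiling((1 - fpr) * n)`-th order statistic of the
#' control scores; a TCR is predicted positive iff its score is strictly
#' above the threshold. By construction the empirical FPR on the
#' calibration set never exceeds `fpr`.
#'
#' @param control_scores scores of control (non-specific) TCRs.
#' @param fpr target false positive rate in (0, 1) (default 0.01).
#' @return The threshold (a score).
#' @export
calibrate_threshold <- function(control_scores, fpr = 0.01) {
  if (length(fpr) != 1 || is.na(fpr) || fpr <= 0 || fpr >= 1) {
    stop("fpr must be a probability strictly inside (0, 1)")
  }
  n <- length(control_scores)
  if (n < 1 / fpr) {
    warning("fewer than 1/fpr control scores (", n,
            "); calibrated threshold is unreliable")
  }
  sort(control_scores)[ceiling((1 - fpr) * n)]
}

#' AUROC and AUPR of a score vector
#'
#' AUROC is the Mann-Whitney probability that a random positive outranks a
#' random negative, with ties counted one half. AUPR is the area under the
#' precision-recall curve by the interpolation-free step rule (average
#' precision), with tied scores processed as one group.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return List with elements `auroc` and `aupr`.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE)) # end of each tie group
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, aupr = aupr)
}

# stratified fold assignment keeping identical CDR3b sequences together;
# greedy size balancing within each label stratum
assign_folds <- function(labels, cdr3b, n_folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      groups <- split(idx, cdr3b[idx])
      groups <- groups[sample.int(length(groups))]
      groups <- groups[order(-lengths(groups))]
      load <- numeric(n_folds)
      for (g in groups) {
        j <- which.min(load)
        fold[g] <- j
        load[j] <- load[j] + length(g)
      }
    }
  })
  fold
}

#' Stratified cross-validation of the GP classifier
#'
#' Folds are stratified by label (per-fold class counts within one of exact
#' proportionality) and records sharing a CDR3-beta are always assigned to
#' the same fold to prevent sequence leakage. Hyperparameters are
#' re-optimized within each training fold. Per-fold AUROC/AUPR are computed
#' on the held-out scores.
#'
#' @param data labeled data frame (`cdr3b`, `v_gene`, `label`).
#' @param n_folds number of folds (default 10).
#' @param cfg optional shared [encoding_config()] (default: built from all
#'   of `data` so every fold encodes identically).
#' @param kernel optional fixed kernel hyperparameters.
#' @param seed integer seed (fold assignment and subsampling).
#' @return List of class `"tcrgp_cv"`: `fold_auroc`, `fold_aupr`,
#'   `mean_auroc`, `mean_aupr`, and out-of-fold `scores`, `labels`, `fold`.
#' @export
crossvalidate <- function(data, n_folds = 10L, cfg = NULL, kernel = NULL,
                          seed = 1L) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  n_folds <- as.integer(n_folds)
  counts <- table(data$label)
  if (length(counts) < 2) stop("both classes must be present")
  if (any(counts < n_folds)) {
    stop("each class needs at least n_folds = ", n_folds, " members")
  }
  if (is.null(cfg)) {
    cfg <- encoding_config(max_len = max(nchar(data$cdr3b)),
                           v_genes = data$v_gene)
  }
  fold <- assign_folds(data$label, data$cdr3b, n_folds, seed)
  scores <- numeric(nrow(data))
  fold_auroc <- fold_aupr <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    model <- train_model(data[tr, , drop = FALSE], cfg = cfg, kernel = kernel,
                         seed = seed + k)
    scores[!tr] <- predict_scores(model, data[!tr, , drop = FALSE])
    ev <- evaluate_scores(scores[!tr], data$label[!tr])
    fold_auroc[k] <- ev$auroc
    fold_aupr[k] <- ev$aupr
  }
  structure(list(fold_auroc = fold_auroc, fold_aupr = fold_aupr,
                 mean_auroc = mean(fold_auroc), mean_aupr = mean(fold_aupr),
                 scores = scores, labels = data$label, fold = fold),
            class = "tcrgp_cv")
}

#' Full training pipeline for one epitope model
#'
#' Assembles positives and controls at the given ratio, runs stratified
#' cross-validation, trains the final model on all assembled data, and
#' calibrates the decision threshold at the target FPR on the
#' cross-validated (out-of-fold) control scores — the less optimistic
#' choice, since those scores come from models that never saw the control.
#'
#' @param positives epitope-specific clonotype data frame.
#' @param control_pool control clonotype data frame.
#' @param ratio controls per positive (default 10).
#' @param n_folds cross-validation folds (default 10).
#' @param fpr target false positive rate (default 0.01).
#' @param seed integer seed.
#' @param epitope epitope label.
#' @param kernel optional fixed kernel hyperparameters.
#' @return A calibrated `"tcrgp_model"` with `cv` metrics attached.
#' @export
train_epitope_model <- function(positives, control_pool, ratio = 10L,
                                n_folds = 10L, fpr = 0.01, seed = 1L,
                                epitope = NA_character_, kernel = NULL) {
  data <- assemble_training_set(positives, control_pool, ratio = ratio,
                                seed = seed)
  cv <- crossvalidate(data, n_folds = n_folds, kernel = kernel, seed = seed)
  model <- train_model(data, kernel = kernel, seed = seed, epitope = epitope)
  model$threshold <- calibrate_threshold(cv$scores[cv$labels == 0L], fpr = fpr)
  model$cv <- cv
  model
}

#' Save a trained model as self-describing JSON
#'
#' Stores the encoding configuration, kernel hyperparameters, training
#' feature matrix and Laplace state, threshold, CV metrics and epitope
#' label at full numeric precision. [load_model()] restores a model whose
#' scores match the original to numerical precision.
#'
#' @param model a `"tcrgp_model"`.
#' @param path output JSON path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tcrgp_model"))
  cfg <- model$encoding
  doc <- list(
    format = "epispec-tcrgp", version = model$version,
    epitope = model$epitope,
    encoding = list(max_len = cfg$max_len, embed_dim = cfg$embed_dim,
                    use_v_features = cfg$use_v_features,
                    v_families = cfg$v_families,
                    v_cdr_table = cfg$v_cdr_table,
                    embedding = list(values = as.vector(cfg$embedding),
                                     residues = rownames(cfg$embedding))),
    kernel = model$kernel,
    state = list(n = length(model$y),
                 p = ncol(model$X),
                 X = as.vector(model$X),
                 y = model$y,
                 grad = model$grad,
                 sW = model$sW,
                 f = model$f),
    threshold = model$threshold,
    cv = if (!is.null(model$cv)) {
      list(fold_auroc = model$cv$fold_auroc, fold_aupr = model$cv$fold_aupr,
           mean_auroc = model$cv$mean_auroc, mean_aupr = model$cv$mean_aupr)
    })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return A `"tcrgp_model"`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "epispec-tcrgp")) {
    stop("not an epispec model file: ", path)
  }
  E <- matrix(doc$encoding$embedding$values, nrow = 20,
              dimnames = list(doc$encoding$embedding$residues, NULL))
  cfg <- structure(list(max_len = as.integer(doc$encoding$max_len),
                        embed_dim = as.integer(doc$encoding$embed_dim),
                        use_v_features = isTRUE(doc$encoding$use_v_features),
                        embedding = E,
                        v_families = as.character(doc$encoding$v_families %||% character(0)),
                        v_cdr_table = doc$encoding$v_cdr_table,
                        v_cdr_len = 0L),
                   class = "encoding_config")
  if (!is.null(cfg$v_cdr_table)) {
    cfg$v_cdr_table <- as.data.frame(cfg$v_cdr_table,
                                     stringsAsFactors = FALSE)
    cfg$v_cdr_len <- max(nchar(cfg$v_cdr_table$cdr1) +
                           nchar(cfg$v_cdr_table$cdr2))
  }
  n <- doc$state$n
  X <- matrix(doc$state$X, nrow = n)
  sW <- doc$state$sW
  K <- se_kernel(sq_dists(X), doc$kernel$sigma_f, doc$kernel$lengthscale) +
    diag(1e-6, n)
  L <- chol(diag(n) + (sW %o% sW) * K)
  structure(list(encoding = cfg,
                 kernel = list(sigma_f = doc$kernel$sigma_f,
                               lengthscale = doc$kernel$lengthscale),
                 X = X, y = doc$state$y,
                 grad = doc$state$grad, sW = sW, L = L, f = doc$state$f,
                 threshold = doc$threshold %||% NA_real_,
                 cv = doc$cv,
                 epitope = as.character(doc$epitope %||% NA_character_),
                 version = doc$version %||% "1"),
            class = "tcrgp_model")
}
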