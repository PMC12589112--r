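make_cfg <- function(max_len = 16, v_genes = c("TRBV19", "TRBV5-1")) {
  encoding_config(max_len = max_len, v_genes = v_genes)
}

test_that("encoding is deterministic and center-gap aligns short CDR3s", {
  cfg <- make_cfg()
  a <- encode_tcrs("CASSLGQAYEQYF", "TRBV19", cfg)
  b <- encode_tcrs("CASSLGQAYEQYF", "TRBV19", cfg)
  expect_identical(a$X, b$X)

  cfg6 <- encoding_config(max_len = 6, v_genes = "TRBV19",
                          use_v_features = FALSE)
  enc <- encode_tcrs("CASF", "TRBV19", cfg6)
  d <- cfg6$embed_dim
  block <- function(slot) enc$X[1, (slot - 1) * d + seq_len(d)]
  E <- cfg6$embedding
  expect_equal(block(1), unname(E["C", ]))
  expect_equal(block(2), unname(E["A", ]))
  expect_equal(block(3), rep(0, d))     # gap
  expect_equal(block(4), rep(0, d))     # gap
  expect_equal(block(5), unname(E["S", ]))
  expect_equal(block(6), unname(E["F", ]))

  expect_error(encode_tcrs("CASXZF", "TRBV19", cfg), "'Z'|'X'")
})

test_that("BLOSUM embedding places similar residues closer (full-eigen oracle)", {
  # oracle: independent eigendecomposition of centered BLOSUM62 at full rank
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[epispec:::AA20, epispec:::AA20]
  H <- diag(20) - 1 / 20
  eg <- eigen((H %*% B %*% H + t(H %*% B %*% H)) / 2, symmetric = TRUE)
  keep <- 1:4
  oracle <- eg$vectors[, keep] %*% diag(sqrt(pmax(eg$values[keep], 0)))
  rownames(oracle) <- epispec:::AA20
  dist_o <- function(x, y) sqrt(sum((oracle[x, ] - oracle[y, ])^2))
  E <- aa_embedding(4)
  dist_e <- function(x, y) sqrt(sum((E[x, ] - E[y, ])^2))
  # same geometry as the oracle (up to sign convention)
  expect_equal(dist_e("L", "I"), dist_o("L", "I"), tolerance = 1e-10)
  expect_equal(dist_e("L", "D"), dist_o("L", "D"), tolerance = 1e-10)
  expect_lt(dist_e("L", "I"), dist_e("L", "D"))
})

test_that("training-set assembly enforces the ratio and forbids label leakage", {
  pos <- random_tcrs(100, seed = 1)
  pool <- random_tcrs(2000, seed = 2)
  out <- assemble_training_set(pos, pool, ratio = 10, seed = 3)
  expect_equal(sum(out$label == 1), 100)
  expect_equal(sum(out$label == 0), 1000)
  key <- paste(out$cdr3b, out$v_gene)
  expect_length(intersect(key[out$label == 1], key[out$label == 0]), 0)

  # a control sharing a positive key is excluded before sampling
  pool2 <- rbind(pos[1, c("cdr3b", "v_gene", "count")],
                 random_tcrs(1500, seed = 4))
  out2 <- assemble_training_set(pos, pool2, ratio = 10, seed = 3)
  k2 <- paste(out2$cdr3b, out2$v_gene)
  expect_length(intersect(k2[out2$label == 1], k2[out2$label == 0]), 0)

  expect_error(assemble_training_set(pos, random_tcrs(500, seed = 5),
                                     ratio = 10, seed = 1),
               "need 1000, available")
  # identical draw under identical seed
  expect_identical(assemble_training_set(pos, pool, ratio = 10, seed = 3),
                   out)
})

test_that("threshold calibration matches the order-statistic rule", {
  expect_equal(calibrate_threshold(seq(0.01, 1, by = 0.01), fpr = 0.01), 0.99)
  expect_equal(sum(seq(0.01, 1, by = 0.01) > 0.99), 1)
  expect_equal(calibrate_threshold(rep(0.5, 200), fpr = 0.01), 0.5)
  expect_equal(sum(rep(0.5, 200) > 0.5), 0)
  expect_equal(calibrate_threshold(c(0.1, 0.2, 0.3, 0.4), fpr = 0.5), 0.2)
  # fewer than 1/fpr controls cannot pin the quantile down
  expect_warning(calibrate_threshold(runif(50), fpr = 0.01), "unreliable")
  expect_error(calibrate_threshold(runif(10), fpr = 0), "probability")
  expect_error(calibrate_threshold(runif(10), fpr = 1), "probability")
})

test_that("AUROC/AUPR match hand examples and the concordant-pair oracle", {
  ev <- evaluate_scores(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$aupr, 1.0)
  expect_equal(evaluate_scores(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))$auroc,
               0.75)
  expect_equal(evaluate_scores(rep(0.3, 10), rep(c(0, 1), 5))$auroc, 0.5)
  expect_error(evaluate_scores(runif(5), rep(1, 5)), "both classes")

  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      scores <- round(runif(n), sample(1:3, 1))  # induce ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(evaluate_scores(scores, labels)$auroc,
                   oracle_auroc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("stratified folds balance classes and keep shared CDR3b together", {
  dat <- rbind(cbind(random_tcrs(100, seed = 1), label = 1L),
               cbind(random_tcrs(1000, seed = 2), label = 0L))
  fold <- epispec:::assign_folds(dat$label, dat$cdr3b, 10, seed = 1)
  tab <- table(fold, dat$label)
  expect_true(all(tab[, "1"] == 10))
  expect_true(all(tab[, "0"] == 100))
  # duplicate CDR3b records land in one fold
  dat2 <- dat
  dat2$cdr3b[2:4] <- dat2$cdr3b[1]
  f2 <- epispec:::assign_folds(dat2$label, dat2$cdr3b, 10, seed = 1)
  expect_length(unique(f2[1:4]), 1)
})

test_that("the GP separates motif-implanted TCRs from background", {
  pos <- implant_motif_positives(sim_config(seed = 21, n_sequences = 60))
  ctl <- generate_background_cdr3s(sim_config(seed = 22, n_sequences = 700))
  dat <- assemble_training_set(pos[, c("cdr3b", "v_gene")], ctl,
                               ratio = 10, seed = 3)
  model <- train_model(dat, seed = 3, epitope = "SIM")
  # scores live strictly inside (0, 1) and are deterministic
  s1 <- predict_scores(model, dat)
  s2 <- predict_scores(model, dat)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
  # a duplicate of a training positive outranks the median control
  expect_gt(predict_scores(model, dat[1, , drop = FALSE]),
            median(s1[dat$label == 0]))
  # fresh implanted TCRs stochastically dominate fresh background
  fp <- implant_motif_positives(sim_config(seed = 31, n_sequences = 200))
  fb <- generate_background_cdr3s(sim_config(seed = 32, n_sequences = 2000))
  sp <- predict_scores(model, fp[, c("cdr3b", "v_gene")])
  sb <- predict_scores(model, fb[, c("cdr3b", "v_gene")])
  expect_lt(wilcox.test(sp, sb, alternative = "greater")$p.value, 0.01)
  # over-length query scores 0 with a warning instead of aborting
  long <- data.frame(cdr3b = paste0("C", strrep("A", 40), "F"),
                     v_gene = "TRBV19")
  expect_warning(s0 <- predict_scores(model, long), "unencodable")
  expect_equal(s0, 0)
})

test_that("perfectly separable data yields CV AUROC 1 and permuted labels do not", {
  # two disjoint sequence families, fixed kernel for speed
  dat <- withr::with_seed(8, {
    mk <- function(n, residues) vapply(seq_len(n), function(i) {
      paste0("CASS", paste(sample(residues, 5, replace = TRUE),
                           collapse = ""), "EQYF")
    }, character(1))
    d <- data.frame(cdr3b = c(mk(30, c("L", "I", "V")),
                              mk(60, c("D", "E", "K"))),
                    v_gene = "TRBV19",
                    label = rep(c(1L, 0L), c(30, 60)),
                    stringsAsFactors = FALSE)
    d[!duplicated(d$cdr3b), ]
  })
  cv <- crossvalidate(dat, n_folds = 3,
                      kernel = list(sigma_f = 1, lengthscale = 2), seed = 1)
  expect_equal(cv$mean_auroc, 1.0)
})

test_that("model JSON round-trip reproduces scores to numerical precision", {
  pos <- implant_motif_positives(sim_config(seed = 41, n_sequences = 30))
  ctl <- generate_background_cdr3s(sim_config(seed = 42, n_sequences = 400))
  dat <- assemble_training_set(pos[, c("cdr3b", "v_gene")], ctl,
                               ratio = 10, seed = 1)
  model <- train_model(dat, kernel = list(sigma_f = 2, lengthscale = 5),
                       seed = 1, epitope = "SIM")
  model$threshold <- 0.42
  probe <- rbind(
    implant_motif_positives(
      sim_config(seed = 43, n_sequences = 20))[, c("cdr3b", "v_gene")],
    generate_background_cdr3s(
      sim_config(seed = 44, n_sequences = 20))[, c("cdr3b", "v_gene")])
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$threshold, 0.42)
  expect_equal(back$epitope, "SIM")
  expect_equal(predict_scores(back, probe[, c("cdr3b", "v_gene")]),
               predict_scores(model, probe[, c("cdr3b", "v_gene")]),
               tolerance = 1e-10)
})

test_that("CV signal strength is non-decreasing in the implant fraction", {
  aurocs <- vapply(c(0.2, 0.5, 1.0), function(fr) {
    pos <- implant_motif_positives(sim_config(seed = 51, n_sequences = 50,
                                              implant_fraction = fr))
    ctl <- generate_background_cdr3s(sim_config(seed = 52, n_sequences = 600))
    dat <- assemble_training_set(pos[, c("cdr3b", "v_gene")], ctl,
                                 ratio = 10, seed = 1)
    crossvalidate(dat, n_folds = 5,
                  kernel = list(sigma_f = 3, lengthscale = 6),
                  seed = 1)$mean_auroc
  }, numeric(1))
  expect_true(all(diff(aurocs) > -0.02))  # non-decreasing up to CV noise
  expect_gt(aurocs[3], aurocs[1])
})
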