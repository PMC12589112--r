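test_that("local motif extraction enumerates interior k-mers and wildcards", {
  p3 <- motif_params(k_min = 3, k_max = 3)
  out <- extract_local_motifs("CASSLGQAYEQYF", p3)
  contiguous <- out[!grepl(".", out, fixed = TRUE)]
  expect_setequal(contiguous, c("SLG", "LGQ", "GQA", "QAY", "AYE", "YEQ"))
  expect_true("S.G" %in% out)                 # middle-position wildcard
  expect_true(all(nchar(out) == 3))
  # degenerate: interior empty
  expect_length(extract_local_motifs("CASSF", p3), 0)
  # k range 3-5 adds longer patterns, wildcards never at terminal positions
  out5 <- extract_local_motifs("CASSLGQAYEQYF", motif_params())
  wild <- out5[grepl(".", out5, fixed = TRUE)]
  expect_false(any(substr(wild, 1, 1) == "."))
  expect_false(any(substr(wild, nchar(wild), nchar(wild)) == "."))
})

test_that("motif enrichment applies depth, p-value and fold gates as configured", {
  params <- motif_params(kmer_min_depth = 5, local_min_pvalue = 1e-4,
                         local_min_ove = 1000)
  # query of 50: 5 sequences carry WQV in the interior, rest inert
  carrier <- paste0("CAS", "SWQVS", "TEQFF")
  inert <- paste0("CAS", strrep("A", 5), "TEQFF")
  query <- c(rep(carrier, 5), rep(inert, 45))
  ref <- structure(list(counts = c(WQV = 1L), n = 100000L, params = params),
                   class = "motif_reference")
  tab <- suppressWarnings(motif_enrichment(query, ref, params))
  row <- tab[tab$motif == "WQV", ]
  expect_equal(row$query_count, 5L)
  expect_equal(row$fold, (5 / 50) / (1 / 100000))  # = 10000, no pseudocount
  expect_equal(row$p, oracle_fisher_greater(5, 45, 1, 99999), tolerance = 1e-12)

  # below depth: 4 carriers never reported
  q4 <- c(rep(carrier, 4), rep(inert, 46))
  t4 <- suppressWarnings(motif_enrichment(q4, ref, params))
  expect_false("WQV" %in% t4$motif)

  # fold below local_min_ove never reported even at tiny p
  ref2 <- structure(list(counts = c(WQV = 120L), n = 100000L, params = params),
                    class = "motif_reference")
  t5 <- suppressWarnings(motif_enrichment(query, ref2, params))
  expect_false("WQV" %in% t5$motif)   # fold = 83.3 < 1000
  expect_error(motif_enrichment(character(0), ref, params), "nonempty")
})

test_that("one-sided Fisher p equals tail enumeration on small tables", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(4:30, 1)
      a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
      c <- sample(0:(n - a - b), 1); d <- n - a - b - c
      p_impl <- epispec:::fisher_p_enrichment(a, a + b, c, c + d)
      expect_equal(p_impl, oracle_fisher_greater(a, b, c, d),
                   tolerance = 1e-12)
    }
  })
})

test_that("relaxing thresholds never shrinks, tightening never grows the motif set", {
  cfg <- sim_config(seed = 77, n_sequences = 400, implant_fraction = 0.4)
  query <- implant_motif_positives(cfg)$cdr3b
  ref <- generate_background_cdr3s(sim_config(seed = 78, n_sequences = 8000))
  rmc <- reference_motif_counts(ref$cdr3b)
  base <- suppressWarnings(
    motif_enrichment(query, rmc, motif_params(local_min_ove = 100)))
  relaxed_p <- suppressWarnings(motif_enrichment(
    query, rmc, motif_params(local_min_pvalue = 1e-2, local_min_ove = 100)))
  expect_true(all(base$motif %in% relaxed_p$motif))
  deeper <- suppressWarnings(motif_enrichment(
    query, rmc, motif_params(kmer_min_depth = 10, local_min_ove = 100)))
  expect_true(all(deeper$motif %in% base$motif))
  higher_ove <- suppressWarnings(motif_enrichment(
    query, rmc, motif_params(local_min_ove = 1000)))
  expect_true(all(higher_ove$motif %in% base$motif))
})

test_that("implanted motif is recovered from background in repeated seeded runs", {
  # A motif carried by 50 of 5000 query sequences has a containment rate of
  # 1%, so the default OVE >= 1000 gate demands a reference containment
  # rate below ~1e-5: the motif must be long enough to be essentially
  # absent from the reference, and long enough sequences are required for
  # it to sit inside the trimmed interior (the enrichment preconditions).
  ref <- generate_background_cdr3s(sim_config(seed = 900, n_sequences = 50000))
  rmc <- reference_motif_counts(ref$cdr3b)
  motif <- "LGQGWS"
  expect_equal(sum(grepl(motif, ref$cdr3b, fixed = TRUE)), 0)
  lens <- 12:20
  long_dist <- setNames(rep(1 / length(lens), length(lens)), lens)
  hits <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    carriers <- implant_motif_positives(
      sim_config(seed = 1000 + s, n_sequences = 50, motif = motif,
                 implant_fraction = 1, length_distribution = long_dist))
    bg <- generate_background_cdr3s(sim_config(seed = 2000 + s,
                                               n_sequences = 4950))
    query <- c(carriers$cdr3b, bg$cdr3b)
    tab <- motif_enrichment(query, rmc)
    # recovered iff an enriched 3-5mer pattern matches the implanted motif
    recovered <- any(vapply(tab$motif, function(p) grepl(p, motif),
                            logical(1)))
    if (recovered) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_runs))
})

test_that("global similarity pairs require same length and V, interior Hamming <= 1", {
  tcrs <- data.frame(
    cdr3b = c("CASSLGQAYEQYF",   # 1
              "CASSLGQSYEQYF",   # 2: interior distance 1 from 1
              "CASSLGQSYEQYF",   # 3: same seq, different V
              "CASSLGQAYEQYYF"), # 4: length 14
    v_gene = c("TRBV19", "TRBV19", "TRBV9", "TRBV19"),
    stringsAsFactors = FALSE)
  e <- global_similarity_pairs(tcrs)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$i, e$j), c(1L, 2L))
})

test_that("global clustering matches brute-force all-pairs Hamming", {
  # restricted alphabet and two fixed lengths so near-duplicates are common
  tcrs <- withr::with_seed(9, {
    n <- 150
    lens <- sample(c(11L, 13L), n, replace = TRUE)
    data.frame(
      cdr3b = vapply(lens, function(L) {
        paste0("CAS", paste(sample(c("G", "A", "S"), L - 5, replace = TRUE),
                            collapse = ""), "YF")
      }, character(1)),
      v_gene = sample(c("TRBV19", "TRBV9"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  params <- motif_params()
  e <- global_similarity_pairs(tcrs, params)
  ints <- epispec:::trim_interior(tcrs$cdr3b, params)
  brute <- list()
  for (i in 1:(nrow(tcrs) - 1)) {
    for (j in (i + 1):nrow(tcrs)) {
      if (nchar(tcrs$cdr3b[i]) != nchar(tcrs$cdr3b[j])) next
      if (tcrs$v_gene[i] != tcrs$v_gene[j]) next
      d <- sum(strsplit(ints[i], "")[[1]] != strsplit(ints[j], "")[[1]])
      if (d <= params$max_global_hamming) {
        brute[[length(brute) + 1]] <- c(i, j)
      }
    }
  }
  brute <- if (length(brute)) do.call(rbind, brute) else
    matrix(integer(0), 0, 2)
  got <- as.matrix(e[order(e$i, e$j), ])
  dimnames(got) <- NULL
  expect_equal(got, brute[order(brute[, 1], brute[, 2]), , drop = FALSE])
})

test_that("clusters form from motifs and edge components; selection takes the union", {
  tcrs <- data.frame(
    cdr3b = c("CASSLGQAYEQYF", "CASSLGQSYEQYF", "CASSLGQTYEQYF",
              "CASRDAAAANTIYF", "CASRDAAASNTIYF", "CATWWWWWWGELFF"),
    v_gene = c("TRBV19", "TRBV19", "TRBV19", "TRBV28", "TRBV28", "TRBV9"),
    source_label = c("healthy", "healthy", "AML", "healthy", "published",
                     "healthy"),
    stringsAsFactors = FALSE)
  motifs <- data.frame(motif = "LGQ", query_count = 3L, ref_count = 0L,
                       fold = 5000, p = 1e-9, stringsAsFactors = FALSE)
  edges <- data.frame(i = c(4L), j = c(5L))
  cl <- build_clusters(tcrs, motifs, edges)
  expect_setequal(unique(cl$cluster_id), c("local:LGQ", "global:4"))
  expect_setequal(cl$idx[cl$cluster_id == "local:LGQ"], 1:3)
  sel <- select_training_repertoire(cl, tcrs, min_cluster_size = 2)
  expect_setequal(sel$cdr3b, tcrs$cdr3b[1:5])
  expect_false(any(duplicated(sel$cdr3b)))
  # all clusters below the size cut -> empty selection with a warning
  expect_warning(
    empty <- select_training_repertoire(cl, tcrs, min_cluster_size = 10),
    "empty")
  expect_equal(nrow(empty), 0)
  # chained edges merge transitively into one component
  ch <- build_clusters(tcrs, motifs[0, ], data.frame(i = c(1L, 2L),
                                                     j = c(2L, 3L)))
  expect_equal(sort(ch$idx), 1:3)
  expect_length(unique(ch$cluster_id), 1)
  # no motifs, no edges -> no clusters
  none <- build_clusters(tcrs, motifs[0, ], edges[0, ])
  expect_equal(nrow(none), 0)
})
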