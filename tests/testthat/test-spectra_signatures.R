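test_that("spectrum counts classes and contexts, collapsing strands", {
  one <- mk_variants(pos = 1, ref = "C", alt = "T", context = "ACA")
  sp <- mutation_spectrum(one)
  expect_equal(unname(sp$class_counts), c(0, 0, 1, 0, 0, 0))
  expect_equal(sum(sp$context_counts), 1)
  expect_equal(unname(sp$context_counts["A[C>T]A"]), 1)

  # G>A at TGT is C>T at ACA on the opposite strand
  rc <- mk_variants(pos = 1, ref = "G", alt = "A", context = "TGT")
  sp_rc <- mutation_spectrum(rc)
  expect_equal(sp_rc$context_counts, sp$context_counts)

  bad <- mk_variants(pos = 1, context = "NCN")
  expect_error(mutation_spectrum(bad), "unannotated")
})

test_that("reverse-complementing every SNV leaves the spectrum unchanged", {
  set.seed(12)
  n <- 200
  labs <- sample(sbs96_contexts(), n, replace = TRUE)
  ref <- substr(labs, 3, 3); alt <- substr(labs, 5, 5)
  ctx <- paste0(substr(labs, 1, 1), ref, substr(labs, 7, 7))
  v <- mk_variants(pos = seq_len(n), ref = ref, alt = alt, context = ctx)
  flip <- v
  flip$ref <- revcomp(v$ref); flip$alt <- revcomp(v$alt)
  flip$context <- revcomp(v$context)
  expect_equal(mutation_spectrum(flip)$context_counts,
               mutation_spectrum(v)$context_counts)
})

test_that("spectrum of signature-1 draws is C>T dominated", {
  set.seed(3)
  catalog <- synthetic_signature_catalog()
  labs <- sample(sbs96_contexts(), 300, replace = TRUE, prob = catalog[, "Sig1"])
  ref <- substr(labs, 3, 3); alt <- substr(labs, 5, 5)
  ctx <- paste0(substr(labs, 1, 1), ref, substr(labs, 7, 7))
  sp <- mutation_spectrum(mk_variants(pos = 1:300, ref = ref, alt = alt,
                                      context = ctx))
  expect_equal(names(which.max(sp$class_counts)), "C>T")
})

test_that("spectra chi-square equals the closed-form Pearson statistic", {
  a <- c(10, 10, 10, 10, 10, 10)
  res0 <- spectra_chisq(a, a)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # collapsed 2x2 table [[10,20],[20,10]]
  res <- spectra_chisq(c(10, 20, 0, 0, 0, 0), c(20, 10, 0, 0, 0, 0))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1L)

  set.seed(9)
  for (i in 1:20) {
    a <- sample(5:60, 6, replace = TRUE)
    b <- sample(5:60, 6, replace = TRUE)
    res <- spectra_chisq(a, b)
    expect_equal(res$statistic, oracle_pearson(res$table), tolerance = 1e-9)
  }
  expect_error(spectra_chisq(rep(0, 6), a), "zero mutations")
})

test_that("sparse low-expectation classes are pooled before testing", {
  a <- c(40, 0, 35, 0, 25, 1)
  b <- c(38, 1, 30, 0, 28, 0)
  res <- spectra_chisq(a, b)
  expect_true("other" %in% colnames(res$table))
  expect_lt(ncol(res$table), 6L)
  expect_equal(res$statistic, oracle_pearson(res$table), tolerance = 1e-9)
})

test_that("signature refit recovers exact columns and noise-free mixtures", {
  catalog <- synthetic_signature_catalog()
  e1 <- fit_signatures(catalog[, "Sig1"], catalog)
  expect_equal(unname(e1$weights["Sig1"]), 1, tolerance = 1e-6)
  expect_lt(e1$residual, 1e-8)

  m <- 0.7 * catalog[, "Sig1"] + 0.3 * catalog[, "Sig4"]
  e2 <- fit_signatures(m, catalog)
  expect_equal(unname(e2$weights["Sig1"]), 0.7, tolerance = 1e-3)
  expect_equal(unname(e2$weights["Sig4"]), 0.3, tolerance = 1e-3)
  expect_lt(max(e2$weights[setdiff(names(e2$weights), c("Sig1", "Sig4"))]), 1e-3)

  expect_error(fit_signatures(rep(0, 96), catalog), "empty")
})

test_that("refit recovers random sparse mixtures above the weight floor", {
  set.seed(19)
  catalog <- synthetic_signature_catalog()
  for (i in 1:15) {
    k <- sample(2:4, 1)
    sigs <- sample(colnames(catalog), k)
    w <- stats::runif(k, 0.1, 1)
    w <- w / sum(w)
    while (any(w < 0.07)) { w <- stats::runif(k, 0.1, 1); w <- w / sum(w) }
    m <- as.numeric(catalog[, sigs, drop = FALSE] %*% w)
    e <- fit_signatures(m, catalog)
    want <- stats::setNames(rep(0, ncol(catalog)), colnames(catalog))
    want[sigs] <- w
    expect_lt(max(abs(e$weights - want)), 1e-3)
  }
})

test_that("weights are nonnegative and sum to at most one on sampled profiles", {
  set.seed(23)
  catalog <- synthetic_signature_catalog()
  p <- as.numeric(catalog[, c("Sig1", "Sig5")] %*% c(0.8, 0.2))
  counts <- as.numeric(stats::rmultinom(1, 200, p))
  names(counts) <- sbs96_contexts()
  e <- fit_signatures(counts, catalog)
  expect_true(all(e$weights >= 0))
  expect_lte(sum(e$weights), 1 + 1e-6)
  expect_equal(names(which.max(e$weights)), "Sig1")
})

test_that("SMG candidates require recurrence across patients", {
  cs <- function(genes, pid, sid = "T") {
    v <- mk_variants(pos = seq_along(genes), gene = genes, patient_id = pid,
                     sample_id = paste0(pid, "_", sid))
    v
  }
  cohort <- list(
    P1 = list(T = cs(c("TP53", "ZZZ3"), "P1")),
    P2 = list(T = cs(c("TP53", "RPL5"), "P2")),
    P3 = list(T = cs(c("TP53", "RPL5", "ONLY1"), "P3"))
  )
  smg <- smg_candidates(cohort)
  expect_equal(smg$gene[1], "TP53")
  expect_equal(smg$n_patients_mutated[1], 3L)
  expect_true("RPL5" %in% smg$gene)
  expect_false("ONLY1" %in% smg$gene)   # single patient
  expect_false("ZZZ3" %in% smg$gene)

  # census restriction and silent exclusion
  smg2 <- smg_candidates(cohort, census_genes = "TP53")
  expect_equal(smg2$gene, "TP53")
  cohort$P1$T$effect <- "synonymous"
  cohort$P2$T$effect <- "synonymous"
  smg3 <- smg_candidates(cohort)
  expect_false("TP53" %in% smg3$gene)
})
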