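test_that("three-set partition matches the Venn regions", {
  cs <- list(T = callset_from_keys(c("1:1:C:A", "1:2:C:A", "1:3:C:A")),
             LN = callset_from_keys(c("1:1:C:A", "1:2:C:A")),
             D = callset_from_keys("1:1:C:A"))
  p <- partition_mutations(cs)
  expect_equal(p$trunk, "1:1:C:A")
  expect_equal(p$branch[["LN&T"]], "1:2:C:A")
  expect_equal(p$private$T, "1:3:C:A")
  expect_equal(length(p$branch[["D&T"]]), 0L)
  expect_equal(p$trunk_fraction, 1 / 3)
  expect_equal(td_shared_count(p), 1L)
})

test_that("two different mutations in one gene partition as branch plus private", {
  # T and LN carry one TP53 hotspot, D carries a different TP53 mutation:
  # no trunk, a T&LN branch, a D private call
  r273h <- mk_variants(pos = 7577120, chrom = "17", ref = "C", alt = "T",
                       gene = "TP53")
  y163c <- mk_variants(pos = 7578442, chrom = "17", ref = "T", alt = "C",
                       gene = "TP53")
  p <- partition_mutations(list(T = r273h, LN = r273h, D = y163c))
  expect_equal(length(p$trunk), 0L)
  expect_equal(p$branch[["LN&T"]],
               mutation_key("17", 7577120, "C", "T"))
  expect_equal(p$private$D, mutation_key("17", 7578442, "T", "C"))
  expect_equal(td_shared_count(p), 0L)
})

test_that("identical callsets give trunk fraction 1 and full T&D sharing", {
  keys <- rand_keys(50)
  cs <- lapply(list(T = 1, LN = 2, D = 3), function(i) callset_from_keys(keys))
  p <- partition_mutations(cs)
  expect_equal(p$trunk_fraction, 1.0)
  expect_equal(td_shared_count(p), 50L)
})

test_that("partition agrees with brute-force Venn membership and covers disjointly", {
  set.seed(31)
  for (rep in 1:30) {
    pool <- rand_keys(40)
    ks <- lapply(stats::setNames(c("T", "LN", "D"), c("T", "LN", "D")),
                 function(s) sample(pool, sample(0:30, 1)))
    if (all(lengths(ks) == 0)) next
    p <- partition_mutations(lapply(ks, callset_from_keys))
    o <- oracle_partition(ks)
    expect_setequal(p$trunk, o$trunk)
    for (nm in names(o$branch)) expect_setequal(p$branch[[nm]], o$branch[[nm]])
    for (nm in names(o$private)) expect_setequal(p$private[[nm]], o$private[[nm]])
    pieces <- c(list(p$trunk), p$branch, p$private)
    expect_equal(sum(lengths(pieces)), p$n_total)
  }
})

test_that("partition is invariant to input row order and to role relabeling symmetry", {
  set.seed(5)
  pool <- rand_keys(30)
  ks <- list(T = sample(pool, 20), LN = sample(pool, 15), D = sample(pool, 10))
  p1 <- partition_mutations(lapply(ks, callset_from_keys))
  shuffled <- lapply(ks, function(k) callset_from_keys(sample(k)))
  p2 <- partition_mutations(shuffled)
  expect_setequal(p1$trunk, p2$trunk)
  expect_equal(p1$trunk_fraction, p2$trunk_fraction)
  # swapping the labels of LN and D swaps the corresponding sets
  p3 <- partition_mutations(lapply(ks[c("T", "D", "LN")], callset_from_keys))
  expect_setequal(p3$trunk, p1$trunk)
  expect_setequal(p3$private$LN, p1$private$LN)
  expect_error(partition_mutations(list(T = callset_from_keys(pool[1]))),
               ">= 2")
})

test_that("tree edge lengths count distinct genes and root-to-leaf paths add up", {
  keys <- paste("1", 1:20, "C", "A", sep = ":")
  cs <- list(T = callset_from_keys(keys[1:15]),
             LN = callset_from_keys(keys[c(1:10, 16, 17)]),
             D = callset_from_keys(keys[c(1:10, 18:20)]))
  genes <- stats::setNames(paste0("G", c(1:10, 11:15, 16, 17, 18:20)), keys)
  # trunk = keys 1:10 (10 genes); branch LN&T empty; privates: T 5, LN 2, D 3
  p <- partition_mutations(cs)
  tr <- build_tree(p, genes)
  expect_equal(tr$trunk_genes, 10)
  d <- ape::cophenetic.phylo(tr$tree)
  expect_equal(unname(d["Germline", "T"]), 15)
  expect_equal(unname(d["Germline", "LN"]), 12)
  expect_equal(unname(d["Germline", "D"]), 13)

  # two variants in one gene inside one set count as one gene
  genes2 <- genes
  genes2[keys[11]] <- "G12"  # T-private keys 11,12 now share gene G12
  tr2 <- build_tree(p, genes2)
  d2 <- ape::cophenetic.phylo(tr2$tree)
  expect_equal(unname(d2["Germline", "T"]), 14)

  # empty trunk gives a star from the germline (zero-length trunk edge)
  cs0 <- list(T = callset_from_keys(keys[1:2]), LN = callset_from_keys(keys[3]),
              D = callset_from_keys(keys[4]))
  tr0 <- build_tree(partition_mutations(cs0), genes)
  d0 <- ape::cophenetic.phylo(tr0$tree)
  expect_equal(unname(d0["Germline", "T"]), 2)
  expect_equal(tr0$trunk_genes, 0)
})

test_that("tree path invariant holds on simulated patients with shared branches", {
  set.seed(77)
  cfg <- simulation_config()
  sim <- simulate_patient(cfg, "related", "P01")
  cs <- split(sim$variants, sub(".*_", "", sim$variants$sample_id))[c("T", "LN", "D")]
  p <- partition_mutations(cs)
  allv <- do.call(rbind, cs)
  gene_of <- stats::setNames(allv$gene,
                             mutation_key(allv$chrom, allv$pos, allv$ref, allv$alt))
  gene_of <- gene_of[!duplicated(names(gene_of))]
  tr <- build_tree(p, gene_of)
  d <- ape::cophenetic.phylo(tr$tree)
  for (s in c("T", "LN", "D")) {
    want <- length(unique(gene_of[callset_keys_for_test(cs[[s]])]))
    expect_equal(unname(d["Germline", s]), want)
  }
})

test_that("BAF comparison pairs VAFs over the key union with the tau statistic", {
  a <- callset_from_keys(c("1:1:C:A", "1:2:C:A"))
  expect_equal(compare_baf(a, a)$statistic, 1.0)
  b <- callset_from_keys(c("1:3:C:A", "1:4:C:A"))
  cmp <- compare_baf(a, b)
  expect_equal(cmp$statistic, 0)
  expect_equal(nrow(cmp$table), 4L)
  expect_true(all(cmp$table$vaf_a[cmp$table$key %in% c("1:3:C:A", "1:4:C:A")] == 0))

  set.seed(41)
  cfg <- simulation_config(trunk_fraction_range = c(0.4, 0.4),
                           mutations_per_tumor_range = c(150L, 150L))
  sim <- simulate_patient(cfg, "related", "P01")
  cs <- split(sim$variants, sub(".*_", "", sim$variants$sample_id))
  stat <- compare_baf(cs$T, cs$D)$statistic
  # trunk fraction 0.4 plus the small T&D branch share
  expect_gt(stat, 0.3)
  expect_lt(stat, 0.55)
})

test_that("cross-patient overlap is zero for disjoint cohorts and counts planted keys", {
  cohort <- list(
    P1 = list(T = callset_from_keys(c("1:1:C:A", "1:2:C:A"))),
    P2 = list(T = callset_from_keys(c("1:5:C:A", "1:6:C:A")))
  )
  m <- cross_patient_overlap(cohort)
  expect_true(all(m[!is.na(m)] == 0))
  expect_true(is.na(m["P1.T", "P1.T"]))

  cohort$P2$T <- callset_from_keys(c("1:1:C:A", "1:6:C:A"))
  m2 <- cross_patient_overlap(cohort)
  expect_equal(m2["P1.T", "P2.T"], 1L)
  expect_equal(m2["P2.T", "P1.T"], 1L)
})

test_that("simulated cohorts show essentially no cross-patient sharing", {
  withr::local_seed(13)
  cfg <- simulation_config(n_patients = 6, seed = 13)
  sc <- simulate_cohort(cfg, withr::local_tempdir())
  cohort <- lapply(sc$manifest, function(p) {
    v <- read_variants(p$variant_file)
    split(v, sub(".*_", "", v$sample_id))
  })
  names(cohort) <- vapply(sc$manifest, `[[`, character(1), "patient_id")
  m <- cross_patient_overlap(cohort)
  expect_lte(max(m, na.rm = TRUE), 1L)
})
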