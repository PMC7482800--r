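# builders for small in-code fixtures

mk_variants <- function(pos, chrom = "1", ref = "C", alt = "T",
                        sample_id = "S1", patient_id = "P1",
                        t_depth = 50L, t_alt = 20L, n_depth = 50L, n_alt = 0L,
                        variant_type = "SNV", gene = "G1",
                        effect = "nonsynonymous", context = NULL) {
  n <- length(pos)
  df <- data.frame(
    patient_id = rep_len(patient_id, n), sample_id = rep_len(sample_id, n),
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    variant_type = rep_len(variant_type, n), gene = rep_len(gene, n),
    effect = rep_len(effect, n),
    t_depth = rep_len(as.integer(t_depth), n),
    t_alt = rep_len(as.integer(t_alt), n),
    n_depth = rep_len(as.integer(n_depth), n),
    n_alt = rep_len(as.integer(n_alt), n),
    stringsAsFactors = FALSE
  )
  df$context <- if (is.null(context)) {
    ifelse(df$variant_type == "SNV", paste0("A", df$ref, "A"), "NNN")
  } else rep_len(context, n)
  df
}

# a callset from bare keys (one sample), VAF ~0.4
callset_from_keys <- function(keys, sample_id = "S1") {
  parts <- strsplit(keys, ":", fixed = TRUE)
  mk_variants(pos = vapply(parts, function(p) as.integer(p[2]), integer(1)),
              chrom = vapply(parts, `[[`, character(1), 1),
              ref = vapply(parts, `[[`, character(1), 3),
              alt = vapply(parts, `[[`, character(1), 4),
              sample_id = sample_id)
}

rand_keys <- function(n, prefix = "1") {
  ref <- sample(c("C", "T"), n, replace = TRUE)
  alt <- ifelse(ref == "C", "A", "G")
  paste(prefix, sample.int(1e6, n), ref, alt, sep = ":")
}

# brute-force re-evaluation of the printed high-confidence inequalities,
# one record at a time (independent oracle for the filter module)
oracle_snv_pass <- function(r, cfg = filter_config()) {
  if (r$t_depth == 0 || r$n_depth == 0) return(FALSE)
  r$t_depth >= cfg$min_depth_tumor &&
    r$n_depth >= cfg$min_depth_normal &&
    (r$t_alt / r$t_depth) > cfg$min_vaf_tumor &&
    (r$n_alt / r$n_depth) < cfg$max_vaf_normal &&
    r$t_alt >= cfg$min_alt_reads
}

oracle_indel_pass <- function(r, cfg = filter_config(), germline = character(0)) {
  key <- mutation_key(r$chrom, r$pos, r$ref, r$alt)
  !(key %in% germline) &&
    r$t_depth >= cfg$min_depth_tumor &&
    r$n_depth >= cfg$min_depth_normal &&
    r$n_alt == 0
}

# brute-force Venn membership partition (independent oracle for clonality)
oracle_partition <- function(keysets) {
  samples <- names(keysets)
  all_keys <- unique(unlist(keysets))
  res <- list(trunk = character(0),
              branch = stats::setNames(
                vector("list", 0), character(0)),
              private = lapply(keysets, function(x) character(0)))
  if (length(samples) == 3L) {
    for (i in 1:2) for (j in (i + 1):3) {
      nm <- paste(sort(c(samples[i], samples[j])), collapse = "&")
      res$branch[[nm]] <- character(0)
    }
  }
  for (k in all_keys) {
    inn <- samples[vapply(keysets, function(s) k %in% s, logical(1))]
    if (length(inn) == length(samples)) {
      res$trunk <- c(res$trunk, k)
    } else if (length(inn) == 2L) {
      nm <- paste(sort(inn), collapse = "&")
      res$branch[[nm]] <- c(res$branch[[nm]], k)
    } else {
      res$private[[inn]] <- c(res$private[[inn]], k)
    }
  }
  res
}

callset_keys_for_test <- function(cs) {
  unique(mutation_key(cs$chrom, cs$pos, cs$ref, cs$alt))
}

# brute-force Pearson chi-square on a 2 x k table
oracle_pearson <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
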