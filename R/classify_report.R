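# Per-patient metastasis-versus-second-primary verdict and the cohort
# pipeline: filter -> partition/tree/BAF -> spectra/signatures -> focal
# SCNA -> classify -> report.

#' Pipeline / classification configuration
#'
#' @param filter A [filter_config()].
#' @param min_shared Minimum T&D-shared mutation count (trunk plus T&D
#'   branch) for a metastasis verdict (default 1: any shared mutation
#'   implies clonal relatedness).
#' @param cosine_high,cosine_low SCNA cosine-similarity reference bounds
#'   recorded as secondary evidence (defaults 0.8 / 0.6, the published
#'   group medians).
#' @param spectra_alpha Two-sided significance level for the spectra
#'   chi-square contrast (default 0.05).
#' @param baf_tau VAF threshold of the shared-BAF-cluster statistic.
#' @param n_perm,alpha Permutation count and p-value threshold of the
#'   focal-SCNA analysis.
#' @param window_size SCNA window width in bp (default 1000).
#' @param weight_floor Signature-refit pruning floor (default 0.06).
#' @param seed Seed for the permutation null.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(), min_shared = 1L,
                            cosine_high = 0.8, cosine_low = 0.6,
                            spectra_alpha = 0.05, baf_tau = 0.05,
                            n_perm = 200L, alpha = 0.05,
                            window_size = 1000L, weight_floor = 0.06,
                            seed = 1L) {
  structure(list(filter = filter, min_shared = as.integer(min_shared),
                 cosine_high = cosine_high, cosine_low = cosine_low,
                 spectra_alpha = spectra_alpha, baf_tau = baf_tau,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 window_size = as.integer(window_size),
                 weight_floor = weight_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Classify one patient as metastasis or second primary
#'
#' Primary rule: at least `min_shared` mutations shared between the index
#' (T) and distant (D) tumor (trunk or T&D branch) imply a common clonal
#' origin, hence metastasis; none imply an independent second primary.
#' SCNA cosine similarity, spectra concordance and signature-1 dominance
#' are recorded as named advisory booleans and a concordance count; they
#' never override the mutation-sharing rule.
#'
#' @param partition A [partition_mutations()] result (roles must include T
#'   and D).
#' @param similarity List with `td_cosine` and optionally `tln_cosine`
#'   (use `NA` when unavailable).
#' @param spectra_tests List with `p_value` (T-vs-D spectra chi-square) and
#'   optionally `sig1_dominant_both` (logical).
#' @param config A [pipeline_config()].
#' @param patient_id Identifier copied into the verdict.
#' @return List of class `clonality_verdict`.
#' @export
classify_patient <- function(partition, similarity = list(td_cosine = NA_real_),
                             spectra_tests = list(p_value = NA_real_),
                             config = pipeline_config(),
                             patient_id = NA_character_) {
  if (is.null(partition)) stop("classify_patient requires a mutation partition")
  n_shared <- td_shared_count(partition)
  verdict <- if (n_shared >= config$min_shared) "metastasis" else "primary"
  td_cos <- similarity$td_cosine %||% NA_real_
  tln_cos <- similarity$tln_cosine %||% NA_real_
  sp <- spectra_tests$p_value %||% NA_real_
  sig1 <- spectra_tests$sig1_dominant_both %||% NA
  evidence <- list(
    high_td_cosine = if (is.na(td_cos)) NA else td_cos >= config$cosine_high,
    low_td_cosine = if (is.na(td_cos)) NA else td_cos <= config$cosine_low,
    spectra_concordant = if (is.na(sp)) NA else sp >= config$spectra_alpha,
    sig1_dominant_both = sig1
  )
  supports_met <- c(evidence$high_td_cosine, evidence$spectra_concordant,
                    evidence$sig1_dominant_both)
  supports_spt <- c(evidence$low_td_cosine,
                    if (is.na(evidence$spectra_concordant)) NA
                    else !evidence$spectra_concordant)
  n_concordant <- if (verdict == "metastasis") {
    sum(supports_met, na.rm = TRUE)
  } else {
    sum(supports_spt, na.rm = TRUE)
  }
  conflict <- if (verdict == "metastasis") {
    isTRUE(evidence$low_td_cosine)
  } else {
    isTRUE(evidence$high_td_cosine)
  }
  structure(list(
    patient_id = patient_id, verdict = verdict,
    td_shared_count = n_shared,
    trunk_fraction = partition$trunk_fraction,
    td_cosine = td_cos, tln_cosine = tln_cos, spectra_p = sp,
    concordant_evidence = evidence, n_concordant = n_concordant,
    scna_conflict = conflict
  ), class = "clonality_verdict")
}

#' @export
print.clonality_verdict <- function(x, ...) {
  cat(sprintf("%s: %s (T&D shared = %d, trunk fraction = %.3f, T-D cosine = %s)\n",
              x$patient_id, x$verdict, x$td_shared_count, x$trunk_fraction,
              ifelse(is.na(x$td_cosine), "NA", sprintf("%.2f", x$td_cosine))))
  invisible(x)
}

role_map <- function(patient) {
  roles <- vapply(patient$samples, `[[`, character(1), "role")
  ids <- vapply(patient$samples, `[[`, character(1), "sample_id")
  stats::setNames(ids, roles)[roles != "N"]
}

#' Run the full clonality pipeline on a cohort
#'
#' For every patient: read and filter variants, partition nonsynonymous
#' mutations, build the clone tree, compare T/D B-allele frequencies,
#' compute spectra, contrast T-vs-D spectra, refit signatures; then run the
#' cohort-level focal-SCNA analysis (windows, G-scores, permutation null,
#' regions, levels, per-patient cosines) and classify each patient. A stage
#' error aborts that patient only; the report marks it failed.
#'
#' @param manifest A `cohort_manifest` or path to a manifest file.
#' @param config A [pipeline_config()].
#' @param catalog Signature catalog (default [synthetic_signature_catalog()]).
#' @param genome Named chromosome-length vector (default [toy_genome()]).
#' @param out_dir Optional directory; when given, the JSON report and
#'   per-stage TSV tables are written there.
#' @return List of class `cohort_report`: `verdicts`, `failed`,
#'   `partitions`, `trees`, `baf`, `spectra`, `exposures`, `scna`
#'   (regions, levels, similarities), `summary` (one row per patient).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         catalog = synthetic_signature_catalog(),
                         genome = toy_genome(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  validate_manifest(manifest)
  patients <- vapply(manifest, `[[`, character(1), "patient_id")

  per_patient <- list()
  failed <- list()
  for (p in manifest) {
    pid <- p$patient_id
    res <- tryCatch({
      rm_ <- role_map(p)
      variants <- read_variants(p$variant_file)
      callsets <- lapply(rm_, function(sid) {
        variants[variants$sample_id == sid, , drop = FALSE]
      })
      filtered <- lapply(callsets, function(cs) filter_variants(cs, config$filter))
      passing <- lapply(filtered, `[[`, "passing")
      nonsyn <- lapply(passing, function(cs) {
        cs[cs$effect == "nonsynonymous", , drop = FALSE]
      })
      if (all(vapply(nonsyn, nrow, integer(1)) == 0L)) {
        stop("no passing nonsynonymous mutations in any tumor sample")
      }
      part <- partition_mutations(nonsyn)
      allv <- do.call(rbind, nonsyn)
      gene_of <- stats::setNames(
        allv$gene, mutation_key(allv$chrom, allv$pos, allv$ref, allv$alt))
      gene_of <- gene_of[!duplicated(names(gene_of))]
      tree <- build_tree(part, gene_of)
      baf <- compare_baf(passing$T, passing$D, tau = config$baf_tau)
      spectra <- lapply(passing, mutation_spectrum)
      sp_test <- tryCatch(
        spectra_chisq(spectra$T, spectra$D),
        error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                 p_value = NA_real_))
      expos <- lapply(spectra, function(s) {
        tryCatch(fit_signatures(s, catalog, weight_floor = config$weight_floor),
                 error = function(e) NULL)
      })
      sig1_both <- tryCatch({
        top <- vapply(expos[c("T", "D")], function(e) {
          names(which.max(e$weights))
        }, character(1))
        all(top == "Sig1")
      }, error = function(e) NA)
      list(filtered = filtered, partition = part, tree = tree, baf = baf,
           spectra = spectra, spectra_test = sp_test, exposures = expos,
           sig1_dominant_both = sig1_both, roles = names(rm_))
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "pipeline_failure"))
    if (inherits(res, "pipeline_failure")) {
      failed[[pid]] <- res$message
    } else {
      per_patient[[pid]] <- res
    }
  }

  # cohort-level focal SCNA
  scna <- tryCatch({
    segs <- do.call(rbind, lapply(manifest, function(p) read_seg(p$seg_file)))
    grid <- segments_to_windows(segs, genome, config$window_size)
    perm <- permutation_null(grid, n_perm = config$n_perm, seed = config$seed,
                             alpha = config$alpha)
    regions <- call_regions(perm)
    uniq <- regions[!duplicated(regions[c("chrom", "start", "end")]), ,
                    drop = FALSE]
    levels <- if (nrow(uniq)) classify_levels(uniq, grid) else NULL
    list(grid_samples = grid$samples, regions = regions, levels = levels)
  }, error = function(e) list(error = conditionMessage(e), regions = NULL,
                              levels = NULL))

  pair_cosine <- function(pid, role_a, role_b) {
    lv <- scna$levels
    a <- paste0(pid, "_", role_a)
    b <- paste0(pid, "_", role_b)
    if (is.null(lv) || !a %in% colnames(lv) || !b %in% colnames(lv)) {
      return(NA_real_)
    }
    tryCatch(cosine_similarity(lv, a, b), error = function(e) NA_real_)
  }

  verdicts <- list()
  for (pid in names(per_patient)) {
    pp <- per_patient[[pid]]
    sim <- list(td_cosine = pair_cosine(pid, "T", "D"),
                tln_cosine = if ("LN" %in% pp$roles) {
                  pair_cosine(pid, "T", "LN")
                } else NA_real_)
    verdicts[[pid]] <- classify_patient(
      pp$partition, sim,
      list(p_value = pp$spectra_test$p_value,
           sig1_dominant_both = pp$sig1_dominant_both),
      config, patient_id = pid)
  }

  summary_df <- if (length(verdicts)) {
    do.call(rbind, lapply(verdicts, function(v) {
      data.frame(patient_id = v$patient_id, verdict = v$verdict,
                 td_shared_count = v$td_shared_count,
                 trunk_fraction = v$trunk_fraction,
                 td_cosine = v$td_cosine, tln_cosine = v$tln_cosine,
                 spectra_p = v$spectra_p, n_concordant = v$n_concordant,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(patient_id = character(0), verdict = character(0),
               td_shared_count = integer(0), trunk_fraction = numeric(0),
               td_cosine = numeric(0), tln_cosine = numeric(0),
               spectra_p = numeric(0), n_concordant = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(summary_df) <- NULL

  report <- structure(list(
    verdicts = verdicts,
    failed = failed,
    partitions = lapply(per_patient, `[[`, "partition"),
    trees = lapply(per_patient, function(x) x$tree$newick),
    baf = lapply(per_patient, function(x) x$baf$statistic),
    spectra = lapply(per_patient, `[[`, "spectra"),
    exposures = lapply(per_patient, `[[`, "exposures"),
    scna = scna,
    summary = summary_df,
    n_patients = length(patients)
  ), class = "cohort_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(verdicts, file.path(out_dir, "report.json"),
                 evidence = list(summary = summary_df,
                                 failed = failed))
    utils::write.table(summary_df, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scna$regions) && nrow(scna$regions)) {
      utils::write.table(scna$regions, file.path(out_dir, "focal_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(report$trees)) {
      writeLines(unlist(report$trees), file.path(out_dir, "trees.nwk"))
    }
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort clonality report:", x$n_patients, "patient(s),",
      length(x$failed), "failed\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  if (length(x$failed)) {
    for (p in names(x$failed)) cat("  failed:", p, "-", x$failed[[p]], "\n")
  }
  invisible(x)
}
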