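# Strand-collapsed mutation spectra (6-class and 96-context), chi-square
# contrasts between spectra, refitting of a 96-context profile against a
# reference signature catalog, and recurrence-based candidate gene listing.

#' Mutation spectrum of a callset
#'
#' Counts SNVs in the six pyrimidine-centred substitution classes and the
#' 96 trinucleotide contexts; purine-reference calls are reverse-
#' complemented into the pyrimidine frame, so the spectrum is invariant to
#' the reported strand.
#'
#' @param callset Variant data.frame; only SNV rows are counted. Records
#'   with unannotated contexts (`"N.N"` placeholders) are an error.
#' @return List of class `spectrum_profile`: `class_counts` (length 6),
#'   `context_counts` (length 96), `total`.
#' @export
mutation_spectrum <- function(callset) {
  snv <- callset[callset$variant_type == "SNV", , drop = FALSE]
  ctx96 <- stats::setNames(rep(0, 96L), sbs96_contexts())
  if (nrow(snv)) {
    if (any(grepl("N", snv$context, fixed = TRUE))) {
      stop("record(s) with unannotated trinucleotide context: ",
           paste(utils::head(which(grepl("N", snv$context, fixed = TRUE)), 5),
                 collapse = ","))
    }
    lab <- sbs96_label(snv$ref, snv$alt, snv$context)
    tab <- table(factor(lab, levels = sbs96_contexts()))
    ctx96[] <- as.numeric(tab)
  }
  cls <- sub(".*\\[(.>.)\\].*", "\\1", names(ctx96))
  cls6 <- vapply(stats::setNames(sbs_classes(), sbs_classes()),
                 function(cl) sum(ctx96[cls == cl]), numeric(1))
  structure(list(class_counts = cls6, context_counts = ctx96,
                 total = sum(ctx96)), class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat("mutation spectrum over", x$total, "SNVs\n")
  print(round(x$class_counts, 2))
  invisible(x)
}

#' Chi-square contrast of two mutation spectra
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of 6-class counts. Classes with zero counts in both profiles are
#' dropped; classes whose expected count under independence falls below
#' `pool_below` are pooled into an `"other"` class so the asymptotic test
#' stays valid on small callsets.
#'
#' @param profile_a,profile_b `spectrum_profile` objects or bare 6-class
#'   count vectors.
#' @param pool_below Expected-count threshold for pooling (default 1).
#' @return List: `statistic`, `df`, `p_value`, `table` (the tested table).
#' @export
spectra_chisq <- function(profile_a, profile_b, pool_below = 1) {
  get6 <- function(p) {
    if (inherits(p, "spectrum_profile")) p$class_counts
    else if (is.numeric(p) && length(p) == 6L) stats::setNames(as.numeric(p), sbs_classes())
    else stop("profiles must be spectrum_profile objects or 6-class count vectors")
  }
  a <- get6(profile_a); b <- get6(profile_b)
  if (sum(a) == 0 || sum(b) == 0) stop("cannot contrast a spectrum with zero mutations")
  keep <- a + b > 0
  a <- a[keep]; b <- b[keep]
  tab <- rbind(a = a, b = b)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- apply(exp_tab, 2L, min) < pool_below
  if (any(small) && sum(small) > 1L) {
    tab <- cbind(tab[, !small, drop = FALSE],
                 other = rowSums(tab[, small, drop = FALSE]))
  }
  if (ncol(tab) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Refit a 96-context profile against a signature catalog
#'
#' Nonnegative least squares of the normalized profile on the catalog,
#' followed by iterative pruning in the style of signature-refitting tools:
#' signatures whose normalized weight falls below `weight_floor` are zeroed
#' and the remainder refit, until all surviving weights clear the floor.
#' Reported weights are the surviving nonnegative coefficients, so they sum
#' to the explained fraction of the profile (capped at 1).
#'
#' @param profile `spectrum_profile`, or a 96-long count/probability vector
#'   named by context.
#' @param catalog 96 x K catalog matrix (see [read_signature_catalog()] or
#'   [synthetic_signature_catalog()]).
#' @param weight_floor Minimum reportable contribution (default 0.06).
#' @return List of class `signature_exposure`: `weights` (named, length K,
#'   zeros for pruned signatures), `residual` (L2 norm of the unexplained
#'   part), `explained` (sum of weights).
#' @export
fit_signatures <- function(profile, catalog, weight_floor = 0.06) {
  m <- if (inherits(profile, "spectrum_profile")) profile$context_counts
  else profile
  if (!is.numeric(m) || length(m) != 96L) {
    stop("profile must be a spectrum_profile or a 96-long vector")
  }
  if (!is.null(names(m))) {
    if (!setequal(names(m), sbs96_contexts())) {
      stop("profile names must be the 96 conventional context labels")
    }
    m <- m[sbs96_contexts()]
  }
  if (sum(m) <= 0) stop("cannot fit signatures to an empty profile")
  catalog <- validate_signature_catalog(catalog, tol = 1e-3)
  m <- as.numeric(m) / sum(m)
  active <- seq_len(ncol(catalog))
  w <- rep(0, ncol(catalog))
  repeat {
    fit <- pracma::lsqnonneg(catalog[, active, drop = FALSE], m)
    w[] <- 0
    w[active] <- fit$x
    tot <- sum(w)
    if (tot <= 0) break
    keep <- active[w[active] / tot >= weight_floor]
    if (length(keep) == length(active) || length(keep) == 0L) break
    active <- keep
  }
  if (sum(w) > 1) w <- w / sum(w)
  fitted <- as.numeric(catalog %*% w)
  structure(list(
    weights = stats::setNames(w, colnames(catalog)),
    residual = sqrt(sum((m - fitted)^2)),
    explained = sum(w)
  ), class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  nz <- sort(x$weights[x$weights > 0], decreasing = TRUE)
  cat("signature exposure (", length(nz), " signatures, residual ",
      signif(x$residual, 3), "):\n", sep = "")
  print(round(nz, 3))
  invisible(x)
}

#' Recurrence-based candidate significantly-mutated genes
#'
#' Lists genes non-silently mutated in at least `min_patients` patients,
#' optionally intersected with a user-supplied census gene set (e.g. COSMIC
#' census symbols). This is a recurrence listing, not a background-model
#' SMG test: no per-gene mutation-rate covariates are modelled.
#'
#' @param cohort_callsets Nested named list: patient -> sample -> variant
#'   data.frame.
#' @param min_patients Minimum number of mutated patients (default 2).
#' @param census_genes Optional character vector restricting the candidates.
#' @return data.frame `gene`, `n_patients_mutated`, `samples`
#'   (comma-separated `"patient.sample"` labels), sorted by descending
#'   patient count then gene name.
#' @export
smg_candidates <- function(cohort_callsets, min_patients = 2L,
                           census_genes = NULL) {
  rows <- list()
  for (p in names(cohort_callsets)) {
    for (s in names(cohort_callsets[[p]])) {
      cs <- cohort_callsets[[p]][[s]]
      cs <- cs[cs$effect != "synonymous", , drop = FALSE]
      if (nrow(cs)) {
        rows[[paste(p, s)]] <- data.frame(patient = p,
                                          label = paste(p, s, sep = "."),
                                          gene = unique(cs$gene),
                                          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), n_patients_mutated = integer(0),
                      samples = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  per_gene <- split(df, df$gene)
  out <- do.call(rbind, lapply(per_gene, function(g) {
    data.frame(gene = g$gene[1],
               n_patients_mutated = length(unique(g$patient)),
               samples = paste(sort(unique(g$label)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_patients_mutated >= min_patients, , drop = FALSE]
  if (!is.null(census_genes)) out <- out[out$gene %in% census_genes, , drop = FALSE]
  out <- out[order(-out$n_patients_mutated, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
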