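# High-confidence somatic variant criteria, applied to candidate calls that
# already carry tumor/normal depths and alt-read counts. SNVs: coverage >= 10
# in both compartments, tumor VAF strictly > 10%, normal VAF strictly < 2%,
# >= 3 tumor alt reads. Indels: not in the caller-supplied germline set,
# coverage >= 10 in both compartments, and no alt reads in the normal.

#' Filtering thresholds for high-confidence somatic calls
#'
#' @param min_depth_tumor Minimum tumor depth (default 10).
#' @param min_depth_normal Minimum normal depth (default 10).
#' @param min_vaf_tumor Tumor VAF must be strictly greater (default 0.10).
#' @param max_vaf_normal Normal VAF must be strictly smaller (default 0.02).
#' @param min_alt_reads Minimum tumor alt-read count (default 3).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth_tumor = 10L, min_depth_normal = 10L,
                          min_vaf_tumor = 0.10, max_vaf_normal = 0.02,
                          min_alt_reads = 3L) {
  stopifnot(min_depth_tumor >= 0, min_depth_normal >= 0, min_alt_reads >= 0,
            min_vaf_tumor >= 0, max_vaf_normal >= 0)
  if (min_vaf_tumor <= max_vaf_normal) {
    stop("min_vaf_tumor must exceed max_vaf_normal")
  }
  structure(list(min_depth_tumor = as.integer(min_depth_tumor),
                 min_depth_normal = as.integer(min_depth_normal),
                 min_vaf_tumor = min_vaf_tumor,
                 max_vaf_normal = max_vaf_normal,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "filter_config")
}

#' Variant allele fraction
#'
#' @param alt Alt-read count(s).
#' @param depth Total depth(s); must be positive.
#' @return `alt / depth`, in \[0, 1\].
#' @export
vaf <- function(alt, depth) {
  if (any(depth <= 0)) stop("VAF undefined at zero depth")
  if (any(alt > depth)) stop("alt reads exceed depth")
  alt / depth
}

reject_reasons <- function() {
  c("zero_depth", "tumor_depth", "normal_depth", "tumor_vaf", "normal_vaf",
    "alt_reads", "germline", "normal_alt")
}

#' Filter candidate somatic SNVs to high confidence
#'
#' A record passes iff tumor depth and normal depth meet their minima,
#' tumor VAF is strictly above `min_vaf_tumor`, normal VAF strictly below
#' `max_vaf_normal`, and the tumor alt-read count meets `min_alt_reads`.
#' Records with zero depth in either compartment are rejected with reason
#' `"zero_depth"` (their VAF is undefined). The first failing criterion, in
#' the order depth(T), depth(N), VAF(T), VAF(N), alt reads, is the reported
#' reason.
#'
#' @param records Variant data.frame (SNV rows only).
#' @param config A [filter_config()].
#' @return List of class `filtered_callset`: `passing` (data.frame),
#'   `rejected` (data.frame with a `reason` column).
#' @export
filter_snvs <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(records) && any(records$variant_type != "SNV")) {
    stop("filter_snvs expects SNV records only")
  }
  if (nrow(records) == 0L) {
    return(new_filtered_callset(records, records, character(0)))
  }
  reason <- rep(NA_character_, nrow(records))
  zero <- records$t_depth == 0L | records$n_depth == 0L
  reason[zero] <- "zero_depth"
  chk <- function(cond, code) {
    hit <- is.na(reason) & cond
    reason[hit] <<- code
  }
  chk(records$t_depth < config$min_depth_tumor, "tumor_depth")
  chk(records$n_depth < config$min_depth_normal, "normal_depth")
  tv <- ifelse(records$t_depth > 0L, records$t_alt / records$t_depth, NA_real_)
  nv <- ifelse(records$n_depth > 0L, records$n_alt / records$n_depth, NA_real_)
  chk(!is.na(tv) & tv <= config$min_vaf_tumor, "tumor_vaf")
  chk(!is.na(nv) & nv >= config$max_vaf_normal, "normal_vaf")
  chk(records$t_alt < config$min_alt_reads, "alt_reads")
  split_callset(records, reason)
}

#' Filter candidate somatic indels to high confidence
#'
#' A record passes iff its mutation key is not in the caller-supplied
#' germline set, both depths meet their minima, and the normal carries no
#' alt reads. The paper-style pipeline states no tumor-VAF rule for indels;
#' the zero-normal-alt requirement is this package's conservative stand-in
#' for "high-confidence somatic".
#'
#' @param records Variant data.frame (indel rows only).
#' @param config A [filter_config()].
#' @param germline_set Character vector of germline [mutation_key()]s
#'   (possibly empty).
#' @return A `filtered_callset` (see [filter_snvs()]).
#' @export
filter_indels <- function(records, config = filter_config(),
                          germline_set = character(0)) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(records) && any(records$variant_type != "indel")) {
    stop("filter_indels expects indel records only")
  }
  if (nrow(records) == 0L) {
    return(new_filtered_callset(records, records, character(0)))
  }
  reason <- rep(NA_character_, nrow(records))
  keys <- mutation_key(records$chrom, records$pos, records$ref, records$alt)
  reason[keys %in% germline_set] <- "germline"
  chk <- function(cond, code) {
    hit <- is.na(reason) & cond
    reason[hit] <<- code
  }
  chk(records$t_depth < config$min_depth_tumor, "tumor_depth")
  chk(records$n_depth < config$min_depth_normal, "normal_depth")
  chk(records$n_alt > 0L, "normal_alt")
  split_callset(records, reason)
}

split_callset <- function(records, reason) {
  pass <- is.na(reason)
  new_filtered_callset(records[pass, , drop = FALSE],
                       records[!pass, , drop = FALSE],
                       reason[!pass])
}

new_filtered_callset <- function(passing, rejected, reasons) {
  rownames(passing) <- NULL
  rejected$reason <- reasons
  rownames(rejected) <- NULL
  structure(list(passing = passing, rejected = rejected),
            class = "filtered_callset")
}

#' @export
print.filtered_callset <- function(x, ...) {
  cat("filtered callset:", nrow(x$passing), "passing,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Filter a mixed SNV/indel callset
#'
#' Convenience wrapper splitting records by `variant_type` and applying
#' [filter_snvs()] / [filter_indels()].
#'
#' @inheritParams filter_indels
#' @param records Variant data.frame (mixed types allowed).
#' @return A `filtered_callset` over all records.
#' @export
filter_variants <- function(records, config = filter_config(),
                            germline_set = character(0)) {
  snv <- filter_snvs(records[records$variant_type == "SNV", , drop = FALSE],
                     config)
  ind <- filter_indels(records[records$variant_type == "indel", , drop = FALSE],
                       config, germline_set)
  new_filtered_callset(rbind(snv$passing, ind$passing),
                       rbind(snv$rejected[setdiff(names(snv$rejected), "reason")],
                             ind$rejected[setdiff(names(ind$rejected), "reason")]),
                       c(snv$rejected$reason, ind$rejected$reason))
}
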