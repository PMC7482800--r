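# External representations: variant TSV/VCF, SEG, signature catalog, cohort
# manifest, cohort report. All readers validate strictly and return plain
# typed data.frames / lists; downstream modules never touch files.

variant_columns <- function() {
  c("patient_id", "sample_id", "chrom", "pos", "ref", "alt", "variant_type",
    "gene", "effect", "t_depth", "t_alt", "n_depth", "n_alt", "context")
}

#' Validate a data.frame of candidate variant records
#'
#' Enforces the on-disk contract: alt counts bounded by depths, SNVs are
#' single-base with a 3-mer context whose middle base is the reference
#' allele. Errors name the offending row numbers (1-based, header excluded).
#'
#' @param df data.frame carrying the columns of [variant_columns()].
#' @return The validated data.frame with normalized chromosome names.
#' @export
validate_variants <- function(df) {
  miss <- setdiff(variant_columns(), names(df))
  if (length(miss)) {
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- df[variant_columns()]
  if (nrow(df) == 0L) return(df)
  for (col in c("pos", "t_depth", "t_alt", "n_depth", "n_alt")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      stop("non-integer value in column '", col, "' at row(s) ",
           paste(which(is.na(v)), collapse = ","))
    }
    df[[col]] <- v
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$context <- toupper(as.character(df$context))
  bad_type <- !df$variant_type %in% c("SNV", "indel")
  if (any(bad_type)) {
    stop("variant_type must be 'SNV' or 'indel'; bad row(s): ",
         paste(which(bad_type), collapse = ","))
  }
  bad_eff <- !df$effect %in% c("nonsynonymous", "synonymous", "other")
  if (any(bad_eff)) {
    stop("effect must be nonsynonymous/synonymous/other; bad row(s): ",
         paste(which(bad_eff), collapse = ","))
  }
  neg <- df$t_depth < 0L | df$n_depth < 0L | df$t_alt < 0L | df$n_alt < 0L
  if (any(neg)) stop("negative count at row(s) ", paste(which(neg), collapse = ","))
  bad_t <- df$t_alt > df$t_depth
  if (any(bad_t)) {
    stop("t_alt > t_depth at row(s) ", paste(which(bad_t), collapse = ","))
  }
  bad_n <- df$n_alt > df$n_depth
  if (any(bad_n)) {
    stop("n_alt > n_depth at row(s) ", paste(which(bad_n), collapse = ","))
  }
  snv <- df$variant_type == "SNV"
  if (any(snv)) {
    # "N<ref>N" marks an SNV whose flanking bases are not annotated
    # (e.g. VCF input); spectra refuse such records, nothing else does
    bad_snv <- snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L |
                        nchar(df$context) != 3L |
                        substr(df$context, 2L, 2L) != df$ref)
    if (any(bad_snv)) {
      stop("SNV must have 1-bp ref/alt and a 3-mer context centred on ref; ",
           "bad row(s): ", paste(which(bad_snv), collapse = ","))
    }
  }
  df
}

#' Read candidate somatic variant calls
#'
#' The canonical dialect is a header-driven TSV with the columns of
#' [variant_columns()]. A VCF 4.x dialect is supported read-only: per-sample
#' AD fields are mapped to depths/alt counts through a tumor/normal
#' sample-name mapping (requires the `vcfR` package).
#'
#' @param path Input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param patient_id Patient identifier for VCF input (TSV carries its own).
#' @param sample_map For VCF: named character vector
#'   `c(tumor = "<vcf sample>", normal = "<vcf sample>")`.
#' @param sample_id Sample identifier for the tumor in VCF input; defaults to
#'   the VCF tumor sample name.
#' @return Validated data.frame of variant records.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"), patient_id = NULL,
                          sample_map = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    return(validate_variants(df))
  }
  read_variants_vcf(path, patient_id = patient_id, sample_map = sample_map,
                    sample_id = sample_id)
}

read_variants_vcf <- function(path, patient_id, sample_map, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the 'vcfR' package")
  }
  if (is.null(sample_map) || !all(c("tumor", "normal") %in% names(sample_map))) {
    stop("VCF input requires sample_map = c(tumor=..., normal=...)")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(validate_variants(empty_variants()))
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in sample_map) {
    if (!s %in% colnames(ad)) stop("VCF lacks sample '", s, "'")
  }
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    ref_n <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    alt_n <- vapply(parts, function(p) {
      if (length(p) < 2L) 0L else as.integer(p[2])
    }, integer(1))
    cbind(ref_n, alt_n)
  }
  t_ad <- split_ad(ad[, sample_map[["tumor"]]])
  n_ad <- split_ad(ad[, sample_map[["normal"]]])
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  ctx <- rep("NNN", nrow(fix))
  ctx[is_snv] <- paste0("N", fix$REF[is_snv], "N")
  df <- data.frame(
    patient_id = patient_id %||% "unknown",
    sample_id = sample_id %||% sample_map[["tumor"]],
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_type = ifelse(is_snv, "SNV", "indel"),
    gene = "NA", effect = "other",
    t_depth = t_ad[, 1] + t_ad[, 2], t_alt = t_ad[, 2],
    n_depth = n_ad[, 1] + n_ad[, 2], n_alt = n_ad[, 2],
    context = ctx, stringsAsFactors = FALSE
  )
  validate_variants(df)
}

empty_variants <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(variant_columns())), variant_columns()),
    stringsAsFactors = FALSE)
  for (col in c("pos", "t_depth", "t_alt", "n_depth", "n_alt")) {
    df[[col]] <- integer(0)
  }
  df
}

#' Write variant records to the canonical TSV dialect
#' @param records Validated variant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(records, path) {
  records <- validate_variants(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SEG-style segmented copy-ratio file
#'
#' Accepts the canonical header (`sample_id`, `chrom`, `start`, `end`,
#' `log2_ratio`) or the common SEG spelling (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `seg.mean`). Coordinates are 1-based inclusive on disk.
#'
#' @param path Input TSV.
#' @return data.frame sorted by (sample_id, chrom, start); overlapping
#'   segments within a sample/chromosome are an error.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  alias <- c(ID = "sample_id", Sample = "sample_id", chromosome = "chrom",
             loc.start = "start", loc.end = "end", seg.mean = "log2_ratio")
  for (a in names(alias)) {
    if (a %in% names(df) && !alias[[a]] %in% names(df)) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  validate_seg(df)
}

#' Validate segmented copy-ratio records
#' @param df data.frame with columns sample_id, chrom, start, end, log2_ratio.
#' @return Validated data.frame sorted by (sample_id, chrom, start).
#' @export
validate_seg <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("SEG table is missing required column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[need]
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$log2_ratio <- as.numeric(df$log2_ratio)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$log2_ratio)) {
    stop("SEG table contains non-numeric coordinates or ratios")
  }
  if (any(df$start > df$end)) {
    stop("SEG start > end at row(s) ",
         paste(which(df$start > df$end), collapse = ","))
  }
  if (any(df$start < 1L)) stop("SEG coordinates are 1-based; start < 1 found")
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    same <- df$sample_id[-1L] == df$sample_id[-nrow(df)] &
      df$chrom[-1L] == df$chrom[-nrow(df)]
    ovl <- same & df$start[-1L] <= df$end[-nrow(df)]
    if (any(ovl)) {
      stop("overlapping segments within one sample/chromosome (sorted row(s) ",
           paste(which(ovl) + 1L, collapse = ","), ")")
    }
  }
  df
}

#' Write segments as canonical SEG TSV
#' @param segs Validated SEG data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  segs <- validate_seg(segs)
  utils::write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 96-context mutational-signature catalog
#'
#' Expects a TSV whose first column holds the 96 trinucleotide context
#' labels (`A[C>A]A` ... `T[T>G]T`) and whose remaining columns are
#' signature probability vectors. Rows are reordered to the conventional
#' order; columns whose sum is within `tol` of 1 are renormalized, anything
#' further off is an error.
#'
#' @param path Input TSV.
#' @param tol Column-sum tolerance before renormalization (default 1e-3).
#' @return Numeric 96 x K matrix with context rownames and signature colnames.
#' @export
read_signature_catalog <- function(path, tol = 1e-3) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("signature catalog needs a context column plus >=1 signature")
  ctx <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ctx
  validate_signature_catalog(mat, tol = tol)
}

#' Validate (and renormalize) a signature catalog matrix
#' @param mat 96 x K numeric matrix with context rownames.
#' @param tol Column-sum tolerance before renormalization.
#' @return The validated matrix in canonical row order.
#' @export
validate_signature_catalog <- function(mat, tol = 1e-3) {
  want <- sbs96_contexts()
  if (nrow(mat) != 96L) stop("signature catalog must have 96 context rows, got ", nrow(mat))
  if (!setequal(rownames(mat), want)) {
    stop("signature catalog context labels do not match the 96 conventional labels")
  }
  mat <- mat[want, , drop = FALSE]
  if (any(mat < 0)) stop("signature catalog contains negative entries")
  cs <- colSums(mat)
  off <- abs(cs - 1) > tol
  if (any(off)) {
    stop("signature column(s) not summing to 1 within ", tol, ": ",
         paste(colnames(mat)[off] %||% which(off), collapse = ", "))
  }
  sweep(mat, 2L, cs, "/")
}

#' Write a signature catalog as TSV
#' @param mat 96 x K catalog matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(mat, path) {
  mat <- validate_signature_catalog(mat)
  df <- data.frame(context = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest (YAML or JSON)
#'
#' The manifest lists, per patient, the sample roles (T = index esophageal
#' tumor, LN = lymph-node metastasis, D = distant tumor, N = matched
#' normal) and the per-patient variant and segment files. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest file; format chosen by extension (.yaml/.yml/.json).
#' @return List of class `cohort_manifest` with one entry per patient.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else stop("manifest must be .yaml/.yml or .json")
  patients <- raw$patients %||% raw
  base <- dirname(normalizePath(path))
  out <- lapply(patients, function(p) {
    p$samples <- lapply(p$samples, function(s) {
      list(sample_id = as.character(s$sample_id), role = as.character(s$role))
    })
    for (f in c("variant_file", "seg_file")) {
      if (!is.null(p[[f]]) && !grepl("^/", p[[f]])) {
        p[[f]] <- file.path(base, p[[f]])
      }
    }
    p
  })
  validate_manifest(structure(out, class = "cohort_manifest"))
}

#' Validate a cohort manifest
#' @param manifest A `cohort_manifest` list.
#' @return The manifest, invisibly on success.
#' @export
validate_manifest <- function(manifest) {
  for (p in manifest) {
    roles <- vapply(p$samples, `[[`, character(1), "role")
    ids <- vapply(p$samples, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids)) {
      stop("patient ", p$patient_id, ": duplicate sample_id")
    }
    bad <- !roles %in% c("T", "LN", "D", "N")
    if (any(bad)) stop("patient ", p$patient_id, ": unknown role ", roles[bad][1])
    if (sum(roles == "N") != 1L) {
      stop("patient ", p$patient_id, ": exactly one normal (N) sample required")
    }
    if (sum(roles == "T") < 1L || sum(roles == "D") < 1L) {
      stop("patient ", p$patient_id, ": at least one T and one D sample required")
    }
  }
  invisible(manifest)
}

#' Write a cohort manifest as YAML
#' @param manifest A `cohort_manifest` list.
#' @param path Output path (.yaml).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  yaml::write_yaml(list(patients = lapply(manifest, unclass)), path)
  invisible(path)
}

#' Serialize a cohort clonality report as versioned JSON
#'
#' @param verdicts List of `clonality_verdict` objects (see
#'   [classify_patient()]), or the `verdicts` element of a pipeline report.
#' @param path Output path.
#' @param evidence Optional named list of per-stage evidence tables
#'   (data.frames), serialized alongside the verdicts.
#' @return `path`, invisibly.
#' @export
write_report <- function(verdicts, path, evidence = NULL) {
  doc <- list(
    schema_version = "1.0",
    n_patients = length(verdicts),
    verdicts = lapply(verdicts, unclass),
    evidence = evidence
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) stop("cannot write report to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a JSON clonality report
#' @param path Report written by [write_report()].
#' @return List with `schema_version`, `n_patients`, `verdicts`, `evidence`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) stop("not a clonemark report: missing schema_version")
  doc
}
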