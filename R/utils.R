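#' Canonical mutation identity key
#'
#' Sharing of somatic mutations between tumors is decided by exact identity
#' of (chromosome, position, ref, alt); no fuzzy matching is attempted, for
#' indels either.
#'
#' @param chrom Chromosome name(s); the "chr" prefix is stripped.
#' @param pos 1-based position(s).
#' @param ref,alt Reference and alternate alleles.
#' @return Character vector of keys of the form `"chrom:pos:ref:alt"`.
#' @export
mutation_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Strip any "chr" prefix from chromosome names
#' @param x Character vector of chromosome names.
#' @return Character vector without "chr" prefixes.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings (ACGT alphabet).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    bad <- !b %in% names(comp)
    if (any(bad)) stop("non-ACGT base in sequence: ", paste(b[bad], collapse = ","))
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' The six pyrimidine-centred substitution classes
#' @return `c("C>A","C>G","C>T","T>A","T>C","T>G")`
#' @export
sbs_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution contexts in conventional order
#'
#' Class-major ordering (all 16 C>A contexts, then C>G, ... T>G), with the
#' 5' base cycling slowest: `A[C>A]A, A[C>A]C, ..., T[T>G]T`.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`.
#' @export
sbs96_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbs_classes(), function(cl) {
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", cl, "]", p3)
    })))
  }))
}

#' Map SNVs to 96-context labels, collapsing purine-reference calls
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @param context 3-mer contexts centred on `ref`.
#' @return Character vector of labels in the `sbs96_contexts()` alphabet.
#' @keywords internal
sbs96_label <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- length(ref)
  bad <- nchar(ref) != 1L | nchar(alt) != 1L | nchar(context) != 3L |
    substr(context, 2L, 2L) != ref
  if (any(bad)) {
    stop("invalid SNV context at record(s) ", paste(which(bad), collapse = ","),
         ": context must be a 3-mer whose middle base equals ref")
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ref[pur] <- revcomp(ref[pur])
    alt[pur] <- revcomp(alt[pur])
    context[pur] <- revcomp(context[pur])
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}

#' Toy genome model used throughout the examples and tests
#'
#' Three 10-Mb chromosomes; real chromosome sizes can be supplied as any
#' named vector of lengths (see [read_genome()]).
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
toy_genome <- function() c(`1` = 1e7, `2` = 1e7, `3` = 1e7)

#' Read a genome model from a two-column TSV (chrom, length)
#' @param path Path to a tab-separated file with columns `chrom`, `length`.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length")
  if (!all(need %in% names(df))) {
    stop("genome file must have columns: ", paste(need, collapse = ", "))
  }
  stats::setNames(as.numeric(df$length), normalize_chrom(df$chrom))
}

# run body with a private RNG seed, restoring the caller's RNG state
with_private_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(body)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
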