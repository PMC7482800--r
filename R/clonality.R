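# Trunk/branch/private partition of a patient's nonsynonymous mutations,
# per-patient phylogeny with gene-count edge lengths, B-allele-frequency
# comparison between tumors, and the cross-patient coincidence control.

callset_keys <- function(callset, nonsynonymous_only = TRUE) {
  if (nonsynonymous_only) {
    callset <- callset[callset$effect == "nonsynonymous", , drop = FALSE]
  }
  unique(mutation_key(callset$chrom, callset$pos, callset$ref, callset$alt))
}

pair_name <- function(a, b) paste(sort(c(a, b)), collapse = "&")

#' Partition a patient's mutations into trunk / branch / private sets
#'
#' Trunk mutations are present in every tumor sample of the patient (for
#' two-sample patients the pairwise intersection is the trunk); branch
#' mutations are present in exactly two of three samples; private mutations
#' in exactly one. The partition is a disjoint cover of the patient's
#' nonsynonymous mutation keys, asserted on every run.
#'
#' @param callsets Named list of filtered variant data.frames, one per tumor
#'   sample; names are the sample roles (e.g. `T`, `LN`, `D`). Two or three
#'   samples are supported. Only nonsynonymous records are used.
#' @return List of class `mutation_partition` with elements `trunk`
#'   (character keys), `branch` (named list, e.g. `$"LN&T"`), `private`
#'   (named list per sample), `trunk_fraction`, `n_total`, `samples`.
#' @export
partition_mutations <- function(callsets) {
  if (length(callsets) < 2L) stop("partition requires >= 2 tumor samples")
  if (length(callsets) > 3L) stop("partition supports at most 3 tumor samples")
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    stop("callsets must be a named list (names = sample roles)")
  }
  keysets <- lapply(callsets, callset_keys)
  samples <- names(keysets)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, samples))
  if (length(all_keys) == 0L) {
    member <- matrix(logical(0), 0L, length(samples),
                     dimnames = list(NULL, samples))
  }
  count <- rowSums(member)
  trunk <- all_keys[count == length(samples)]
  branch <- list()
  if (length(samples) == 3L) {
    for (i in 1:2) for (j in (i + 1):3) {
      in_pair <- member[, i] & member[, j] & count == 2L
      branch[[pair_name(samples[i], samples[j])]] <- all_keys[in_pair]
    }
  }
  private <- lapply(stats::setNames(samples, samples), function(s) {
    all_keys[member[, s] & count == 1L]
  })
  part <- structure(list(
    trunk = trunk, branch = branch, private = private,
    trunk_fraction = if (length(all_keys)) length(trunk) / length(all_keys) else NA_real_,
    n_total = length(all_keys), samples = samples
  ), class = "mutation_partition")
  assert_disjoint_cover(part, all_keys)
  part
}

assert_disjoint_cover <- function(part, all_keys) {
  pieces <- c(list(part$trunk), part$branch, part$private)
  flat <- unlist(pieces, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, all_keys)) {
    stop("internal error: partition is not a disjoint cover")  # nocov
  }
  invisible(TRUE)
}

#' @export
print.mutation_partition <- function(x, ...) {
  cat("mutation partition over", paste(x$samples, collapse = "/"),
      "-", x$n_total, "keys\n")
  cat("  trunk:", length(x$trunk),
      sprintf("(fraction %.3f)\n", x$trunk_fraction))
  for (b in names(x$branch)) cat("  branch", b, ":", length(x$branch[[b]]), "\n")
  for (p in names(x$private)) cat("  private", p, ":", length(x$private[[p]]), "\n")
  invisible(x)
}

#' Count mutations shared between the index (T) and distant (D) tumors
#'
#' The quantity the metastasis-versus-primary verdict rests on: trunk
#' mutations plus T&D-shared branch mutations (the branch term is zero for
#' two-sample patients).
#'
#' @param partition A [partition_mutations()] result whose samples include
#'   roles `T` and `D`.
#' @return Integer count.
#' @export
td_shared_count <- function(partition) {
  stopifnot(inherits(partition, "mutation_partition"))
  if (!all(c("T", "D") %in% partition$samples)) {
    stop("td_shared_count requires samples with roles T and D")
  }
  n <- length(partition$trunk)
  td <- partition$branch[[pair_name("T", "D")]]
  n + length(td %||% character(0))
}

#' Build the per-patient phylogenetic tree
#'
#' A rooted tree with a germline root, a trunk edge, at most one internal
#' branch node (the largest pairwise shared set, by gene count), and one
#' leaf per tumor sample. Edge lengths are counts of distinct
#' nonsynonymous mutated genes, so the root-to-leaf path length equals the
#' number of distinct mutated genes in that sample.
#'
#' @param partition A [partition_mutations()] result.
#' @param gene_of Named character vector mapping mutation keys to gene
#'   symbols (must cover every key in the partition).
#' @return List of class `clone_tree`: `tree` (an [ape::phylo] with a
#'   zero-length `Germline` leaf), `newick`, and the per-set distinct gene
#'   counts.
#' @export
build_tree <- function(partition, gene_of) {
  stopifnot(inherits(partition, "mutation_partition"))
  all_keys <- c(partition$trunk, unlist(partition$branch, use.names = FALSE),
                unlist(partition$private, use.names = FALSE))
  missing <- setdiff(all_keys, names(gene_of))
  if (length(missing)) {
    stop("gene_of lacks ", length(missing), " key(s), e.g. ", missing[1])
  }
  genes <- function(keys) unique(unname(gene_of[keys]))
  samples <- partition$samples
  sample_keys <- lapply(stats::setNames(samples, samples), function(s) {
    br <- partition$branch[grepl(paste0("(^|&)", s, "(&|$)"), names(partition$branch))]
    c(partition$trunk, unlist(br, use.names = FALSE), partition$private[[s]])
  })
  trunk_genes <- genes(partition$trunk)
  branch_sizes <- vapply(partition$branch, function(k) {
    length(setdiff(genes(k), trunk_genes))
  }, numeric(1))
  big <- if (length(branch_sizes) && max(branch_sizes) > 0) {
    names(branch_sizes)[which.max(branch_sizes)]
  } else NULL
  big_members <- if (is.null(big)) character(0) else strsplit(big, "&", fixed = TRUE)[[1]]
  big_len <- if (is.null(big)) 0 else unname(branch_sizes[[big]])
  leaf_edge <- vapply(samples, function(s) {
    anc <- trunk_genes
    if (s %in% big_members) anc <- union(anc, genes(partition$branch[[big]]))
    length(setdiff(genes(sample_keys[[s]]), anc))
  }, numeric(1))
  inner <- if (length(big_members)) {
    paste0("(", paste0(big_members, ":", leaf_edge[big_members], collapse = ","),
           "):", big_len)
  } else NULL
  rest <- setdiff(samples, big_members)
  tips <- c(inner, paste0(rest, ":", leaf_edge[rest]))
  newick <- paste0("(Germline:0,(", paste(tips, collapse = ","), "):",
                   length(trunk_genes), ");")
  structure(list(
    tree = ape::read.tree(text = newick),
    newick = newick,
    trunk_genes = length(trunk_genes),
    branch_genes = stats::setNames(as.numeric(branch_sizes),
                                   names(branch_sizes)),
    leaf_genes = leaf_edge
  ), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone tree:", x$newick, "\n")
  invisible(x)
}

#' Compare the B-allele (variant allele) frequency distributions of two tumors
#'
#' Pairs the VAFs of the union of the two callsets' mutation keys (0 where a
#' key is absent from a sample) and reports a shared-cluster statistic: the
#' fraction of union keys whose VAF reaches `tau` in both samples. The
#' statistic operationalizes the visual shared-BAF-cluster comparison; the
#' threshold is an explicit knob, not a published rule.
#'
#' @param callset_a,callset_b Filtered variant data.frames with depths.
#' @param tau VAF threshold for calling a mutation present (default 0.05).
#' @return List of class `baf_comparison`: `table` (key, vaf_a, vaf_b),
#'   `statistic`, `tau`.
#' @export
compare_baf <- function(callset_a, callset_b, tau = 0.05) {
  vaf_of <- function(cs) {
    keys <- mutation_key(cs$chrom, cs$pos, cs$ref, cs$alt)
    v <- ifelse(cs$t_depth > 0L, cs$t_alt / cs$t_depth, 0)
    stats::setNames(v, keys)[!duplicated(keys)]
  }
  va <- vaf_of(callset_a)
  vb <- vaf_of(callset_b)
  keys <- union(names(va), names(vb))
  tab <- data.frame(
    key = keys,
    vaf_a = ifelse(keys %in% names(va), va[keys], 0),
    vaf_b = ifelse(keys %in% names(vb), vb[keys], 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  stat <- if (nrow(tab)) mean(tab$vaf_a >= tau & tab$vaf_b >= tau) else NA_real_
  structure(list(table = tab, statistic = stat, tau = tau),
            class = "baf_comparison")
}

#' Cross-patient shared-mutation control
#'
#' Counts mutation keys shared between every pair of tumors from different
#' patients. Within-patient sharing is real clonal signal; between-patient
#' sharing would indicate coincidence or artifacts, and the matrix lets the
#' analyst verify it is (near) zero.
#'
#' @param cohort_callsets Nested named list: patient -> sample -> variant
#'   data.frame.
#' @return Symmetric integer matrix over `"patient.sample"` tumor labels;
#'   same-patient cells are `NA` (excluded from the control).
#' @export
cross_patient_overlap <- function(cohort_callsets) {
  if (length(cohort_callsets) < 2L) stop("need >= 2 patients")
  flat <- list()
  owner <- character(0)
  for (p in names(cohort_callsets)) {
    for (s in names(cohort_callsets[[p]])) {
      flat[[paste(p, s, sep = ".")]] <- callset_keys(cohort_callsets[[p]][[s]])
      owner[paste(p, s, sep = ".")] <- p
    }
  }
  n <- length(flat)
  m <- matrix(NA_integer_, n, n, dimnames = list(names(flat), names(flat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (owner[i] != owner[j]) {
        m[i, j] <- length(intersect(flat[[i]], flat[[j]]))
      }
    }
  }
  m
}
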