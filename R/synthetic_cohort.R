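# Synthetic multi-tumor patients with known ground truth. Each patient has
# an esophageal index tumor (T), a lymph-node metastasis (LN), a distant
# lung tumor (D) and a matched normal (N). "related" patients share a trunk
# mutation set across T/LN/D and most focal SCNAs between T and D;
# "independent" patients share mutations and SCNAs between T and LN only,
# with a C>A-dominated signature mixture in D.

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the published cohort summaries: trunk fractions spanning
#' 12.0%-70.5%, 13-237 somatic mutations per patient subtree, ~149x mean
#' depth, an age-related (Sig1-dominated) mixture for clonally related
#' tumors and a C>A-dominated (Sig4/Sig29) mixture for independent lung
#' tumors, 100 focal regions with a 60% copy-neutral prior per region.
#'
#' @param n_patients Number of patients (default 20).
#' @param fraction_spt Fraction of patients simulated as independent second
#'   primaries; allocation is deterministic (`round(n * fraction)`), not
#'   Bernoulli.
#' @param trunk_fraction_range Range the per-patient trunk fraction is
#'   drawn from, uniformly.
#' @param mutations_per_tumor_range Range of the per-patient mutation-union
#'   size (drawn uniformly; a tumor carries the trunk plus its branch and
#'   private shares of the union).
#' @param mean_depth Poisson mean sequencing depth for tumor and normal.
#' @param tumor_purity Tumor cell fraction in (0, 1].
#' @param signature_mix_related Named weights over catalog signatures for
#'   clonally related tumors (sums to 1).
#' @param signature_mix_independent_D Named weights for the independent
#'   distant tumor.
#' @param n_focal_regions Number of focal SCNA regions laid out on the
#'   genome.
#' @param shared_scna_fraction_related Fraction of a related T/D pair's
#'   pooled aberrant regions that are shared (ancestral).
#' @param shared_scna_fraction_independent Same, for independent T/D pairs.
#' @param seed Integer seed making the cohort reproducible.
#' @param genome Named chromosome-length vector (default [toy_genome()]).
#' @param ccf_trunk,ccf_branch,ccf_private Cancer-cell fractions used for
#'   read-count sampling per mutation class.
#' @param normal_error Per-read error rate in the normal compartment.
#' @param aberrant_prob Per-region probability of a non-neutral level
#'   (level prior: P(0) = 1 - aberrant_prob, others uniform).
#' @param region_width_kb Width of each focal region in kb.
#' @param seg_chunk_kb Segmentation resolution: one SEG row (one noise
#'   draw, sd `scna_noise_sd`) per chunk of this many kb.
#' @param scna_noise_sd Gaussian noise added to level-midpoint log2 ratios.
#' @param branch_probs For related trios, the split of non-trunk mutation
#'   mass assigned to the `T&LN`, `T&D` and `LN&D` branches (remainder is
#'   private, equally per sample).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20L,
                              fraction_spt = 0.5,
                              trunk_fraction_range = c(0.12, 0.705),
                              mutations_per_tumor_range = c(13L, 237L),
                              mean_depth = 149L,
                              tumor_purity = 0.8,
                              signature_mix_related = c(Sig1 = 0.8, Sig5 = 0.2),
                              signature_mix_independent_D = c(Sig4 = 0.5, Sig29 = 0.3, Sig1 = 0.2),
                              n_focal_regions = 100L,
                              shared_scna_fraction_related = 0.8,
                              shared_scna_fraction_independent = 0.05,
                              seed = 1L,
                              genome = toy_genome(),
                              ccf_trunk = 1.0, ccf_branch = 1.0,
                              ccf_private = 0.6,
                              normal_error = 0.001,
                              aberrant_prob = 0.4,
                              region_width_kb = 30L,
                              seg_chunk_kb = 5L,
                              scna_noise_sd = 0.1,
                              branch_probs = c(0.12, 0.04, 0.04)) {
  cfg <- list(n_patients = as.integer(n_patients), fraction_spt = fraction_spt,
              trunk_fraction_range = trunk_fraction_range,
              mutations_per_tumor_range = as.integer(mutations_per_tumor_range),
              mean_depth = as.integer(mean_depth), tumor_purity = tumor_purity,
              signature_mix_related = signature_mix_related,
              signature_mix_independent_D = signature_mix_independent_D,
              n_focal_regions = as.integer(n_focal_regions),
              shared_scna_fraction_related = shared_scna_fraction_related,
              shared_scna_fraction_independent = shared_scna_fraction_independent,
              seed = as.integer(seed), genome = genome,
              ccf_trunk = ccf_trunk, ccf_branch = ccf_branch,
              ccf_private = ccf_private, normal_error = normal_error,
              aberrant_prob = aberrant_prob,
              region_width_kb = as.integer(region_width_kb),
              seg_chunk_kb = as.integer(seg_chunk_kb),
              scna_noise_sd = scna_noise_sd,
              branch_probs = branch_probs)
  validate_simulation_config(structure(cfg, class = "simulation_config"))
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0L,
            cfg$fraction_spt >= 0, cfg$fraction_spt <= 1,
            length(cfg$trunk_fraction_range) == 2L,
            diff(cfg$trunk_fraction_range) >= 0,
            all(cfg$trunk_fraction_range >= 0),
            all(cfg$trunk_fraction_range <= 1),
            length(cfg$mutations_per_tumor_range) == 2L,
            diff(cfg$mutations_per_tumor_range) >= 0,
            cfg$mutations_per_tumor_range[1] >= 1L,
            cfg$tumor_purity > 0, cfg$tumor_purity <= 1,
            cfg$aberrant_prob >= 0, cfg$aberrant_prob <= 1,
            cfg$shared_scna_fraction_related >= 0,
            cfg$shared_scna_fraction_related <= 1,
            cfg$shared_scna_fraction_independent >= 0,
            cfg$shared_scna_fraction_independent <= 1,
            length(cfg$branch_probs) == 3L, sum(cfg$branch_probs) < 1)
  for (nm in c("signature_mix_related", "signature_mix_independent_D")) {
    w <- cfg[[nm]]
    if (is.null(names(w)) || abs(sum(w) - 1) > 1e-6 || any(w < 0)) {
      stop(nm, " must be a named nonnegative weight vector summing to 1")
    }
  }
  if (cfg$trunk_fraction_range[1] > 0 &&
      cfg$mutations_per_tumor_range[1] * cfg$trunk_fraction_range[1] < 1) {
    stop("mutations_per_tumor lower bound too small for the requested trunk fraction")
  }
  cfg
}

level_midpoints <- function() c(`-2` = -1.6, `-1` = -0.7, `0` = 0, `1` = 0.5, `2` = 1.2)

#' Deterministic focal-region layout for a genome model
#'
#' Places `n_regions` equal-width regions, evenly spaced and aligned to the
#' segmentation chunk size, allocating regions to chromosomes in proportion
#' to their length.
#'
#' @param genome Named chromosome-length vector.
#' @param n_regions Number of regions.
#' @param width_kb Region width in kb.
#' @param chunk_kb Alignment granularity in kb.
#' @return data.frame `region`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
focal_region_layout <- function(genome, n_regions = 100L, width_kb = 30L,
                                chunk_kb = 5L) {
  width <- width_kb * 1000L
  alloc <- floor(n_regions * genome / sum(genome))
  rem <- n_regions - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  rows <- list()
  for (ch in names(genome)) {
    k <- alloc[[ch]]
    if (k == 0L) next
    spacing <- floor(genome[[ch]] / k)
    start <- (seq_len(k) - 1L) * spacing + chunk_kb * 1000L
    start <- floor(start / (chunk_kb * 1000L)) * (chunk_kb * 1000L) + 1L
    if (any(start + width - 1L > genome[[ch]])) {
      stop("genome too small for the requested focal-region layout")
    }
    rows[[ch]] <- data.frame(chrom = ch, start = start,
                             end = start + width - 1L,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(region = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

draw_level <- function(n, aberrant_prob) {
  lv <- numeric(n)
  ab <- stats::runif(n) < aberrant_prob
  lv[ab] <- sample(c(-2, -1, 1, 2), sum(ab), replace = TRUE)
  lv
}

# partner shares m = round(2*A*s/(1+s)) of tumor A's aberrant regions (so the
# shared fraction of the pooled aberrant regions is s) and draws |A|-m
# private aberrations on regions neutral in A
partner_levels <- function(levels_a, share, aberrant_prob) {
  out <- numeric(length(levels_a))
  ab <- which(levels_a != 0)
  A <- length(ab)
  if (A == 0L) return(out)
  m <- round(2 * A * share / (1 + share))
  m <- min(m, A)
  shared <- if (m > 0) sample(ab, m) else integer(0)
  out[shared] <- levels_a[shared]
  pool <- which(levels_a == 0)
  n_priv <- min(A - m, length(pool))
  if (n_priv > 0) {
    priv <- sample(pool, n_priv)
    out[priv] <- sample(c(-2, -1, 1, 2), n_priv, replace = TRUE)
  }
  out
}

draw_positions <- function(n, genome, taken) {
  chrom <- character(0); pos <- integer(0)
  while (length(chrom) < n) {
    need <- n - length(chrom)
    ci <- sample(length(genome), 2L * need + 4L, replace = TRUE,
                 prob = genome / sum(genome))
    p <- floor(stats::runif(length(ci)) * genome[ci]) + 1L
    key <- paste(names(genome)[ci], p)
    ok <- !key %in% taken & !duplicated(key)
    chrom <- c(chrom, names(genome)[ci][ok])
    pos <- c(pos, p[ok])
    taken <- c(taken, key[ok])
  }
  list(chrom = unname(chrom[seq_len(n)]), pos = unname(as.integer(pos[seq_len(n)])),
       taken = taken)
}

context_from_label <- function(lab) {
  ref <- substr(lab, 3L, 3L)
  alt <- substr(lab, 5L, 5L)
  ctx <- paste0(substr(lab, 1L, 1L), ref, substr(lab, 7L, 7L))
  list(ref = ref, alt = alt, context = ctx)
}

gene_of_position <- function(chrom, pos) {
  paste0("G", chrom, "_", sprintf("%03d", pos %/% 100000L))
}

#' Simulate one multi-tumor patient
#'
#' Draws the patient's mutation union, assigns each mutation to
#' trunk/branch/private compartments (Bernoulli per mutation, so realized
#' trunk fractions carry binomial sampling error around the drawn
#' parameter), samples trinucleotide contexts through the signature
#' catalog, and samples read counts: tumor depth Poisson(`mean_depth`),
#' alt reads Binomial(depth, purity x CCF / 2), normal alt reads
#' Binomial(depth, `normal_error`). Focal SCNA levels are drawn per region
#' and partner tumors share a controlled fraction of aberrant regions (see
#' [simulation_config()]).
#'
#' For `truth = "related"` the trunk is present in T, LN and D. For
#' `truth = "independent"` T and LN share a drawn fraction of mutations
#' while D's mutation set is disjoint from T and LN and its contexts come
#' from `signature_mix_independent_D`.
#'
#' @param config A [simulation_config()]. Uses the current RNG state;
#'   callers wanting reproducibility seed beforehand (see
#'   [simulate_cohort()]).
#' @param truth `"related"` (lung metastasis) or `"independent"` (second
#'   primary).
#' @param patient_id Patient identifier.
#' @param catalog Signature catalog matrix (default
#'   [synthetic_signature_catalog()]).
#' @param regions Focal-region layout (default derived from the config).
#' @return List: `variants` (data.frame over all tumor samples), `segs`
#'   (SEG data.frame), `truth` (ground-truth bookkeeping: drawn trunk
#'   fraction, per-mutation compartments, per-sample region levels).
#' @export
simulate_patient <- function(config, truth = c("related", "independent"),
                             patient_id = "P01",
                             catalog = synthetic_signature_catalog(),
                             regions = NULL) {
  truth <- match.arg(truth)
  cfg <- validate_simulation_config(config)
  if (is.null(regions)) {
    regions <- focal_region_layout(cfg$genome, cfg$n_focal_regions,
                                   cfg$region_width_kb, cfg$seg_chunk_kb)
  }
  roles <- c("T", "LN", "D")
  sample_ids <- stats::setNames(paste0(patient_id, "_", roles), roles)
  f <- stats::runif(1, cfg$trunk_fraction_range[1], cfg$trunk_fraction_range[2])

  mix_p <- function(mix) {
    bad <- setdiff(names(mix), colnames(catalog))
    if (length(bad)) stop("signature mix names absent from catalog: ",
                          paste(bad, collapse = ","))
    as.numeric(catalog[, names(mix), drop = FALSE] %*% (mix / sum(mix)))
  }
  p_rel <- mix_p(cfg$signature_mix_related)
  p_ind <- mix_p(cfg$signature_mix_independent_D)

  draw_union <- function() {
    r <- cfg$mutations_per_tumor_range
    if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
  }

  # the shared-set size is deterministic (round(f * U)) so the trunk
  # fraction is a controllable parameter; the remaining mutations are
  # assigned multinomially to branches and privates
  if (truth == "related") {
    U <- draw_union()
    k <- round(f * U)
    rest_cats <- c("T&LN", "D&T", "D&LN", "T", "LN", "D")
    rest_pr <- c(cfg$branch_probs, rep((1 - sum(cfg$branch_probs)) / 3, 3))
    compartment <- c(rep("trunk", k),
                     sample(rest_cats, U - k, replace = TRUE, prob = rest_pr))
    ctx_class <- sample.int(96L, U, replace = TRUE, prob = p_rel)
  } else {
    U1 <- draw_union()
    k1 <- round(f * U1)
    compartment1 <- c(rep("T&LN", k1),
                      sample(c("T", "LN"), U1 - k1, replace = TRUE))
    U2 <- draw_union()
    compartment <- c(compartment1, rep("D", U2))
    U <- U1 + U2
    ctx_class <- c(sample.int(96L, U1, replace = TRUE, prob = p_rel),
                   sample.int(96L, U2, replace = TRUE, prob = p_ind))
  }

  posd <- draw_positions(U, cfg$genome, character(0))
  lab <- sbs96_contexts()[ctx_class]
  parts <- context_from_label(lab)
  members_of <- function(comp) switch(comp,
    trunk = roles, `T&LN` = c("T", "LN"), `D&T` = c("T", "D"),
    `D&LN` = c("LN", "D"), T = "T", LN = "LN", D = "D")
  ccf_of <- function(comp) switch(comp,
    trunk = cfg$ccf_trunk, `T&LN` = , `D&T` = , `D&LN` = cfg$ccf_branch,
    cfg$ccf_private)

  n_depth <- pmax(1L, stats::rpois(U, cfg$mean_depth))
  n_alt <- stats::rbinom(U, n_depth, cfg$normal_error)
  rows <- vector("list", U)
  for (i in seq_len(U)) {
    mem <- members_of(compartment[i])
    td <- pmax(1L, stats::rpois(length(mem), cfg$mean_depth))
    ta <- stats::rbinom(length(mem), td,
                        cfg$tumor_purity * ccf_of(compartment[i]) / 2)
    rows[[i]] <- data.frame(
      patient_id = patient_id, sample_id = unname(sample_ids[mem]),
      chrom = posd$chrom[i], pos = posd$pos[i],
      ref = parts$ref[i], alt = parts$alt[i],
      variant_type = "SNV",
      gene = gene_of_position(posd$chrom[i], posd$pos[i]),
      effect = "nonsynonymous",
      t_depth = td, t_alt = ta, n_depth = n_depth[i], n_alt = n_alt[i],
      context = parts$context[i], stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL

  # focal SCNA levels per sample
  lvl <- matrix(0, nrow(regions), 3L,
                dimnames = list(NULL, roles))
  lvl[, "T"] <- draw_level(nrow(regions), cfg$aberrant_prob)
  lvl[, "LN"] <- partner_levels(lvl[, "T"], cfg$shared_scna_fraction_related,
                                cfg$aberrant_prob)
  d_share <- if (truth == "related") cfg$shared_scna_fraction_related
  else cfg$shared_scna_fraction_independent
  lvl[, "D"] <- partner_levels(lvl[, "T"], d_share, cfg$aberrant_prob)

  segs <- do.call(rbind, lapply(roles, function(rl) {
    simulate_seg_sample(sample_ids[[rl]], lvl[, rl], regions, cfg)
  }))
  rownames(segs) <- NULL

  truth_entry <- list(
    patient_id = patient_id, truth = truth,
    trunk_fraction_drawn = if (truth == "related") f else 0,
    tln_shared_fraction_drawn = if (truth == "independent") f else NA_real_,
    n_union = U,
    mutations = data.frame(
      key = mutation_key(posd$chrom, posd$pos, parts$ref, parts$alt),
      compartment = compartment, stringsAsFactors = FALSE),
    region_levels = lvl
  )
  list(variants = variants, segs = segs, truth = truth_entry)
}

# one SEG row per seg_chunk_kb chunk: midpoint of the region level covering
# the chunk (0 outside regions) plus Gaussian noise
simulate_seg_sample <- function(sample_id, levels, regions, cfg) {
  chunk <- cfg$seg_chunk_kb * 1000L
  mids <- level_midpoints()
  out <- lapply(names(cfg$genome), function(ch) {
    len <- cfg$genome[[ch]]
    n_chunk <- as.integer(ceiling(len / chunk))
    start <- (seq_len(n_chunk) - 1L) * chunk + 1L
    end <- pmin(start + chunk - 1L, len)
    base <- numeric(n_chunk)
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(rr)) {
      for (k in seq_len(nrow(rr))) {
        lv <- levels[rr$region[k]]
        if (lv != 0) {
          c1 <- (rr$start[k] - 1L) %/% chunk + 1L
          c2 <- (rr$end[k] - 1L) %/% chunk + 1L
          base[c1:c2] <- mids[[as.character(lv)]]
        }
      }
    }
    data.frame(sample_id = sample_id, chrom = ch, start = start, end = end,
               log2_ratio = base + stats::rnorm(n_chunk, 0, cfg$scna_noise_sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a cohort and write it to disk
#'
#' Deterministically allocates `round(n_patients * fraction_spt)` patients
#' to the independent (second-primary) regime and the rest to the related
#' (metastasis) regime, simulates every patient under the config's seed,
#' and writes one variant TSV and one SEG TSV per patient plus a YAML
#' manifest and a ground-truth JSON. Output is byte-identical across runs
#' with the same config.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param catalog Signature catalog (default [synthetic_signature_catalog()]).
#' @return List: `manifest` (a `cohort_manifest`), `truth` (per-patient
#'   ground truth), `regions` (the focal-region layout), `dir`,
#'   `manifest_file`.
#' @export
simulate_cohort <- function(config, out_dir,
                            catalog = synthetic_signature_catalog()) {
  cfg <- validate_simulation_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_patients
  n_spt <- round(n * cfg$fraction_spt)
  status <- rep(c("related", "independent"),
                c(n - n_spt, n_spt))
  ids <- sprintf("P%02d", seq_len(n))
  regions <- focal_region_layout(cfg$genome, cfg$n_focal_regions,
                                 cfg$region_width_kb, cfg$seg_chunk_kb)
  manifest <- list()
  truth <- list()
  with_private_seed(cfg$seed, {
    for (i in seq_len(n)) {
      sim <- simulate_patient(cfg, status[i], ids[i], catalog = catalog,
                              regions = regions)
      vf <- paste0(ids[i], ".variants.tsv")
      sf <- paste0(ids[i], ".seg.tsv")
      write_variants(sim$variants, file.path(out_dir, vf))
      write_seg(sim$segs, file.path(out_dir, sf))
      manifest[[i]] <- list(
        patient_id = ids[i],
        samples = c(lapply(c("T", "LN", "D"), function(rl) {
          list(sample_id = paste0(ids[i], "_", rl), role = rl)
        }), list(list(sample_id = paste0(ids[i], "_N"), role = "N"))),
        variant_file = vf, seg_file = sf
      )
      truth[[ids[i]]] <- sim$truth
    }
  })
  manifest <- structure(manifest, class = "cohort_manifest")
  mf <- file.path(out_dir, "manifest.yaml")
  if (n > 0) {
    write_manifest(manifest, mf)
  } else {
    yaml::write_yaml(list(patients = list()), mf)
  }
  # the YAML carries file names relative to its own directory; the returned
  # object resolves them so it is usable without re-reading the manifest
  manifest <- structure(lapply(manifest, function(p) {
    p$variant_file <- file.path(normalizePath(out_dir), p$variant_file)
    p$seg_file <- file.path(normalizePath(out_dir), p$seg_file)
    p
  }), class = "cohort_manifest")
  truth_json <- lapply(truth, function(t) {
    list(patient_id = t$patient_id, truth = t$truth,
         trunk_fraction_drawn = t$trunk_fraction_drawn,
         n_union = t$n_union)
  })
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, truth = truth, regions = regions, dir = out_dir,
       manifest_file = mf)
}
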