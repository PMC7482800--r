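# A deterministic, fully synthetic stand-in for the 30-signature COSMIC v2
# catalog. It is NOT the published matrix: it is constructed so that the
# signatures this package's defaults rely on reproduce the dominant
# substitution classes reported for their real counterparts (signature 1:
# C>T concentrated at NpCpG; signatures 4/29/24: C>A-dominated; 5/3: flat;
# 6: C>T; 16: T>C). The remaining signatures get reproducible sparse random
# profiles so that refitting is identifiable. Users with the real COSMIC v2
# TSV load it through read_signature_catalog() instead.

#' Synthetic 30-signature reference catalog
#'
#' Deterministic 96 x 30 probability matrix (`Sig1` ... `Sig30`), columns
#' summing to 1. Synthetic: shaped to mimic the class composition of the
#' correspondingly numbered COSMIC v2 signatures where this package's
#' defaults depend on them, random (but fixed) elsewhere. See Details.
#'
#' @details Sig1 puts most of its mass on C>T at `N[C>T]G` contexts (the
#' spontaneous-deamination pattern); Sig4, Sig24 and Sig29 are C>A-dominated
#' with distinct context weightings (tobacco smoking, aflatoxin, tobacco
#' chewing); Sig5 and Sig3 are near-flat; Sig6 is C>T-dominated; Sig16 is
#' T>C-dominated. All other signatures are sparse Dirichlet-like draws from
#' a fixed internal seed, so the catalog is identical across sessions.
#'
#' @param k Number of signatures (default 30; smaller values take the first k).
#' @return 96 x k matrix with context rownames and `Sig*` colnames.
#' @export
synthetic_signature_catalog <- function(k = 30L) {
  stopifnot(k >= 1L, k <= 30L)
  ctx <- sbs96_contexts()
  cls <- sub(".*\\[(.>.)\\].*", "\\1", ctx)
  p3 <- substr(ctx, 7L, 7L)
  mat <- with_private_seed(903157L, {
    m <- matrix(0, 96L, 30L, dimnames = list(ctx, paste0("Sig", 1:30)))
    # class-level propensities for the biologically anchored signatures
    shaped <- list(
      Sig1  = c(`C>A` = .02, `C>G` = .02, `C>T` = .82, `T>A` = .03, `T>C` = .08, `T>G` = .03),
      Sig3  = c(.18, .16, .18, .15, .18, .15),
      Sig4  = c(.55, .08, .15, .06, .12, .04),
      Sig5  = c(.12, .10, .25, .09, .33, .11),
      Sig6  = c(.06, .04, .62, .04, .20, .04),
      Sig16 = c(.05, .03, .07, .08, .72, .05),
      Sig24 = c(.60, .06, .16, .05, .09, .04),
      Sig29 = c(.65, .10, .10, .05, .06, .04)
    )
    for (nm in names(shaped)) {
      w6 <- stats::setNames(as.numeric(shaped[[nm]]), sbs_classes())
      col <- numeric(96L)
      for (cl in sbs_classes()) {
        idx <- which(cls == cl)
        # context weighting inside the class: random but fixed, mildly peaked
        u <- stats::rgamma(length(idx), shape = 0.8)
        if (nm == "Sig1" && cl == "C>T") {
          u[p3[idx] == "G"] <- u[p3[idx] == "G"] + 25  # NpCpG deamination peak
        }
        col[idx] <- w6[[cl]] * u / sum(u)
      }
      m[, nm] <- col / sum(col)
    }
    for (j in setdiff(colnames(m), names(shaped))) {
      u <- stats::rgamma(96L, shape = 0.25)  # sparse, distinct support
      m[, j] <- u / sum(u)
    }
    m
  })
  mat[, seq_len(k), drop = FALSE]
}
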