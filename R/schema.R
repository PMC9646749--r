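# The full feature schema in one place so the reconstruction of the
# 57-feature layout can be revised without touching the extraction code.

SIF_FEATURES <- c(
  "gc_content", "fickett",
  "orf_t0_length", "orf_t1_length", "orf_t2_length", "orf_t3_length",
  "orf_t0_coverage", "orf_t1_coverage", "orf_t2_coverage", "orf_t3_coverage",
  "orf_avg_length", "orf_avg_coverage",
  "hexamer_transcript",
  "hexamer_orf_t0", "hexamer_orf_t1", "hexamer_orf_t2", "hexamer_orf_t3",
  "rcb_t0", "rcb_t1", "rcb_t2", "rcb_t3"
)

SSF_FEATURES <- c(
  "mfe", "paired_ratio",
  "n_hairpin", "n_interior", "n_bulge", "n_multi",
  "c_hairpin", "c_interior", "c_bulge", "c_multi",
  "gc_paired",
  "sass_k1", "sass_k2", "sass_k3", "sass_k4", "sass_k5"
)

PF_FEATURES <- as.vector(t(outer(
  c("pi_", "mw_", "gravy_", "aromaticity_", "instability_"),
  c("t0", "t1", "t2", "t3"), paste0
)))

FULL_57 <- c(SIF_FEATURES, SSF_FEATURES, PF_FEATURES)

# default deployed subset: 14 SIFs + 6 SSFs + 8 PFs
TOP_28 <- c(
  "gc_content", "fickett",
  "orf_t0_length", "orf_t1_length", "orf_t2_length",
  "orf_t0_coverage", "orf_t1_coverage", "orf_t3_coverage",
  "hexamer_orf_t0", "hexamer_orf_t1", "hexamer_orf_t2", "hexamer_orf_t3",
  "rcb_t0", "rcb_t1",
  "sass_k1", "sass_k2", "sass_k3", "sass_k4", "sass_k5", "gc_paired",
  "pi_t0", "mw_t0", "aromaticity_t0", "instability_t0",
  "mw_t1", "instability_t1", "mw_t2", "mw_t3"
)

NO_SSF_22 <- setdiff(TOP_28, SSF_FEATURES)

#' Feature schema subsets
#'
#' Returns the ordered feature names of a named subset: `"full57"` (every
#' extracted feature), `"top28"` (the default
#' deployed subset: 14 sequence-intrinsic + 6 secondary-structure + 8
#' protein features) or `"no_ssf22"` (`top28` without its 6
#' secondary-structure features, for structure-free operation).
#'
#' @param subset One of `"top28"`, `"full57"`, `"no_ssf22"`.
#' @return Character vector of feature names, in schema order.
#' @export
feature_schema <- function(subset = c("top28", "full57", "no_ssf22")) {
  subset <- match.arg(subset)
  switch(subset, full57 = FULL_57, top28 = TOP_28, no_ssf22 = NO_SSF_22)
}

#' Feature category lookup
#'
#' @return A tibble mapping every feature of the full schema to its
#'   category: `"SIF"` (sequence-intrinsic), `"SSF"` (secondary-structure)
#'   or `"PF"` (protein).
#' @export
feature_categories <- function() {
  tibble(
    feature = FULL_57,
    category = c(rep("SIF", length(SIF_FEATURES)),
                 rep("SSF", length(SSF_FEATURES)),
                 rep("PF", length(PF_FEATURES)))
  )
}
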