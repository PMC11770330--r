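#' Canonical tract name registry
#'
#' Returns the canonical naming schema for tract-level disconnection
#' profiles: 65 bundle names (30 bilateral pairs plus 5 midline bundles)
#' and 5 callosal segment names, 70 names in total. The callosal segments
#' follow the usual five-way split of the corpus callosum (anterior frontal,
#' posterior frontal, parietal, temporal, occipital); their labels are
#' configurable because the exact anatomical boundaries of the split are a
#' convention, not a computation. This registry is a naming schema only --
#' synthetic atlases borrow its names, but no geometry is attached to it.
#'
#' @param callosal_names character vector of 5 names for the callosal
#'   segments.
#' @return character vector of 70 unique tract names.
#' @examples
#' length(canonical_registry())  # 70
#' @export
canonical_registry <- function(callosal_names = paste(
  "corpus callosum -",
  c("anterior frontal", "posterior frontal", "parietal", "temporal",
    "occipital"))) {
  stop_if(length(callosal_names) != 5L || anyDuplicated(callosal_names) > 0L,
          "exactly 5 unique callosal segment names are required")
  bilateral <- c(
    "arcuate fasciculus",
    "superior longitudinal fasciculus I",
    "superior longitudinal fasciculus II",
    "superior longitudinal fasciculus III",
    "inferior longitudinal fasciculus",
    "inferior fronto-occipital fasciculus",
    "uncinate fasciculus",
    "frontal aslant tract",
    "cingulum",
    "extreme capsule",
    "middle longitudinal fasciculus",
    "vertical occipital fasciculus",
    "optic radiation",
    "optic tract",
    "acoustic radiation",
    "corticospinal tract",
    "corticobulbar tract",
    "corticostriatal pathway",
    "corticothalamic pathway",
    "fornix",
    "medial lemniscus",
    "spinothalamic tract",
    "rubrospinal tract",
    "reticulospinal tract",
    "dentatorubrothalamic tract",
    "inferior cerebellar peduncle",
    "superior cerebellar peduncle",
    "medial forebrain bundle",
    "frontopontine tract",
    "occipitopontine tract"
  )
  midline <- c(
    "anterior commissure",
    "posterior commissure",
    "middle cerebellar peduncle",
    "cerebellar vermis",
    "spinal trigeminal tract"
  )
  out <- c(
    as.vector(t(outer(c("left", "right"), bilateral, paste))),
    midline,
    callosal_names
  )
  stopifnot(length(out) == 70L, anyDuplicated(out) == 0L)
  out
}
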