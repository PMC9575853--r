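# Shared synthetic study conditions used across test files.

# Strong planted signal: many small classes give a sparse network (prevalence
# around 3%) whose class blocks the profile measures recover essentially
# noise-free.
strongSignalSpec <- function(seed, drugDatasets = c(DDA = 1),
                             targetDatasets = c(PW = 1)) {
  comp <- matrix(0.0005, 10, 10)
  diag(comp) <- 0.35
  syntheticSpec(nDrugClasses = 10, nTargetClasses = 10,
                compatibility = comp, drugDatasets = drugDatasets,
                targetDatasets = targetDatasets, flipRate = 0, seed = seed)
}

# No class signal in any data source.
nullSignalSpec <- function(seed) {
  syntheticSpec(drugDatasets = c(DDA = 0), targetDatasets = c(PW = 0),
                seed = seed)
}

# Single informative measure per side plus pure-noise decoys, for selection
# tests.
selectionSpec <- function(seed) {
  comp <- matrix(0.0005, 10, 10)
  diag(comp) <- 0.35
  syntheticSpec(nDrugClasses = 10, nTargetClasses = 10,
                compatibility = comp,
                drugDatasets = c(DDA = 1, DX1 = 0, DX2 = 0),
                targetDatasets = c(PW = 1, TX1 = 0, TX2 = 0),
                flipRate = 0, seed = seed)
}

# Normalised single-measure heterogeneous network from a bundle's profile
# catalog.
bundleNetwork <- function(bundle, drugMeasure, targetMeasure) {
  ct <- bundleProfileCatalog(bundle)
  heterogeneousNetwork(
    normalizeSimilarity(simValues(ct[[drugMeasure]])),
    normalizeSimilarity(simValues(ct[[targetMeasure]])),
    bundle$dti)
}
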