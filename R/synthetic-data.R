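#' @include AllClasses.R utils.R similarity-kernels.R
NULL

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Specification for a synthetic drug-target benchmark
#'
#' Describes a fully synthetic study: drugs and targets carry latent
#' classes; interactions are sampled from a class-compatibility matrix; and
#' each data source (binary profiles, a confidence-weighted PPI graph,
#' protein sequences) reflects the classes to a controllable degree. At
#' informativeness 1 with no flip noise, entities of one class have
#' identical profiles; at informativeness 0 a source is i.i.d. noise
#' carrying no class signal, so similarity measures built from it are
#' uninformative by construction.
#'
#' @param nDrugs,nTargets entity counts (defaults 60 and 80: a desk-scale
#'   network on which a full forward-selection run takes seconds).
#' @param nDrugClasses,nTargetClasses latent class counts (default 4 each).
#' @param compatibility class x class interaction probability matrix;
#'   default 0.2 for matched class indices, 0.01 otherwise (roughly 300
#'   positives at the default sizes, prevalence ~6\%).
#' @param drugDatasets,targetDatasets named numeric vectors: dataset tag ->
#'   informativeness in \[0, 1\] for the binary-profile sources.
#' @param nFeatures features per profile dataset (default 100).
#' @param prototypeDensity Bernoulli rate of 1s in class prototypes
#'   (default 0.3).
#' @param flipRate profile bit-flip noise applied after prototype mixing
#'   (default 0.05).
#' @param ppiInformativeness class signal of the PPI graph in \[0, 1\]
#'   (within-class edge probability interpolates 0.02 -> 0.3).
#' @param seqInformativeness probability a target's sequence descends from
#'   its class ancestor rather than being random (default 0.9).
#' @param seqLength,mutationRate ancestor sequence length (default 120
#'   residues) and per-site mutation probability (default 0.05).
#' @param seed integer; the whole bundle is reproducible from it.
#' @return a \code{SyntheticSpec} (validated list).
#' @export
syntheticSpec <- function(nDrugs = 60L, nTargets = 80L,
                          nDrugClasses = 4L, nTargetClasses = 4L,
                          compatibility = NULL,
                          drugDatasets = c(FP = 0.9, DDA = 0.9, DDI = 0.9,
                                           SE = 0.9),
                          targetDatasets = c(PW = 0.9),
                          nFeatures = 100L, prototypeDensity = 0.3,
                          flipRate = 0.05, ppiInformativeness = 0.9,
                          seqInformativeness = 0.9, seqLength = 120L,
                          mutationRate = 0.05, seed = 1L) {
  if (is.null(compatibility)) {
    compatibility <- matrix(0.01, nDrugClasses, nTargetClasses)
    k <- min(nDrugClasses, nTargetClasses)
    compatibility[cbind(seq_len(k), seq_len(k))] <- 0.2
  }
  spec <- list(nDrugs = as.integer(nDrugs), nTargets = as.integer(nTargets),
               nDrugClasses = as.integer(nDrugClasses),
               nTargetClasses = as.integer(nTargetClasses),
               compatibility = compatibility, drugDatasets = drugDatasets,
               targetDatasets = targetDatasets,
               nFeatures = as.integer(nFeatures),
               prototypeDensity = prototypeDensity, flipRate = flipRate,
               ppiInformativeness = ppiInformativeness,
               seqInformativeness = seqInformativeness,
               seqLength = as.integer(seqLength),
               mutationRate = mutationRate, seed = as.integer(seed))
  if (spec$nDrugClasses > spec$nDrugs || spec$nTargetClasses > spec$nTargets)
    stop("more classes than entities")
  if (any(compatibility < 0 | compatibility > 1))
    stop("compatibility probabilities must lie in [0, 1]")
  if (any(dim(compatibility) != c(spec$nDrugClasses, spec$nTargetClasses)))
    stop("compatibility must be nDrugClasses x nTargetClasses")
  probs <- c(unlist(spec$drugDatasets), unlist(spec$targetDatasets),
             prototypeDensity, flipRate, ppiInformativeness,
             seqInformativeness, mutationRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(spec, class = "SyntheticSpec")
}

# Binary profile matrix with class structure: each entity copies its class
# prototype bit with probability `info`, otherwise draws a fresh Bernoulli
# bit; a final flip layer adds measurement noise.
.classProfiles <- function(classes, nFeatures, info, density, flipRate, ids) {
  nClass <- max(classes)
  proto <- matrix(stats::rbinom(nClass * nFeatures, 1, density),
                  nClass, nFeatures)
  n <- length(classes)
  useProto <- matrix(stats::rbinom(n * nFeatures, 1, info), n, nFeatures)
  noise <- matrix(stats::rbinom(n * nFeatures, 1, density), n, nFeatures)
  X <- useProto * proto[classes, , drop = FALSE] + (1 - useProto) * noise
  flip <- matrix(stats::rbinom(n * nFeatures, 1, flipRate), n, nFeatures)
  X <- abs(X - flip)
  dimnames(X) <- list(ids, sprintf("f%03d", seq_len(nFeatures)))
  X
}

#' Generate a synthetic drug-target bundle
#'
#' Draws every input the pipeline consumes -- binary profile tables per
#' dataset tag, a confidence-weighted PPI graph, protein sequences and the
#' ground-truth interaction matrix -- from one [syntheticSpec()], fully
#' deterministically given its seed.
#'
#' @param spec a \code{SyntheticSpec}.
#' @return a \code{SyntheticBundle}: list with \code{dti} (binary matrix),
#'   \code{drugProfiles} / \code{targetProfiles} (named lists of binary
#'   matrices by tag), \code{ppi} (a [ConfidenceGraph]), \code{sequences}
#'   (named character), \code{drugClasses}, \code{targetClasses} and the
#'   originating \code{spec}.
#' @export
generateBundle <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withLocalSeed(spec$seed, {
    drugIds <- sprintf("D%03d", seq_len(spec$nDrugs))
    targetIds <- sprintf("T%03d", seq_len(spec$nTargets))
    drugClasses <- rep_len(seq_len(spec$nDrugClasses), spec$nDrugs)
    targetClasses <- rep_len(seq_len(spec$nTargetClasses), spec$nTargets)
    pMat <- spec$compatibility[drugClasses, targetClasses, drop = FALSE]
    dti <- matrix(stats::rbinom(length(pMat), 1, pMat),
                  spec$nDrugs, spec$nTargets,
                  dimnames = list(drugIds, targetIds))
    drugProfiles <- lapply(spec$drugDatasets, function(info)
      .classProfiles(drugClasses, spec$nFeatures, info,
                     spec$prototypeDensity, spec$flipRate, drugIds))
    targetProfiles <- lapply(spec$targetDatasets, function(info)
      .classProfiles(targetClasses, spec$nFeatures, info,
                     spec$prototypeDensity, spec$flipRate, targetIds))
    # PPI: within-class edges become more likely with informativeness and
    # carry confidences above the 0.5 filter; a sprinkle of low-confidence
    # edges exercises the filter.
    pIn <- 0.02 + 0.28 * spec$ppiInformativeness
    edges <- list(); ei <- 0L
    for (i in seq_len(spec$nTargets - 1L)) {
      for (j in (i + 1L):spec$nTargets) {
        same <- targetClasses[i] == targetClasses[j]
        if (stats::runif(1) < if (same) pIn else 0.02) {
          ei <- ei + 1L
          edges[[ei]] <- data.frame(from = targetIds[i], to = targetIds[j],
                                    confidence = stats::runif(1, 0.55, 1))
        } else if (stats::runif(1) < 0.02) {
          ei <- ei + 1L
          edges[[ei]] <- data.frame(from = targetIds[i], to = targetIds[j],
                                    confidence = stats::runif(1, 0, 0.45))
        }
      }
    }
    edges <- if (ei) do.call(rbind, edges) else
      data.frame(from = character(), to = character(),
                 confidence = numeric())
    ppi <- confidenceGraph(edges, nodes = targetIds)
    ancestors <- replicate(spec$nTargetClasses, paste(
      sample(.AA, spec$seqLength, replace = TRUE), collapse = ""))
    sequences <- vapply(seq_len(spec$nTargets), function(i) {
      base <- if (stats::runif(1) < spec$seqInformativeness)
        ancestors[targetClasses[i]]
      else paste(sample(.AA, spec$seqLength, replace = TRUE), collapse = "")
      chars <- strsplit(base, "")[[1L]]
      mut <- stats::runif(length(chars)) < spec$mutationRate
      chars[mut] <- sample(.AA, sum(mut), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
    names(sequences) <- targetIds
    structure(list(dti = dti, drugProfiles = drugProfiles,
                   targetProfiles = targetProfiles, ppi = ppi,
                   sequences = sequences, drugClasses = drugClasses,
                   targetClasses = targetClasses, spec = spec),
              class = "SyntheticBundle")
  })
}

#' Build a similarity catalog from a synthetic bundle
#'
#' Convenience wrapper turning each profile dataset of a bundle into a
#' Jaccard similarity measure (tagged by its dataset), ready for
#' integration and forward selection. PPI- and sequence-based measures can
#' be added separately via [ispSimilarity()], [commonNeighborSimilarity()]
#' and [alignmentSimilarity()].
#'
#' @param bundle a \code{SyntheticBundle}.
#' @param index "jaccard" (default) or "cosine".
#' @return a [SimilarityCatalog].
#' @export
bundleProfileCatalog <- function(bundle, index = c("jaccard", "cosine")) {
  index <- match.arg(index)
  fun <- if (index == "jaccard") jaccardSimilarity else cosineSimilarity
  entries <- c(
    lapply(names(bundle$drugProfiles), function(tag)
      fun(bundle$drugProfiles[[tag]], side = "drug",
          measureName = paste0(tag, "_", if (index == "jaccard") "Jac" else "Cos"),
          datasetTag = tag)),
    lapply(names(bundle$targetProfiles), function(tag)
      fun(bundle$targetProfiles[[tag]], side = "target",
          measureName = paste0(tag, "_", if (index == "jaccard") "Jac" else "Cos"),
          datasetTag = tag)))
  similarityCatalog(entries)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits exactly the formats the readers consume: one long-form TSV per
#' profile dataset, the PPI edge TSV, a FASTA of target sequences, the DTI
#' edge TSV, latent class labels, and a manifest JSON recording entity and
#' feature universes so the round trip is lossless.
#'
#' @param bundle a \code{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @seealso [readBundle()]
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProfileTSV <- function(X, path) {
    idx <- which(X == 1, arr.ind = TRUE)
    df <- data.frame(entity_id = rownames(X)[idx[, 1L]],
                     feature_id = colnames(X)[idx[, 2L]])
    df <- df[order(df$entity_id, df$feature_id), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  datasets <- list()
  for (tag in names(bundle$drugProfiles)) {
    f <- paste0("drug_", tag, ".tsv")
    writeProfileTSV(bundle$drugProfiles[[tag]], file.path(dir, f))
    datasets[[length(datasets) + 1L]] <- list(
      tag = tag, side = "drug", kind = "profiles", path = f,
      features = colnames(bundle$drugProfiles[[tag]]))
  }
  for (tag in names(bundle$targetProfiles)) {
    f <- paste0("target_", tag, ".tsv")
    writeProfileTSV(bundle$targetProfiles[[tag]], file.path(dir, f))
    datasets[[length(datasets) + 1L]] <- list(
      tag = tag, side = "target", kind = "profiles", path = f,
      features = colnames(bundle$targetProfiles[[tag]]))
  }
  utils::write.table(bundle$ppi@edges, file.path(dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  datasets[[length(datasets) + 1L]] <- list(tag = "PPI", side = "target",
                                            kind = "graph", path = "ppi.tsv")
  seqs <- Biostrings::AAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"),
                              width = 60L)
  datasets[[length(datasets) + 1L]] <- list(tag = "Seq", side = "target",
                                            kind = "sequences",
                                            path = "sequences.fasta")
  pos <- which(bundle$dti == 1, arr.ind = TRUE)
  dti <- data.frame(drug_id = rownames(bundle$dti)[pos[, 1L]],
                    target_id = colnames(bundle$dti)[pos[, 2L]])
  dti <- dti[order(dti$drug_id, dti$target_id), , drop = FALSE]
  utils::write.table(dti, file.path(dir, "dti.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels <- data.frame(
    entity_id = c(rownames(bundle$dti), colnames(bundle$dti)),
    side = rep(c("drug", "target"),
               c(nrow(bundle$dti), ncol(bundle$dti))),
    class = c(bundle$drugClasses, bundle$targetClasses))
  utils::write.table(labels, file.path(dir, "classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(drugIds = rownames(bundle$dti),
                   targetIds = colnames(bundle$dti),
                   dti = "dti.tsv", classes = "classes.tsv",
                   seed = bundle$spec$seed, datasets = datasets)
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifestPath)
}

#' Read a bundle written by [writeBundle()]
#'
#' @param dir directory containing \code{manifest.json} and the data files.
#' @return a \code{SyntheticBundle}-shaped list (without the generating
#'   spec; classes restored from the label file).
#' @export
readBundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  drugIds <- manifest$drugIds
  targetIds <- manifest$targetIds
  dti <- readDTIEdges(file.path(dir, manifest$dti),
                      drugIds = drugIds, targetIds = targetIds)
  drugProfiles <- list(); targetProfiles <- list()
  ppi <- NULL; sequences <- NULL
  ds <- manifest$datasets
  for (i in seq_len(nrow(ds))) {
    entry <- ds[i, ]
    path <- file.path(dir, entry$path)
    if (entry$kind == "profiles") {
      ids <- if (entry$side == "drug") drugIds else targetIds
      X <- readProfiles(path, entityIds = ids,
                        featureIds = entry$features[[1L]])
      if (entry$side == "drug") drugProfiles[[entry$tag]] <- X
      else targetProfiles[[entry$tag]] <- X
    } else if (entry$kind == "graph") {
      ppi <- readPPI(path, nodes = targetIds)
    } else if (entry$kind == "sequences") {
      sequences <- readSequences(path)
    }
  }
  classes <- utils::read.delim(file.path(dir, manifest$classes))
  structure(list(dti = dti, drugProfiles = drugProfiles,
                 targetProfiles = targetProfiles, ppi = ppi,
                 sequences = sequences,
                 drugClasses = classes$class[classes$side == "drug"],
                 targetClasses = classes$class[classes$side == "target"],
                 spec = NULL),
            class = "SyntheticBundle")
}
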