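#' @include AllClasses.R utils.R similarity-kernels.R
NULL

#' Read a drug-target interaction edge list
#'
#' TSV with a header line and two id columns (drug, target). Duplicate
#' edges are collapsed to a single interaction with a warning; malformed
#' rows raise an error naming the line.
#'
#' @param path TSV file path.
#' @param drugIds,targetIds optional entity universes; defaults to the ids
#'   seen in the file, in order of first appearance.
#' @return binary interaction matrix (drugs x targets) with id dimnames.
#' @export
readDTIEdges <- function(path, drugIds = NULL, targetIds = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("DTI file needs two id columns")
  if (nrow(df) == 0L) stop("DTI file has no edges after the header")
  bad <- which(is.na(df[[1L]]) | is.na(df[[2L]]) |
                 df[[1L]] == "" | df[[2L]] == "")
  if (length(bad))
    stop("malformed DTI row at line ", bad[1L] + 1L)
  key <- paste(df[[1L]], df[[2L]], sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate DTI edge(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (is.null(drugIds)) drugIds <- unique(df[[1L]])
  if (is.null(targetIds)) targetIds <- unique(df[[2L]])
  missing <- c(setdiff(df[[1L]], drugIds), setdiff(df[[2L]], targetIds))
  if (length(missing))
    stop("edge references id(s) outside the declared universe: ",
         paste(head(missing, 5), collapse = ", "))
  W <- matrix(0, length(drugIds), length(targetIds),
              dimnames = list(drugIds, targetIds))
  W[cbind(df[[1L]], df[[2L]])] <- 1
  W
}

#' Read a long-form binary profile table
#'
#' TSV with header and two columns, \code{entity_id} and \code{feature_id};
#' each row records one existing association (a 1 in the incidence matrix).
#'
#' @param path TSV file path.
#' @param entityIds,featureIds optional universes (rows/columns of the
#'   result); defaults to ids seen in the file. Entities in the universe
#'   without any association get all-zero profiles.
#' @return binary entity x feature matrix.
#' @export
readProfiles <- function(path, entityIds = NULL, featureIds = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("profile file needs two id columns")
  if (is.null(entityIds)) entityIds <- unique(df[[1L]])
  if (is.null(featureIds)) featureIds <- unique(df[[2L]])
  X <- matrix(0, length(entityIds), length(featureIds),
              dimnames = list(entityIds, featureIds))
  keep <- df[[1L]] %in% entityIds & df[[2L]] %in% featureIds
  X[cbind(df[[1L]][keep], df[[2L]][keep])] <- 1
  X
}

#' Read a PPI edge list with confidences
#'
#' TSV \code{protein_a<TAB>protein_b<TAB>confidence}. Confidences are
#' accepted either as floats in \[0, 1\] or in the 0-1000 integer dialect
#' (detected when any value exceeds 1 and divided by 1000).
#'
#' @param path TSV file path.
#' @param nodes optional node universe (isolated nodes kept).
#' @return a [ConfidenceGraph].
#' @export
readPPI <- function(path, nodes = NULL) {
  df <- utils::read.delim(path)
  if (ncol(df) < 3L) stop("PPI file needs columns: a, b, confidence")
  names(df)[1:3] <- c("from", "to", "confidence")
  df$confidence <- as.numeric(df$confidence)
  if (any(is.na(df$confidence))) stop("non-numeric confidence value")
  if (nrow(df) && max(df$confidence) > 1) df$confidence <- df$confidence / 1000
  confidenceGraph(df[, c("from", "to", "confidence")], nodes = nodes)
}

#' Read sequences from FASTA
#' @param path FASTA file; record ids are the entity ids.
#' @return named character vector of sequences.
#' @export
readSequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write a similarity matrix as TSV
#'
#' Full symmetric matrix with entity ids as the first row and first column.
#'
#' @param sim a [SimilarityMatrix] or square matrix with id dimnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSimilarityMatrixTSV <- function(sim, path) {
  v <- if (is(sim, "SimilarityMatrix")) simValues(sim) else as.matrix(sim)
  df <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from TSV
#'
#' Expects the layout written by [writeSimilarityMatrixTSV()]. Row and
#' column ids must match; values must lie in \[0, 1\] (an offending cell is
#' named in the error); asymmetry up to 1e-9 is repaired by averaging (with
#' a warning above 1e-12), larger asymmetry is an error.
#'
#' @param path TSV file path.
#' @param side,measureName,datasetTag labels for the resulting object.
#' @return a [SimilarityMatrix].
#' @export
readSimilarityMatrixTSV <- function(path, side = "drug",
                                    measureName = "precomputed",
                                    datasetTag = measureName) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square")
  if (!identical(ids, colnames(v)))
    stop("row ids and column ids differ")
  rownames(v) <- ids
  outOfRange <- which(v < 0 | v > 1, arr.ind = TRUE)
  if (nrow(outOfRange))
    stop(sprintf("value %g out of [0, 1] at (%s, %s)",
                 v[outOfRange[1L, , drop = FALSE]],
                 ids[outOfRange[1L, 1L]], ids[outOfRange[1L, 2L]]))
  asym <- max(abs(v - t(v)))
  if (asym > 1e-9)
    stop(sprintf("matrix asymmetric beyond tolerance (max deviation %g)",
                 asym))
  if (asym > 1e-12) {
    warning("asymmetry up to ", asym, " symmetrised by averaging")
  }
  v <- (v + t(v)) / 2
  diag(v) <- 1
  similarityMatrix(v, side, measureName, datasetTag)
}

#' Summarise a drug-target interaction network
#'
#' Counts, bipartite density, and degree structure (mean and maximum
#' degrees, fraction of low-degree nodes, degree histograms per side).
#'
#' @param Wdt0 binary interaction matrix or [HeterogeneousNetwork].
#' @return list: \code{nDrugs}, \code{nTargets}, \code{nInteractions},
#'   \code{densityPercent} (percentage, e.g. 0.2740 for 0.2740\%),
#'   \code{meanDrugDegree}, \code{meanTargetDegree}, \code{maxDrugDegree},
#'   \code{maxTargetDegree}, \code{fracDrugsDegreeBelow5},
#'   \code{fracTargetsDegreeBelow5}, \code{drugDegreeTable},
#'   \code{targetDegreeTable}.
#' @examples
#' W <- matrix(0, 3, 4); W[1, 1] <- W[2, 3] <- 1
#' describeNetwork(W)$densityPercent
#' @export
describeNetwork <- function(Wdt0) {
  if (is(Wdt0, "HeterogeneousNetwork")) Wdt0 <- Wdt0@Wdt0
  Wdt0 <- as.matrix(Wdt0)
  m <- nrow(Wdt0); n <- ncol(Wdt0)
  pos <- sum(Wdt0)
  dd <- rowSums(Wdt0); td <- colSums(Wdt0)
  list(nDrugs = m, nTargets = n, nInteractions = pos,
       densityPercent = if (m * n > 0) 100 * pos / (m * n) else 0,
       meanDrugDegree = mean(dd), meanTargetDegree = mean(td),
       maxDrugDegree = max(dd), maxTargetDegree = max(td),
       fracDrugsDegreeBelow5 = mean(dd < 5),
       fracTargetsDegreeBelow5 = mean(td < 5),
       drugDegreeTable = table(dd), targetDegreeTable = table(td))
}

# Align a similarity matrix onto an entity universe: entities absent from
# the source get zero similarity off-diagonal and 1 on the diagonal.
.alignSimilarity <- function(sim, ids) {
  have <- entityIds(sim)
  missing <- setdiff(ids, have)
  if (length(missing))
    warning("entity id(s) absent from '", measureName(sim),
            "', filled with zero similarity: ",
            paste(head(missing, 5), collapse = ", "))
  v <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- intersect(ids, have)
  v[keep, keep] <- simValues(sim)[keep, keep]
  diag(v) <- 1
  similarityMatrix(v, measureSide(sim), measureName(sim), datasetTag(sim))
}

#' Build a similarity catalog from a manifest
#'
#' The manifest (JSON file or list) declares measures as
#' \code{\{name, side, tag, kind, path, method, params\}} with
#' \code{kind} in profiles/graph/sequences/matrix and \code{method} in
#' tanimoto/jaccard/cosine (profiles), isp/cn_jaccard/cn_cosine (graph),
#' align_local/align_global (sequences), precomputed (matrix). Each entry
#' is dispatched to the matching kernel or reader and aligned to the
#' supplied entity universe: entities absent from a source keep zero
#' profiles, hence zero similarity off-diagonal (with a warning). With
#' \code{intersect = TRUE} the universe is instead restricted to the
#' entities present in every source on each side.
#'
#' @param manifest path to a JSON manifest or an equivalent list with a
#'   \code{measures} element.
#' @param drugIds,targetIds entity universes (from the DTI network).
#' @param baseDir directory for relative paths (defaults to the manifest's
#'   directory).
#' @param intersect restrict to entities covered by every source
#'   (default FALSE: keep all, zero-filling).
#' @return a [SimilarityCatalog].
#' @export
buildCatalog <- function(manifest, drugIds, targetIds, baseDir = NULL,
                         intersect = FALSE) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (is.null(baseDir)) baseDir <- "."
  measures <- manifest$measures
  if (is.null(measures)) stop("manifest has no 'measures' element")
  if (length(intersect(drugIds, targetIds)))
    stop("entity-id collision between drug and target universes")
  built <- lapply(measures, function(e) {
    path <- file.path(baseDir, e$path)
    ids <- if (e$side == "drug") drugIds else targetIds
    prm <- if (is.null(e$params)) list() else e$params
    sim <- switch(e$method,
      tanimoto = ,
      jaccard = ,
      cosine = {
        if (e$kind != "profiles")
          stop("method '", e$method, "' requires kind 'profiles' (measure ",
               e$name, ")")
        X <- readProfiles(path)
        X <- X[intersect(rownames(X), ids), , drop = FALSE]
        fun <- switch(e$method, tanimoto = tanimotoSimilarity,
                      jaccard = jaccardSimilarity, cosine = cosineSimilarity)
        fun(X, side = e$side, measureName = e$name, datasetTag = e$tag)
      },
      isp = ,
      cn_jaccard = ,
      cn_cosine = {
        if (e$kind != "graph")
          stop("method '", e$method, "' requires kind 'graph' (measure ",
               e$name, ")")
        g <- readPPI(path, nodes = NULL)
        minConf <- if (is.null(prm$minConfidence)) 0.5 else prm$minConfidence
        if (e$method == "isp")
          ispSimilarity(g,
                        A = if (is.null(prm$A)) 0.9 else prm$A,
                        b = if (is.null(prm$b)) 1 else prm$b,
                        minConfidence = minConf, side = e$side,
                        measureName = e$name, datasetTag = e$tag)
        else
          commonNeighborSimilarity(
            g, index = sub("^cn_", "", e$method), minConfidence = minConf,
            side = e$side, measureName = e$name, datasetTag = e$tag)
      },
      align_local = ,
      align_global = {
        if (e$kind != "sequences")
          stop("method '", e$method, "' requires kind 'sequences' (measure ",
               e$name, ")")
        seqs <- readSequences(path)
        seqs <- seqs[intersect(names(seqs), ids)]
        alignmentSimilarity(
          seqs, mode = sub("^align_", "", e$method),
          gapOpening = if (is.null(prm$gapOpening)) 10 else prm$gapOpening,
          gapExtension = if (is.null(prm$gapExtension)) 0.5
                         else prm$gapExtension,
          side = e$side, measureName = e$name, datasetTag = e$tag)
      },
      precomputed = {
        if (e$kind != "matrix")
          stop("method 'precomputed' requires kind 'matrix' (measure ",
               e$name, ")")
        readSimilarityMatrixTSV(path, side = e$side, measureName = e$name,
                                datasetTag = e$tag)
      },
      stop("unknown method '", e$method, "' for measure ", e$name))
    sim
  })
  if (intersect) {
    for (s in c("drug", "target")) {
      idx <- which(vapply(built, measureSide, character(1)) == s)
      if (!length(idx)) next
      universe <- if (s == "drug") drugIds else targetIds
      common <- Reduce(intersect, lapply(built[idx], entityIds), universe)
      if (length(common) < 1L)
        stop("no ", s, " entities shared by all sources")
      for (i in idx) {
        v <- simValues(built[[i]])[common, common, drop = FALSE]
        built[[i]] <- similarityMatrix(v, s, measureName(built[[i]]),
                                       datasetTag(built[[i]]))
      }
    }
  } else {
    built <- lapply(built, function(sim) {
      ids <- if (measureSide(sim) == "drug") drugIds else targetIds
      .alignSimilarity(sim, ids)
    })
  }
  similarityCatalog(built)
}
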