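#' Read a taxon-by-sample abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row of sample IDs, taxon
#' IDs in the first column and, optionally, a \code{taxonomy} column of
#' semicolon-separated rank strings. Lines starting with \code{#} are
#' ignored. Values must be non-negative and, for \code{kind = "count"},
#' integers.
#'
#' @param path file path
#' @param kind \code{"count"} or \code{"signal"}
#' @return an \linkS4class{AbundanceExperiment}
#' @export
readAbundanceTable <- function(path, kind = c("count", "signal")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 2, "abundance table needs a taxon column and samples")
  taxa <- as.character(df[[1L]])
  dup <- taxa[duplicated(taxa)]
  stopIfNot(length(dup) == 0, "duplicate taxon ID: %s", dup[1L])
  taxonomy <- NULL
  valueCols <- setdiff(colnames(df)[-1L], "taxonomy")
  if ("taxonomy" %in% colnames(df)) taxonomy <- as.character(df$taxonomy)
  dupS <- valueCols[duplicated(valueCols)]
  stopIfNot(length(dupS) == 0, "duplicate sample ID: %s", dupS[1L])
  m <- matrix(NA_real_, length(taxa), length(valueCols),
              dimnames = list(taxa, valueCols))
  for (sc in valueCols) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    bad <- which(is.na(v) & !is.na(df[[sc]]))
    stopIfNot(length(bad) == 0,
              "non-numeric value '%s' at taxon %s, sample %s",
              as.character(df[[sc]])[bad[1L]], taxa[bad[1L]], sc)
    neg <- which(v < 0)
    stopIfNot(length(neg) == 0,
              "negative value %s at taxon %s, sample %s",
              format(v[neg[1L]]), taxa[neg[1L]], sc)
    m[, sc] <- v
  }
  AbundanceExperiment(m, taxonomy = taxonomy, kind = kind)
}

#' Write an abundance table to TSV
#'
#' Inverse of \code{\link{readAbundanceTable}}: taxon IDs in the first
#' column, a \code{taxonomy} column of semicolon-joined ranks, then one
#' column per sample.
#'
#' @param x an AbundanceExperiment
#' @param path output file
#' @export
writeAbundanceTable <- function(x, path) {
  m <- abundances(x)
  tax <- taxonomyTable(x)
  df <- data.frame(taxon = rownames(m),
                   taxonomy = apply(tax, 1L, paste, collapse = ";"),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Requires columns \code{sample_id}, \code{digester_id}, \code{group}
#' (control/treatment) and \code{day}; environmental and performance
#' parameter columns are kept as-is. A \code{phase_group} column
#' (\code{"C 45-76"}, \code{"T 45-76"}, \code{"C 80-97"}, \code{"T 80-97"})
#' is derived from group and day when absent: days 45-76 form the first
#' phase, days 80-97 the second.
#'
#' @param path file path
#' @return data.frame with one row per sample, rownames = sample IDs
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "digester_id", "group", "day")
  miss <- setdiff(need, colnames(df))
  stopIfNot(length(miss) == 0, "metadata missing column(s): %s",
            paste(miss, collapse = ", "))
  stopIfNot(!anyDuplicated(df$sample_id), "duplicate sample_id in metadata")
  stopIfNot(all(df$group %in% c("control", "treatment")),
            "group must be control or treatment")
  if (!"phase_group" %in% colnames(df))
    df$phase_group <- phaseGroup(df$group, df$day)
  num <- setdiff(colnames(df), c(need, "phase_group"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    stopIfNot(all(is.finite(v)), "non-finite value in metadata column %s", cn)
    df[[cn]] <- v
  }
  rownames(df) <- df$sample_id
  df
}

#' Derive phase-group labels from group and sampling day
#'
#' @param group "control"/"treatment" per sample
#' @param day sampling day per sample
#' @return character vector of phase-group labels
#' @export
phaseGroup <- function(group, day) {
  stopIfNot(all(day >= 45 & day <= 97), "day must lie in 45..97")
  phase <- ifelse(day <= 76, "45-76", "80-97")
  paste(ifelse(group == "control", "C", "T"), phase)
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement so every retained
#' column sums exactly to \code{depth} (the study design rarefies to 11,558
#' reads per sample). Samples with fewer than \code{depth} total reads are
#' dropped with a warning rather than up-sampled.
#'
#' @param x an AbundanceExperiment of kind \code{"count"}
#' @param depth target reads per sample
#' @param seed RNG seed for reproducible subsampling
#' @return a rarefied AbundanceExperiment
#' @export
rarefyCounts <- function(x, depth = 11558L, seed = NULL) {
  stopIfNot(identical(abundanceKind(x), "count"),
            "rarefaction applies to count tables only")
  stopIfNot(is.numeric(depth) && length(depth) == 1L && depth >= 1,
            "depth must be a positive integer")
  depth <- as.integer(depth)
  m <- abundances(x)
  tot <- colSums(m)
  keep <- tot >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(m)[!keep], collapse = ", ")))
  stopIfNot(any(keep), "no sample reaches the rarefaction depth")
  m <- m[, keep, drop = FALSE]
  out <- withSeed(seed, t(vegan::rrarefy(t(m), depth)))
  dimnames(out) <- dimnames(m)
  cd <- as.data.frame(colData(x))[keep, , drop = FALSE]
  AbundanceExperiment(out, taxonomy = taxonomyTable(x), kind = "count",
                      sampleData = if (ncol(cd)) cd else NULL)
}

#' Aggregate functional-gene signals to organism abundances
#'
#' For each organism, its relative abundance in a sample is the arithmetic
#' mean of the signal intensities of the functional genes derived from that
#' organism (signals assumed already normalised upstream; absent signals are
#' zeros in the input matrix). Genes missing from the mapping are excluded
#' and counted in a message; organisms with no mapped genes are omitted.
#'
#' @param geneTable gene-by-sample numeric matrix (rownames = gene IDs)
#' @param geneToOrganism named character vector, gene ID -> organism
#' @param taxonomy optional taxonomy for the organisms (vector or data.frame
#'   as in \code{\link{AbundanceExperiment}}), one entry per distinct
#'   organism in mapping order
#' @return an AbundanceExperiment of kind \code{"signal"}
#' @export
aggregateGeneSignals <- function(geneTable, geneToOrganism, taxonomy = NULL) {
  geneTable <- as.matrix(geneTable)
  stopIfNot(length(geneToOrganism) > 0, "empty gene-to-organism mapping")
  stopIfNot(!is.null(names(geneToOrganism)), "mapping must be named by gene")
  stopIfNot(!anyDuplicated(names(geneToOrganism)),
            "a gene may map to at most one organism")
  mapped <- rownames(geneTable) %in% names(geneToOrganism)
  if (any(!mapped))
    message(sprintf("%d gene(s) absent from mapping excluded", sum(!mapped)))
  stopIfNot(any(mapped), "no gene in the table is covered by the mapping")
  gt <- geneTable[mapped, , drop = FALSE]
  org <- geneToOrganism[rownames(gt)]
  cnt <- table(org)
  agg <- rowsum(gt, group = org)
  agg <- agg / as.numeric(cnt[rownames(agg)])
  AbundanceExperiment(agg, taxonomy = taxonomy, kind = "signal")
}

#' Inverse Simpson diversity (effective number of taxa)
#'
#' \eqn{n_{eff} = 1 / \sum_i p_i^2} with \eqn{p_i} the relative abundance of
#' taxon i in the sample; equals the taxon count for a perfectly even
#' community and 1 for a single-taxon community.
#'
#' @param x an AbundanceExperiment
#' @param samples sample IDs (default: all)
#' @return named numeric vector of n_eff values
#' @export
inverseSimpson <- function(x, samples = NULL) {
  m <- abundances(x)
  samples <- samples %||% colnames(m)
  stopIfNot(all(samples %in% colnames(m)), "unknown sample ID")
  tot <- colSums(m[, samples, drop = FALSE])
  stopIfNot(all(tot > 0), "all-zero sample: n_eff undefined")
  vegan::diversity(t(m[, samples, drop = FALSE]), index = "invsimpson")
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)}; symmetric, zero
#' diagonal, values in [0, 1].
#'
#' @param x an AbundanceExperiment with at least two samples
#' @return a \code{dist} over samples
#' @export
brayCurtis <- function(x) {
  m <- abundances(x)
  stopIfNot(ncol(m) >= 2, "need at least 2 samples")
  stopIfNot(all(colSums(m) > 0),
            "all-zero sample: Bray-Curtis distance undefined")
  vegan::vegdist(t(m), method = "bray")
}
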