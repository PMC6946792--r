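PHASE_GROUPS <- c("C 45-76", "T 45-76", "C 80-97", "T 80-97")
SAMPLING_DAYS <- c(45L, 62L, 66L, 69L, 73L, 76L, 80L, 83L, 87L, 90L, 97L)

ARCHAEAL_CLASSES <- c("Methanobacteria", "Methanomicrobia", "Methanococci",
                      "Thermoprotei", "Thermoplasmata")
BACTERIAL_CLASSES <- c("Clostridia", "Bacteroidia", "Bacilli",
                       "Anaerolineae", "Alphaproteobacteria",
                       "Gammaproteobacteria")

# 66-sample design: control/treatment x 3 digesters x 11 sampling days.
designFrame <- function() {
  dig <- c(paste0("C", 1:3), paste0("T", 1:3))
  df <- expand.grid(digester_id = dig, day = SAMPLING_DAYS,
                    stringsAsFactors = FALSE)
  df$group <- ifelse(startsWith(df$digester_id, "C"), "control", "treatment")
  df$sample_id <- sprintf("%s_d%02d", df$digester_id, df$day)
  df$phase_group <- phaseGroup(df$group, df$day)
  rownames(df) <- df$sample_id
  df[, c("sample_id", "digester_id", "group", "day", "phase_group")]
}

#' Generate a synthetic digester community with planted structure
#'
#' Emulates the statistical structure the downstream analysis assumes: a
#' 66-sample design (2 groups x 3 replicate digesters x 11 sampling days),
#' latent Gaussian module factors driving member taxa's log-abundances,
#' compositional closure by multinomial sampling at a fixed library size,
#' and a fraction of independent background taxa.
#'
#' Module sizes may differ (the default plants a large archaeal
#' methanogen-like module, a small archaeal module, and two bacterial
#' modules), so module membership induces the degree heterogeneity real
#' networks show. Module 1's members are the performance-driver taxa used
#' by \code{\link{generateMetadata}}. The last \code{nGroupSpecific}
#' modules are coupled mainly within \code{groupSpecificPhase}: their
#' members carry the module signal at full amplitude inside that phase
#' group and scaled down to \code{outGroupAmplitude} outside (with a mean
#' correction on the abundance scale), so the phase group's samples carry
#' the correlation and the module's pairs are the planted group-specific
#' edges. A \code{sparsity} fraction of background taxa is made rare so the
#' prevalence filter has work to do.
#'
#' @param nTaxa total taxa (default 150)
#' @param nModules number of planted modules (default 4)
#' @param moduleSize taxa per module; a vector of length \code{nModules} or
#'   a scalar (default c(20, 6, 13, 15))
#' @param withinModuleRho latent within-module correlation (0 <= rho < 1;
#'   rho = 0 gives independent, unplanted taxa)
#' @param noiseSD SD of independent log-abundance noise on top of the module
#'   signal (default 0.3)
#' @param sparsity fraction of taxa made rare (default 0.1)
#' @param nGroupSpecific how many modules (taken from the end) are
#'   group-specific (default 1)
#' @param groupSpecificPhase phase group carrying the group-specific
#'   coupling (default "T 80-97")
#' @param outGroupAmplitude amplitude multiplier of group-specific module
#'   signal outside the phase group (default 0.45); the scaled-down
#'   out-of-group signal dilutes the pooled correlation without changing
#'   the expected abundance
#' @param moduleDomains "Archaea"/"Bacteria" per module (default: modules 1
#'   and 2 archaeal, the rest bacterial)
#' @param archaealFraction fraction of taxa labelled Archaea (default 0.3;
#'   archaeal modules count towards it, the remainder comes from background
#'   taxa)
#' @param libSize multinomial library size per sample (default 11558, the
#'   rarefaction depth of the emulated design)
#' @param seed RNG seed (required for a reproducible truth)
#' @return list with \code{table} (an \linkS4class{AbundanceExperiment} of
#'   kind count, with the design in \code{colData}) and \code{truth} (a
#'   \linkS4class{PlantedTruth})
#' @export
generateCommunity <- function(nTaxa = 150L, nModules = 4L,
                              moduleSize = c(20L, 6L, 13L, 15L),
                              withinModuleRho = 0.9, noiseSD = 0.3,
                              sparsity = 0.1, nGroupSpecific = 1L,
                              groupSpecificPhase = "T 80-97",
                              outGroupAmplitude = 0.45,
                              moduleDomains = NULL,
                              archaealFraction = 0.3,
                              libSize = 11558L, seed = 1L) {
  stopIfNot(withinModuleRho >= 0 && withinModuleRho < 1,
            "withinModuleRho must lie in [0, 1)")
  stopIfNot(nModules >= 1, "nModules must be >= 1")
  sizes <- rep_len(as.integer(moduleSize), nModules)
  stopIfNot(sum(sizes) <= nTaxa, "modules cannot hold more taxa than nTaxa")
  stopIfNot(nGroupSpecific <= nModules, "nGroupSpecific > nModules")
  stopIfNot(groupSpecificPhase %in% PHASE_GROUPS, "unknown phase group")
  if (is.null(moduleDomains))
    moduleDomains <- ifelse(seq_len(nModules) <= 2, "Archaea", "Bacteria")
  moduleDomains <- rep_len(moduleDomains, nModules)
  des <- designFrame()
  nS <- nrow(des)
  taxa <- sprintf("OTU_%03d", seq_len(nTaxa))
  mod <- rep("background", nTaxa)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (m in seq_len(nModules))
    mod[starts[m]:ends[m]] <- sprintf("M%d", m)
  names(mod) <- taxa
  gsModules <- if (nGroupSpecific > 0)
    sprintf("M%d", seq(nModules - nGroupSpecific + 1L, nModules)) else
      character()
  inPhase <- des$phase_group == groupSpecificPhase

  archMods <- sprintf("M%d", which(moduleDomains == "Archaea"))
  out <- withSeed(seed, {
    mu <- stats::rnorm(nTaxa, 0, 0.35)
    # archaeal modules sit at ~5% of reads (the usual archaeal share of
    # digester communities); this also keeps their compositional footprint
    # on the bacterial fraction small
    mu[mod %in% archMods] <- mu[mod %in% archMods] - 1.25
    rare <- rep(FALSE, nTaxa)
    nRare <- round(sparsity * nTaxa)
    if (nRare > 0) {
      bg <- which(mod == "background")
      rare[bg[seq_len(min(nRare, length(bg)))]] <- TRUE
      mu[rare] <- mu[rare] - 9
    }
    z <- matrix(stats::rnorm(nTaxa * nS, 0, 1), nTaxa, nS)
    if (withinModuleRho > 0) {
      for (m in seq_len(nModules)) {
        mid <- sprintf("M%d", m)
        idx <- which(mod == mid)
        f <- stats::rnorm(nS)
        zi <- sqrt(withinModuleRho) * matrix(f, length(idx), nS,
                                             byrow = TRUE) +
          sqrt(1 - withinModuleRho) * z[idx, , drop = FALSE]
        if (mid %in% gsModules) {
          # group-specific coupling: the whole module signal is scaled down
          # outside the phase group, so the group's samples carry the
          # correlation; the mean correction keeps exp(amp * z) at the same
          # expected abundance in both phases (E exp(a z) = exp(a^2/2))
          amp <- ifelse(inPhase, 1, outGroupAmplitude)
          zi <- sweep(zi, 2L, amp, `*`)
          # z is later scaled by 0.85 on the log-abundance scale, hence the
          # factor in the offset
          zi <- sweep(zi, 2L, 0.85 * (amp^2 - 1) / 2, `-`)
        }
        z[idx, ] <- zi
      }
    }
    # 0.85 tempers the log-abundance swings so no single taxon or module
    # spike collapses a sample's effective diversity below the n_eff > 23
    # regime the generator targets
    logLambda <- mu + 0.85 * z + noiseSD * matrix(stats::rnorm(nTaxa * nS),
                                                  nTaxa, nS)
    counts <- vapply(seq_len(nS), function(s) {
      pr <- exp(logLambda[, s])
      stats::rmultinom(1L, size = libSize, prob = pr / sum(pr))[, 1L]
    }, integer(nTaxa))
    list(counts = counts, rare = rare)
  })
  counts <- out$counts
  dimnames(counts) <- list(taxa, des$sample_id)

  tax <- syntheticTaxonomy(taxa, mod, moduleDomains, archaealFraction, seed)
  table <- AbundanceExperiment(counts, taxonomy = tax, kind = "count",
                               sampleData = des)
  planted <- if (withinModuleRho > 0) {
    do.call(rbind, lapply(seq_len(nModules), function(m) {
      mid <- sprintf("M%d", m)
      mt <- taxa[mod == mid]
      cmb <- t(utils::combn(mt, 2L))
      data.frame(taxon1 = cmb[, 1L], taxon2 = cmb[, 2L], module = mid,
                 phaseGroup = if (mid %in% gsModules) groupSpecificPhase
                              else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(taxon1 = character(), taxon2 = character(),
               module = character(), phaseGroup = character(),
               stringsAsFactors = FALSE)
  }
  truth <- new("PlantedTruth",
               moduleAssignments = if (withinModuleRho > 0) mod else
                 structure(rep("background", nTaxa), names = taxa),
               plantedEdges = planted,
               driverTaxa = if (withinModuleRho > 0) taxa[mod == "M1"] else
                 character(),
               params = list(nTaxa = nTaxa, nModules = nModules,
                             moduleSize = moduleSize,
                             withinModuleRho = withinModuleRho,
                             noiseSD = noiseSD, sparsity = sparsity,
                             nGroupSpecific = nGroupSpecific,
                             groupSpecificPhase = groupSpecificPhase,
                             outGroupAmplitude = outGroupAmplitude,
                             libSize = libSize),
               seed = as.numeric(seed))
  list(table = table, truth = truth)
}

# Taxonomy strings for the synthetic taxa: archaeal modules get
# methanogen-like classes; extra archaea (up to archaealFraction) are drawn
# from the background; everything else is bacterial.
syntheticTaxonomy <- function(taxa, mod, moduleDomains, archaealFraction,
                              seed) {
  n <- length(taxa)
  withSeed(deriveSeed(seed, 101L), {
    archMods <- sprintf("M%d", which(moduleDomains == "Archaea"))
    isArch <- mod %in% archMods
    nArch <- round(archaealFraction * n)
    extra <- nArch - sum(isArch)
    if (extra > 0) {
      pool <- which(mod == "background")
      isArch[sample(pool, min(extra, length(pool)))] <- TRUE
    }
    cls <- character(n)
    cls[isArch] <- sample(ARCHAEAL_CLASSES, sum(isArch), replace = TRUE)
    cls[mod == "M1" & isArch] <-
      sample(c("Methanobacteria", "Methanomicrobia"),
             sum(mod == "M1" & isArch), replace = TRUE)
    cls[!isArch] <- sample(BACTERIAL_CLASSES, sum(!isArch), replace = TRUE)
    data.frame(
      domain = ifelse(isArch, "Archaea", "Bacteria"),
      phylum = ifelse(isArch,
                      ifelse(cls %in% c("Thermoprotei"), "Crenarchaeota",
                             "Euryarchaeota"),
                      ifelse(cls %in% c("Clostridia", "Bacilli"),
                             "Firmicutes",
                      ifelse(cls == "Bacteroidia", "Bacteroidetes",
                      ifelse(cls == "Anaerolineae", "Chloroflexi",
                             "Proteobacteria")))),
      class = cls,
      order = "unclassified", family = "unclassified",
      genus = paste0("g_", cls), species = "unclassified",
      row.names = taxa, stringsAsFactors = FALSE
    )
  })
}

#' Generate sample metadata driven by the planted community
#'
#' Environmental parameters follow the organic-loading-rate design: the
#' control digesters stay at a flat OLR while the treatment digesters step
#' from 1.3 to 1.5 g VS/liter/day between the two phases; total ammonia
#' tracks the VS load, pH and acetate fluctuate around constants.
#' Performance parameters (biogas, methane, VS removal) are a linear
#' combination of the driver taxa's standardised log abundances (coefficient
#' \code{beta}) plus Gaussian noise: performance is determined by the
#' methanogen-like driver taxa, not by the loading rate directly. With
#' beta = 0 the performance parameters are pure noise and every taxon's GS
#' sits at the null.
#'
#' @param table the AbundanceExperiment from \code{\link{generateCommunity}}
#' @param truth the matching \linkS4class{PlantedTruth}
#' @param beta effect size of the driver taxa on performance (default 1)
#' @param noiseSD SD of the performance/environment noise (default 0.4)
#' @param olrStep treatment OLR levels for the two phases (default
#'   c(1.3, 1.5); control stays at 1.0)
#' @param seed RNG seed
#' @return metadata data.frame (rownames = sample IDs) with design columns
#'   plus vs_load, ph, acetate, ammonia, vs_removal, biogas, methane
#' @export
generateMetadata <- function(table, truth, beta = 1, noiseSD = 0.4,
                             olrStep = c(1.3, 1.5), seed = 1L) {
  stopIfNot(length(olrStep) == 2, "olrStep must give the two phase levels")
  des <- as.data.frame(colData(table))
  stopIfNot(all(c("group", "day", "phase_group") %in% colnames(des)),
            "table must carry the sampling design in colData")
  m <- abundances(table)
  drv <- driverTaxa(truth)
  stopIfNot(beta == 0 || length(drv) > 0,
            "truth has no performance-driver taxa")
  driverScore <- if (length(drv) > 0) {
    la <- log1p(m[drv, , drop = FALSE])
    colMeans(t(scale(t(la))))
  } else {
    rep(0, ncol(m))
  }
  nS <- nrow(des)
  treat <- des$group == "treatment"
  late <- des$day >= 80
  withSeed(seed, {
    olr <- ifelse(treat, ifelse(late, olrStep[2L], olrStep[1L]), 1.0)
    des$vs_load <- olr + stats::rnorm(nS, 0, 0.05)
    des$ph <- 7.3 + stats::rnorm(nS, 0, 0.1)
    des$acetate <- 1.2 + stats::rnorm(nS, 0, 0.2)
    des$ammonia <- 1.5 + 0.8 * (olr - 1) + stats::rnorm(nS, 0, 0.1)
    perf <- function(base, scale) {
      base + scale * (beta * driverScore + stats::rnorm(nS, 0, noiseSD))
    }
    des$vs_removal <- perf(45, 10)
    des$biogas <- perf(2.0, 0.5)
    des$methane <- perf(1.2, 0.3)
  })
  des
}

#' Write a synthetic data set to disk
#'
#' Writes the abundance TSV, metadata TSV and a JSON record of the planted
#' truth, the on-disk interface of the generator.
#'
#' @param community output of \code{\link{generateCommunity}}
#' @param meta output of \code{\link{generateMetadata}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSyntheticData <- function(community, meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pAb <- file.path(dir, "abundance.tsv")
  pMeta <- file.path(dir, "metadata.tsv")
  pTruth <- file.path(dir, "truth.json")
  writeAbundanceTable(community$table, pAb)
  utils::write.table(meta, pMeta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- community$truth
  jsonlite::write_json(
    list(moduleAssignments = as.list(moduleAssignments(tr)),
         plantedEdges = plantedEdges(tr),
         driverTaxa = driverTaxa(tr),
         params = tr@params, seed = tr@seed),
    pTruth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(abundance = pAb, metadata = pMeta, truth = pTruth))
}
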