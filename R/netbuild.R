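#' Prevalence filter
#'
#' Keeps taxa detected (nonzero) in strictly more than \code{minSamples}
#' samples; the default mirrors the study design of requiring detection in
#' more than 9 of 66 samples. A value below 1 is read as a fraction of the
#' sample count.
#'
#' @param x an AbundanceExperiment
#' @param minSamples prevalence cutoff (count, or fraction if < 1)
#' @return the filtered AbundanceExperiment
#' @export
prevalenceFilter <- function(x, minSamples = 9) {
  stopIfNot(minSamples > 0, "minSamples must be positive")
  m <- abundances(x)
  cut <- if (minSamples < 1) minSamples * ncol(m) else minSamples
  keep <- rowSums(m > 0) > cut
  stopIfNot(sum(keep) >= 2,
            "fewer than 2 taxa pass the prevalence filter")
  cd <- as.data.frame(colData(x))
  AbundanceExperiment(m[keep, , drop = FALSE],
                      taxonomy = taxonomyTable(x)[keep, , drop = FALSE],
                      kind = abundanceKind(x),
                      sampleData = if (ncol(cd)) cd else NULL)
}

#' All-pairs Spearman correlation with BH-adjusted p-values
#'
#' Computes Spearman rho (average-rank ties) and a two-sided p-value for
#' every taxon pair, then adjusts the p-values with the Benjamini-Hochberg
#' step-up procedure over all defined pairs. Pairs involving a taxon that is
#' constant across samples are undefined (\code{NA}), excluded from the FDR
#' adjustment and never become edges.
#'
#' The p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom, the
#' standard form for tied, moderately large samples.
#'
#' @param x an AbundanceExperiment with >= 4 samples
#' @return a \linkS4class{CorrelationSet}
#' @export
spearmanAllPairs <- function(x) {
  m <- abundances(x)
  n <- ncol(m)
  stopIfNot(n >= 4, "need at least 4 samples for correlation")
  stopIfNot(nrow(m) >= 2, "need at least 2 taxa")
  const <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  if (any(const))
    message(sprintf("%d constant taxa excluded from correlation: %s",
                    sum(const),
                    paste(utils::head(rownames(m)[const], 5), collapse = ", ")))
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- NA_real_
  ut <- upper.tri(p)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  ok <- ut & !is.na(p)
  q[ok] <- bhAdjust(p[ok])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  new("CorrelationSet", rho = rho, p = p, q = q, nSamples = as.integer(n))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, capped at 1 and mapped back
#' to the input order; delegates to \code{stats::p.adjust(method = "BH")}
#' after validating the input range.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed through)
#' @return adjusted q-values
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' RMT-based correlation threshold scan
#'
#' Scans candidate cutoffs in ascending order. For each cutoff s, the
#' correlation matrix is hard-thresholded (entries with |rho| < s zeroed,
#' unit diagonal), its eigenvalues are computed, degenerate eigenvalues are
#' collapsed, and the spectrum is unfolded with a cubic smoothing spline
#' through the empirical cumulative spectral function. The nearest-neighbour
#' spacing distribution (NNSD) of the unfolded eigenvalues is tested by a
#' chi-square goodness of fit on equal-probability bins against (i) the
#' Poisson form \eqn{e^{-d}} and (ii) the GOE Wigner surmise
#' \eqn{(\pi/2) d e^{-\pi d^2/4}}. The chosen cutoff is the smallest s whose
#' NNSD is consistent with Poisson (p > alpha) and inconsistent with GOE
#' (p < alpha) — the point where residual random correlations have been
#' removed and only modular structure remains. A cutoff at which no
#' off-diagonal entry survives is the fully uncorrelated limit and counts as
#' Poisson-consistent.
#'
#' @param cs a \linkS4class{CorrelationSet} from enough taxa (>= ~50) that
#'   the spectrum carries a usable number of spacings
#' @param scanStart,scanEnd,step scan grid for the cutoff
#' @param alpha significance level for both goodness-of-fit decisions
#' @param minSpacings smallest number of unfolded spacings on which the
#'   goodness of fit is attempted
#' @return a \linkS4class{ThresholdScan}
#' @export
rmtThreshold <- function(cs, scanStart = 0.30, scanEnd = 0.95, step = 0.01,
                         alpha = 0.05, minSpacings = 15L) {
  rho <- corRho(cs)
  stopIfNot(nrow(rho) >= 10, "too few taxa for a spectral scan")
  rho0 <- rho
  rho0[is.na(rho0)] <- 0
  diag(rho0) <- 1
  cutoffs <- seq(scanStart, scanEnd, by = step)
  rows <- vector("list", length(cutoffs))
  chosen <- NA_real_
  for (k in seq_along(cutoffs)) {
    s <- cutoffs[k]
    A <- rho0
    A[abs(A) < s] <- 0
    diag(A) <- 1
    nOff <- sum(A[upper.tri(A)] != 0)
    if (nOff == 0L) {
      # fully uncorrelated limit: Poisson by convention
      rows[[k]] <- data.frame(cutoff = s, nOffdiag = 0L, nSpacings = 0L,
                              poissonChisq = NA_real_, poissonP = 1,
                              goeChisq = NA_real_, goeP = 0,
                              decision = TRUE)
    } else {
      ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
      sp <- unfoldedSpacings(ev)
      if (length(sp) < minSpacings) {
        rows[[k]] <- data.frame(cutoff = s, nOffdiag = nOff,
                                nSpacings = length(sp),
                                poissonChisq = NA_real_, poissonP = NA_real_,
                                goeChisq = NA_real_, goeP = NA_real_,
                                decision = FALSE)
      } else {
        pois <- nnsdGof(sp, "poisson")
        goe <- nnsdGof(sp, "goe")
        rows[[k]] <- data.frame(cutoff = s, nOffdiag = nOff,
                                nSpacings = length(sp),
                                poissonChisq = pois$stat, poissonP = pois$p,
                                goeChisq = goe$stat, goeP = goe$p,
                                decision = pois$p > alpha && goe$p < alpha)
      }
    }
    if (rows[[k]]$decision && is.na(chosen)) {
      chosen <- s
      break
    }
  }
  scan <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.na(chosen))
    stop("no cutoff in [", scanStart, ", ", scanEnd,
         "] meets the Poisson/GOE criterion; widen the scan range")
  new("ThresholdScan", scan = scan, chosenCutoff = chosen, alpha = alpha)
}

# Collapse degenerate eigenvalues, unfold via a cubic smoothing spline on
# the empirical cumulative spectral function, and return spacings rescaled
# to unit mean.
unfoldedSpacings <- function(ev, tol = 1e-8) {
  ev <- sort(ev)
  keep <- c(TRUE, diff(ev) > tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < 3L) return(numeric())
  cum <- seq_len(n)
  fit <- tryCatch(
    stats::smooth.spline(ev, cum, df = min(max(4, n %/% 4), 12)),
    error = function(e) NULL
  )
  unf <- if (is.null(fit)) cum else stats::predict(fit, ev)$y
  d <- diff(sort(unf))
  d <- d[d >= 0]
  if (!length(d) || mean(d) <= 0) return(numeric())
  d / mean(d)
}

# Chi-square GoF of unit-mean spacings against Poisson exp(-d) or the GOE
# Wigner surmise, on equal-probability bins. Bin count adapts to the sample
# size (>= ~5 expected per bin) up to 20 bins.
nnsdGof <- function(sp, form = c("poisson", "goe")) {
  form <- match.arg(form)
  n <- length(sp)
  nb <- min(20L, max(4L, n %/% 5L))
  probs <- seq(0, 1, length.out = nb + 1L)
  qf <- if (form == "poisson") {
    function(p) stats::qexp(p)
  } else {
    function(p) sqrt(-4 / pi * log(1 - p))
  }
  brk <- qf(probs)
  brk[1L] <- -Inf
  brk[nb + 1L] <- Inf
  obs <- as.vector(table(cut(sp, brk)))
  expd <- n / nb
  stat <- sum((obs - expd)^2 / expd)
  list(stat = stat, p = stats::pchisq(stat, df = nb - 1L, lower.tail = FALSE))
}

#' Build the signed association network
#'
#' An edge joins taxa i and j iff \eqn{q_{ij} \le} \code{qCutoff} and
#' \eqn{|\rho_{ij}| \ge} \code{rhoCutoff} (FDR 0.001 and the RMT-chosen
#' correlation cutoff by default in the pipeline). Edge sign is the sign of
#' rho. Taxa with no retained edge are not nodes of the network.
#'
#' @param cs a \linkS4class{CorrelationSet}
#' @param qCutoff FDR-adjusted p cutoff (default 0.001)
#' @param rhoCutoff absolute-correlation cutoff, e.g. from
#'   \code{\link{rmtThreshold}}
#' @param taxonomy optional taxonomy data.frame (rownames = taxa) used to
#'   annotate vertices with rank columns and a domain flag
#' @return an \linkS4class{AssociationNetwork}
#' @export
buildNetwork <- function(cs, qCutoff = 0.001, rhoCutoff, taxonomy = NULL) {
  stopIfNot(qCutoff > 0 && qCutoff <= 1, "qCutoff must lie in (0, 1]")
  stopIfNot(rhoCutoff > 0 && rhoCutoff <= 1, "rhoCutoff must lie in (0, 1]")
  rho <- corRho(cs)
  q <- corQ(cs)
  sel <- which(upper.tri(rho) & !is.na(q) & q <= qCutoff &
                 abs(rho) >= rhoCutoff, arr.ind = TRUE)
  taxa <- corTaxa(cs)
  if (nrow(sel) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    ed <- data.frame(from = taxa[sel[, 1L]], to = taxa[sel[, 2L]],
                     rho = rho[sel],
                     sign = ifelse(rho[sel] > 0, "positive", "negative"),
                     q = q[sel], stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  }
  net <- new("AssociationNetwork", graph = g)
  if (!is.null(taxonomy)) net <- annotateNetwork(net, taxonomy)
  net
}

#' Attach taxonomy and a domain flag to network vertices
#'
#' @param net an AssociationNetwork
#' @param taxonomy data.frame with rank columns, rownames = taxa
#' @return the annotated network
#' @export
annotateNetwork <- function(net, taxonomy) {
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0L) return(net)
  nm <- igraph::V(g)$name
  stopIfNot(all(nm %in% rownames(taxonomy)),
            "taxonomy must cover every network node")
  for (rk in intersect(TAXONOMY_RANKS, colnames(taxonomy)))
    g <- igraph::set_vertex_attr(g, rk, value = taxonomy[nm, rk])
  new("AssociationNetwork", graph = g)
}
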