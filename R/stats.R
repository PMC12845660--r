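## Paired upstream/downstream testing per compound: exact Wilcoxon
## signed-rank with midrank ties, Shapiro-Wilk normality of paired
## differences, and Benjamini-Hochberg FDR correction.

#' Paired downstream - upstream differences
#'
#' For each compound, the per-settlement difference between the downstream
#' and the upstream sample; non-detected concentrations enter as zero
#' (lower-bound convention).
#'
#' @param experiment A [PfasExperiment-class] whose samples pair one
#'   upstream and one downstream sample per settlement.
#' @return Numeric compounds x settlements matrix of differences (ng/L).
#' @export
pairedDifferences <- function(experiment) {
  si <- sampleInfo(experiment)
  conc <- concentrations(experiment)
  st <- quantStatus(experiment)
  conc[st %in% c("not_detected", "below_mql")] <- 0
  setts <- unique(si$settlement)
  d <- sapply(setts, function(s) {
    up <- si$sample_id[si$settlement == s & si$position == "upstream"]
    down <- si$sample_id[si$settlement == s & si$position == "downstream"]
    if (length(up) != 1L || length(down) != 1L) {
      stop("settlement '", s, "' is not a complete upstream/downstream pair")
    }
    conc[, down] - conc[, up]
  })
  colnames(d) <- setts
  d
}

# exact null distribution of the positive-rank sum: probability of each
# value of 2*W over all 2^n sign assignments, by generating-function
# convolution over the (doubled, hence integer) midranks
.signedRankDistribution <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1L) # index k+1 = probability of 2W = k
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1L - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Signed-rank statistic W = sum of ranks of the positive differences,
#' with midranks for tied absolute values. Zero differences are dropped
#' (classical convention) or handled by the Pratt method (ranked, then
#' removed from the statistic). The two-sided p-value is exact — computed
#' from the full distribution over all 2^n sign assignments — for
#' n <= `exactMax`, and uses the tie-corrected normal approximation above.
#'
#' @param differences Numeric vector of paired differences.
#' @param zeroPolicy `"drop"` (default) or `"pratt"`.
#' @param exactMax Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `statistic` (W), `p_value` (two-sided), `n` (pairs
#'   used) and `method`. All-zero input returns `NA` statistics.
#' @export
wilcoxonSignedRank <- function(differences, zeroPolicy = c("drop", "pratt"),
                               exactMax = 25L) {
  zeroPolicy <- match.arg(zeroPolicy)
  d <- differences[!is.na(differences)]
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "undefined (all differences zero)"))
  }
  if (zeroPolicy == "drop") {
    d <- d[nz]
    r <- rank(abs(d))
    keep <- rep(TRUE, length(d))
  } else {
    r <- rank(abs(d))
    keep <- d != 0
  }
  n <- sum(keep)
  W <- sum(r[keep & d > 0])
  if (n <= exactMax) {
    ranks2 <- as.integer(round(2 * r[keep]))
    dist <- .signedRankDistribution(ranks2)
    w2 <- as.integer(round(2 * W))
    pLe <- sum(dist[seq_len(w2 + 1L)])
    pGe <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- sum(r[keep]) / 2
    sigma2 <- sum(r[keep]^2) / 4 # tie-corrected: uses the midranks directly
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Shapiro-Wilk normality test
#'
#' Normality check of the paired differences (3 <= n <= 50; constant data
#' are rejected), via the standard W statistic and p-value.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiroWilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("Shapiro-Wilk requires n >= 3")
  if (length(x) > 50L) stop("Shapiro-Wilk supported for n <= 50")
  if (diff(range(x)) == 0) stop("Shapiro-Wilk undefined for constant data")
  ht <- stats::shapiro.test(x)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' order-preserving, never below the raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s passed through).
#' @return Adjusted p-values.
#' @export
fdrAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired upstream/downstream tests for every compound
#'
#' Runs the paired Wilcoxon signed-rank test (exact for the small paired
#' designs used here) on the downstream - upstream differences of each
#' compound, checks the differences for normality with Shapiro-Wilk, and
#' adjusts the Wilcoxon p-values across compounds with the
#' Benjamini-Hochberg FDR procedure.
#'
#' @param experiment A [PfasExperiment-class].
#' @param zeroPolicy Zero-difference handling for the Wilcoxon test.
#' @return `data.frame` with one row per compound: `compound_id`,
#'   `n_pairs`, `n_nonzero_pairs`, `w_statistic`, `p_value`,
#'   `p_adjusted`, `shapiro_w`, `shapiro_p`.
#' @export
upstreamDownstreamTests <- function(experiment, zeroPolicy = "drop") {
  d <- pairedDifferences(experiment)
  rows <- lapply(rownames(d), function(cmp) {
    di <- d[cmp, ]
    wt <- wilcoxonSignedRank(di, zeroPolicy = zeroPolicy)
    sw <- tryCatch(shapiroWilk(di),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_))
    data.frame(compound_id = cmp, n_pairs = length(di),
               n_nonzero_pairs = sum(di != 0),
               w_statistic = wt$statistic, p_value = wt$p_value,
               shapiro_w = sw$statistic, shapiro_p = sw$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- fdrAdjust(res$p_value)
  res <- res[, c("compound_id", "n_pairs", "n_nonzero_pairs", "w_statistic",
                 "p_value", "p_adjusted", "shapiro_w", "shapiro_p")]
  rownames(res) <- NULL
  res
}
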