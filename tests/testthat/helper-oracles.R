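# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately use different algorithms from the
# implementation (enumeration, matrix closure, expand.grid search).

# truth-table oracle for confidence assignment, coded from the level
# definitions independently of assignConfidence()
oracleConfidence <- function(mass, formula, lib, insilico, rt) {
  if (!any(c(mass, formula, lib, insilico, rt))) stop("no evidence")
  if (rt && !mass) stop("inconsistent")
  if (rt && mass && (lib || insilico)) return(1L)
  if (mass && lib) return(2L)
  if (formula && insilico) return(3L)
  if (formula) return(4L)
  if (mass) return(5L)
  NA_integer_
}

# exact two-sided Wilcoxon signed-rank p by explicit enumeration of all
# 2^n sign assignments (midranks on |d|, zeros dropped)
oracleWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  pLe <- mean(Ws <= W + 1e-9)
  pGe <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# hand-rolled Benjamini-Hochberg step-up with monotonicity enforcement
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force transitive closure grouping via boolean matrix powers
oracleGrouping <- function(features, rtTol = 0.2, mzTolPpm = 5) {
  n <- nrow(features)
  A <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(features$rt[i] - features$rt[j]) <= rtTol &&
          abs(features$mz[i] - features$mz[j]) <=
            mzTolPpm * 1e-6 * max(features$mz[i], features$mz[j])) {
        A[i, j] <- TRUE
      }
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # canonical labels: smallest member index of each closure row
  apply(A, 1, function(row) min(which(row)))
}

# O(n^3) brute-force homologous-series construction: pairwise link test,
# then closure by matrix powers
oracleSeries <- function(features, base = "CF2", kmdTol = 0.002,
                         unitTolPpm = 5, maxUnits = 10) {
  unit <- monoisotopicMass(base)
  kmd <- kendrickCoords(features$mz, base)$kmd
  n <- nrow(features)
  A <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (abs(kmd[i] - kmd[j]) > kmdTol) next
      dm <- abs(features$mz[i] - features$mz[j])
      k <- round(dm / unit)
      if (k >= 1 && k <= maxUnits &&
          abs(dm - k * unit) <= unitTolPpm * 1e-6 * max(features$mz[i],
                                                        features$mz[j])) {
        A[i, j] <- TRUE
      }
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  lab <- apply(A, 1, function(row) min(which(row)))
  keep <- lab %in% names(which(table(lab) >= 2))
  split(as.character(features$feature_id[keep]), lab[keep])
}

# unordered co-membership pairs of a partition, as "a|b" strings
membershipPairs <- function(groups) {
  out <- character(0)
  for (g in groups) {
    g <- sort(as.character(g))
    if (length(g) >= 2) {
      cmb <- utils::combn(g, 2)
      out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "|"))
    }
  }
  sort(out)
}

# brute-force formula search over a full expand.grid (no pruning)
oracleFormulas <- function(mz, tolPpm, elements, maxCounts) {
  target <- mz + 1.007276466879
  grids <- lapply(elements, function(e) 0:maxCounts[[e]])
  names(grids) <- elements
  g <- expand.grid(grids)
  hits <- character(0)
  for (i in seq_len(nrow(g))) {
    cnt <- unlist(g[i, , drop = TRUE])
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) next
    m <- sum(vapply(names(cnt), function(e)
      monoisotopicMass(stats::setNames(1, e)), numeric(1)) * cnt)
    if (abs((target - m) / m * 1e6) <= tolPpm) {
      gf <- function(e) if (e %in% names(cnt)) cnt[[e]] else 0
      rdbe <- gf("C") + 1 + (gf("N") + gf("P")) / 2 -
        (gf("H") + gf("F") + gf("Cl") + gf("Br")) / 2
      if (rdbe < 0) next
      if (gf("F") > 2 * gf("C") + 1) next
      if (gf("H") + gf("F") + gf("Cl") + gf("Br") >
            2 * gf("C") + 2 + gf("N") + gf("P")) next
      hits <- c(hits, formatFormula(cnt))
    }
  }
  sort(hits)
}

# small paired-survey design scaled down for repeated simulation
smallDesign <- function(seed, nCompounds = 6) {
  roster <- pfasCompoundRoster()[seq_len(nCompounds), ]
  defaultStudyDesign(seed = seed, compounds = roster)
}
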