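## Mass-defect analytics: standard and Kendrick mass defects, carbon-
## normalized PFAS-plot coordinates, homologous-series detection and
## constrained formula enumeration.

.KENDRICK_BASES <- list(
  CF2 = list(nominal = 50, exact = 12.0 + 2 * 18.99840322),
  CH2 = list(nominal = 14, exact = 12.0 + 2 * 1.00782503207)
)

# round-half-up so that defects land in [-0.5, 0.5); base round() would
# banker's-round x.5 to the even integer
.roundHalfUp <- function(x) floor(x + 0.5)

#' Standard mass defect
#'
#' Difference between an exact mass and its nearest integer,
#' `m - round(m)`, constrained to `[-0.5, 0.5)`. Heavily fluorinated
#' molecules have negative mass defects, which is the basis of the
#' mass-defect filters used to separate PFAS from CHNO organics.
#'
#' @param m Exact mass in Da, `> 0`. Vectorized.
#' @return Mass defect in Da, in `[-0.5, 0.5)`.
#' @examples
#' massDefect(monoisotopicMass("CF2")) # -0.0031934
#' @export
massDefect <- function(m) {
  stopifnot(is.numeric(m), all(m > 0))
  m - .roundHalfUp(m)
}

#' Kendrick mass and Kendrick mass defect
#'
#' Rescales masses so the chosen repeat unit (CF2 for perfluoroalkyl
#' homologues, CH2 for alkyl homologues) has integer nominal mass:
#' `KM = m * nominal/exact`, `KMD = round(KM) - KM`. Members of a homologous
#' series differing by repeat units share the same KMD.
#'
#' @param m Exact mass(es) in Da, `> 0`.
#' @param base `"CF2"` (default) or `"CH2"`.
#' @return `data.frame` with columns `base`, `kendrick_mass`, `kmd`,
#'   `nominal_km`.
#' @examples
#' kendrickCoords(monoisotopicMass("C4HF7O2"), "CF2") # PFBA
#' @export
kendrickCoords <- function(m, base = c("CF2", "CH2")) {
  base <- match.arg(base)
  stopifnot(is.numeric(m), all(m > 0))
  b <- .KENDRICK_BASES[[base]]
  km <- m * (b$nominal / b$exact)
  nom <- .roundHalfUp(km)
  data.frame(base = base, kendrick_mass = km, kmd = nom - km,
             nominal_km = as.integer(nom))
}

#' Carbon-normalized PFAS-plot coordinates
#'
#' Mass defect and mass divided by carbon number; on these coordinates
#' perfluorinated compounds separate from non-fluorinated organics
#' regardless of chain length.
#'
#' @param m Exact mass in Da.
#' @param nCarbon Carbon count, `>= 1`.
#' @return `data.frame` with `md_per_c` and `mz_per_c` (Da per carbon).
#' @export
pfasPlotCoords <- function(m, nCarbon) {
  stopifnot(is.numeric(m), all(m > 0))
  if (any(nCarbon < 1) || any(nCarbon != round(nCarbon))) {
    stop("nCarbon must be an integer >= 1")
  }
  data.frame(md_per_c = massDefect(m) / nCarbon, mz_per_c = m / nCarbon)
}

# straightforward union-find over an edge matrix; returns root label per node
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect CF2/CH2 homologous series among features
#'
#' Groups features whose Kendrick mass defects agree within `kmdTol` and
#' whose pairwise mass differences are integer multiples (1 to `maxUnits`)
#' of the repeat-unit exact mass, within `unitTolPpm` of the larger mass.
#' Connected sets with at least two members are reported as homologous
#' series. Features are processed in ascending m/z order, so the result is
#' deterministic for any input order.
#'
#' @param features `data.frame` with columns `feature_id` and `mz`.
#' @param base Repeat unit, `"CF2"` (default) or `"CH2"`.
#' @param kmdTol KMD agreement tolerance in Da (default 0.002).
#' @param unitTolPpm Spacing tolerance in ppm of the larger mass (default 5).
#' @param maxUnits Largest number of repeat units allowed between two linked
#'   members (default 10).
#' @return `data.frame` with one row per series member: `series_id`,
#'   `base_unit`, `feature_id`, `mz`, `kmd`, `kmd_centroid`. Zero rows when
#'   no series is found.
#' @export
findHomologousSeries <- function(features, base = c("CF2", "CH2"),
                                 kmdTol = 0.002, unitTolPpm = 5,
                                 maxUnits = 10L) {
  base <- match.arg(base)
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz") %in% names(features)))
  if (nrow(features) < 2L) {
    stop("need at least 2 features to search for homologous series")
  }
  f <- features[order(features$mz), , drop = FALSE]
  kc <- kendrickCoords(f$mz, base)
  unit <- .KENDRICK_BASES[[base]]$exact
  n <- nrow(f)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(kc$kmd[i] - kc$kmd[j]) > kmdTol) next
      dm <- f$mz[j] - f$mz[i]
      k <- round(dm / unit)
      if (k < 1 || k > maxUnits) next
      if (abs(dm - k * unit) <= unitTolPpm * 1e-6 * f$mz[j]) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  comp <- .unionFind(n, edges)
  keep <- comp %in% names(which(table(comp) >= 2))
  if (!any(keep)) {
    return(data.frame(series_id = integer(0), base_unit = character(0),
                      feature_id = character(0), mz = numeric(0),
                      kmd = numeric(0), kmd_centroid = numeric(0)))
  }
  comp_kept <- comp[keep]
  sid <- as.integer(factor(comp_kept, levels = unique(comp_kept)))
  cent <- tapply(kc$kmd[keep], sid, mean)
  data.frame(series_id = sid, base_unit = base,
             feature_id = as.character(f$feature_id[keep]),
             mz = f$mz[keep], kmd = kc$kmd[keep],
             kmd_centroid = as.numeric(cent[as.character(sid)]),
             row.names = NULL)
}

#' Enumerate molecular formulas within a ppm window
#'
#' Bounded exhaustive search over element counts for formulas whose
#' (de)protonated ion mass lies within `tolPpm` of the measured m/z.
#' Candidates are filtered with documented heuristics that favour
#' PFAS-like elemental compositions and are returned sorted by absolute
#' ppm error.
#'
#' Heuristic filters (configurable via `rules`):
#' * ring-double-bond equivalents `C + 1 + (N+P)/2 - (H+F+Cl+Br)/2 >= 0`;
#' * `F <= 2C + 1` (a perfluoroalkyl chain cannot carry more fluorines);
#' * `H + F + Cl + Br <= 2C + 2 + N + P` (acyclic valence bound).
#'
#' @param mz Measured m/z (Da), `> 0`.
#' @param charge Ion charge; `-1` (default) interprets `mz` as `[M-H]-`,
#'   `0` as a neutral mass.
#' @param tolPpm Mass tolerance in ppm (default 5).
#' @param elements Character vector of elements to search over.
#' @param maxCounts Named integer vector of per-element maximum counts;
#'   elements without an entry default to 0.
#' @param rules Character subset of `c("rdbe", "fluorine", "valence")`;
#'   filters to apply.
#' @return `data.frame` with columns `formula`, `neutral_mass`, `ppm_error`,
#'   sorted by `abs(ppm_error)`.
#' @examples
#' enumerateFormulas(112.98554, elements = c("C", "H", "F", "O"),
#'                   maxCounts = c(C = 6, H = 6, F = 6, O = 4))
#' @export
enumerateFormulas <- function(mz, charge = -1L, tolPpm = 5,
                              elements = c("C", "H", "F", "O", "S"),
                              maxCounts = NULL,
                              rules = c("rdbe", "fluorine", "valence")) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  if (length(elements) == 0L) stop("element set is empty")
  bad <- setdiff(elements, supportedElements())
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (!charge %in% c(-1L, 0L)) stop("only charge -1 or 0 supported")
  rules <- match.arg(rules, several.ok = TRUE)
  target <- if (charge == -1L) mz + .PROTON_MASS else mz
  if (is.null(maxCounts)) {
    maxCounts <- vapply(elements, function(e)
      floor(target / .ATOMIC_MASS[[e]]), numeric(1))
  }
  mc <- rep(0L, length(elements)); names(mc) <- elements
  mc[names(maxCounts)[names(maxCounts) %in% elements]] <-
    as.integer(maxCounts[names(maxCounts) %in% elements])
  tolDa <- tolPpm * 1e-6 * target
  # search heaviest elements first so mass pruning bites early
  els <- elements[order(-.ATOMIC_MASS[elements])]
  masses <- .ATOMIC_MASS[els]
  res <- list()
  counts <- integer(length(els)); names(counts) <- els
  recurse <- function(i, remaining) {
    if (i > length(els)) {
      if (abs(remaining) <= tolDa) {
        cnt <- counts[counts > 0]
        if (length(cnt) && .passesRules(cnt, rules)) {
          res[[length(res) + 1L]] <<- cnt
        }
      }
      return(invisible())
    }
    m <- masses[i]
    # lightest remaining element bounds how much mass later elements can add
    maxLater <- if (i < length(els)) {
      sum(masses[(i + 1L):length(els)] * mc[els[(i + 1L):length(els)]])
    } else 0
    for (k in 0:mc[els[i]]) {
      rem <- remaining - k * m
      if (rem < -tolDa) break
      if (rem - tolDa > maxLater) next
      counts[i] <<- k
      recurse(i + 1L, rem)
    }
    counts[i] <<- 0L
  }
  recurse(1L, target)
  if (!length(res)) {
    return(data.frame(formula = character(0), neutral_mass = numeric(0),
                      ppm_error = numeric(0)))
  }
  fml <- vapply(res, formatFormula, character(1))
  nm <- vapply(res, monoisotopicMass, numeric(1))
  out <- data.frame(formula = fml, neutral_mass = nm,
                    ppm_error = ppmError(target, nm))
  # ppm error expressed on the measured scale (measured vs candidate)
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.passesRules <- function(counts, rules) {
  g <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  C <- g("C"); H <- g("H"); F_ <- g("F"); N <- g("N"); P <- g("P")
  X <- g("Cl") + g("Br")
  if ("rdbe" %in% rules) {
    rdbe <- C + 1 + (N + P) / 2 - (H + F_ + X) / 2
    if (rdbe < 0) return(FALSE)
  }
  if ("fluorine" %in% rules && F_ > 2 * C + 1) return(FALSE)
  if ("valence" %in% rules && H + F_ + X > 2 * C + 2 + N + P) return(FALSE)
  TRUE
}
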