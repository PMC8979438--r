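# Accessible surface area by Shrake-Rupley sphere-point sampling, relative
# accessibility, and the three-class exposure rule.

# van der Waals radii (A) by element; default carbon-like
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Reference maximal accessible surface areas
#'
#' Theoretical per-residue maximum ASA (A^2) in a Gly-X-Gly tripeptide,
#' from Tien et al. (2013) PLoS ONE 8:e80635, used as the denominator of
#' relative accessibility.
#'
#' @return named numeric vector over the 20 one-letter codes.
#' @export
maxAsaReference <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}

# deterministic Fibonacci lattice of n points on the unit sphere
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling on every heavy atom with a solvent probe. The
#' point lattice is a deterministic Fibonacci spiral, so results are exact
#' functions of (structure, probeRadius, nPoints). When the model has no
#' heavy atoms (coarse-grained structures) the C-alpha/C-beta
#' representation is used with carbon radii.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param probeRadius solvent probe radius in A (default 1.4).
#' @param nPoints sphere points per atom (default 960).
#' @return data.frame (chain, position, asa) with ASA in A^2.
#' @export
computeAsa <- function(struct, probeRadius = 1.4, nPoints = 960L) {
  a <- struct@atoms
  r <- struct@residues
  if (nrow(a)) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    radii <- .VDW_RADII[toupper(a$element)]
    radii[is.na(radii)] <- 1.70
    resOf <- match(residueKey(a$chain, a$position),
                   residueKey(r$chain, r$position))
  } else {
    # coarse-grained fallback: CA and CB pseudo-atoms
    ca <- as.matrix(r[, c("ca.x", "ca.y", "ca.z")])
    cb <- as.matrix(r[, c("cb.x", "cb.y", "cb.z")])
    hasCb <- is.finite(cb[, 1])
    xyz <- rbind(ca, cb[hasCb, , drop = FALSE])
    radii <- rep(1.70, nrow(xyz))
    resOf <- c(seq_len(nrow(r)), which(hasCb))
  }
  bad <- !is.finite(xyz[, 1])
  if (any(bad)) {
    warnf("%d atoms with missing coordinates skipped in ASA", sum(bad))
    xyz <- xyz[!bad, , drop = FALSE]
    radii <- radii[!bad]
    resOf <- resOf[!bad]
  }
  pts <- .spherePoints(as.integer(nPoints))
  n <- nrow(xyz)
  ext <- radii + probeRadius
  atomAsa <- numeric(n)
  maxReach <- max(ext)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ext[i] + maxReach)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < ext[i] + ext[nb]]
    p <- pts * ext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
              (p[, 3] - xyz[j, 3])^2
        free <- free & dj > ext[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    atomAsa[i] <- 4 * pi * ext[i]^2 * frac
  }
  asa <- vapply(seq_len(nrow(r)),
                function(k) sum(atomAsa[resOf == k]), numeric(1))
  data.frame(chain = r$chain, position = r$position, asa = asa,
             stringsAsFactors = FALSE)
}

#' Relative accessible surface area and exposure classes
#'
#' RASA = ASA / reference maximum for the residue type. Classes follow the
#' three-class rule: buried (RASA < 5 percent), semi-exposed (5 to 30
#' percent, both boundaries included), exposed (> 30 percent). Boundary
#' conventions are configurable.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param asa optional precomputed result of \code{\link{computeAsa}}.
#' @param reference named per-type maximal ASA table
#'   (default \code{\link{maxAsaReference}}).
#' @param buriedMax,exposedMin class thresholds as fractions
#'   (defaults 0.05 and 0.30).
#' @param ... passed to \code{\link{computeAsa}} when asa is NULL.
#' @return data.frame (chain, position, asa, rasa, exposure_class).
#' @export
computeRasa <- function(struct, asa = NULL, reference = maxAsaReference(),
                        buriedMax = 0.05, exposedMin = 0.30, ...) {
  if (is.null(asa)) asa <- computeAsa(struct, ...)
  r <- struct@residues
  ref <- reference[r$aa]
  rasa <- asa$asa / unname(ref)
  cls <- rep(NA_character_, length(rasa))
  ok <- !is.na(rasa)
  cls[ok & rasa < buriedMax] <- "buried"
  cls[ok & rasa >= buriedMax & rasa <= exposedMin] <- "semi-exposed"
  cls[ok & rasa > exposedMin] <- "exposed"
  data.frame(chain = r$chain, position = r$position, asa = asa$asa,
             rasa = rasa, exposure_class = cls, stringsAsFactors = FALSE)
}
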