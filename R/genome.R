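#' Sample founder allele frequencies
#'
#' Initial frequencies of the alternative allele at each locus are drawn from
#' the U-shaped Beta(0.5, 0.5) distribution, reflecting the excess of extreme
#' frequencies expected under mutation-drift equilibrium. Frequencies are
#' clipped away from exact fixation so every locus is polymorphic at
#' initialization.
#'
#' @param n_loci Number of loci.
#' @param clip Half-width kept away from 0 and 1, default 1e-6.
#' @return Numeric vector of length `n_loci` with values in (0, 1).
#' @examples
#' set.seed(1)
#' p <- sample_founder_frequencies(1000)
#' mean(p)  # close to 0.5
#' @export
sample_founder_frequencies <- function(n_loci, clip = 1e-6) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("'n_loci' must be a positive integer")
  p <- stats::rbeta(n_loci, 0.5, 0.5)
  pmin(pmax(p, clip), 1 - clip)
}

## bivariate symmetric Laplace: sqrt(Exp(1)) * N(0, I2)
.rlaplace2 <- function(n) {
  w <- sqrt(stats::rexp(n))
  cbind(w * stats::rnorm(n), w * stats::rnorm(n))
}

## symmetric matrix square root / inverse square root via eigen;
## tolerates positive semi-definite input (zero targets allowed)
.sym_sqrt <- function(S, inverse = FALSE, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  v <- e$values
  if (any(v < -tol * max(abs(v), 1)))
    stop("matrix is not positive semi-definite")
  v <- pmax(v, 0)
  d <- if (inverse) ifelse(v > tol * max(v, 1), 1 / sqrt(v), 0) else sqrt(v)
  e$vectors %*% (d * t(e$vectors))
}

#' Sample and calibrate allele effects
#'
#' Draws raw bivariate (maternal, direct) allele substitution effects from a
#' weighted mixture of a bivariate Laplace and a bivariate normal distribution
#' (heavy-tailed, L-shaped effect sizes), then applies an exact linear
#' transformation so that the base-population genic (co)variances
#' \deqn{\sigma^2_x = \sum_i 2 p_i (1-p_i)\, \alpha_{x,i}^2, \qquad
#'       \sigma_{md} = \sum_i 2 p_i (1-p_i)\, \alpha_{m,i}\alpha_{d,i}}
#' hit the targets in `params` exactly. The calibration makes the realized
#' base variances invariant to the mixture's shape parameters.
#'
#' @param params A [trait_params()] object with the target variances.
#' @param frequencies Founder allele frequencies
#'   (from [sample_founder_frequencies()]).
#' @param laplace_weight Mixture weight of the Laplace component in (0, 1),
#'   default 0.5; the remainder is bivariate normal. Unit-scale components.
#' @return An object of class `allele_effects`: list with `alpha` (n_loci x 2
#'   matrix, columns `m` and `d`), `p` (founder frequencies) and `transform`
#'   (the 2x2 calibration matrix applied to the raw draws).
#' @examples
#' set.seed(1)
#' pars <- trait_params(n_loci = 200)
#' eff <- sample_allele_effects(pars, sample_founder_frequencies(200))
#' genic_covariance(eff)        # equals trait_covariance(pars)
#' @export
sample_allele_effects <- function(params, frequencies, laplace_weight = 0.5) {
  stopifnot(inherits(params, "trait_params"),
            length(frequencies) == params$n_loci,
            all(frequencies > 0), all(frequencies < 1),
            laplace_weight >= 0, laplace_weight <= 1)
  n <- params$n_loci
  from_laplace <- stats::runif(n) < laplace_weight
  raw <- matrix(stats::rnorm(2L * n), n, 2L)
  if (any(from_laplace)) raw[from_laplace, ] <- .rlaplace2(sum(from_laplace))
  calibrate_allele_effects(raw, frequencies, trait_covariance(params))
}

#' Calibrate raw allele effects to target genic covariances
#'
#' Finds the linear map `M` such that the heterozygosity-weighted covariance
#' of the transformed effects equals `target` exactly, and applies it:
#' with `C = sum_i w_i a_i a_i'` (`w_i = 2 p_i (1 - p_i)`), the map is
#' `M = target^{1/2} C^{-1/2}` (symmetric roots), so
#' `sum_i w_i (M a_i)(M a_i)' = target`.
#'
#' @param raw n_loci x 2 matrix of raw (maternal, direct) effects.
#' @param frequencies Founder allele frequencies.
#' @param target Symmetric 2x2 target genic covariance matrix.
#' @return An `allele_effects` object (see [sample_allele_effects()]).
#' @export
calibrate_allele_effects <- function(raw, frequencies, target) {
  stopifnot(is.matrix(raw), ncol(raw) == 2L,
            nrow(raw) == length(frequencies),
            is.matrix(target), all(dim(target) == 2L))
  w <- 2 * frequencies * (1 - frequencies)
  C <- crossprod(raw * sqrt(w))
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-12 * max(abs(C)))
    stop("calibration failure: raw heterozygosity-weighted effect covariance ",
         "is (near-)singular; frequencies may be degenerate")
  M <- .sym_sqrt(target) %*% .sym_sqrt(C, inverse = TRUE)
  alpha <- raw %*% t(M)
  colnames(alpha) <- c("m", "d")
  structure(list(alpha = alpha, p = as.numeric(frequencies), transform = M),
            class = "allele_effects")
}

#' @export
print.allele_effects <- function(x, ...) {
  gc0 <- genic_covariance(x)
  cat(sprintf("Allele effects over %d loci; base genic variances m=%.4f d=%.4f r=%.4f\n",
              nrow(x$alpha), gc0[1, 1], gc0[2, 2],
              gc0[1, 2] / sqrt(gc0[1, 1] * gc0[2, 2])))
  invisible(x)
}

#' Genic covariance realized by a set of allele effects
#'
#' @param effects An `allele_effects` object.
#' @param p Allele frequencies at which to evaluate; defaults to the founder
#'   frequencies stored in `effects`. Pass current frequencies to track the
#'   depletion of genic variance over a run.
#' @return Symmetric 2x2 genic covariance matrix.
#' @export
genic_covariance <- function(effects, p = effects$p) {
  stopifnot(inherits(effects, "allele_effects"), length(p) == nrow(effects$alpha))
  w <- 2 * p * (1 - p)
  crossprod(effects$alpha * sqrt(w))
}

#' Draw gametes from a queen genome
#'
#' At each (unlinked) locus one of the queen's two alleles is transmitted with
#' probability 1/2, independently across loci and across gametes. A drone is
#' exactly one such gamete.
#'
#' @param h1,h2 The queen's two haplotypes, 0/1 integer vectors of equal
#'   length.
#' @param n Number of gametes to draw, default 1.
#' @return If `n == 1` an integer vector, otherwise an `n_loci x n` integer
#'   matrix with one gamete per column.
#' @examples
#' set.seed(1)
#' g <- make_gametes(c(0L, 1L, 1L), c(1L, 1L, 0L), n = 4)
#' @export
make_gametes <- function(h1, h2, n = 1L) {
  L <- length(h1)
  stopifnot(length(h2) == L, n >= 1L)
  pick <- matrix(stats::runif(L * n) < 0.5, L, n)
  out <- matrix(rep.int(h2, n), L, n)
  sel <- which(pick)
  out[sel] <- rep(h1, n)[sel]
  storage.mode(out) <- "integer"
  if (n == 1L) out[, 1L] else out
}

#' True breeding values from allele dosages
#'
#' Breeding values are sums of allele-substitution effects over loci, centered
#' at the base-population mean: `bv_x = sum_i (dosage_i - 2 p_i) alpha_{x,i}`
#' for `x` in maternal, direct. Dosages may be fractional (expected dosages of
#' a worker group).
#'
#' @param dosage Per-locus allele dosage vector in \[0, 2\], or a matrix with
#'   one individual per column.
#' @param effects An `allele_effects` object.
#' @return Named numeric vector `c(m=, d=)`, or a 2-row matrix for matrix
#'   input.
#' @export
true_breeding_values <- function(dosage, effects) {
  stopifnot(inherits(effects, "allele_effects"))
  if (is.matrix(dosage)) {
    if (nrow(dosage) != nrow(effects$alpha))
      stop("dosage length does not match the number of loci")
    bv <- crossprod(effects$alpha, dosage - 2 * effects$p)
    rownames(bv) <- c("m", "d")
    bv
  } else {
    if (length(dosage) != nrow(effects$alpha))
      stop("dosage length does not match the number of loci")
    d <- as.numeric(dosage) - 2 * effects$p
    c(m = sum(d * effects$alpha[, 1L]), d = sum(d * effects$alpha[, 2L]))
  }
}

#' Worker group of a mated queen
#'
#' The worker group is represented by its expected per-locus allele dosage:
#' half the queen's dosage (the maternal gamete averages her two haplotypes)
#' plus the mean allele of the mate drones (each worker's paternal allele is a
#' drone's single allele). Maternal and direct true breeding values of the
#' group follow via [true_breeding_values()].
#'
#' @param h1,h2 Queen haplotypes (0/1 vectors).
#' @param drones `n_loci x n_mates` 0/1 matrix of the mate drones' alleles,
#'   one drone per column.
#' @param effects An `allele_effects` object.
#' @return List with `dosage` (numeric vector in \[0, 2\]), `bv_m`, `bv_d`.
#' @export
worker_group_of <- function(h1, h2, drones, effects) {
  stopifnot(inherits(effects, "allele_effects"))
  if (!is.matrix(drones) || ncol(drones) < 1L)
    stop("'drones' must be a matrix with at least one mate drone")
  if (nrow(drones) != length(h1) || length(h1) != length(h2))
    stop("haplotype / drone dimensions disagree")
  dos <- (h1 + h2) / 2 + rowMeans(drones)
  bv <- true_breeding_values(dos, effects)
  list(dosage = dos, bv_m = unname(bv["m"]), bv_d = unname(bv["d"]))
}
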