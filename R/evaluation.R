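#' Simulate colony performance-test phenotypes
#'
#' Each colony's observed value is the queen's maternal true breeding value
#' plus the worker group's direct true breeding value, plus the effect of the
#' apiary the colony is tested on, plus residual noise:
#' `y = bv_m(queen) + bv_d(workers) + apiary + e`, `e ~ N(0, sigma2_e)`.
#' Colonies are assigned to apiaries at random; apiary effects are drawn
#' i.i.d. `N(0, sigma2_apiary)` per apiary (and, in the year loop, per year).
#'
#' @param colonies data.frame with columns `id`, `bv_m` (queen maternal true
#'   breeding value) and `bv_d` (worker-group direct true breeding value).
#' @param n_apiaries Number of apiaries.
#' @param sigma2_e Residual variance.
#' @param sigma2_apiary Variance of apiary effects, default 1.
#' @param apiary_effects Optional fixed vector of apiary effects (length
#'   `n_apiaries`) overriding the random draw.
#' @return data.frame with columns `id`, `apiary`, `y` and attribute
#'   `apiary_effects`.
#' @export
simulate_phenotypes <- function(colonies, n_apiaries, sigma2_e,
                                sigma2_apiary = 1, apiary_effects = NULL) {
  stopifnot(is.data.frame(colonies),
            all(c("id", "bv_m", "bv_d") %in% names(colonies)),
            n_apiaries >= 1L, sigma2_e >= 0)
  n <- nrow(colonies)
  if (n == 0L) stop("invalid state: no colonies to phenotype")
  if (is.null(apiary_effects))
    apiary_effects <- stats::rnorm(n_apiaries, 0, sqrt(sigma2_apiary))
  stopifnot(length(apiary_effects) == n_apiaries)
  ap <- sample.int(n_apiaries, n, replace = TRUE)
  y <- colonies$bv_m + colonies$bv_d + apiary_effects[ap] +
    stats::rnorm(n, 0, sqrt(sigma2_e))
  out <- data.frame(id = as.character(colonies$id), apiary = ap, y = y,
                    stringsAsFactors = FALSE)
  attr(out, "apiary_effects") <- apiary_effects
  out
}

.ebv_design <- function(records, A, fixed_effects) {
  ids <- as.character(records$id)
  ents <- rownames(A)
  qi <- match(ids, ents)
  wi <- match(paste0("W:", ids), ents)
  if (anyNA(qi) || anyNA(wi))
    stop("relationship matrix must contain every record queen and its ",
         "worker group ('W:<id>')")
  X <- if (fixed_effects) stats::model.matrix(~ 0 + factor(records$apiary))
       else matrix(0, nrow(records), 0L)
  list(qi = qi, wi = wi, X = X)
}

#' Best linear unbiased prediction of maternal and direct breeding values
#'
#' Bivariate animal-model BLUP for the honeybee two-effect model: the
#' phenotype of a colony carries its queen's maternal effect and its worker
#' group's direct effect, apiaries are fixed effects, and the random effects
#' of all pedigree entities have covariance `G0 (x) A`, where `A` is the
#' accessible relationship matrix (including worker-group entities) and `G0`
#' the 2x2 genetic covariance. Residuals are i.i.d. with variance `sigma2_e`.
#'
#' Two algebraically identical solvers are provided: `"mme"` assembles and
#' solves Henderson's mixed-model equations (requires inverting `A`), while
#' `"gls"` works in the observation space (one linear system of the size of
#' the record count) and is preferred when there are many more entities than
#' records, as in the year loop's evaluation window.
#'
#' @param records data.frame with columns `id` (queen), `apiary`, `y`.
#' @param A Relationship matrix (numerator scale, `a = 2f`) whose dimnames
#'   contain every record queen id and its worker group as `"W:<id>"`, e.g.
#'   from `relationship_matrix(accessible_kinship(ped, include_workers =
#'   TRUE))`.
#' @param G0 2x2 genetic covariance matrix (maternal, direct).
#' @param sigma2_e Residual variance.
#' @param targets Entity ids for which breeding values are returned;
#'   default all rows of `A`.
#' @param method `"gls"` (default) or `"mme"`.
#' @param fixed_effects Estimate apiary fixed effects (default `TRUE`); set
#'   `FALSE` when phenotypes are already corrected for known fixed effects.
#' @return data.frame with columns `id`, `ebv_m`, `ebv_d`; the estimated
#'   fixed effects are attached as attribute `fixed`.
#' @export
estimate_breeding_values <- function(records, A, G0, sigma2_e,
                                     targets = rownames(A),
                                     method = c("gls", "mme"),
                                     fixed_effects = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records), all(c("id", "apiary", "y") %in% names(records)),
            is.matrix(A), nrow(A) == ncol(A), !is.null(rownames(A)),
            all(dim(G0) == 2L), sigma2_e > 0)
  if (anyDuplicated(records$id)) stop("one record per colony expected")
  d <- .ebv_design(records, A, fixed_effects)
  ti <- match(as.character(targets), rownames(A))
  if (anyNA(ti)) stop("unknown target entity id(s)")
  n <- nrow(records); E <- nrow(A)
  y <- records$y
  if (method == "mme") {
    X <- d$X
    Zm <- matrix(0, n, E); Zm[cbind(seq_len(n), d$qi)] <- 1
    Zd <- matrix(0, n, E); Zd[cbind(seq_len(n), d$wi)] <- 1
    Z <- cbind(Zm, Zd)
    Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
      stop("numerical error: relationship matrix not positive definite: ",
           conditionMessage(e)))
    Ginv <- kronecker(solve(G0), Ainv)
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + sigma2_e * Ginv))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    sol <- tryCatch(solve(C, rhs), error = function(e)
      stop("numerical error: singular mixed-model equations: ",
           conditionMessage(e)))
    p <- ncol(X)
    fixed <- sol[seq_len(p)]
    um <- sol[p + seq_len(E)]
    ud <- sol[p + E + seq_len(E)]
    out <- data.frame(id = rownames(A)[ti], ebv_m = um[ti], ebv_d = ud[ti],
                      stringsAsFactors = FALSE)
  } else {
    g <- G0
    Aqq <- A[d$qi, d$qi, drop = FALSE]
    Aqw <- A[d$qi, d$wi, drop = FALSE]
    Aww <- A[d$wi, d$wi, drop = FALSE]
    V <- g[1, 1] * Aqq + g[1, 2] * (Aqw + t(Aqw)) + g[2, 2] * Aww
    diag(V) <- diag(V) + sigma2_e
    ch <- tryCatch(chol(V), error = function(e)
      stop("numerical error: phenotype covariance not positive definite: ",
           conditionMessage(e)))
    X <- d$X
    if (ncol(X) > 0L) {
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      fixed <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
      r <- y - X %*% fixed
    } else {
      fixed <- numeric(0)
      r <- y
    }
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    Atq <- A[ti, d$qi, drop = FALSE]
    Atw <- A[ti, d$wi, drop = FALSE]
    um <- (g[1, 1] * Atq + g[1, 2] * Atw) %*% Vi_r
    ud <- (g[2, 1] * Atq + g[2, 2] * Atw) %*% Vi_r
    out <- data.frame(id = rownames(A)[ti], ebv_m = as.numeric(um),
                      ebv_d = as.numeric(ud), stringsAsFactors = FALSE)
    fixed <- as.numeric(fixed)
  }
  names(fixed) <- colnames(d$X)
  attr(out, "fixed") <- fixed
  out
}

#' Re-estimate the genetic covariance from a cohort
#'
#' The genetic covariance used by BLUP drifts away from the base-population
#' values as selection and drift deplete variation. Every few years the year
#' loop replaces it by the empirical covariance of the newest cohort's true
#' (maternal, direct) breeding values. Eigenvalues are floored to keep the
#' matrix usable in the mixed-model equations even in depleted populations.
#'
#' @param bv Numeric matrix with one row per queen and columns (maternal,
#'   direct) true breeding values; at least 2 rows.
#' @param floor Minimum eigenvalue, default 1e-8.
#' @return 2x2 covariance matrix; attribute `degenerate` is `TRUE` when the
#'   floor was applied.
#' @export
reassess_variances <- function(bv, floor = 1e-8) {
  if (!is.matrix(bv) || ncol(bv) != 2L || nrow(bv) < 2L)
    stop("'bv' must be a matrix of (maternal, direct) breeding values ",
         "with at least 2 rows")
  G <- stats::cov(bv)
  e <- eigen(G, symmetric = TRUE)
  degenerate <- any(e$values < floor)
  if (degenerate)
    G <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
  dimnames(G) <- list(c("m", "d"), c("m", "d"))
  attr(G, "degenerate") <- degenerate
  G
}
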