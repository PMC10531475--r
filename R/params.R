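#' Genetic trait parameters
#'
#' Defines the quantitative-genetic parameters of the (single) selection trait.
#' Colony phenotypes are the sum of a maternal (queen) and a direct (worker
#' group) genetic component plus residual noise. The base population is
#' calibrated so that its genic variances and the maternal-direct correlation
#' equal these targets exactly (see [sample_allele_effects()]).
#'
#' @param sigma2_m Maternal additive genetic variance in the base population
#'   (trait units squared). Default 1.
#' @param sigma2_d Direct additive genetic variance. Default 2.
#' @param r_md Correlation between maternal and direct allele effects, weighted
#'   by base heterozygosity. Typically negative for honeybee traits;
#'   defaults to -0.18 (the low-correlation parameter set; -0.53 is the
#'   medium-correlation set).
#' @param sigma2_e Residual (environmental) variance of the colony phenotype.
#'   Default 4.
#' @param n_loci Number of unlinked biallelic loci underlying the trait.
#'   Default 400.
#' @return An object of class `trait_params`.
#' @examples
#' trait_params()
#' trait_params(r_md = -0.53)
#' @export
trait_params <- function(sigma2_m = 1, sigma2_d = 2, r_md = -0.18,
                         sigma2_e = 4, n_loci = 400L) {
  stopifnot(is.numeric(sigma2_m), length(sigma2_m) == 1L, sigma2_m >= 0,
            is.numeric(sigma2_d), length(sigma2_d) == 1L, sigma2_d >= 0,
            is.numeric(r_md), length(r_md) == 1L, r_md > -1, r_md < 1,
            is.numeric(sigma2_e), length(sigma2_e) == 1L, sigma2_e >= 0)
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("'n_loci' must be a positive integer")
  structure(list(sigma2_m = sigma2_m, sigma2_d = sigma2_d, r_md = r_md,
                 sigma2_e = sigma2_e, n_loci = n_loci),
            class = "trait_params")
}

#' @export
print.trait_params <- function(x, ...) {
  cat("Trait parameters (base population):\n")
  cat(sprintf("  maternal variance  %.3f\n", x$sigma2_m))
  cat(sprintf("  direct variance    %.3f\n", x$sigma2_d))
  cat(sprintf("  correlation r_md   %.3f\n", x$r_md))
  cat(sprintf("  residual variance  %.3f\n", x$sigma2_e))
  cat(sprintf("  loci               %d\n", x$n_loci))
  invisible(x)
}

#' Genetic covariance matrix implied by trait parameters
#'
#' @param params A [trait_params()] object.
#' @return Symmetric 2x2 matrix with maternal and direct variances on the
#'   diagonal and covariance `r_md * sqrt(sigma2_m * sigma2_d)` off it.
#' @export
trait_covariance <- function(params) {
  stopifnot(inherits(params, "trait_params"))
  cv <- params$r_md * sqrt(params$sigma2_m * params$sigma2_d)
  matrix(c(params$sigma2_m, cv, cv, params$sigma2_d), 2L, 2L,
         dimnames = list(c("m", "d"), c("m", "d")))
}

#' Mating-control strategy configuration
#'
#' Configures one of the four mating-control strategies: `"IMS"` (isolated
#' mating stations stocked with a sister group of drone-producing queens,
#' DPQ), or instrumental insemination stations with drones from a single
#' colony at a two-year (`"IIS2"`), three-year (`"IIS3"`) or mixed
#' (`"IISmix"`) paternal generation interval.
#'
#' @param strategy One of `"IMS"`, `"IIS2"`, `"IIS3"`, `"IISmix"`.
#' @param n_stations Number of fertilization stations operated per year
#'   (`N_FertS`). The study grid uses 5, 20 or 50.
#' @param n_dpq Drone producers per station (`N_DPQ`), default 8.
#' @param n_mates Number of drones mated/inseminated per queen, default 12.
#' @param dam_fraction Fraction of two-year-old queens selected as dams,
#'   default 0.20.
#' @param daughters_per_dam Daughter queens raised per selected dam, default 5.
#'   `dam_fraction * daughters_per_dam` must equal 1 so the yearly number of
#'   breeding queens stays constant.
#' @return An object of class `strategy_config`.
#' @examples
#' strategy_config("IIS2", n_stations = 5)
#' @export
strategy_config <- function(strategy = c("IMS", "IIS2", "IIS3", "IISmix"),
                            n_stations = 5L, n_dpq = 8L, n_mates = 12L,
                            dam_fraction = 0.2, daughters_per_dam = 5L) {
  strategy <- match.arg(strategy)
  n_stations <- as.integer(n_stations)
  n_dpq <- as.integer(n_dpq)
  n_mates <- as.integer(n_mates)
  daughters_per_dam <- as.integer(daughters_per_dam)
  stopifnot(n_stations >= 1L, n_dpq >= 1L, n_mates >= 1L,
            daughters_per_dam >= 1L, dam_fraction > 0, dam_fraction <= 1)
  if (abs(dam_fraction * daughters_per_dam - 1) > 1e-8)
    stop("dam_fraction * daughters_per_dam must equal 1 ",
         "(constant population size)")
  structure(list(strategy = strategy, n_stations = n_stations, n_dpq = n_dpq,
                 n_mates = n_mates, dam_fraction = dam_fraction,
                 daughters_per_dam = daughters_per_dam),
            class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("Mating strategy %s: %d station(s)/year, %d DPQ/station, %d drones/queen\n",
              x$strategy, x$n_stations, x$n_dpq, x$n_mates))
  cat(sprintf("  dams: best %.0f%% of two-year-olds, %d daughters each\n",
              100 * x$dam_fraction, x$daughters_per_dam))
  invisible(x)
}

#' Simulation run configuration
#'
#' Bundles everything a single breeding-program run needs: yearly population
#' size, trait parameters, mating strategy, horizon and bookkeeping options.
#'
#' @param n_queens Breeding queens per year (`N_Q`; DPQ on mating stations are
#'   not counted). The study grid uses 500 or 1000; any positive value works
#'   for scaled runs.
#' @param trait A [trait_params()] object.
#' @param strategy A [strategy_config()] object.
#' @param years Simulated years, default 70. The first two years are the
#'   randomly mated base population.
#' @param n_apiaries Number of apiaries colonies are spread over for the
#'   performance test (one fixed effect per apiary and year). Default scales
#'   as `n_queens / 12.5` (40 apiaries for 500 queens, 80 for 1000).
#' @param sigma2_apiary Variance of the yearly apiary effects, default 1.
#' @param eval_window Number of most recent phenotype years entering each
#'   genetic evaluation, default 4 (covers all selection candidates).
#' @param reassess_every Interval in years at which the genetic covariance
#'   used by BLUP is re-estimated from the newest cohort, default 5.
#' @param finite_mates Logical; use the finite mate count in the worker-group
#'   diagonal of the accessible relationship matrix (default `TRUE`) or the
#'   infinite-mates approximation.
#' @param keep_years Birth-year window kept in the in-memory kinship stores;
#'   default `eval_window + 3`, the oldest birth year any evaluation or
#'   kinship recursion can still reference (a window record queen's mates may
#'   stem from producers three years her senior).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_queens = 100, years = 20,
#'                   strategy = strategy_config("IIS2"))
#' @export
sim_config <- function(n_queens = 500L, trait = trait_params(),
                       strategy = strategy_config(), years = 70L,
                       n_apiaries = NULL, sigma2_apiary = 1,
                       eval_window = 4L, reassess_every = 5L,
                       finite_mates = TRUE, keep_years = NULL) {
  n_queens <- as.integer(n_queens)
  years <- as.integer(years)
  if (is.null(keep_years)) keep_years <- as.integer(eval_window) + 3L
  stopifnot(inherits(trait, "trait_params"), inherits(strategy, "strategy_config"),
            n_queens >= 10L, years >= 3L, sigma2_apiary >= 0,
            eval_window >= 2L, reassess_every >= 1L,
            keep_years >= eval_window + 3L)
  if (is.null(n_apiaries)) n_apiaries <- max(1L, as.integer(round(n_queens / 12.5)))
  n_apiaries <- as.integer(n_apiaries)
  n_dams <- round(n_queens * strategy$dam_fraction)
  if (abs(n_dams * strategy$daughters_per_dam - n_queens) > 0)
    stop("n_queens * dam_fraction must be a whole number of dams reproducing ",
         "to exactly n_queens daughters")
  structure(list(n_queens = n_queens, trait = trait, strategy = strategy,
                 years = years, n_apiaries = n_apiaries,
                 sigma2_apiary = sigma2_apiary,
                 eval_window = as.integer(eval_window),
                 reassess_every = as.integer(reassess_every),
                 finite_mates = isTRUE(finite_mates),
                 keep_years = as.integer(keep_years)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Breeding-program configuration: %d queens/year over %d years\n",
              x$n_queens, x$years))
  print(x$strategy)
  print(x$trait)
  cat(sprintf("  apiaries/year %d, evaluation window %d years, variance reassessment every %d years\n",
              x$n_apiaries, x$eval_window, x$reassess_every))
  invisible(x)
}
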