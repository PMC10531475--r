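#' Generational inbreeding rate
#'
#' Converts the mean inbreeding coefficient reached at the end of a breeding
#' horizon into a per-generation rate:
#' \deqn{\Delta F = 1 - (1 - F_{end})^{GI / (years - 1)}}
#' where `GI` is the average generation interval in years and `years - 1` the
#' number of yearly transitions in the horizon (69 for the standard 70-year
#' programme). Sustainable breeding programmes are conventionally required to
#' stay below 1% per generation.
#'
#' @param F_end Mean inbreeding coefficient at the end of the horizon, in
#'   \[0, 1).
#' @param gi Average generation interval in years (> 0).
#' @param horizon_years Length of the breeding horizon in years, default 70.
#' @param percent Return percent instead of a fraction, default `FALSE`.
#' @return Generational inbreeding rate.
#' @examples
#' delta_F(0.549, 2, percent = TRUE)    # 2.28
#' delta_F(0.046, 2.5, percent = TRUE)  # 0.17
#' @export
delta_F <- function(F_end, gi, horizon_years = 70L, percent = FALSE) {
  stopifnot(is.numeric(F_end), is.numeric(gi), all(gi > 0), horizon_years >= 2L)
  if (any(F_end < 0 | F_end >= 1))
    stop("'F_end' must be in [0, 1)")
  out <- 1 - (1 - F_end)^(gi / (horizon_years - 1))
  if (percent) 100 * out else out
}

#' Paternal identity-by-descent probability of a sire group
#'
#' Probability that two offspring queens sired by a given group of drone
#' producers carry identical-by-descent paternal alleles at a locus. For
#' `mode = "unrelated"` (instrumental insemination with unrelated, non-inbred
#' producers) the probability is `1 / (2 N_s)` with `N_s = n_stations *
#' n_dpq` individual sires. For `mode = "ims_pool"` (sister groups of DPQ on
#' isolated mating stations, average within-station relationship `a_ss`,
#' stations mutually unrelated):
#' \deqn{p_{pat,ibd} = \frac{1 + a_{ss}(N_{DPQ} - 1)}{2\, N_{FertS} N_{DPQ}}}
#'
#' @param n_stations Number of fertilization stations (`N_FertS`).
#' @param n_dpq Drone producers per station (`N_DPQ`).
#' @param a_ss Average pairwise relationship of DPQ on one station (pool mode
#'   only), in \[0, 1\]; default 0.
#' @param mode `"unrelated"` or `"ims_pool"`.
#' @return Probability in (0, 1\].
#' @examples
#' paternal_ibd(1, 1, mode = "unrelated")           # single sire: 0.5
#' paternal_ibd(1, 8, a_ss = 0.4, mode = "ims_pool") # 0.2375
#' @export
paternal_ibd <- function(n_stations, n_dpq, a_ss = 0,
                         mode = c("unrelated", "ims_pool")) {
  mode <- match.arg(mode)
  stopifnot(n_stations >= 1, n_dpq >= 1, a_ss >= 0, a_ss <= 1)
  if (mode == "unrelated") {
    1 / (2 * n_stations * n_dpq)
  } else {
    (1 + a_ss * (n_dpq - 1)) / (2 * n_stations * n_dpq)
  }
}

#' Effective number of sires
#'
#' The effective number of sires of a drone-producer group is defined through
#' the paternal identity-by-descent probability of its offspring,
#' `N_s,eff = 1 / (2 p_pat,ibd)`. For unrelated non-inbred producers it
#' coincides with the total producer count; for sister groups of DPQ on
#' isolated mating stations it is reduced by the within-station relationship:
#' `N_s,eff = N_FertS * N_DPQ / (1 + a_ss (N_DPQ - 1))`.
#'
#' @inheritParams paternal_ibd
#' @return Effective number of sires.
#' @examples
#' effective_sires(5, 8)                             # 40 unrelated producers
#' effective_sires(5, 8, a_ss = 0.4, mode = "ims_pool")  # about 10.5
#' @export
effective_sires <- function(n_stations, n_dpq, a_ss = 0,
                            mode = c("unrelated", "ims_pool")) {
  1 / (2 * paternal_ibd(n_stations, n_dpq, a_ss, mode))
}

#' Wright's effective population size
#'
#' `N_e = 4 N_d N_s / (N_d + N_s)` for `N_d` dams and `N_s` (effective)
#' sires per generation.
#'
#' @param n_dams,n_sires Generational numbers of selected dams and sires
#'   (sires may be an effective number).
#' @return Effective population size.
#' @export
wright_ne <- function(n_dams, n_sires) {
  stopifnot(n_dams > 0, n_sires > 0)
  4 * n_dams * n_sires / (n_dams + n_sires)
}

#' Generation-interval summary of a breeding year
#'
#' The maternal generation interval of the simulated programmes is fixed at
#' two years (dams reproduce at age 2); the paternal interval is the mean age
#' of the selected drone producers. The overall interval is the average of
#' the two paths. Optionally computes Wright's effective population size from
#' the dam count and an effective sire count.
#'
#' @param producer_ages Ages (years) of the selected drone producers.
#' @param maternal_gi Maternal generation interval, default 2.
#' @param n_dams,n_sires_eff Optional counts for Wright's formula.
#' @return List with `paternal_gi`, `mean_gi` and (if counts given) `ne`.
#' @examples
#' generation_metrics(rep(3, 5))  # IMS: paternal 3, mean 2.5
#' @export
generation_metrics <- function(producer_ages, maternal_gi = 2,
                               n_dams = NULL, n_sires_eff = NULL) {
  if (length(producer_ages) == 0L || anyNA(producer_ages))
    stop("'producer_ages' must be a non-empty numeric vector")
  pat <- mean(producer_ages)
  out <- list(paternal_gi = pat, mean_gi = (maternal_gi + pat) / 2)
  if (!is.null(n_dams) && !is.null(n_sires_eff))
    out$ne <- wright_ne(n_dams, n_sires_eff)
  out
}

#' Welch's t-test between two replicate samples
#'
#' Compares replicate-level means of a simulation metric (e.g. final genetic
#' gain under two mating strategies) with the unequal-variance t-test.
#' Degenerate inputs where both samples are constant are handled by
#' convention: p = 1 for equal means, p = 0 otherwise.
#'
#' @param a,b Numeric vectors of replicate values (length >= 2 each).
#' @param alternative Passed to [stats::t.test()], default two-sided.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' welch_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_compare <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
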