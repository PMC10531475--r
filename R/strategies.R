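#' Truncation selection of dams
#'
#' Selects the best fraction of two-year-old queens by their worker-group
#' selection criterion (the sum of the worker group's estimated maternal and
#' direct breeding values, i.e. the expected genetic quality of a daughter
#' queen) to each produce a fixed number of daughter queens. Ties are broken
#' deterministically by entity id (ascending).
#'
#' @param candidates data.frame with columns `id` and `criterion`.
#' @param dam_fraction Fraction selected, default 0.2.
#' @param daughters_per_dam Daughters per selected dam, default 5.
#' @return data.frame of the selected dams (columns `id`, `criterion`,
#'   `n_daughters`), best first.
#' @examples
#' cand <- data.frame(id = 1:10, criterion = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
#' select_dams(cand, 0.2, 5)
#' @export
select_dams <- function(candidates, dam_fraction = 0.2, daughters_per_dam = 5L) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "criterion") %in% names(candidates)),
            dam_fraction > 0, dam_fraction <= 1)
  n_dams <- as.integer(round(nrow(candidates) * dam_fraction))
  if (n_dams < 1L)
    stop("invalid state: fewer candidates than required dams")
  ord <- order(-candidates$criterion, candidates$id)
  out <- candidates[ord[seq_len(n_dams)], c("id", "criterion"), drop = FALSE]
  out$n_daughters <- as.integer(daughters_per_dam)
  rownames(out) <- NULL
  out
}

#' Selection of drone producers and station assembly
#'
#' Implements the paternal selection path of each strategy. For `"IMS"` the
#' best `n_stations` three-year-old queens (by the worker-group criterion)
#' are selected; each founds one mating station stocked with a sister group
#' of `n_dpq` drone-producing queens. For the instrumental insemination
#' strategies the best `8 * n_stations` queens of the eligible age cohort(s)
#' are selected by their own queen criterion (maternal plus direct estimated
#' breeding value of the queen: drone quality is determined by the producer
#' queen alone) and partitioned randomly into stations of `n_dpq`. Eligible
#' ages: `"IIS2"` two-year-olds, `"IIS3"` three-year-olds, `"IISmix"` both.
#'
#' @param candidates data.frame with columns `id`, `age` and `criterion`
#'   (already the criterion appropriate to the strategy).
#' @param strategy A [strategy_config()] object.
#' @return data.frame of the selected producers with columns `id`, `age`,
#'   `criterion` and `station` (station index within the year).
#' @export
select_drone_producers <- function(candidates, strategy) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "age", "criterion") %in% names(candidates)),
            inherits(strategy, "strategy_config"))
  if (strategy$strategy == "IMS") {
    eligible <- candidates[candidates$age == 3L, , drop = FALSE]
    need <- strategy$n_stations
    if (nrow(eligible) < need)
      stop("invalid state: fewer three-year-old queens than mating stations")
    ord <- order(-eligible$criterion, eligible$id)
    out <- eligible[ord[seq_len(need)], c("id", "age", "criterion"), drop = FALSE]
    out$station <- seq_len(need)
  } else {
    ages <- switch(strategy$strategy, IIS2 = 2L, IIS3 = 3L, IISmix = c(2L, 3L))
    eligible <- candidates[candidates$age %in% ages, , drop = FALSE]
    need <- strategy$n_stations * strategy$n_dpq
    if (nrow(eligible) < need)
      stop("invalid state: eligible cohort smaller than the required ",
           need, " drone producers")
    ord <- order(-eligible$criterion, eligible$id)
    out <- eligible[ord[seq_len(need)], c("id", "age", "criterion"), drop = FALSE]
    out$station <- sample(rep_len(seq_len(strategy$n_stations), need))
  }
  rownames(out) <- NULL
  out
}

## Admissible producers on an IIS for one virgin queen: drones must not come
## from the queen's own dam or from an aunt (a queen sharing the accessible
## dam with the queen's dam).
.admissible_producers <- function(producers, producer_dams, queen_dam,
                                  queen_granddam) {
  ok <- is.na(queen_dam) | producers != queen_dam
  if (!is.na(queen_granddam))
    ok <- ok & (is.na(producer_dams) | producer_dams != queen_granddam)
  producers[ok]
}
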