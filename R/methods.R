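#' @export
print.bee_sim <- function(x, ...) {
  yr <- x$yearly
  cat(sprintf("Honeybee breeding simulation: strategy %s, %d queens/year, %d years (seed %d)\n",
              x$config$strategy$strategy, x$config$n_queens,
              x$config$years, x$seed))
  cat(sprintf("  final mean performance criterion %.3f (gain %.3f)\n",
              yr$mean_criterion[nrow(yr)],
              yr$mean_criterion[nrow(yr)] - yr$mean_criterion[1L]))
  cat(sprintf("  final mean inbreeding coefficient %.4f\n", yr$mean_F[nrow(yr)]))
  invisible(x)
}

#' @export
summary.bee_sim <- function(object, ...) {
  yr <- object$yearly
  pg <- yr$pat_gi[!is.na(yr$pat_gi)]
  pat <- if (length(pg)) mean(pg) else NA_real_
  gi <- (2 + pat) / 2
  out <- list(
    strategy = object$config$strategy$strategy,
    years = object$config$years,
    n_queens = object$config$n_queens,
    gain = yr$mean_criterion[nrow(yr)] - yr$mean_criterion[1L],
    F_end = yr$mean_F[nrow(yr)],
    pat_gi = pat,
    mean_gi = gi,
    dF = delta_F(yr$mean_F[nrow(yr)], gi, object$config$years),
    gv_depletion = yr$gv_d[nrow(yr)] / yr$gv_d[1L])
  class(out) <- "summary.bee_sim"
  out
}

#' @export
print.summary.bee_sim <- function(x, ...) {
  cat(sprintf("Strategy %s, %d queens/year, %d years\n",
              x$strategy, x$n_queens, x$years))
  cat(sprintf("  genetic gain             %8.3f trait units\n", x$gain))
  cat(sprintf("  final inbreeding         %8.4f\n", x$F_end))
  cat(sprintf("  paternal GI              %8.3f years (mean GI %.3f)\n",
              x$pat_gi, x$mean_gi))
  cat(sprintf("  inbreeding rate          %8.2f %% per generation\n",
              100 * x$dF))
  cat(sprintf("  direct genic variance kept %6.1f %%\n", 100 * x$gv_depletion))
  invisible(x)
}

#' @export
as.data.frame.bee_sim <- function(x, ...) x$yearly

#' @export
plot.bee_sim <- function(x, which = c("gain", "inbreeding"), ...) {
  which <- match.arg(which)
  yr <- x$yearly
  if (which == "gain") {
    graphics::plot(yr$year, yr$mean_criterion, type = "l",
                   xlab = "year", ylab = "mean performance criterion", ...)
  } else {
    graphics::plot(yr$year, yr$mean_F, type = "l",
                   xlab = "year", ylab = "mean inbreeding coefficient", ...)
  }
  invisible(x)
}

#' @export
print.bee_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Ensemble of %d replicates: strategy %s, %d queens/year, %d years\n",
              length(x$replicates), x$config$strategy$strategy,
              x$config$n_queens, x$config$years))
  n <- nrow(s)
  cat(sprintf("  final criterion %.3f +/- %.3f, final inbreeding %.4f +/- %.4f\n",
              s$mean_criterion_mean[n], s$mean_criterion_sd[n],
              s$mean_F_mean[n], s$mean_F_sd[n]))
  invisible(x)
}

#' @export
summary.bee_ensemble <- function(object, ...) {
  fm <- final_metrics(object)
  out <- list(config = object$config, n = nrow(fm),
              gain = mean(fm$gain), gain_sd = stats::sd(fm$gain),
              F_end = mean(fm$F_end), F_end_sd = stats::sd(fm$F_end),
              pat_gi = mean(fm$pat_gi, na.rm = TRUE),
              dF = mean(fm$dF))
  class(out) <- "summary.bee_ensemble"
  out
}

#' @export
print.summary.bee_ensemble <- function(x, ...) {
  cat(sprintf("Strategy %s (%d replicates, %d queens/year, %d years):\n",
              x$config$strategy$strategy, x$n, x$config$n_queens,
              x$config$years))
  cat(sprintf("  genetic gain      %8.3f +/- %.3f trait units\n", x$gain, x$gain_sd))
  cat(sprintf("  final inbreeding  %8.4f +/- %.4f\n", x$F_end, x$F_end_sd))
  cat(sprintf("  paternal GI       %8.3f years\n", x$pat_gi))
  cat(sprintf("  inbreeding rate   %8.2f %% per generation\n", 100 * x$dF))
  invisible(x)
}

#' @export
as.data.frame.bee_ensemble <- function(x, ...) x$summary

#' @export
plot.bee_ensemble <- function(x, which = c("gain", "inbreeding", "gi"), ...) {
  which <- match.arg(which)
  s <- x$summary
  col <- switch(which, gain = "mean_criterion", inbreeding = "mean_F",
                gi = "pat_gi")
  m <- s[[paste0(col, "_mean")]]
  sd <- s[[paste0(col, "_sd")]]
  ylab <- switch(which, gain = "mean performance criterion",
                 inbreeding = "mean inbreeding coefficient",
                 gi = "paternal generation interval")
  graphics::plot(s$year, m, type = "l", xlab = "year", ylab = ylab, ...)
  ok <- !is.na(sd)
  graphics::lines(s$year[ok], (m + sd)[ok], lty = 3)
  graphics::lines(s$year[ok], (m - sd)[ok], lty = 3)
  invisible(x)
}

#' Export a simulation's recorded pedigree
#'
#' Converts the per-queen table of a [run_simulation()] result into the
#' generic pedigree format consumed by [true_kinship()],
#' [accessible_kinship()] and [gene_drop_kinship()]. The true variant
#' materializes the individual father drones (ids `"D:<mated queen>:<slot>"`,
#' one per used sperm slot); the accessible variant records pool entities
#' (full-sister shortcut) and producer-queen sires, plus each queen's own
#' mating in the `mated` column.
#'
#' @param sim A `bee_sim` object (run with `keep_pedigree = TRUE`).
#' @param type `"true"` or `"accessible"`.
#' @return A pedigree data.frame (see [pedigree_table()]).
#' @export
as_pedigree <- function(sim, type = c("true", "accessible")) {
  stopifnot(inherits(sim, "bee_sim"))
  type <- match.arg(type)
  ped <- sim$pedigree
  if (is.null(ped)) stop("simulation was run with keep_pedigree = FALSE")
  if (type == "true") {
    qid <- as.character(ped$id)
    has_f <- !is.na(ped$fdam)
    dkey <- ifelse(has_f, paste0("D:", ped$dam, ":", ped$fslot), NA_character_)
    drones <- data.frame(id = dkey[has_f],
                         dam = as.character(ped$fdam[has_f]),
                         ord = ped$id[has_f])
    drones <- drones[!duplicated(drones$id), ]
    rows <- rbind(
      data.frame(id = qid, kind = "queen", dam = as.character(ped$dam),
                 sire = dkey, ord = ped$id + 0.5),
      data.frame(id = drones$id, kind = "drone", dam = drones$dam,
                 sire = NA_character_, ord = drones$ord))
    rows <- rows[order(rows$ord), c("id", "kind", "dam", "sire")]
    rownames(rows) <- NULL
    pedigree_table(rows$id, rows$kind, rows$dam, rows$sire)
  } else {
    # breeding queens only; DPQ are represented through the pool shortcut
    pq <- ped[ped$kind != "dpq", , drop = FALSE]
    pool_keys <- names(sim$pools)
    pool_rows <- NULL
    if (length(pool_keys)) {
      dam4a <- vapply(sim$pools, function(m)
        as.character(ped$dam[ped$id == m[1L]]), "")
      sire4a <- vapply(sim$pools, function(m)
        ped$mated_acc[ped$id == as.integer(ped$dam[ped$id == m[1L]])], "")
      nmem <- vapply(sim$pools, length, 0L)
      # pools appear after their dam; order by the first member's id
      ord <- vapply(sim$pools, function(m) m[1L], 0L)
      pool_rows <- data.frame(id = pool_keys, kind = "pool", dam = dam4a,
                              sire = sire4a, mated = NA_character_,
                              members = NA_character_, n_members = nmem,
                              ord = ord - 0.25)
    }
    qrows <- data.frame(id = as.character(pq$id), kind = "queen",
                        dam = as.character(pq$dam), sire = pq$sire_acc,
                        mated = pq$mated_acc, members = NA_character_,
                        n_members = NA_integer_, ord = pq$id + 0)
    rows <- rbind(qrows, pool_rows)
    rows <- rows[order(rows$ord), ]
    pedigree_table(rows$id, rows$kind, rows$dam, rows$sire, rows$mated,
                   rows$members, rows$n_members)
  }
}
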