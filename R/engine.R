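## Year-loop engine.
##
## Life cycle (year y):
##   - queens born in year y-1 are performance tested (their worker groups
##     exist because every queen is mated in her birth year);
##   - BLUP on the records of the evaluation window;
##   - dams: best 20% of queens born y-2 by the worker-group criterion;
##   - drone producers of year y are selected and the year's fertilization
##     stations assembled (IMS: DPQ sister groups of the best three-year-
##     olds; IIS: the best 8*N_FertS queens of the eligible cohorts);
##   - the new cohort hatches (5 daughters per dam, fathered by drones the
##     dam stored at her own mating two years earlier) and is mated at the
##     year's stations;
##   - both kinship stores are updated and the yearly record appended.
## Years 1-2 are a randomly mated founder base; IIS2/IISmix stations first
## exist in year 3, IMS/IIS3 in year 4 (first three-year-olds).

.floor_psd <- function(G, floor = 1e-8) {
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

#' Run one breeding-program simulation
#'
#' Simulates a closed honeybee breeding population under the configured
#' mating-control strategy, tracking true breeding values and genomes at the
#' finite-locus level, a true kinship matrix (individual drone fathers
#' known) for realized inbreeding, and an accessible kinship matrix
#' (pedigree-recorded sire entities) that drives the yearly BLUP evaluation
#' and selection.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical results.
#' @param keep_pedigree Keep the full per-queen pedigree table in the result
#'   (default `TRUE`; disable to save memory in large ensembles).
#' @return An object of class `bee_sim`: list with `yearly` (one row per
#'   year: `year`, `mean_criterion`, `mean_F`, `mean_F_acc`, `pat_gi`,
#'   `gv_m`, `gv_d`), `pedigree` (per-queen table), `config`, `seed`,
#'   and `effects` (the calibrated allele effects).
#' @examples
#' cfg <- sim_config(n_queens = 50, years = 10,
#'                   trait = trait_params(n_loci = 100),
#'                   strategy = strategy_config("IIS2", n_stations = 2))
#' sim <- run_simulation(cfg, seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(config, seed = 1L, keep_pedigree = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config
  NQ <- cfg$n_queens
  L <- cfg$trait$n_loci
  strat <- cfg$strategy
  n_mates <- strat$n_mates
  n_dpq <- strat$n_dpq
  keep_from <- function(y) y - (cfg$keep_years - 1L)

  p0 <- sample_founder_frequencies(L)
  eff <- sample_allele_effects(cfg$trait, p0)
  G0 <- trait_covariance(cfg$trait)
  G0_blup <- .floor_psd(G0)

  max_dpq <- if (strat$strategy == "IMS") cfg$years * strat$n_stations * n_dpq else 0L
  maxid <- (cfg$years + 2L) * NQ + max_dpq + 16L

  birth <- integer(maxid)
  is_dpq <- logical(maxid)
  dam <- rep(NA_integer_, maxid)
  fslot <- rep(NA_integer_, maxid)
  fdam <- rep(NA_integer_, maxid)
  sire_acc <- rep(NA_character_, maxid)   # father entity (dam's mating station)
  mated_acc <- rep(NA_character_, maxid)  # entity this queen was mated to
  station_of <- rep(NA_character_, maxid)
  Ftrue <- rep(NA_real_, maxid)
  Facc <- rep(NA_real_, maxid)
  bvm <- rep(NA_real_, maxid)
  wgd <- rep(NA_real_, maxid)
  bvd <- rep(NA_real_, maxid)
  genomes <- vector("list", maxid)
  mates <- vector("list", maxid)
  n_ids <- 0L
  new_ids <- function(n) {
    ids <- n_ids + seq_len(n)
    n_ids <<- n_ids + n
    ids
  }

  ## --- true kinship store (queens + DPQ, individual drone fathers) -------
  Kt <- matrix(0, 0L, 0L)
  kt_ids <- integer(0)
  add_true <- function(ids, founder = FALSE) {
    m <- length(ids)
    n <- length(kt_ids)
    if (founder) {
      Fv <- rep(0, m)
      Cross <- matrix(0, m, n)
      Within <- matrix(0, m, m)
    } else {
      di <- match(dam[ids], kt_ids)
      pi <- match(fdam[ids], kt_ids)
      if (anyNA(di) || anyNA(pi))
        stop("internal error: parent left the true kinship window")
      Cross <- 0.5 * Kt[di, , drop = FALSE] + 0.5 * Kt[pi, , drop = FALSE]
      Fv <- Kt[cbind(di, pi)]
      Within <- 0.25 * (Kt[di, di, drop = FALSE] + Kt[di, pi, drop = FALSE] +
                        Kt[pi, di, drop = FALSE] + Kt[pi, pi, drop = FALSE])
      same_father <- outer(dam[ids], dam[ids], "==") &
        outer(fslot[ids], fslot[ids], "==")
      same_father[is.na(same_father)] <- FALSE
      diag(same_father) <- FALSE
      if (any(same_father)) {
        KPP <- Kt[pi, pi, drop = FALSE]
        Within[same_father] <- Within[same_father] +
          0.25 * (1 - KPP[same_father])
      }
      # entities already in the store may share an individual father drone
      # with the new cohort (same dam, same sperm slot): e.g. a queen's
      # daughters and her later DPQ draw from the same stored mates
      kn <- paste0(dam[ids], ":", fslot[ids])
      ko <- paste0(dam[kt_ids], ":", fslot[kt_ids])
      hits <- which(!is.na(dam[kt_ids]) & !is.na(fslot[kt_ids]) & ko %in% kn)
      for (j in hits) {
        iN <- which(kn == ko[j])
        Cross[iN, j] <- Cross[iN, j] + 0.25 * (1 - Kt[cbind(pi[iN], pi[iN])])
      }
    }
    diag(Within) <- (1 + Fv) / 2
    Kt <<- rbind(cbind(Kt, t(Cross)), cbind(Cross, Within))
    kt_ids <<- c(kt_ids, ids)
    Ftrue[ids] <<- Fv
    invisible(NULL)
  }

  ## --- accessible kinship store (queens + pool entities) -----------------
  Ka <- matrix(0, 0L, 0L)
  ka_keys <- character(0)
  ka_birth <- integer(0)
  ka_pad <- function() {
    n <- length(ka_keys)
    Kp <- matrix(0, n + 1L, n + 1L)  # index n+1 = "unknown" (all-zero row)
    if (n) Kp[seq_len(n), seq_len(n)] <- Ka
    Kp
  }
  ka_idx <- function(keys) {
    i <- match(keys, ka_keys)
    i[is.na(keys)] <- length(ka_keys) + 1L
    if (anyNA(i)) stop("internal error: entity left the accessible window")
    i
  }
  add_acc <- function(keys, damk, sirek, year) {
    m <- length(keys)
    damk <- rep_len(damk, m)
    sirek <- rep_len(sirek, m)
    n <- length(ka_keys)
    Kp <- ka_pad()
    di <- ka_idx(damk)
    si <- ka_idx(sirek)
    Cross <- 0.5 * Kp[di, seq_len(n), drop = FALSE] +
             0.5 * Kp[si, seq_len(n), drop = FALSE]
    Fv <- Kp[cbind(di, si)]
    Fv[is.na(damk) | is.na(sirek)] <- 0
    Within <- 0.25 * (Kp[di, di, drop = FALSE] + Kp[di, si, drop = FALSE] +
                      Kp[si, di, drop = FALSE] + Kp[si, si, drop = FALSE])
    diag(Within) <- (1 + Fv) / 2
    Ka <<- rbind(cbind(Ka, t(Cross)), cbind(Cross, Within))
    ka_keys <<- c(ka_keys, keys)
    ka_birth <<- c(ka_birth, rep(year, m))
    Fv
  }
  add_pool <- function(key, damk, sirek, N, year) {
    n <- length(ka_keys)
    Kp <- ka_pad()
    di <- ka_idx(damk)
    si <- ka_idx(sirek)
    row <- 0.5 * Kp[di, seq_len(n)] + 0.5 * Kp[si, seq_len(n)]
    Fd <- Kp[di, si]
    self_d <- (1 + Fd) / 2
    cross_d <- 0.25 * (Kp[di, di] + 2 * Fd + Kp[si, si])
    s <- self_d / N + (1 - 1 / N) * cross_d
    Ka <<- rbind(cbind(Ka, row), c(row, s))
    ka_keys <<- c(ka_keys, key)
    ka_birth <<- c(ka_birth, year)
    invisible(NULL)
  }
  prune <- function(y) {
    lo <- keep_from(y)
    keep_t <- birth[kt_ids] >= lo
    if (!all(keep_t)) {
      Kt <<- Kt[keep_t, keep_t, drop = FALSE]
      kt_ids <<- kt_ids[keep_t]
    }
    keep_a <- ka_birth >= lo
    if (!all(keep_a)) {
      Ka <<- Ka[keep_a, keep_a, drop = FALSE]
      ka_keys <<- ka_keys[keep_a]
      ka_birth <<- ka_birth[keep_a]
    }
    old <- which(birth[seq_len(n_ids)] < lo - 1L)
    old <- old[!vapply(genomes[old], is.null, TRUE)]
    if (length(old)) {
      genomes[old] <<- list(NULL)
      mates[old] <<- list(NULL)
    }
    invisible(NULL)
  }

  ## --- helpers ------------------------------------------------------------
  drone_from <- function(qid) make_gametes(genomes[[qid]]$h1, genomes[[qid]]$h2)
  random_mating <- function(ids, partner_pool) {
    for (q in ids) {
      dams_q <- sample(partner_pool[partner_pool != q], n_mates, replace = TRUE)
      haps <- vapply(dams_q, drone_from, integer(L))
      mates[[q]] <<- list(dams = dams_q, haps = haps)
      mated_acc[q] <<- NA_character_
    }
  }
  finish_cohort <- function(ids) {
    # worker groups, phenotypic bookkeeping
    for (q in ids) {
      g <- genomes[[q]]
      wg <- worker_group_of(g$h1, g$h2, mates[[q]]$haps, eff)
      wgd[q] <<- wg$bv_d
      bv <- true_breeding_values(g$h1 + g$h2, eff)
      bvm[q] <<- bv[["m"]]
      bvd[q] <<- bv[["d"]]
    }
  }

  pheno <- vector("list", cfg$years)   # records by test year
  cohort <- vector("list", cfg$years)  # queen ids by birth year
  pools <- list()                      # pool id -> member DPQ ids
  n_pools <- 0L
  yearly <- vector("list", cfg$years)
  ebv <- NULL                          # current EBV lookup (named vectors)

  dam_criterion <- function(ids) {
    keys <- paste0("W:", ids)
    unname(ebv$m[keys] + ebv$d[keys])
  }
  queen_criterion <- function(ids) {
    keys <- as.character(ids)
    unname(ebv$m[keys] + ebv$d[keys])
  }

  for (y in seq_len(cfg$years)) {
    ## 1. performance test of queens born y-1
    if (y >= 2L && !is.null(cohort[[y - 1L]])) {
      ids <- cohort[[y - 1L]]
      colonies <- data.frame(id = ids, bv_m = bvm[ids], bv_d = wgd[ids])
      rec <- simulate_phenotypes(colonies, cfg$n_apiaries, cfg$trait$sigma2_e,
                                 cfg$sigma2_apiary)
      rec$apiary <- paste0("y", y, "a", rec$apiary)
      pheno[[y]] <- rec
    }

    ## 2. periodic variance reassessment from the newest tested cohort
    if (y %% cfg$reassess_every == 0L && y >= 2L) {
      ids <- cohort[[y - 1L]]
      G0 <- reassess_variances(cbind(bvm[ids], bvd[ids]))
      G0_blup <- .floor_psd(G0)
    }

    ## 3. BLUP on the evaluation window
    if (y >= 3L) {
      yrs <- seq.int(max(2L, y - cfg$eval_window + 1L), y)
      recs <- do.call(rbind, pheno[yrs])
      rq <- as.integer(recs$id)
      keys <- recs$id
      S <- mated_acc[rq]
      B <- unique(c(keys, S[!is.na(S)]))
      nB <- length(B)
      bi <- match(B, ka_keys)
      if (anyNA(bi)) stop("internal error: evaluation entity missing")
      FBp <- rbind(cbind(Ka[bi, bi, drop = FALSE], 0), 0)
      qix <- match(keys, B)
      six <- match(S, B)
      six[is.na(six)] <- nB + 1L
      Rq <- FBp[qix, seq_len(nB), drop = FALSE]
      Rs <- FBp[six, seq_len(nB), drop = FALSE]
      Wrow <- cbind(0.5 * Rq + 0.5 * Rs, 0)   # padded col = unknown entity
      M1 <- Wrow[, qix, drop = FALSE]
      M2 <- Wrow[, six, drop = FALSE]
      FWW <- 0.5 * (M1 + M2)
      fqq <- FBp[cbind(qix, qix)]
      fqs <- FBp[cbind(qix, six)]
      sdg <- FBp[cbind(six, six)]
      ppat <- if (cfg$finite_mates) 1 / n_mates + (1 - 1 / n_mates) * sdg else sdg
      diag(FWW) <- 0.25 * (fqq + 2 * fqs + ppat)
      Fqq <- FBp[qix, qix, drop = FALSE]
      Afull <- 2 * rbind(cbind(Fqq, t(M1)), cbind(M1, FWW))
      ents <- c(keys, paste0("W:", keys))
      dimnames(Afull) <- list(ents, ents)
      eb <- estimate_breeding_values(recs, Afull, G0_blup,
                                     cfg$trait$sigma2_e, method = "gls")
      ebv <- list(m = stats::setNames(eb$ebv_m, eb$id),
                  d = stats::setNames(eb$ebv_d, eb$id))
    }

    ## 4. dam selection (queens born y-2)
    dams_y <- NULL
    if (y >= 3L) {
      cand <- cohort[[y - 2L]]
      dams_y <- select_dams(data.frame(id = cand, criterion = dam_criterion(cand)),
                            strat$dam_fraction, strat$daughters_per_dam)
    }

    ## 5. station assembly of year y
    stations <- NULL
    pat_gi <- NA_real_
    if (y >= 3L) {
      two <- cohort[[y - 2L]]
      three <- if (y >= 4L) cohort[[y - 3L]] else NULL
      three <- three[!is_dpq[three]]
      active <- switch(strat$strategy,
                       IMS = , IIS3 = y >= 4L,
                       IIS2 = , IISmix = TRUE)
      if (active) {
        if (strat$strategy == "IMS") {
          cand <- data.frame(id = three, age = 3L,
                             criterion = dam_criterion(three))
          sel <- select_drone_producers(cand, strat)
          stations <- vector("list", strat$n_stations)
          for (k in seq_len(nrow(sel))) {
            g4a <- sel$id[k]
            dids <- new_ids(n_dpq)
            slots <- sample.int(n_mates, n_dpq, replace = TRUE)
            h1 <- make_gametes(genomes[[g4a]]$h1, genomes[[g4a]]$h2, n = n_dpq)
            for (j in seq_len(n_dpq)) {
              q <- dids[j]
              birth[q] <- y - 1L
              is_dpq[q] <- TRUE
              dam[q] <- g4a
              fslot[q] <- slots[j]
              fdam[q] <- mates[[g4a]]$dams[slots[j]]
              genomes[[q]] <- list(h1 = h1[, j], h2 = mates[[g4a]]$haps[, slots[j]])
            }
            add_true(dids)
            n_pools <- n_pools + 1L
            pk <- paste0("P", n_pools)
            add_pool(pk, as.character(g4a), mated_acc[g4a], n_dpq, y)
            pools[[pk]] <- dids
            stations[[k]] <- list(type = "IMS", key = pk, members = dids,
                                  ages = 3L)
          }
          pat_gi <- 3
        } else {
          elig2 <- if (strat$strategy %in% c("IIS2", "IISmix")) two else NULL
          elig3 <- if (strat$strategy %in% c("IIS3", "IISmix")) three else NULL
          cand <- rbind(
            if (length(elig2)) data.frame(id = elig2, age = 2L,
                                          criterion = queen_criterion(elig2)),
            if (length(elig3)) data.frame(id = elig3, age = 3L,
                                          criterion = queen_criterion(elig3)))
          sel <- select_drone_producers(cand, strat)
          stations <- lapply(seq_len(strat$n_stations), function(k) {
            rows <- sel[sel$station == k, , drop = FALSE]
            list(type = "IIS", members = rows$id, ages = rows$age)
          })
          pat_gi <- mean(sel$age)
        }
      }
    }

    ## 6. hatch the new cohort
    if (y <= 2L) {
      ids <- new_ids(NQ)
      birth[ids] <- y
      H <- matrix(stats::runif(L * 2L * NQ) < p0, L, 2L * NQ)
      storage.mode(H) <- "integer"
      for (j in seq_len(NQ)) {
        genomes[[ids[j]]] <- list(h1 = H[, 2L * j - 1L], h2 = H[, 2L * j])
      }
      add_true(ids, founder = TRUE)
      Facc[ids] <- add_acc(as.character(ids), NA_character_, NA_character_, y)
      groups <- split(ids, rep(seq_len(NQ %/% strat$daughters_per_dam),
                               each = strat$daughters_per_dam, length.out = NQ))
    } else {
      ids <- integer(0)
      groups <- list()
      for (k in seq_len(nrow(dams_y))) {
        M <- dams_y$id[k]
        nd <- dams_y$n_daughters[k]
        qs <- new_ids(nd)
        slots <- sample.int(n_mates, nd, replace = TRUE)
        h1 <- make_gametes(genomes[[M]]$h1, genomes[[M]]$h2, n = nd)
        for (j in seq_len(nd)) {
          q <- qs[j]
          birth[q] <- y
          dam[q] <- M
          fslot[q] <- slots[j]
          fdam[q] <- mates[[M]]$dams[slots[j]]
          sire_acc[q] <- mated_acc[M]
          genomes[[q]] <- list(h1 = h1[, j], h2 = mates[[M]]$haps[, slots[j]])
        }
        ids <- c(ids, qs)
        groups <- c(groups, list(qs))
      }
      add_true(ids)
      Facc[ids] <- add_acc(as.character(ids), as.character(dam[ids]),
                           sire_acc[ids], y)
    }
    cohort[[y]] <- ids

    ## 7. mate the new cohort
    if (is.null(stations)) {
      partner_pool <- if (y <= 2L) ids else cohort[[y - 2L]]
      random_mating(ids, partner_pool)
    } else {
      st_assign <- integer(length(groups))
      st_assign[sample(length(groups))] <- rep_len(seq_along(stations),
                                                   length(groups))
      for (gi in seq_along(groups)) {
        sidx <- st_assign[gi]
        grp <- groups[[gi]]
        st <- stations[[sidx]]
        if (st$type == "IMS") {
          for (q in grp) {
            dams_q <- st$members[sample.int(n_dpq, n_mates, replace = TRUE)]
            haps <- vapply(dams_q, drone_from, integer(L))
            mates[[q]] <- list(dams = dams_q, haps = haps)
            mated_acc[q] <- st$key
            station_of[q] <- st$key
          }
        } else {
          tries <- 0L
          repeat {
            st <- stations[[sidx]]
            adm <- .admissible_producers(st$members, dam[st$members],
                                         dam[grp[1L]],
                                         if (!is.na(dam[grp[1L]]))
                                           dam[dam[grp[1L]]] else NA_integer_)
            if (length(adm)) break
            sidx <- sidx %% length(stations) + 1L
            tries <- tries + 1L
            if (tries >= length(stations))
              stop("invalid state: no admissible drone producer on any station")
          }
          for (q in grp) {
            P <- if (length(adm) == 1L) adm else sample(adm, 1L)
            haps <- make_gametes(genomes[[P]]$h1, genomes[[P]]$h2, n = n_mates)
            mates[[q]] <- list(dams = rep.int(P, n_mates), haps = haps)
            mated_acc[q] <- as.character(P)
            station_of[q] <- paste0("S", y, ".", sidx)
          }
        }
      }
    }
    finish_cohort(ids)

    ## 8. yearly record
    dos_sum <- numeric(L)
    for (q in ids) dos_sum <- dos_sum + genomes[[q]]$h1 + genomes[[q]]$h2
    pfreq <- dos_sum / (2 * NQ)
    gv <- genic_covariance(eff, pfreq)
    yearly[[y]] <- data.frame(
      year = y,
      mean_criterion = mean(bvm[ids] + wgd[ids]),
      mean_F = mean(Ftrue[ids]),
      mean_F_acc = mean(Facc[ids]),
      pat_gi = pat_gi,
      gv_m = gv[1, 1], gv_d = gv[2, 2])

    prune(y)
  }

  last <- cohort[[cfg$years]]
  dos_sum <- numeric(L)
  for (q in last) dos_sum <- dos_sum + genomes[[q]]$h1 + genomes[[q]]$h2
  yearly <- do.call(rbind, yearly)
  test_year <- rep.int(seq_len(cfg$years), vapply(pheno, NROW, 0L))
  records <- do.call(rbind, pheno)
  if (!is.null(records)) records$year <- test_year
  out <- list(yearly = yearly, config = cfg, seed = as.integer(seed),
              effects = eff, p_final = dos_sum / (2 * NQ),
              records = records)
  if (keep_pedigree) {
    all_ids <- seq_len(n_ids)
    out$pedigree <- data.frame(
      id = all_ids,
      kind = ifelse(is_dpq[all_ids], "dpq",
                    ifelse(is.na(dam[all_ids]), "founder", "queen")),
      birth = birth[all_ids],
      dam = dam[all_ids],
      fslot = fslot[all_ids],
      fdam = fdam[all_ids],
      sire_acc = sire_acc[all_ids],
      mated_acc = mated_acc[all_ids],
      station = station_of[all_ids],
      F_true = Ftrue[all_ids],
      F_acc = Facc[all_ids],
      bv_m = bvm[all_ids],
      bv_d = bvd[all_ids],
      wg_d = wgd[all_ids],
      stringsAsFactors = FALSE)
    out$pools <- pools
  }
  class(out) <- "bee_sim"
  out
}

#' Run replicated simulations
#'
#' Runs `replicates` independent simulations of the same configuration with
#' per-replicate seeds derived from the master seed (`seed + r`), and
#' aggregates yearly means and standard deviations across replicates.
#'
#' @param config A [sim_config()] object.
#' @param replicates Number of replicates, default 200.
#' @param seed Master seed.
#' @return An object of class `bee_ensemble`: list with `summary` (per-year
#'   across-replicate mean and SD of each metric), `replicates` (list of
#'   per-replicate `yearly` tables), `config`, `seed`.
#' @export
run_replicates <- function(config, replicates = 200L, seed = 1L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a positive integer")
  runs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    runs[[r]] <- run_simulation(config, seed = as.integer(seed) + r,
                                keep_pedigree = FALSE)$yearly
  }
  yrs <- runs[[1L]]$year
  metrics <- c("mean_criterion", "mean_F", "mean_F_acc", "pat_gi",
               "gv_m", "gv_d")
  agg <- data.frame(year = yrs)
  for (m in metrics) {
    vals <- vapply(runs, function(df) df[[m]], numeric(length(yrs)))
    vals <- matrix(vals, nrow = length(yrs))
    agg[[paste0(m, "_mean")]] <- rowMeans(vals)
    agg[[paste0(m, "_sd")]] <- if (replicates > 1L) apply(vals, 1L, stats::sd)
                               else NA_real_
  }
  structure(list(summary = agg, replicates = runs, config = config,
                 seed = as.integer(seed)),
            class = "bee_ensemble")
}

#' Final-state metrics of each replicate
#'
#' Extracts, per replicate, the quantities the strategy comparison is based
#' on: genetic gain over the horizon (final minus first-year mean performance
#' criterion), the final mean inbreeding coefficient, the mean paternal
#' generation interval over the years with operating stations, and the
#' generational inbreeding rate implied by the run's own horizon and
#' generation interval.
#'
#' @param ens A `bee_ensemble` from [run_replicates()].
#' @return data.frame with one row per replicate: `gain`, `F_end`, `pat_gi`,
#'   `mean_gi`, `dF` (fraction per generation).
#' @export
final_metrics <- function(ens) {
  stopifnot(inherits(ens, "bee_ensemble"))
  horizon <- ens$config$years
  out <- lapply(seq_along(ens$replicates), function(r) {
    df <- ens$replicates[[r]]
    pg <- df$pat_gi[!is.na(df$pat_gi)]
    pat <- if (length(pg)) mean(pg) else NA_real_
    gi <- (2 + pat) / 2
    data.frame(replicate = r,
               gain = df$mean_criterion[nrow(df)] - df$mean_criterion[1L],
               F_end = df$mean_F[nrow(df)],
               pat_gi = pat, mean_gi = gi,
               dF = delta_F(df$mean_F[nrow(df)], gi, horizon))
  })
  do.call(rbind, out)
}
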