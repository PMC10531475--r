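# Independent oracles and fixture builders used across the suite.

# Naive GLS/BLUP oracle: builds the full joint covariance with explicit
# Kronecker products and dense inversion. Deliberately assembled differently
# from the package solvers.
gls_oracle <- function(records, A, G0, sigma2_e, fixed_effects = TRUE) {
  n <- nrow(records)
  E <- nrow(A)
  ids <- as.character(records$id)
  qi <- match(ids, rownames(A))
  wi <- match(paste0("W:", ids), rownames(A))
  Zm <- matrix(0, n, E); Zm[cbind(seq_len(n), qi)] <- 1
  Zd <- matrix(0, n, E); Zd[cbind(seq_len(n), wi)] <- 1
  Z <- cbind(Zm, Zd)
  G <- kronecker(G0, A)
  V <- Z %*% G %*% t(Z) + sigma2_e * diag(n)
  Vi <- solve(V)
  if (fixed_effects) {
    X <- stats::model.matrix(~ 0 + factor(records$apiary))
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% records$y)
    r <- records$y - X %*% b
  } else {
    b <- numeric(0)
    r <- records$y
  }
  u <- G %*% t(Z) %*% Vi %*% r
  list(ebv_m = stats::setNames(u[seq_len(E)], rownames(A)),
       ebv_d = stats::setNames(u[E + seq_len(E)], rownames(A)),
       fixed = as.numeric(b))
}

# Random true-mode pedigree: founder queens, then layers of queens whose
# dams and father-drone dams are drawn from earlier layers.
random_true_pedigree <- function(n_founders = 4, n_layers = 3, per_layer = 4) {
  id <- paste0("F", seq_len(n_founders))
  kind <- rep("queen", n_founders)
  dam <- rep(NA_character_, n_founders)
  sire <- rep(NA_character_, n_founders)
  queens <- id
  k <- 0
  for (l in seq_len(n_layers)) {
    new_q <- character(0)
    for (j in seq_len(per_layer)) {
      k <- k + 1
      d <- sample(queens, 1)
      pd <- sample(queens, 1)
      # a father drone may be reused by several queens (super sisters)
      dr_id <- paste0("D", k)
      if (runif(1) < 0.3 && sum(kind == "drone") > 0) {
        dr_id <- sample(id[kind == "drone"], 1)
      } else {
        id <- c(id, dr_id); kind <- c(kind, "drone")
        dam <- c(dam, pd); sire <- c(sire, NA_character_)
      }
      q_id <- paste0("Q", l, ".", j)
      id <- c(id, q_id); kind <- c(kind, "queen")
      dam <- c(dam, d); sire <- c(sire, dr_id)
      new_q <- c(new_q, q_id)
    }
    queens <- c(queens, new_q)
  }
  pedigree_table(id, kind, dam, sire)
}

# Small population built from package primitives: founder queens mated
# IIS-style to founder producers, phenotyped once. Used for EBV accuracy.
toy_population <- function(n_queens = 40, n_producers = 8, sigma2_e = 4,
                           n_loci = 200) {
  pars <- trait_params(n_loci = n_loci, sigma2_e = sigma2_e)
  p <- sample_founder_frequencies(n_loci)
  eff <- sample_allele_effects(pars, p)
  rq <- function() {
    h <- matrix(as.integer(stats::runif(2 * n_loci) < p), n_loci, 2)
    list(h1 = h[, 1], h2 = h[, 2])
  }
  prods <- replicate(n_producers, rq(), simplify = FALSE)
  queens <- replicate(n_queens, rq(), simplify = FALSE)
  mated <- sample.int(n_producers, n_queens, replace = TRUE)
  ids <- paste0("Q", seq_len(n_queens))
  pids <- paste0("P", seq_len(n_producers))
  bv_m <- bv_d <- wg_d <- numeric(n_queens)
  for (i in seq_len(n_queens)) {
    g <- queens[[i]]
    pr <- prods[[mated[i]]]
    drones <- make_gametes(pr$h1, pr$h2, n = 12)
    wg <- worker_group_of(g$h1, g$h2, drones, eff)
    bv <- true_breeding_values(g$h1 + g$h2, eff)
    bv_m[i] <- bv[["m"]]; bv_d[i] <- bv[["d"]]; wg_d[i] <- wg$bv_d
  }
  ped <- pedigree_table(c(pids, ids), "queen",
                        dam = NA, sire = NA,
                        mated = c(rep(NA, n_producers), pids[mated]))
  A <- relationship_matrix(accessible_kinship(ped, include_workers = TRUE))
  colonies <- data.frame(id = ids, bv_m = bv_m, bv_d = wg_d)
  recs <- simulate_phenotypes(colonies, n_apiaries = 4, sigma2_e = sigma2_e)
  list(records = recs, A = A, G0 = trait_covariance(pars),
       sigma2_e = sigma2_e, ids = ids,
       true_crit = bv_m + bv_d)
}

# Scaled simulation config used by engine-level tests.
scaled_config <- function(strategy, n_queens = 100, years = 30,
                          n_stations = 5, r_md = -0.18) {
  sim_config(n_queens = n_queens, years = years,
             trait = trait_params(r_md = r_md),
             strategy = strategy_config(strategy, n_stations = n_stations))
}
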