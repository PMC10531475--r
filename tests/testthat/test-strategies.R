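test_that("dam selection truncates at the configured fraction", {
  set.seed(71)
  cand <- data.frame(id = 1:500, criterion = rnorm(500))
  sel <- select_dams(cand, 0.2, 5)
  expect_equal(nrow(sel), 100)
  expect_equal(sum(sel$n_daughters), 500)
  # truncation: worst selected beats best unselected
  expect_gte(min(sel$criterion), max(cand$criterion[!cand$id %in% sel$id]))
  # ties broken deterministically by id
  tie <- data.frame(id = 10:1, criterion = 1)
  expect_equal(select_dams(tie, 0.2, 5)$id, c(1, 2))
  expect_error(select_dams(data.frame(id = 1, criterion = 1)[0, ], 0.2, 5),
               "invalid state|candidates")
})

test_that("producer selection respects strategy age cohorts and counts", {
  set.seed(73)
  cand <- data.frame(id = 1:300, age = rep(c(2L, 3L), 150),
                     criterion = rnorm(300))
  s5 <- strategy_config("IIS2", n_stations = 5)
  sel <- select_drone_producers(cand, s5)
  expect_equal(nrow(sel), 40)                       # 8 per station, 5 stations
  expect_true(all(sel$age == 2L))
  expect_equal(as.integer(table(sel$station)), rep(8L, 5))
  sel3 <- select_drone_producers(cand, strategy_config("IIS3", n_stations = 5))
  expect_true(all(sel3$age == 3L))
  # mixed selection collapses to the dominating cohort
  cand2 <- cand
  cand2$criterion <- ifelse(cand2$age == 3L, cand2$criterion + 100,
                            cand2$criterion)
  selm <- select_drone_producers(cand2, strategy_config("IISmix", n_stations = 5))
  expect_equal(mean(selm$age), 3)
  # IMS: one three-year-old founds each station
  seli <- select_drone_producers(cand, strategy_config("IMS", n_stations = 5))
  expect_equal(nrow(seli), 5)
  expect_true(all(seli$age == 3L))
  expect_error(select_drone_producers(cand[1:10, ],
                                      strategy_config("IIS2", n_stations = 5)),
               "invalid state")
})

test_that("the admissibility rule excludes the dam and her sisters", {
  producers <- c(11L, 12L, 13L, 14L)
  producer_dams <- c(1L, 2L, 2L, NA)
  # queen's dam is 12, her grand-dam is 2: excludes 12 (own dam) and 13
  # (shares dam 2 with the queen's dam), keeps 11 and the founder 14
  adm <- beebreed:::.admissible_producers(producers, producer_dams, 12L, 2L)
  expect_equal(adm, c(11L, 14L))
  # unknown grand-dam: only the dam herself is excluded
  expect_equal(beebreed:::.admissible_producers(producers, producer_dams,
                                                12L, NA_integer_),
               c(11L, 13L, 14L))
})

test_that("population bookkeeping holds through a run", {
  cfg <- sim_config(n_queens = 50, years = 10,
                    trait = trait_params(n_loci = 100),
                    strategy = strategy_config("IIS2", n_stations = 2))
  sim <- run_simulation(cfg, seed = 5)
  ped <- sim$pedigree
  bq <- ped[ped$kind != "dpq", ]
  # exactly N_Q new queens every year
  expect_true(all(table(bq$birth) == 50))
  # every queen from year 3 on has a dam, a father drone and one sire entity
  late <- bq[bq$birth >= 5, ]
  expect_true(all(!is.na(late$dam) & !is.na(late$fdam) & !is.na(late$fslot)))
  expect_true(all(!is.na(late$sire_acc)))
  # all daughters of one dam were mated at the same station
  st <- tapply(late$station, late$dam, function(s) length(unique(s)))
  expect_true(all(st == 1))
  # IIS: a queen's father drone comes from the producer her dam was mated to
  expect_true(all(late$fdam == as.integer(bq$mated_acc[match(late$dam, bq$id)])))
})

test_that("the insemination avoidance rule is never violated", {
  cfg <- sim_config(n_queens = 60, years = 12,
                    trait = trait_params(n_loci = 100),
                    strategy = strategy_config("IISmix", n_stations = 2))
  sim <- run_simulation(cfg, seed = 9)
  ped <- sim$pedigree
  bq <- ped[ped$kind != "dpq" & !is.na(ped$mated_acc), ]
  P <- as.integer(bq$mated_acc)
  dam_of <- function(i) ped$dam[match(i, ped$id)]
  # never inseminated with drones from the own dam
  expect_true(all(is.na(bq$dam) | P != bq$dam))
  # never from an aunt (producer sharing a dam with the queen's dam)
  pd <- dam_of(P)
  gd <- dam_of(bq$dam)
  expect_true(all(is.na(pd) | is.na(gd) | pd != gd))
})

test_that("IMS matings draw drones uniformly from the station's DPQ", {
  cfg <- sim_config(n_queens = 100, years = 7,
                    trait = trait_params(n_loci = 50),
                    strategy = strategy_config("IMS", n_stations = 1))
  sim <- run_simulation(cfg, seed = 13)
  ped <- sim$pedigree
  # fathers of the final cohort are drones of the single pool's 8 DPQ
  last <- ped[ped$birth == 7 & ped$kind != "dpq", ]
  pool <- sim$pools[[ped$mated_acc[match(last$dam[1], ped$id)]]]
  expect_true(all(last$fdam %in% pool))
  counts <- table(factor(last$fdam, levels = pool))
  # 100 draws over 8 DPQ: each share within 5 sd of uniform
  expect_true(all(abs(counts - 100 / 8) < 5 * sqrt(100 * (1 / 8) * (7 / 8))))
})
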