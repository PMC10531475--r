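test_that("true kinship reproduces textbook sister relationships", {
  ped <- pedigree_table(
    id   = c("A", "B", "D1", "D2", "Q1", "Q2", "Q3"),
    kind = c("queen", "queen", "drone", "drone", "queen", "queen", "queen"),
    dam  = c(NA, NA, "B", "B", "A", "A", "A"),
    sire = c(NA, NA, NA, NA, "D1", "D1", "D2"))
  tk <- true_kinship(ped)
  # super sisters: same dam, same father drone
  expect_equal(tk$f["Q1", "Q2"], 0.375)
  # drones of the same dam: their daughters are 3/4 sisters here, but with
  # unrelated drone dams they would be half sisters
  ped2 <- pedigree_table(
    id   = c("A", "B", "C", "D1", "D2", "Q1", "Q2"),
    kind = c("queen", "queen", "queen", "drone", "drone", "queen", "queen"),
    dam  = c(NA, NA, NA, "B", "C", "A", "A"),
    sire = c(NA, NA, NA, NA, NA, "D1", "D2"))
  expect_equal(true_kinship(ped2)$f["Q1", "Q2"], 0.125)
  expect_equal(true_kinship(ped2)$F[["Q1"]], 0)
  # haploid self-kinship
  expect_equal(tk$f["D1", "D1"], 1)
  expect_error(true_kinship(pedigree_table("X", "pool", NA, NA)), "pool")
})

test_that("gene drop confirms the recursion on sister pedigrees", {
  ped <- pedigree_table(
    id   = c("A", "B", "D1", "D2", "Q1", "Q2", "Q3"),
    kind = c("queen", "queen", "drone", "drone", "queen", "queen", "queen"),
    dam  = c(NA, NA, "B", "B", "A", "A", "A"),
    sire = c(NA, NA, NA, NA, "D1", "D1", "D2"))
  set.seed(31)
  gd <- gene_drop_kinship(ped, n_loci = 40000, mode = "true")
  expect_lt(abs(gd$f["Q1", "Q2"] - 0.375), 3 * gd$se_f["Q1", "Q2"] + 1e-12)
  expect_lt(abs(gd$f["Q1", "Q3"] - 0.25), 3 * gd$se_f["Q1", "Q3"] + 1e-12)
  expect_equal(unname(gd$F[c("A", "B")]), c(0, 0))  # founders exactly 0
  expect_equal(gd$f["D1", "D1"], 1)                  # haploid vs itself
})

test_that("recursion and gene drop agree on random pedigrees", {
  set.seed(77)
  worst <- 0
  for (r in 1:20) {
    ped <- random_true_pedigree(n_founders = 3 + r %% 3, n_layers = 3,
                                per_layer = 3)
    tk <- true_kinship(ped)
    gd <- gene_drop_kinship(ped, n_loci = 5000, mode = "true")
    z <- abs(gd$f - tk$f) / pmax(gd$se_f, 1 / 5000)
    worst <- max(worst, max(z))
  }
  # ~20 * 200 comparisons: the largest |z| should behave like the max of
  # that many (correlated) standard normals
  expect_lt(worst, 4.5)
})

test_that("pool kinship follows the pseudo-sire rules", {
  # 8 full-sister DPQ: dam G, all sired by drones of producer P0
  ped <- pedigree_table(
    id = c("G", "P0", paste0("D", 1:8), "P", "M1", "M2", "O1", "O2"),
    kind = c("queen", "queen", rep("queen", 8), "pool",
             "queen", "queen", "queen", "queen"),
    dam = c(NA, NA, rep("G", 8), NA, NA, NA, "M1", "M2"),
    sire = c(NA, NA, rep("P0", 8), NA, NA, NA, "P", "P"))
  ped$members[ped$id == "P"] <- paste(paste0("D", 1:8), collapse = ";")
  ak <- accessible_kinship(ped)
  # realized mean member relationship
  Dm <- paste0("D", 1:8)
  fmat <- ak$f[Dm, Dm]
  a_ss <- 2 * mean(fmat[upper.tri(fmat)])
  expect_equal(a_ss, 0.5)
  # pool pair-ibd reproduces the closed form (1 + a_ss(N-1)) / (2N)
  expect_equal(ak$f["P", "P"], (1 + a_ss * 7) / (2 * 8))
  expect_equal(ak$f["P", "P"], paternal_ibd(1, 8, a_ss, "ims_pool"))
  # two station offspring: paternal ibd becomes their kinship share
  expect_equal(ak$f["O1", "O2"], 0.25 * ak$f["P", "P"])
  expect_equal(ak$F[["O1"]], 0)
  # members of different unrelated stations are unrelated
  ped2 <- pedigree_table(
    id = c("G1", "G2", "A1", "A2", "B1", "B2", "PA", "PB"),
    kind = c(rep("queen", 6), "pool", "pool"),
    dam = c(NA, NA, "G1", "G1", "G2", "G2", NA, NA),
    sire = NA)
  ped2$members[7] <- "A1;A2"
  ped2$members[8] <- "B1;B2"
  ak2 <- accessible_kinship(ped2)
  expect_equal(ak2$f["A1", "B1"], 0)
  expect_equal(ak2$f["PA", "PB"], 0)
})

test_that("explicit pool members and the full-sister shortcut coincide", {
  base <- list(id = c("G", "P0"), kind = c("queen", "queen"),
               dam = c(NA, NA), sire = c(NA, NA))
  ped_m <- pedigree_table(
    id = c(base$id, paste0("D", 1:8), "P", "M", "O"),
    kind = c(base$kind, rep("queen", 8), "pool", "queen", "queen"),
    dam = c(base$dam, rep("G", 8), NA, NA, "M"),
    sire = c(base$sire, rep("P0", 8), NA, NA, "P"))
  ped_m$members[ped_m$id == "P"] <- paste(paste0("D", 1:8), collapse = ";")
  ped_s <- pedigree_table(
    id = c("G", "P0", "P", "M", "O"),
    kind = c("queen", "queen", "pool", "queen", "queen"),
    dam = c(NA, NA, "G", NA, "M"),
    sire = c(NA, NA, "P0", NA, "P"),
    n_members = c(NA, NA, 8, NA, NA))
  fm <- accessible_kinship(ped_m)$f
  fs <- accessible_kinship(ped_s)$f
  common <- c("G", "P0", "P", "M", "O")
  expect_equal(fm[common, common], fs[common, common], tolerance = 1e-12)
})

test_that("a single recorded producer behaves like an individual sire", {
  # one unrelated, non-inbred producer: two offspring have paternal ibd 1/2
  ped <- pedigree_table(
    id = c("P1", "M1", "M2", "O1", "O2"),
    kind = "queen",
    dam = c(NA, NA, NA, "M1", "M2"),
    sire = c(NA, NA, NA, "P1", "P1"))
  ak <- accessible_kinship(ped)
  expect_equal(ak$f["P1", "P1"], 0.5)  # = paternal pair-ibd for one sire
  expect_equal(ak$f["O1", "O2"], 0.25 * 0.5)
  expect_equal(paternal_ibd(1, 1, mode = "unrelated"), 0.5)
})

test_that("accessible equals true kinship for recorded single-producer sires", {
  # IIS pedigree where every offspring has its own father drone from the
  # recorded producer: the pedigree-only rules lose nothing
  idq <- c("P", "M1", "M2", "Q1", "Q2")
  true_ped <- pedigree_table(
    id = c("P", "M1", "M2", "d1", "d2", "Q1", "Q2"),
    kind = c("queen", "queen", "queen", "drone", "drone", "queen", "queen"),
    dam = c(NA, NA, NA, "P", "P", "M1", "M2"),
    sire = c(NA, NA, NA, NA, NA, "d1", "d2"))
  acc_ped <- pedigree_table(
    id = idq, kind = "queen",
    dam = c(NA, NA, NA, "M1", "M2"),
    sire = c(NA, NA, NA, "P", "P"))
  ft <- true_kinship(true_ped)$f[idq, idq]
  fa <- accessible_kinship(acc_ped)$f[idq, idq]
  expect_equal(ft, fa, tolerance = 1e-12)
})

test_that("inbreeding never decreases along a closed full-sib line", {
  # closed 2-queen line: each generation, two super sisters; the next
  # generation is bred from one sister and a drone of the other
  id <- c("A0", "B0"); kind <- c("queen", "queen")
  dam <- c(NA, NA); sire <- c(NA, NA)
  for (g in 1:8) {
    a <- paste0("A", g - 1); b <- paste0("B", g - 1)
    dr <- paste0("d", g)
    id <- c(id, dr, paste0("A", g), paste0("B", g))
    kind <- c(kind, "drone", "queen", "queen")
    dam <- c(dam, b, a, a)
    sire <- c(sire, NA, dr, dr)
  }
  tk <- true_kinship(pedigree_table(id, kind, dam, sire))
  Fline <- tk$F[paste0("A", 1:8)]
  expect_true(all(diff(Fline) >= -1e-12))
  expect_gt(Fline[8], Fline[1])
})

test_that("worker-group entities use the finite mate count on the diagonal", {
  ped <- pedigree_table(
    id = c("P", "Q"), kind = "queen",
    dam = c(NA, NA), sire = c(NA, NA), mated = c(NA, "P"))
  f12 <- accessible_kinship(ped, include_workers = TRUE, n_mates = 12)$f
  finf <- accessible_kinship(ped, include_workers = TRUE, n_mates = Inf)$f
  # diag = (f(Q,Q) + 2 f(Q,P) + p_pat) / 4 with p_pat = 1/12 + 11/12 * 1/2
  expect_equal(f12["W:Q", "W:Q"], (0.5 + 0 + 1 / 12 + 11 / 12 * 0.5) / 4)
  expect_equal(finf["W:Q", "W:Q"], (0.5 + 0 + 0.5) / 4)
  expect_equal(f12["W:Q", "P"], 0.25)  # half the producer row
})
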