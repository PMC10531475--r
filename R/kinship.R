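## Pedigree tables
##
## A pedigree is a data.frame in topological order (parents before offspring)
## with columns:
##   id      entity identifier (character)
##   kind    "queen", "drone" or "pool"
##   dam     id of the dam queen, or NA (unknown / founder)
##   sire    id of the father: an individual drone (true pedigrees), a pool or
##           producer queen (accessible pedigrees), or NA
##   mated   optional: id of the sire entity (pool / producer queen) whose
##           drones the queen herself was mated with; determines her worker
##           group's paternal side
##   members optional, pools only: ";"-separated ids of the member
##           drone-producing queens
##   n_members optional, pools only: member count for the full-sister
##           shortcut (members are n full sisters with the pool's dam/sire)

.ped_norm <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "kind", "dam", "sire") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$dam <- as.character(ped$dam)
  ped$sire <- as.character(ped$sire)
  if (is.null(ped$mated)) ped$mated <- NA_character_ else ped$mated <- as.character(ped$mated)
  if (is.null(ped$members)) ped$members <- NA_character_ else ped$members <- as.character(ped$members)
  if (is.null(ped$n_members)) ped$n_members <- NA_integer_
  if (anyDuplicated(ped$id)) stop("duplicated pedigree ids")
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  for (col in c("dam", "sire", "mated")) {
    ref <- ped[[col]]
    known <- !is.na(ref)
    bad <- known & is.na(idx[ref])
    if (any(bad)) stop("pedigree column '", col, "' references unknown id(s): ",
                       paste(unique(ref[bad]), collapse = ", "))
    if (any(idx[ref[known]] >= idx[known]))
      stop("pedigree is not in topological order (", col,
           " listed at or after offspring)")
  }
  ped
}

#' Construct a pedigree table
#'
#' Convenience constructor for the pedigree data.frame format used by
#' [true_kinship()], [accessible_kinship()] and [gene_drop_kinship()]. Rows
#' must be in topological order (parents before offspring).
#'
#' @param id,kind,dam,sire,mated,members,n_members Column vectors, recycled to
#'   a common length; see the format description in the package vignette.
#' @return A validated pedigree `data.frame`.
#' @export
pedigree_table <- function(id, kind = "queen", dam = NA, sire = NA,
                           mated = NA, members = NA, n_members = NA) {
  ped <- data.frame(id = as.character(id), kind = kind,
                    dam = as.character(dam), sire = as.character(sire),
                    mated = as.character(mated),
                    members = as.character(members),
                    n_members = as.integer(n_members),
                    stringsAsFactors = FALSE)
  .ped_norm(ped)
}

#' True kinship from a pedigree with individual drone sires
#'
#' Computes coancestry (kinship) coefficients by tabular recursion for a
#' haplodiploid pedigree in which every queen's individual father drone is
#' known. Rules: founder queens have self-kinship 1/2 and zero cross-kinship;
#' a drone is a single gamete of his dam (kinship with any other entity equals
#' his dam's, self-kinship 1); a queen averages her dam and father drone, her
#' inbreeding coefficient is the kinship between dam and father drone, and her
#' self-kinship is `(1 + F)/2`. Unknown parents are treated as unrelated
#' non-inbred founders.
#'
#' @param ped Pedigree data.frame (see [pedigree_table()]); kinds `"queen"`
#'   and `"drone"` are used, `"pool"` rows are not allowed here.
#' @return An object of class `kinship_store`: list with `f` (symmetric
#'   coancestry matrix), `F` (named inbreeding coefficients of queens) and
#'   `kind`.
#' @examples
#' ped <- pedigree_table(
#'   id   = c("A", "B", "D1", "Q1", "Q2"),
#'   kind = c("queen", "queen", "drone", "queen", "queen"),
#'   dam  = c(NA, NA, "B", "A", "A"),
#'   sire = c(NA, NA, NA, "D1", "D1"))
#' true_kinship(ped)$f["Q1", "Q2"]  # super sisters: 0.375
#' @export
true_kinship <- function(ped) {
  ped <- .ped_norm(ped)
  if (any(ped$kind == "pool"))
    stop("invalid pedigree: pool entities are not part of the true pedigree")
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Fcoef <- rep(NA_real_, n)
  names(Fcoef) <- ped$id
  idx <- seq_len(n); names(idx) <- ped$id
  for (i in seq_len(n)) {
    di <- ped$dam[i]; si <- ped$sire[i]
    prev <- seq_len(i - 1L)
    if (ped$kind[i] == "drone") {
      if (!is.na(si)) stop("invalid pedigree: drones have no sire")
      if (!is.na(di)) {
        K[i, prev] <- K[idx[di], prev]
        K[prev, i] <- K[i, prev]
      }
      K[i, i] <- 1
    } else {
      row <- numeric(i - 1L)
      if (!is.na(di)) row <- row + 0.5 * K[idx[di], prev]
      if (!is.na(si)) row <- row + 0.5 * K[idx[si], prev]
      K[i, prev] <- row
      K[prev, i] <- row
      Fi <- if (!is.na(di) && !is.na(si)) K[idx[di], idx[si]] else 0
      Fcoef[i] <- Fi
      K[i, i] <- (1 + Fi) / 2
    }
  }
  structure(list(f = K, F = Fcoef[ped$kind != "drone"], kind = ped$kind),
            class = "kinship_store")
}

#' @export
print.kinship_store <- function(x, ...) {
  cat(sprintf("Kinship store over %d entities; mean queen inbreeding %.4f\n",
              nrow(x$f), mean(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Pairwise relationship coefficients
#'
#' Relationships on the numerator-relationship scale, `a = 2 f`.
#'
#' @param ks A `kinship_store` from [true_kinship()] or
#'   [accessible_kinship()].
#' @return Symmetric matrix of relationship coefficients.
#' @export
relationship_matrix <- function(ks) {
  stopifnot(inherits(ks, "kinship_store"))
  2 * ks$f
}

.pool_members <- function(ped, i) {
  if (!is.na(ped$members[i])) {
    strsplit(ped$members[i], ";", fixed = TRUE)[[1L]]
  } else NULL
}

#' Accessible (pedigree-only) kinship with sire entities
#'
#' Computes the probabilistic kinship matrix available from recorded honeybee
#' pedigrees, where a queen's recorded "father" is a sire entity: the pool of
#' drone-producing queens (DPQ) of an isolated mating station, or the single
#' drone-producer queen of an instrumental insemination. Pool rows are the
#' member-average of the DPQ rows; the pool's diagonal entry is the
#' probability that two independently drawn drones from the pool carry
#' identical-by-descent alleles (the paternal pair-ibd value), which is what
#' the offspring recursion needs. Optionally appends worker-group entities
#' (`"W:<queen id>"`) for every queen with a recorded mating, whose diagonal
#' uses the finite mate count.
#'
#' @param ped Pedigree data.frame; queen `sire` fields must reference pools or
#'   queens (producers), not individual drones.
#' @param include_workers Logical; append worker-group entities, default
#'   `FALSE`.
#' @param n_mates Mates per queen for the worker-group diagonal, default 12;
#'   `Inf` gives the infinite-mates approximation.
#' @return A `kinship_store` (see [true_kinship()]); `F` holds queen
#'   inbreeding coefficients as recorded by the accessible pedigree.
#' @examples
#' # a station pool of 8 full-sister DPQ (dam G, single producer sire P0):
#' # members have pairwise relationship 0.5, so the pool's paternal pair-ibd
#' # equals (1 + 0.5 * 7) / (2 * 8) = 0.28125
#' ped <- pedigree_table(
#'   id = c("G", "P0", paste0("D", 1:8), "P"),
#'   kind = c("queen", "queen", rep("queen", 8), "pool"),
#'   dam = c(NA, NA, rep("G", 8), NA),
#'   sire = c(NA, NA, rep("P0", 8), NA),
#'   members = c(rep(NA, 10), paste(paste0("D", 1:8), collapse = ";")))
#' accessible_kinship(ped)$f["P", "P"]
#' @export
accessible_kinship <- function(ped, include_workers = FALSE, n_mates = 12L) {
  ped <- .ped_norm(ped)
  if (any(ped$kind == "drone"))
    stop("invalid pedigree: accessible pedigrees record sire entities, ",
         "not individual drones")
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Fcoef <- rep(NA_real_, n); names(Fcoef) <- ped$id
  idx <- seq_len(n); names(idx) <- ped$id
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    di <- ped$dam[i]; si <- ped$sire[i]
    if (ped$kind[i] == "pool") {
      mem <- .pool_members(ped, i)
      if (!is.null(mem)) {
        mi <- idx[mem]
        if (anyNA(mi) || any(mi >= i))
          stop("invalid pedigree: pool members must be earlier entities")
        N <- length(mi)
        K[i, prev] <- colMeans(K[mi, prev, drop = FALSE])
        K[prev, i] <- K[i, prev]
        self_mean <- mean(K[cbind(mi, mi)])
        cross_mean <- if (N > 1L) (sum(K[mi, mi]) - sum(K[cbind(mi, mi)])) /
            (N * (N - 1L)) else 0
        K[i, i] <- self_mean / N + (1 - 1 / N) * cross_mean
      } else {
        # full-sister shortcut: n_members daughters of (dam, sire)
        N <- ped$n_members[i]
        if (is.na(N) || N < 1L)
          stop("invalid pedigree: pool needs 'members' or 'n_members'")
        row <- numeric(i - 1L)
        Fd <- 0
        if (!is.na(di)) row <- row + 0.5 * K[idx[di], prev]
        if (!is.na(si)) row <- row + 0.5 * K[idx[si], prev]
        if (!is.na(di) && !is.na(si)) Fd <- K[idx[di], idx[si]]
        K[i, prev] <- row; K[prev, i] <- row
        self_d <- (1 + Fd) / 2
        cross_d <- 0.25 * ((if (!is.na(di)) K[idx[di], idx[di]] else 0.5) +
                           2 * Fd +
                           (if (!is.na(si)) K[idx[si], idx[si]] else 0))
        K[i, i] <- self_d / N + (1 - 1 / N) * cross_d
      }
    } else {
      row <- numeric(i - 1L)
      if (!is.na(di)) row <- row + 0.5 * K[idx[di], prev]
      if (!is.na(si)) row <- row + 0.5 * K[idx[si], prev]
      K[i, prev] <- row; K[prev, i] <- row
      Fi <- if (!is.na(di) && !is.na(si)) K[idx[di], idx[si]] else 0
      Fcoef[i] <- Fi
      K[i, i] <- (1 + Fi) / 2
    }
  }
  if (include_workers) {
    qi <- which(ped$kind == "queen")
    wids <- paste0("W:", ped$id[qi])
    m <- length(qi)
    W <- matrix(0, m, n, dimnames = list(wids, ped$id))
    Wd <- numeric(m)
    WW <- matrix(0, m, m, dimnames = list(wids, wids))
    srow <- function(j) if (!is.na(ped$mated[j])) K[idx[ped$mated[j]], ] else numeric(n)
    sdiag <- function(j) if (!is.na(ped$mated[j])) K[idx[ped$mated[j]], idx[ped$mated[j]]] else 0
    sq <- function(j) if (!is.na(ped$mated[j])) K[j, idx[ped$mated[j]]] else 0
    for (a in seq_len(m)) {
      j <- qi[a]
      W[a, ] <- 0.5 * K[j, ] + 0.5 * srow(j)
      ppat <- if (is.finite(n_mates)) 1 / n_mates + (1 - 1 / n_mates) * sdiag(j)
              else sdiag(j)
      Wd[a] <- 0.25 * (K[j, j] + 2 * sq(j) + ppat)
    }
    for (a in seq_len(m)) {
      j <- qi[a]
      WW[a, ] <- 0.5 * W[, j] + 0.5 * (if (!is.na(ped$mated[j]))
        W[, idx[ped$mated[j]]] else numeric(m))
      WW[, a] <- WW[a, ]
    }
    diag(WW) <- Wd
    K <- rbind(cbind(K, t(W)), cbind(W, WW))
  }
  structure(list(f = K, F = Fcoef[ped$kind == "queen"], kind = ped$kind),
            class = "kinship_store")
}

#' Monte-Carlo gene-drop estimate of kinship and inbreeding
#'
#' Independent validation oracle for the recursive kinship engines. Unique
#' allele labels are assigned to founder haplotypes and dropped through the
#' pedigree at `n_loci` virtual unlinked loci: drones receive one random
#' allele of their dam per locus; queens receive a random maternal allele and
#' their father's allele (drone sperm is clonal); for accessible pedigrees a
#' pool sire contributes, per locus, a random allele of a uniformly drawn
#' member, and a producer-queen sire a random allele of that producer.
#' Identity-by-descent probabilities are estimated as equality frequencies
#' over loci.
#'
#' @param ped Pedigree data.frame. With `mode = "true"`, sires are individual
#'   drones; with `mode = "accessible"`, sires are pools/producer queens and
#'   each transmission resamples the member and gamete.
#' @param n_loci Number of virtual loci, default 10000.
#' @param mode `"true"` or `"accessible"`.
#' @return List with `f` (estimated coancestry matrix, pool diagonals are
#'   pair-ibd probabilities), `F` (estimated queen inbreeding), `se_f`,
#'   `se_F` (Monte-Carlo standard errors) and `n_loci`.
#' @export
gene_drop_kinship <- function(ped, n_loci = 10000L, mode = c("true", "accessible")) {
  ped <- .ped_norm(ped)
  mode <- match.arg(mode)
  n <- nrow(ped)
  L <- as.integer(n_loci)
  idx <- seq_len(n); names(idx) <- ped$id
  A1 <- matrix(0L, n, L)
  A2 <- matrix(0L, n, L)
  label <- 0L
  new_labels <- function() {
    label <<- label + 1L
    rep.int(label, L)
  }
  draw <- function(j) {
    # one random allele per locus from entity j
    pick <- stats::runif(L) < 0.5
    ifelse(pick, A1[j, ], A2[j, ])
  }
  pool_draw <- function(i) {
    mem <- .pool_members(ped, i)
    if (is.null(mem))
      stop("gene drop requires explicit pool members (use 'members')")
    mi <- idx[mem]
    pickm <- mi[sample.int(length(mi), L, replace = TRUE)]
    picka <- stats::runif(L) < 0.5
    ifelse(picka, A1[cbind(pickm, seq_len(L))], A2[cbind(pickm, seq_len(L))])
  }
  for (i in seq_len(n)) {
    di <- ped$dam[i]; si <- ped$sire[i]
    if (ped$kind[i] == "drone") {
      A1[i, ] <- if (!is.na(di)) draw(idx[di]) else new_labels()
      A2[i, ] <- A1[i, ]
    } else if (ped$kind[i] == "pool") {
      # two independent drone draws represent the pool
      A1[i, ] <- pool_draw(i)
      A2[i, ] <- pool_draw(i)
    } else {
      A1[i, ] <- if (!is.na(di)) draw(idx[di]) else new_labels()
      if (is.na(si)) {
        A2[i, ] <- new_labels()
      } else if (mode == "true") {
        if (ped$kind[idx[si]] != "drone")
          stop("true-mode sires must be individual drones")
        A2[i, ] <- A1[idx[si], ]
      } else {
        j <- idx[si]
        A2[i, ] <- if (ped$kind[j] == "pool") pool_draw(j) else draw(j)
      }
    }
  }
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) {
        if (ped$kind[i] == "drone") { f[i, i] <- 1; next }
        s <- (A1[i, ] == A2[i, ])
        if (ped$kind[i] == "pool") {
          f[i, i] <- mean(s)
        } else {
          f[i, i] <- (1 + mean(s)) / 2
        }
        se[i, i] <- stats::sd(s) / sqrt(L)
      } else {
        s <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
              (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
        f[i, j] <- f[j, i] <- mean(s)
        se[i, j] <- se[j, i] <- stats::sd(s) / sqrt(L)
      }
    }
  }
  qs <- ped$kind == "queen"
  Fhat <- rep(NA_real_, n); seF <- rep(NA_real_, n)
  for (i in which(qs)) {
    s <- (A1[i, ] == A2[i, ])
    Fhat[i] <- mean(s); seF[i] <- stats::sd(s) / sqrt(L)
  }
  names(Fhat) <- names(seF) <- ped$id
  list(f = f, F = Fhat[qs], se_f = se, se_F = seF[qs], n_loci = L)
}
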