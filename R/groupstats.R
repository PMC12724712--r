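## Group-level inference over per-cell metrics with per-animal
## exchangeability: sign-flip permutation of the median, animal-level
## permuted Mann-Whitney U, and Kruskal-Wallis.

check_metrics <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("animal", "value") %in% names(metrics)))
  if (any(!is.finite(metrics$value))) stop("metric values must be finite")
  metrics
}

#' Sign-flip permutation test of a median metric
#'
#' Tests whether the median of per-cell metric values (e.g. pseudo-R²)
#' differs from zero, respecting within-animal correlation: each permutation
#' flips the sign of *all* cells of an animal jointly (one independent ±1
#' per animal), and the median over cells is recomputed. Two-sided p-value
#' with the add-one correction,
#' \code{p = (1 + #(|null| >= |observed|)) / (1 + nPerm)}. When the animal
#' count is small enough (\code{2^nAnimals <= nPerm}) all flip patterns are
#' enumerated exactly instead.
#'
#' @param metrics data.frame with columns \code{animal} and \code{value}
#'   (one row per cell).
#' @param nPerm number of permutations; default 10000.
#' @return List with \code{observed} (median), \code{p}, \code{nPerm},
#'   \code{exact} (logical), \code{null} (the null medians).
#' @export
signFlipMedianTest <- function(metrics, nPerm = 10000) {
  metrics <- check_metrics(metrics)
  animals <- unique(metrics$animal)
  nA <- length(animals)
  if (nA < 2) stop("need at least 2 animals for sign-flip exchangeability")
  obs <- median(metrics$value)
  aidx <- match(metrics$animal, animals)
  exact <- 2^nA <= nPerm
  if (exact) {
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), nA)))
    null <- apply(signs_mat, 1, function(s) median(s[aidx] * metrics$value))
    # exact enumeration: proportion of the full group with |null| >= |obs|
    p <- sum(abs(null) >= abs(obs) - 1e-12) / length(null)
    nP <- length(null)
  } else {
    null <- replicate(nPerm, {
      s <- sample(c(-1, 1), nA, replace = TRUE)
      median(s[aidx] * metrics$value)
    })
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + nPerm)
    nP <- nPerm
  }
  list(observed = obs, p = min(p, 1), nPerm = nP, exact = exact,
       null = null)
}

mann_whitney_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Animal-level permuted Mann-Whitney U test
#'
#' Compares a metric between two cell groups with a Mann-Whitney U
#' statistic whose null distribution is built by permuting group labels at
#' the animal level (all cells of an animal move together). The reported
#' p-value is Bonferroni-multiplied by \code{bonferroniM} and capped at 1.
#' Exact enumeration of animal-label assignments is used when feasible.
#'
#' @param groupA,groupB data.frames with columns \code{animal},
#'   \code{value}. Animal ids must not overlap between groups.
#' @param nPerm permutations; default 10000.
#' @param bonferroniM multiple-comparison multiplier; default 1.
#' @return List with \code{observed} (U), \code{p} (corrected),
#'   \code{pUncorrected}, \code{nPerm}, \code{exact}.
#' @export
permutedMannWhitney <- function(groupA, groupB, nPerm = 10000,
                                bonferroniM = 1) {
  groupA <- check_metrics(groupA); groupB <- check_metrics(groupB)
  if (!nrow(groupA) || !nrow(groupB)) stop("both groups must be nonempty")
  aA <- unique(groupA$animal); aB <- unique(groupB$animal)
  values <- c(groupA$value, groupB$value)
  animal <- c(paste0("A.", groupA$animal), paste0("B.", groupB$animal))
  anim_ids <- unique(animal)
  nA_anim <- length(unique(paste0("A.", aA)))
  nTot <- length(anim_ids)
  obs <- mann_whitney_u(groupA$value, groupB$value)
  obs_c <- obs - nrow(groupA) * nrow(groupB) / 2
  # group sizes vary across animal-level assignments, so each null U is
  # centered by its own assignment's n1 n2 / 2 before the two-sided
  # comparison
  stat_for <- function(assignA) {
    inA <- animal %in% assignA
    if (!any(inA) || all(inA)) return(NA_real_)
    mann_whitney_u(values[inA], values[!inA]) -
      sum(inA) * sum(!inA) / 2
  }
  nComb <- choose(nTot, nA_anim)
  exact <- nComb <= nPerm
  if (exact) {
    combs <- utils::combn(anim_ids, nA_anim, simplify = FALSE)
    null <- vapply(combs, stat_for, 0)
    p <- sum(abs(null) >= abs(obs_c) - 1e-12) / length(null)
    nP <- length(null)
  } else {
    null <- replicate(nPerm, stat_for(sample(anim_ids, nA_anim)))
    p <- (1 + sum(abs(null) >= abs(obs_c) - 1e-12)) / (1 + nPerm)
    nP <- nPerm
  }
  list(observed = obs, p = min(p * bonferroniM, 1), pUncorrected = min(p, 1),
       nPerm = nP, exact = exact)
}

#' Kruskal-Wallis test across three or more cell classes
#'
#' Standard rank-based H statistic with the chi-square reference
#' distribution (ties mid-ranked), via \code{stats::kruskal.test}.
#'
#' @param groups list (length >= 3) of data.frames with a \code{value}
#'   column, or of numeric vectors.
#' @return List with \code{H}, \code{df}, \code{p}.
#' @export
kruskalWallisMetrics <- function(groups) {
  if (length(groups) < 3) stop("need at least 3 groups")
  vals <- lapply(groups, function(g) if (is.data.frame(g)) g$value else g)
  if (any(!vapply(vals, length, 0L))) stop("all groups must be nonempty")
  kt <- kruskal.test(vals)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
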