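#' Mean expected-progeny dissimilarity for a candidate parent (GDM)
#'
#' For a candidate parent i and potential offspring k, GDM is the mean Gower
#' dissimilarity between k and the expected progenies of i crossed with every
#' possible co-parent j. An individual is, on average, more closely related
#' to a population of its (hypothetical) siblings than to a population of
#' random individuals, so a true parent's GDM is depressed relative to the
#' other candidates'.
#'
#' @param gm A \code{genotype_matrix}.
#' @param parent,offspring Individual IDs.
#' @param coparents Non-empty character vector of co-parent IDs, excluding
#'   \code{parent}.
#' @return List with \code{gdm} and \code{per_coparent_gds} (one GD per
#'   co-parent, named; undefined GDs are dropped from the mean with a
#'   warning).
#' @export
compute_gdm <- function(gm, parent, offspring, coparents) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(coparents) == 0L) stop("empty co-parent set", call. = FALSE)
  if (parent %in% coparents) {
    stop("the candidate parent cannot be its own co-parent", call. = FALSE)
  }
  ko <- gm$states[.match_id(gm, offspring), ]
  gds <- vapply(coparents, function(j) {
    suppressWarnings(
      gower_dissimilarity(expected_progeny(gm, parent, j), ko)$gd
    )
  }, numeric(1))
  if (anyNA(gds)) {
    warning(sprintf("%d co-parent GD(s) undefined for parent %s / offspring %s; dropped from GDM",
                    sum(is.na(gds)), parent, offspring), call. = FALSE)
  }
  list(gdm = mean(gds, na.rm = TRUE), per_coparent_gds = gds)
}

#' Relative variability of expected-progeny dissimilarities (GDCV)
#'
#' The sample standard deviation of the per-co-parent GDs (divisor j - 1),
#' re-expressed in units of the direct parent-offspring Gower dissimilarity
#' \code{gd_ik}. Variation in GD is higher between an individual and a
#' population of its siblings than between an individual and the progenies of
#' its siblings, so a true parent's GDCV is an upper outlier; this second
#' statistic is what separates true parents from full siblings.
#'
#' @param per_coparent_gds Numeric vector of at least 2 GDs (\code{NA}
#'   dropped).
#' @param gd_ik Direct Gower dissimilarity between the candidate parent and
#'   the offspring, over all comparable loci; must be positive (a
#'   zero-distance "parent" is a duplicate sample, not a parent).
#' @return List with \code{sigma_gd} and \code{gdcv} (\code{NA} when
#'   undefined).
#' @export
compute_gdcv <- function(per_coparent_gds, gd_ik) {
  g <- per_coparent_gds[!is.na(per_coparent_gds)]
  if (length(g) < 2L) {
    return(list(sigma_gd = NA_real_, gdcv = NA_real_))
  }
  s <- stats::sd(g)
  if (is.na(gd_ik) || gd_ik <= 0) {
    return(list(sigma_gd = s, gdcv = NA_real_))
  }
  list(sigma_gd = s, gdcv = s / gd_ik)
}

#' Two-stage dyad analysis for single-parent identification
#'
#' For each potential offspring k, every candidate parent i receives a GDM
#' (stage 1) and a GDCV (stage 2). Each offspring's set of GDM values over
#' the candidates is treated as a normal distribution; candidates whose
#' normal score falls below the lower bound of the confidence interval are
#' flagged as potential parents. For flagged candidates, the GDCV normal
#' score — computed against the offspring's GDCV set over all candidates, so
#' the null distribution is stable — must exceed the upper bound for the
#' pair to be reported. The reported cumulative p-value is the product of the
#' stage-1 lower-tail and stage-2 upper-tail normal probabilities.
#'
#' Co-parents for candidate i range over the whole genotyped population
#' except i itself — including the offspring k and its relatives — not merely
#' the labelled parent candidates: the true co-parent is by hypothesis absent
#' from, or unlabelled in, the population, and the stage-2 signal — the
#' elevated variability of a true parent's expected-progeny dissimilarities —
#' arises precisely from co-parents closely related to the offspring. The
#' expected progeny of i with k itself is the sharpest such probe: it is
#' nearly identical to k exactly when i is a true parent. Class keys
#' therefore restrict who can be \emph{reported} as a parent, not who can
#' serve as a hypothetical co-parent. Candidates with undefined GDCV (direct
#' GD of zero, or fewer than two defined co-parent GDs) are excluded from
#' stage 2 with a warning.
#'
#' @param gm A \code{genotype_matrix}.
#' @param offspring_set Offspring IDs to analyse (typically those without a
#'   declared triad).
#' @param parent_candidates Candidate parent IDs; at least 3 are required for
#'   normal scores to be meaningful.
#' @param confidence Two-sided confidence level in (0, 1) (default 0.99).
#' @param coparents IDs eligible as hypothetical co-parents (default: every
#'   individual in \code{gm}).
#' @return Data frame with one row per (candidate parent, offspring):
#'   \code{parent_id}, \code{offspring_id}, \code{gdm}, \code{gdm_z},
#'   \code{sigma_gd}, \code{gd_ik}, \code{gdcv}, \code{gdcv_z},
#'   \code{cumulative_p}, \code{stage1_flag}, \code{stage2_flag}. Reported
#'   pairs are those with \code{stage2_flag} (a subset of stage-1 flags).
#' @export
run_dyad <- function(gm, offspring_set, parent_candidates, confidence = 0.99,
                     coparents = gm$ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!(confidence > 0 && confidence < 1)) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  parent_candidates <- unique(as.character(parent_candidates))
  offspring_set <- unique(as.character(offspring_set))
  if (length(parent_candidates) < 3L) {
    stop("dyad analysis needs at least 3 candidate parents", call. = FALSE)
  }
  if (length(offspring_set) == 0L) {
    return(.empty_dyad_frame())
  }
  z_lo <- stats::qnorm((1 - confidence) / 2)
  z_hi <- -z_lo

  # all unordered pairs within the co-parent universe (candidates included),
  # scored once against all offspring
  universe <- union(parent_candidates, coparents)
  nu <- length(universe)
  i1 <- rep(seq_len(nu - 1L), times = (nu - 1L):1L)
  i2 <- unlist(lapply(seq_len(nu - 1L), function(a) (a + 1L):nu))
  pi1 <- match(universe[i1], gm$ids)
  pi2 <- match(universe[i2], gm$ids)
  ki <- match(offspring_set, gm$ids)
  if (anyNA(c(pi1, pi2, ki))) {
    stop("dyad analysis references IDs absent from the genotype matrix",
         call. = FALSE)
  }
  pair_gd <- .pair_gd_matrix(gm$states, pi1, pi2, ki)$gd
  direct <- .plain_gd_matrix(gm$states, match(parent_candidates, gm$ids), ki)$gd

  # pair rows containing each candidate, and the partner in each such pair
  cand_pos <- match(parent_candidates, universe)
  rows_of <- lapply(cand_pos, function(a) which(i1 == a | i2 == a))
  partner_of <- lapply(seq_along(cand_pos), function(s) {
    a <- cand_pos[s]
    o <- ifelse(i1[rows_of[[s]]] == a, i2[rows_of[[s]]], i1[rows_of[[s]]])
    universe[o]
  })

  res <- vector("list", length(offspring_set))
  for (kk in seq_along(offspring_set)) {
    k <- offspring_set[kk]
    cand <- which(parent_candidates != k)
    gdm <- sigma <- gdcv <- rep(NA_real_, length(cand))
    gd_ik <- direct[cand, kk]
    for (a in seq_along(cand)) {
      ci <- cand[a]
      use <- partner_of[[ci]] %in% coparents
      g <- pair_gd[rows_of[[ci]][use], kk]
      g <- g[!is.na(g)]
      if (length(g) >= 1L) gdm[a] <- mean(g)
      if (length(g) >= 2L) {
        sigma[a] <- stats::sd(g)
        if (!is.na(gd_ik[a]) && gd_ik[a] > 0) gdcv[a] <- sigma[a] / gd_ik[a]
      }
    }
    if (anyNA(gdcv) && any(!is.na(gdm))) {
      nbad <- sum(!is.na(gdm) & is.na(gdcv))
      if (nbad > 0L) {
        warning(sprintf(
          "offspring %s: %d candidate(s) with undefined GDCV excluded from stage 2",
          k, nbad), call. = FALSE)
      }
    }

    z1 <- .normal_scores(gdm)
    z2 <- .normal_scores(gdcv)
    stage1 <- !is.na(z1) & z1 < z_lo
    stage2 <- stage1 & !is.na(z2) & z2 > z_hi
    if (all(is.na(z1)) && any(!is.na(gdm))) {
      warning(sprintf("offspring %s: degenerate (zero-spread) GDM set; no pairs flagged", k),
              call. = FALSE)
    }
    res[[kk]] <- data.frame(
      parent_id = parent_candidates[cand],
      offspring_id = k,
      gdm = gdm, gdm_z = z1, sigma_gd = sigma, gd_ik = gd_ik,
      gdcv = gdcv, gdcv_z = z2,
      cumulative_p = stats::pnorm(z1) * (1 - stats::pnorm(z2)),
      stage1_flag = stage1, stage2_flag = stage2,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.normal_scores <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) return(rep(NA_real_, length(x)))
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x[ok])) / s
}

.empty_dyad_frame <- function() {
  data.frame(parent_id = character(0), offspring_id = character(0),
             gdm = numeric(0), gdm_z = numeric(0), sigma_gd = numeric(0),
             gd_ik = numeric(0), gdcv = numeric(0), gdcv_z = numeric(0),
             cumulative_p = numeric(0), stage1_flag = logical(0),
             stage2_flag = logical(0), stringsAsFactors = FALSE)
}
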