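#' Enumerate candidate parent-pair/offspring triads
#'
#' Builds the exploratory triad space implied by the class keys: mother
#' candidates are individuals keyed Mo, Pa or All; father candidates Fa, Pa
#' or All; offspring candidates Off or All. Parent pairs are unordered with
#' mother != father, deduplicated when an individual qualifies for both
#' parental roles, and every offspring candidate is combined with every pair
#' — including the pair members themselves, which is flagged
#' (\code{self_overlap}) and can never be declared true. With all n
#' individuals keyed All the space therefore holds exactly
#' n * n * (n - 1) / 2 triads.
#'
#' @param roster A \code{genotype_matrix}, \code{raw_genotype_table}, or a
#'   data frame with columns \code{id} and \code{class}.
#' @return A data frame with columns \code{mother_id}, \code{father_id},
#'   \code{offspring_id}, \code{self_overlap}; the unique parent pairs and
#'   offspring candidates are attached as attributes \code{"pairs"} and
#'   \code{"offspring"}.
#' @export
enumerate_triads <- function(roster) {
  if (inherits(roster, "genotype_matrix") ||
      inherits(roster, "raw_genotype_table")) {
    ids <- roster$ids
    classes <- roster$classes
  } else {
    ids <- as.character(roster$id)
    classes <- as.character(roster$class)
  }
  mothers <- ids[classes %in% c("Mo", "Pa", "All")]
  fathers <- ids[classes %in% c("Fa", "Pa", "All")]
  offspring <- ids[classes %in% c("Off", "All")]
  if (length(mothers) == 0L) stop("no mother candidates (Mo/Pa/All) in roster",
                                  call. = FALSE)
  if (length(fathers) == 0L) stop("no father candidates (Fa/Pa/All) in roster",
                                  call. = FALSE)
  if (length(offspring) == 0L) stop("no offspring candidates (Off/All) in roster",
                                    call. = FALSE)

  pm <- rep(mothers, times = length(fathers))
  pf <- rep(fathers, each = length(mothers))
  keep <- pm != pf
  pm <- pm[keep]; pf <- pf[keep]
  key <- paste(pmin(pm, pf), pmax(pm, pf), sep = "\r")
  first <- !duplicated(key)
  pairs <- data.frame(mother_id = pm[first], father_id = pf[first],
                      stringsAsFactors = FALSE)

  np <- nrow(pairs); nk <- length(offspring)
  out <- data.frame(
    mother_id = rep(pairs$mother_id, each = nk),
    father_id = rep(pairs$father_id, each = nk),
    offspring_id = rep(offspring, times = np),
    stringsAsFactors = FALSE
  )
  out$self_overlap <- out$offspring_id == out$mother_id |
    out$offspring_id == out$father_id
  attr(out, "pairs") <- pairs
  attr(out, "offspring") <- offspring
  out
}

#' Score triads by expected-progeny Gower dissimilarity
#'
#' For every enumerated triad (i, j, k) computes GD between the expected
#' progeny of parents i and j and the genotype of potential offspring k,
#' along with the number of comparable (parental-homozygous, non-missing)
#' loci. Expected progenies are computed once per parent pair and reused
#' across all offspring; results are identical to per-triad recomputation
#' with [expected_progeny()] and [gower_dissimilarity()].
#'
#' @param gm A \code{genotype_matrix}.
#' @param triads Data frame from [enumerate_triads()].
#' @return The triad data frame augmented with \code{gd},
#'   \code{usable_loci}, \code{declared} (all \code{FALSE} until
#'   [declare_triads()]) and \code{p_value} (\code{NA}). Triads with no
#'   comparable loci carry \code{NA} GD and are excluded from ranking with a
#'   warning.
#' @export
score_triads <- function(gm, triads) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pairs <- attr(triads, "pairs")
  offspring <- attr(triads, "offspring")
  if (is.null(pairs) || is.null(offspring)) {
    pairs <- unique(triads[, c("mother_id", "father_id")])
    offspring <- unique(triads$offspring_id)
  }
  mi <- match(pairs$mother_id, gm$ids)
  fi <- match(pairs$father_id, gm$ids)
  ki <- match(offspring, gm$ids)
  if (anyNA(c(mi, fi, ki))) {
    stop("triad list references IDs absent from the genotype matrix",
         call. = FALSE)
  }
  eng <- .pair_gd_matrix(gm$states, mi, fi, ki)

  pr <- match(paste(triads$mother_id, triads$father_id),
              paste(pairs$mother_id, pairs$father_id))
  kc <- match(triads$offspring_id, offspring)
  idx <- cbind(pr, kc)
  out <- triads
  out$gd <- eng$gd[idx]
  out$usable_loci <- as.integer(eng$usable[idx])
  out$declared <- FALSE
  out$p_value <- NA_real_
  if (anyNA(out$gd)) {
    warning(sprintf(
      "%d triad(s) have no comparable loci; their GD is undefined and they are excluded from ranking",
      sum(is.na(out$gd))), call. = FALSE)
  }
  attr(out, "pairs") <- pairs
  attr(out, "offspring") <- offspring
  out
}

#' Locate the gap separating putative true triads from spurious ones
#'
#' Scans the ordered GD values below the \code{max_ident} ceiling for the
#' largest difference between adjacent values; the midpoint of that gap is
#' the declaration threshold. The significance of the gap relative to the
#' distribution of all adjacent-gap lengths in the scanned region is assessed
#' with a Dixon test on the largest gap. GD values at or above
#' \code{max_ident} cannot, by definition, belong to true triads and are
#' ignored here (they remain in the full triad table).
#'
#' @param gds Numeric GD values (unsorted is fine; \code{NA} dropped).
#' @param max_ident Search ceiling on GD (default 0.1).
#' @param nrep,seed Monte-Carlo settings passed to [dixon_test()].
#' @return An object of class \code{gap_result}: list with
#'   \code{determinable}, \code{threshold}, \code{gap_size}, \code{gap_p},
#'   \code{n_below}, \code{n_region} and \code{search_ceiling}. When fewer
#'   than 3 values fall below the ceiling the gap is undeterminable and no
#'   triads can be declared. Ties in gap size resolve to the lower-GD gap.
#' @export
find_gap <- function(gds, max_ident = 0.1, nrep = 10000L, seed = 1905L) {
  gds <- sort(gds[!is.na(gds)])
  region <- gds[gds < max_ident]
  if (length(region) < 3L) {
    return(structure(
      list(determinable = FALSE, threshold = NA_real_, gap_size = NA_real_,
           gap_p = NA_real_, n_below = 0L, n_region = length(region),
           search_ceiling = max_ident),
      class = "gap_result"
    ))
  }
  d <- diff(region)
  imax <- which.max(d)  # first maximum: ties resolve to the lower-GD gap
  threshold <- (region[imax] + region[imax + 1L]) / 2
  gap_p <- if (length(d) >= 3L) {
    dixon_test(d, position = "max", nrep = nrep, seed = seed)
  } else {
    NA_real_
  }
  structure(
    list(determinable = TRUE, threshold = threshold, gap_size = d[imax],
         gap_p = gap_p, n_below = sum(gds < threshold),
         n_region = length(region), search_ceiling = max_ident),
    class = "gap_result"
  )
}

#' @export
print.gap_result <- function(x, ...) {
  if (!x$determinable) {
    cat(sprintf("Gap undeterminable: %d GD value(s) below ceiling %.3g (>= 3 needed)\n",
                x$n_region, x$search_ceiling))
  } else {
    cat(sprintf(
      "Gap threshold %.6g (gap size %.6g, Dixon p %s); %d of %d in-region GDs below\n",
      x$threshold, x$gap_size,
      if (is.na(x$gap_p)) "NA" else format(x$gap_p, digits = 4),
      x$n_below, x$n_region))
  }
  invisible(x)
}

#' Declare significant triads below the gap threshold
#'
#' Gate 1: the gap itself must be a significant outlier among adjacent-gap
#' lengths (\code{gap_p <= alpha}); otherwise nothing is declared. Gate 2:
#' each below-threshold triad is tested individually — its GD is pooled with
#' the \code{comparison_sample} smallest above-gap GDs in the scanned region
#' (the most closely related spurious triads) and a Dixon test asks whether
#' it is an outlying minimum of that set. Triads whose offspring is one of
#' its own putative parents (\code{self_overlap}) are never declared.
#'
#' @param records Scored triad data frame from [score_triads()].
#' @param gap A \code{gap_result} from [find_gap()].
#' @param alpha Significance level (default 0.01, i.e. 99 percent confidence).
#' @param comparison_sample Number of above-gap GDs in the per-triad test set
#'   (default 30); when fewer are available all are used, with a warning.
#' @param nrep,seed Monte-Carlo settings passed to [dixon_test()].
#' @return \code{records} with \code{declared} and \code{p_value} filled in.
#' @export
declare_triads <- function(records, gap, alpha = 0.01, comparison_sample = 30L,
                           nrep = 10000L, seed = 1905L) {
  stopifnot(inherits(gap, "gap_result"))
  records$declared <- FALSE
  records$p_value <- NA_real_
  if (!gap$determinable || is.na(gap$gap_p) || gap$gap_p > alpha) {
    return(records)
  }
  gds <- records$gd
  above <- sort(gds[!is.na(gds) & gds > gap$threshold &
                      gds < gap$search_ceiling])
  if (length(above) < comparison_sample) {
    warning(sprintf(
      "only %d above-gap GD values available for the comparison sample (%d requested)",
      length(above), comparison_sample), call. = FALSE)
  }
  comp <- above[seq_len(min(comparison_sample, length(above)))]
  if (length(comp) < 2L) {
    warning("fewer than 2 above-gap GD values: no triads can be declared",
            call. = FALSE)
    return(records)
  }
  below <- which(!is.na(gds) & gds < gap$threshold)
  for (b in below) {
    p <- dixon_test(c(gds[b], comp), position = "min", nrep = nrep,
                    seed = seed)
    records$p_value[b] <- p
    records$declared[b] <- !records$self_overlap[b] && p <= alpha
  }
  # one parent pair per offspring: when several below-gap triads for the same
  # offspring pass the individual test, only the most identical (lowest GD,
  # then lowest p) hypothesis is declared; the others keep their p-values
  dec <- which(records$declared)
  if (length(dec) > 1L) {
    ord <- dec[order(records$gd[dec], records$p_value[dec])]
    keep <- ord[!duplicated(records$offspring_id[ord])]
    records$declared[setdiff(dec, keep)] <- FALSE
  }
  records
}
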