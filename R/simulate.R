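#' Configuration for a simulated pedigree population
#'
#' Defaults emulate a germplasm-collection validation design: 62 unrelated
#' founders plus 15 offspring in five full-sib families of three (77
#' individuals), 1000 bi-allelic SNPs, a per-call genotyping-error rate of
#' 1 percent and a missing-data rate of 11.8 percent. Founder allele
#' frequencies are drawn uniformly on \code{allele_freq_range}; the default
#' range (0.05, 0.95) yields an expected population heterozygosity of about
#' 36.5 percent under Hardy-Weinberg proportions.
#'
#' @param n_founders Number of unrelated founders.
#' @param n_families Number of full-sib families; each family's two parents
#'   are drawn from the founders without replacement, so full-sib confounders
#'   exist by construction.
#' @param sibs_per_family Offspring per family.
#' @param n_loci Number of bi-allelic SNP loci.
#' @param allele_freq_range Uniform range for per-locus founder allele
#'   frequencies.
#' @param missing_rate Independent per-call probability of a missing genotype.
#' @param error_rate Per-call probability that a genotype state is perturbed
#'   to an adjacent state (homozygote to heterozygote, heterozygote to either
#'   homozygote with equal probability; opposite homozygotes only arise via
#'   double perturbation, which this single-step model excludes).
#' @param remove_parents Optional data frame with columns \code{family}
#'   (1-based index) and \code{parent} ("mother" or "father"): these parents
#'   are excluded from the output table but retained in the truth.
#' @param generational_labels If \code{TRUE}, adults are keyed \code{Pa} and
#'   offspring \code{Off}; otherwise everyone is keyed \code{All}
#'   (no guiding information).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_founders = 62L, n_families = 5L,
                       sibs_per_family = 3L, n_loci = 1000L,
                       allele_freq_range = c(0.05, 0.95),
                       missing_rate = 0.118, error_rate = 0.01,
                       remove_parents = NULL, generational_labels = FALSE,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              n_loci = as.integer(n_loci),
              allele_freq_range = as.numeric(allele_freq_range),
              missing_rate = as.numeric(missing_rate),
              error_rate = as.numeric(error_rate),
              remove_parents = remove_parents,
              generational_labels = isTRUE(generational_labels),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_founders >= 2L, n_families >= 1L, sibs_per_family >= 1L,
              n_loci >= 1L,
              length(allele_freq_range) == 2L,
              allele_freq_range[1] > 0, allele_freq_range[2] < 1,
              allele_freq_range[1] <= allele_freq_range[2],
              missing_rate >= 0, missing_rate <= 1,
              error_rate >= 0, error_rate <= 1)
  })
  if (2L * cfg$n_families > cfg$n_founders) {
    stop("infeasible configuration: ", cfg$n_families,
         " families need ", 2L * cfg$n_families,
         " distinct parents but only ", cfg$n_founders,
         " founders are available", call. = FALSE)
  }
  if (!is.null(cfg$remove_parents)) {
    rp <- cfg$remove_parents
    stopifnot(is.data.frame(rp), all(c("family", "parent") %in% names(rp)),
              all(rp$family %in% seq_len(cfg$n_families)),
              all(rp$parent %in% c("mother", "father")))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a population with a known pedigree
#'
#' Founder genotypes are drawn locus-wise in Hardy-Weinberg proportions from
#' the configured allele-frequency distribution. Offspring are produced by
#' Mendelian transmission at the call level: each parent transmits one of its
#' two alleles, so two homozygous parents deterministically fix the offspring
#' state (matching the expected-progeny construction) while a heterozygous
#' parent transmits either allele with probability one half. Per-call
#' genotyping error and missingness are then applied independently.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{table} (a \code{raw_genotype_table}, with any
#'   removed parents excluded) and \code{truth} (class \code{sim_truth}: a
#'   data frame \code{trios} of mother/father/offspring IDs plus
#'   \code{removed}, the IDs excluded from the table).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    nf <- cfg$n_founders
    L <- cfg$n_loci
    n_off <- cfg$n_families * cfg$sibs_per_family

    p <- stats::runif(L, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
    founders <- matrix(
      stats::rbinom(nf * L, 2L, rep(p, each = nf)), nf, L
    )

    parent_rows <- sample.int(nf, 2L * cfg$n_families)
    mothers <- parent_rows[seq(1L, by = 2L, length.out = cfg$n_families)]
    fathers <- parent_rows[seq(2L, by = 2L, length.out = cfg$n_families)]

    transmit <- function(s) {
      # allele (0 or 1 copy of the B allele) transmitted by a parent state
      ifelse(s == 0L, 0L, ifelse(s == 2L, 1L, stats::rbinom(length(s), 1L, 0.5)))
    }
    off <- matrix(0L, n_off, L)
    fam_of <- rep(seq_len(cfg$n_families), each = cfg$sibs_per_family)
    for (o in seq_len(n_off)) {
      f <- fam_of[o]
      off[o, ] <- transmit(founders[mothers[f], ]) +
        transmit(founders[fathers[f], ])
    }

    states <- rbind(founders, off)
    n <- nrow(states)

    if (cfg$error_rate > 0) {
      hit <- matrix(stats::runif(n * L) < cfg$error_rate, n, L)
      het <- states == 1L
      to <- matrix(2L * stats::rbinom(n * L, 1L, 0.5), n, L)
      states[hit & het] <- to[hit & het]       # HET -> either HOM
      states[hit & !het] <- 1L                 # HOM -> HET
    }
    if (cfg$missing_rate > 0) {
      states[matrix(stats::runif(n * L) < cfg$missing_rate, n, L)] <- NA_integer_
    }

    founder_ids <- sprintf("F%02d", seq_len(nf))
    off_ids <- sprintf("Fam%d_Off%d", fam_of,
                       sequence(rep(cfg$sibs_per_family, cfg$n_families)))
    ids <- c(founder_ids, off_ids)

    classes <- if (cfg$generational_labels) {
      c(rep("Pa", nf), rep("Off", n_off))
    } else {
      rep("All", n)
    }

    # allele letters per locus; heterozygotes written in sorted order
    letters2 <- vapply(seq_len(L),
                       function(l) sort(sample(c("A", "C", "G", "T"), 2L)),
                       character(2))
    tok <- matrix("-/-", n, L)
    for (l in seq_len(L)) {
      a <- letters2[1L, l]; b <- letters2[2L, l]
      s <- states[, l]
      tok[!is.na(s) & s == 0L, l] <- paste0(a, "/", a)
      tok[!is.na(s) & s == 1L, l] <- paste0(a, "/", b)
      tok[!is.na(s) & s == 2L, l] <- paste0(b, "/", b)
    }
    dimnames(tok) <- list(ids, sprintf("L%04d", seq_len(L)))

    trios <- data.frame(
      mother_id = founder_ids[mothers][fam_of],
      father_id = founder_ids[fathers][fam_of],
      offspring_id = off_ids,
      stringsAsFactors = FALSE
    )

    removed <- character(0)
    if (!is.null(cfg$remove_parents)) {
      for (r in seq_len(nrow(cfg$remove_parents))) {
        f <- cfg$remove_parents$family[r]
        removed <- c(removed, if (cfg$remove_parents$parent[r] == "mother") {
          founder_ids[mothers[f]]
        } else {
          founder_ids[fathers[f]]
        })
      }
      removed <- unique(removed)
      keep <- !(ids %in% removed)
      tok <- tok[keep, , drop = FALSE]
      ids <- ids[keep]
      classes <- classes[keep]
    }

    list(
      table = new_raw_genotype_table(ids, classes, tok),
      truth = structure(list(trios = trios, removed = removed),
                        class = "sim_truth")
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d trios", nrow(x$trios)))
  if (length(x$removed) > 0L) {
    cat(sprintf("; removed from population: %s",
                paste(x$removed, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Score declared relationships against simulation truth
#'
#' Type I errors are declared records absent from the truth; Type II errors
#' are true relationships left undeclared; accuracy is
#' \code{100 * declared_true / (n_true + type1)}. Triad records (with
#' \code{mother_id}/\code{father_id} columns) are matched as unordered parent
#' pairs plus offspring. Dyad records (with a \code{parent_id} column) are
#' matched against all true (parent, offspring) pairs whose parent is present
#' in the population (i.e. not removed).
#'
#' @param declared Data frame of declared triads (rows with
#'   \code{declared == TRUE} are used if the column is present) or reported
#'   dyads (rows with \code{stage2_flag == TRUE} if present).
#' @param truth A \code{sim_truth}.
#' @return List with \code{type1}, \code{type2}, \code{accuracy},
#'   \code{n_true} and \code{n_declared}.
#' @export
score_against_truth <- function(declared, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if ("mother_id" %in% names(declared)) {
    if ("declared" %in% names(declared)) {
      declared <- declared[declared$declared, , drop = FALSE]
    }
    dk <- paste(pmin(declared$mother_id, declared$father_id),
                pmax(declared$mother_id, declared$father_id),
                declared$offspring_id)
    tk <- paste(pmin(truth$trios$mother_id, truth$trios$father_id),
                pmax(truth$trios$mother_id, truth$trios$father_id),
                truth$trios$offspring_id)
  } else if ("parent_id" %in% names(declared)) {
    if ("stage2_flag" %in% names(declared)) {
      declared <- declared[declared$stage2_flag, , drop = FALSE]
    }
    dk <- paste(declared$parent_id, declared$offspring_id)
    tr <- truth$trios
    tk <- c(paste(tr$mother_id, tr$offspring_id),
            paste(tr$father_id, tr$offspring_id))
    present <- !(c(tr$mother_id, tr$father_id) %in% truth$removed)
    tk <- tk[present]
  } else {
    stop("declared records are neither triads nor dyads", call. = FALSE)
  }
  n_true <- length(tk)
  if (n_true == 0L) stop("empty truth set", call. = FALSE)
  hits <- sum(dk %in% tk)
  type1 <- length(dk) - hits
  type2 <- n_true - sum(tk %in% dk)
  list(type1 = type1, type2 = type2,
       accuracy = 100 * hits / (n_true + type1),
       n_true = n_true, n_declared = length(dk))
}
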