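#' SNP-based parentage analysis without pedigree information
#'
#' Fits the full parentage model to a genotyped population: enumerates the
#' candidate triad space implied by the class keys, scores every triad by the
#' Gower dissimilarity between the parents' expected progeny and the
#' offspring, locates the gap separating true from spurious triads among the
#' ordered dissimilarities, declares individually significant triads with
#' Dixon outlier tests, and (optionally) runs the two-stage GDM/GDCV dyad
#' analysis for offspring left unresolved, identifying a likely single parent
#' when the other parent is absent from the population.
#'
#' @param genotypes A file path, a \code{raw_genotype_table}, or a
#'   \code{genotype_matrix}.
#' @param max_ident Ceiling on GD for gap detection and significance testing
#'   (default 0.1): triads with larger GD cannot be declared true.
#' @param alpha Significance level for the gap and per-triad Dixon tests
#'   (default 0.01, i.e. 99 percent confidence).
#' @param dyad When to run the dyad analysis: \code{"auto"} (offspring with
#'   no declared triad; the default), \code{"always"} (all offspring), or
#'   \code{"never"}.
#' @param dyad_confidence Confidence level for the dyad normal-score tests
#'   (default 0.99).
#' @param comparison_sample Number of above-gap GDs pooled into each
#'   per-triad Dixon test (default 30).
#' @param seed Seed for the Dixon Monte-Carlo null distributions; fixes all
#'   randomness of the analysis.
#' @param nrep Monte-Carlo replicates for Dixon p-values (default 10000).
#' @param drop_monomorphic Passed to [encode_genotypes()].
#' @param verbose Emit progress messages.
#' @return An object of class \code{parentage}; see
#'   [print.parentage()] and [summary.parentage()]. Key components:
#'   \code{triads} (all scored triads), \code{gap} (the gap analysis),
#'   \code{declared} (significant triads), \code{dyads} (all dyad records or
#'   \code{NULL}), \code{dyad_reported} (pairs passing both dyad stages),
#'   \code{qc} (per-individual mean GD and usable-locus diagnostics).
#' @examples
#' sim <- simulate_population(sim_config(n_founders = 14, n_families = 2,
#'                                       n_loci = 300, seed = 7))
#' fit <- parentage(sim$table)
#' fit
#' score_against_truth(fit$declared, sim$truth)
#' @export
parentage <- function(genotypes, max_ident = 0.1, alpha = 0.01,
                      dyad = c("auto", "always", "never"),
                      dyad_confidence = 0.99, comparison_sample = 30L,
                      seed = 1905L, nrep = 10000L, drop_monomorphic = FALSE,
                      verbose = FALSE) {
  dyad <- match.arg(dyad)
  stopifnot(max_ident > 0, max_ident <= 1, alpha > 0, alpha < 1,
            dyad_confidence > 0, dyad_confidence < 1, comparison_sample >= 2)
  t0 <- proc.time()[["elapsed"]]

  if (is.character(genotypes)) genotypes <- read_genotype_table(genotypes)
  gm <- if (inherits(genotypes, "genotype_matrix")) {
    genotypes
  } else {
    encode_genotypes(genotypes, drop_monomorphic = drop_monomorphic)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("encoded %d individuals x %d loci (%d loci dropped)",
      nrow(gm$states), ncol(gm$states), nrow(gm$dropped))

  triads <- enumerate_triads(gm)
  say("enumerated %d triads (%d parent pairs x %d offspring candidates)",
      nrow(triads), nrow(attr(triads, "pairs")),
      length(attr(triads, "offspring")))
  records <- score_triads(gm, triads)

  gap <- find_gap(records$gd, max_ident = max_ident, nrep = nrep, seed = seed)
  records <- declare_triads(records, gap, alpha = alpha,
                            comparison_sample = comparison_sample,
                            nrep = nrep, seed = seed)
  records <- records[order(records$gd, na.last = TRUE), ]
  rownames(records) <- NULL
  declared <- records[records$declared, , drop = FALSE]
  say("gap %s; %d triad(s) declared",
      if (gap$determinable) sprintf("at %.6g (p = %.4g)", gap$threshold,
                                    gap$gap_p) else "undeterminable",
      nrow(declared))

  offspring <- attr(triads, "offspring")
  dyads <- NULL
  dyad_offspring <- character(0)
  if (dyad != "never") {
    dyad_offspring <- if (dyad == "always") {
      offspring
    } else {
      setdiff(offspring, declared$offspring_id)
    }
    parent_candidates <- union(attr(triads, "pairs")$mother_id,
                               attr(triads, "pairs")$father_id)
    if (length(dyad_offspring) > 0L) {
      say("dyad analysis for %d offspring against %d candidate parents",
          length(dyad_offspring), length(parent_candidates))
      dyads <- run_dyad(gm, dyad_offspring, parent_candidates,
                        confidence = dyad_confidence)
    }
  }
  dyad_reported <- if (is.null(dyads)) {
    NULL
  } else {
    dyads[dyads$stage2_flag, , drop = FALSE]
  }

  fit <- structure(list(
    call = match.call(),
    genotypes = gm,
    params = list(max_ident = max_ident, alpha = alpha, dyad = dyad,
                  dyad_confidence = dyad_confidence,
                  comparison_sample = comparison_sample, seed = seed,
                  nrep = nrep),
    n_triads = nrow(records),
    triads = records,
    gap = gap,
    declared = declared,
    dyad_offspring = dyad_offspring,
    dyads = dyads,
    dyad_reported = dyad_reported,
    qc = .parentage_qc(records),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "parentage")
  say("completed in %.1f s", fit$elapsed)
  fit
}

# Per-individual QC over the scored triad table: mean GD and mean usable-locus
# count across all triads an individual takes part in. Individuals more than
# 3 sd below the population mean on either metric are flagged; such
# individuals (e.g. degraded samples) are candidates for culling.
.parentage_qc <- function(records) {
  ind <- c(records$mother_id, records$father_id, records$offspring_id)
  gd <- rep(records$gd, 3L)
  ul <- rep(records$usable_loci, 3L)
  mean_gd <- tapply(gd, ind, mean, na.rm = TRUE)
  mean_ul <- tapply(ul, ind, mean, na.rm = TRUE)
  qc <- data.frame(id = names(mean_gd), mean_gd = as.numeric(mean_gd),
                   mean_usable = as.numeric(mean_ul),
                   stringsAsFactors = FALSE)
  flag <- function(x) x < mean(x, na.rm = TRUE) - 3 * stats::sd(x, na.rm = TRUE)
  qc$low_gd_flag <- flag(qc$mean_gd)
  qc$low_usable_flag <- flag(qc$mean_usable)
  rownames(qc) <- NULL
  qc
}

#' @export
print.parentage <- function(x, ...) {
  cat("SNP-based parentage analysis\n")
  cat(sprintf("  population: %d individuals x %d loci\n",
              nrow(x$genotypes$states), ncol(x$genotypes$states)))
  cat(sprintf("  triads explored: %d\n", x$n_triads))
  if (x$gap$determinable) {
    cat(sprintf("  gap threshold: %.6g (gap %.6g, Dixon p %s)\n",
                x$gap$threshold, x$gap$gap_size,
                if (is.na(x$gap$gap_p)) "NA" else
                  format(x$gap$gap_p, digits = 4)))
  } else {
    cat(sprintf("  gap undeterminable (only %d GDs below MaxIdent %.3g)\n",
                x$gap$n_region, x$gap$search_ceiling))
  }
  cat(sprintf("  triads declared true at alpha %.3g: %d\n",
              x$params$alpha, nrow(x$declared)))
  if (!is.null(x$dyads)) {
    cat(sprintf("  dyad analysis (%d offspring): %d pair(s) reported at %.3g confidence\n",
                length(x$dyad_offspring), nrow(x$dyad_reported),
                x$params$dyad_confidence))
  }
  invisible(x)
}

#' Summarise a parentage fit
#'
#' @param object A \code{parentage} fit.
#' @param ... Unused.
#' @return \code{object}, invisibly, after printing declared triads, reported
#'   dyads and QC flags.
#' @export
summary.parentage <- function(object, ...) {
  print(object)
  if (nrow(object$declared) > 0L) {
    cat("\nDeclared triads (mother, father, offspring, GD, p):\n")
    d <- object$declared
    for (r in seq_len(nrow(d))) {
      cat(sprintf("  %s x %s -> %s  GD=%.6g  p=%.4g\n",
                  d$mother_id[r], d$father_id[r], d$offspring_id[r],
                  d$gd[r], d$p_value[r]))
    }
  }
  if (!is.null(object$dyad_reported) && nrow(object$dyad_reported) > 0L) {
    cat("\nReported dyads (parent -> offspring, GDM z, GDCV z, cumulative p):\n")
    d <- object$dyad_reported
    for (r in seq_len(nrow(d))) {
      cat(sprintf("  %s -> %s  z1=%.2f  z2=%.2f  p=%.3g\n",
                  d$parent_id[r], d$offspring_id[r], d$gdm_z[r],
                  d$gdcv_z[r], d$cumulative_p[r]))
    }
  }
  qc <- object$qc[object$qc$low_gd_flag | object$qc$low_usable_flag, ,
                  drop = FALSE]
  if (nrow(qc) > 0L) {
    cat("\nQC: individuals > 3 sd below the population mean (consider culling):\n")
    for (r in seq_len(nrow(qc))) {
      cat(sprintf("  %s  mean GD %.4g  mean usable loci %.1f\n",
                  qc$id[r], qc$mean_gd[r], qc$mean_usable[r]))
    }
  }
  invisible(object)
}

#' Diagnostic plots for a parentage fit
#'
#' \code{which = "triad"} draws the ordered GD values for all scored triads
#' with the MaxIdent ceiling and, when determinable, the gap threshold;
#' declared triads are highlighted. \code{which = "dyad"} draws, for each
#' offspring analysed, its candidates' GDM and GDCV values with reported
#' parents highlighted.
#'
#' @param x A \code{parentage} fit.
#' @param which \code{"triad"} or \code{"dyad"}.
#' @param ... Passed to the underlying plot call.
#' @return \code{x}, invisibly.
#' @export
plot.parentage <- function(x, which = c("triad", "dyad"), ...) {
  which <- match.arg(which)
  if (which == "triad") {
    gd <- sort(x$triads$gd[!is.na(x$triads$gd)])
    col <- ifelse(gd < ifelse(x$gap$determinable, x$gap$threshold, -Inf),
                  "firebrick", "grey40")
    graphics::plot(seq_along(gd), gd, pch = 20, cex = 0.5, col = col,
                   xlab = "triad rank", ylab = "Gower dissimilarity", ...)
    graphics::abline(h = x$gap$search_ceiling, lty = 3, col = "grey60")
    if (x$gap$determinable) {
      graphics::abline(h = x$gap$threshold, lty = 2, col = "firebrick")
    }
  } else {
    if (is.null(x$dyads) || nrow(x$dyads) == 0L) {
      stop("no dyad analysis in this fit", call. = FALSE)
    }
    d <- x$dyads
    ko <- factor(d$offspring_id)
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    for (stat in c("gdm", "gdcv")) {
      graphics::plot(jitter(as.integer(ko)), d[[stat]],
                     pch = 20, cex = 0.6,
                     col = ifelse(d$stage2_flag, "firebrick", "grey40"),
                     xaxt = "n", xlab = "offspring", ylab = toupper(stat), ...)
      graphics::axis(1, at = seq_along(levels(ko)), labels = levels(ko),
                     las = 2, cex.axis = 0.6)
    }
  }
  invisible(x)
}

#' Write the three result tables of a parentage fit
#'
#' Writes \code{Triad-All.tsv} (every scored triad, sorted by GD),
#' \code{Triad-Sig.tsv} (declared triads only) and, when a dyad analysis was
#' run, \code{Dyad-Sig.tsv} (pairs passing both dyad stages).
#'
#' @param fit A \code{parentage} fit.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_results <- function(fit, dir = ".", prefix = "") {
  stopifnot(inherits(fit, "parentage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    write_triad_table(fit$triads, file.path(dir, paste0(prefix, "Triad-All.tsv")),
                      which = "all"),
    write_triad_table(fit$triads, file.path(dir, paste0(prefix, "Triad-Sig.tsv")),
                      which = "significant")
  )
  if (!is.null(fit$dyads)) {
    paths <- c(paths,
               write_dyad_table(fit$dyads,
                                file.path(dir, paste0(prefix, "Dyad-Sig.tsv"))))
  }
  invisible(paths)
}

#' Run a parentage analysis end to end, writing result files and a log
#'
#' Thin driver around [parentage()] and [write_results()] for scripted and
#' command-line use: reads the input table, runs the triad and (optionally)
#' dyad analyses, writes the result tables, optionally writes diagnostic
#' plots, and logs locus counts, the gap location/size/p-value and
#' declaration counts. A run that declares nothing still succeeds; on error,
#' partial output files are removed.
#'
#' @param input Path to a genotype table.
#' @param output_dir Output directory.
#' @param plots Also write diagnostic PNG plots (default \code{FALSE}).
#' @param prefix File-name prefix for outputs.
#' @param quiet Suppress log messages.
#' @inheritParams parentage
#' @return Invisibly, the \code{parentage} fit.
#' @export
run_parentage <- function(input, output_dir = ".", max_ident = 0.1,
                          alpha = 0.01, dyad = c("auto", "always", "never"),
                          dyad_confidence = 0.99, comparison_sample = 30L,
                          seed = 1905L, nrep = 10000L, plots = FALSE,
                          prefix = "", quiet = FALSE) {
  dyad <- match.arg(dyad)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  fit <- parentage(input, max_ident = max_ident, alpha = alpha, dyad = dyad,
                   dyad_confidence = dyad_confidence,
                   comparison_sample = comparison_sample, seed = seed,
                   nrep = nrep, verbose = !quiet)
  written <- write_results(fit, output_dir, prefix = prefix)
  if (plots) {
    p <- file.path(output_dir, paste0(prefix, "triad-gd.png"))
    grDevices::png(p, width = 900, height = 600)
    plot(fit, which = "triad")
    grDevices::dev.off()
    written <- c(written, p)
    if (!is.null(fit$dyads) && nrow(fit$dyads) > 0L) {
      p <- file.path(output_dir, paste0(prefix, "dyad-stats.png"))
      grDevices::png(p, width = 1200, height = 600)
      plot(fit, which = "dyad")
      grDevices::dev.off()
      written <- c(written, p)
    }
  }
  if (!quiet) {
    message(sprintf("wrote: %s", paste(basename(written), collapse = ", ")))
  }
  ok <- TRUE
  invisible(fit)
}
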