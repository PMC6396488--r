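#' Read a class-annotated SNP genotype table
#'
#' Reads the tab-delimited genotype format used throughout the package: no
#' header row; column 1 is the individual ID, column 2 a classification key,
#' and columns 3+ one bi-allelic SNP genotype per column written as
#' \code{"X/Y"}, with missing data coded \code{"-/-"}. The classification key
#' controls the role(s) an individual may play in the analysis:
#' \describe{
#'   \item{Mo}{potential mother only}
#'   \item{Fa}{potential father only}
#'   \item{Pa}{potential parent, both mother and father}
#'   \item{Off}{potential offspring only}
#'   \item{All}{potential mother, father and offspring}
#' }
#'
#' @param path Path to a tab-delimited genotype file.
#' @return An object of class \code{raw_genotype_table}: a list with
#'   \code{ids}, \code{classes} and a character matrix \code{genotypes}
#'   (individuals x loci). Loci are named \code{L0001, L0002, ...} in column
#'   order since the format carries no locus names.
#' @seealso [encode_genotypes()], [write_genotype_table()]
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty genotype file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf(
      "ragged genotype table: line %d has %d tab-delimited fields, expected %d",
      bad, nf[bad], nf[1L]
    ), call. = FALSE)
  }
  if (nf[1L] < 3L) {
    stop("each row needs an ID, a class key, and at least one genotype column",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  ids <- m[, 1L]
  classes <- m[, 2L]
  gen <- m[, -(1:2), drop = FALSE]

  bad_class <- which(!(classes %in% .class_keys))
  if (length(bad_class) > 0L) {
    stop(sprintf(
      "unknown class key '%s' for individual '%s' (line %d); expected one of %s",
      classes[bad_class[1L]], ids[bad_class[1L]], bad_class[1L],
      paste(.class_keys, collapse = ", ")
    ), call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated individual ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  ok <- gen == "-/-" |
    (grepl("^[^/]+/[^/]+$", gen) & !grepl("-", gen, fixed = TRUE))
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf(
      "malformed genotype token '%s' (individual '%s', locus column %d)",
      gen[bad], ids[(bad - 1L) %% nrow(gen) + 1L], (bad - 1L) %/% nrow(gen) + 1L
    ), call. = FALSE)
  }
  dimnames(gen) <- list(ids, sprintf("L%04d", seq_len(ncol(gen))))
  new_raw_genotype_table(ids, classes, gen)
}

.class_keys <- c("Mo", "Fa", "Off", "Pa", "All")

new_raw_genotype_table <- function(ids, classes, genotypes) {
  structure(
    list(ids = as.character(ids), classes = as.character(classes),
         genotypes = genotypes),
    class = "raw_genotype_table"
  )
}

#' Write a genotype table in the package input format
#'
#' Inverse of [read_genotype_table()]: writes the tab-delimited, headerless
#' format so that a read/write/read round trip reproduces IDs, class keys and
#' genotype tokens exactly. Used mainly to persist simulated populations.
#'
#' @param table A \code{raw_genotype_table}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "raw_genotype_table"))
  rows <- paste(table$ids, table$classes,
                apply(table$genotypes, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.raw_genotype_table <- function(x, ...) {
  cat(sprintf("SNP genotype table: %d individuals x %d loci\n",
              length(x$ids), ncol(x$genotypes)))
  tab <- table(factor(x$classes, levels = .class_keys))
  cat("class keys:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Encode genotype tokens into three states plus missing
#'
#' Determines the (at most two) alleles observed at each locus and maps each
#' token to one of three states: 0 (homozygous for the first allele), 1
#' (heterozygous) and 2 (homozygous for the second allele), with \code{NA}
#' for missing calls. The first allele is the lexicographically smaller of
#' the two observed; heterozygotes are unordered (\code{"A/T"} and
#' \code{"T/A"} encode identically). All downstream dissimilarities are
#' invariant to the allele ordering. Loci with more than two observed alleles
#' or no non-missing call are dropped with a warning. Monomorphic loci
#' (a single observed allele) are retained by default: they are homozygous in
#' every parent and always match, so they dilute but never flip a comparison.
#'
#' Heterozygosity of any dosage collapses to the single heterozygous state,
#' so polyploid data are handled without a dosage model.
#'
#' @param table A \code{raw_genotype_table} from [read_genotype_table()].
#' @param drop_monomorphic Drop loci with a single observed allele
#'   (default \code{FALSE}).
#' @return An object of class \code{genotype_matrix}: list with \code{ids},
#'   \code{classes}, numeric matrix \code{states} (individuals x loci, values
#'   0/1/2/NA), 2 x loci character matrix \code{alleles}, and a data frame
#'   \code{dropped} describing removed loci.
#' @export
encode_genotypes <- function(table, drop_monomorphic = FALSE) {
  stopifnot(inherits(table, "raw_genotype_table"))
  gen <- table$genotypes
  n <- nrow(gen)
  L <- ncol(gen)
  miss <- gen == "-/-"
  a1 <- matrix(sub("/.*$", "", gen), n, L)
  a2 <- matrix(sub("^.*/", "", gen), n, L)

  states <- matrix(NA_real_, n, L, dimnames = dimnames(gen))
  alleles <- matrix(NA_character_, 2L, L,
                    dimnames = list(c("A", "B"), colnames(gen)))
  drop_reason <- character(0)
  drop_locus <- character(0)

  for (l in seq_len(L)) {
    obs <- !miss[, l]
    u <- sort(unique(c(a1[obs, l], a2[obs, l])))
    if (length(u) == 0L) {
      drop_locus <- c(drop_locus, colnames(gen)[l])
      drop_reason <- c(drop_reason, "no non-missing call")
      next
    }
    if (length(u) > 2L) {
      drop_locus <- c(drop_locus, colnames(gen)[l])
      drop_reason <- c(drop_reason, "more than two alleles")
      next
    }
    if (length(u) == 1L && drop_monomorphic) {
      drop_locus <- c(drop_locus, colnames(gen)[l])
      drop_reason <- c(drop_reason, "monomorphic")
      next
    }
    A <- u[1L]
    alleles[, l] <- c(A, if (length(u) == 2L) u[2L] else NA_character_)
    # count of non-A alleles: 0 = hom A, 1 = het, 2 = hom B
    states[obs, l] <- (a1[obs, l] != A) + (a2[obs, l] != A)
  }

  keep <- !(colnames(gen) %in% drop_locus)
  if (!any(keep)) stop("no usable loci after encoding", call. = FALSE)
  if (length(drop_locus) > 0L) {
    warning(sprintf("dropped %d of %d loci during encoding (%s)",
                    length(drop_locus), L,
                    paste(sprintf("%s: %s", drop_locus, drop_reason),
                          collapse = "; ")),
            call. = FALSE)
  }

  structure(
    list(ids = table$ids, classes = table$classes,
         states = states[, keep, drop = FALSE],
         alleles = alleles[, keep, drop = FALSE],
         dropped = data.frame(locus = drop_locus, reason = drop_reason,
                              stringsAsFactors = FALSE)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  s <- x$states
  cat(sprintf("Encoded genotype matrix: %d individuals x %d loci\n",
              nrow(s), ncol(s)))
  cat(sprintf("heterozygous %.1f%%, missing %.1f%% of calls; %d loci dropped\n",
              100 * mean(s == 1, na.rm = TRUE), 100 * mean(is.na(s)),
              nrow(x$dropped)))
  invisible(x)
}

.match_id <- function(gm, id) {
  i <- match(id, gm$ids)
  if (is.na(i)) stop("unknown individual ID: ", id, call. = FALSE)
  i
}
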