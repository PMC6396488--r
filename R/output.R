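.fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "", format(signif(x, digits), trim = TRUE,
                              scientific = FALSE, drop0trailing = TRUE))
}

#' Write a triad result table
#'
#' Tab-delimited, sorted ascending by GD (undefined GDs last). The
#' \code{"all"} variant contains every enumerated triad, with the p-value
#' column empty for triads that were not declared; the \code{"significant"}
#' variant contains only declared triads. GD and p-values are written with 6
#' significant digits.
#'
#' @param records Scored (and optionally declared) triad data frame.
#' @param path Output file path.
#' @param which \code{"all"} or \code{"significant"}.
#' @return Invisibly, \code{path}.
#' @export
write_triad_table <- function(records, path, which = c("all", "significant")) {
  which <- match.arg(which)
  if (which == "significant") {
    records <- records[!is.na(records$declared) & records$declared, ,
                       drop = FALSE]
  }
  records <- records[order(records$gd, na.last = TRUE), , drop = FALSE]
  out <- data.frame(
    MotherID = records$mother_id,
    FatherID = records$father_id,
    OffspringID = records$offspring_id,
    GD = .fmt_num(records$gd),
    UsableLoci = records$usable_loci,
    Pvalue = if (which == "all") {
      ifelse(records$declared, .fmt_num(records$p_value), "")
    } else {
      .fmt_num(records$p_value)
    },
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the significant dyad result table
#'
#' Tab-delimited; one row per (parent, offspring) pair passing both dyad
#' stages, with the GDM and GDCV statistics, their normal scores, and the
#' cumulative p-value.
#'
#' @param records Dyad data frame from [run_dyad()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_dyad_table <- function(records, path) {
  if (nrow(records) > 0L && "stage2_flag" %in% names(records)) {
    records <- records[records$stage2_flag, , drop = FALSE]
  }
  records <- records[order(records$cumulative_p), , drop = FALSE]
  out <- data.frame(
    ParentID = records$parent_id,
    OffspringID = records$offspring_id,
    GDM = .fmt_num(records$gdm),
    GDMNormalScore = .fmt_num(records$gdm_z),
    GDCV = .fmt_num(records$gdcv),
    GDCVNormalScore = .fmt_num(records$gdcv_z),
    CumulativePvalue = .fmt_num(records$cumulative_p),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
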