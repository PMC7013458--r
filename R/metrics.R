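# Headline specificity metrics: specificity factor (on/off ratio), residual
# on-target activity and off-target reduction versus a reference construct.
# Rounding is half away from zero: 1 decimal for ratios, integers for
# percentages, matching how such summaries are conventionally printed.

#' Specificity factor
#'
#' Ratio of average on-target to average off-target methylation, the single
#' number summarizing how strongly an EpiEditor prefers its target (e.g.
#' on 84% / off 53% gives 1.6).
#'
#' @param on_pct average on-target methylation (percent)
#' @param off_pct average off-target methylation (percent)
#' @return ratio rounded half away from zero to 1 decimal; `Inf` with a
#'   `capped` attribute when `off_pct` is 0
#' @export
specificity_factor <- function(on_pct, off_pct) {
  stopifnot(on_pct >= 0, off_pct >= 0)
  if (off_pct == 0) {
    out <- Inf
    attr(out, "capped") <- TRUE
    return(out)
  }
  round_half_away(on_pct / off_pct, 1)
}

#' Residual on-target activity
#'
#' A mutant's on-target methylation as a percentage of the reference
#' (wild-type) construct's.
#'
#' @param mut_on_pct mutant on-target methylation (percent)
#' @param ref_on_pct reference on-target methylation (percent)
#' @return percent, rounded half away from zero to integer
#' @export
residual_activity <- function(mut_on_pct, ref_on_pct) {
  if (ref_on_pct <= 0)
    stop("residual activity undefined for zero reference", call. = FALSE)
  round_half_away(100 * mut_on_pct / ref_on_pct, 0)
}

#' Off-target reduction
#'
#' Percent reduction of off-target methylation relative to the reference;
#' negative values indicate an increase.
#'
#' @param mut_off_pct mutant off-target methylation (percent)
#' @param ref_off_pct reference off-target methylation (percent)
#' @return percent, rounded half away from zero to integer
#' @export
off_target_reduction <- function(mut_off_pct, ref_off_pct) {
  if (ref_off_pct <= 0)
    stop("off-target reduction undefined for zero reference", call. = FALSE)
  round_half_away(100 * (1 - mut_off_pct / ref_off_pct), 0)
}

#' Build a specificity report table
#'
#' One row per sample with specificity factor, residual activity and
#' off-target reduction versus the named reference sample.
#'
#' @param summaries data.frame with columns `sample`, `on_pct`, `off_pct` (or
#'   a TSV path)
#' @param reference reference sample name (must be a row of `summaries`)
#' @return data.frame: sample, on_target_pct, off_target_pct,
#'   specificity_factor, residual_activity_pct, off_target_reduction_pct
#' @export
build_report <- function(summaries, reference) {
  if (is.character(summaries)) summaries <- read_tsv_table(summaries)
  stopifnot(all(c("sample", "on_pct", "off_pct") %in% names(summaries)))
  if (nrow(summaries) == 0L)
    return(data.frame(sample = character(), on_target_pct = numeric(),
                      off_target_pct = numeric(),
                      specificity_factor = numeric(),
                      residual_activity_pct = numeric(),
                      off_target_reduction_pct = numeric()))
  ref <- summaries[summaries$sample == reference, , drop = FALSE]
  if (nrow(ref) != 1L)
    stop("reference sample '", reference, "' not found exactly once",
         call. = FALSE)
  data.frame(
    sample = summaries$sample,
    on_target_pct = summaries$on_pct,
    off_target_pct = summaries$off_pct,
    specificity_factor = vapply(seq_len(nrow(summaries)), function(i)
      as.numeric(specificity_factor(summaries$on_pct[i],
                                    summaries$off_pct[i])), numeric(1)),
    residual_activity_pct = vapply(summaries$on_pct, residual_activity,
                                   numeric(1), ref_on_pct = ref$on_pct),
    off_target_reduction_pct = vapply(summaries$off_pct, off_target_reduction,
                                      numeric(1), ref_off_pct = ref$off_pct))
}

#' Export a specificity report as JSON
#'
#' @param report [build_report()] result
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
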