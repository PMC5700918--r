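#' Behavioural metrics of a bioassay table
#'
#' Computes the per-plant behavioural proportions from classified larval
#' counts:
#' * `survival` — larvae recovered alive / larvae released ("unrecovered"
#'   jointly absorbs death and escape);
#' * `host_acceptance` — recovered larvae found on the plant;
#' * `dispersal_rate` — recovered larvae found off the plant;
#' * `pfd` — post-feeding dispersal: recovered larvae that fed and were
#'   found off the plant;
#' * `ifp` — recovered larvae that fed and were found on the plant.
#'
#' With `denominator_mode = "recovered"` (the default) the last four
#' metrics are proportions of recovered-alive larvae, which keeps the
#' on/off categories complementary (`host_acceptance + dispersal_rate = 1`
#' whenever any larva is recovered). `"released"` divides everything by
#' the number released instead. When a plant recovers no larvae the
#' recovered-based metrics are `NA`, never 0/0.
#'
#' @param records bioassay table as returned by [generate_bioassay()] or
#'   [read_bioassay_csv()].
#' @param denominator_mode `"recovered"` or `"released"`.
#' @return data.frame keyed by `block`, `strain`, `variety`, `interval_h`
#'   with columns `released`, `recovered`, `survival`, `host_acceptance`,
#'   `dispersal_rate`, `pfd`, `ifp`.
#' @export
compute_metrics <- function(records,
                            denominator_mode = c("recovered", "released")) {
  denominator_mode <- match.arg(denominator_mode)
  validate_bioassay(records)
  on_all <- records$on_fed + records$on_notfed
  off_all <- records$off_fed + records$off_notfed
  recovered <- on_all + off_all
  denom <- if (denominator_mode == "recovered") recovered
           else records$released
  denom <- ifelse(denom == 0, NA_real_, denom)
  data.frame(
    records[intersect(c("block", "strain", "variety", "interval_h"),
                      names(records))],
    released = records$released,
    recovered = recovered,
    survival = recovered / records$released,
    host_acceptance = on_all / denom,
    dispersal_rate = off_all / denom,
    pfd = records$off_fed / denom,
    ifp = records$on_fed / denom,
    stringsAsFactors = FALSE)
}

#' Validate a bioassay table
#'
#' Checks schema, non-negative counts, and the exact five-category count
#' conservation identity `on_fed + on_notfed + off_fed + off_notfed +
#' unrecovered == released` on every row.
#'
#' @param records data.frame to validate.
#' @return `records`, invisibly; offending row numbers are listed in the
#'   error message otherwise.
#' @export
validate_bioassay <- function(records) {
  cols <- c("strain", "variety", "interval_h", "released", "on_fed",
            "on_notfed", "off_fed", "off_notfed", "unrecovered")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    abort("bioassay table is missing columns: ",
          paste(missing, collapse = ", "))
  if (nrow(records) == 0) abort("bioassay table is empty")
  countcols <- c("released", "on_fed", "on_notfed", "off_fed",
                 "off_notfed", "unrecovered")
  counts <- as.matrix(records[countcols])
  if (anyNA(counts) || any(counts < 0))
    abort("counts must be non-negative and non-missing")
  total <- rowSums(counts[, -1, drop = FALSE])
  bad <- which(total != records$released)
  if (length(bad))
    abort("count conservation violated (categories must sum to released) ",
          "in rows: ", paste(bad, collapse = ", "))
  invisible(records)
}
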