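#' Read a long-format UPDRS-III item table
#'
#' Expected columns: \code{patient, med_state, stim_state, item, side,
#' score}, with lateralized items 20--26 carrying \code{side} "left"/"right"
#' and axial items 27--31 carrying \code{side} "axial".
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_updrs <- function(path) {
  if (!file.exists(path)) stopf("UPDRS file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "med_state", "stim_state", "item", "side", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("UPDRS table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(df$score < 0)) stopf("negative UPDRS item score")
  if (any(df$item < 18 | df$item > 31)) stopf("item number outside 18-31")
  df
}

item_groups <- list(tremor = 20:21, brady_rigidity = 22:26, axial = 27:31)

#' Hemibody subscores from one exam
#'
#' Sums item scores into the three symptom-domain subscores: tremor (items
#' 20--21) and bradykinesia-rigidity (items 22--26) per hemibody, axial
#' (items 27--31) once (identical across hemibodies). Missing required
#' items raise an error; nothing is imputed.
#'
#' @param exam data.frame of one (patient, med_state, stim_state) exam with
#'   columns \code{item, side, score}.
#' @return data.frame with one row per hemibody and columns
#'   \code{hemibody, tremor, brady_rigidity, axial}.
#' @export
updrs_subscores <- function(exam) {
  sum_items <- function(items, side) {
    rows <- exam[exam$item %in% items & exam$side == side, , drop = FALSE]
    got <- sort(unique(rows$item))
    if (!identical(got, as.integer(sort(items))))
      stopf("missing item(s) %s for side '%s'",
            paste(setdiff(items, got), collapse = ","), side)
    sum(rows$score)
  }
  ax <- sum_items(item_groups$axial, "axial")
  do.call(rbind, lapply(c("left", "right"), function(h) {
    data.frame(hemibody = h,
               tremor = sum_items(item_groups$tremor, h),
               brady_rigidity = sum_items(item_groups$brady_rigidity, h),
               axial = ax,
               stringsAsFactors = FALSE)
  }))
}

#' Stimulation efficacy for one domain
#'
#' Percent improvement from stimulation with medication withdrawn:
#' \code{100 * (OFF_stim - ON_stim) / OFF_stim}. A zero OFF-stim baseline
#' leaves the efficacy undefined and flags the record excluded. Negative
#' values (worsening on stimulation) are retained.
#'
#' @param off_score OFF-stimulation (med-OFF) subscore.
#' @param on_score ON-stimulation (med-OFF) subscore.
#' @param domain \code{"tremor"}, \code{"brady_rigidity"} or \code{"axial"}.
#' @param side STN side or hemibody identifier carried into the result.
#' @return list with \code{side, domain, value} (percent or NA),
#'   \code{included}, \code{reason}.
#' @export
stimulation_efficacy <- function(off_score, on_score, domain, side = NA) {
  domain <- match.arg(domain, names(item_groups))
  if (off_score < 0 || on_score < 0) stopf("negative subscore")
  if (off_score == 0)
    return(list(side = side, domain = domain, value = NA_real_,
                included = FALSE, reason = "undefined denominator"))
  list(side = side, domain = domain,
       value = 100 * (off_score - on_score) / off_score,
       included = TRUE, reason = "")
}

#' Hemibody contralateral to an STN side
#'
#' Motor improvement is assessed on the body side opposite the stimulated
#' nucleus: a left STN maps to the right hemibody and vice versa.
#'
#' @param stn_side \code{"left"} or \code{"right"}.
#' @return the contralateral hemibody label.
#' @export
contralateral_hemibody <- function(stn_side) {
  stn_side <- match.arg(stn_side, c("left", "right"))
  c(left = "right", right = "left")[[stn_side]]
}

#' Per-domain analysis sets
#'
#' Applies the side-inclusion rules: the bradykinesia-rigidity set contains
#' every quality-passing side; the tremor set additionally requires a
#' positive OFF-stimulation tremor baseline (a zero baseline leaves the
#' percent improvement undefined); the axial set contains one record per
#' patient (axial scores are not lateralized, so bilateral-average power is
#' paired with them downstream).
#'
#' @param side_table data.frame with one row per side and columns
#'   \code{side_id, patient_id, poor_quality} and
#'   \code{tremor_off} (OFF-stim tremor baseline of the contralateral
#'   hemibody).
#' @return list with \code{brady_sides}, \code{tremor_sides} (side ids) and
#'   \code{axial_patients} (patient ids).
#' @export
build_inclusion <- function(side_table) {
  ok <- !side_table$poor_quality
  brady <- side_table$side_id[ok]
  tremor <- side_table$side_id[ok & side_table$tremor_off > 0]
  list(brady_sides = brady,
       tremor_sides = tremor,
       axial_patients = unique(side_table$patient_id[ok]))
}
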