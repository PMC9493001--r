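#' DBS lead geometry
#'
#' Geometry of a cylindrical quadripolar DBS lead. The default corresponds to
#' the Medtronic 3389: four 1.5 mm contacts separated by 0.5 mm gaps, i.e. a
#' 2.0 mm center-to-center spacing. Contacts are indexed 0 (deepest) to 3;
#' clinical labels are C0--C3 on the left lead and C8--C11 on the right.
#'
#' @param model_name lead model identifier.
#' @param n_contacts number of contacts.
#' @param contact_length_mm contact length in mm.
#' @param inter_contact_gap_mm gap between adjacent contacts in mm.
#' @return an object of class \code{lead_model}.
#' @examples
#' lead <- lead_model()
#' contact_distance(3, 1, lead)  # 4 mm
#' @export
lead_model <- function(model_name = "3389", n_contacts = 4L,
                       contact_length_mm = 1.5, inter_contact_gap_mm = 0.5) {
  stopifnot(n_contacts >= 2, contact_length_mm > 0, inter_contact_gap_mm >= 0)
  out <- list(
    model_name = model_name,
    n_contacts = as.integer(n_contacts),
    contact_length_mm = contact_length_mm,
    inter_contact_gap_mm = inter_contact_gap_mm,
    center_spacing_mm = contact_length_mm + inter_contact_gap_mm,
    label_offset = c(left = 0L, right = 8L)
  )
  class(out) <- "lead_model"
  out
}

#' Contact depths along the lead axis
#'
#' Depth coordinate (mm) of each contact center, measured from the deepest
#' contact (index 0 at 0 mm).
#'
#' @param lead a \code{lead_model}.
#' @return numeric vector of length \code{n_contacts}.
#' @export
contact_depths <- function(lead = lead_model()) {
  (seq_len(lead$n_contacts) - 1) * lead$center_spacing_mm
}

#' Map a clinical contact label to a within-lead index
#'
#' Labels follow the bilateral numbering convention: C0--C3 on the left lead
#' and C8--C11 on the right, both mapping to indices 0--3.
#'
#' @param label character label, e.g. \code{"C10"}.
#' @param side \code{"left"} or \code{"right"}.
#' @param lead a \code{lead_model}.
#' @return integer index in 0..(n_contacts - 1).
#' @export
contact_index <- function(label, side, lead = lead_model()) {
  side <- match.arg(side, c("left", "right"))
  num <- suppressWarnings(as.integer(sub("^[Cc]", "", label)))
  if (any(is.na(num)))
    stopf("unparseable contact label '%s'", label[is.na(num)][1])
  idx <- num - lead$label_offset[[side]]
  bad <- idx < 0 | idx >= lead$n_contacts
  if (any(bad))
    stopf("contact label '%s' is not valid on a %s lead", label[bad][1], side)
  as.integer(idx)
}

#' Inverse of \code{contact_index}
#' @param index integer index 0..3.
#' @param side \code{"left"} or \code{"right"}.
#' @param lead a \code{lead_model}.
#' @return character label.
#' @export
contact_label <- function(index, side, lead = lead_model()) {
  if (!all(side %in% c("left", "right"))) stopf("side must be left or right")
  stopifnot(all(index >= 0 & index < lead$n_contacts))
  paste0("C", as.integer(index) +
           lead$label_offset[match(side, c("left", "right"))])
}

#' Center-to-center distance between two contacts
#'
#' Distance along the lead axis between contact centers, the quantity the
#' outcome analysis pairs with the active contact and the contact carrying
#' the maximum band power.
#'
#' @param active index of the chronic stimulation contact (0--3).
#' @param max_band index of the contact with the maximum band power (0--3).
#' @param lead a \code{lead_model}.
#' @return distance in mm (0, 2, 4 or 6 on a default lead).
#' @export
contact_distance <- function(active, max_band, lead = lead_model()) {
  ok <- function(i) all(i == floor(i) & i >= 0 & i < lead$n_contacts)
  if (!ok(active) || !ok(max_band)) stopf("contact index out of range 0..%d",
                                          lead$n_contacts - 1)
  abs(active - max_band) * lead$center_spacing_mm
}
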