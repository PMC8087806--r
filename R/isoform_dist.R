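# Isoform distributions: a probability mapping from co-editing patterns
# (sets of site labels; the empty set is the non-edited transcript) to the
# fraction of transcripts carrying exactly that pattern.

#' Construct an isoform distribution
#'
#' @param probs Named numeric vector. Names are isoform labels: `"NonEdited"`
#'   for the unedited pattern, otherwise the concatenated site letters of
#'   the pattern (e.g. `"B"`, `"BC"`). Values are fractions summing to 1.
#' @param ref Optional `reference_amplicon`; when given, every label must
#'   reference only sites present on the amplicon.
#' @return Named numeric vector of class `isoform_distribution`.
#' @export
isoform_distribution <- function(probs, ref = NULL) {
  stopifnot(is.numeric(probs), !is.null(names(probs)))
  if (anyDuplicated(names(probs))) stop("duplicate isoform labels")
  if (any(probs < 0)) stop("isoform probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("isoform probabilities must sum to 1 (got ", sum(probs), ")")
  }
  if (!is.null(ref)) {
    known <- ref$sites$label
    for (lab in names(probs)) {
      for (s in isoform_sites(lab)) {
        if (!s %in% known) {
          stop("isoform '", lab, "' references unknown site '", s, "'")
        }
      }
    }
  }
  structure(probs, class = "isoform_distribution")
}

#' Site letters of an isoform label
#'
#' `"NonEdited"` maps to the empty set; any other label is split into its
#' single-letter site names.
#'
#' @param label Isoform label.
#' @return Character vector of site letters (possibly empty).
#' @export
isoform_sites <- function(label) {
  if (identical(label, "NonEdited")) return(character(0))
  strsplit(label, "", fixed = TRUE)[[1L]]
}

#' Default control-group isoform distribution
#'
#' Calibrated so the site-level profile of the control group shows one
#' dominant site (B, 20% editing) and four minor sites (C-F, between 0.2%
#' and 0.6%), with every multi-site pattern containing site B. Background
#' positions (A, G-N) carry no true editing; any signal observed there
#' comes from sequencing error alone.
#'
#' @return An `isoform_distribution`.
#' @export
default_control_distribution <- function() {
  isoform_distribution(c(
    NonEdited = 0.8000,
    B  = 0.1845,
    BC = 0.0045,
    BD = 0.0025,
    BE = 0.0055,
    BF = 0.0030
  ))
}

#' Scale the edited mass of a distribution
#'
#' Multiplies every edited isoform's probability by `factor` and moves the
#' released mass to the non-edited pattern. This is how the default patient
#' groups are derived from the control distribution: a global decrease in
#' editing activity mirrored by a rise of the non-edited isoform.
#'
#' @param dist An `isoform_distribution`.
#' @param factor Multiplier in `[0, 1]` (or above 1 to increase editing, as
#'   long as probabilities stay valid).
#' @return An `isoform_distribution`.
#' @export
scale_edited_mass <- function(dist, factor) {
  stopifnot(factor >= 0)
  p <- unclass(dist)
  edited <- names(p) != "NonEdited"
  p[edited] <- p[edited] * factor
  if (!"NonEdited" %in% names(p)) p <- c(NonEdited = 0, p)
  p["NonEdited"] <- 1 - sum(p[names(p) != "NonEdited"])
  if (p["NonEdited"] < 0) stop("edited mass exceeds 1 after scaling")
  isoform_distribution(p)
}

#' True per-site editing fractions implied by an isoform distribution
#'
#' The editing level of a site is the total probability of all isoforms
#' whose pattern contains that site.
#'
#' @param dist An `isoform_distribution`.
#' @param ref A `reference_amplicon` (defines the site universe).
#' @return Named numeric vector over all candidate sites (fractions).
#' @export
site_fractions <- function(dist, ref) {
  out <- setNames(numeric(nrow(ref$sites)), ref$sites$label)
  for (lab in names(dist)) {
    for (s in isoform_sites(lab)) out[s] <- out[s] + unclass(dist)[[lab]]
  }
  out
}
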