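#' Sample preparation protocol
#'
#' Encodes the wet-chemistry scaling of the assay: `sample_mass` grams of
#' homogenised coffee grains extracted into `extraction_volume` mL of water,
#' back-extracted into `back_extraction_volume` mL of solvent (treated as
#' volume-preserving; any partition loss is absorbed into the recovery bias),
#' with an optional further dilution. The defaults are 0.5 g into 10 mL.
#'
#' @param sample_mass Sample mass, g.
#' @param extraction_volume Aqueous extraction volume, mL.
#' @param back_extraction_volume Final (injected) extract volume, mL.
#' @param dilution_factor Post-extraction dilution factor (>= 1).
#' @return A `prep_protocol` object.
#' @examples
#' prep_protocol()
#' @export
prep_protocol <- function(sample_mass = 0.5, extraction_volume = 10,
                          back_extraction_volume = 10, dilution_factor = 1) {
  assert_scalar_number(sample_mass, "sample_mass", lower = 0, strict_lower = TRUE)
  assert_scalar_number(extraction_volume, "extraction_volume", lower = 0, strict_lower = TRUE)
  assert_scalar_number(back_extraction_volume, "back_extraction_volume",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(dilution_factor, "dilution_factor", lower = 1)
  structure(
    list(sample_mass = sample_mass, extraction_volume = extraction_volume,
         back_extraction_volume = back_extraction_volume,
         dilution_factor = dilution_factor),
    class = "prep_protocol"
  )
}

#' Convert extract concentration to sample content
#'
#' With the default 0.5 g / 10 mL protocol every mg/L in the final extract
#' corresponds to 20 mg/kg in the grains:
#' `mg/kg = conc * (final_volume_L / sample_mass_kg) * dilution_factor`,
#' and `%w/w = mg/kg / 10000` exactly.
#'
#' @param conc Extract concentration(s), mg/L (>= 0).
#' @param prep A [prep_protocol()].
#' @return Tibble with `conc_mg_L`, `mg_per_kg`, `pct_w_w`.
#' @examples
#' extract_to_sample(c(3.1, 9.3))
#' @export
extract_to_sample <- function(conc, prep = prep_protocol()) {
  stopifnot(inherits(prep, "prep_protocol"))
  if (any(conc < 0)) {
    abort("`conc` must be non-negative.", class = "caffval_invalid_argument")
  }
  factor <- (prep$back_extraction_volume / 1000) / (prep$sample_mass / 1000) *
    prep$dilution_factor
  mg_kg <- conc * factor
  tibble::tibble(conc_mg_L = conc, mg_per_kg = mg_kg, pct_w_w = mg_kg / 10000)
}

#' Invert [extract_to_sample()]
#'
#' @param mg_per_kg Sample content, mg/kg.
#' @param prep A [prep_protocol()].
#' @return Extract concentration, mg/L.
#' @export
sample_to_extract <- function(mg_per_kg, prep = prep_protocol()) {
  stopifnot(inherits(prep, "prep_protocol"))
  factor <- (prep$back_extraction_volume / 1000) / (prep$sample_mass / 1000) *
    prep$dilution_factor
  mg_per_kg / factor
}

#' Theoretical content of a fortified sample
#'
#' @param background Background content, %w/w (>= 0).
#' @param spike Spiked amount, %w/w (>= 0).
#' @return Tibble with `background_pct`, `spike_pct`, `total_pct`; the spike
#'   is kept separately for recovery bookkeeping.
#' @examples
#' theoretical_fortified_content(1.3, c(0.5, 1, 2))
#' @export
theoretical_fortified_content <- function(background, spike) {
  if (any(background < 0) || any(spike < 0)) {
    abort("Contents must be non-negative.", class = "caffval_invalid_argument")
  }
  tibble::tibble(background_pct = background, spike_pct = spike,
                 total_pct = background + spike)
}
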