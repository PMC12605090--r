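#' Tissue-to-tissue drug-level ratio
#'
#' Ratio of two group-mean concentrations (ratio of means; per-animal
#' pairing is not available in summary tables), rounded half-even at the
#' requested precision.
#'
#' @param numerator,denominator Mean concentrations (same units family:
#'   ng/mL for plasma, ng/g for tissue).
#' @param decimals Displayed precision.
#' @return Rounded ratio.
#' @examples
#' tissue_ratio(14671.30, 30560)   # placenta : plasma = 0.48
#' tissue_ratio(2405.60, 14671.30) # embryo brain : placenta = 0.16
#' @export
tissue_ratio <- function(numerator, denominator, decimals = 2) {
  stopifnot(numerator >= 0, decimals >= 0)
  if (denominator <= 0) stop("denominator concentration must be positive",
                             call. = FALSE)
  round(numerator / denominator, decimals)
}

#' Ratios between PK compartments
#'
#' Convenience wrapper computing compartment ratios from a tidy PK table
#' (columns `compartment`, `group`, `gestation_day`, `mean_concentration`).
#' Both rows must share the group and gestation day.
#'
#' @param pk PK table (data frame).
#' @param numerator,denominator Compartment names.
#' @param group,gestation_day Row selectors.
#' @param decimals Displayed precision.
#' @return Rounded ratio.
#' @export
pk_ratio <- function(pk, numerator, denominator, group, gestation_day,
                     decimals = 2) {
  pick <- function(comp) {
    r <- pk[pk$compartment == comp & pk$group == group &
              pk$gestation_day == gestation_day, ]
    if (nrow(r) != 1) stop("expected exactly one row for compartment ", comp,
                           call. = FALSE)
    r$mean_concentration
  }
  tissue_ratio(pick(numerator), pick(denominator), decimals)
}

#' Litter phenotype summary
#'
#' Per-group litter arithmetic from implantation counts: implants, viable
#' embryos and resorptions per litter (1 decimal), and resorption / viable
#' percentages of total implants (1 decimal). Validates the identity
#' `total_viable + total_resorptions = total_implants`; before rounding,
#' resorption and viable percentages sum to exactly 100.
#'
#' @param t Data frame with one row per group and columns `group`,
#'   `n_litters`, `total_implants`, `total_resorptions`, `total_viable`,
#'   `n_abnormal`.
#' @return A tibble with the derived quantities per group.
#' @examples
#' tab <- data.frame(group = c("vehicle", "dtg"), n_litters = c(5, 5),
#'                   total_implants = c(33, 34), total_resorptions = c(2, 5),
#'                   total_viable = c(31, 29), n_abnormal = c(0, 0))
#' phenotype_summary(tab)
#' @export
phenotype_summary <- function(t) {
  need <- c("group", "n_litters", "total_implants", "total_resorptions",
            "total_viable", "n_abnormal")
  stopifnot(all(need %in% names(t)))
  bad <- t$total_viable + t$total_resorptions != t$total_implants
  if (any(bad)) {
    stop("violated identity total_viable + total_resorptions = total_implants in group(s): ",
         paste(t$group[bad], collapse = ", "), call. = FALSE)
  }
  if (any(t$n_litters < 1) || any(t[-1] < 0)) {
    stop("counts must be non-negative with at least one litter", call. = FALSE)
  }
  tibble::tibble(
    group = t$group,
    implants_per_litter = round(t$total_implants / t$n_litters, 1),
    viable_per_litter = round(t$total_viable / t$n_litters, 1),
    resorptions_per_litter = round(t$total_resorptions / t$n_litters, 1),
    resorption_pct = round(100 * t$total_resorptions / t$total_implants, 1),
    viable_pct = round(100 * t$total_viable / t$total_implants, 1),
    abnormal_pct = round(100 * t$n_abnormal / pmax(t$total_viable, 1), 1))
}
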