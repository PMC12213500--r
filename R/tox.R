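epa_levels <- c("practically_nontoxic", "slightly", "moderately",
                "highly", "very_highly")

#' Classify an acute aquatic toxicity concentration into EPA categories
#'
#' Maps an EC50/LC50 concentration (mg/L) onto the US EPA five-level acute
#' aquatic toxicity scheme: practically non-toxic (> 100 mg/L), slightly
#' toxic (10-100 mg/L), moderately toxic (1-10 mg/L), highly toxic
#' (0.1-1 mg/L), very highly toxic (< 0.1 mg/L).
#'
#' The shared boundary values are assigned half-open: each interval includes
#' its upper endpoint, so exactly 100 mg/L is "slightly", 10 is "moderately",
#' 1 is "highly" and 0.1 is "highly" (the "very highly" class is strictly
#' below 0.1, matching the strict "> 100" of the printed definition).
#'
#' @param concentration Positive concentration(s) in mg/L.
#' @return An ordered factor with levels from `practically_nontoxic` (least
#'   severe) to `very_highly` (most severe).
#' @examples
#' classify_epa(c(150, 50, 5, 0.5, 0.05))
#' @export
classify_epa <- function(concentration) {
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be positive (mg/L)", call. = FALSE)
  }
  cat_chr <- ifelse(concentration > 100, "practically_nontoxic",
             ifelse(concentration > 10,  "slightly",
             ifelse(concentration > 1,   "moderately",
             ifelse(concentration >= 0.1, "highly", "very_highly"))))
  factor(cat_chr, levels = epa_levels, ordered = TRUE)
}

#' Negative log10 toxicity transform
#'
#' Returns `-log10(concentration)` so that larger values indicate higher
#' toxicity, the usual axis for comparing EC50/LC50 values across classes.
#'
#' @param concentration Positive concentration(s) in mg/L.
#' @return Numeric vector of `-log10` values.
#' @examples
#' neg_log10_toxicity(c(1, 0.1, 100))  # 0, 1, -2
#' @export
neg_log10_toxicity <- function(concentration) {
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be positive (mg/L)", call. = FALSE)
  }
  -log10(concentration)
}

#' Annotate a toxicity table with EPA categories
#'
#' Takes per-compound toxicity records — e.g. predicted 48 h EC50 values for
#' *Tetrahymena pyriformis*, 48 h LC50 for *Daphnia magna* or 96 h LC50 for
#' *Pimephales promelas* — and appends the EPA category and the `-log10`
#' transform of each concentration.
#'
#' @param tox Data frame with a `concentration_mg_L` column (positive), plus
#'   any identifier/species/endpoint columns, which are passed through.
#' @return The input as a tibble with added `category` and `neg_log10`
#'   columns.
#' @export
annotate_toxicity <- function(tox) {
  if (!is.data.frame(tox) || !"concentration_mg_L" %in% names(tox)) {
    stop("tox must be a data frame with a concentration_mg_L column",
         call. = FALSE)
  }
  tox <- dplyr::as_tibble(tox)
  tox$category <- classify_epa(tox$concentration_mg_L)
  tox$neg_log10 <- neg_log10_toxicity(tox$concentration_mg_L)
  tox
}

#' Plot toxicity category counts per species
#'
#' @param tox Annotated toxicity tibble from [annotate_toxicity()]; uses a
#'   `species` column when present.
#' @return A ggplot bar chart of category counts.
#' @export
plot_toxicity_categories <- function(tox) {
  if (!"category" %in% names(tox)) tox <- annotate_toxicity(tox)
  p <- ggplot2::ggplot(tox, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "#7570b3") +
    ggplot2::labs(x = "EPA acute toxicity category", y = "compounds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if ("species" %in% names(tox)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p
}
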