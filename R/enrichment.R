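#' Half-up rounding
#'
#' Rounds away from zero on ties (`0.5 -> 1`), matching how frequencies
#' and incidences are conventionally printed, and independent of the
#' banker's rounding used by [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Allele frequency as a printed percentage
#'
#' `100 * ac / an`, rounded half-up — the arithmetic behind
#' population-database allele-frequency quotes such as "0.094%
#' (112/118,908)".
#'
#' @param ac Alternate allele count.
#' @param an Total allele number (`> 0`).
#' @param decimals Decimal places (default 3, the precision such
#'   frequencies are usually quoted at).
#' @return Percentage, rounded half-up.
#' @examples
#' allele_frequency_percent(112, 118908)  # 0.094
#' @export
allele_frequency_percent <- function(ac, an, decimals = 3) {
  stopifnot(is.numeric(ac), is.numeric(an))
  if (any(an <= 0)) stop("allele number must be positive")
  if (any(ac < 0 | ac > an)) stop("allele count must lie in [0, allele number]")
  round_half_up(100 * ac / an, decimals)
}

#' Cohort count records
#'
#' Light-weight constructor for the count table used by
#' [incidence_table()] and [carrier_summary()]: allele counts (`ac`/`an`)
#' and biallelic case counts (`cases`/`participants`) per cohort or
#' diagnostic category.
#'
#' @param label Cohort/category names.
#' @param ac,an Alternate allele count and total allele number.
#' @param cases,participants Biallelic case and participant counts.
#' @return A validated data.frame.
#' @export
cohort_counts <- function(label, ac = NA_real_, an = NA_real_,
                          cases = NA_real_, participants = NA_real_) {
  n <- length(label)
  out <- data.frame(label = as.character(label),
                    ac = rep_len(ac, n), an = rep_len(an, n),
                    cases = rep_len(cases, n),
                    participants = rep_len(participants, n),
                    stringsAsFactors = FALSE)
  with(out, {
    if (any(ac < 0 | ac > an, na.rm = TRUE)) stop("need 0 <= ac <= an")
    if (any(cases < 0 | cases > participants, na.rm = TRUE))
      stop("need 0 <= cases <= participants")
  })
  out
}

#' Incidence table across diagnostic categories
#'
#' Per-category percentage of biallelic cases among participants, with a
#' combined row that pools cases and participants before dividing.
#'
#' @param rows Data.frame with columns `label`, `cases`, `participants`
#'   (e.g. from [cohort_counts()]).
#' @param decimals Decimal places for the printed percentage (default 2).
#' @return `rows` with a `percent` column and a final `"combined"` row.
#' @examples
#' incidence_table(cohort_counts(c("CMT", "paediatric motor neuronopathies"),
#'                               cases = c(6, 1), participants = c(708, 116)))
#' @export
incidence_table <- function(rows, decimals = 2) {
  stopifnot(all(c("label", "cases", "participants") %in% names(rows)))
  bad <- which(is.na(rows$participants) | rows$participants <= 0)
  if (length(bad))
    stop("zero or missing participant count in row: ",
         paste(rows$label[bad], collapse = ", "))
  out <- rows[, c("label", "cases", "participants")]
  combined <- data.frame(label = "combined",
                         cases = sum(rows$cases),
                         participants = sum(rows$participants),
                         stringsAsFactors = FALSE)
  out <- rbind(out, combined)
  out$percent <- round_half_up(100 * out$cases / out$participants, decimals)
  rownames(out) <- NULL
  out
}

#' Homozygote-excess test against the Hardy-Weinberg expectation
#'
#' With allele frequency `q` in a cohort of `N` individuals, the expected
#' number of homozygotes under Hardy-Weinberg equilibrium (no inbreeding,
#' no stratification) is `N * q^2`.  The upper-tail probability of
#' observing at least `observed` homozygotes is computed under an exact
#' Poisson(`N q^2`) or Binomial(`N`, `q^2`) null — exact tail summation,
#' no normal approximation.  The two nulls converge as `q^2 -> 0`.
#'
#' @param q Allele frequency, in \eqn{[0, 1]}.
#' @param N Cohort size (individuals).
#' @param observed Observed homozygote count, `0 <= observed <= N`.
#' @param null `"poisson"` (default) or `"binomial"`.
#' @return A list of class `enrichment_result`: `q`, `N`, `expected_hom`,
#'   `observed_hom`, `p_value`, `null`.
#' @examples
#' homozygote_excess(q = 0.00094, N = 74180, observed = 7)
#' @export
homozygote_excess <- function(q, N, observed, null = c("poisson", "binomial")) {
  null <- match.arg(null)
  stopifnot(q >= 0, q <= 1, N >= observed, observed >= 0)
  expected <- N * q^2
  p <- if (null == "poisson") {
    stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  } else {
    stats::pbinom(observed - 1, size = N, prob = q^2, lower.tail = FALSE)
  }
  structure(list(q = q, N = N, expected_hom = expected,
                 observed_hom = as.integer(observed),
                 p_value = p, null = null),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Homozygote excess (%s null): expected %.4g, observed %d, p = %.3g\n",
              x$null, x$expected_hom, x$observed_hom, x$p_value))
  invisible(x)
}

#' Ranked allele-frequency comparison across cohorts
#'
#' Sorts cohort allele-count entries by descending frequency with a
#' formatted percentage column; ties keep their input order.  Used to put
#' a founder allele's frequency alongside comparable recessive-disease
#' alleles across population databases.
#'
#' @param entries Data.frame with columns `label`, `ac`, `an`.
#' @param decimals Decimal places for the percentage column (default 3).
#' @return `entries` with `frequency` and `percent` columns, ranked.
#' @export
carrier_summary <- function(entries, decimals = 3) {
  stopifnot(all(c("label", "ac", "an") %in% names(entries)), nrow(entries) >= 1)
  out <- entries[, c("label", "ac", "an")]
  out$frequency <- out$ac / out$an
  out <- out[order(-out$frequency), , drop = FALSE]  # stable: ties keep input order
  out$percent <- round_half_up(100 * out$frequency, decimals)
  rownames(out) <- NULL
  out
}
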