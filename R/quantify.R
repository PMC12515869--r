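#' Median-normalize samples of an intensity table
#'
#' Rescales each sample column multiplicatively so that all column medians
#' (over present values) equal the median of the original column medians.
#' This removes per-sample global scaling (loading, instrument drift) while
#' preserving within-column rank order.
#'
#' @param tab An [intensity_table()].
#' @param factors Optional named per-sample scaling factors (e.g. from
#'   [sample_scaling_factors()] on another table over the same samples).
#'   When given, columns are multiplied by these instead of factors derived
#'   from `tab` itself — used to apply one consistent loading correction to
#'   paired site/protein tables.
#' @return An [intensity_table()]; with `factors = NULL`, its column medians
#'   are equalized.
#' @export
normalize_samples <- function(tab, factors = NULL) {
  stopifnot(inherits(tab, "intensity_table"))
  if (is.null(factors)) factors <- sample_scaling_factors(tab)
  if (!all(colnames(tab$values) %in% names(factors))) {
    stop_validation("'factors' must cover every sample")
  }
  set_values(tab, sweep(tab$values, 2, factors[colnames(tab$values)], `*`))
}

#' Per-sample median scaling factors
#'
#' The multiplicative factor per sample column that equalizes all column
#' medians (over present values) at the median of the original medians.
#'
#' @param tab An [intensity_table()].
#' @return Named numeric vector of factors, one per sample.
#' @export
sample_scaling_factors <- function(tab) {
  stopifnot(inherits(tab, "intensity_table"))
  meds <- apply(tab$values, 2, median, na.rm = TRUE)
  if (any(is.na(meds))) {
    stop_validation("sample column(s) with no present values: ",
                    paste(colnames(tab$values)[is.na(meds)], collapse = ", "))
  }
  median(meds) / meds
}

#' Center features to relative quantification values
#'
#' Divides every feature row by the mean of its present values, so that each
#' row of the result has mean 1 over present cells. Division (rather than
#' subtraction) keeps values positive, so downstream fold changes remain
#' ratios of means.
#'
#' @param tab An [intensity_table()]; every feature needs at least one
#'   present value.
#' @return An [intensity_table()] of unitless relative quantifications with
#'   row means (over present values) equal to 1.
#' @export
center_features <- function(tab) {
  stopifnot(inherits(tab, "intensity_table"))
  mu <- rowMeans(tab$values, na.rm = TRUE)
  if (any(is.nan(mu))) {
    stop_validation("feature(s) with no present values: ",
                    paste(rownames(tab$values)[is.nan(mu)], collapse = ", "))
  }
  set_values(tab, tab$values / mu)
}

#' Correct site quantifications by parent-protein abundance
#'
#' Divides each modification site's relative quantification by that of its
#' parent protein, sample by sample, so the result reflects modification
#' stoichiometry rather than protein expression. Cells missing in either
#' operand stay missing. Sites whose parent protein is absent from the
#' protein table ("orphan sites") are dropped with a message. The output is
#' re-centered so row means over present values are 1.
#'
#' @param site_rel Centered site [intensity_table()] (from
#'   [center_features()]).
#' @param prot_rel Centered protein [intensity_table()] over the same
#'   samples.
#' @param map Named character vector mapping site id -> protein accession;
#'   must cover every site feature.
#' @return A protein-corrected, re-centered site [intensity_table()].
#' @export
correct_site_by_protein <- function(site_rel, prot_rel, map) {
  stopifnot(inherits(site_rel, "intensity_table"),
            inherits(prot_rel, "intensity_table"))
  if (!identical(colnames(site_rel$values), colnames(prot_rel$values))) {
    stop_validation("site and protein tables must share identical samples")
  }
  sites <- rownames(site_rel$values)
  if (!all(sites %in% names(map))) {
    stop_validation("'map' must cover every site feature")
  }
  parent <- map[sites]
  orphan <- !(parent %in% rownames(prot_rel$values))
  if (any(orphan)) {
    message(sprintf("dropping %d orphan site(s) without a quantified parent protein",
                    sum(orphan)))
    sites <- sites[!orphan]
    parent <- parent[!orphan]
  }
  if (length(sites) == 0L) {
    stop_validation("no sites left after dropping orphans")
  }
  corrected <- site_rel$values[sites, , drop = FALSE] /
    prot_rel$values[parent, , drop = FALSE]
  rownames(corrected) <- sites
  center_features(set_values(site_rel, corrected))
}

#' Run the full site quantification chain
#'
#' Convenience wrapper: estimates per-sample loading factors once, from the
#' protein table, applies them to both tables, centers features to relative
#' quantifications, and corrects sites by their parent proteins. A single
#' per-sample factor is used for both tables because sample loading is a
#' property of the sample, not of the feature class — and because it leaves
#' every site/protein ratio untouched, so the correction cannot be distorted
#' by asymmetric modification changes shifting the site-table medians. The
#' composition is invariant to per-sample global scaling of the raw inputs.
#'
#' @inheritParams correct_site_by_protein
#' @param site_raw,prot_raw Raw [intensity_table()]s over the same samples.
#' @return List with `sites` (corrected site table) and `proteins` (centered
#'   protein table).
#' @export
quantify_sites <- function(site_raw, prot_raw, map) {
  factors <- sample_scaling_factors(prot_raw)
  prot_rel <- center_features(normalize_samples(prot_raw, factors))
  site_rel <- center_features(normalize_samples(site_raw, factors))
  list(sites = correct_site_by_protein(site_rel, prot_rel, map),
       proteins = prot_rel)
}
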