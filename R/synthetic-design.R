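#' Approximate vertebrate amino-acid composition
#'
#' Background residue frequencies used by [generate_proteome()] when no
#' composition is supplied. Values are approximate frequencies of the 20
#' standard residues in vertebrate proteomes, normalized to sum to 1.
#'
#' @return Named numeric vector over the 20 standard one-letter codes,
#'   summing to 1.
#' @export
default_aa_composition <- function() {
  comp <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036,
            G = 0.066, H = 0.026, I = 0.043, K = 0.057, L = 0.100,
            M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
            S = 0.083, T = 0.053, V = 0.060, W = 0.011, Y = 0.026)
  comp / sum(comp)
}

#' Describe a synthetic two-group lactylome experiment
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' structure of a mouse-heart lactylome study: a 3 vs 3 label-free design,
#' roughly 477 modified proteins carrying roughly 1,674 sites with about 44%
#' singly-modified proteins, spiked site-level fold changes of 2 (half up,
#' half down), partly decoupled protein-level changes, log-normal intensities
#' with per-sample scaling, and 5% missing values.
#'
#' @param n_control,n_case Samples per group (each >= 2). Default 3 vs 3.
#' @param frac_modified_proteins Fraction of proteome proteins that carry at
#'   least one lactylation site. Default 0.477 (so a 1,000-protein proteome
#'   yields ~477 modified proteins).
#' @param single_site_frac Expected fraction of modified proteins with
#'   exactly one site. Default 0.4403.
#' @param mean_sites_per_protein Target mean number of sites per modified
#'   protein; default 3.51 (~1,674 sites on ~477 proteins).
#' @param spike_frac_sites Fraction of sites given a true site-level group
#'   effect. Default 0.10.
#' @param true_site_fc True case/control fold change of spiked sites (half
#'   are spiked at `true_site_fc`, half at its reciprocal). Default 2.0, so
#'   spikes clear the 1.5 fold-change calling threshold.
#' @param spike_frac_proteins Fraction of proteins given a true protein-level
#'   abundance change (decoupled from site spikes). Default 0.10.
#' @param true_protein_fc True fold change of spiked proteins. Default 2.0.
#' @param sample_scale_sd SD (natural-log space) of per-sample global scaling
#'   factors. Default 0.25.
#' @param noise_sd Residual measurement SD (natural-log space) applied
#'   independently to every site and protein observation. Default 0.15.
#' @param missing_rate Fraction of cells set missing. Default 0.05.
#' @param mnar If `TRUE`, missingness is intensity-dependent (lower-abundance
#'   cells are more likely to be missing) at the same overall rate; default
#'   `FALSE` (missing completely at random).
#' @param seed Integer seed making every generator deterministic.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_control = 3L, n_case = 3L,
                             frac_modified_proteins = 0.477,
                             single_site_frac = 0.4403,
                             mean_sites_per_protein = 3.51,
                             spike_frac_sites = 0.10,
                             true_site_fc = 2.0,
                             spike_frac_proteins = 0.10,
                             true_protein_fc = 2.0,
                             sample_scale_sd = 0.25,
                             noise_sd = 0.15,
                             missing_rate = 0.05,
                             mnar = FALSE,
                             seed = 1L) {
  n_control <- assert_count(n_control, "n_control", min = 2L)
  n_case <- assert_count(n_case, "n_case", min = 2L)
  for (nm in c("frac_modified_proteins", "single_site_frac",
               "spike_frac_sites", "spike_frac_proteins", "missing_rate")) {
    assert_fraction(get(nm), nm)
  }
  if (true_site_fc <= 0 || true_protein_fc <= 0) {
    stop_validation("true fold changes must be > 0")
  }
  if (sample_scale_sd < 0 || noise_sd < 0) {
    stop_validation("'sample_scale_sd' and 'noise_sd' must be >= 0")
  }
  if (mean_sites_per_protein < 1) {
    stop_validation("'mean_sites_per_protein' must be >= 1")
  }
  structure(list(n_control = n_control, n_case = n_case,
                 frac_modified_proteins = frac_modified_proteins,
                 single_site_frac = single_site_frac,
                 mean_sites_per_protein = mean_sites_per_protein,
                 spike_frac_sites = spike_frac_sites,
                 true_site_fc = true_site_fc,
                 spike_frac_proteins = spike_frac_proteins,
                 true_protein_fc = true_protein_fc,
                 sample_scale_sd = sample_scale_sd,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 mnar = isTRUE(mnar),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}
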