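#' Generate site- and protein-level intensity tables with ground truth
#'
#' Simulates the label-free quantification layer of a lactylome experiment.
#' Each protein gets a log-normal base abundance; each sample a global
#' multiplicative scaling factor (`exp(N(0, sample_scale_sd))`); spiked
#' proteins change abundance between groups by `true_protein_fc`. A site's
#' intensity is its parent protein's realized per-sample quantity (including
#' the protein-level log-normal variation, which in a small animal design is
#' dominated by biology and therefore shared with the site peptide) times a
#' site stoichiometry drawn uniform(0.05, 0.5), times the site-level group
#' effect for spiked sites, times independent site-level log-normal noise. Half of all spikes are up (`fc`), half down (`1/fc`). Missing
#' values are inserted at `design$missing_rate`, completely at random by
#' default or intensity-dependently when `design$mnar` is set.
#'
#' Protein-level spikes propagate to the raw intensities of their sites (a
#' site rides on its protein); the site/protein correction implemented in
#' [correct_site_by_protein()] is designed to remove exactly this component.
#'
#' @param catalog Site catalog from [generate_lactylome()].
#' @param design A [synthetic_design()].
#' @return A list with elements `sites` and `proteins` (both
#'   [intensity_table()]s) and `truth`, a data.frame with one row per feature
#'   (`feature`, `level` = `"site"`/`"protein"`, `is_spiked`, `true_fc`,
#'   `spike_level` = `"site"`, `"protein"` or `"none"`). For a site on a
#'   spiked protein but without its own spike, `true_fc` is the
#'   protein-corrected site fold change, i.e. 1.
#' @export
generate_intensities <- function(catalog, design = synthetic_design()) {
  if (nrow(catalog) == 0L) stop_validation("'catalog' must be non-empty")
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed + 2L, {
    accs <- sort(unique(catalog$accession))
    n_prot <- length(accs)
    n_site <- nrow(catalog)
    n_samp <- design$n_control + design$n_case
    group <- c(rep("control", design$n_control), rep("case", design$n_case))
    samples <- c(sprintf("ctrl_%d", seq_len(design$n_control)),
                 sprintf("case_%d", seq_len(design$n_case)))

    base <- setNames(rlnorm(n_prot, meanlog = log(1e7), sdlog = 1.2), accs)
    scale_j <- exp(rnorm(n_samp, 0, design$sample_scale_sd))

    spike_prot <- sample(accs, round(design$spike_frac_proteins * n_prot))
    prot_dir <- setNames(rep_len(c(1, -1), length(spike_prot)), spike_prot)
    prot_fc <- setNames(rep(1, n_prot), accs)
    prot_fc[spike_prot] <- design$true_protein_fc ^ prot_dir

    spike_site <- sample(catalog$site,
                         round(design$spike_frac_sites * n_site))
    site_dir <- setNames(rep_len(c(1, -1), length(spike_site)), spike_site)
    site_fc <- setNames(rep(1, n_site), catalog$site)
    site_fc[spike_site] <- design$true_site_fc ^ site_dir

    is_case <- group == "case"
    ## true protein abundance per sample (before measurement noise)
    prot_true <- outer(base, scale_j) *
      outer(prot_fc, ifelse(is_case, 1, 0), `^`)
    dimnames(prot_true) <- list(accs, samples)
    prot_obs <- prot_true *
      matrix(exp(rnorm(n_prot * n_samp, 0, design$noise_sd)), n_prot)

    stoich <- setNames(runif(n_site, 0.05, 0.5), catalog$site)
    ## Sites ride on the realized per-sample protein quantity (biological
    ## variation shared between a protein and its site peptides), times an
    ## independent site-level measurement noise.
    site_true <- prot_obs[catalog$accession, , drop = FALSE] * stoich *
      outer(site_fc, ifelse(is_case, 1, 0), `^`)
    rownames(site_true) <- catalog$site
    site_obs <- site_true *
      matrix(exp(rnorm(n_site * n_samp, 0, design$noise_sd)), n_site)

    site_obs <- insert_missing(site_obs, design)
    prot_obs <- insert_missing(prot_obs, design)

    truth <- data.frame(
      feature = c(catalog$site, accs),
      level = c(rep("site", n_site), rep("protein", n_prot)),
      is_spiked = c(catalog$site %in% spike_site, accs %in% spike_prot),
      true_fc = c(unname(site_fc), unname(prot_fc)),
      spike_level = c(ifelse(catalog$site %in% spike_site, "site", "none"),
                      ifelse(accs %in% spike_prot, "protein", "none")),
      stringsAsFactors = FALSE)

    list(sites = intensity_table(site_obs, group),
         proteins = intensity_table(prot_obs, group),
         truth = truth)
  })
}

## Insert missing values at design$missing_rate. MCAR by default; when
## design$mnar, cells are dropped with probability inversely related to
## their log intensity while preserving the overall expected rate.
insert_missing <- function(mat, design) {
  rate <- design$missing_rate
  if (rate == 0 || length(mat) == 0L) return(mat)
  if (!design$mnar) {
    drop <- runif(length(mat)) < rate
  } else {
    r <- rank(mat)  # low intensity -> low rank
    ## linear weighting in rank: lowest cell ~3x the rate of the highest
    wgt <- 1.5 - (r - 1) / (length(mat) - 1)
    p <- pmin(1, rate * wgt / mean(wgt))
    drop <- runif(length(mat)) < p
  }
  mat[drop] <- NA_real_
  mat
}
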