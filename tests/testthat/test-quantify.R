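mk <- function(vals, features, samples,
               groups = c("control", "control", "case", "case")) {
  intensity_table(matrix(vals, nrow = length(features), byrow = TRUE,
                         dimnames = list(features, samples)), groups)
}

test_that("median normalization equalizes column medians, preserves ranks", {
  tab <- mk(c(1, 2, 1, 2,
              10, 20, 10, 20,
              100, 200, 100, 200), c("f1", "f2", "f3"),
            c("A", "B", "C", "D"))
  out <- normalize_samples(tab)
  meds <- apply(out$values, 2, median)
  # medians 10,20,10,20 -> target 15: A,C x1.5; B,D x0.75
  expect_equal(unname(meds), rep(15, 4))
  expect_equal(out$values[, "A"], c(f1 = 1.5, f2 = 15, f3 = 150))
  expect_equal(out$values[, "B"], c(f1 = 1.5, f2 = 15, f3 = 150))

  # identity when all columns already share a median
  same <- mk(c(1, 1, 1, 1, 3, 3, 3, 3), c("f1", "f2"), c("A", "B", "C", "D"))
  expect_equal(normalize_samples(same)$values, same$values)

  # monotone scaling: per-column rank order unchanged on random input
  set.seed(11)
  r <- mk(rlnorm(40), sprintf("f%d", 1:10), c("A", "B", "C", "D"))
  rn <- normalize_samples(r)
  for (j in 1:4) {
    expect_equal(rank(rn$values[, j]), rank(r$values[, j]))
  }
})

test_that("feature centering divides by the mean of present values", {
  tab <- mk(c(2, 2, 2, 2,
              1, 2, 3, 2), c("f1", "f2"), c("A", "B", "C", "D"))
  out <- center_features(tab)
  expect_equal(unname(out$values["f1", ]), rep(1, 4))
  expect_equal(unname(out$values["f2", ]), c(0.5, 1, 1.5, 1))

  v <- matrix(c(4, NA, 8, 6), nrow = 1,
              dimnames = list("f1", c("A", "B", "C", "D")))
  withNA <- intensity_table(rbind(v, f2 = c(1, 1, 1, 1)),
                            c("control", "control", "case", "case"))
  ctr <- center_features(withNA)
  expect_equal(unname(ctr$values["f1", c("A", "C")]), c(4 / 6, 8 / 6))
  expect_true(is.na(ctr$values["f1", "B"]))
  expect_equal(unname(rowMeans(ctr$values, na.rm = TRUE)), c(1, 1),
               tolerance = 1e-9)
})

test_that("site/protein correction cancels protein trends", {
  samples <- c("A", "B", "C", "D")
  prot <- center_features(mk(c(1, 2, 3, 4), "P1", samples))
  site_same <- center_features(mk(c(2, 4, 6, 8), "P1_K5", samples))
  corr <- correct_site_by_protein(site_same, prot, c(P1_K5 = "P1"))
  expect_equal(unname(corr$values["P1_K5", ]), rep(1, 4))

  # explicit ratio: site 3.0 / protein 1.5 = 2.0 before re-centering
  site <- center_features(mk(c(3, 1.5, 0.75, 0.75), "P1_K9", samples))
  prot2 <- center_features(mk(c(1.5, 1.5, 0.5, 0.5), "P1", samples))
  raw_ratio <- site$values["P1_K9", ] / prot2$values["P1", ]
  expect_equal(unname(raw_ratio[1]), 2 * unname(raw_ratio[2]))
  corr2 <- correct_site_by_protein(site, prot2, c(P1_K9 = "P1"))
  expect_equal(unname(corr2$values["P1_K9", ]),
               unname(raw_ratio / mean(raw_ratio)))

  # orphan sites are dropped with a message
  two <- center_features(mk(c(1, 2, 3, 4, 4, 3, 2, 1),
                            c("P1_K5", "P9_K2"), samples))
  expect_message(
    dropped <- correct_site_by_protein(two, prot, c(P1_K5 = "P1", P9_K2 = "P9")),
    "1 orphan")
  expect_equal(rownames(dropped$values), "P1_K5")
})

test_that("the quantification chain is invariant to per-sample scaling", {
  set.seed(21)
  samples <- c("A", "B", "C", "D")
  sites <- sprintf("P%d_K%d", rep(1:5, each = 2), 1:10)
  map <- setNames(rep(sprintf("P%d", 1:5), each = 2), sites)
  sv <- matrix(rlnorm(40), 10, dimnames = list(sites, samples))
  pv <- matrix(rlnorm(20), 5, dimnames = list(sprintf("P%d", 1:5), samples))
  sv[2, 3] <- NA  # missingness must not break the invariance
  groups <- c("control", "control", "case", "case")
  base <- quantify_sites(intensity_table(sv, groups),
                         intensity_table(pv, groups), map)
  scale <- c(3, 0.2, 1.7, 5)
  scaled <- quantify_sites(
    intensity_table(sweep(sv, 2, scale, `*`), groups),
    intensity_table(sweep(pv, 2, scale, `*`), groups), map)
  expect_equal(scaled$sites$values, base$sites$values, tolerance = 1e-12)

  # row means over present values are 1 after every centered stage
  expect_equal(unname(rowMeans(base$sites$values, na.rm = TRUE)),
               rep(1, 10), tolerance = 1e-9)
  expect_equal(unname(rowMeans(base$proteins$values, na.rm = TRUE)),
               rep(1, 5), tolerance = 1e-9)
})

test_that("protein-only abundance changes vanish after correction", {
  des <- synthetic_design(spike_frac_sites = 0, spike_frac_proteins = 0.5,
                          true_protein_fc = 3, noise_sd = 0,
                          sample_scale_sd = 0.3, missing_rate = 0,
                          frac_modified_proteins = 1, seed = 6)
  prot <- generate_proteome(80, seed = 6)
  catalog <- generate_lactylome(prot, des)
  tabs <- generate_intensities(catalog, des)
  quant <- quantify_sites(tabs$sites, tabs$proteins,
                          setNames(catalog$accession, catalog$site))
  fc <- compute_fold_change(quant$sites)
  expect_true(all(abs(fc$log2fc) < 0.1))
  # while the raw site table carries the protein trend
  raw_fc <- compute_fold_change(center_features(normalize_samples(tabs$sites)))
  expect_gt(max(abs(raw_fc$log2fc)), 1)
})
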