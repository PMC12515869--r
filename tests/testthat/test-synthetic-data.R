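test_that("proteome generation is deterministic and respects composition", {
  expect_equal(nrow(generate_proteome(0)), 0L)

  a <- generate_proteome(5, seed = 1)
  b <- generate_proteome(5, seed = 1)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(a, f1)
  write_fasta(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a$sequence, generate_proteome(5, seed = 2)$sequence))
  expect_true(all(nchar(a$sequence) >= 30))
  expect_false(anyDuplicated(a$accession) > 0)

  uniform <- setNames(rep(1 / 20, 20), c("A", "C", "D", "E", "F", "G", "H",
                                         "I", "K", "L", "M", "N", "P", "Q",
                                         "R", "S", "T", "V", "W", "Y"))
  big <- generate_proteome(1000, composition = uniform, seed = 3)
  pooled <- table(strsplit(paste(big$sequence, collapse = ""), "")[[1]])
  freqs <- pooled / sum(pooled)
  expect_true(all(abs(freqs - 1 / 20) < 0.05))

  bad <- uniform[-1]
  expect_error(generate_proteome(5, composition = bad), "20 standard")
  expect_error(generate_proteome(5, composition = uniform * 2), "sum to 1")
})

test_that("lactylome sites land on lysines with the configured structure", {
  no_k <- data.frame(accession = "X1", sequence = "MAAAA")
  des <- synthetic_design(frac_modified_proteins = 1, seed = 1)
  expect_warning(cat0 <- generate_lactylome(no_k, des), "no lysine")
  expect_equal(nrow(cat0), 0L)

  prot <- generate_proteome(200, seed = 2)
  des1 <- synthetic_design(frac_modified_proteins = 1, single_site_frac = 1,
                           seed = 2)
  cat1 <- generate_lactylome(prot, des1)
  expect_true(all(table(cat1$accession) == 1L))

  des7 <- synthetic_design(seed = 7)
  prot500 <- generate_proteome(500, seed = 7)
  cat7 <- generate_lactylome(prot500, des7)
  counts <- table(cat7$accession)
  expect_lt(abs(mean(counts == 1) - des7$single_site_frac), 0.05)
  # every site is a K at its recorded position, no duplicates
  seqs <- setNames(prot500$sequence, prot500$accession)
  residues <- substring(seqs[cat7$accession], cat7$position, cat7$position)
  expect_true(all(residues == "K"))
  expect_false(anyDuplicated(cat7[, c("accession", "position")]) > 0)
  expect_true(all(nchar(cat7$flank) == 21L))
  expect_identical(generate_lactylome(prot500, des7), cat7)
})

test_that("intensity generation follows the generative formula", {
  prot <- generate_proteome(60, seed = 3)
  des0 <- synthetic_design(missing_rate = 0, seed = 3,
                           frac_modified_proteins = 1)
  catalog <- generate_lactylome(prot, des0)
  tabs <- generate_intensities(catalog, des0)
  expect_false(anyNA(tabs$sites$values))
  expect_false(anyNA(tabs$proteins$values))

  # noiseless, unspiked: every feature row is constant across samples
  quiet <- synthetic_design(missing_rate = 0, sample_scale_sd = 0,
                            noise_sd = 0, spike_frac_sites = 0,
                            spike_frac_proteins = 0,
                            frac_modified_proteins = 1, seed = 4)
  t0 <- generate_intensities(catalog, quiet)
  expect_true(all(apply(t0$sites$values, 1, sd) == 0))
  expect_true(all(apply(t0$proteins$values, 1, sd) == 0))

  # spiked, noiseless: observed group ratio equals the recorded truth exactly
  spiked <- synthetic_design(missing_rate = 0, sample_scale_sd = 0,
                             noise_sd = 0, spike_frac_sites = 0.2,
                             true_site_fc = 2, spike_frac_proteins = 0,
                             frac_modified_proteins = 1, seed = 5)
  ts <- generate_intensities(catalog, spiked)
  grp <- ts$sites$group
  ratio <- rowMeans(ts$sites$values[, grp == "case"]) /
    rowMeans(ts$sites$values[, grp == "control"])
  truth <- ts$truth[match(rownames(ts$sites$values), ts$truth$feature), ]
  expect_equal(unname(ratio), truth$true_fc, tolerance = 1e-12)
  expect_true(all(truth$true_fc[truth$is_spiked] != 1))
  # spike conservation
  expect_equal(sum(truth$is_spiked), round(0.2 * nrow(catalog)))

  # generative fidelity: zero noise, no spikes -> site/protein ratio constant
  ratio_sp <- t0$sites$values / t0$proteins$values[catalog$accession, ]
  expect_true(all(apply(ratio_sp, 1, function(r) diff(range(r))) < 1e-9))
})

test_that("planted-partition graphs honor their probabilities and seed", {
  g <- generate_ppi_graph(4, list(c(4, 1)), p_out = 0, seed = 1)
  expect_equal(igraph::ecount(g), 6)        # K4
  expect_equal(min(igraph::degree(g)), 3)

  g2 <- generate_ppi_graph(30, list(c(10, 0.8), c(10, 0.8)), p_out = 0,
                           seed = 2)
  memb <- igraph::V(g2)$planted
  el <- igraph::as_edgelist(g2, names = FALSE)
  expect_true(all(memb[el[, 1]] == memb[el[, 2]]))

  e1 <- igraph::as_edgelist(generate_ppi_graph(20, list(c(8, 0.5)), 0.1, seed = 5))
  e2 <- igraph::as_edgelist(generate_ppi_graph(20, list(c(8, 0.5)), 0.1, seed = 5))
  expect_identical(e1, e2)
})

test_that("gene-set generation is bounded, deterministic, GMT-stable", {
  expect_length(generate_gene_sets(letters, 0, c(2, 5)), 0)
  sets <- generate_gene_sets(letters, 8, c(4, 4), seed = 1)
  expect_true(all(lengths(sets) == 4L))
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(generate_gene_sets(letters, 5, c(2, 6), seed = 9), f1)
  write_gmt(generate_gene_sets(letters, 5, c(2, 6), seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_gene_sets(character(0), 3, c(1, 2)), "non-empty")
  expect_error(generate_gene_sets(letters, 3, c(2, 40)), "exceeds")
})
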