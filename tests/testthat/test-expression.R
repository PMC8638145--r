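make_meta <- function(reps = 3L) {
  stages <- stage_levels()
  data.frame(sample_id = as.vector(t(outer(stages, seq_len(reps),
                                           function(s, r) sprintf("%s_r%d", s, r)))),
             stage = rep(stages, each = reps),
             replicate = rep(seq_len(reps), times = length(stages)),
             stringsAsFactors = FALSE)
}

test_that("TPM normalizes by length and sums to one million", {
  counts <- matrix(c(100L, 100L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  tpm <- compute_tpm(counts, c(g1 = 2000, g2 = 1000))
  expect_equal(unname(tpm["g2", 1] / tpm["g1", 1]), 2)

  set.seed(61)
  counts <- matrix(rpois(60, 200), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  lens <- stats::setNames(sample(500:3000, 10), paste0("g", 1:10))
  tpm <- compute_tpm(counts, lens)
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)

  # scaling all counts of one sample leaves its TPM unchanged
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7L
  expect_equal(compute_tpm(scaled, lens)[, 3], tpm[, 3])

  bad <- counts; bad[, 2] <- 0L
  expect_error(compute_tpm(bad, lens), "s2")
})

test_that("stage profiles label temporal patterns", {
  meta <- make_meta(1L)
  colnames_order <- meta$sample_id
  tpm <- rbind(
    up_down = c(1, 2, 10, 5, 2, 1),
    rising = c(0, 0, 1, 2, 5, 9),
    flat = c(3, 3, 3, 3, 3, 3))
  colnames(tpm) <- colnames_order
  prof <- profile_stages(tpm, meta)
  expect_equal(prof$pattern, c("rise_then_fall", "rising", "flat"))
  expect_equal(prof$peak_stage[1], "flowering")

  expect_error(profile_stages(tpm, transform(meta, stage = "weird")),
               "unknown stage")
})

test_that("profiles are invariant to replicate order", {
  set.seed(62)
  meta <- make_meta(3L)
  tpm <- matrix(rpois(5 * 18, 50), nrow = 5,
                dimnames = list(paste0("g", 1:5), meta$sample_id))
  p1 <- profile_stages(tpm, meta)
  shuffle <- sample(ncol(tpm))
  p2 <- profile_stages(tpm[, shuffle], meta[shuffle, ])
  expect_equal(p1, p2)
})

test_that("fold changes between genes are recovered", {
  meta <- make_meta(1L)
  tpm <- rbind(a = rep(600, 6), b = rep(100, 6))
  colnames(tpm) <- meta$sample_id
  expect_equal(fold_between(tpm, meta, "a", "b", "grain"), 6)
  expect_equal(fold_between(tpm, meta, "a", "a", "grain"), 1)
  tpm["b", ] <- 0
  expect_error(fold_between(tpm, meta, "a", "b", "grain"), "zero")
})

test_that("a planted gamma-gliadin fold change survives NB noise", {
  set.seed(63)
  arrays <- data.frame(chrom = "1E", subfamily = "gamma", size = 2)
  syn <- assemble_genome(synthetic_genome_spec(arrays, divergence_pct = 2))
  truth <- plant_expression(syn$truth, scale_sd = 0,
                            fold_overrides = c(Syn_gamma_1E_1 = 5.5,
                                               Syn_gamma_1E_2 = 1))
  sim <- generate_counts(truth, nchar(syn$cds), reps = 3, dispersion = 0.1)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  f <- fold_between(tpm, sim$metadata, "Syn_gamma_1E_1", "Syn_gamma_1E_2",
                    "grain")
  expect_gt(f, 3.5)
  expect_lt(f, 8.5)
})

test_that("count simulation is seed-deterministic and mean-faithful", {
  set.seed(64)
  arrays <- data.frame(chrom = "1E", subfamily = "alpha", size = 2)
  syn <- assemble_genome(synthetic_genome_spec(arrays, divergence_pct = 2))
  truth <- plant_expression(syn$truth)

  set.seed(99)
  sim1 <- generate_counts(truth, nchar(syn$cds))
  set.seed(99)
  sim2 <- generate_counts(truth, nchar(syn$cds))
  expect_identical(sim1$counts, sim2$counts)

  # near-zero dispersion: counts concentrate on the scaled means (within 3 sd)
  set.seed(100)
  sim <- generate_counts(truth, nchar(syn$cds), dispersion = 1e-6,
                         libsize_sd = 0, depth = 50)
  mu <- truth$mean_grain * nchar(syn$cds)[truth$gene_id] / 1000 * 50
  got <- sim$counts[truth$gene_id, "grain_r1"]
  expect_true(all(abs(got - mu) <= 3 * sqrt(mu) + 3))

  expect_error(generate_counts(truth, nchar(syn$cds), dispersion = 0),
               "dispersion")
})

test_that("planted expression patterns are recovered from simulated counts", {
  set.seed(65)
  arrays <- data.frame(chrom = c("1E", "1E", "6E"),
                       subfamily = c("gamma", "LMW", "alpha"),
                       size = c(8, 8, 8))
  syn <- assemble_genome(synthetic_genome_spec(arrays, divergence_pct = 2))
  truth <- plant_expression(syn$truth)
  sim <- generate_counts(truth, nchar(syn$cds), reps = 3, dispersion = 0.1)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  prof <- profile_stages(tpm, sim$metadata)
  patterned <- truth$planted_pattern %in% c("rise_then_fall", "rising")
  agree <- prof$pattern[match(truth$gene_id[patterned], prof$gene_id)] ==
    truth$planted_pattern[patterned]
  expect_gte(mean(agree), 0.95)
})
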