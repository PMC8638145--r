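test_that("generated subfamily proteins classify to their own subfamily", {
  set.seed(31)
  for (sf in c("alpha", "gamma", "omega", "delta", "LMW", "HMW_x", "HMW_y")) {
    for (rep in 1:3) {
      g <- generate_gene(sf)
      expect_equal(classify_subfamily(g$protein)$subfamily, sf,
                   label = paste("subfamily", sf))
    }
  }
})

test_that("random proteins stay unclassified and the null motif rate is low", {
  set.seed(32)
  aas <- names(prolaminr:::RESIDUE_MASS)
  draws <- vapply(1:1000, function(i) {
    paste(sample(aas, 200, replace = TRUE), collapse = "")
  }, "")
  labels <- vapply(draws, function(p) classify_subfamily(p)$subfamily, "")
  expect_true(all(labels == "unclassified"))
  # expected motif-hit count under the null stays far below the rule minimum
  hits <- vapply(draws, function(p) {
    prolaminr:::count_motif(p, subfamily_rules()$alpha$motif)
  }, numeric(1))
  expect_lt(mean(hits), subfamily_rules()$alpha$min_motif)
})

test_that("call_status assembles defects and is deterministic", {
  set.seed(33)
  g <- generate_gene("alpha")
  cds <- coding_sequence("a1", g$cds)
  cl <- call_status(cds)
  expect_equal(cl$status, "functional")
  expect_length(cl$defects, 0)

  # one mid-sequence codon mutated to TAG
  mut <- g$cds
  substr(mut, 301, 303) <- "TAG"
  cl2 <- call_status(coding_sequence("a1", mut))
  expect_equal(cl2$status, "pseudogene")
  expect_equal(cl2$defects, "internal_stop")

  # missing start
  mut <- g$cds
  substr(mut, 1, 3) <- "CTG"
  expect_true("no_start" %in% call_status(coding_sequence("a1", mut))$defects)

  # missing terminal stop
  mut <- substr(g$cds, 1, nchar(g$cds) - 3)
  expect_true("no_terminal_stop" %in%
                call_status(coding_sequence("a1", mut))$defects)

  # frameshift
  mut <- paste0(substr(g$cds, 1, 200), substr(g$cds, 202, nchar(g$cds)))
  expect_true("frameshift" %in% call_status(coding_sequence("a1", mut))$defects)

  # intact sequence that is no prolamin: structure_incomplete pseudogene
  junk <- prolaminr:::reverse_translate(
    paste0("M", paste(sample(c("A", "L", "S", "T", "V"), 200, TRUE),
                      collapse = "")))
  cl3 <- call_status(coding_sequence("j", junk))
  expect_equal(cl3$defects, "structure_incomplete")
  expect_equal(cl3$status, "pseudogene")

  # determinism
  expect_identical(call_status(cds), call_status(cds))
})

test_that("pseudogene rates match printed-precision arithmetic", {
  rate <- pseudogene_rate(c(rep("pseudogene", 16), rep("functional", 3)))
  expect_equal(rate$pct, 84.2)
  expect_equal(rate$n_total, 19)

  expect_equal(pseudogene_rate(c(rep("pseudogene", 7),
                                 rep("functional", 2)))$pct, 77.8)
  expect_equal(pseudogene_rate(rep("functional", 5))$pct, 0)
  expect_error(pseudogene_rate(character(0)), "no calls")

  set.seed(34)
  # rate is always within [0, 1] and order-independent
  st <- sample(c("functional", "pseudogene"), 50, replace = TRUE)
  r1 <- pseudogene_rate(st)
  r2 <- pseudogene_rate(rev(st))
  expect_identical(r1, r2)
  expect_gte(r1$fraction, 0); expect_lte(r1$fraction, 1)
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(round(compute_mw("G"), 2), 75.07)
  expect_equal(round(compute_mw("GG"), 2), 132.12)
  expect_error(compute_mw(""), "empty")
  expect_error(compute_mw("GXG"), "undefined")
})

test_that("pI bisection agrees with a fine-grid charge-zero oracle", {
  pka <- bjellqvist_pka()
  grid_pi <- function(res) {
    aa <- strsplit(res, "")[[1]]
    counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                     function(a) sum(aa == a), integer(1))
    ph <- seq(0, 14, by = 1e-4)
    ch <- vapply(ph, function(p) {
      prolaminr:::protein_charge(counts, aa[1], aa[length(aa)], p, pka)
    }, numeric(1))
    ph[which.min(abs(ch))]
  }
  probes <- c("ACDEFGHIKLMNPQRSTVWY", "KKKKAAAA", "DDEEYY", "GGHHRR")
  for (p in probes) {
    expect_lt(abs(compute_pi(p) - grid_pi(p)), 0.01, label = p)
  }
  # bracket validity: charge positive at pH 0, negative at pH 14
  aa <- strsplit(probes[1], "")[[1]]
  counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                   function(a) sum(aa == a), integer(1))
  expect_gt(prolaminr:::protein_charge(counts, aa[1], aa[length(aa)], 0, pka), 0)
  expect_lt(prolaminr:::protein_charge(counts, aa[1], aa[length(aa)], 14, pka), 0)
})

test_that("pI is monotone in basic and acidic residue additions", {
  set.seed(35)
  expect_gt(compute_pi("KKKK"), compute_pi("DDDD"))
  aas <- names(prolaminr:::RESIDUE_MASS)
  for (rep in 1:10) {
    base <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    expect_gte(compute_pi(paste0(base, "K")), compute_pi(base) - 0.011)
    expect_lte(compute_pi(paste0(base, "D")), compute_pi(base) + 0.011)
  }
})
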