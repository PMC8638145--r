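random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("pair_stats reports identity, coverage and genomic distance", {
  set.seed(41)
  s <- random_dna(900)
  st <- pair_stats(s, s)
  expect_equal(st$identity_pct, 100)
  expect_equal(st$coverage_pct, 100)

  # a 50% prefix covers half of the longer sequence
  st <- pair_stats(substr(s, 1, 450), s)
  expect_equal(st$coverage_pct, 50, tolerance = 0.01)

  # 10% diverged pair: identity near 90, checked against the DP oracle
  m <- mutate_sequence(s, 10)
  st <- pair_stats(s, m)
  expect_gte(st$identity_pct, 88.5)
  expect_lte(st$identity_pct, 91.5)

  expect_error(pair_stats("", s), "empty")

  # symmetry
  a <- random_dna(600); b <- mutate_sequence(a, 8)
  expect_equal(pair_stats(a, b)$identity_pct, pair_stats(b, a)$identity_pct)

  # genomic distance is the inner gap; overlap gives 0
  ma <- gene_model("a", "c1", "+", 1000, 1899)
  mb <- gene_model("b", "c1", "+", 11900, 12799)
  st <- pair_stats(s, s, ma, mb)
  expect_equal(st$genomic_distance_bp, 10000)
  expect_true(st$same_chrom)
  mc <- gene_model("c", "c1", "+", 1500, 2399)
  expect_equal(pair_stats(s, s, ma, mc)$genomic_distance_bp, 0)
})

test_that("tandem-pair rules are strict on all three thresholds", {
  base <- list(gene_a = "a", gene_b = "b", identity_pct = 95,
               coverage_pct = 95, genomic_distance_bp = 10000,
               same_chrom = TRUE)
  expect_true(is_tandem_pair(base))
  expect_false(is_tandem_pair(modifyList(base, list(same_chrom = FALSE))))
  expect_false(is_tandem_pair(modifyList(base, list(genomic_distance_bp = 100000))))
  expect_true(is_tandem_pair(modifyList(base, list(genomic_distance_bp = 99999))))
  expect_false(is_tandem_pair(modifyList(base, list(coverage_pct = 70))))
  expect_false(is_tandem_pair(modifyList(base, list(identity_pct = 70))))
})

test_that("transitive rule links A and C through B", {
  set.seed(42)
  s <- random_dna(900)
  # A-B and B-C within 100 kb, A-C beyond it
  models <- rbind(
    gene_model("A", "c1", "+", 1000, 1899),
    gene_model("B", "c1", "+", 96000, 96899),
    gene_model("C", "c1", "+", 191000, 191899))
  seqs <- c(A = s, B = s, C = s)
  cl <- cluster_tandem(models, seqs)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("A", "B", "C"))

  # no qualifying pair: empty cluster list, and the proportion is 0
  far <- rbind(
    gene_model("A", "c1", "+", 1000, 1899),
    gene_model("B", "c1", "+", 301000, 301899))
  expect_length(cluster_tandem(far, seqs[1:2]), 0L)
  expect_equal(tandem_proportion(list(), c("A", "B"))$pct, 0)
})

test_that("planted tandem arrays are recovered with exact membership", {
  set.seed(43)
  arrays <- data.frame(chrom = c("1E", "1E", "1E"),
                       subfamily = c("gamma", "gamma", "omega"),
                       size = c(3, 1, 4))
  syn <- assemble_genome(synthetic_genome_spec(arrays, divergence_pct = 10))
  cl <- cluster_tandem(syn$models, syn$cds)
  got <- lapply(cl, `[[`, "members")
  truth_clusters <- split(syn$truth$gene_id, syn$truth$cluster_id)
  expect_length(got, length(truth_clusters))
  for (tc in truth_clusters) {
    expect_true(any(vapply(got, function(g) setequal(g, tc), logical(1))),
                label = paste("cluster", paste(tc, collapse = ",")))
  }
  # every cluster member has at least one in-cluster partner passing all rules
  for (cc in cl) {
    for (m in cc$members) {
      others <- setdiff(cc$members, m)
      ok <- vapply(others, function(o) {
        st <- pair_stats(syn$cds[[m]], syn$cds[[o]],
                         syn$models[syn$models$gene_id == m, ],
                         syn$models[syn$models$gene_id == o, ])
        is_tandem_pair(st)
      }, logical(1))
      expect_true(any(ok), label = paste("partner for", m))
    }
  }
})

test_that("collinear chains are extracted with orientation labels", {
  ch <- chain_collinear(data.frame(i = 1:3, j = 1:3))
  expect_length(ch$blocks, 1L)
  expect_equal(ch$blocks[[1]]$orientation[1], "forward")
  expect_equal(nrow(ch$blocks[[1]]), 3L)

  ch <- chain_collinear(data.frame(i = 1:3, j = 3:1))
  expect_equal(ch$blocks[[1]]$orientation[1], "inverted")

  # a forward run with an embedded inversion decomposes into two blocks and
  # leftover anchors are isolated
  anchors <- data.frame(i = c(1, 2, 3, 4, 5, 6), j = c(1, 2, 5, 4, 3, 9))
  ch <- chain_collinear(anchors)
  orient <- vapply(ch$blocks, function(b) b$orientation[1], "")
  expect_true("inverted" %in% orient)
})

test_that("chain decomposition matches brute-force search on small instances", {
  set.seed(44)
  is_monotone <- function(b) {
    ord <- order(b$i)
    jj <- b$j[ord]
    all(diff(b$i[ord]) > 0) &&
      (if (b$orientation[1] == "forward") all(diff(jj) > 0)
       else all(diff(jj) < 0))
  }
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    anchors <- data.frame(i = sample(20, n), j = sample(20, n))
    got <- chain_collinear(anchors)
    # first block attains the brute-force maximum chain length
    brute_max <- max(length(brute_longest_chain(anchors$i, anchors$j, FALSE)),
                     length(brute_longest_chain(anchors$i, anchors$j, TRUE)))
    if (brute_max >= 2L) {
      expect_equal(nrow(got$blocks[[1]]), brute_max)
    } else {
      expect_length(got$blocks, 0L)
    }
    # every block is strictly monotone in its labeled orientation
    for (b in got$blocks) expect_true(is_monotone(b))
    # blocks + isolated anchors partition the input
    all_rows <- rbind(do.call(rbind, lapply(got$blocks, function(b) b[, c("i", "j")])),
                      got$isolated[, c("i", "j")])
    expect_setequal(paste(all_rows$i, all_rows$j), paste(anchors$i, anchors$j))
    # no chain of length >= 2 remains among isolated anchors
    if (nrow(got$isolated) >= 2L) {
      expect_lte(max(length(brute_longest_chain(got$isolated$i, got$isolated$j, FALSE)),
                     length(brute_longest_chain(got$isolated$i, got$isolated$j, TRUE))),
                 1L)
    }
  }
})

test_that("reversing the second genome swaps forward and inverted blocks", {
  # a 4-anchor forward run plus a separate 2-anchor inversion
  anchors <- data.frame(i = c(1, 2, 3, 4, 5, 6), j = c(5, 6, 7, 8, 4, 3))
  fwd <- chain_collinear(anchors)
  expect_equal(vapply(fwd$blocks, function(b) b$orientation[1], ""),
               c("forward", "inverted"))
  flipped <- chain_collinear(data.frame(i = anchors$i, j = 10 - anchors$j))
  expect_equal(vapply(flipped$blocks, function(b) b$orientation[1], ""),
               c("inverted", "forward"))
  expect_equal(vapply(fwd$blocks, nrow, 0L), vapply(flipped$blocks, nrow, 0L))
})

test_that("anchor pairs + chaining recover a planted local inversion", {
  set.seed(46)
  pair <- synthetic_region_pair(
    c("gamma", "omega", "LMW", "alpha", "delta", "HMW_x"),
    divergence_pct = 12, invert = 2:4)
  anchors <- anchor_pairs(pair$seqs1, pair$seqs2)
  expect_equal(nrow(anchors), 6L) # unambiguous reciprocal-best anchors
  ch <- chain_collinear(anchors)
  orient <- vapply(ch$blocks, function(b) b$orientation[1], "")
  expect_true("inverted" %in% orient)
  # the planted inversion surfaces as a decreasing block of two anchors
  inv <- ch$blocks[[which(orient == "inverted")[1]]]
  expect_equal(nrow(inv), 2L)
})
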