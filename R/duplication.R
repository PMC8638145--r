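#' Pairwise alignment statistics for duplication calling
#'
#' Aligns two CDS nucleotide sequences globally with free end gaps and
#' reports the identity (matches / alignment columns, gaps included in the
#' denominator), the coverage (aligned non-terminal-gap span on the longer
#' sequence / longer sequence length), the genomic distance (inner gap
#' between the nearer gene boundaries, 0 when the genes overlap) and whether
#' the genes share a chromosome.
#'
#' @param seq_a,seq_b CDS nucleotide strings (or `coding_sequence`s).
#' @param model_a,model_b Optional one-row gene-model tables supplying the
#'   genomic coordinates; without them distance and chromosome are NA.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @return List with gene_a, gene_b, identity_pct, coverage_pct,
#'   genomic_distance_bp, same_chrom, score.
#' @export
pair_stats <- function(seq_a, seq_b, model_a = NULL, model_b = NULL,
                       match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  id_a <- "a"; id_b <- "b"
  if (inherits(seq_a, "coding_sequence")) { id_a <- seq_a$gene_id; seq_a <- seq_a$nucleotides }
  if (inherits(seq_b, "coding_sequence")) { id_b <- seq_b$gene_id; seq_b <- seq_b$nucleotides }
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence in pair_stats")
  if (!is.null(model_a)) id_a <- model_a$gene_id
  if (!is.null(model_b)) id_b <- model_b$gene_id
  # align with the longer sequence as the reference for coverage
  swap <- nchar(seq_a) < nchar(seq_b)
  long <- if (swap) seq_b else seq_a
  short <- if (swap) seq_a else seq_b
  aln <- cpp_align_overlap(short, long, match, mismatch, gap_open, gap_extend)
  coverage <- 100 * (aln$b_end - aln$b_start + 1) / nchar(long)
  if (aln$columns == 0L) coverage <- 0
  dist <- NA_real_; same <- NA
  if (!is.null(model_a) && !is.null(model_b)) {
    same <- model_a$chrom == model_b$chrom
    dist <- max(0L, max(model_a$start, model_b$start) -
                  min(model_a$end, model_b$end) - 1L)
  }
  list(gene_a = id_a, gene_b = id_b,
       identity_pct = aln$identity_pct, coverage_pct = coverage,
       genomic_distance_bp = dist, same_chrom = same, score = aln$score)
}

#' Tandem-duplication test for one gene pair
#'
#' A pair is tandem iff (a) both genes lie on the same chromosome less than
#' `max_dist` apart, (b) the shorter aligned sequence covers more than
#' `min_coverage` percent of the longer, and (c) the aligned identity exceeds
#' `min_identity` percent.  All three inequalities are strict.
#'
#' @param stats Output of [pair_stats()].
#' @param max_dist Maximum genomic distance in bp (default 100 kb).
#' @param min_coverage,min_identity Percent thresholds (default 70).
#' @return Logical flag.
#' @export
is_tandem_pair <- function(stats, max_dist = 1e5,
                           min_coverage = 70, min_identity = 70) {
  isTRUE(stats$same_chrom) &&
    stats$genomic_distance_bp < max_dist &&
    stats$coverage_pct > min_coverage &&
    stats$identity_pct > min_identity
}

#' Tandem clustering with the transitive rule
#'
#' Evaluates the tandem-pair relation for all same-chromosome gene pairs
#' within the distance window and extracts connected components: if A-B and
#' B-C are tandem pairs, A and C belong to one cluster even when the A-C
#' pair itself fails the criteria.  Singleton genes form no cluster.
#'
#' @param models Gene-model table.
#' @param cds_seqs Named character vector of CDS nucleotides keyed by gene id.
#' @param max_dist,min_coverage,min_identity Tandem thresholds, see
#'   [is_tandem_pair()].
#' @return List of clusters; each cluster is a list with `chrom` and
#'   `members` (gene ids ordered by coordinate).
#' @export
cluster_tandem <- function(models, cds_seqs, max_dist = 1e5,
                           min_coverage = 70, min_identity = 70) {
  n <- nrow(models)
  if (n == 0L) return(list())
  edges <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (models$chrom[i] != models$chrom[j]) next
      dist <- max(0L, max(models$start[i], models$start[j]) -
                    min(models$end[i], models$end[j]) - 1L)
      if (dist >= max_dist) next # rule (a) can never hold; skip the alignment
      st <- pair_stats(cds_seqs[[models$gene_id[i]]],
                       cds_seqs[[models$gene_id[j]]],
                       models[i, ], models[j, ])
      if (is_tandem_pair(st, max_dist, min_coverage, min_identity)) {
        edges <- c(edges, models$gene_id[i], models$gene_id[j])
      }
    }
  }
  if (length(edges) == 0L) return(list())
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  ids <- names(comp$membership)
  clusters <- lapply(seq_len(comp$no), function(k) {
    members <- ids[comp$membership == k]
    ord <- order(models$start[match(members, models$gene_id)])
    list(chrom = models$chrom[match(members[1], models$gene_id)],
         members = members[ord])
  })
  # stable order: by chromosome then leftmost member coordinate
  first_start <- vapply(clusters, function(cl) {
    models$start[match(cl$members[1], models$gene_id)]
  }, numeric(1))
  chroms <- vapply(clusters, function(cl) cl$chrom, character(1))
  clusters[order(chroms, first_start)]
}

#' Tandem-gene proportion of a subfamily
#'
#' Fraction of subfamily genes that belong to a tandem cluster of size >= 2,
#' reported with an explicit numerator and denominator (the denominator
#' convention for printed proportions is not standardized across studies).
#'
#' @param clusters Cluster list from [cluster_tandem()].
#' @param gene_ids Gene ids of the subfamily (the denominator).
#' @return List with `n_tandem`, `n_total`, `fraction`, `pct` (one decimal).
#' @export
tandem_proportion <- function(clusters, gene_ids) {
  if (length(gene_ids) == 0L) stop("no genes supplied")
  in_cluster <- unlist(lapply(clusters, function(cl) {
    if (length(cl$members) >= 2L) cl$members else character(0)
  }))
  n_tandem <- sum(gene_ids %in% in_cluster)
  frac <- n_tandem / length(gene_ids)
  list(n_tandem = n_tandem, n_total = length(gene_ids), fraction = frac,
       pct = round_half_up(100 * frac, 1L))
}

#' Chain collinear anchors into synteny blocks
#'
#' Greedy chain decomposition of reciprocal-best anchors between two ordered
#' gene lists: repeatedly extract the longest strictly monotone chain
#' (increasing in both genomes = forward, increasing in the first and
#' decreasing in the second = inverted) until no chain of length >= 2
#' remains; leftover anchors are reported as isolated.  Ties between a
#' forward and an inverted chain of equal length resolve to forward.
#'
#' @param anchors data.frame with columns `i` (index in genome 1 order),
#'   `j` (index in genome 2 order) and optionally `score`.
#' @return List with `blocks` (list of data.frames with an `orientation`
#'   attribute, also exposed as `$orientation`) and `isolated` (data.frame of
#'   unchained anchors).
#' @export
chain_collinear <- function(anchors) {
  stopifnot(all(c("i", "j") %in% names(anchors)))
  anchors <- anchors[order(anchors$i, anchors$j), , drop = FALSE]
  blocks <- list()
  remaining <- anchors
  while (nrow(remaining) >= 2L) {
    fwd <- longest_monotone_chain(remaining$i, remaining$j, decreasing = FALSE)
    inv <- longest_monotone_chain(remaining$i, remaining$j, decreasing = TRUE)
    use_fwd <- length(fwd) >= length(inv)
    chain <- if (use_fwd) fwd else inv
    if (length(chain) < 2L) break
    block <- remaining[chain, , drop = FALSE]
    block$orientation <- if (use_fwd) "forward" else "inverted"
    blocks[[length(blocks) + 1L]] <- block
    remaining <- remaining[-chain, , drop = FALSE]
  }
  rownames(remaining) <- NULL
  list(blocks = blocks, isolated = remaining)
}

# indices of the longest chain with i strictly increasing and j strictly
# increasing (forward) or strictly decreasing (inverted); O(n^2) DP
longest_monotone_chain <- function(i, j, decreasing = FALSE) {
  n <- length(i)
  if (n == 0L) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (b in seq_len(n)) {
    for (a in seq_len(b - 1L)) {
      ok <- i[a] < i[b] && (if (decreasing) j[a] > j[b] else j[a] < j[b])
      if (ok && len[a] + 1L > len[b]) {
        len[b] <- len[a] + 1L
        prev[b] <- a
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  chain
}

#' Reciprocal-best similarity anchors between two gene lists
#'
#' Aligns all gene pairs between two ordered gene lists and keeps pairs that
#' are mutual best hits by alignment score with identity above
#' `min_identity` (a stand-in for a collinearity c-score filter).  Best hits
#' are decided on the alignment score because percent identity of a short
#' spurious overlap can exceed that of a full-length homolog.
#'
#' @param seqs1,seqs2 Character vectors of CDS nucleotides, in gene order.
#' @param min_identity Minimum percent identity for an anchor (default 50).
#' @return data.frame with columns `i`, `j`, `score` (identity percent of
#'   the anchor alignment).
#' @export
anchor_pairs <- function(seqs1, seqs2, min_identity = 50) {
  n1 <- length(seqs1); n2 <- length(seqs2)
  idm <- matrix(0, n1, n2)
  scm <- matrix(-Inf, n1, n2)
  for (a in seq_len(n1)) {
    for (b in seq_len(n2)) {
      st <- pair_stats(seqs1[[a]], seqs2[[b]])
      idm[a, b] <- st$identity_pct
      scm[a, b] <- st$score
    }
  }
  out <- list()
  for (a in seq_len(n1)) {
    b <- which.max(scm[a, ])
    if (idm[a, b] > min_identity && which.max(scm[, b]) == a) {
      out[[length(out) + 1L]] <- data.frame(i = a, j = b, score = idm[a, b])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(), j = integer(), score = numeric()))
  }
  do.call(rbind, out)
}
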