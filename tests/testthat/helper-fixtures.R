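# shared fixture builders; everything is generated in code at test time

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_temp_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# brute-force overlap-aware substring counter (independent oracle)
count_sliding <- function(s, pat) {
  n <- nchar(s); m <- nchar(pat)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(s, i, i + m - 1L) == pat, logical(1)))
}

# independent local-alignment oracle (Biostrings dynamic programming)
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  Biostrings::score(pa)
}

# brute-force longest strictly monotone chain over all index subsets
brute_longest_chain <- function(i, j, decreasing = FALSE) {
  n <- length(i)
  best <- integer(0)
  for (size in rev(seq_len(n))) {
    if (size <= length(best)) break
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      ii <- i[comb]; jj <- j[comb]
      ord <- order(ii)
      ii <- ii[ord]; jj <- jj[ord]
      mono_i <- all(diff(ii) > 0)
      mono_j <- if (decreasing) all(diff(jj) < 0) else all(diff(jj) > 0)
      if (mono_i && mono_j) { best <- comb[ord]; break }
    }
    if (length(best) == size) break
  }
  best
}

# greedy block decomposition driven by the brute-force chain finder
brute_chain_blocks <- function(anchors) {
  remaining <- anchors[order(anchors$i, anchors$j), , drop = FALSE]
  sizes <- integer(0); orients <- character(0)
  while (nrow(remaining) >= 2L) {
    fwd <- brute_longest_chain(remaining$i, remaining$j, FALSE)
    inv <- brute_longest_chain(remaining$i, remaining$j, TRUE)
    use_fwd <- length(fwd) >= length(inv)
    chain <- if (use_fwd) fwd else inv
    if (length(chain) < 2L) break
    sizes <- c(sizes, length(chain))
    orients <- c(orients, if (use_fwd) "forward" else "inverted")
    remaining <- remaining[-chain, , drop = FALSE]
  }
  list(sizes = sizes, orients = orients, n_isolated = nrow(remaining))
}
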