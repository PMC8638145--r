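# required for data.table [] semantics inside the package namespace
.datatable.aware <- TRUE

#' Default homology-scan parameters
#'
#' blastn-like defaults at desk scale: word size 11, match +1 / mismatch -2,
#' affine gaps (open 5, extend 2, as positive penalties), diagonal band width
#' 32 for seed chaining, and an expected-hit-count cutoff of 1e-10.  The
#' Karlin-Altschul lambda for the chosen match/mismatch scores is solved
#' numerically at call time; K is a calibration constant.
#'
#' @param k Seed word size (8-16).
#' @param match,mismatch Match reward / mismatch penalty (mismatch negative).
#' @param gap_open,gap_extend Positive affine gap penalties.
#' @param band Diagonal band width for seed chaining.
#' @param evalue_cutoff Maximum expected random-hit count for a reported hit.
#' @param K Karlin-Altschul K constant.
#' @param max_kmer_hits Seeds from words occurring more often than this in
#'   the genome are masked (repeat/low-complexity protection).
#' @return A named list of parameters.
#' @export
scan_params <- function(k = 11L, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2,
                        band = 32L, evalue_cutoff = 1e-10, K = 0.1,
                        max_kmer_hits = 100L) {
  k <- as.integer(k)
  if (k < 8L || k > 16L) stop("seed word size k must be in [8, 16]")
  list(k = k, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       band = as.integer(band), evalue_cutoff = evalue_cutoff, K = K,
       max_kmer_hits = as.integer(max_kmer_hits),
       lambda = ka_lambda(match, mismatch))
}

# Solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for lambda under uniform base
# frequencies (the ungapped Karlin-Altschul scale parameter).
ka_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Build a k-mer seed index over a genome
#'
#' Indexes every exact k-mer of the forward strand of each chromosome;
#' k-mers containing N are skipped.  Minus-strand occurrences are retrieved
#' by looking up the reverse complement of a query word, so both strands are
#' fully searchable.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Word size (8-16).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(genome, k = 11L) {
  k <- as.integer(k)
  if (k < 8L || k > 16L) stop("seed word size k must be in [8, 16]")
  tabs <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    words <- substring(s, pos, pos + k - 1L)
    keep <- !stringi::stri_detect_fixed(words, "N")
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = words[keep], chrom = chrom, pos = pos[keep])
  })
  dt <- data.table::rbindlist(tabs)
  if (nrow(dt) > 0L) {
    kmer <- .N <- n_occ <- NULL # data.table NSE
    dt[, n_occ := .N, by = kmer]
    data.table::setkey(dt, kmer)
  }
  structure(list(table = dt, k = k,
                 genome_length = sum(nchar(genome))),
            class = "kmer_index")
}

#' Look up a k-mer in a seed index
#'
#' Returns forward-strand positions of the word and minus-strand positions,
#' i.e. forward positions of its reverse complement (the 1-based start of the
#' k-mer on the forward strand whose reverse complement equals the word).
#'
#' @param index A `kmer_index`.
#' @param word A k-length word.
#' @return A data frame with columns chrom, pos, strand.
#' @export
lookup_kmer <- function(index, word) {
  stopifnot(nchar(word) == index$k)
  kmer <- NULL # data.table NSE
  fwd <- index$table[data.table::J(word), , nomatch = NULL]
  rev <- index$table[data.table::J(revcomp(word)), , nomatch = NULL]
  out <- rbind(
    if (nrow(fwd)) data.frame(chrom = fwd$chrom, pos = fwd$pos, strand = "+"),
    if (nrow(rev)) data.frame(chrom = rev$chrom, pos = rev$pos, strand = "-"))
  if (is.null(out)) out <- data.frame(chrom = character(), pos = integer(),
                                      strand = character())
  out
}

#' Scan a genome for homologs of a query sequence
#'
#' Seed-chain-extend nucleotide homology search: exact k-mer seeds are
#' grouped per chromosome/strand into diagonal bands, each band defines a
#' candidate window, and the window is aligned to the query with an
#' affine-gap local aligner.  Hits are filtered by an expected random-hit
#' count (Karlin-Altschul form, database length = genome length) and
#' returned sorted by score.
#'
#' @param query Query nucleotide string (or `coding_sequence`).
#' @param index `kmer_index` built on `genome`.
#' @param genome Named character vector of chromosome sequences.
#' @param params [scan_params()].
#' @param query_id Identifier copied into the hit table.
#' @return data.frame with columns query_id, chrom, strand, start, end,
#'   score, identity_pct, evalue; empty on no hit.
#' @export
scan_homology <- function(query, index, genome, params = scan_params(),
                          query_id = "query") {
  if (inherits(query, "coding_sequence")) {
    query_id <- query$gene_id
    query <- query$nucleotides
  }
  k <- index$k
  qlen <- nchar(query)
  if (qlen < k) return(empty_hits())
  qpos <- seq_len(qlen - k + 1L)
  qwords <- substring(query, qpos, qpos + k - 1L)
  keep <- !stringi::stri_detect_fixed(qwords, "N")
  if (!any(keep)) return(empty_hits())
  qdt <- data.table::data.table(kmer = qwords[keep], qpos = qpos[keep])
  # forward-strand seeds: query word at genome position
  fwd <- index$table[qdt, on = "kmer", nomatch = NULL]
  # minus-strand seeds: revcomp of the query matches forward genome; a query
  # word at qpos corresponds to the genome word whose revcomp it equals
  rdt <- data.table::data.table(kmer = revcomp(qwords[keep]), qpos = qpos[keep])
  rev <- index$table[rdt, on = "kmer", nomatch = NULL]
  # mask seeds from over-represented words (repeats, low complexity)
  if (!is.null(params$max_kmer_hits)) {
    fwd <- fwd[fwd$n_occ <= params$max_kmer_hits, ]
    rev <- rev[rev$n_occ <= params$max_kmer_hits, ]
  }
  wins <- list()
  if (nrow(fwd)) {
    fwd$diag <- fwd$pos - fwd$qpos
    wins[["+"]] <- band_windows(fwd, params$band, k, qlen)
  }
  if (nrow(rev)) {
    # on the minus strand the anti-diagonal pos + qpos is conserved
    rev$diag <- rev$pos + rev$qpos
    wins[["-"]] <- band_windows(rev, params$band, k, qlen)
  }
  windows <- data.table::rbindlist(wins, idcol = "strand")
  if (nrow(windows) == 0L) return(empty_hits())
  windows$gmin <- pmax(1L, windows$gmin)
  windows$gmax <- pmin(nchar(genome)[windows$chrom], windows$gmax)
  params$genome_length <- index$genome_length
  windows <- merge_windows(as.data.frame(windows))
  out <- lapply(seq_len(nrow(windows)), function(i) {
    align_window(windows[i, ], query, genome, params)
  })
  out <- do.call(rbind, out)
  out$query_id <- query_id
  out <- out[out$evalue <= params$evalue_cutoff & out$score > 0, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  # drop hits nested inside a better hit on the same chrom/strand
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (out$chrom[i] == out$chrom[j] && out$strand[i] == out$strand[j] &&
            out$start[i] >= out$start[j] - 50 && out$end[i] <= out$end[j] + 50) {
          keep[i] <- FALSE; break
        }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("query_id", "chrom", "strand", "start", "end",
          "score", "identity_pct", "evalue")]
}

empty_hits <- function() {
  data.frame(query_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), score = numeric(),
             identity_pct = numeric(), evalue = numeric())
}

# group seeds on one strand into diagonal bands (transitive closure within
# `band`), split bands at large genomic gaps (distinct loci can share a
# diagonal by chance), and emit one candidate window per band of >= 2 seeds;
# windows spawned by low-complexity seed chains are clamped to the densest
# region since a real hit cannot be much longer than the query
band_windows <- function(dt, band, k, qlen, max_gap = 5000L) {
  chrom <- diag <- pos <- g1 <- g2 <- n <- gmin <- gmax <- mid <- NULL
  dt <- data.table::as.data.table(dt)
  data.table::setorder(dt, chrom, diag)
  dt[, g1 := cumsum(c(1L, diff(diag) > band)), by = chrom]
  data.table::setorder(dt, chrom, g1, pos)
  dt[, g2 := cumsum(c(1L, diff(pos) > max_gap)), by = list(chrom, g1)]
  w <- dt[, list(n = .N, gmin = min(pos), gmax = max(pos),
                 mid = as.integer(stats::median(pos))),
          by = list(chrom, g1, g2)]
  w <- w[n >= 2L]
  flank <- max(200L, qlen %/% 4L)
  cap <- qlen + 2L * flank + 500L
  w[, gmax := gmax + k - 1L + flank]
  w[, gmin := gmin - flank]
  too_wide <- w$gmax - w$gmin + 1L > cap
  w$gmin[too_wide] <- w$mid[too_wide] - cap %/% 2L
  w$gmax[too_wide] <- w$mid[too_wide] + cap %/% 2L
  w[, list(chrom, gmin, gmax)]
}

# union overlapping / adjacent candidate windows per chromosome and strand
merge_windows <- function(w, slop = 100L) {
  w <- w[order(w$chrom, w$strand, w$gmin), , drop = FALSE]
  key <- paste(w$chrom, w$strand)
  out <- list()
  for (kk in unique(key)) {
    sub <- w[key == kk, , drop = FALSE]
    cur <- sub[1, ]
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$gmin[i] <= cur$gmax + slop) {
          cur$gmax <- max(cur$gmax, sub$gmax[i])
        } else {
          out[[length(out) + 1L]] <- cur
          cur <- sub[i, ]
        }
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# local alignment of the query against one merged candidate window
align_window <- function(win, query, genome, params) {
  window <- substr(genome[[win$chrom]], win$gmin, win$gmax)
  q <- if (win$strand == "-") revcomp(query) else query
  aln <- cpp_align_local(q, window, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
  evalue <- params$K * nchar(query) * params$genome_length *
    exp(-params$lambda * aln$score)
  data.frame(chrom = win$chrom, strand = win$strand,
             start = win$gmin + aln$b_start - 1L,
             end = win$gmin + aln$b_end - 1L,
             score = aln$score, identity_pct = aln$identity_pct,
             evalue = evalue)
}

#' Merge homology hits into candidate loci
#'
#' Hits on the same chromosome and strand whose spans lie within `merge_gap`
#' of each other are unioned into one candidate locus.  For each locus the
#' longest open reading frame (ATG to in-frame stop, on the locus strand)
#' within the locus extended by `flank` is reported; loci without a complete
#' ORF are retained with an empty ORF span, which is what later flags them as
#' pseudogene candidates.
#'
#' @param hits Hit table from [scan_homology()] (possibly several queries).
#' @param genome Named character vector of chromosome sequences.
#' @param merge_gap Maximum gap (nt) between hits merged into one locus.
#' @param flank Flank (nt) searched for the ORF beyond the merged span.
#' @return data.frame with columns chrom, strand, start, end, n_hits,
#'   best_identity, orf_start, orf_end (NA when no complete ORF).
#' @export
merge_to_loci <- function(hits, genome, merge_gap = 2000L, flank = 1000L) {
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), n_hits = integer(),
                      best_identity = numeric(), orf_start = integer(),
                      orf_end = integer()))
  }
  hits <- hits[order(hits$chrom, hits$strand, hits$start), , drop = FALSE]
  key <- paste(hits$chrom, hits$strand)
  loci <- list()
  for (kk in unique(key)) {
    sub <- hits[key == kk, , drop = FALSE]
    cur_start <- sub$start[1]; cur_end <- sub$end[1]
    cur_n <- 1L; cur_id <- sub$identity_pct[1]
    flush <- function(s, e, n, id) {
      loci[[length(loci) + 1L]] <<- data.frame(
        chrom = sub$chrom[1], strand = sub$strand[1], start = s, end = e,
        n_hits = n, best_identity = id)
    }
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] <= cur_end + merge_gap) {
          cur_end <- max(cur_end, sub$end[i])
          cur_n <- cur_n + 1L
          cur_id <- max(cur_id, sub$identity_pct[i])
        } else {
          flush(cur_start, cur_end, cur_n, cur_id)
          cur_start <- sub$start[i]; cur_end <- sub$end[i]
          cur_n <- 1L; cur_id <- sub$identity_pct[i]
        }
      }
    }
    flush(cur_start, cur_end, cur_n, cur_id)
  }
  out <- do.call(rbind, loci)
  orf <- lapply(seq_len(nrow(out)), function(i) {
    ws <- max(1L, out$start[i] - flank)
    we <- min(nchar(genome[[out$chrom[i]]]), out$end[i] + flank)
    window <- substr(genome[[out$chrom[i]]], ws, we)
    find_longest_orf(window, out$strand[i], offset = ws)
  })
  out$orf_start <- as.integer(vapply(orf, function(o) as.numeric(o$start), numeric(1)))
  out$orf_end <- as.integer(vapply(orf, function(o) as.numeric(o$end), numeric(1)))
  rownames(out) <- NULL
  out
}

# longest ATG..stop ORF in a window; returns genomic coordinates (1-based,
# inclusive, including the stop codon) or NA/NA when none exists
find_longest_orf <- function(window, strand, offset = 1L) {
  seq <- if (strand == "-") revcomp(window) else window
  n <- nchar(seq)
  best_len <- 0L; best_s <- NA_integer_; best_e <- NA_integer_
  starts <- stringi::stri_locate_all_fixed(seq, "ATG")[[1]][, 1]
  stops <- sort(unlist(lapply(STOP_CODONS, function(sc) {
    stringi::stri_locate_all_fixed(seq, sc)[[1]][, 1]
  })))
  stops <- stops[!is.na(stops)]
  if (length(starts) == 0L || all(is.na(starts))) {
    return(list(start = NA_integer_, end = NA_integer_))
  }
  for (fr in 0:2) {
    fstarts <- starts[!is.na(starts) & (starts - 1L) %% 3L == fr]
    fstops <- stops[(stops - 1L) %% 3L == fr]
    if (length(fstarts) == 0L || length(fstops) == 0L) next
    i <- 1L
    for (s in fstarts) {
      nxt <- fstops[fstops >= s + 3L]
      if (length(nxt) == 0L) next
      e <- nxt[1] + 2L
      len <- e - s + 1L
      if (len > best_len) { best_len <- len; best_s <- s; best_e <- e }
    }
  }
  if (is.na(best_s)) return(list(start = NA_integer_, end = NA_integer_))
  if (strand == "-") {
    # map back from reverse-complemented coordinates
    s2 <- n - best_e + 1L; e2 <- n - best_s + 1L
    list(start = offset + s2 - 1L, end = offset + e2 - 1L)
  } else {
    list(start = offset + best_s - 1L, end = offset + best_e - 1L)
  }
}
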