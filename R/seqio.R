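#' @useDynLib prolaminr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a nucleotide FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector of uppercase
#' nucleotide sequences.  IUPAC ambiguity codes other than N are coerced to N
#' so that downstream translation and pseudogene calling stay conservative
#' (codons containing N translate to X, never to a stop).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header, values are sequences over `{A,C,G,T,N}`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA (no '>' header on first line): ", path)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(seqs))) stop("empty sequence record in FASTA: ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is a one-row data frame describing a located gene: id,
#' chromosome, strand, 1-based inclusive genomic span, an ordered set of CDS
#' segments (stored as a list column of two-column start/end matrices in
#' genomic order) and a genome/subgenome label.  Multiple models are combined
#' with `rbind()`.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive genomic coordinates of the gene.
#' @param cds_segments Two-column matrix (start, end) of CDS segments,
#'   1-based inclusive; defaults to the full gene span (prolamin genes are
#'   intronless).
#' @param genome Genome or subgenome label (e.g. `"E"`, `"A"`).
#' @return A one-row `data.frame` with a `cds` list column.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       cds_segments = NULL, genome = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("gene ", gene_id, ": start must be <= end")
  }
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": strand must be '+' or '-'")
  if (is.null(cds_segments)) cds_segments <- cbind(start, end)
  cds_segments <- matrix(as.integer(cds_segments), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  cds_segments <- cds_segments[order(cds_segments[, 1]), , drop = FALSE]
  if (any(cds_segments[, 1] > cds_segments[, 2])) {
    stop("gene ", gene_id, ": CDS segment with start > end")
  }
  if (any(cds_segments[, 1] < start) || any(cds_segments[, 2] > end)) {
    stop("gene ", gene_id, ": CDS segment outside gene span")
  }
  if (nrow(cds_segments) > 1 &&
      any(cds_segments[-1, 1] <= cds_segments[-nrow(cds_segments), 2])) {
    stop("gene ", gene_id, ": overlapping CDS segments")
  }
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    start = start, end = end, genome = genome,
                    stringsAsFactors = FALSE)
  out$cds <- list(cds_segments)
  out
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file restricted to gene/mRNA/CDS features with ID/Parent
#' attributes and returns a gene-model table (one row per gene, CDS segments
#' grouped under their gene).  CDS features are resolved to a gene either
#' directly or through an mRNA parent; a gene with a single CDS and no mRNA
#' line is accepted (intronless prolamin convention).
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model `data.frame` as produced by [gene_model()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  genes <- which(type == "gene")
  if (length(genes) == 0L) stop("no gene features in GFF3: ", path)
  # map mRNA id -> gene id
  mrna2gene <- list()
  for (i in which(type == "mRNA")) {
    par <- unlist(gr$Parent[i])
    if (length(par) != 1L) stop("mRNA without single Parent in GFF3: ", ids[i])
    mrna2gene[[ids[i]]] <- par
  }
  gene_ids <- ids[genes]
  cds_by_gene <- stats::setNames(vector("list", length(genes)), gene_ids)
  for (i in which(type == "CDS")) {
    par <- unlist(gr$Parent[i])
    if (length(par) == 0L) {
      stop("CDS feature without Parent in GFF3 (record ", i, ")")
    }
    gid <- if (par %in% gene_ids) par else unlist(mrna2gene[par])
    if (is.null(gid) || !gid %in% gene_ids) {
      stop("CDS with unresolvable Parent '", par, "' in GFF3 (record ", i, ")")
    }
    cds_by_gene[[gid]] <- rbind(cds_by_gene[[gid]],
                                c(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }
  rows <- lapply(seq_along(genes), function(k) {
    i <- genes[k]
    gid <- gene_ids[k]
    segs <- cds_by_gene[[gid]]
    if (is.null(segs)) segs <- cbind(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    genome <- if (!is.null(gr$genome)) as.character(gr$genome[i]) else NA_character_
    gene_model(gid, as.character(GenomicRanges::seqnames(gr)[i]),
               as.character(GenomicRanges::strand(gr)[i]),
               GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
               cds_segments = segs, genome = genome)
  })
  do.call(rbind, rows)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS lines for each model, with ID/Parent attributes.
#'
#' @param models Gene-model table ([gene_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    segs <- m$cds[[1]]
    n <- nrow(segs)
    # CDS phase in transcription order per the GFF3 spec
    tx <- if (m$strand == "-") rev(seq_len(n)) else seq_len(n)
    lens <- segs[tx, 2] - segs[tx, 1] + 1L
    phase_tx <- c(0L, cumsum(lens)[-n] %% 3L)
    phase_tx <- (3L - phase_tx) %% 3L
    phase <- integer(n)
    phase[tx] <- phase_tx
    data.frame(
      chrom = m$chrom,
      start = c(m$start, m$start, segs[, 1]),
      end = c(m$end, m$end, segs[, 2]),
      strand = m$strand,
      type = c("gene", "mRNA", rep("CDS", n)),
      ID = c(m$gene_id, paste0(m$gene_id, ".1"),
             paste0(m$gene_id, ".1.cds", seq_len(n))),
      Parent = c(NA, m$gene_id, rep(paste0(m$gene_id, ".1"), n)),
      phase = c(NA, NA, phase),
      genome = m$genome,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = unique(df$chrom)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    type = df$type, ID = df$ID, Parent = df$Parent,
    phase = df$phase, genome = df$genome)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse complement(s).
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Extract a spliced coding sequence from a genome
#'
#' Splices the CDS segments of a gene model out of the genome and orients
#' them 5' to 3' (reverse complementing minus-strand genes).  The result is a
#' `coding_sequence` whose `complete_flag` is `TRUE` iff the sequence length
#' is a multiple of 3 and its final codon is a stop (`TAA`/`TAG`/`TGA`).
#'
#' @param model One-row gene-model table.
#' @param genome Named character vector of chromosome sequences.
#' @return A `coding_sequence`: list with `gene_id`, `nucleotides`,
#'   `complete_flag`.
#' @export
extract_cds <- function(model, genome) {
  stopifnot(nrow(model) == 1L)
  chrom_seq <- genome[[model$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", model$chrom)
  segs <- model$cds[[1]]
  if (any(segs[, 1] < 1L) || any(segs[, 2] > nchar(chrom_seq))) {
    stop("gene ", model$gene_id, ": CDS segment outside chromosome bounds")
  }
  parts <- substring(chrom_seq, segs[, 1], segs[, 2])
  nt <- paste(parts, collapse = "")
  if (model$strand == "-") nt <- revcomp(nt)
  coding_sequence(model$gene_id, nt)
}

#' Construct a coding sequence record
#'
#' @param gene_id Gene identifier.
#' @param nucleotides Spliced, 5'-to-3' oriented CDS nucleotides.
#' @return A `coding_sequence` list.
#' @export
coding_sequence <- function(gene_id, nucleotides) {
  nucleotides <- toupper(nucleotides)
  n <- nchar(nucleotides)
  complete <- n >= 3L && n %% 3L == 0L &&
    substr(nucleotides, n - 2L, n) %in% STOP_CODONS
  structure(list(gene_id = gene_id, nucleotides = nucleotides,
                 complete_flag = complete),
            class = "coding_sequence")
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation.  A terminal stop codon is dropped; any
#' stop before the final codon is rendered as `X` in the residues and its
#' 1-based codon index recorded in `internal_stop_positions`.  Codons
#' containing `N` translate to `X`.  A trailing incomplete codon is dropped
#' and flagged as a frameshift.
#'
#' @param cds A `coding_sequence` (or plain nucleotide string).
#' @param gene_id Identifier used when `cds` is a plain string.
#' @return A `protein_record`: list with `gene_id`, `residues`,
#'   `internal_stop_positions`, `frameshift`.
#' @export
translate_cds <- function(cds, gene_id = NULL) {
  if (is.character(cds)) cds <- coding_sequence(gene_id %||% "seq", cds)
  nt <- cds$nucleotides
  n <- nchar(nt)
  if (n < 3L) stop("coding sequence shorter than one codon: ", cds$gene_id)
  frameshift <- n %% 3L != 0L
  ncod <- n %/% 3L
  codons <- substring(nt, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # codons containing N (or other coerced ambiguity)
  is_stop <- codons %in% STOP_CODONS
  terminal_stop <- !frameshift && is_stop[ncod]
  if (terminal_stop) {
    aa <- aa[-ncod]
    is_stop <- is_stop[-ncod]
  }
  internal <- which(is_stop)
  aa[is_stop] <- "X"
  structure(list(gene_id = cds$gene_id,
                 residues = paste(aa, collapse = ""),
                 internal_stop_positions = as.integer(internal),
                 frameshift = frameshift),
            class = "protein_record")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt, terminal stop: %s\n",
              x$gene_id, nchar(x$nucleotides), x$complete_flag))
  invisible(x)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, internal stops: %d%s\n",
              x$gene_id, nchar(x$residues), length(x$internal_stop_positions),
              if (isTRUE(x$frameshift)) ", frameshift" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
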