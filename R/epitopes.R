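#' Default celiac-disease epitope definitions
#'
#' The six alpha-gliadin-derived peptides most relevant to celiac disease:
#' DQ2.5-glia-alpha1a (PFPQPQLPY), DQ2.5-glia-alpha1b (PYPQPQLPY),
#' DQ2.5-glia-alpha2 (PQPQLPYPQ), DQ2.5-glia-alpha3, DQ8-glia-alpha1 /
#' DQ8.5-glia-alpha1 (QGSFQPSQQ), and the proteolysis-resistant 33-mer
#' (LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF) which itself contains multiple
#' overlapping copies of the first three.  Two spellings of
#' DQ2.5-glia-alpha3 circulate in the literature (a 9-mer FRPQQPYPQ and a
#' 10-mer FRPQQQPYPQ); the 9-mer is active by default and the alternative is
#' selectable.
#'
#' @param alpha3 Which DQ2.5-glia-alpha3 spelling to use: `"9mer"`
#'   (FRPQQPYPQ, default) or `"10mer"` (FRPQQQPYPQ).
#' @return data.frame with columns `name`, `peptide`.
#' @export
default_epitopes <- function(alpha3 = c("9mer", "10mer")) {
  alpha3 <- match.arg(alpha3)
  data.frame(
    name = c("DQ2.5-glia-a1a", "DQ2.5-glia-a1b", "DQ2.5-glia-a2",
             "DQ2.5-glia-a3", "DQ8-glia-a1", "33mer"),
    peptide = c("PFPQPQLPY", "PYPQPQLPY", "PQPQLPYPQ",
                if (alpha3 == "9mer") "FRPQQPYPQ" else "FRPQQQPYPQ",
                "QGSFQPSQQ",
                "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"),
    stringsAsFactors = FALSE)
}

#' Read an epitope definition table
#'
#' Two-column whitespace- or tab-delimited text: name, peptide.
#'
#' @param path Path to the table.
#' @return data.frame with columns `name`, `peptide`.
#' @export
read_epitopes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("name", "peptide"))
  if (any(nchar(df$peptide) < 9L)) stop("epitope peptides must be >= 9 residues")
  df
}

#' Scan a protein for CD epitopes
#'
#' Counts all exact occurrences of each epitope peptide by sliding window,
#' counting overlapping occurrences separately, and assigns a multiplicity
#' class (absent / single / multiple).  Epitope retrieval is defined on
#' deduced functional proteins; scanning a pseudogene translation requires
#' an explicit override.
#'
#' @param protein A `protein_record` or residue string.
#' @param defs Epitope definitions ([default_epitopes()]).
#' @param status Functional status of the protein (`"functional"` or
#'   `"pseudogene"`); pseudogenes are refused unless `force = TRUE`.
#' @param force Scan even if `status != "functional"`.
#' @return An `epitope_profile`: data.frame with columns `name`, `peptide`,
#'   `count`, `class`, and a `gene_id` attribute.
#' @export
scan_epitopes <- function(protein, defs = default_epitopes(),
                          status = "functional", force = FALSE) {
  gene_id <- "protein"
  res <- protein
  if (inherits(protein, "protein_record")) {
    gene_id <- protein$gene_id
    res <- protein$residues
  }
  if (status != "functional" && !force) {
    stop("epitope scan refused for non-functional protein '", gene_id,
         "' (set force = TRUE to override)")
  }
  counts <- vapply(defs$peptide, function(p) {
    stringi::stri_count_fixed(res, p, overlap = TRUE)
  }, integer(1))
  out <- data.frame(name = defs$name, peptide = defs$peptide,
                    count = unname(counts),
                    class = ifelse(counts == 0L, "absent",
                                   ifelse(counts == 1L, "single", "multiple")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gene_id") <- gene_id
  class(out) <- c("epitope_profile", "data.frame")
  out
}

#' Summarize epitope repertoires per genome
#'
#' Carrier fractions over the functional alpha-gliadins of one genome: for
#' each epitope the percentage of proteins carrying it at least once, for
#' the union set DQ2.5-glia-alpha1a or DQ2.5-glia-alpha3, and for proteins
#' whose only epitope is DQ8-glia-alpha1/DQ8.5-glia-alpha1 (the 33-mer is a
#' container peptide, not a separate epitope type, and is excluded from the
#' "no other epitope" test).  Percentages are one-decimal.
#'
#' @param profiles List of `epitope_profile`s (one per functional protein).
#' @param genome_label Genome name for the summary row.
#' @return List with `genome`, `n_proteins`, `carrier_pct` (named vector),
#'   `alpha1a_or_alpha3_pct`, `dq8_only_pct`.
#' @export
summarize_genome <- function(profiles, genome_label = "genome") {
  if (length(profiles) == 0L) stop("no epitope profiles supplied")
  counts <- do.call(rbind, lapply(profiles, function(p) {
    stats::setNames(p$count, p$name)
  }))
  n <- nrow(counts)
  carrier <- 100 * colMeans(counts > 0L)
  nm <- colnames(counts)
  a1a <- counts[, grep("a1a$", nm), drop = TRUE]
  a3 <- counts[, grep("a3$", nm), drop = TRUE]
  dq8 <- counts[, grep("DQ8", nm), drop = TRUE]
  small <- counts[, !grepl("33mer", nm) & !grepl("DQ8", nm), drop = FALSE]
  dq8_only <- dq8 > 0L & rowSums(small > 0L) == 0L
  list(genome = genome_label, n_proteins = n,
       carrier_pct = round_half_up(carrier, 1L),
       alpha1a_or_alpha3_pct = round_half_up(100 * mean(a1a > 0L | a3 > 0L), 1L),
       dq8_only_pct = round_half_up(100 * mean(dq8_only), 1L))
}
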