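test_that("read_fasta parses records, folds lines and normalizes case/alphabet", {
  p <- write_temp_fasta(c(">c1", "ACGT"))
  expect_equal(read_fasta(p), c(c1 = "ACGT"))

  p <- write_temp_fasta(c(">c1", "AC", "GT", ">c2", "NN"))
  got <- read_fasta(p)
  expect_equal(got, c(c1 = "ACGT", c2 = "NN"))
  expect_equal(names(got), c("c1", "c2"))

  p <- write_temp_fasta(c(">c1 description here", "acgt"))
  expect_equal(read_fasta(p), c(c1 = "ACGT"))

  # ambiguity codes other than N are coerced to N
  p <- write_temp_fasta(c(">c1", "ACRYGT"))
  expect_equal(unname(read_fasta(p)), "ACNNGT")

  p <- tempfile(); writeLines("ACGT", p)
  expect_error(read_fasta(p), "malformed")
})

test_that("fasta write/read round trip preserves sequences", {
  set.seed(42)
  seqs <- stats::setNames(
    vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T"), 137 * i, replace = TRUE),
            collapse = "")
    }, ""),
    paste0("chr", 1:5))
  p <- tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  expect_identical(read_fasta(p), seqs)
  # wrapped at 60 columns
  expect_lte(max(nchar(readLines(p))), 60L)
})

test_that("read_gff3 groups CDS under genes and validates structure", {
  p <- write_temp_gff(c(
    gff_line("c1", "gene", 100, 250, "+", "ID=g1"),
    gff_line("c1", "mRNA", 100, 250, "+", "ID=g1.t1;Parent=g1"),
    gff_line("c1", "CDS", 100, 150, "+", "ID=g1.c1;Parent=g1.t1"),
    gff_line("c1", "CDS", 200, 250, "+", "ID=g1.c2;Parent=g1.t1")))
  m <- read_gff3(p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cds[[1]], cbind(start = c(100L, 200L), end = c(150L, 250L)))

  # minus strand: segments kept in genomic order, strand propagated
  p <- write_temp_gff(c(
    gff_line("c1", "gene", 100, 250, "-", "ID=g1"),
    gff_line("c1", "mRNA", 100, 250, "-", "ID=g1.t1;Parent=g1"),
    gff_line("c1", "CDS", 200, 250, "-", "ID=g1.c1;Parent=g1.t1"),
    gff_line("c1", "CDS", 100, 150, "-", "ID=g1.c2;Parent=g1.t1")))
  m <- read_gff3(p)
  expect_equal(m$strand, "-")
  expect_equal(m$cds[[1]][, "start"], c(100L, 200L))

  # single-CDS gene without an mRNA line is accepted (intronless convention)
  p <- write_temp_gff(c(
    gff_line("c1", "gene", 10, 60, "+", "ID=g1"),
    gff_line("c1", "CDS", 10, 60, "+", "ID=g1.c1;Parent=g1")))
  expect_equal(nrow(read_gff3(p)), 1L)

  # CDS outside the gene span violates the gene-model invariant
  p <- write_temp_gff(c(
    gff_line("c1", "gene", 100, 200, "+", "ID=g1"),
    gff_line("c1", "CDS", 150, 250, "+", "ID=g1.c1;Parent=g1")))
  expect_error(read_gff3(p), "outside gene span")

  # CDS with unresolvable parent
  p <- write_temp_gff(c(
    gff_line("c1", "gene", 100, 200, "+", "ID=g1"),
    gff_line("c1", "CDS", 100, 200, "+", "ID=x.c1;Parent=ghost")))
  expect_error(read_gff3(p), "unresolvable Parent")
})

test_that("gene models round trip through GFF3", {
  m <- rbind(
    gene_model("gA", "1E", "+", 1000, 1899, genome = "E"),
    gene_model("gB", "1E", "-", 5000, 5899, genome = "E"))
  p <- tempfile(fileext = ".gff3")
  write_gff3(m, p)
  m2 <- read_gff3(p)
  expect_equal(m2$gene_id, m$gene_id)
  expect_equal(m2$strand, m$strand)
  expect_equal(m2$start, m$start)
  expect_equal(m2$cds, m$cds, ignore_attr = TRUE)
})

test_that("extract_cds splices, orients and flags terminal stops", {
  g <- c(c1 = "ATGTAA")
  m <- gene_model("g1", "c1", "+", 1, 6)
  cds <- extract_cds(m, g)
  expect_equal(cds$nucleotides, "ATGTAA")
  expect_true(cds$complete_flag)

  g <- c(c1 = "TTACAT")
  m <- gene_model("g1", "c1", "-", 1, 6)
  expect_equal(extract_cds(m, g)$nucleotides, "ATGTAA")

  g <- c(c1 = "ATGTA")
  m <- gene_model("g1", "c1", "+", 1, 5)
  cds <- extract_cds(m, g)
  expect_equal(cds$nucleotides, "ATGTA")
  expect_false(cds$complete_flag)

  g <- c(c1 = "ATG")
  m <- gene_model("g1", "c1", "+", 1, 3)
  m$cds[[1]] <- cbind(start = 1L, end = 9L)
  expect_error(extract_cds(m, g), "outside chromosome bounds")
})

test_that("minus-strand extraction equals reverse complement of the mirror", {
  set.seed(11)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    g <- c(c1 = s)
    st <- sample(1:100, 1); en <- st + sample(30:150, 1)
    plus <- extract_cds(gene_model("g", "c1", "+", st, en), g)
    minus <- extract_cds(gene_model("g", "c1", "-", st, en), g)
    expect_equal(minus$nucleotides, revcomp(plus$nucleotides))
  }
})

test_that("translation handles stops, internal stops and frameshifts", {
  p <- translate_cds(coding_sequence("t", "ATGTAA"))
  expect_equal(p$residues, "M")
  expect_length(p$internal_stop_positions, 0)

  p <- translate_cds(coding_sequence("t", "ATGTAGGGCTAA"))
  expect_equal(p$residues, "MXG")
  expect_equal(p$internal_stop_positions, 2L)

  p <- translate_cds(coding_sequence("t", "ATGGG"))
  expect_equal(p$residues, "M")
  expect_true(p$frameshift)

  # codons containing N translate to X, never to a stop
  p <- translate_cds(coding_sequence("t", "ATGANATAA"))
  expect_equal(p$residues, "MX")
  expect_length(p$internal_stop_positions, 0)

  expect_error(translate_cds(coding_sequence("t", "AT")), "shorter")
})

test_that("translated length follows spliced length arithmetic", {
  set.seed(13)
  for (rep in 1:10) {
    ncod <- sample(20:80, 1)
    aa <- sample(setdiff(names(prolaminr:::RESIDUE_MASS), "M"), ncod - 1,
                 replace = TRUE)
    prot <- paste0("M", paste(aa, collapse = ""))
    cds <- prolaminr:::reverse_translate(prot) # includes terminal stop
    p <- translate_cds(coding_sequence("t", cds))
    expect_equal(nchar(p$residues), nchar(cds) / 3 - 1)
    expect_equal(p$residues, prot)
  }
})
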