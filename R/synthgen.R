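# Fixed reverse-translation codon table (one common codon per amino acid);
# synonymous wobble variants are introduced separately when array copies are
# diverged, so the protein-level truth labels stay exact.
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAC", I = "ATC", L = "CTT", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT")

reverse_translate <- function(residues, stop_codon = "TAA") {
  aa <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(aa), names(CODON_OF))
  if (length(bad)) stop("cannot reverse-translate residues: ",
                        paste(bad, collapse = ","))
  paste0(paste(CODON_OF[aa], collapse = ""), stop_codon)
}

# repeat `unit` to exactly `len` residues
make_block <- function(len, unit) {
  substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
}

# place n cysteines at roughly even positions inside a cysteine-free block
with_cys <- function(block, n) {
  if (n == 0L) return(block)
  pos <- round(seq(3, nchar(block) - 2, length.out = n))
  for (p in pos) substr(block, p, p) <- "C"
  block
}

SIGNAL_GLIADIN <- "MKTFLILALLAIVATTA"
SIGNAL_LMW <- "MKTFLVFALLAVAATSA"
SIGNAL_HMW <- "MAKRLVLFAAVVIALVALSA"

#' Generate a synthetic prolamin-like gene
#'
#' Builds a protein with the canonical prolamin domain architecture of the
#' requested subfamily -- signal peptide, subfamily-specific repetitive
#' domain, polyglutamine tracts where applicable, and a cysteine-bearing
#' C-terminal domain with the subfamily's diagnostic cysteine count -- and
#' reverse-translates it into a CDS (ATG start, terminal stop).  The repeat
#' count and C-terminal length are drawn within the subfamily's length range
#' from the session RNG, so output is reproducible under `set.seed()`, and
#' the translation always satisfies [classify_subfamily()] for the requested
#' subfamily (closed loop by construction).
#'
#' @param subfamily One of `alpha`, `gamma`, `omega`, `delta`, `LMW`,
#'   `HMW_x`, `HMW_y`.
#' @param gene_id Identifier for the returned records.
#' @return List with `gene_id`, `subfamily`, `protein` (residues), `cds`
#'   (nucleotides).
#' @export
generate_gene <- function(subfamily, gene_id = subfamily) {
  # cysteine-free, motif-inert C-terminal filler, distinct per subfamily so
  # that cross-subfamily sequence identity stays at a realistic level (well
  # below the 70% tandem/duplication thresholds)
  protein <- switch(
    subfamily,
    alpha = paste0(
      SIGNAL_GLIADIN,
      strrep("PQPQPF", sample(11:13, 1L)),
      strrep("Q", 8L), "L", strrep("Q", 8L), "L",
      with_cys(make_block(sample(150:170, 1L), "LQESKPAS"), 6L)),
    gamma = paste0(
      SIGNAL_GLIADIN,
      strrep("PQQPFPQ", sample(9:11, 1L)),
      strrep("Q", 7L), "L",
      with_cys(make_block(sample(170:190, 1L), "VQGSIIQP"), 8L)),
    omega = paste0(
      SIGNAL_GLIADIN,
      strrep("PQQPF", sample(22:28, 1L)),
      strrep("Q", 7L), "L",
      make_block(sample(170:200, 1L), "ARELNPSH")),
    delta = paste0(
      SIGNAL_GLIADIN,
      strrep("PQQQF", sample(4:6, 1L)),
      strrep("Q", 7L), "L",
      with_cys(make_block(sample(140:160, 1L), "TIESRLAG"), 7L)),
    LMW = paste0(
      SIGNAL_LMW, "SHIPGLERPSQQ",
      strrep("QQQPPFS", sample(7:9, 1L)),
      with_cys(make_block(sample(200:220, 1L), "VDERLSAT"), 8L)),
    HMW_x = paste0(
      SIGNAL_HMW,
      with_cys(make_block(80L, "EGEASRQL"), 3L),
      strrep("GYYPTSGQQPGQ", sample(40:45, 1L)),
      with_cys(make_block(40L, "GERTLAES"), 1L)),
    HMW_y = paste0(
      SIGNAL_HMW,
      with_cys(make_block(80L, "EGEASRQL"), 5L),
      strrep("GYYPTSGQQPGQ", sample(40:45, 1L)),
      with_cys(make_block(40L, "GERTLAES"), 2L)),
    stop("unknown subfamily: ", subfamily))
  list(gene_id = gene_id, subfamily = subfamily, protein = protein,
       cds = reverse_translate(protein))
}

#' Plant epitope peptides into a synthetic alpha-gliadin
#'
#' Splices the peptides (concatenated, in order) into the repetitive domain
#' immediately after the signal peptide, consuming an equivalent stretch of
#' repeat units, and rebuilds the CDS.  The repeat region of generated genes
#' carries enough spare units that classification is unaffected.
#'
#' @param gene A gene from [generate_gene()].
#' @param peptides Character vector of epitope peptides.
#' @return The gene with modified `protein` and `cds`.
#' @export
plant_epitopes <- function(gene, peptides) {
  if (length(peptides) == 0L) return(gene)
  insert <- paste(peptides, collapse = "")
  sig_len <- nchar(SIGNAL_GLIADIN)
  consumed <- 6L * ceiling(nchar(insert) / 6L) # whole repeat units
  pre <- substr(gene$protein, 1L, sig_len)
  post <- substr(gene$protein, sig_len + consumed + 1L, nchar(gene$protein))
  gene$protein <- paste0(pre, insert, post)
  gene$cds <- reverse_translate(gene$protein)
  gene
}

#' Introduce one pseudogenizing defect into a CDS
#'
#' Plants exactly one defect of the requested mode at a random admissible
#' position: `internal_stop` converts a mid-sequence codon to TAA,
#' `frameshift` deletes one nucleotide, `no_start` mutates the initial ATG.
#' [call_status()] on the result detects the planted defect class.
#'
#' @param cds CDS nucleotide string.
#' @param mode One of `internal_stop`, `frameshift`, `no_start`.
#' @return Mutated CDS string.
#' @export
pseudogenize <- function(cds, mode = c("internal_stop", "frameshift", "no_start")) {
  mode <- match.arg(mode)
  n <- nchar(cds)
  ncod <- n %/% 3L
  if (ncod < 25L) stop("sequence too short to host a planted defect")
  if (mode == "internal_stop") {
    i <- sample(10:(ncod - 10L), 1L)
    substr(cds, 3L * i - 2L, 3L * i) <- "TAA"
    cds
  } else if (mode == "frameshift") {
    p <- sample(30:(n - 30L), 1L)
    paste0(substr(cds, 1L, p - 1L), substr(cds, p + 1L, n))
  } else {
    substr(cds, 3L, 3L) <- "A" # ATG -> ATA
    cds
  }
}

# synonymous single-base third-position alternatives for each codon, derived
# from the standard genetic code
synonymous_alts <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  cands <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  cands <- cands[cands != codon]
  cands[Biostrings::GENETIC_CODE[cands] == aa]
}

#' Apply synonymous divergence to a CDS
#'
#' Substitutes approximately `pct` percent of nucleotides, restricted to
#' synonymous third-codon-position changes, so the encoded protein (and with
#' it every protein-level truth label: subfamily, epitopes, functional
#' status) is preserved exactly while nucleotide identity drops.  The
#' achievable divergence is bounded by the fraction of degenerate sites
#' (roughly a third); requests beyond that are capped.
#'
#' @param cds CDS nucleotide string.
#' @param pct Target percent divergence.
#' @return Mutated CDS string.
#' @export
diverge_cds <- function(cds, pct) {
  if (pct <= 0) return(cds)
  n <- nchar(cds)
  ncod <- n %/% 3L
  idx <- 2:(ncod - 1L) # keep start and stop codons intact
  codons <- substring(cds, 3L * idx - 2L, 3L * idx)
  alts <- lapply(codons, synonymous_alts)
  can <- which(lengths(alts) > 0L)
  m <- min(length(can), round(pct / 100 * n))
  pick <- sample(can, m)
  for (k in pick) {
    new <- alts[[k]]
    new <- if (length(new) == 1L) new else sample(new, 1L)
    i <- idx[k]
    substr(cds, 3L * i - 2L, 3L * i) <- new
  }
  cds
}

#' Random substitution mutant of a nucleotide sequence
#'
#' Unconstrained point substitutions at `pct` percent of positions (used for
#' divergence in homology-scan and alignment exercises, where reading-frame
#' integrity does not matter).
#'
#' @param seq Nucleotide string.
#' @param pct Percent of positions to substitute.
#' @return Mutated string.
#' @export
mutate_sequence <- function(seq, pct) {
  n <- nchar(seq)
  m <- round(pct / 100 * n)
  if (m == 0L) return(seq)
  pos <- sample(n, m)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# order-2 Markov transition matrix (16 x 4) fitted from a set of sequences
fit_markov2 <- function(seqs) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(1, 16, 4) # add-one smoothing
  for (s in seqs) {
    n <- nchar(s)
    if (n < 3L) next
    v <- match(strsplit(s, "")[[1]], bases)
    v <- v[!is.na(v)]
    if (length(v) < 3L) next
    row <- 4L * (v[-c(length(v) - 1L, length(v))] - 1L) + v[-c(1L, length(v))]
    nxt <- v[-c(1L, 2L)]
    for (k in seq_along(row)) counts[row[k], nxt[k]] <- counts[row[k], nxt[k]] + 1
  }
  counts / rowSums(counts)
}

#' Specification for a synthetic prolamin genome
#'
#' Defines the planted gene content of a genome: tandem arrays (rows with
#' `size >= 2`) and singleton genes (`size = 1`) per chromosome and
#' subfamily, the intra-array synonymous divergence, per-subfamily
#' pseudogenization (exact-count planting, `round(p * n)` defects), and an
#' epitope planting plan for functional alpha-gliadins.
#'
#' @param arrays data.frame with columns `chrom`, `subfamily`, `size` and
#'   optionally `n_pseudo` (exact pseudogene count inside that array; NA
#'   defers to the subfamily rate).
#' @param divergence_pct Intra-array nucleotide divergence (synonymous).
#' @param pseudo_rate Named numeric vector of per-subfamily pseudogene rates
#'   applied (exact-count) to genes not covered by an `n_pseudo` entry.
#' @param epitope_plan data.frame with columns `epitope` (name in `defs`),
#'   `subfamily`, `n` and optionally `offset`: the peptide is planted into
#'   functional genes `offset + 1 .. offset + n` of that subfamily, in
#'   placement order.
#' @param defs Epitope definition table ([default_epitopes()]).
#' @param label Genome label (e.g. `"E"`).
#' @param prefix Gene-id prefix (e.g. `"Tel"`).
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(arrays, divergence_pct = 5,
                                  pseudo_rate = NULL, epitope_plan = NULL,
                                  defs = default_epitopes(),
                                  label = "E", prefix = "Syn") {
  stopifnot(all(c("chrom", "subfamily", "size") %in% names(arrays)))
  if (is.null(arrays$n_pseudo)) arrays$n_pseudo <- NA_integer_
  if (divergence_pct < 0 || divergence_pct > 50) {
    stop("divergence_pct must be in [0, 50]")
  }
  if (!is.null(pseudo_rate) &&
      (any(pseudo_rate < 0) || any(pseudo_rate > 1))) {
    stop("pseudo_rate values must be in [0, 1]")
  }
  structure(list(arrays = arrays, divergence_pct = divergence_pct,
                 pseudo_rate = pseudo_rate, epitope_plan = epitope_plan,
                 defs = defs, label = label, prefix = prefix),
            class = "synthetic_genome_spec")
}

DEFECT_CYCLE <- c("internal_stop", "frameshift", "no_start")

#' Assemble a synthetic genome with a truth table
#'
#' Generates the genes of the specification, plants epitopes into the
#' designated functional alpha-gliadins, diverges tandem-array copies
#' synonymously, introduces the planted pseudogene defects (cycling through
#' internal stop / frameshift / missing start), and embeds everything in an
#' order-2 Markov intergenic background fitted to the gene set (so the
#' background is GC- and dinucleotide-matched, which keeps homology-scan
#' specificity honest).  Array members are spaced well under 100 kb apart;
#' everything else is separated by more than 100 kb.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `genome` (named chromosome sequences), `models`
#'   (gene-model table), `truth` (truth table, one row per planted gene),
#'   `cds` and `proteins` (named character vectors).
#' @export
assemble_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  arrays <- spec$arrays
  # 1. generate base genes and array copies
  genes <- list() # per gene: list(id, subfamily, chrom, cluster, protein, cds)
  counter <- stats::setNames(integer(length(unique(arrays$subfamily))),
                             unique(arrays$subfamily))
  for (a in seq_len(nrow(arrays))) {
    sf <- arrays$subfamily[a]
    base <- generate_gene(sf)
    for (copy in seq_len(arrays$size[a])) {
      counter[sf] <- counter[sf] + 1L
      id <- sprintf("%s_%s_%s_%d", spec$prefix, tolower(sf),
                    arrays$chrom[a], counter[sf])
      cds <- if (copy == 1L) base$cds else diverge_cds(base$cds, spec$divergence_pct)
      genes[[length(genes) + 1L]] <- list(
        id = id, subfamily = sf, chrom = arrays$chrom[a],
        array = a, array_size = arrays$size[a],
        cluster = if (arrays$size[a] >= 2L) sprintf("arr%d", a) else NA_character_,
        protein = base$protein, cds = cds)
    }
  }
  # 2. choose pseudogenes: explicit per-array counts first, then subfamily
  #    rates (exact count round(p * n)) over the remaining genes
  status <- stats::setNames(rep("functional", length(genes)),
                            vapply(genes, `[[`, "", "id"))
  defect <- stats::setNames(rep(NA_character_, length(genes)), names(status))
  gene_sf <- vapply(genes, `[[`, "", "subfamily")
  gene_arr <- vapply(genes, `[[`, 0L, "array")
  d <- 0L
  for (a in which(!is.na(arrays$n_pseudo))) {
    members <- which(gene_arr == a)
    take <- members[seq_len(min(arrays$n_pseudo[a], length(members)))]
    for (g in take) {
      d <- d + 1L
      status[g] <- "pseudogene"
      defect[g] <- DEFECT_CYCLE[(d - 1L) %% 3L + 1L]
    }
  }
  for (sf in names(spec$pseudo_rate)) {
    all_sf <- which(gene_sf == sf)
    want <- round(spec$pseudo_rate[[sf]] * length(all_sf))
    have <- sum(status[all_sf] == "pseudogene")
    pool <- all_sf[status[all_sf] == "functional" &
                     is.na(arrays$n_pseudo[gene_arr[all_sf]])]
    extra <- max(0L, want - have)
    if (extra > length(pool)) stop("pseudo_rate not attainable for ", sf)
    if (extra > 0L) {
      take <- if (length(pool) == 1L) pool else sample(pool, extra)
      for (g in take) {
        d <- d + 1L
        status[g] <- "pseudogene"
        defect[g] <- DEFECT_CYCLE[(d - 1L) %% 3L + 1L]
      }
    }
  }
  # 3. plant epitopes into designated functional genes
  planted <- stats::setNames(rep("", length(genes)), names(status))
  if (!is.null(spec$epitope_plan)) {
    plan <- spec$epitope_plan
    if (is.null(plan$offset)) plan$offset <- 0L
    for (r in seq_len(nrow(plan))) {
      sf_fun <- which(gene_sf == plan$subfamily[r] & status == "functional")
      sel <- sf_fun[seq_len(plan$n[r]) + plan$offset[r]]
      if (any(is.na(sel))) stop("epitope plan exceeds functional gene count")
      pep <- spec$defs$peptide[spec$defs$name == plan$epitope[r]]
      if (length(pep) != 1L) stop("unknown epitope: ", plan$epitope[r])
      for (g in sel) {
        planted[g] <- paste0(planted[g],
                             if (nzchar(planted[g])) ";", plan$epitope[r])
      }
    }
    for (g in which(nzchar(planted))) {
      peps <- spec$defs$peptide[match(strsplit(planted[g], ";")[[1]],
                                      spec$defs$name)]
      upd <- plant_epitopes(list(protein = genes[[g]]$protein), peps)
      genes[[g]]$protein <- upd$protein
      genes[[g]]$cds <- upd$cds
    }
  }
  # 4. apply the planted defects at CDS level
  for (g in which(status == "pseudogene")) {
    genes[[g]]$cds <- pseudogenize(genes[[g]]$cds, defect[g])
  }
  # 5. place genes on chromosomes and synthesize the background
  trans <- fit_markov2(vapply(genes, `[[`, "", "cds"))
  chrom_seqs <- character(0)
  rows <- list()
  for (ch in unique(arrays$chrom)) {
    idx <- which(vapply(genes, `[[`, "", "chrom") == ch)
    cursor <- 50000L
    placements <- list()
    prev_array <- NA_integer_
    for (g in idx) {
      if (!is.na(prev_array)) {
        gap <- if (genes[[g]]$array == prev_array && genes[[g]]$array_size >= 2L) {
          sample(5000:20000, 1L)
        } else {
          150000L + sample(0:20000, 1L)
        }
        cursor <- cursor + gap
      }
      len <- nchar(genes[[g]]$cds)
      strand <- sample(c("+", "-"), 1L)
      placements[[length(placements) + 1L]] <-
        list(g = g, start = cursor, end = cursor + len - 1L, strand = strand)
      cursor <- cursor + len
      prev_array <- genes[[g]]$array
    }
    chrom_len <- cursor + 50000L
    seq <- cpp_markov2_sample(trans, chrom_len,
                              start_state = sample(0:15, 1L))
    for (p in placements) {
      ins <- if (p$strand == "-") revcomp(genes[[p$g]]$cds) else genes[[p$g]]$cds
      stringi::stri_sub(seq, p$start, p$end) <- ins
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[[p$g]]$id, chrom = ch, strand = p$strand,
        start = p$start, end = p$end,
        subfamily = genes[[p$g]]$subfamily,
        status = status[p$g], defect = defect[p$g],
        cluster_id = if (is.na(genes[[p$g]]$cluster)) NA_character_ else
          paste0(ch, "_", genes[[p$g]]$cluster),
        epitopes = planted[p$g],
        stringsAsFactors = FALSE)
    }
    chrom_seqs[ch] <- seq
  }
  truth <- do.call(rbind, rows)
  models <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    gene_model(truth$gene_id[i], truth$chrom[i], truth$strand[i],
               truth$start[i], truth$end[i], genome = spec$label)
  }))
  cds <- stats::setNames(vapply(genes, `[[`, "", "cds"),
                         vapply(genes, `[[`, "", "id"))
  proteins <- stats::setNames(vapply(genes, `[[`, "", "protein"),
                              vapply(genes, `[[`, "", "id"))
  list(genome = chrom_seqs, models = models, truth = truth,
       cds = cds[truth$gene_id], proteins = proteins[truth$gene_id])
}

# planted stage-mean templates (TPM scale) per subfamily for functional
# genes; pseudogenes get a low flat profile
STAGE_TEMPLATES <- list(
  alpha = c(0.5, 2, 8, 30, 300, 110),
  gamma = c(0.5, 1, 4, 20, 80, 160),
  omega = c(0.5, 2, 8, 30, 250, 90),
  delta = c(0.5, 2, 8, 30, 250, 90),
  LMW = c(1, 3, 10, 40, 400, 150),
  HMW_x = c(1, 2, 10, 40, 500, 180),
  HMW_y = c(1, 2, 10, 40, 160, 260),
  pseudogene = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))

TEMPLATE_PATTERN <- c(alpha = "rise_then_fall", gamma = "rising",
                      omega = "rise_then_fall", delta = "rise_then_fall",
                      LMW = "rise_then_fall", HMW_x = "rise_then_fall",
                      HMW_y = "rising", pseudogene = "flat")

#' Plant developmental expression profiles into a truth table
#'
#' Attaches a stage-mean vector and a planted pattern label to every gene:
#' functional genes receive their subfamily's developmental template
#' (early-peaking for alpha-gliadins, LMW and x-type HMW subunits, rising
#' through the grain stage for gamma-gliadins and y-type HMW subunits),
#' scaled by a per-gene log-normal factor; pseudogenes receive a low flat
#' profile.
#'
#' @param truth Truth table from [assemble_genome()].
#' @param scale_sd SD of the per-gene log-normal expression scale.
#' @param fold_overrides Named numeric vector of per-gene scale multipliers
#'   (e.g. to plant a known fold change between two genes).
#' @return The truth table with `mean_<stage>` columns and
#'   `planted_pattern`.
#' @export
plant_expression <- function(truth, scale_sd = 0.25, fold_overrides = NULL) {
  stages <- stage_levels()
  mm <- matrix(NA_real_, nrow(truth), length(stages))
  pat <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    key <- if (truth$status[i] == "pseudogene") "pseudogene" else truth$subfamily[i]
    scale <- exp(stats::rnorm(1, 0, scale_sd))
    if (!is.null(fold_overrides) && truth$gene_id[i] %in% names(fold_overrides)) {
      scale <- fold_overrides[[truth$gene_id[i]]]
    }
    mm[i, ] <- STAGE_TEMPLATES[[key]] * scale
    pat[i] <- TEMPLATE_PATTERN[[key]]
  }
  colnames(mm) <- paste0("mean_", stages)
  cbind(truth, mm, data.frame(planted_pattern = pat, stringsAsFactors = FALSE))
}

#' Simulate a negative-binomial count matrix from planted stage means
#'
#' Counts for gene g in a replicate of stage s are drawn from a negative
#' binomial with mean `mean_s(g) * length_g / 1000 * depth * libsize_factor`
#' and the given dispersion (variance mu + dispersion * mu^2); library-size
#' factors are log-normal per sample.  In addition to the prolamin genes the
#' matrix carries `n_background` stage-constant background genes emulating
#' the rest of the transcriptome: TPM is compositional, and without a stable
#' background the per-sample normalization would distort every stage
#' profile (a whole-transcriptome property the truth table cannot supply).
#'
#' @param truth Truth table with planted `mean_<stage>` columns
#'   ([plant_expression()]).
#' @param lengths Named vector of CDS lengths (nt) per gene.
#' @param reps Replicates per stage.
#' @param dispersion NB dispersion (> 0).
#' @param depth Sequencing-depth multiplier.
#' @param libsize_sd SD of log library-size factors.
#' @param n_background Number of background genes added to the matrix
#'   (ids `bg_<i>`).
#' @param background_mean Mean TPM-scale expression of background genes.
#' @return List with `counts` (genes x samples), `metadata` (sample sheet),
#'   `lengths` (including background genes).
#' @export
generate_counts <- function(truth, lengths, reps = 3L, dispersion = 0.1,
                            depth = 50, libsize_sd = 0.05,
                            n_background = 300L, background_mean = 50) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  stages <- stage_levels()
  meancols <- paste0("mean_", stages)
  stopifnot(all(meancols %in% names(truth)))
  samples <- expand.grid(replicate = seq_len(reps), stage = stages,
                         stringsAsFactors = FALSE)[, c("stage", "replicate")]
  samples$sample_id <- sprintf("%s_r%d", samples$stage, samples$replicate)
  lib <- exp(stats::rnorm(nrow(samples), 0, libsize_sd))
  gene_ids <- truth$gene_id
  lens <- lengths[gene_ids]
  means <- as.matrix(truth[, meancols])
  if (n_background > 0L) {
    bg_ids <- sprintf("bg_%03d", seq_len(n_background))
    bg_lens <- stats::setNames(
      sample(600:3000, n_background, replace = TRUE), bg_ids)
    bg_means <- matrix(background_mean * exp(stats::rnorm(n_background, 0, 0.5)),
                       n_background, length(stages))
    gene_ids <- c(gene_ids, bg_ids)
    lens <- c(lens, bg_lens)
    means <- rbind(means, bg_means)
  }
  counts <- matrix(0L, length(gene_ids), nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    stage_i <- match(samples$stage[s], stages)
    mu <- means[, stage_i] * lens / 1000 * depth * lib[s]
    counts[, s] <- stats::rnbinom(length(gene_ids), mu = mu,
                                  size = 1 / dispersion)
  }
  list(counts = counts,
       metadata = samples[, c("sample_id", "stage", "replicate")],
       lengths = lens)
}

#' Synthetic pair of collinear gene regions
#'
#' Generates an ordered list of prolamin-like genes, copies it at the given
#' divergence, optionally reverses the order of an internal run (a local
#' inversion) and optionally drops genes from the second region, to exercise
#' anchor building and collinearity chaining.
#'
#' @param subfamilies Character vector of subfamily labels, one per gene, in
#'   region order.
#' @param divergence_pct Unconstrained nucleotide divergence of region 2.
#' @param invert Integer range of region-2 positions to reverse (NULL for
#'   none).
#' @param drop Integer positions removed from region 2.
#' @return List with `seqs1`, `seqs2` (CDS vectors in region order) and
#'   `map` (region-1 index of each region-2 gene).
#' @export
synthetic_region_pair <- function(subfamilies, divergence_pct = 10,
                                  invert = NULL, drop = integer(0)) {
  g1 <- lapply(seq_along(subfamilies), function(i) {
    generate_gene(subfamilies[i], sprintf("r1_g%d", i))
  })
  seqs1 <- vapply(g1, `[[`, "", "cds")
  map <- seq_along(subfamilies)
  if (!is.null(invert)) map[invert] <- rev(map[invert])
  if (length(drop)) map <- map[-drop]
  seqs2 <- vapply(map, function(i) mutate_sequence(seqs1[i], divergence_pct), "")
  list(seqs1 = seqs1, seqs2 = seqs2, map = map)
}
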