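# Average residue masses (Da) for the 20 standard amino acids; total protein
# mass = sum of residue masses + one water (18.0153 Da).
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153

#' Bjellqvist pKa set for theoretical pI
#'
#' The pKa values used by the classical Expasy-style pI calculator:
#' side chains of C, D, E, H, K, R, Y, a residue-specific N-terminal pKa
#' (generic 7.5) and a C-terminal pKa of 3.55 (4.55/4.75 when the terminal
#' residue is D/E).  Returned as a plain list so an alternative set can be
#' swapped in.
#'
#' @return List with elements `side` (named vector), `nterm` (named vector
#'   with element `default`), `cterm` (named vector with element `default`).
#' @export
bjellqvist_pka <- function() {
  list(
    side = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98,
             K = 10.00, R = 12.00, Y = 10.00),
    nterm = c(default = 7.50, A = 7.59, M = 7.00, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.70, G = 7.50),
    cterm = c(default = 3.55, D = 4.55, E = 4.75))
}

#' Default prolamin subfamily rule set
#'
#' Declarative classification rules for the prolamin subfamilies: each rule
#' carries a repeat-motif regular expression with a minimum (overlap-aware)
#' occurrence count, an expected cysteine-count range, a mature-protein
#' length range, and optional extras (polyglutamine tracts for alpha, an
#' N-terminal SHIPGL-type start for LMW, an x/y split on cysteines in the
#' first 120 residues for HMW).  All thresholds are configuration values and
#' can be overridden by editing the returned list.
#'
#' @return Named list of rules, one per subfamily label
#'   (`alpha`, `gamma`, `omega`, `delta`, `LMW`, `HMW_x`, `HMW_y`).
#' @export
subfamily_rules <- function() {
  list(
    alpha = list(motif = "PQPQP[FY]", min_motif = 5L,
                 cys_range = c(5L, 7L), len_range = c(250L, 350L),
                 polyq_min = 2L),
    gamma = list(motif = "PQQP[FY]PQ", min_motif = 5L,
                 cys_range = c(8L, 9L), len_range = c(250L, 350L)),
    omega = list(motif = "PQQP[FY]", min_motif = 8L,
                 cys_range = c(0L, 1L), len_range = c(300L, 450L)),
    delta = list(motif = "PQQQF", min_motif = 3L,
                 cys_range = c(7L, 7L), len_range = c(180L, 300L)),
    LMW   = list(motif = "QQ.PPFS", min_motif = 4L,
                 cys_range = c(7L, 9L), len_range = c(280L, 400L),
                 nterm_motif = "SHIPGL", nterm_window = 40L),
    HMW_x = list(motif = "G[YQ][YQ]P[TG][SQ]", min_motif = 15L,
                 cys_range = c(3L, 10L), len_range = c(600L, 1000L),
                 cys120 = c(0L, 4L)),
    HMW_y = list(motif = "G[YQ][YQ]P[TG][SQ]", min_motif = 15L,
                 cys_range = c(3L, 10L), len_range = c(600L, 1000L),
                 cys120 = c(5L, 120L)))
}

# overlap-aware regex occurrence count (zero-width lookahead)
count_motif <- function(residues, motif) {
  stringi::stri_count_regex(residues, paste0("(?=", motif, ")"))
}

count_cys <- function(residues) stringi::stri_count_fixed(residues, "C")

# number of polyglutamine tracts of >= min_q consecutive Q
count_polyq <- function(residues, min_q = 6L) {
  stringi::stri_count_regex(residues, sprintf("Q{%d,}", min_q))
}

#' Classify a protein into a prolamin subfamily
#'
#' Evaluates each subfamily rule on the protein: the motif count, cysteine
#' count, length window and rule-specific extras must all be satisfied; among
#' satisfied subfamilies the one with the highest motif evidence relative to
#' its threshold wins.  Returns `"unclassified"` when no rule is satisfied.
#'
#' @param protein A `protein_record` (or plain residue string).
#' @param rules Rule set from [subfamily_rules()].
#' @return List with `subfamily` (label) and `evidence` (data.frame, one row
#'   per rule: motif hits, cysteines, length, pass flag, score).
#' @export
classify_subfamily <- function(protein, rules = subfamily_rules()) {
  res <- if (inherits(protein, "protein_record")) protein$residues else protein
  if (nchar(res) < 30L) stop("protein too short to classify (< 30 residues)")
  len <- nchar(res)
  cys <- count_cys(res)
  ev <- lapply(names(rules), function(nm) {
    r <- rules[[nm]]
    hits <- count_motif(res, r$motif)
    ok <- hits >= r$min_motif &&
      cys >= r$cys_range[1] && cys <= r$cys_range[2] &&
      len >= r$len_range[1] && len <= r$len_range[2]
    if (ok && !is.null(r$polyq_min)) ok <- count_polyq(res) >= r$polyq_min
    if (ok && !is.null(r$nterm_motif)) {
      ok <- stringi::stri_detect_fixed(substr(res, 1L, r$nterm_window),
                                       r$nterm_motif)
    }
    if (ok && !is.null(r$cys120)) {
      c120 <- count_cys(substr(res, 1L, 120L))
      ok <- c120 >= r$cys120[1] && c120 <= r$cys120[2]
    }
    data.frame(subfamily = nm, motif_hits = hits, cysteines = cys,
               length = len, pass = ok, score = hits / r$min_motif)
  })
  ev <- do.call(rbind, ev)
  passed <- ev[ev$pass, , drop = FALSE]
  label <- if (nrow(passed) == 0L) "unclassified" else
    passed$subfamily[which.max(passed$score)]
  list(subfamily = label, evidence = ev)
}

#' Call functional vs pseudogene status for one gene
#'
#' Assembles sequence-level defects from the coding sequence and its
#' translation: missing ATG start (`no_start`), premature stop codons
#' (`internal_stop`), missing terminal stop (`no_terminal_stop`), length not
#' a multiple of 3 (`frameshift`).  When the sequence itself is intact, the
#' deduced protein must additionally satisfy a subfamily rule (complete
#' domain structure); otherwise the gene is defective as
#' `structure_incomplete`.  A gene is functional iff the defect list is
#' empty.
#'
#' @param cds A `coding_sequence`.
#' @param protein Matching `protein_record` (computed if missing).
#' @param subfamily Subfamily label from [classify_subfamily()] (computed
#'   from the protein if missing).
#' @param rules Rule set used for the structural check.
#' @return A `prolamin_call`: list with `gene_id`, `subfamily`, `status`,
#'   `defects` (character vector).
#' @export
call_status <- function(cds, protein = NULL, subfamily = NULL,
                        rules = subfamily_rules()) {
  if (is.null(protein)) protein <- translate_cds(cds)
  stopifnot(cds$gene_id == protein$gene_id)
  defects <- character()
  if (substr(cds$nucleotides, 1L, 3L) != "ATG") defects <- c(defects, "no_start")
  if (length(protein$internal_stop_positions) > 0L) {
    defects <- c(defects, "internal_stop")
  }
  if (!cds$complete_flag) defects <- c(defects, "no_terminal_stop")
  if (nchar(cds$nucleotides) %% 3L != 0L) defects <- c(defects, "frameshift")
  if (is.null(subfamily)) {
    subfamily <- classify_subfamily(protein, rules)$subfamily
  }
  # structural completeness is only assessable on an intact translation
  if (length(defects) == 0L && subfamily == "unclassified") {
    defects <- "structure_incomplete"
  }
  structure(list(gene_id = cds$gene_id, subfamily = subfamily,
                 status = if (length(defects)) "pseudogene" else "functional",
                 defects = defects),
            class = "prolamin_call")
}

#' @export
print.prolamin_call <- function(x, ...) {
  cat(sprintf("<prolamin_call> %s: %s, %s%s\n", x$gene_id, x$subfamily,
              x$status,
              if (length(x$defects)) paste0(" [", paste(x$defects, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Pseudogene rate of a set of calls
#'
#' Number of pseudogenes divided by the total number of genes, with the
#' percentage reported at one decimal (round half up), matching the printed
#' precision convention of gene-family surveys.
#'
#' @param calls List of `prolamin_call` objects (or a character vector of
#'   statuses).
#' @return List with `n_pseudo`, `n_total`, `fraction`, `pct` (one decimal).
#' @export
pseudogene_rate <- function(calls) {
  status <- if (is.character(calls)) calls
  else vapply(calls, function(x) x$status, character(1))
  if (length(status) == 0L) stop("no calls supplied")
  n_pseudo <- sum(status == "pseudogene")
  n_total <- length(status)
  frac <- n_pseudo / n_total
  list(n_pseudo = n_pseudo, n_total = n_total, fraction = frac,
       pct = round_half_up(100 * frac, 1L))
}

# round half up at `digits` decimals (printed-precision convention)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass (18.0153 Da).  Refuses
#' sequences containing `X`: molecular weight is undefined for pseudogene
#' translations.
#'
#' @param protein A `protein_record` or residue string.
#' @return Molecular mass in Daltons.
#' @export
compute_mw <- function(protein) {
  res <- if (inherits(protein, "protein_record")) protein$residues else protein
  if (!nzchar(res)) stop("empty protein sequence")
  aa <- strsplit(res, "")[[1]]
  bad <- setdiff(unique(aa), names(RESIDUE_MASS))
  if (length(bad)) {
    stop("molecular weight undefined for residues: ", paste(bad, collapse = ","))
  }
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

# net charge of a protein at a given pH under Henderson-Hasselbalch
protein_charge <- function(counts, first, last, pH, pka) {
  pos_pka <- c(nterm_pka(first, pka),
               rep(pka$side[["H"]], counts[["H"]]),
               rep(pka$side[["K"]], counts[["K"]]),
               rep(pka$side[["R"]], counts[["R"]]))
  neg_pka <- c(cterm_pka(last, pka),
               rep(pka$side[["D"]], counts[["D"]]),
               rep(pka$side[["E"]], counts[["E"]]),
               rep(pka$side[["C"]], counts[["C"]]),
               rep(pka$side[["Y"]], counts[["Y"]]))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

nterm_pka <- function(first, pka) {
  if (first %in% names(pka$nterm)) pka$nterm[[first]] else pka$nterm[["default"]]
}

cterm_pka <- function(last, pka) {
  if (last %in% names(pka$cterm)) pka$cterm[[last]] else pka$cterm[["default"]]
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge over the free termini and
#' the ionizable side chains (D, E, C, Y, H, K, R) is zero, located by
#' bisection on \[0, 14\] to a tolerance of 0.01 pH units, using the
#' Bjellqvist pKa set by default.
#'
#' @param protein A `protein_record` or residue string (no `X`).
#' @param pka pKa set, see [bjellqvist_pka()].
#' @param tol Bisection tolerance in pH units.
#' @return Theoretical pI.
#' @export
compute_pi <- function(protein, pka = bjellqvist_pka(), tol = 0.01) {
  res <- if (inherits(protein, "protein_record")) protein$residues else protein
  if (!nzchar(res)) stop("empty protein sequence")
  aa <- strsplit(res, "")[[1]]
  bad <- setdiff(unique(aa), names(RESIDUE_MASS))
  if (length(bad)) {
    stop("pI undefined for residues: ", paste(bad, collapse = ","))
  }
  counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                   function(a) sum(aa == a), integer(1))
  first <- aa[1]; last <- aa[length(aa)]
  lo <- 0; hi <- 14
  # net charge is positive at pH 0 and negative at pH 14 for free termini
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (protein_charge(counts, first, last, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical annotation of functional proteins
#'
#' Computes MW and pI for each functional call; pseudogenes are reported
#' with NA (their translations contain X and have no defined mass or pI).
#'
#' @param calls List of `prolamin_call` objects.
#' @param proteins Named list of `protein_record`s keyed by gene id.
#' @return data.frame with gene_id, subfamily, status, mw_da, pi.
#' @export
physchem_table <- function(calls, proteins) {
  rows <- lapply(calls, function(cl) {
    p <- proteins[[cl$gene_id]]
    ok <- cl$status == "functional"
    data.frame(gene_id = cl$gene_id, subfamily = cl$subfamily,
               status = cl$status,
               mw_da = if (ok) compute_mw(p) else NA_real_,
               pi = if (ok) compute_pi(p) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
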