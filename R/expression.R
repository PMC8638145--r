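#' Developmental stage vocabulary
#'
#' The six grain-development stages, in temporal order.
#'
#' @return Character vector of stage names.
#' @export
stage_levels <- function() {
  c("young_spike", "pre_flowering", "flowering",
    "ovary_expansion", "half_grain", "grain")
}

#' Transcripts per million from a count matrix
#'
#' Per sample: each gene's count is divided by its effective length (spliced
#' CDS length in nt for intronless prolamins), and the per-gene rates are
#' scaled to sum to one million.
#'
#' @param counts Genes x samples matrix of non-negative integer counts, with
#'   row and column names.
#' @param lengths Named numeric vector of effective gene lengths (nt).
#' @return Matrix of TPM values, same dimensions as `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("every gene needs a positive effective length")
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Per-gene developmental stage profiles
#'
#' Averages TPM over replicates within each stage and labels the temporal
#' pattern: `rise_then_fall` when the peak stage is interior and both
#' neighboring stages are at least `drop_frac` below the peak; `rising` when
#' means are non-decreasing (within a small relative tolerance) and the
#' dynamic range exceeds the flatness ratio; `flat` when max/min does not
#' exceed `flat_ratio`; otherwise `other`.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param metadata data.frame with columns `sample_id`, `stage`,
#'   `replicate`; stages must be drawn from [stage_levels()].
#' @param stages Stage order (default [stage_levels()]).
#' @param drop_frac Required fractional drop of peak neighbors (default 0.2).
#' @param flat_ratio Max/min ratio at or below which a profile is flat
#'   (default 1.5).
#' @param rise_tol Relative tolerance for non-decreasing steps (default 0.05).
#' @return data.frame with gene_id, one `mean_<stage>` column per stage,
#'   `peak_stage`, `pattern`.
#' @export
profile_stages <- function(tpm, metadata, stages = stage_levels(),
                           drop_frac = 0.2, flat_ratio = 1.5,
                           rise_tol = 0.05) {
  stopifnot(all(c("sample_id", "stage") %in% names(metadata)))
  bad <- setdiff(unique(metadata$stage), stages)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  metadata <- metadata[match(colnames(tpm), metadata$sample_id), ]
  if (any(is.na(metadata$sample_id))) stop("metadata missing for some samples")
  means <- sapply(stages, function(s) {
    cols <- metadata$sample_id[metadata$stage == s]
    if (length(cols) == 0L) stop("no replicates for stage ", s)
    rowMeans(tpm[, cols, drop = FALSE])
  })
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(tpm), stages))
  }
  pat <- apply(means, 1, function(m) classify_pattern(m, drop_frac, flat_ratio, rise_tol))
  peak <- stages[apply(means, 1, which.max)]
  out <- data.frame(gene_id = rownames(tpm), means,
                    peak_stage = peak, pattern = pat,
                    stringsAsFactors = FALSE)
  colnames(out)[1 + seq_along(stages)] <- paste0("mean_", stages)
  rownames(out) <- NULL
  out
}

classify_pattern <- function(m, drop_frac = 0.2, flat_ratio = 1.5,
                             rise_tol = 0.05) {
  k <- length(m)
  pk <- which.max(m)
  if (max(m) == 0) return("flat")
  if (pk > 1L && pk < k &&
      m[pk - 1L] <= (1 - drop_frac) * m[pk] &&
      m[pk + 1L] <= (1 - drop_frac) * m[pk]) {
    return("rise_then_fall")
  }
  ratio <- if (min(m) == 0) Inf else max(m) / min(m)
  nondec <- all(diff(m) >= -rise_tol * m[-k])
  if (nondec && ratio > flat_ratio) return("rising")
  if (ratio <= flat_ratio) return("flat")
  "other"
}

#' Expression fold change between two genes at a stage
#'
#' Ratio of replicate-mean TPM of gene A over gene B at one stage.
#'
#' @param tpm TPM matrix.
#' @param metadata Sample sheet (`sample_id`, `stage`, `replicate`).
#' @param gene_a,gene_b Gene ids.
#' @param stage Stage name.
#' @return Numeric ratio.
#' @export
fold_between <- function(tpm, metadata, gene_a, gene_b, stage) {
  stopifnot(gene_a %in% rownames(tpm), gene_b %in% rownames(tpm))
  cols <- metadata$sample_id[metadata$stage == stage]
  if (length(cols) == 0L) stop("no samples for stage ", stage)
  a <- mean(tpm[gene_a, cols])
  b <- mean(tpm[gene_b, cols])
  if (b == 0) stop("undefined ratio: mean TPM of ", gene_b, " is zero at ", stage)
  a / b
}

#' Write / read a count matrix as TSV
#'
#' One-line header of sample ids; first column `gene_id`.
#'
#' @param counts Genes x samples matrix.
#' @param path Output path.
#' @return `path` invisibly (write) / matrix (read).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
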