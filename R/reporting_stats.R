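#' GC fraction of a DNA string
#' @param seq non-empty ACGT string.
#' @return Fraction of G+C in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (!nchar(seq)) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("G", "C"))
  sum(f) / nchar(seq)
}

#' Genome and gene-composition summary
#'
#' Reproduces the composition statistics a mitogenome report prints:
#' length, GC, gene counts by category, intron-bearing genes, start-codon
#' usage, multi-copy genes, the protein-coding gene length extremes and a
#' protein-length class histogram in 100-aa bins. Bins are left-closed
#' right-open (a 200-aa protein falls in `[200,300)`); proteins below
#' 100 aa are counted in an `underflow` bucket and above 700 aa in
#' `overflow`.
#'
#' @param genome a `circular_genome`.
#' @param ann an [mt_annotation()] table.
#' @return A list of class `"genome_summary"`.
#' @export
summarize_genome <- function(genome, ann) {
  L <- genome$length
  cats <- c("ORF", "protein_coding", "tRNA", "rRNA")
  counts <- vapply(cats, function(cc) sum(ann$category == cc), integer(1))
  n_exons <- vapply(ann$exons, nrow, integer(1))
  pc <- ann$category == "protein_coding"
  clens <- if (any(pc)) vapply(which(pc), function(i)
    coding_length(ann$exons[[i]], L), integer(1)) else integer()
  coding <- ann$category %in% c("protein_coding", "ORF")
  aa <- if (any(coding)) vapply(which(coding), function(i)
    coding_length(ann$exons[[i]], L) / 3 - 1, numeric(1)) else numeric()
  breaks <- seq(100, 700, by = 100)
  labs <- paste0("[", breaks[-7], ",", breaks[-1], ")")
  hist <- vapply(seq_len(6), function(b)
    sum(aa >= breaks[b] & aa < breaks[b + 1]), integer(1))
  names(hist) <- labs
  structure(list(
    length_bp = L,
    gc_fraction = gc_content(genome$seq),
    counts = counts,
    n_genes_total = nrow(ann),
    n_genes_total_with_copies = sum(ann$copies),
    n_intron_genes = sum(n_exons > 1L),
    start_codon_usage = table(factor(ann$start_codon[pc],
                                     levels = c("ATG", "ACG", "ATT"))),
    multi_copy_genes = ann$name[ann$copies > 1L],
    min_protein_coding_bp = if (length(clens)) min(clens) else NA_integer_,
    min_protein_coding_gene = if (length(clens))
      ann$name[pc][which.min(clens)] else NA_character_,
    max_protein_coding_bp = if (length(clens)) max(clens) else NA_integer_,
    max_protein_coding_gene = if (length(clens))
      ann$name[pc][which.max(clens)] else NA_character_,
    protein_length_hist = hist,
    underflow = sum(aa < 100),
    overflow = sum(aa >= 700)), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %s bp, GC %.2f%%\n",
              format(x$length_bp, big.mark = ","), 100 * x$gc_fraction))
  cat("  genes:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                        collapse = ", "), "\n")
  cat(sprintf("  intron-bearing genes: %d; protein-coding span %d bp (%s) to %d bp (%s)\n",
              x$n_intron_genes, x$min_protein_coding_bp,
              x$min_protein_coding_gene, x$max_protein_coding_bp,
              x$max_protein_coding_gene))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; relative to the
#' calibrator sample, `ddCt = dCt_sample - dCt_calibrator`; the fold
#' change is `2^-ddCt`, so the calibrator's fold change is 1 by
#' construction.
#'
#' @param ct data frame with columns `sample`, `gene`, `ct` (cycle
#'   thresholds, > 0).
#' @param target target gene name.
#' @param calibrator calibrator sample name.
#' @param reference internal reference gene (default `"18S"`, the usual
#'   cotton rRNA reference).
#' @return Data frame `sample`, `dct`, `ddct`, `fold`.
#' @export
rel_expression <- function(ct, target, calibrator, reference = "18S") {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  samples <- unique(ct$sample)
  get_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  ref_ct <- vapply(samples, get_ct, numeric(1), g = reference)
  if (anyNA(ref_ct))
    stop("missing reference Ct for sample: ",
         paste(samples[is.na(ref_ct)], collapse = ", "))
  tgt_ct <- vapply(samples, get_ct, numeric(1), g = target)
  if (anyNA(tgt_ct))
    stop("missing target Ct for sample: ",
         paste(samples[is.na(tgt_ct)], collapse = ", "))
  if (!calibrator %in% samples) stop("calibrator sample not in table")
  dct <- tgt_ct - ref_ct
  ddct <- dct - dct[match(calibrator, samples)]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             fold = unname(2^(-ddct)), stringsAsFactors = FALSE)
}
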