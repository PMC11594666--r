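#' Run the full CMS candidate screen
#'
#' Orchestrates the whole comparison of a CMS-line mitogenome against its
#' maintainer: ORF calling on both genomes, AS/TM/CH classification of the
#' CMS ORFs, Venn intersection counts and candidate ranking.
#'
#' @param cms,maintainer either a list with fields `genome`
#'   (`circular_genome`) and `ann` ([mt_annotation()]), or a character
#'   vector `c(fasta, gff3)` of file paths.
#' @param min_aa ORF-calling protein-length threshold (default 101).
#' @param start_codons permitted start codons.
#' @param window chimeric proximity window in bp (default 500).
#' @param as_mode,id_min,cov_min line-specificity settings
#'   ([find_specific_orfs()]).
#' @param tm_args list of [predict_tm_segments()] overrides.
#' @return An object of class `"cms_screen"`: `orfs_cms`,
#'   `orfs_maintainer`, `classification`, `venn`, `candidates`, `params`.
#' @export
run_screen <- function(cms, maintainer, min_aa = 101L,
                       start_codons = c("ATG", "ACG", "ATT"),
                       window = 500L, as_mode = "exact",
                       id_min = 0.95, cov_min = 0.9, tm_args = list()) {
  load_side <- function(x) {
    if (is.character(x)) {
      g <- load_genome(x[[1L]])
      list(genome = g, ann = load_annotations(x[[2L]], g))
    } else x
  }
  cms <- load_side(cms)
  maintainer <- load_side(maintainer)
  orfs_cms <- find_orfs(cms$genome, min_aa = min_aa,
                        start_codons = start_codons)
  orfs_m <- find_orfs(maintainer$genome, min_aa = min_aa,
                      start_codons = start_codons)
  cls <- classify_orfs(orfs_cms, orfs_m, cms$ann, cms$genome$length,
                       window = window, as_mode = as_mode,
                       id_min = id_min, cov_min = cov_min, tm_args = tm_args)
  structure(list(
    orfs_cms = orfs_cms, orfs_maintainer = orfs_m,
    classification = cls,
    venn = venn_counts(cls),
    candidates = rank_candidates(cls),
    params = list(min_aa = min_aa, start_codons = start_codons,
                  window = window, as_mode = as_mode,
                  id_min = id_min, cov_min = cov_min, tm_args = tm_args)),
    class = "cms_screen")
}

#' @export
print.cms_screen <- function(x, ...) {
  v <- x$venn
  cat(sprintf("<cms_screen> %d CMS ORFs vs %d maintainer ORFs\n",
              nrow(x$orfs_cms), nrow(x$orfs_maintainer)))
  cat(sprintf("  AS-ORFs: %d  TM-ORFs: %d  CH-ORFs: %d\n",
              v$n_AS, v$n_TM, v$n_CH))
  cat("  Venn regions:",
      paste(sprintf("%s=%d", names(v$regions), v$regions), collapse = " "), "\n")
  if (nrow(x$candidates)) {
    top <- x$candidates[1L, ]
    cat(sprintf("  top candidate: %s (AS%s%s)", top$orf_id,
                if (top$tm_flag) "+TM" else "",
                if (top$ch_flag) "+CH" else ""))
    if (top$ch_flag)
      cat(sprintf(", %s %s (gap %d bp, overlap %d bp)", top$neighbor_side,
                  top$nearest_gene, top$gap_bp, top$overlap_bp))
    cat("\n")
  } else cat("  no line-specific candidates\n")
  invisible(x)
}

#' Write screen artifacts
#'
#' @param screen a [run_screen()] result.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(screen$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$classification, file.path(dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_AS = screen$venn$n_AS, n_TM = screen$venn$n_TM,
                            n_CH = screen$venn$n_CH,
                            regions = as.list(screen$venn$regions)),
                       file.path(dir, "venn.json"), auto_unbox = TRUE)
  invisible(dir)
}
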