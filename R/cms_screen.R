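#' CMS-line-specific ORFs (AS-ORFs)
#'
#' An ORF of the CMS genome is line-specific when its protein has no
#' counterpart among the maintainer's ORF proteins. The default criterion
#' is exact protein-string identity, which is fully reproducible; the
#' `identity` mode instead accepts a counterpart when a global pairwise
#' alignment reaches at least `id_min` identity with length coverage at
#' least `cov_min`, which tolerates SNP-carrying homologs.
#'
#' @param orfs_cms,orfs_maintainer `orf_set` tables from [find_orfs()] run
#'   with the same settings on the two genomes.
#' @param mode `"exact"` (default) or `"identity"`.
#' @param id_min,cov_min identity-mode thresholds. Identity is
#'   matches / alignment length under a global alignment with match 1,
#'   mismatch -1, gap -2; coverage is `min(len) / max(len)`.
#' @return Character vector of CMS orf ids that are line-specific.
#' @export
find_specific_orfs <- function(orfs_cms, orfs_maintainer,
                               mode = c("exact", "identity"),
                               id_min = 0.95, cov_min = 0.9) {
  mode <- match.arg(mode)
  if (!nrow(orfs_cms)) return(character())
  if (mode == "exact") {
    return(orfs_cms$id[!(orfs_cms$protein %in% orfs_maintainer$protein)])
  }
  if (!nrow(orfs_maintainer)) return(orfs_cms$id)
  aas <- Biostrings::AAStringSet(orfs_maintainer$protein)
  alpha <- Biostrings::AA_STANDARD
  mat <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- 1
  specific <- vapply(seq_len(nrow(orfs_cms)), function(i) {
    p <- orfs_cms$protein[i]
    lens <- nchar(orfs_maintainer$protein)
    cov <- pmin(nchar(p), lens) / pmax(nchar(p), lens)
    cand <- which(cov >= cov_min)
    for (j in cand) {
      al <- Biostrings::pairwiseAlignment(p, aas[[j]], type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 2)
      idf <- Biostrings::nmatch(al) / Biostrings::nchar(al)
      if (idf >= id_min) return(FALSE)
    }
    TRUE
  }, logical(1))
  orfs_cms$id[specific]
}

#' Classify an ORF as chimeric (CH-ORF)
#'
#' An ORF is chimeric when its genomic span overlaps a conserved
#' mitochondrial protein-coding gene, or lies within `window` bp (default
#' 500) upstream or downstream of one, measured on the circle and
#' strand-agnostically over the full gene span (introns included).
#'
#' @param orf_interval a [circ_interval()] for the ORF (stop codon
#'   included).
#' @param ann an [mt_annotation()] table; only `protein_coding` rows anchor
#'   the chimeric call (tRNA/rRNA genes do not).
#' @param genome_length circle length in bp.
#' @param window proximity window in bp (default 500).
#' @return A list: `ch_flag`, `nearest_gene`, `gap_bp`, `overlap_bp`,
#'   `neighbor_side` (`upstream` / `downstream` / `overlapping` / `none`),
#'   and `neighbors`, a data frame of every conserved gene with its gap and
#'   overlap to the ORF (sorted by overlap descending then gap ascending).
#' @export
classify_chimeric <- function(orf_interval, ann, genome_length, window = 500L) {
  if (window < 0) stop("window must be >= 0")
  cons <- ann[ann$category == "protein_coding", , drop = FALSE]
  none <- list(ch_flag = FALSE, nearest_gene = NA_character_,
               gap_bp = NA_integer_, overlap_bp = NA_integer_,
               neighbor_side = "none",
               neighbors = data.frame(gene = character(), gap_bp = integer(),
                                      overlap_bp = integer(),
                                      side = character()))
  if (!nrow(cons)) return(none)
  rows <- lapply(seq_len(nrow(cons)), function(i) {
    span <- gene_span(cons$exons[[i]], genome_length)
    d <- circular_distance(orf_interval, span, genome_length)
    side <- if (d$overlap_bp > 0) "overlapping" else {
      # gene downstream = clockwise from ORF end to gene start
      down <- (span$start - (if (orf_interval$wraps) orf_interval$end
                             else orf_interval$end)) %% genome_length
      if (down == d$gap_bp) "downstream" else "upstream"
    }
    data.frame(gene = cons$name[i], gap_bp = d$gap_bp,
               overlap_bp = d$overlap_bp, side = side,
               stringsAsFactors = FALSE)
  })
  nb <- do.call(rbind, rows)
  nb <- nb[order(-nb$overlap_bp, nb$gap_bp, nb$gene), , drop = FALSE]
  rownames(nb) <- NULL
  best <- nb[1L, ]
  list(ch_flag = any(nb$overlap_bp > 0 | nb$gap_bp <= window),
       nearest_gene = best$gene,
       gap_bp = best$gap_bp,
       overlap_bp = best$overlap_bp,
       neighbor_side = best$side,
       neighbors = nb)
}

#' Classify every ORF of a CMS genome
#'
#' Combines the three axes of the screen: line specificity (AS), predicted
#' transmembrane segments (TM) and chimeric position (CH).
#'
#' @param orfs_cms,orfs_maintainer `orf_set` tables for the two genomes.
#' @param ann_cms annotations of the CMS genome (conserved genes anchor the
#'   CH call).
#' @param genome_length CMS circle length.
#' @param window CH proximity window in bp (default 500).
#' @param as_mode,id_min,cov_min passed to [find_specific_orfs()].
#' @param tm_args list of arguments for [predict_tm_segments()].
#' @return A data frame of class `"orf_classification"`: `orf_id`,
#'   `as_flag`, `tm_flag`, `ch_flag`, `nearest_gene`, `gap_bp`,
#'   `overlap_bp`, `neighbor_side`.
#' @export
classify_orfs <- function(orfs_cms, orfs_maintainer, ann_cms, genome_length,
                          window = 500L, as_mode = "exact",
                          id_min = 0.95, cov_min = 0.9, tm_args = list()) {
  as_ids <- find_specific_orfs(orfs_cms, orfs_maintainer, mode = as_mode,
                               id_min = id_min, cov_min = cov_min)
  cons <- ann_cms[ann_cms$category == "protein_coding", , drop = FALSE]
  out <- lapply(seq_len(nrow(orfs_cms)), function(i) {
    iv <- circ_interval(orfs_cms$start[i], orfs_cms$end[i], orfs_cms$wraps[i])
    ch <- classify_chimeric(iv, cons, genome_length, window)
    data.frame(orf_id = orfs_cms$id[i],
               as_flag = orfs_cms$id[i] %in% as_ids,
               tm_flag = do.call(is_tm_orf, c(list(orfs_cms$protein[i]), tm_args)),
               ch_flag = ch$ch_flag,
               nearest_gene = ch$nearest_gene,
               gap_bp = ch$gap_bp, overlap_bp = ch$overlap_bp,
               neighbor_side = ch$neighbor_side,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(orf_id = character(), as_flag = logical(),
                                    tm_flag = logical(), ch_flag = logical(),
                                    nearest_gene = character(),
                                    gap_bp = integer(), overlap_bp = integer(),
                                    neighbor_side = character())
  class(df) <- c("orf_classification", "data.frame")
  df
}

#' Venn region counts for the AS/TM/CH classification
#'
#' @param classifications an `orf_classification` table (one row per ORF).
#' @return A list with `n_AS`, `n_TM`, `n_CH` (marginal class counts) and
#'   `regions`, a named integer vector over the seven disjoint Venn
#'   regions (`AS_only`, `TM_only`, `CH_only`, `AS_TM`, `AS_CH`, `TM_CH`,
#'   `AS_TM_CH`).
#' @export
venn_counts <- function(classifications) {
  if (anyDuplicated(classifications$orf_id))
    stop("duplicate orf_id in classifications")
  a <- classifications$as_flag
  t <- classifications$tm_flag
  c_ <- classifications$ch_flag
  regions <- c(
    AS_only = sum(a & !t & !c_), TM_only = sum(!a & t & !c_),
    CH_only = sum(!a & !t & c_), AS_TM = sum(a & t & !c_),
    AS_CH = sum(a & !t & c_), TM_CH = sum(!a & t & c_),
    AS_TM_CH = sum(a & t & c_))
  list(n_AS = sum(a), n_TM = sum(t), n_CH = sum(c_),
       regions = regions)
}

#' Rank CMS candidate ORFs
#'
#' Candidates are line-specific ORFs, ordered by the strength of their
#' evidence: AS+TM+CH first (the chimeric transmembrane archetype), then
#' AS+CH, AS+TM, and plain AS. Ties are broken by larger overlap with the
#' nearest conserved gene, then smaller gap, then id.
#'
#' @param classifications an `orf_classification` table.
#' @return The AS rows, ordered, with a `rank` column prepended.
#' @export
rank_candidates <- function(classifications) {
  x <- classifications[classifications$as_flag, , drop = FALSE]
  if (!nrow(x)) {
    x$rank <- integer()
    return(x[, c("rank", setdiff(names(x), "rank"))])
  }
  tier <- ifelse(x$tm_flag & x$ch_flag, 1L,
          ifelse(x$ch_flag, 2L,
          ifelse(x$tm_flag, 3L, 4L)))
  ov <- ifelse(is.na(x$overlap_bp), -1L, x$overlap_bp)
  gp <- ifelse(is.na(x$gap_bp), .Machine$integer.max, x$gap_bp)
  ord <- order(tier, -ov, gp, x$orf_id)
  x <- x[ord, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  rownames(x) <- NULL
  x[, c("rank", setdiff(names(x), "rank"))]
}
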