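#' Translate a coding sequence
#'
#' Uses the standard genetic code (plant mitochondria translate with the
#' standard table). Plant mt genes may begin with ACG or ATT at the DNA
#' level -- C-to-U editing creates a canonical AUG on the transcript -- so
#' by default a leading ACG/ATT is read as methionine. A trailing stop
#' codon is removed; an internal stop is an error.
#'
#' @param cds a DNA string whose length is a multiple of 3.
#' @param start_codon_as_met read a leading ACG/ATT as M (default `TRUE`).
#' @return The protein as a character scalar, without the stop symbol.
#' @examples
#' translate_cds("ATGGCTTAA")            # "MA"
#' translate_cds("ACGGCTTAA")            # "MA"
#' translate_cds("ACGGCTTAA", FALSE)     # "TA"
#' @export
translate_cds <- function(cds, start_codon_as_met = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length ", n, " is not divisible by 3")
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "error")), "")[[1L]]
  n_cod <- length(aa)
  stops <- which(aa == "*")
  if (length(stops) && any(stops < n_cod))
    stop("internal stop codon at codon ", stops[stops < n_cod][1L])
  if (length(stops)) aa <- aa[-n_cod]
  if (start_codon_as_met && length(aa) &&
      substr(cds, 1L, 3L) %in% c("ACG", "ATT"))
    aa[1L] <- "M"
  paste(aa, collapse = "")
}

# Positions (1-based) of every overlapping occurrence of each codon in `seq`.
codon_positions <- function(seq, codons) {
  subj <- Biostrings::DNAString(seq)
  sort(unique(unlist(lapply(codons, function(cd)
    BiocGenerics::start(Biostrings::matchPattern(cd, subj))))))
}

# Scan one strand string for maximal ORFs. Returns a data.frame of 1-based
# start positions (of the start codon) and stop positions (of the stop
# codon's first base) in the coordinates of `txt`.
scan_strand <- function(txt, circular, L, min_aa, start_codons, stop_codons) {
  starts <- codon_positions(txt, start_codons)
  stops <- codon_positions(txt, stop_codons)
  out <- list()
  for (f in 0:2) {
    A <- starts[(starts - 1L) %% 3L == f]
    S <- stops[(stops - 1L) %% 3L == f]
    if (!length(A) || !length(S)) next
    # next in-frame stop strictly after each start
    idx <- findInterval(A, S) + 1L
    ok <- idx <= length(S)
    A <- A[ok]; idx <- idx[ok]
    if (!length(A)) next
    # a circular ORF cannot exceed one genome length; drop impossible
    # start/stop pairings before picking the defining start
    ok <- (S[idx] + 3L - A) <= L
    A <- A[ok]; idx <- idx[ok]
    if (!length(A)) next
    # most upstream (valid) start per stop-bounded segment
    first <- !duplicated(idx)
    A <- A[first]; Send <- S[idx[first]]
    # which segments are opened by a stop seen in this scan?
    prev_stop <- c(-Inf, S)[match(idx[first], seq_along(S))]  # stop before
    keep <- rep(TRUE, length(A))
    if (circular) {
      # canonical representative: start in (L, 2L]; bounded segment only
      keep <- A > L & A <= 2L * L & is.finite(prev_stop)
    }
    aa_len <- (Send - A) %/% 3L
    nt_len <- Send + 2L - A + 1L
    keep <- keep & aa_len >= min_aa & nt_len <= L
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(pos = A[keep], aa = aa_len[keep],
                                            nt = nt_len[keep], frame = f)
  }
  if (!length(out)) return(data.frame(pos = integer(), aa = integer(),
                                      nt = integer(), frame = integer()))
  do.call(rbind, out)
}

#' Find open reading frames on a (circular) genome
#'
#' Scans all six reading frames; on a circular genome the scan continues
#' across the origin, so ORFs spanning the origin are found at their true
#' coordinates. Within one stop-bounded segment only the most upstream
#' permitted start codon defines the ORF (the maximal-ORF convention), and
#' only ORFs whose protein exceeds the plant-mitochondrial annotation
#' threshold of 100 amino acids are reported by default
#' (`min_aa = 101`).
#'
#' @param genome a `circular_genome`.
#' @param min_aa minimum protein length in residues (default 101, i.e.
#'   strictly more than 100 amino acids).
#' @param start_codons permitted start codons. ACG and ATT are accepted by
#'   default because conserved plant mt genes use them (RNA editing restores
#'   AUG in vivo).
#' @param stop_codons stop codons (standard table).
#' @return A data frame of class `"orf_set"`, sorted by start position then
#'   strand, with columns `id` (`orf<aa_length>` plus `a`/`b`/... suffixes on
#'   ties), `start`, `end`, `wraps` (0-based half-open genomic interval
#'   including the stop codon), `strand`, `frame`, `start_codon`,
#'   `nt_length`, `aa_length`, `protein`.
#' @export
find_orfs <- function(genome, min_aa = 101L,
                      start_codons = c("ATG", "ACG", "ATT"),
                      stop_codons = c("TAA", "TAG", "TGA")) {
  if (min_aa < 1) stop("min_aa must be >= 1")
  L <- genome$length
  empty <- data.frame(id = character(), start = integer(), end = integer(),
                      wraps = logical(), strand = character(),
                      frame = integer(), start_codon = character(),
                      nt_length = integer(), aa_length = integer(),
                      protein = character(), stringsAsFactors = FALSE)
  class(empty) <- c("orf_set", "data.frame")
  if (L < 3L) return(empty)
  rows <- list()
  strand_txt <- list()
  for (strand in c("+", "-")) {
    T1 <- if (strand == "+") genome$seq else revcomp(genome$seq)
    txt <- if (genome$circular) paste0(T1, T1, T1) else T1
    strand_txt[[strand]] <- txt
    hits <- scan_strand(txt, genome$circular, L, min_aa,
                        start_codons, stop_codons)
    if (!nrow(hits)) next
    # map scan coordinates back to genome coordinates
    p0 <- (hits$pos - 1L) %% L                # 0-based start on strand string
    if (strand == "+") {
      gstart <- p0
    } else {
      gstart <- (L - p0 - hits$nt) %% L
    }
    iv <- lapply(seq_along(gstart), function(i)
      interval_from_length(gstart[i], hits$nt[i], L, genome$circular))
    rows[[length(rows) + 1L]] <- data.frame(
      start = vapply(iv, `[[`, integer(1), "start"),
      end = vapply(iv, `[[`, integer(1), "end"),
      wraps = vapply(iv, `[[`, logical(1), "wraps"),
      strand = strand, frame = p0 %% 3L,
      start_codon = substr(txt, hits$pos, hits$pos + 2L),
      nt_length = hits$nt, aa_length = hits$aa,
      scan_pos = hits$pos, scan_strand = strand,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  # translate
  df$protein <- vapply(seq_len(nrow(df)), function(i) {
    txt <- strand_txt[[df$scan_strand[i]]]
    translate_cds(substr(txt, df$scan_pos[i], df$scan_pos[i] + df$nt_length[i] - 1L))
  }, character(1))
  df$scan_pos <- NULL; df$scan_strand <- NULL
  df$id <- orf_ids(df$aa_length)
  rownames(df) <- NULL
  df <- df[, c("id", "start", "end", "wraps", "strand", "frame",
               "start_codon", "nt_length", "aa_length", "protein")]
  class(df) <- c("orf_set", "data.frame")
  df
}

# Field-style ids: orf<aa>, with a/b/c... suffixes (in sorted order) when
# several ORFs share a protein length.
orf_ids <- function(aa_length) {
  base <- paste0("orf", aa_length)
  dup <- ave(seq_along(base), base, FUN = length) > 1L
  rank <- ave(seq_along(base), base, FUN = seq_along)
  suffix <- ifelse(dup, c(letters, paste0(rep(letters, each = 26),
                                          letters))[rank], "")
  paste0(base, suffix)
}

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("<orf_set> %d ORFs\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(
    x[, setdiff(names(x), "protein")], 10L))
  invisible(x)
}

#' Export called ORFs
#'
#' @param orfs an `orf_set`.
#' @param genome the source genome.
#' @param gff3_path,fasta_path optional output paths for a GFF3 of
#'   `open_reading_frame` features and a protein FASTA.
#' @return Invisibly, a list of the paths written.
#' @export
write_orfs <- function(orfs, genome, gff3_path = NULL, fasta_path = NULL) {
  out <- list()
  if (!is.null(gff3_path)) {
    ann <- mt_annotation(orfs$id, rep("ORF", nrow(orfs)), orfs$strand,
                         orfs$start_codon, rep(1L, nrow(orfs)),
                         lapply(seq_len(nrow(orfs)), function(i)
                           data.frame(start = orfs$start[i], end = orfs$end[i],
                                      wraps = orfs$wraps[i])))
    write_annotations(ann, genome, gff3_path)
    out$gff3 <- gff3_path
  }
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(orfs$protein)
    names(aa) <- orfs$id
    Biostrings::writeXStringSet(aa, fasta_path, width = 70L)
    out$fasta <- fasta_path
  }
  invisible(out)
}
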