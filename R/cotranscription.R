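#' Build a transcript model from genomic intervals
#'
#' The transcript sequence is the concatenation of the strand-corrected
#' genomic segments (spliced order). RNA is represented as DNA (T for U).
#'
#' @param genome a `circular_genome`.
#' @param intervals list of [circ_interval()] in transcription order
#'   (genomic coordinates).
#' @param strand `"+"` or `"-"`.
#' @param id transcript id.
#' @return A list of class `"transcript_model"`: `id`, `genome_id`,
#'   `strand`, `intervals`, `sequence`.
#' @export
make_transcript <- function(genome, intervals, strand = "+", id = "tx") {
  segs <- vapply(intervals, function(iv) interval_seq(genome, iv), character(1))
  seq <- if (strand == "+") paste(segs, collapse = "")
         else revcomp(paste(segs, collapse = ""))
  structure(list(id = id, genome_id = genome$id, strand = strand,
                 intervals = intervals, sequence = seq),
            class = "transcript_model")
}

#' Read a primer-pair table
#'
#' @param path TSV with columns `name`, `fwd`, `rev` (both primers written
#'   5' to 3', 15-35 nt).
#' @return A data frame of primer pairs.
#' @export
load_primers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "fwd", "rev") %in% names(df)))
  validate_primers(df)
  df
}

validate_primers <- function(df) {
  lens <- c(nchar(df$fwd), nchar(df$rev))
  if (any(lens < 15 | lens > 35))
    stop("primer lengths must be 15-35 nt")
  invisible(df)
}

# All 1-based positions where `probe` matches `txt` with at most
# `max_mismatch` mismatches and an exactly matching 3'-terminal base.
match_sites <- function(txt, probe, max_mismatch = 0L) {
  k <- nchar(probe)
  m <- nchar(txt)
  if (m < k) return(integer())
  tv <- strsplit(txt, "")[[1L]]
  pv <- strsplit(probe, "")[[1L]]
  npos <- m - k + 1L
  mism <- integer(npos)
  for (j in seq_len(k))
    mism <- mism + (tv[j:(j + npos - 1L)] != pv[j])
  which(mism <= max_mismatch & tv[k:(k + npos - 1L)] == pv[k])
}

#' Predict a PCR amplicon on a transcript
#'
#' The forward primer must match the template sense strand and the
#' reverse-complement of the reverse primer must match downstream of it;
#' the leftmost forward site and its nearest downstream reverse site
#' define the product. The primer's 3'-terminal base must match exactly
#' (extension cannot start from a 3' mismatch); elsewhere up to
#' `max_mismatch` mismatches are tolerated (default 0: the screen models a
#' band present/absent readout, not hybridization thermodynamics).
#'
#' @param template a [make_transcript()] model.
#' @param pair one row of a primer table (list/data.frame with `name`,
#'   `fwd`, `rev`).
#' @param max_mismatch allowed mismatches per primer (3' base always exact).
#' @return A list: `present`, `length` (bp, `NA` when absent), `fwd_pos`
#'   (5' start of the forward site, 1-based), `rev_pos` (3'-end coordinate
#'   of the product), `multiproduct`, and `products`, a data frame of all
#'   distinct predicted products.
#' @export
predict_amplicon <- function(template, pair, max_mismatch = 0L) {
  txt <- template$sequence
  if (!nchar(txt)) stop("empty template")
  validate_primers(data.frame(fwd = pair$fwd, rev = pair$rev))
  f_sites <- match_sites(txt, toupper(pair$fwd), max_mismatch)
  # reverse primer binds the antisense strand: its site on the sense strand
  # is revcomp(rev); its 3' end is the leftmost base of that site, so the
  # exact-3' requirement applies to the first base of revcomp(rev).
  rc <- revcomp(toupper(pair$rev))
  r_sites_raw <- match_sites(paste(rev(strsplit(txt, "")[[1L]]), collapse = ""),
                             paste(rev(strsplit(rc, "")[[1L]]), collapse = ""),
                             max_mismatch)
  # map reversed-string positions back: site start on sense strand
  kr <- nchar(rc)
  r_sites <- sort(nchar(txt) - (r_sites_raw + kr - 1L) + 1L)
  absent <- list(present = FALSE, length = NA_integer_,
                 fwd_pos = NA_integer_, rev_pos = NA_integer_,
                 multiproduct = FALSE,
                 products = data.frame(fwd_pos = integer(),
                                       rev_pos = integer(),
                                       length = integer()))
  if (!length(f_sites) || !length(r_sites)) return(absent)
  kf <- nchar(pair$fwd)
  prods <- list()
  for (f in f_sites) {
    r_ok <- r_sites[r_sites >= f + kf]  # rev site fully downstream
    if (!length(r_ok)) next
    r <- r_ok[1L]
    end3 <- r + kr - 1L
    prods[[length(prods) + 1L]] <- c(f, end3, end3 - f + 1L)
  }
  if (!length(prods)) return(absent)
  pm <- unique(do.call(rbind, prods))
  products <- data.frame(fwd_pos = pm[, 1L], rev_pos = pm[, 2L],
                         length = pm[, 3L])
  list(present = TRUE, length = products$length[1L],
       fwd_pos = products$fwd_pos[1L], rev_pos = products$rev_pos[1L],
       multiproduct = nrow(products) > 1L, products = products)
}

#' Co-transcription presence matrix
#'
#' Runs [predict_amplicon()] for every template x primer-pair combination,
#' mirroring a gel readout: a junction-spanning pair yields a band only on
#' a transcript that carries both the ORF and its neighboring gene.
#'
#' @param models list of [make_transcript()] templates.
#' @param pairs primer table ([load_primers()] format).
#' @param max_mismatch passed to [predict_amplicon()].
#' @return A list with `present` (logical matrix, templates x pairs) and
#'   `length` (integer matrix of product lengths, `NA` when absent).
#' @export
evaluate_cotranscription <- function(models, pairs, max_mismatch = 0L) {
  if (!length(models)) stop("need at least one template")
  if (anyDuplicated(pairs$name)) stop("duplicate primer pair names")
  ids <- vapply(models, `[[`, character(1), "id")
  pres <- matrix(FALSE, length(models), nrow(pairs),
                 dimnames = list(ids, pairs$name))
  len <- matrix(NA_integer_, length(models), nrow(pairs),
                dimnames = list(ids, pairs$name))
  for (i in seq_along(models)) for (j in seq_len(nrow(pairs))) {
    p <- predict_amplicon(models[[i]], pairs[j, ], max_mismatch)
    pres[i, j] <- p$present
    if (p$present) len[i, j] <- p$length
  }
  list(present = pres, length = len)
}
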