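#' Kyte-Doolittle hydropathy index
#'
#' The 20 published per-residue hydropathy values. Sustained high windowed
#' means (window 19, mean above ~1.6) are the classic indicator of a
#' membrane-spanning helix.
#'
#' @return A named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Sliding-window hydropathy profile
#'
#' @param protein amino-acid string over the standard 20-letter alphabet,
#'   at least `window` residues long.
#' @param window odd window width in residues (default 19, the classic
#'   membrane-helix window).
#' @return Numeric vector of length `nchar(protein) - window + 1`; element
#'   `i` is the mean Kyte-Doolittle index of residues `i .. i+window-1`.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  res <- strsplit(protein, "")[[1L]]
  kd <- kyte_doolittle()
  bad <- which(!res %in% names(kd))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1L]], bad[1L]))
  n <- length(res)
  if (n < window) stop("protein shorter than the window")
  v <- unname(kd[res])
  cs <- c(0, cumsum(v))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Predict transmembrane segments by hydropathy
#'
#' A deterministic Kyte-Doolittle window scan: maximal runs of
#' above-threshold window centres are expanded to the full windows,
#' nearby runs are merged, and short segments are dropped. This is the
#' packaged stand-in for an HMM-based topology predictor: it is
#' dependency-free and reproducible, and it cleanly separates the
#' hydrophobic-stretch proteins the synthetic generator plants from
#' hydrophilic ones, but it will not reproduce HMM calls on arbitrary real
#' proteins residue-for-residue.
#'
#' @param protein amino-acid string.
#' @param window window width (residues, odd; default 19).
#' @param threshold mean-hydropathy calling threshold (default 1.6, the
#'   classic membrane-spanning criterion).
#' @param min_len minimum segment length in residues after expansion
#'   (default 18).
#' @param min_gap segments separated by fewer than this many residues are
#'   merged (default 5).
#' @return A data frame with one row per segment: `start_res`, `end_res`
#'   (1-based inclusive residue coordinates) and `mean_hydropathy`. A
#'   protein shorter than the window yields zero rows with attribute
#'   `too_short = TRUE`.
#' @export
predict_tm_segments <- function(protein, window = 19L, threshold = 1.6,
                                min_len = 18L, min_gap = 5L) {
  empty <- data.frame(start_res = integer(), end_res = integer(),
                      mean_hydropathy = numeric())
  if (nchar(protein) < window) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  prof <- hydropathy_profile(protein, window)
  above <- prof >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # expand run of centres [i1, i2] to residues [i1, i2 + window - 1]
  seg <- cbind(runs[, 1L], runs[, 2L] + window - 1L)
  # merge segments separated by < min_gap residues
  if (nrow(seg) > 1L) {
    merged <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg[i, 1L] - last[2L] - 1L < min_gap) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], seg[i, 2L]))
      } else merged[[length(merged) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, merged)
  }
  seg <- seg[seg[, 2L] - seg[, 1L] + 1L >= min_len, , drop = FALSE]
  if (!nrow(seg)) return(empty)
  kd <- kyte_doolittle()
  res <- strsplit(protein, "")[[1L]]
  data.frame(start_res = as.integer(seg[, 1L]),
             end_res = as.integer(seg[, 2L]),
             mean_hydropathy = vapply(seq_len(nrow(seg)), function(i)
               mean(kd[res[seg[i, 1L]:seg[i, 2L]]]), numeric(1)))
}

#' Is an ORF a TM-ORF?
#'
#' `TRUE` when [predict_tm_segments()] finds at least one segment in the
#' ORF's protein at the given settings.
#'
#' @param protein amino-acid string (or a single `orf_set` row's protein).
#' @param ... passed to [predict_tm_segments()].
#' @return Logical scalar.
#' @export
is_tm_orf <- function(protein, ...) {
  nrow(predict_tm_segments(protein, ...)) >= 1L
}

#' Tabulate TM predictions for a set of ORFs
#'
#' @param orfs an `orf_set`.
#' @param ... passed to [predict_tm_segments()].
#' @return A data frame: `orf_id`, `n_segments`, `segments` (list column),
#'   `tm_flag`.
#' @export
tm_report <- function(orfs, ...) {
  segs <- lapply(orfs$protein, predict_tm_segments, ...)
  data.frame(orf_id = orfs$id,
             n_segments = vapply(segs, nrow, integer(1)),
             segments = I(segs),
             tm_flag = vapply(segs, nrow, integer(1)) >= 1L,
             stringsAsFactors = FALSE)
}
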