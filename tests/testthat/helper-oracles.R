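# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: membership sets for circular
# distances, a per-position codon walk for ORF calling, naive sliding means
# for hydropathy, and substring scans for amplicons.

oracle_bases <- function(start, end, wraps, L) {
  if (!wraps) seq(start, end - 1L)
  else c(if (start < L) seq(start, L - 1L), if (end > 0) seq(0L, end - 1L))
}

oracle_circular_distance <- function(a, b, L) {
  A <- oracle_bases(a$start, a$end, a$wraps, L)
  B <- oracle_bases(b$start, b$end, b$wraps, L)
  ov <- length(intersect(A, B))
  if (ov > 0) return(list(gap_bp = 0L, overlap_bp = ov))
  gap <- min(vapply(A, function(x) min((B - x) %% L, (x - B) %% L), numeric(1)))
  # gap counts bases strictly between the features
  list(gap_bp = as.integer(gap - 1L), overlap_bp = 0L)
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# Codon-walk ORF oracle. Returns data.frame(start, end, wraps, strand,
# aa_length, protein-less) in the package's coordinate convention.
oracle_orfs <- function(seq, circular = TRUE, min_aa = 1L,
                        starts = c("ATG", "ACG", "ATT"),
                        stops = c("TAA", "TAG", "TGA")) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    T1 <- if (strand == "+") seq else oracle_revcomp(seq)
    ch <- strsplit(T1, "")[[1L]]
    codon_at <- function(p0) {
      idx <- if (circular) (p0 + 0:2) %% L else p0 + 0:2
      if (!circular && any(idx >= L)) return(NA_character_)
      paste(ch[idx + 1L], collapse = "")
    }
    cands <- list()
    for (p0 in 0:(L - 1L)) {
      if (!(codon_at(p0) %in% starts)) next
      d <- 3L
      found <- NA_integer_
      while (d <= L) {
        q <- if (circular) (p0 + d) %% L else p0 + d
        cod <- codon_at(q)
        if (is.na(cod)) break
        if (cod %in% stops) { found <- d; break }
        d <- d + 3L
      }
      if (is.na(found)) next
      nt <- found + 3L
      if (nt > L) next
      stop_pos <- if (circular) (p0 + found) %% L else p0 + found
      # bounded segment: on a circle, require an in-frame stop upstream
      # within L nt of the start
      if (circular) {
        ok <- FALSE
        for (back in seq(3L, L, by = 3L)) {
          q <- (p0 - back) %% L
          if (codon_at(q) %in% stops) { ok <- TRUE; break }
        }
        if (!ok) next
      }
      cands[[length(cands) + 1L]] <- c(p0 = p0, stop = stop_pos, nt = nt)
    }
    if (!length(cands)) next
    cm <- do.call(rbind, cands)
    # maximal ORF per stop-bounded segment = longest candidate per stop
    keep <- unlist(lapply(split(seq_len(nrow(cm)), cm[, "stop"]),
                          function(ix) ix[which.max(cm[ix, "nt"])]))
    cm <- cm[keep, , drop = FALSE]
    aa <- cm[, "nt"] %/% 3L - 1L
    sel <- aa >= min_aa
    if (!any(sel)) next
    cm <- cm[sel, , drop = FALSE]; aa <- aa[sel]
    gstart <- if (strand == "+") cm[, "p0"] else (L - cm[, "p0"] - cm[, "nt"]) %% L
    gend_raw <- gstart + cm[, "nt"]
    out[[length(out) + 1L]] <- data.frame(
      start = as.integer(gstart),
      end = as.integer(ifelse(gend_raw > L, gend_raw - L, gend_raw)),
      wraps = gend_raw > L,
      strand = strand, aa_length = as.integer(aa))
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      wraps = logical(), strand = character(),
                                      aa_length = integer()))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

orf_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$start, df$end, df$wraps, df$strand, df$aa_length, sep = "/"))
}

oracle_hydropathy <- function(protein, window = 19L) {
  kd <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
          G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
          H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
          R = -4.5)
  v <- kd[strsplit(protein, "")[[1L]]]
  n <- length(v)
  vapply(seq_len(n - window + 1L), function(i) mean(v[i:(i + window - 1L)]),
         numeric(1))
}

# Naive amplicon oracle: exact substring scan, leftmost fwd, nearest
# downstream revcomp(rev).
oracle_amplicon <- function(template, fwd, rev) {
  hit_all <- function(txt, pat) {
    res <- integer()
    p <- 1L
    repeat {
      h <- regexpr(pat, substr(txt, p, nchar(txt)), fixed = TRUE)
      if (h < 0) break
      res <- c(res, p + h - 1L)
      p <- p + h
    }
    res
  }
  f <- hit_all(template, fwd)
  r <- hit_all(template, oracle_revcomp(rev))
  if (!length(f) || !length(r)) return(list(present = FALSE, length = NA))
  f1 <- f[1L]
  r_ok <- r[r >= f1 + nchar(fwd)]
  if (!length(r_ok)) {
    # try later forward sites
    for (fx in f[-1L]) {
      r_ok <- r[r >= fx + nchar(fwd)]
      if (length(r_ok)) { f1 <- fx; break }
    }
    if (!length(r_ok)) return(list(present = FALSE, length = NA))
  }
  list(present = TRUE, length = r_ok[1L] + nchar(rev) - f1)
}

random_genome <- function(L, gc = 0.45, circular = TRUE, id = "rnd") {
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  mitocms:::new_circular_genome(id, s, circular)
}
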