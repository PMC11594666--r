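#' Read a single-record FASTA file as a circular genome
#'
#' @param path path to a FASTA file holding exactly one DNA record over
#'   `{A,C,G,T}` (case-insensitive). Plant mitochondrial assemblies of
#'   finished quality contain no ambiguous bases, and the downstream ORF
#'   arithmetic relies on that.
#' @param circular treat the sequence as a circle (default `TRUE`).
#' @return An object of class `"circular_genome"`: a list with fields
#'   `id`, `seq` (uppercase character scalar), `length`, `circular`.
#' @export
load_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    stop("expected a single FASTA record, found ", length(set), ": ",
         paste(names(set), collapse = ", "))
  seq <- toupper(as.character(set[[1L]]))
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop(sprintf("non-ACGT symbol '%s' at position %d",
                 substr(seq, bad, bad), as.integer(bad)))
  id <- sub("\\s.*$", "", names(set)[1L])
  new_circular_genome(id, seq, circular)
}

new_circular_genome <- function(id, seq, circular = TRUE) {
  structure(list(id = id, seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Write a genome to FASTA (70-column wrap)
#' @param genome a `circular_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# ---- annotations ----------------------------------------------------------

gff3_child_type <- c(protein_coding = "CDS", ORF = "open_reading_frame",
                     tRNA = "tRNA", rRNA = "rRNA")

#' Construct an annotation table
#'
#' One row per gene; `exons` is a list column of data frames with 0-based
#' half-open `start`/`end`/`wraps` columns, in transcription order.
#'
#' @param name,category,strand,start_codon,copies per-gene vectors.
#' @param exons list of exon data frames.
#' @return A data frame of class `"mt_annotation"`.
#' @export
mt_annotation <- function(name, category, strand, start_codon, copies, exons) {
  stopifnot(all(category %in% names(gff3_child_type)),
            all(strand %in% c("+", "-")),
            length(exons) == length(name))
  df <- data.frame(name = name, category = category, strand = strand,
                   start_codon = start_codon, copies = as.integer(copies),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  class(df) <- c("mt_annotation", "data.frame")
  df
}

# Interval covering a gene's full span (introns included): the minimal
# circular interval containing every exon, i.e. the complement of the
# largest inter-exon gap on the circle.
gene_span <- function(exons, genome_length) {
  if (nrow(exons) == 1L)
    return(circ_interval(exons$start[1L], exons$end[1L], exons$wraps[1L]))
  segs <- do.call(rbind, lapply(seq_len(nrow(exons)), function(j)
    interval_segments(circ_interval(exons$start[j], exons$end[j],
                                    exons$wraps[j]), genome_length)))
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  n <- nrow(segs)
  # circular gap after each segment (to the start of the next one)
  gaps <- vapply(seq_len(n), function(j) {
    nxt <- if (j == n) segs[1L, 1L] + genome_length else segs[j + 1L, 1L]
    nxt - segs[j, 2L]
  }, numeric(1))
  jmax <- which.max(gaps)
  span_start <- if (jmax == n) segs[1L, 1L] else segs[jmax + 1L, 1L]
  span_len <- genome_length - max(gaps)
  interval_from_length(span_start, span_len, genome_length)
}

# Coding length = sum of exon lengths.
coding_length <- function(exons, genome_length) {
  sum(vapply(seq_len(nrow(exons)), function(i)
    interval_length(circ_interval(exons$start[i], exons$end[i],
                                  exons$wraps[i]), genome_length),
    integer(1)))
}

#' Read GFF3 annotations for a genome
#'
#' Coordinates are converted from the 1-based inclusive GFF3 convention to
#' internal 0-based half-open intervals. Multi-exon genes are assembled from
#' child features sharing a `Parent`. On a circular genome a feature whose
#' end exceeds the sequence length (the GFF3 convention for origin-crossing
#' features on an `Is_circular` landmark) becomes a wrapping interval.
#'
#' @param path a GFF3 file.
#' @param genome the matching [load_genome()] result.
#' @return An [mt_annotation()] table.
#' @export
load_annotations <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  keep <- m$type != "region"
  gr <- gr[keep]; m <- m[keep, , drop = FALSE]
  st <- as.character(BiocGenerics::strand(gr))
  if (any(!st %in% c("+", "-")))
    stop("unknown strand symbol in ", path)
  L <- genome$length
  s1 <- BiocGenerics::start(gr); e1 <- BiocGenerics::end(gr)
  if (any(e1 > L) && !genome$circular)
    stop("feature extends beyond the end of a linear genome")
  is_gene <- m$type == "gene"
  parent <- vapply(m$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))
  genes <- which(is_gene)
  ids <- m$ID[genes]
  to_iv <- function(i) {
    s0 <- s1[i] - 1L; e0 <- e1[i]
    if (e0 > L) data.frame(start = s0, end = e0 - L, wraps = TRUE)
    else data.frame(start = s0, end = e0, wraps = FALSE)
  }
  res <- lapply(seq_along(genes), function(k) {
    g <- genes[k]
    kids <- which(!is_gene & parent == m$ID[g])
    rows <- if (length(kids)) kids[order((s1[kids] - s1[g]) %% max(L, 1L))] else g
    exons <- do.call(rbind, lapply(rows, to_iv))
    list(name = if (!is.null(m$Name)) m$Name[g] else m$ID[g],
         category = if (!is.null(m$category)) m$category[g] else "protein_coding",
         strand = st[g],
         start_codon = if (!is.null(m$start_codon) && !is.na(m$start_codon[g]))
           m$start_codon[g] else "ATG",
         copies = if (!is.null(m$copies) && !is.na(m$copies[g]))
           as.integer(m$copies[g]) else 1L,
         exons = exons)
  })
  mt_annotation(vapply(res, `[[`, character(1), "name"),
                vapply(res, `[[`, character(1), "category"),
                vapply(res, `[[`, character(1), "strand"),
                vapply(res, `[[`, character(1), "start_codon"),
                vapply(res, `[[`, integer(1), "copies"),
                lapply(res, `[[`, "exons"))
}

#' Write annotations to GFF3
#'
#' Emits a `##sequence-region` pragma, a `region` feature carrying
#' `Is_circular=true` when appropriate, and one `gene` line per gene with
#' child exon lines (`CDS` for protein-coding genes). Origin-crossing
#' features are written on one line with `end` past the sequence length,
#' the GFF3 convention for circular landmarks. Output is deterministic
#' (sorted by start, then name).
#'
#' @param ann an [mt_annotation()] table.
#' @param genome the genome the coordinates refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, genome, path) {
  L <- genome$length
  esc <- function(x) gsub("([,;=%&\t])", "", x)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, L),
             paste(genome$id, "mitocms", "region", 1L, L, ".", "+", ".",
                   sprintf("ID=region:%s%s", genome$id,
                           if (genome$circular) ";Is_circular=true" else ""),
                   sep = "\t"))
  ord <- order(vapply(ann$exons, function(e) e$start[1L], numeric(1)), ann$name)
  for (i in ord) {
    e <- ann$exons[[i]]
    span <- gene_span(e, L)
    gid <- sprintf("gene:%s", esc(ann$name[i]))
    span_end <- if (span$wraps) span$end + L else span$end
    attrs <- sprintf("ID=%s;Name=%s;category=%s;start_codon=%s;copies=%d",
                     gid, esc(ann$name[i]), ann$category[i],
                     ann$start_codon[i], ann$copies[i])
    lines <- c(lines, paste(genome$id, "mitocms", "gene", span$start + 1L,
                            span_end, ".", ann$strand[i], ".", attrs,
                            sep = "\t"))
    ctype <- gff3_child_type[[ann$category[i]]]
    for (j in seq_len(nrow(e))) {
      ee <- if (e$wraps[j]) e$end[j] + L else e$end[j]
      lines <- c(lines, paste(genome$id, "mitocms", ctype, e$start[j] + 1L,
                              ee, ".", ann$strand[i], ".",
                              sprintf("ID=%s.exon%d;Parent=%s", gid, j, gid),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sequence length declared in a GFF3 `##sequence-region` pragma
#' @param path a GFF3 file.
#' @return Integer length, or `NA` when no pragma is present.
#' @export
gff3_declared_length <- function(path) {
  ln <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (!length(ln)) return(NA_integer_)
  as.integer(strsplit(ln[[1L]], "\\s+")[[1L]][4L])
}

# ---- rotation -------------------------------------------------------------

#' Rotate the origin of a circular genome
#'
#' Moves the coordinate origin forward by `offset` bp: the new sequence
#' starts at old position `offset`, and every annotation interval is
#' shifted accordingly. Rotating by `offset` and then by
#' `length - offset` restores the input exactly.
#'
#' @param genome a circular `circular_genome`.
#' @param ann an [mt_annotation()] table (may be `NULL`).
#' @param offset bp in `[0, length)`.
#' @return A list with fields `genome` and `ann`.
#' @export
rotate_origin <- function(genome, ann, offset) {
  if (!genome$circular) stop("cannot rotate a linear genome")
  offset <- as.integer(offset)
  if (offset < 0 || offset >= genome$length)
    stop("offset must be in [0, genome length)")
  if (offset == 0L) return(list(genome = genome, ann = ann))
  seq2 <- paste0(substr(genome$seq, offset + 1L, genome$length),
                 substr(genome$seq, 1L, offset))
  g2 <- new_circular_genome(genome$id, seq2, TRUE)
  if (!is.null(ann)) {
    ann$exons <- lapply(ann$exons, function(e) {
      out <- e
      for (j in seq_len(nrow(e))) {
        iv <- interval_shift(circ_interval(e$start[j], e$end[j], e$wraps[j]),
                             offset, genome$length)
        out$start[j] <- iv$start; out$end[j] <- iv$end; out$wraps[j] <- iv$wraps
      }
      out
    })
  }
  list(genome = g2, ann = ann)
}

# Extract the sequence covered by an interval (forward strand).
interval_seq <- function(genome, iv) {
  if (!iv$wraps) return(substr(genome$seq, iv$start + 1L, iv$end))
  paste0(substr(genome$seq, iv$start + 1L, genome$length),
         substr(genome$seq, 1L, iv$end))
}

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
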