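# Seedable maintainer/CMS mitogenome-pair generator with a planted truth
# table. The maintainer carries the 36 conserved protein-coding genes of
# conserved_gene_table() separated by random intergenic spacers; the CMS
# genome is derived from it by neutral spacer translocations plus insertion
# of novel-ORF cassettes that reproduce the chimeric-ORF geometry of a
# rearranged mitogenome (ORFs overlapping, or within a configured distance
# of, conserved genes). Conserved CDS are moved, never mutated.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "ACG", "ATT")

# 14-bp AT-only guard containing a stop codon in all six reading frames
# (it equals its own reverse complement); placed at every engineered
# junction so that rearrangement can never create an unplanned reading
# frame across one.
INSULATOR <- "TAATTAATTAATTA"

# 38-bp dual guard: its own reverse complement, carries stop codons in all
# six frames, every start codon inside it (the insulator repeat is full of
# ATT triplets) reaches an in-frame stop before leaving it on either
# strand, and its terminal bases cannot combine with downstream sequence
# into a start codon spanning the junction. Used at every junction the CMS
# derivation engineers, so neither strand can read across or out of one.
DUAL_GUARD <- paste0("CTATT", INSULATOR, INSULATOR, "AATAG")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

codon_gc_weight <- function(codons, gc_target) {
  pb <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
          G = gc_target / 2, T = (1 - gc_target) / 2)
  vapply(strsplit(codons, ""), function(b) prod(pb[b]), numeric(1))
}

sample_codons <- function(n, gc_target, residues = NULL) {
  pool <- sense_codons()
  if (!is.null(residues)) pool <- pool[codon_aa(pool) %in% residues]
  sample(pool, n, replace = TRUE, prob = codon_gc_weight(pool, gc_target))
}

random_dna <- function(n, gc_target) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_target) / 2, gc_target / 2,
                        gc_target / 2, (1 - gc_target) / 2)),
        collapse = "")
}

# Five sense codons (Leu-Thr-Lys-Leu-His) that contain a stop codon in
# both shifted forward frames and in all three reverse-strand frames of
# the local sequence. Spliced into planted ORF bodies every ~25 residues
# so that no unplanned reading frame can run through a cassette.
FRAME_BREAKER <- c("CTA", "ACT", "AAG", "CTT", "CAT")

# Overwrite 5-codon blocks of a residue-codon vector with FRAME_BREAKER,
# every `step` codons, skipping positions in `skip` (e.g. a planted TM run).
salt_frames <- function(res_cod, skip = integer(), step = 25L) {
  n <- length(res_cod)
  at <- 1L
  while (at + 4L <= n) {
    idx <- at:(at + 4L)
    if (!any(idx %in% skip)) {
      res_cod[idx] <- FRAME_BREAKER
      at <- at + step
    } else {
      at <- max(skip) + 1L
    }
  }
  res_cod
}

# residue sets used to dial the TM status of planted ORFs: with every
# residue at Kyte-Doolittle <= -0.4 no 19-residue window can reach the 1.6
# calling threshold, while a 21-residue run from the strongly hydrophobic
# set always produces exactly one segment.
HYDROPHILIC_RES <- c("G", "S", "T", "P", "E", "D", "N", "Q", "K", "R",
                     "H", "Y", "W")
HYDROPHOBIC_RES <- c("L", "I", "V", "F")

#' Synthetic mitogenome-pair generator settings
#'
#' @param seed integer seed; every byte of generator output is a
#'   deterministic function of the configuration.
#' @param genome_length maintainer genome length in bp (default 200,000 --
#'   a desk-scale stand-in for the several-hundred-kb scale of real plant
#'   mitogenomes; full-scale generation works, it is just slower).
#' @param gc_target genomic GC fraction (default 0.45, the plant
#'   mitochondrial regime).
#' @param n_as_orfs number of novel ORFs planted in the CMS genome and
#'   absent from the maintainer (default 15).
#' @param n_tm_orfs how many of the planted ORFs carry a transmembrane
#'   hydrophobic stretch (default 6; must be `<= n_as_orfs`).
#' @param n_ch_orfs how many of the planted ORFs are placed chimerically,
#'   overlapping or near a conserved gene (default 4; `<= n_as_orfs`).
#' @param ch_overlap_range bp range for planted ORF/gene overlaps
#'   (default 10-60; values must not be multiples of 3, which would put
#'   the ORF in frame with the gene, and must be >= 7).
#' @param ch_gap_range bp range for planted ORF-to-gene gaps
#'   (default 20-450).
#' @param ch_window the screening proximity window the truth table assumes
#'   when declaring a planted ORF chimeric (default 500 bp).
#' @param min_aa ORF-calling threshold the truth table assumes
#'   (default 101).
#' @param min_spacer minimum intergenic spacer in bp (default 2500; large
#'   enough to hold any planted cassette with clearance).
#' @param n_translocations neutral spacer-segment translocations applied
#'   when deriving the CMS genome (default 2).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, genome_length = 200000L,
                             gc_target = 0.45, n_as_orfs = 15L,
                             n_tm_orfs = 6L, n_ch_orfs = 4L,
                             ch_overlap_range = c(10L, 60L),
                             ch_gap_range = c(20L, 450L),
                             ch_window = 500L, min_aa = 101L,
                             min_spacer = 2500L, n_translocations = 2L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_target = gc_target, n_as_orfs = as.integer(n_as_orfs),
              n_tm_orfs = as.integer(n_tm_orfs), n_ch_orfs = as.integer(n_ch_orfs),
              ch_overlap_range = as.integer(ch_overlap_range),
              ch_gap_range = as.integer(ch_gap_range),
              ch_window = as.integer(ch_window), min_aa = as.integer(min_aa),
              min_spacer = as.integer(min_spacer),
              n_translocations = as.integer(n_translocations))
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1) stop("gc_target must be in (0,1)")
  if (cfg$n_tm_orfs > cfg$n_as_orfs || cfg$n_ch_orfs > cfg$n_as_orfs)
    stop("n_tm_orfs and n_ch_orfs cannot exceed n_as_orfs")
  if (cfg$min_spacer < 2 * nchar(DUAL_GUARD) + 10)
    stop("min_spacer too small")
  class(cfg) <- "generator_config"
  cfg
}

# Deterministic event plan shared by generate_maintainer() and
# derive_cms(): which planted ORF is TM, which is chimeric (and how), and
# which conserved gene anchors it. Seeds the RNG with config$seed.
plan_events <- function(config) {
  set.seed(config$seed)
  tab <- conserved_gene_table()
  n <- config$n_as_orfs
  eligible <- tab$name[tab$introns == 0]
  if (n > length(eligible))
    stop("n_as_orfs larger than the number of intronless conserved genes")
  if (n == 0L)
    return(data.frame(event = integer(), aa_len = integer(), tm = logical(),
                      type = character(), anchor = character(),
                      overlap_bp = integer(), gap_bp = integer()))
  tm <- rep(FALSE, n)
  if (config$n_tm_orfs) tm[sample.int(n, config$n_tm_orfs)] <- TRUE
  type <- rep("none", n)
  if (config$n_ch_orfs) {
    # overlap-type chimerism is reserved for TM events (the classic
    # chimeric-transmembrane candidate architecture); others get gaps
    ch <- sample.int(n, config$n_ch_orfs)
    for (i in ch) type[i] <- if (tm[i] && stats::runif(1) < 0.5) "overlap" else "gap"
  }
  ov_pool <- seq(config$ch_overlap_range[1], config$ch_overlap_range[2])
  ov_pool <- ov_pool[ov_pool %% 3 != 0 & ov_pool >= 7]
  if (!length(ov_pool)) stop("ch_overlap_range admits no usable overlap")
  gap_pool <- seq(config$ch_gap_range[1], config$ch_gap_range[2])
  data.frame(
    event = seq_len(n),
    aa_len = sample(101:250, n, replace = TRUE),
    tm = tm, type = type,
    anchor = sample(eligible, n),
    overlap_bp = ifelse(type == "overlap",
                        ov_pool[sample.int(length(ov_pool), n, replace = TRUE)],
                        NA_integer_),
    gap_bp = ifelse(type == "gap",
                    gap_pool[sample.int(length(gap_pool), n, replace = TRUE)],
                    NA_integer_),
    stringsAsFactors = FALSE)
}

# Overwrite bases [at-2, at] of a codon string with TAA without creating a
# stop in the host frame (the overwritten patterns x-y-T, x-T-A and A-?-?
# are always sense codons as long as `at` is not a multiple-of-3 boundary
# mismatch; asserted by the caller).
force_cross_frame_stop <- function(s, at) {
  substr(s, at - 2L, at) <- "TAA"
  s
}

# Remove stop codons read in the docking ORF's frame from a conserved-gene
# CDS prefix, keeping the gene's own codons sense. ORF-frame triplets sit
# at positions at, at-3, ... where `at` is the first base of the terminal
# TAA (gene coordinates).
scrub_frame_stops <- function(s, at, protect = integer()) {
  p <- at - 3L
  while (p >= 1L) {
    tri <- substr(s, p, p + 2L)
    if (tri %in% STOP_CODONS) {
      fixed <- FALSE
      for (q in (p:(p + 2L))) {
        if (q %in% protect || q <= 3L) next
        host_cod <- (q - 1L) %/% 3L  # 0-based gene codon index
        hs <- host_cod * 3L + 1L
        for (b in c("C", "G", "A", "T")) {
          if (b == substr(s, q, q)) next
          s2 <- s
          substr(s2, q, q) <- b
          if (substr(s2, p, p + 2L) %in% STOP_CODONS) next
          if (substr(s2, hs, hs + 2L) %in% STOP_CODONS) next
          s <- s2
          fixed <- TRUE
          break
        }
        if (fixed) break
      }
      if (!fixed) stop("internal: could not scrub cross-frame stop")
    }
    p <- p - 3L
  }
  s
}

# Build one conserved-gene CDS (reading orientation, stop included).
# When dock_overlap is set the prefix is made dockable: a TAA in the frame
# of a future ORF whose last `dock_overlap` bases will coincide with this
# prefix, and no earlier stop in that frame.
make_cds <- function(cds_len, start_codon, gc_target, dock_overlap = NA) {
  n_cod <- cds_len %/% 3L
  s <- paste(c(start_codon, sample_codons(n_cod - 2L, gc_target), "TAA"),
             collapse = "")
  if (!is.na(dock_overlap)) {
    o <- as.integer(dock_overlap)
    stopifnot(o %% 3L != 0L, o >= 7L, o < cds_len)
    s <- force_cross_frame_stop(s, o)
    s <- scrub_frame_stops(s, o - 2L, protect = (o - 2L):o)
  }
  s
}

split_exons <- function(n_cod, n_exons) {
  # interior split points at codon boundaries, each exon >= 10 codons
  if (n_exons == 1L) return(n_cod)
  repeat {
    cuts <- sort(sample(10:(n_cod - 10), n_exons - 1L))
    lens <- diff(c(0L, cuts, n_cod))
    if (all(lens >= 10L)) return(lens)
  }
}

make_intron <- function(gc_target) {
  len <- sample(80:200, 1L)
  paste0("GT", INSULATOR, random_dna(len - 18L, gc_target), "AG")
}

#' Generate a synthetic maintainer mitogenome
#'
#' Places the 36 conserved protein-coding genes ([conserved_gene_table()])
#' in random order and orientation on a circle, separated by random
#' intergenic spacers at the target GC. Intron-bearing genes receive their
#' documented intron counts; every CDS is a valid translatable frame with
#' a terminal stop, and an in-frame stop codon immediately precedes each
#' gene so that the ORF caller recovers every intronless conserved CDS at
#' exactly its annotated coordinates. Output is byte-deterministic for a
#' given configuration.
#'
#' @param config a [generator_config()].
#' @return A list with fields `genome` (`circular_genome`) and `ann`
#'   ([mt_annotation()]).
#' @export
generate_maintainer <- function(config) {
  plan <- plan_events(config)  # seeds the RNG stream
  tab <- conserved_gene_table()
  ng <- nrow(tab)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  dock <- rep(NA_integer_, ng)
  ov <- plan[plan$type == "overlap", , drop = FALSE]
  if (nrow(ov)) {
    idx <- match(ov$anchor, tab$name)
    strand[idx] <- "+"           # docked ORFs are built on the plus strand
    dock[idx] <- ov$overlap_bp
  }
  cds <- vapply(seq_len(ng), function(i)
    make_cds(tab$cds_len[i], tab$start_codon[i], config$gc_target, dock[i]),
    character(1))
  # split intron genes into exons and interleave introns
  bodies <- vector("list", ng)
  exon_layout <- vector("list", ng)
  for (i in seq_len(ng)) {
    k <- tab$introns[i] + 1L
    lens_cod <- split_exons(tab$cds_len[i] %/% 3L, k)
    lens <- lens_cod * 3L
    parts <- character(0)
    offs <- integer(0)   # reading-orientation exon starts within body
    pos <- 0L
    cpos <- 1L
    for (j in seq_len(k)) {
      ex <- substr(cds[i], cpos, cpos + lens[j] - 1L)
      offs <- c(offs, pos)
      parts <- c(parts, ex)
      pos <- pos + lens[j]
      cpos <- cpos + lens[j]
      if (j < k) {
        intr <- make_intron(config$gc_target)
        parts <- c(parts, intr)
        pos <- pos + nchar(intr)
      }
    }
    bodies[[i]] <- paste(parts, collapse = "")
    exon_layout[[i]] <- data.frame(off = offs, len = lens)
  }
  # genomic block per gene: upstream in-frame stop guard + oriented body
  blocks <- vapply(seq_len(ng), function(i) {
    if (strand[i] == "+") paste0("TAA", bodies[[i]])
    else paste0(revcomp(bodies[[i]]), "TTA")
  }, character(1))
  ord <- sample.int(ng)
  nslots <- ng + 1L
  total_blocks <- sum(nchar(blocks))
  avail <- config$genome_length - total_blocks - nslots * config$min_spacer
  if (avail < 0)
    stop("conserved genes do not fit: increase genome_length (need >= ",
         total_blocks + nslots * config$min_spacer, " bp)")
  extra <- as.vector(stats::rmultinom(1L, avail, rep(1, nslots)))
  spacer_len <- config$min_spacer + extra
  make_spacer <- function(len)
    paste0(DUAL_GUARD, random_dna(len - 2L * nchar(DUAL_GUARD), config$gc_target),
           DUAL_GUARD)
  pieces <- character(0)
  cursor <- 0L
  exon_rows <- vector("list", ng)
  for (k in seq_len(ng)) {
    sp <- make_spacer(spacer_len[k])
    pieces <- c(pieces, sp)
    cursor <- cursor + nchar(sp)
    i <- ord[k]
    blk <- blocks[i]
    body_len <- nchar(bodies[[i]])
    body_start <- if (strand[i] == "+") cursor + 3L else cursor
    lay <- exon_layout[[i]]
    ex <- lapply(seq_len(nrow(lay)), function(j) {
      if (strand[i] == "+") {
        s0 <- body_start + lay$off[j]
        c(s0, s0 + lay$len[j])
      } else {
        s0 <- body_start + body_len - (lay$off[j] + lay$len[j])
        c(s0, s0 + lay$len[j])
      }
    })
    exon_rows[[i]] <- data.frame(start = vapply(ex, `[`, numeric(1), 1),
                                 end = vapply(ex, `[`, numeric(1), 2),
                                 wraps = FALSE)
    pieces <- c(pieces, blk)
    cursor <- cursor + nchar(blk)
  }
  pieces <- c(pieces, make_spacer(spacer_len[nslots]))
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == config$genome_length)
  ann <- mt_annotation(tab$name, rep("protein_coding", ng), strand,
                       tab$start_codon, tab$copies, exon_rows)
  list(genome = new_circular_genome(sprintf("synthetic_maintainer_seed%d",
                                            config$seed), seq),
       ann = ann)
}
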