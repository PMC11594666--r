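# Deterministic synthetic fixture reproducing the archetypal CMS candidate
# locus: a 116-aa, two-TM-segment ORF whose 3' end shares 41 bp with the
# 5' end of an rpl2-labelled gene and which lies 187 bp (non-coding) from
# an rpl5-labelled gene, plus a distant 103-aa one-TM-segment ORF far from
# every conserved gene. The fixture is synthetic: gene contents are
# generated, only the locus geometry and the two protein archetypes are
# modelled on the real candidate architecture.

fixture_orf116_body <- function(rpl2_seq) {
  # residues 2..103: leucine runs at 20-40 and 70-90, serine elsewhere.
  # Codons alternate (TCA/TCT, CTA/CTT) so the reverse strand is salted
  # with stop codons and the body contains no G outside its start codon,
  # which keeps every shifted reading frame free of start codons.
  cods <- vapply(2:103, function(i) {
    leu <- (i >= 20 && i <= 40) || (i >= 70 && i <= 90)
    if (leu) { if (i %% 2 == 0) "CTA" else "CTT" }
    else { if (i %% 2 == 0) "TCA" else "TCT" }
  }, character(1))
  # frame-breaker blocks in the serine stretches so no unplanned reading
  # frame survives a pass through the ORF body (residue r = cods[r - 1])
  for (r0 in c(8L, 50L, 93L)) cods[(r0 - 1L):(r0 + 3L)] <- FRAME_BREAKER
  body <- paste(c("ATG", cods, "C"), collapse = "")  # 310 nt; 'C' opens codon 104
  stopifnot(nchar(body) == 310L)
  # guard: rpl2-frame TAA immediately before the gene start
  body <- force_cross_frame_stop(body, 310L)
  mixed <- paste0(substr(body, 310L, 310L), substr(rpl2_seq, 1L, 2L))
  stopifnot(!(mixed %in% STOP_CODONS))
  body
}

fixture_orf103 <- function() {
  cods <- vapply(2:103, function(i) {
    leu <- i >= 40 && i <= 60
    if (leu) { if (i %% 2 == 0) "CTA" else "CTT" }
    else { if (i %% 2 == 0) "TCA" else "TCT" }
  }, character(1))
  for (r0 in c(10L, 70L, 90L)) cods[(r0 - 1L):(r0 + 3L)] <- FRAME_BREAKER
  paste(c("ATG", cods, "TAA"), collapse = "")  # 312 nt
}

# rpl2 CDS whose first 41 bases are dockable by construction: read in the
# frame of the docked ORF they are twelve aspartate codons ending in TAA,
# while in rpl2's own frame they are sense codons.
fixture_rpl2 <- function(gc_target = 0.45) {
  prefix <- paste0("AT", strrep("GAT", 12L), "TAA")  # nt 1..41
  stopifnot(nchar(prefix) == 41L)
  body <- paste(c(prefix, "A", sample_codons(318L, gc_target), "TAA"),
                collapse = "")
  stopifnot(nchar(body) == 999L)
  # rpl2's own frame must be sense throughout the constrained prefix
  cods <- substring(body, seq(1L, 42L, by = 3L), seq(3L, 44L, by = 3L))
  stopifnot(!any(cods %in% STOP_CODONS))
  body
}

#' Write the packaged CMS-candidate locus fixture
#'
#' Emits a deterministic synthetic genome pair (`orf116b_cms.fasta/.gff3`,
#' `orf116b_maintainer.fasta/.gff3`) and a junction-spanning primer table
#' (`orf116b_primers.tsv`). The CMS genome carries a 116-aa ORF with two
#' predicted TM segments whose 3' end overlaps the 5' end of the
#' rpl2-labelled gene by 41 bp and whose start lies 187 bp from the
#' rpl5-labelled gene, plus a 103-aa one-TM-segment ORF more than 500 bp
#' from every conserved gene; the maintainer genome carries the identical
#' conserved CDS without either ORF. Output is byte-identical across runs.
#'
#' @param dir output directory; when `NULL` (default) nothing is written
#'   and the in-memory objects are returned.
#' @return A list: `cms`, `maintainer` (each `genome` + `ann`), `primers`,
#'   and `paths` when `dir` was given.
#' @export
make_orf116b_fixture <- function(dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(116L)
  gc <- 0.45
  rpl5 <- make_cds(555L, "ATG", gc)
  rpl2 <- fixture_rpl2(gc)
  orf116_body <- fixture_orf116_body(rpl2)
  orf103 <- fixture_orf103()
  ins <- INSULATOR
  spacerA <- paste0(ins, random_dna(600L - nchar(ins) - 3L, gc), "TAA")
  gap187 <- paste0(ins, random_dna(187L - nchar(ins) - 3L, gc), "TAA")
  gapM <- paste0(ins, random_dna(400L - nchar(ins) - 3L, gc), "TAA")
  spacerB <- paste0(ins, random_dna(1200L - 2L * nchar(ins), gc), ins)
  spacerC <- paste0(ins, random_dna(700L - nchar(ins), gc))
  cms_seq <- paste0(spacerA, rpl5, gap187, orf116_body, rpl2,
                    spacerB, "TAA", orf103, ins, spacerC)
  # coordinates (0-based)
  rpl5_s <- 600L
  orf116_s <- rpl5_s + 555L + 187L
  rpl2_s <- orf116_s + 310L
  orf103_s <- rpl2_s + 999L + 1200L + 3L
  cms <- new_circular_genome("orf116b_locus_cms", cms_seq)
  one_exon <- function(s, len) data.frame(start = s, end = s + len, wraps = FALSE)
  cms_ann <- mt_annotation(
    c("rpl5", "rpl2", "orf116", "orf103"),
    c("protein_coding", "protein_coding", "ORF", "ORF"),
    c("+", "+", "+", "+"), c("ATG", "ATG", "ATG", "ATG"), rep(1L, 4L),
    list(one_exon(rpl5_s, 555L), one_exon(rpl2_s, 999L),
         one_exon(orf116_s, 351L), one_exon(orf103_s, 312L)))
  m_seq <- paste0(spacerA, rpl5, gapM, rpl2, spacerB, spacerC)
  m_rpl2_s <- rpl5_s + 555L + 400L
  maintainer <- new_circular_genome("orf116b_locus_maintainer", m_seq)
  m_ann <- mt_annotation(c("rpl5", "rpl2"), rep("protein_coding", 2L),
                         c("+", "+"), c("ATG", "ATG"), c(1L, 1L),
                         list(one_exon(rpl5_s, 555L), one_exon(m_rpl2_s, 999L)))
  primers <- data.frame(
    name = c("2O", "5O"),
    fwd = c(substr(cms_seq, orf116_s + 101L, orf116_s + 120L),
            substr(cms_seq, rpl5_s + 101L, rpl5_s + 120L)),
    rev = c(revcomp(substr(cms_seq, rpl2_s + 201L, rpl2_s + 220L)),
            revcomp(substr(cms_seq, orf116_s + 151L, orf116_s + 170L))),
    stringsAsFactors = FALSE)
  out <- list(cms = list(genome = cms, ann = cms_ann),
              maintainer = list(genome = maintainer, ann = m_ann),
              primers = primers)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      cms_fasta = file.path(dir, "orf116b_cms.fasta"),
      cms_gff3 = file.path(dir, "orf116b_cms.gff3"),
      maintainer_fasta = file.path(dir, "orf116b_maintainer.fasta"),
      maintainer_gff3 = file.path(dir, "orf116b_maintainer.gff3"),
      primers = file.path(dir, "orf116b_primers.tsv"))
    write_genome(cms, paths$cms_fasta)
    write_annotations(cms_ann, cms, paths$cms_gff3)
    write_genome(maintainer, paths$maintainer_fasta)
    write_annotations(m_ann, maintainer, paths$maintainer_gff3)
    utils::write.table(primers, paths$primers, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Load the packaged CMS-candidate locus fixture
#'
#' Reads the fixture shipped under `inst/extdata/orf116b/` (identical to
#' what [make_orf116b_fixture()] regenerates).
#'
#' @return Same shape as [make_orf116b_fixture()].
#' @export
load_orf116b_fixture <- function() {
  dir <- system.file("extdata", "orf116b", package = "mitocms", mustWork = TRUE)
  cg <- load_genome(file.path(dir, "orf116b_cms.fasta"))
  mg <- load_genome(file.path(dir, "orf116b_maintainer.fasta"))
  list(cms = list(genome = cg,
                  ann = load_annotations(file.path(dir, "orf116b_cms.gff3"), cg)),
       maintainer = list(genome = mg,
                         ann = load_annotations(file.path(dir, "orf116b_maintainer.gff3"), mg)),
       primers = load_primers(file.path(dir, "orf116b_primers.tsv")))
}
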