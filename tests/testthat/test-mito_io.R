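# Genome/annotation I/O and circular-coordinate arithmetic.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("FASTA loading enforces a single clean ACGT record", {
  f <- write_tmp_fasta(c(">rec1 a circular genome",
                         paste(rep("ACGTGCAT", 6), collapse = "")))
  g <- load_genome(f)
  expect_s3_class(g, "circular_genome")
  expect_equal(g$length, 48L)
  expect_equal(g$id, "rec1")
  expect_true(g$circular)

  # lower-case input is uppercased
  f2 <- write_tmp_fasta(c(">x", "acgtacgt"))
  expect_equal(load_genome(f2)$seq, "ACGTACGT")

  # ambiguity codes are rejected with the offending position
  f3 <- write_tmp_fasta(c(">x", "ACGTACGTANACGT"))
  expect_error(load_genome(f3), "position 10")

  f4 <- write_tmp_fasta(c(">a", "ACGT", ">b", "ACGT"))
  expect_error(load_genome(f4), "a, b")
})

test_that("GFF3 coordinates convert 1-based inclusive to 0-based half-open", {
  set.seed(11)
  g <- mitocms:::new_circular_genome("t", paste(
    sample(c("A", "C", "G", "T"), 600, TRUE), collapse = ""))
  ann <- mt_annotation("g1", "protein_coding", "+", "ATG", 1L,
                       list(data.frame(start = 0L, end = 303L, wraps = FALSE)))
  f <- tempfile(fileext = ".gff3")
  write_annotations(ann, g, f)
  lines <- readLines(f)
  gene_line <- grep("\tgene\t", lines, value = TRUE)
  expect_match(gene_line, "\t1\t303\t")  # GFF3 start=1, end=303
  back <- load_annotations(f, g)
  expect_equal(back$exons[[1]]$start, 0L)
  expect_equal(back$exons[[1]]$end, 303L)
})

test_that("multi-exon genes assemble from shared Parent with introns", {
  set.seed(12)
  g <- mitocms:::new_circular_genome("t", paste(
    sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""))
  ann <- mt_annotation("g2", "protein_coding", "+", "ATG", 1L,
                       list(data.frame(start = c(100L, 400L),
                                       end = c(250L, 520L),
                                       wraps = c(FALSE, FALSE))))
  f <- tempfile(fileext = ".gff3")
  write_annotations(ann, g, f)
  back <- load_annotations(f, g)
  expect_equal(nrow(back$exons[[1]]), 2L)  # 2 exons -> 1 intron
  expect_equal(back$exons[[1]]$start, c(100L, 400L))
})

test_that("GFF3 write/read round trip reproduces annotations field by field", {
  fx <- make_orf116b_fixture()
  for (side in list(fx$cms, fx$maintainer)) {
    f <- tempfile(fileext = ".gff3")
    write_annotations(side$ann, side$genome, f)
    back <- load_annotations(f, side$genome)
    a1 <- as.data.frame(side$ann)[order(side$ann$name), ]
    a2 <- as.data.frame(back)[order(back$name), ]
    rownames(a1) <- rownames(a2) <- NULL
    for (col in c("name", "category", "strand", "start_codon", "copies"))
      expect_identical(a1[[col]], a2[[col]])
    for (i in seq_len(nrow(a1)))
      expect_equal(unname(a1$exons[[i]]), unname(a2$exons[[i]]))
  }
  # declared sequence-region length cross-checks the FASTA
  dir <- system.file("extdata", "orf116b", package = "mitocms")
  expect_equal(gff3_declared_length(file.path(dir, "orf116b_cms.gff3")),
               load_genome(file.path(dir, "orf116b_cms.fasta"))$length)
})

test_that("origin-crossing features survive a GFF3 round trip", {
  set.seed(13)
  g <- mitocms:::new_circular_genome("w", paste(
    sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))
  ann <- mt_annotation("wg", "protein_coding", "+", "ATG", 1L,
                       list(data.frame(start = c(450L, 40L),
                                       end = c(20L, 100L),
                                       wraps = c(TRUE, FALSE))))
  f <- tempfile(fileext = ".gff3")
  write_annotations(ann, g, f)
  back <- load_annotations(f, g)
  expect_equal(unname(back$exons[[1]]), unname(ann$exons[[1]]))
  # the same file on a linear genome is an error
  gl <- mitocms:::new_circular_genome("w", g$seq, circular = FALSE)
  expect_error(load_annotations(f, gl), "linear")
})

test_that("circular_distance matches the worked intergenic example", {
  d <- circular_distance(circ_interval(0, 100), circ_interval(287, 400), 1000)
  expect_equal(d$gap_bp, 187L)
  expect_equal(d$overlap_bp, 0L)
  # identical intervals: gap 0, overlap = length
  d2 <- circular_distance(circ_interval(10, 60), circ_interval(10, 60), 100)
  expect_equal(d2$gap_bp, 0L)
  expect_equal(d2$overlap_bp, 50L)
  # straddling the origin
  d3 <- circular_distance(circ_interval(950, 30, wraps = TRUE),
                          circ_interval(20, 60), 1000)
  expect_equal(d3$overlap_bp, 10L)
  expect_error(circular_distance(circ_interval(0, 10), circ_interval(1, 5), 0))
})

test_that("circular_distance agrees with a base-membership oracle and is symmetric", {
  set.seed(21)
  for (rep in 1:60) {
    L <- sample(50:2000, 1)
    mk <- function() {
      s <- sample(0:(L - 1L), 1)
      len <- sample(1:(L - 1L), 1)
      interval_from_length(s, len, L)
    }
    a <- mk(); b <- mk()
    d <- circular_distance(a, b, L)
    dr <- circular_distance(b, a, L)
    expect_identical(d, dr)
    o <- oracle_circular_distance(a, b, L)
    expect_equal(d$overlap_bp, o$overlap_bp)
    expect_equal(d$gap_bp, o$gap_bp)
  }
})

test_that("rotate_origin composes to the identity and preserves ORFs", {
  fx <- make_orf116b_fixture()
  g <- fx$cms$genome
  r0 <- rotate_origin(g, fx$cms$ann, 0)
  expect_identical(r0$genome$seq, g$seq)
  r <- rotate_origin(g, fx$cms$ann, 1234)
  r2 <- rotate_origin(r$genome, r$ann, g$length - 1234)
  expect_identical(r2$genome$seq, g$seq)
  expect_equal(as.data.frame(r2$ann), as.data.frame(fx$cms$ann))
  # ORF protein multiset invariant under rotation
  p0 <- sort(find_orfs(g)$protein)
  for (off in c(17, 2439)) {
    rr <- rotate_origin(g, NULL, off)
    expect_identical(sort(find_orfs(rr$genome)$protein), p0)
  }
  gl <- mitocms:::new_circular_genome("l", g$seq, circular = FALSE)
  expect_error(rotate_origin(gl, NULL, 5), "linear")
})
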