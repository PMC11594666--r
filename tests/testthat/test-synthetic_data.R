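# Synthetic mitogenome-pair generator: determinism, conservation, planted
# truth, and the packaged candidate-locus fixture.

test_that("generation is byte-deterministic for a fixed configuration", {
  cfg <- generator_config(seed = 3, n_as_orfs = 3L, n_tm_orfs = 1L,
                          n_ch_orfs = 1L)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$maintainer$genome$seq, b$maintainer$genome$seq)
  expect_identical(a$cms$genome$seq, b$cms$genome$seq)
  expect_identical(a$truth, b$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(a, d1)
  write_simulation(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("conserved CDS sequences are shared exactly between the pair", {
  cfg <- generator_config(seed = 5, n_as_orfs = 4L, n_tm_orfs = 2L,
                          n_ch_orfs = 2L)
  sim <- simulate_pair(cfg)
  get_cds <- function(side, name) {
    i <- match(name, side$ann$name)
    ex <- side$ann$exons[[i]]
    segs <- vapply(seq_len(nrow(ex)), function(j)
      mitocms:::interval_seq(side$genome,
                             circ_interval(ex$start[j], ex$end[j], ex$wraps[j])),
      character(1))
    s <- paste(segs[order(ex$start)], collapse = "")
    if (side$ann$strand[i] == "-") mitocms:::revcomp(s) else s
  }
  tab <- conserved_gene_table()
  for (nm in tab$name) {
    cds_m <- get_cds(sim$maintainer, nm)
    cds_c <- get_cds(sim$cms, nm)
    expect_identical(cds_c, cds_m)
    expect_equal(nchar(cds_m), tab$cds_len[tab$name == nm])
    # valid translatable frame with terminal stop
    expect_no_error(translate_cds(cds_m))
  }
})

test_that("the ORF caller recovers intronless conserved CDS at planted coordinates", {
  cfg <- generator_config(seed = 9, n_as_orfs = 0L, n_tm_orfs = 0L,
                          n_ch_orfs = 0L)
  m <- generate_maintainer(cfg)
  orfs <- find_orfs(m$genome)
  tab <- conserved_gene_table()
  keys <- paste(orfs$start, orfs$end, orfs$strand, sep = "/")
  for (i in which(tab$introns == 0 & tab$cds_len >= 306)) {
    j <- match(tab$name[i], m$ann$name)
    ex <- m$ann$exons[[j]]
    expect_true(paste(ex$start, ex$end, m$ann$strand[j], sep = "/") %in% keys,
                label = paste("recovered", tab$name[i]))
  }
})

test_that("a zero-event derivation yields no line-specific ORFs", {
  cfg <- generator_config(seed = 11, n_as_orfs = 0L, n_tm_orfs = 0L,
                          n_ch_orfs = 0L)
  sim <- simulate_pair(cfg)
  expect_equal(nrow(sim$truth), 0L)
  # the CMS genome still differs (neutral translocations moved spacers)
  expect_false(identical(sim$cms$genome$seq, sim$maintainer$genome$seq))
  scr <- run_screen(sim$cms, sim$maintainer)
  expect_equal(scr$venn$n_AS, 0L)
  expect_equal(nrow(scr$candidates), 0L)
})

test_that("planted chimeric geometry is reproduced exactly by the classifier", {
  cfg <- generator_config(seed = 13, n_as_orfs = 2L, n_tm_orfs = 2L,
                          n_ch_orfs = 2L, ch_overlap_range = c(41L, 41L),
                          ch_gap_range = c(187L, 187L))
  sim <- simulate_pair(cfg)
  tr <- sim$truth
  L <- sim$cms$genome$length
  cons <- sim$cms$ann[sim$cms$ann$category == "protein_coding", ]
  for (i in seq_len(nrow(tr))) {
    cl <- classify_chimeric(circ_interval(tr$start[i], tr$end[i], tr$wraps[i]),
                            cons, L)
    if (tr$event_type[i] == "overlap") {
      expect_equal(cl$overlap_bp, 41L)
      expect_equal(cl$nearest_gene, tr$neighbor[i])
    } else if (tr$event_type[i] == "gap") {
      expect_equal(cl$gap_bp, 187L)
      expect_equal(cl$nearest_gene, tr$neighbor[i])
    }
    expect_true(cl$ch_flag)
  }
})

test_that("the emitted GC fraction tracks the target", {
  for (gc in c(0.40, 0.45)) {
    cfg <- generator_config(seed = 17, gc_target = gc, n_as_orfs = 0L,
                            n_tm_orfs = 0L, n_ch_orfs = 0L)
    m <- generate_maintainer(cfg)
    expect_lt(abs(gc_content(m$genome$seq) - gc), 0.01)
  }
})

test_that("generator configurations are validated", {
  expect_error(generator_config(n_as_orfs = 2, n_tm_orfs = 3), "exceed")
  expect_error(generator_config(gc_target = 1.2), "gc_target")
  expect_error(generate_maintainer(generator_config(genome_length = 50000L)),
               "increase genome_length")
})

test_that("the packaged candidate-locus fixture is byte-stable and correct", {
  d <- tempfile()
  fx <- make_orf116b_fixture(d)
  pkg_dir <- system.file("extdata", "orf116b", package = "mitocms")
  for (f in list.files(pkg_dir)) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(pkg_dir, f)),
                     label = paste("regenerated", f))
  }
  orfs <- find_orfs(fx$cms$genome)
  o116 <- orfs[orfs$aa_length == 116, ]
  expect_equal(nrow(o116), 1L)
  expect_equal(nchar(o116$protein), 116L)
  expect_equal(nrow(predict_tm_segments(o116$protein)), 2L)
  o103 <- orfs[orfs$aa_length == 103, ]
  expect_equal(nrow(predict_tm_segments(o103$protein)), 1L)
})
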