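# Composition summaries and 2^-ddCt relative expression.

test_that("gc_content counts G+C and is strand-invariant", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_error(gc_content(""), "empty")
  set.seed(81)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_equal(gc_content(s), gc_content(mitocms:::revcomp(s)))
})

test_that("the default synthetic maintainer reproduces the documented composition", {
  cfg <- generator_config(seed = 7)
  m <- generate_maintainer(cfg)
  sm <- summarize_genome(m$genome, m$ann)
  expect_equal(unname(sm$counts["protein_coding"]), 36L)
  expect_equal(sm$n_intron_genes, 8L)
  expect_equal(sm$min_protein_coding_bp, 303L)
  expect_equal(sm$min_protein_coding_gene, "nad4L")
  expect_equal(sm$max_protein_coding_bp, 2013L)
  expect_equal(sm$max_protein_coding_gene, "nad5")
  expect_equal(unname(sm$start_codon_usage["ACG"]), 3L)
  expect_equal(unname(sm$start_codon_usage["ATT"]), 1L)
  expect_equal(unname(sm$start_codon_usage["ATG"]), 32L)
  # nad5 carries four introns -> five exons
  expect_equal(nrow(m$ann$exons[[which(m$ann$name == "nad5")]]), 5L)
  # GC tracks the target within a percent on a 200 kb genome
  expect_lt(abs(sm$gc_fraction - cfg$gc_target), 0.01)
  # summary is invariant under origin rotation
  r <- rotate_origin(m$genome, m$ann, 54321L)
  sr <- summarize_genome(r$genome, r$ann)
  sr$length_bp <- sm$length_bp  # identical anyway
  expect_equal(sr, sm)
})

test_that("empty annotations give zero counts and an all-zero histogram", {
  g <- mitocms:::new_circular_genome("e", "ACGTACGT")
  ann <- mt_annotation(character(), character(), character(), character(),
                       integer(), list())
  sm <- summarize_genome(g, ann)
  expect_true(all(sm$counts == 0L))
  expect_true(all(sm$protein_length_hist == 0L))
})

test_that("protein-length histogram uses left-closed bins and matches counting", {
  set.seed(82)
  L <- 1000000L
  n <- 50
  aa <- sample(c(90:750), n, TRUE)
  aa[1:2] <- c(200L, 100L)  # boundary cases fall in [200,300) and [100,200)
  lens <- (aa + 1L) * 3L
  starts <- cumsum(c(0L, rep(3000L, n - 1L)))
  ann <- mt_annotation(sprintf("g%02d", 1:n), rep("protein_coding", n),
                       rep("+", n), rep("ATG", n), rep(1L, n),
                       lapply(seq_len(n), function(i)
                         data.frame(start = starts[i], end = starts[i] + lens[i],
                                    wraps = FALSE)))
  g2 <- mitocms:::new_circular_genome("h", strrep("ACGT", 10))
  g2$length <- L  # intervals live on a large virtual circle
  sm <- summarize_genome(g2, ann)
  oracle <- vapply(1:6, function(b)
    sum(aa >= b * 100 & aa < (b + 1) * 100), integer(1))
  expect_equal(unname(sm$protein_length_hist), oracle)
  expect_equal(sm$underflow, sum(aa < 100))
  expect_equal(sm$overflow, sum(aa >= 700))
  expect_equal(sum(sm$protein_length_hist) + sm$underflow + sm$overflow, n)
})

test_that("2^-ddCt has the documented closed-form behavior", {
  ct <- data.frame(sample = rep(c("cal", "s1"), each = 2),
                   gene = rep(c("tgt", "18S"), 2),
                   ct = c(25, 20, 25, 20))
  r <- rel_expression(ct, "tgt", "cal")
  expect_equal(r$fold, c(1, 1))
  # ddCt of -1 doubles expression
  ct2 <- ct; ct2$ct[3] <- 24
  r2 <- rel_expression(ct2, "tgt", "cal")
  expect_equal(r2$fold[r2$sample == "s1"], 2)
  expect_equal(r2$fold[r2$sample == "cal"], 1)
  expect_error(rel_expression(ct[ct$gene != "18S" | ct$sample != "s1", ],
                              "tgt", "cal"), "s1")
})

test_that("ddCt is scale-free and matches a spreadsheet-style recomputation", {
  set.seed(83)
  samples <- c("maint_pistil", "cms_pistil", "cms_anther", "maint_anther")
  ct <- expand.grid(sample = samples, gene = c("orf116b", "18S"),
                    stringsAsFactors = FALSE)
  ct$ct <- runif(nrow(ct), 15, 32)
  r <- rel_expression(ct, "orf116b", "maint_pistil")
  # independent recomputation
  for (s in samples) {
    dct <- ct$ct[ct$sample == s & ct$gene == "orf116b"] -
      ct$ct[ct$sample == s & ct$gene == "18S"]
    dct0 <- ct$ct[ct$sample == "maint_pistil" & ct$gene == "orf116b"] -
      ct$ct[ct$sample == "maint_pistil" & ct$gene == "18S"]
    expect_equal(r$fold[r$sample == s], 2^-(dct - dct0))
  }
  # adding a constant to one sample's two Cts leaves its fold unchanged
  ct3 <- ct
  sel <- ct3$sample == "cms_anther"
  ct3$ct[sel] <- ct3$ct[sel] + 3.7
  r3 <- rel_expression(ct3, "orf116b", "maint_pistil")
  expect_equal(r3$fold[r3$sample == "cms_anther"],
               r$fold[r$sample == "cms_anther"])
})
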