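# AS/TM/CH classification, Venn counts and candidate ranking.

test_that("identical genomes have no line-specific ORFs; swap is symmetric", {
  fx <- make_orf116b_fixture()
  orfs <- find_orfs(fx$cms$genome)
  expect_length(find_specific_orfs(orfs, orfs), 0L)
  oc <- orfs
  om <- find_orfs(fx$maintainer$genome)
  as_cms <- find_specific_orfs(oc, om)
  as_m <- find_specific_orfs(om, oc)
  # exact mode: no protein can be specific to both sides
  expect_length(intersect(oc$protein[oc$id %in% as_cms],
                          om$protein[om$id %in% as_m]), 0L)
  expect_length(find_specific_orfs(oc[0, ], om), 0L)
})

test_that("identity mode tolerates near-identical homologs, exact does not", {
  fx <- make_orf116b_fixture()
  oc <- find_orfs(fx$cms$genome)
  # fake maintainer carrying a 1-residue variant of every CMS protein
  om <- oc
  om$protein <- vapply(om$protein, function(p) {
    substr(p, 5, 5) <- if (substr(p, 5, 5) == "A") "G" else "A"
    p
  }, character(1))
  expect_setequal(find_specific_orfs(oc, om, mode = "exact"), oc$id)
  expect_length(find_specific_orfs(oc, om, mode = "identity"), 0L)
})

test_that("the chimeric window is a hard 500 bp boundary", {
  set.seed(61)
  L <- 10000L
  ann <- mt_annotation("nad3", "protein_coding", "+", "ATG", 1L,
                       list(data.frame(start = 5000L, end = 5357L, wraps = FALSE)))
  orf_at_gap <- function(gap) circ_interval(5000L - gap - 351L, 5000L - gap)
  for (gap in c(499L, 500L)) {
    cl <- classify_chimeric(orf_at_gap(gap), ann, L)
    expect_true(cl$ch_flag)
    expect_equal(cl$gap_bp, gap)
  }
  cl <- classify_chimeric(orf_at_gap(501L), ann, L)
  expect_false(cl$ch_flag)
  expect_equal(cl$neighbor_side, "downstream")
  # monotone in the window
  expect_true(classify_chimeric(orf_at_gap(501L), ann, L, window = 600)$ch_flag)
  expect_error(classify_chimeric(orf_at_gap(10L), ann, L, window = -1), "window")
})

test_that("chimeric calls across the origin match the membership oracle", {
  set.seed(62)
  for (rep in 1:25) {
    L <- sample(2000:4000, 1)
    gs <- sample(0:(L - 1), 1)
    giv <- interval_from_length(gs, 900L, L)
    ann <- mt_annotation("g", "protein_coding", "+", "ATG", 1L,
                         list(data.frame(start = giv$start, end = giv$end,
                                         wraps = giv$wraps)))
    ost <- sample(0:(L - 1), 1)
    orf <- interval_from_length(ost, 351L, L)
    cl <- classify_chimeric(orf, ann, L)
    o <- oracle_circular_distance(orf, mitocms:::gene_span(ann$exons[[1]], L), L)
    expect_equal(cl$overlap_bp, o$overlap_bp)
    expect_equal(cl$gap_bp, o$gap_bp)
    expect_equal(cl$ch_flag, o$overlap_bp > 0 || o$gap_bp <= 500)
  }
})

test_that("tRNA and rRNA genes never anchor a chimeric call", {
  L <- 5000L
  ann <- mt_annotation(c("trnA", "rrn18"), c("tRNA", "rRNA"), c("+", "+"),
                       c("ATG", "ATG"), c(1L, 1L),
                       list(data.frame(start = 1000L, end = 1070L, wraps = FALSE),
                            data.frame(start = 2000L, end = 3500L, wraps = FALSE)))
  cl <- classify_chimeric(circ_interval(1100L, 1451L), ann, L)
  expect_false(cl$ch_flag)
  expect_equal(cl$neighbor_side, "none")
})

test_that("Venn regions are disjoint and reconstruct the marginals", {
  cls1 <- data.frame(orf_id = "a", as_flag = TRUE, tm_flag = TRUE,
                     ch_flag = TRUE)
  v1 <- venn_counts(cls1)
  expect_equal(unname(v1$regions["AS_TM_CH"]), 1L)
  expect_equal(c(v1$n_AS, v1$n_TM, v1$n_CH), c(1L, 1L, 1L))
  cls0 <- data.frame(orf_id = letters[1:4], as_flag = FALSE, tm_flag = FALSE,
                     ch_flag = FALSE)
  expect_true(all(venn_counts(cls0)$regions == 0L))
  expect_error(venn_counts(data.frame(orf_id = c("a", "a"), as_flag = TRUE,
                                      tm_flag = FALSE, ch_flag = FALSE)),
               "duplicate")
  set.seed(63)
  cls <- data.frame(orf_id = sprintf("o%02d", 1:30),
                    as_flag = sample(c(TRUE, FALSE), 30, TRUE),
                    tm_flag = sample(c(TRUE, FALSE), 30, TRUE),
                    ch_flag = sample(c(TRUE, FALSE), 30, TRUE))
  v <- venn_counts(cls)
  # exhaustive set-algebra oracle
  sets <- with(cls, list(AS = orf_id[as_flag], TM = orf_id[tm_flag],
                         CH = orf_id[ch_flag]))
  expect_equal(sum(v$regions), length(unique(unlist(sets))) +
                 sum(!cls$as_flag & !cls$tm_flag & !cls$ch_flag) * 0)
  expect_equal(unname(v$regions["AS_TM_CH"]),
               length(Reduce(intersect, sets)))
  expect_equal(v$n_AS, length(sets$AS))
  expect_equal(unname(v$regions["AS_only"]),
               length(setdiff(sets$AS, union(sets$TM, sets$CH))))
  expect_equal(unname(v$regions["AS_TM"]),
               length(setdiff(intersect(sets$AS, sets$TM), sets$CH)))
  # marginal reconstruction from the four covering regions
  expect_equal(v$n_AS, sum(v$regions[c("AS_only", "AS_TM", "AS_CH", "AS_TM_CH")]))
  expect_equal(v$n_CH, sum(v$regions[c("CH_only", "AS_CH", "TM_CH", "AS_TM_CH")]))
})

test_that("candidate ranking follows the evidence tiers and tie-breaks", {
  set.seed(64)
  n <- 20
  cls <- data.frame(orf_id = sprintf("orf%03d", sample(100:400, n)),
                    as_flag = sample(c(TRUE, FALSE), n, TRUE, prob = c(.8, .2)),
                    tm_flag = sample(c(TRUE, FALSE), n, TRUE),
                    ch_flag = sample(c(TRUE, FALSE), n, TRUE),
                    nearest_gene = "x",
                    gap_bp = sample(0:400, n, TRUE),
                    overlap_bp = sample(0:60, n, TRUE),
                    neighbor_side = "upstream")
  r <- rank_candidates(cls)
  expect_true(all(r$as_flag))
  tier <- function(row) {
    if (row$tm_flag && row$ch_flag) 1 else if (row$ch_flag) 2
    else if (row$tm_flag) 3 else 4
  }
  key <- lapply(seq_len(nrow(r)), function(i) r[i, ])
  ord <- order(vapply(key, tier, numeric(1)), -r$overlap_bp, r$gap_bp, r$orf_id)
  expect_equal(ord, seq_len(nrow(r)))  # already sorted by the oracle key
  expect_equal(nrow(rank_candidates(cls[0, ])), 0L)
})

test_that("the fixture pair ranks the chimeric TM candidate first", {
  fx <- make_orf116b_fixture()
  scr <- run_screen(fx$cms, fx$maintainer)
  cand <- scr$candidates
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$orf_id[1], "orf116")
  expect_true(cand$tm_flag[1] && cand$ch_flag[1])
  expect_equal(cand$overlap_bp[1], 41L)
  expect_equal(cand$orf_id[2], "orf103")
  expect_false(cand$ch_flag[2])
})
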