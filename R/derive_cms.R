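# Derivation of the CMS genome from a generated maintainer: neutral
# spacer-segment translocations plus insertion of novel-ORF cassettes,
# with a machine-readable truth table of every planted property.

# ---- sequence-edit engine -------------------------------------------------
# state: list(seq, ann, orf_iv = list of tracked circ-interval-like lists)

edit_insert <- function(state, pos, str) {
  L0 <- nchar(state$seq)
  stopifnot(pos >= 0, pos <= L0)
  n <- nchar(str)
  state$seq <- paste0(substr(state$seq, 1L, pos), str,
                      substr(state$seq, pos + 1L, L0))
  shift <- function(s, e) {
    if (s < pos && e > pos) stop("internal: insertion inside a feature")
    if (s >= pos) c(s + n, e + n) else c(s, e)
  }
  state$ann$exons <- lapply(state$ann$exons, function(ex) {
    for (j in seq_len(nrow(ex))) {
      se <- shift(ex$start[j], ex$end[j])
      ex$start[j] <- se[1]; ex$end[j] <- se[2]
    }
    ex
  })
  state$orf_iv <- lapply(state$orf_iv, function(iv) {
    se <- shift(iv$start, iv$end)
    iv$start <- se[1]; iv$end <- se[2]
    iv
  })
  state
}

edit_delete <- function(state, from, len) {
  L0 <- nchar(state$seq)
  to <- from + len
  stopifnot(from >= 0, to <= L0)
  hits <- function(s, e) s < to && e > from
  for (ex in state$ann$exons) for (j in seq_len(nrow(ex)))
    if (hits(ex$start[j], ex$end[j])) stop("internal: deletion hits a feature")
  for (iv in state$orf_iv)
    if (hits(iv$start, iv$end)) stop("internal: deletion hits a planted ORF")
  state$seq <- paste0(substr(state$seq, 1L, from),
                      substr(state$seq, to + 1L, L0))
  shift <- function(s, e) if (s >= to) c(s - len, e - len) else c(s, e)
  state$ann$exons <- lapply(state$ann$exons, function(ex) {
    for (j in seq_len(nrow(ex))) {
      se <- shift(ex$start[j], ex$end[j])
      ex$start[j] <- se[1]; ex$end[j] <- se[2]
    }
    ex
  })
  state$orf_iv <- lapply(state$orf_iv, function(iv) {
    se <- shift(iv$start, iv$end)
    iv$start <- se[1]; iv$end <- se[2]
    iv
  })
  state
}

# Intergenic spacers of the current state, as 0-based [start, end) rows in
# genomic order (head and tail regions included as separate linear runs).
spacer_table <- function(state) {
  L <- nchar(state$seq)
  spans <- t(vapply(state$ann$exons, function(ex)
    c(min(ex$start), max(ex$end)), numeric(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  starts <- c(0, spans[, 2])
  ends <- c(spans[, 1], L)
  data.frame(start = starts, end = ends, len = ends - starts)[ends - starts > 0, ]
}

gene_start0 <- function(state, gene) {
  i <- match(gene, state$ann$name)
  min(state$ann$exons[[i]]$start)
}

# ---- planted ORF construction --------------------------------------------

# ORF nucleotides for a free-standing (gap/none) planted ORF.
build_free_orf <- function(aa_len, tm, gc_target) {
  n_res <- aa_len
  res_cod <- character(n_res - 1L)  # residues 2..aa_len
  if (tm) {
    run_start <- sample(10:(n_res - 30L), 1L)  # residue index of 21-aa run
    body_idx <- setdiff(seq_len(n_res - 1L), (run_start - 1L):(run_start + 19L))
    res_cod[(run_start - 1L):(run_start + 19L)] <-
      sample_codons(21L, gc_target, HYDROPHOBIC_RES)
    res_cod[body_idx] <- sample_codons(length(body_idx), gc_target,
                                       HYDROPHILIC_RES)
    res_cod <- salt_frames(res_cod, skip = (run_start - 1L):(run_start + 19L))
  } else {
    res_cod[] <- sample_codons(n_res - 1L, gc_target, HYDROPHILIC_RES)
    res_cod <- salt_frames(res_cod)
  }
  paste(c("ATG", res_cod, "TAA"), collapse = "")
}

# Body of an ORF docked onto a conserved-gene prefix: the ORF's last
# `o` bases are the gene's first `o` bases (made dockable at generation
# time), so only the first n - o bases are built here. The body ends with
# a TAA in the *gene's* frame immediately before the gene start, so the
# gene's own ORF still begins at its annotated start codon.
build_docked_body <- function(aa_len, o, gene_seq, gc_target) {
  n <- 3L * (aa_len + 1L)
  nb <- n - o
  stopifnot(nb %% 3L != 0L, nb > 40L)
  K <- nb %/% 3L          # fully free codons
  r <- nb - 3L * K        # free bases of the mixed codon (1 or 2)
  res_cod <- character(K - 1L)  # codons 2..K
  run_start <- sample(5:(K - 25L), 1L)
  res_cod[(run_start - 1L):(run_start + 19L)] <-
    sample_codons(21L, gc_target, HYDROPHOBIC_RES)
  free <- setdiff(seq_len(K - 1L), (run_start - 1L):(run_start + 19L))
  res_cod[free] <- sample_codons(length(free), gc_target, HYDROPHILIC_RES)
  res_cod <- salt_frames(res_cod, skip = (run_start - 1L):(run_start + 19L))
  body <- paste(c("ATG", res_cod), collapse = "")
  # mixed codon: r free bases completed by the gene's first 3 - r bases
  gpre <- substr(gene_seq, 1L, 3L - r)
  repeat {
    fb <- paste(sample(c("A", "C", "G", "T"), r, replace = TRUE), collapse = "")
    if (!(paste0(fb, gpre) %in% STOP_CODONS)) break
  }
  body <- paste0(body, fb)
  stopifnot(nchar(body) == nb)
  # gene-frame TAA guard at body positions nb-2..nb (never a stop in the
  # ORF frame: the overwritten patterns are x-y-T / x-T-A plus an A-led
  # codon)
  body <- force_cross_frame_stop(body, nb)
  # the overwrite may have clipped the mixed codon; recheck it is not a
  # stop in the ORF frame
  mixed <- paste0(substr(body, 3L * K + 1L, nb), gpre)
  stopifnot(!(mixed %in% STOP_CODONS))
  body
}

# ---- derivation -----------------------------------------------------------

#' Derive a CMS mitogenome from a synthetic maintainer
#'
#' Applies seeded rearrangements to a [generate_maintainer()] genome:
#' neutral translocations of intergenic segments, plus insertion of novel
#' ORF cassettes that are absent from the maintainer. Each cassette is
#' flanked by all-frame stop insulators so rearrangement junctions cannot
#' create unplanned reading frames; chimeric cassettes either overlap a
#' conserved gene's 5' end by the planted number of bases (sharing
#' sequence with the untouched gene prefix) or end a planted distance
#' short of one. Conserved CDS sequence is never mutated. The derivation
#' verifies itself against the actual ORF caller: the CMS-specific ORF
#' set must equal the planted set at the planted coordinates, with the
#' planted TM status.
#'
#' @param maintainer result of [generate_maintainer()].
#' @param config the same [generator_config()].
#' @return A list: `genome`, `ann` (conserved genes plus planted ORF
#'   features), and `truth`, a data frame with one row per planted ORF
#'   (`orf_id`, coordinates, `aa_length`, `as_expected`, `tm_expected`,
#'   `ch_expected`, `event_type`, `neighbor`, `planted_gap_bp`,
#'   `planted_overlap_bp`).
#' @export
derive_cms <- function(maintainer, config) {
  plan <- plan_events(config)
  tab <- conserved_gene_table()
  for (attempt in seq_len(5L)) {
    set.seed(config$seed + 1L + 1000L * (attempt - 1L))
    out <- try(derive_once(maintainer, config, plan, tab), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("derive_cms failed verification after 5 attempts: ",
       attr(out, "condition")$message)
}

derive_once <- function(maintainer, config, plan, tab) {
  G2 <- DUAL_GUARD
  nG <- nchar(G2)
  L0 <- maintainer$genome$length
  state <- list(seq = maintainer$genome$seq, ann = maintainer$ann,
                orf_iv = list())
  sp0 <- spacer_table(state)
  # background ORFs of the maintainer: no engineered junction may fall
  # strictly inside one, otherwise its truncation remainder would surface
  # as an unplanned line-specific ORF
  ko <- find_orfs(maintainer$genome, min_aa = config$min_aa)
  inside_ko <- function(x) {
    if (!nrow(ko)) return(FALSE)
    any(ifelse(ko$wraps, x > ko$start | x < ko$end,
               x > ko$start & x < ko$end))
  }
  zones <- list()
  zone_free <- function(a, b) {
    for (z in zones) if (a <= z[2] && z[1] <= b) return(FALSE)
    TRUE
  }
  claim_zone <- function(a, b) zones[[length(zones) + 1L]] <<- c(a, b)
  ops <- list()   # list(pos, del_len, ins, orf_rel, orf_len, event)
  push_op <- function(pos, del_len, ins, orf_rel = NA, orf_len = NA,
                      event = NA)
    ops[[length(ops) + 1L]] <<- list(pos = pos, del_len = del_len, ins = ins,
                                     orf_rel = orf_rel, orf_len = orf_len,
                                     event = event)
  gspan <- function(name) {
    i <- match(name, state$ann$name)
    ex <- state$ann$exons[[i]]
    c(min(ex$start), max(ex$end))
  }
  upstream_spacer <- function(gs) {
    row <- sp0[sp0$end == gs, , drop = FALSE]
    if (!nrow(row)) NULL else row[1L, ]
  }

  # 1. neutral spacer translocations (all positions in maintainer coords)
  trans_sp <- sp0[sp0$len >= 1500, , drop = FALSE]
  if (config$n_translocations > 0 && nrow(trans_sp) >= 2L) {
    for (k in seq_len(config$n_translocations)) {
      pick <- sample.int(nrow(trans_sp), 2L)
      donor <- trans_sp[pick[1L], ]
      tgt <- trans_sp[pick[2L], ]
      seg_len <- floor(donor$len / 4)
      placed <- FALSE
      for (off in c(0L, 41L, -41L, 83L, -83L, 127L, -127L)) {
        d1 <- donor$start + floor((donor$len - seg_len) / 2) + off
        d2 <- d1 + seg_len
        t1 <- tgt$start + floor(tgt$len / 2) + off
        if (d1 <= donor$start || d2 >= donor$end) next
        if (t1 <= tgt$start || t1 >= tgt$end) next
        if (inside_ko(d1) || inside_ko(d2) || inside_ko(t1)) next
        if (!zone_free(d1 - 1L, d2 + 1L) || !zone_free(t1 - 1L, t1 + 1L)) next
        seg <- substr(state$seq, d1 + 1L, d2)
        push_op(d1, seg_len, G2)
        push_op(t1, 0L, paste0(G2, seg, G2))
        claim_zone(d1 - 1L, d2 + 1L)
        claim_zone(t1 - 1L, t1 + 1L)
        placed <- TRUE
        break
      }
      if (!placed) next
    }
  }

  # 2. planted cassettes
  events <- plan
  truth_rows <- vector("list", nrow(events))
  other_genes <- sample(setdiff(tab$name[tab$introns == 0], events$anchor))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    n <- 3L * (ev$aa_len + 1L)
    if (ev$type == "overlap") {
      gs <- gspan(ev$anchor)[1L]
      ge <- gspan(ev$anchor)[2L]
      if (inside_ko(gs)) stop("gene start blocked by a background ORF")
      if (!zone_free(gs - 1L, ge + 1L)) stop("overlap anchor zone taken")
      o <- ev$overlap_bp
      gene_seq <- substr(state$seq, gs + 1L,
                         gs + tab$cds_len[match(ev$anchor, tab$name)])
      body <- build_docked_body(ev$aa_len, o, gene_seq, config$gc_target)
      cassette <- paste0(G2, "TAA", body)
      push_op(gs, 0L, cassette, orf_rel = nG + 3L, orf_len = n, event = i)
      claim_zone(gs - 1L, ge + 1L)
      anchor_used <- ev$anchor
      planted_gap <- 0L; planted_ov <- o
    } else if (ev$type == "gap") {
      g <- ev$gap_bp
      orf_nt <- build_free_orf(ev$aa_len, ev$tm, config$gc_target)
      cassette <- if (g >= nG) paste0(G2, "TAA", orf_nt, G2)
                  else paste0(G2, "TAA", orf_nt)
      placed <- FALSE
      for (anchor in c(ev$anchor, other_genes)) {
        gs <- gspan(anchor)[1L]
        p <- if (g >= nG) gs + nG - g else gs - g
        row <- upstream_spacer(gs)
        if (is.null(row)) next
        if (p - row$start <= max(g, config$ch_window)) next
        if (inside_ko(p)) next
        if (!zone_free(p - 1L, gs + 1L)) next
        push_op(p, 0L, cassette, orf_rel = nG + 3L, orf_len = n, event = i)
        claim_zone(p - 1L, gs + 1L)
        placed <- TRUE
        anchor_used <- anchor
        break
      }
      if (!placed) stop("no anchor with clearance for a gap event")
      planted_gap <- g; planted_ov <- 0L
    } else {
      orf_nt <- build_free_orf(ev$aa_len, ev$tm, config$gc_target)
      cassette <- paste0(G2, "TAA", orf_nt, G2)
      nc <- nchar(cassette)
      placed <- FALSE
      for (anchor in c(ev$anchor, other_genes)) {
        gs <- gspan(anchor)[1L]
        row <- upstream_spacer(gs)
        if (is.null(row)) next
        mid <- row$start + floor((row$len - nc) / 2)
        for (off in c(0L, 101L, -101L, 203L, -203L)) {
          p <- mid + off
          clear <- min(p - row$start, row$end - (p + nc))
          if (clear <= config$ch_window) next
          if (inside_ko(p)) next
          if (!zone_free(p - 1L, p + nc + 1L)) next
          push_op(p, 0L, cassette, orf_rel = nG + 3L, orf_len = n, event = i)
          claim_zone(p - config$ch_window, p + nc + config$ch_window)
          placed <- TRUE
          anchor_used <- anchor
          break
        }
        if (placed) break
      }
      if (!placed) stop("no spacer with clearance for a non-chimeric event")
      planted_gap <- NA_integer_; planted_ov <- 0L
    }
    truth_rows[[i]] <- data.frame(
      event = ev$event, aa_length = ev$aa_len,
      as_expected = TRUE, tm_expected = ev$tm,
      ch_expected = ev$type == "overlap" ||
        (ev$type == "gap" && ev$gap_bp <= config$ch_window),
      event_type = ev$type, neighbor = anchor_used,
      planted_gap_bp = planted_gap, planted_overlap_bp = planted_ov,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)

  # 3. apply the edits from the highest position down, so every remaining
  # position stays valid in the original coordinate system; the edit
  # engine shifts annotations and already-placed ORF intervals
  ord <- order(vapply(ops, `[[`, numeric(1), "pos"), decreasing = TRUE)
  ev_iv <- vector("list", nrow(events))
  for (oi in ord) {
    op <- ops[[oi]]
    if (op$del_len > 0L) state <- edit_delete(state, op$pos, op$del_len)
    state <- edit_insert(state, op$pos, op$ins)
    if (!is.na(op$event)) {
      orf_start <- op$pos + op$orf_rel
      state$orf_iv <- c(state$orf_iv,
                        list(list(start = orf_start,
                                  end = orf_start + op$orf_len,
                                  event = op$event)))
    }
  }
  for (iv in state$orf_iv) ev_iv[[iv$event]] <- iv
  genome <- new_circular_genome(sprintf("synthetic_cms_seed%d", config$seed),
                                state$seq)

  # 4. verification against the real pipeline
  orfs_cms <- find_orfs(genome, min_aa = config$min_aa)
  as_ids <- find_specific_orfs(orfs_cms, ko, mode = "exact")
  planted_key <- vapply(ev_iv, function(iv)
    paste(iv$start, iv$end, sep = ":"), character(1))
  called <- orfs_cms[match(planted_key,
                           paste(orfs_cms$start, orfs_cms$end, sep = ":")), ]
  if (anyNA(called$id))
    stop("a planted ORF was not recovered at its coordinates")
  if (!setequal(as_ids, called$id))
    stop("CMS-specific ORF set differs from the planted set (unplanned: ",
         paste(setdiff(as_ids, called$id), collapse = ","),
         "; missing: ", paste(setdiff(called$id, as_ids), collapse = ","), ")")
  tm_called <- vapply(called$protein, is_tm_orf, logical(1))
  if (!is.null(truth) && !identical(unname(tm_called), truth$tm_expected))
    stop("planted TM status not reproduced")
  if (!is.null(truth)) {
    truth <- cbind(data.frame(orf_id = called$id,
                              start = called$start, end = called$end,
                              wraps = called$wraps, strand = called$strand,
                              stringsAsFactors = FALSE),
                   truth)
  } else {
    truth <- data.frame(orf_id = character(), start = integer(),
                        end = integer(), wraps = logical(),
                        strand = character(), event = integer(),
                        aa_length = integer(), as_expected = logical(),
                        tm_expected = logical(), ch_expected = logical(),
                        event_type = character(), neighbor = character(),
                        planted_gap_bp = integer(),
                        planted_overlap_bp = integer())
    if (length(as_ids)) stop("unplanned CMS-specific ORFs present")
  }
  ann <- state$ann
  if (nrow(truth)) {
    orf_ann <- mt_annotation(truth$orf_id, rep("ORF", nrow(truth)),
                             truth$strand, rep("ATG", nrow(truth)),
                             rep(1L, nrow(truth)),
                             lapply(seq_len(nrow(truth)), function(j)
                               data.frame(start = truth$start[j],
                                          end = truth$end[j],
                                          wraps = truth$wraps[j])))
    ann <- rbind(ann, orf_ann)
    class(ann) <- c("mt_annotation", "data.frame")
  }
  list(genome = genome, ann = ann, truth = truth)
}

#' Generate a maintainer/CMS genome pair with truth table
#'
#' @param config a [generator_config()].
#' @return A list: `maintainer` (genome + ann), `cms` (genome + ann +
#'   truth), `truth`, `config`.
#' @export
simulate_pair <- function(config = generator_config()) {
  maintainer <- generate_maintainer(config)
  cms <- derive_cms(maintainer, config)
  list(maintainer = maintainer, cms = cms, truth = cms$truth,
       config = config)
}

#' Write a simulated pair to disk
#'
#' Emits FASTA and GFF3 for both genomes, the truth table as TSV, and a
#' JSON echo of the configuration. All outputs are deterministic.
#'
#' @param sim a [simulate_pair()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$maintainer$genome, file.path(dir, "maintainer.fasta"))
  write_annotations(sim$maintainer$ann, sim$maintainer$genome,
                    file.path(dir, "maintainer.gff3"))
  write_genome(sim$cms$genome, file.path(dir, "cms.fasta"))
  write_annotations(sim$cms$ann, sim$cms$genome, file.path(dir, "cms.gff3"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
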