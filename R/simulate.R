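# Synthetic three-species benchmark. The generator states a small but
# complete world: a rat-like reference genome, mouse- and human-like genomes
# derived from it by a block-evolution walk (retained alignment blocks,
# junction insertions, point substitutions), CpG methylomes for three
# tissues with planted tissue-specific hypomethylated windows, pairwise
# chain files that are three-way consistent by construction, conserved
# elements and conservation-score tracks coupled to the planted epigenetic
# conservation, histone peaks whose summits fall in conserved regions at a
# configured rate, and planted motif instances with conserved / turnover /
# loss / gain fates. Every planted fact is recorded in a truth table so
# each pipeline stage can be scored.

BASES <- c("A", "C", "G", "T")

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Configuration for the synthetic three-species trio
#'
#' Defaults are the generator's stated world: a desk-scale trio (2 contigs
#' of 1 Mb per species), mammalian-like CpG density (~1 per 100 bp, with
#' CpG-enriched DMR windows), 300 planted tsDMRs per tissue, 30% of mouse
#' orthologs and 15% of human orthologs epigenetically conserved, 90%
#' orthology retention, bimodal methylation (hypomethylated mean 0.1,
#' intermediate 0.5, hypermethylated 0.85, sd 0.05), motif planting enriched
#' in EC regions, and conserved-element / peak / score couplings that
#' reproduce the EC-vs-ENC contrasts qualitatively.
#'
#' @param seed mandatory RNG seed; the bundle is a pure function of the
#'   configuration.
#' @param ... overrides for any default listed above (see the source for
#'   the full field list).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed, ...) {
  cfg <- list(
    seed = seed,
    n_contigs = 2L, contig_length = 1000000L,
    cpg_rate = 0.01, block_mean = 1000, indel_rate = 0.2, indel_mean = 50,
    substitution_rate = 0.01,
    tissues = c("blood", "brain", "sperm"),
    n_dmrs = 300L, dmr_length = 500L,
    p_ec_mouse = 0.3, p_ec_human = 0.15, p_ortholog_retained = 0.9,
    rearrangement_rate = 0,
    hypo_mean = 0.1, intermediate_mean = 0.5, hyper_mean = 0.85,
    level_sd = 0.05, intermediate_fraction = 0.1,
    motifs = c(Erg = "ACAGGAAGTG", Fli1 = "TCAGGAAGCC", Lhx3 = "CTAATTAATT"),
    p_motif_in_ec = 0.8, p_motif_in_enc = 0.1,
    p_turnover_given_motif = 0.2, p_loss_given_motif = 0.2,
    p_motif_gain = 0.05,
    element_overlap_rate_ec = 0.6, element_overlap_rate_enc = 0.2,
    peak_rate_ec = 0.5, peak_rate_enc = 0.1,
    score_coupling = 2,
    n_genes_per_contig = 15L, n_cgi_per_contig = 20L,
    n_repeats_per_contig = 40L, n_bg_elements_per_contig = 50L,
    n_bg_peaks_per_contig = 50L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg[names(dots)] <- dots
  probs <- cfg[grep("^p_|_rate$|fraction$", names(cfg))]
  probs$cpg_rate <- NULL; probs$substitution_rate <- NULL
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  if (is.null(cfg$seed)) stop("seed is mandatory")
  class(cfg) <- "simulation_config"
  cfg
}

# vectorized point substitution: each selected base becomes one of the
# other three uniformly
mutate_bases <- function(seq, rate) {
  mut <- which(stats::runif(length(seq)) < rate)
  if (!length(mut)) return(seq)
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3)
  seq[mut] <- alt[cbind(sample.int(3, length(mut), TRUE),
                        match(seq[mut], BASES))]
  seq
}

rand_intervals <- function(n, clen, min_len, max_len, chrom) {
  len <- sample(min_len:max_len, n, TRUE)
  start <- vapply(len, function(l) sample.int(clen - l, 1) - 1L, integer(1))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

make_sim_chain <- function(id, tName, tSize, qName, qSize,
                           t_starts, q_starts, lens) {
  n <- length(lens)
  dt <- c(t_starts[-1] - (t_starts[-n] + lens[-n]), 0L)
  dq <- c(q_starts[-1] - (q_starts[-n] + lens[-n]), 0L)
  h <- list(score = sum(lens) * 100, tName = tName, tSize = tSize,
            tStrand = "+", tStart = t_starts[1], tEnd = t_starts[n] + lens[n],
            qName = qName, qSize = qSize, qStrand = "+",
            qStart = q_starts[1], qEnd = q_starts[n] + lens[n],
            id = as.character(id))
  new_chain(h, data.frame(size = as.integer(lens), dt = as.integer(dt),
                          dq = as.integer(dq)))
}

# first base that does NOT satisfy the IUPAC class of the consensus's
# first position; writing it destroys the motif
iupac_breaker <- function(consensus) {
  classes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A","G"),
                  Y = c("C","T"), S = c("C","G"), W = c("A","T"),
                  K = c("G","T"), M = c("A","C"), B = c("C","G","T"),
                  D = c("A","G","T"), H = c("A","C","T"), V = c("A","C","G"),
                  N = BASES)
  first <- substr(consensus, 1, 1)
  cand <- setdiff(BASES, classes[[first]])
  if (!length(cand)) stop("cannot break an all-N consensus")
  cand[1]
}

#' Generate the synthetic three-species benchmark
#'
#' Emits, under `out_dir`: per-species genome FASTA, per species x tissue
#' CpG-level bedGraphs, gene tables, CGI and repeat BEDs, rat conserved
#' elements, mouse/human fixed-step conservation-score wigs, mouse/human
#' peak files with summits (narrowPeak layout), the three pairwise chain
#' files, the motif list, and `truth.tsv`. Deterministic: the same
#' configuration (including seed) yields a byte-identical bundle.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a `trio_bundle`: list with `dir`, `files` (named
#'   paths), `truth` (data.frame), `genomes` (per-species `DNAStringSet`),
#'   and `config`.
#' @export
simulate_trio <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, sim_trio_impl(config, out_dir))
}

sim_trio_impl <- function(cfg, out_dir) {
  clen <- cfg$contig_length
  win <- cfg$dmr_length
  contigs <- paste0("chr", seq_len(cfg$n_contigs))
  tissues <- cfg$tissues
  files <- list()
  pth <- function(...) file.path(out_dir, paste0(...))

  ## reference (rat-like) sequences, CpG-scrubbed then CpG-planted
  rat <- list()
  for (ctg in contigs) {
    b <- sample(BASES, clen, TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
    i <- which(b[-clen] == "C" & b[-1] == "G")
    if (length(i)) b[i + 1L] <- "A"
    rat[[ctg]] <- b
  }

  ## planted DMR windows on the 500-bp grid
  wins <- tile_genome(stats::setNames(rep(clen, length(contigs)), contigs), win)
  n_dmr <- 3L * cfg$n_dmrs
  if (n_dmr > nrow(wins))
    stop("infeasible config: ", n_dmr, " DMRs exceed ", nrow(wins), " windows")
  pick <- sort(sample.int(nrow(wins), n_dmr))
  truth <- as.data.frame(wins[pick, ])
  truth$tissue <- sample(rep(tissues, cfg$n_dmrs))
  truth$criterion <- ifelse(stats::runif(n_dmr) < cfg$intermediate_fraction,
                            2L, 1L)

  ## CpGs: background at cpg_rate (even positions, hence non-adjacent),
  ## plus a fixed grid of 10 CpGs inside every DMR window
  cpg_offsets <- seq(25L, win - 25L, by = 50L)
  for (ctg in contigs) {
    k <- round(clen * cfg$cpg_rate)
    pos <- sort(sample.int(clen %/% 2L - 2L, k)) * 2L
    rat[[ctg]][pos + 1L] <- "C"; rat[[ctg]][pos + 2L] <- "G"
    tw <- truth[truth$chrom == ctg, ]
    if (nrow(tw)) {
      p <- rep(tw$start, each = length(cpg_offsets)) + cpg_offsets
      rat[[ctg]][p + 1L] <- "C"; rat[[ctg]][p + 2L] <- "G"
    }
  }

  ## segmentation into ancestral alignment blocks; cuts never fall inside
  ## a DMR window so each planted window lives in exactly one block
  segs <- list()
  for (ctg in contigs) {
    cuts <- 0
    while (cuts[length(cuts)] < clen)
      cuts <- c(cuts, cuts[length(cuts)] +
                  max(200, round(stats::rexp(1, 1 / cfg$block_mean))))
    cuts[length(cuts)] <- clen
    cuts <- unique(cuts)
    tw <- truth[truth$chrom == ctg, ]
    if (nrow(tw)) {
      bad <- vapply(cuts, function(x) any(x > tw$start & x < tw$end),
                    logical(1))
      bad[c(1, length(cuts))] <- FALSE
      cuts <- cuts[!bad]
    }
    segs[[ctg]] <- data.frame(start = as.integer(cuts[-length(cuts)]),
                              end = as.integer(cuts[-1]))
  }
  truth$segment <- NA_integer_
  for (ctg in contigs) {
    rows <- which(truth$chrom == ctg)
    truth$segment[rows] <- findInterval(truth$start[rows], segs[[ctg]]$start)
  }

  ## block retention: DMR blocks use the joint scheme so the three-way
  ## recovery rate estimates p_ortholog_retained directly
  ret <- list()
  for (ctg in contigs) {
    ns <- nrow(segs[[ctg]])
    rm_ <- stats::runif(ns) < cfg$p_ortholog_retained
    rh_ <- stats::runif(ns) < cfg$p_ortholog_retained
    for (s in unique(truth$segment[truth$chrom == ctg])) {
      if (stats::runif(1) < cfg$p_ortholog_retained) {
        rm_[s] <- TRUE; rh_[s] <- TRUE
      } else if (stats::runif(1) < 0.5) {
        rm_[s] <- FALSE; rh_[s] <- TRUE
      } else {
        rm_[s] <- TRUE; rh_[s] <- FALSE
      }
    }
    ret[[ctg]] <- data.frame(m = rm_, h = rh_)
  }

  ## derive mouse/human sequences: retained blocks with substitutions,
  ## junction insertions between blocks
  derive <- function(ctg, keep) {
    sg <- segs[[ctg]]; ns <- nrow(sg)
    ins <- as.integer(ifelse(stats::runif(ns) < cfg$indel_rate,
                             pmax(1, round(stats::rexp(ns, 1 / cfg$indel_mean))),
                             0))
    ins[ns] <- 0L
    pieces <- vector("list", 2L * ns)
    xs <- rep(NA_integer_, ns)
    cur <- 0L
    for (s in seq_len(ns)) {
      if (keep[s]) {
        sq <- mutate_bases(rat[[ctg]][(sg$start[s] + 1L):sg$end[s]],
                           cfg$substitution_rate)
        xs[s] <- cur; cur <- cur + length(sq)
        pieces[[2L * s - 1L]] <- sq
      }
      if (ins[s] > 0L) {
        pieces[[2L * s]] <- sample(BASES, ins[s], TRUE)
        cur <- cur + ins[s]
      }
    }
    list(seq = unlist(pieces), x_start = xs, len = as.integer(cur))
  }
  mouse <- lapply(contigs, function(ctg) derive(ctg, ret[[ctg]]$m))
  human <- lapply(contigs, function(ctg) derive(ctg, ret[[ctg]]$h))
  names(mouse) <- names(human) <- contigs

  ## truth coordinates in the derived species
  xcoord <- function(sp, rows) {
    out <- matrix(NA_integer_, length(rows), 2)
    for (k in seq_along(rows)) {
      i <- rows[k]; ctg <- truth$chrom[i]; s <- truth$segment[i]
      xs <- sp[[ctg]]$x_start[s]
      if (!is.na(xs)) {
        st <- xs + (truth$start[i] - segs[[ctg]]$start[s])
        out[k, ] <- c(st, st + win)
      }
    }
    out
  }
  rows <- seq_len(n_dmr)
  mcoords <- xcoord(mouse, rows); hcoords <- xcoord(human, rows)
  truth$retained_mouse <- !is.na(mcoords[, 1])
  truth$retained_human <- !is.na(hcoords[, 1])
  truth$mouse_start <- mcoords[, 1]; truth$mouse_end <- mcoords[, 2]
  truth$human_start <- hcoords[, 1]; truth$human_end <- hcoords[, 2]
  ## epigenetic conservation: a standard-normal latent conservation score
  ## per window drives EC through a logistic with slope score_coupling,
  ## with the intercept calibrated so the marginal EC rate equals p_ec;
  ## the same latent is written into the species' score track, giving the
  ## graded EC-vs-score dependence the score-bin curve measures
  for (sp in c("mouse", "human")) {
    z <- stats::rnorm(n_dmr)
    a <- logistic_intercept(cfg[[paste0("p_ec_", sp)]], cfg$score_coupling)
    truth[[paste0("score_latent_", sp)]] <- z
    truth[[paste0("ec_", sp)]] <- ifelse(
      truth[[paste0("retained_", sp)]],
      stats::runif(n_dmr) < stats::plogis(a + cfg$score_coupling * z), NA)
  }

  ## rearrangements: selected DMR blocks are removed from the mouse-human
  ## chain and mapped by a decoy chain to an unrelated human location, so
  ## the composed path disagrees with the direct one
  rearr_seg <- list()
  truth$rearranged <- FALSE
  if (cfg$rearrangement_rate > 0) {
    cand <- which(truth$retained_mouse & truth$retained_human)
    hit <- cand[stats::runif(length(cand)) < cfg$rearrangement_rate]
    # a rearrangement moves a whole block, so every DMR sharing the block
    # is rearranged with it
    seg_key <- paste(truth$chrom, truth$segment)
    truth$rearranged <- seg_key %in% seg_key[hit]
    hit <- which(truth$rearranged)
    rearr_seg <- lapply(split(truth$segment[hit], truth$chrom[hit]), unique)
  }

  ## motif planting with per-species fates
  motif_models <- lapply(names(cfg$motifs), function(nm)
    motif_model(nm, consensus = cfg$motifs[[nm]]))
  names(motif_models) <- names(cfg$motifs)
  slots <- seq(28L, win - 22L, by = 50L)
  truth$motif <- NA_character_
  truth$fate_mouse <- ifelse(truth$retained_mouse, "none", NA_character_)
  truth$fate_human <- ifelse(truth$retained_human, "none", NA_character_)
  write_at <- function(seqs, ctg, pos, txt) {
    seqs[[ctg]][(pos + 1L):(pos + nchar(txt))] <-
      strsplit(txt, "")[[1]]
    seqs
  }
  mouse_seq <- lapply(mouse, `[[`, "seq")
  human_seq <- lapply(human, `[[`, "seq")
  for (i in rows) {
    ec_label <- isTRUE(truth$ec_mouse[i])
    p_have <- if (ec_label) cfg$p_motif_in_ec else cfg$p_motif_in_enc
    ctg <- truth$chrom[i]
    nm <- sample(names(cfg$motifs), 1)
    cons <- cfg$motifs[[nm]]
    broken <- paste0(iupac_breaker(cons), substr(cons, 2, nchar(cons)))
    slot <- sample(slots, 1)
    if (stats::runif(1) < p_have) {
      truth$motif[i] <- nm
      rat <- write_at(rat, ctg, truth$start[i] + slot, cons)
      for (sp in c("mouse", "human")) {
        if (!truth[[paste0("retained_", sp)]][i]) next
        xst <- truth[[paste0(sp, "_start")]][i]
        sseq <- if (sp == "mouse") mouse_seq else human_seq
        u <- stats::runif(1)
        fate <- if (u < cfg$p_turnover_given_motif) "turnover"
        else if (u < cfg$p_turnover_given_motif + cfg$p_loss_given_motif) "loss"
        else "conserved"
        if (fate == "conserved") {
          sseq <- write_at(sseq, ctg, xst + slot, cons)
        } else if (fate == "loss") {
          sseq <- write_at(sseq, ctg, xst + slot, broken)
        } else {
          sseq <- write_at(sseq, ctg, xst + slot, broken)
          alt <- sample(setdiff(slots, slot), 1)
          sseq <- write_at(sseq, ctg, xst + alt, cons)
        }
        truth[[paste0("fate_", sp)]][i] <- fate
        if (sp == "mouse") mouse_seq <- sseq else human_seq <- sseq
      }
    } else if (stats::runif(1) < cfg$p_motif_gain) {
      truth$motif[i] <- nm
      for (sp in c("mouse", "human")) {
        if (!truth[[paste0("retained_", sp)]][i]) next
        xst <- truth[[paste0(sp, "_start")]][i]
        sseq <- if (sp == "mouse") mouse_seq else human_seq
        sseq <- write_at(sseq, ctg, xst + slot, cons)
        truth[[paste0("fate_", sp)]][i] <- "gain"
        if (sp == "mouse") mouse_seq <- sseq else human_seq <- sseq
      }
    }
  }

  ## assemble genomes
  genomes <- list(
    rat = Biostrings::DNAStringSet(vapply(rat, paste, "", collapse = "")),
    mouse = Biostrings::DNAStringSet(vapply(mouse_seq, paste, "", collapse = "")),
    human = Biostrings::DNAStringSet(vapply(human_seq, paste, "", collapse = "")))
  for (sp in names(genomes)) {
    files[[paste0(sp, ".fa")]] <- pth(sp, ".fa")
    Biostrings::writeXStringSet(genomes[[sp]], files[[paste0(sp, ".fa")]],
                                width = 80L)
  }

  ## methylomes: per-CpG clipped-normal levels around the tissue-state
  ## means; DMR windows (and their EC images) carry the planted pattern
  cpg_positions <- function(g)
    lapply(stats::setNames(names(g), names(g)), function(ctg)
      Biostrings::start(Biostrings::matchPattern("CG", g[[ctg]])) - 1L)
  sp_coords <- list(
    rat = list(start = truth$start, keep = rep(TRUE, n_dmr),
               ec = rep(TRUE, n_dmr)),
    mouse = list(start = truth$mouse_start, keep = truth$retained_mouse,
                 ec = isTRUE_v(truth$ec_mouse)),
    human = list(start = truth$human_start, keep = truth$retained_human,
                 ec = isTRUE_v(truth$ec_human)))
  for (sp in names(genomes)) {
    cpg <- cpg_positions(genomes[[sp]])
    crd <- sp_coords[[sp]]
    for (tis in tissues) {
      sites <- list()
      for (ctg in contigs) {
        pos <- cpg[[ctg]]
        lv <- clip01(stats::rnorm(length(pos), cfg$hyper_mean, cfg$level_sd))
        sel <- which(truth$chrom == ctg & crd$keep & crd$ec)
        for (i in sel) {
          ws <- crd$start[i]
          lo <- findInterval(ws - 1L, pos)         # pos sorted: CpGs < ws
          hi <- findInterval(ws + win - 1L, pos)   # CpGs < ws + win
          if (hi <= lo) next
          idx <- (lo + 1L):hi
          mu <- if (truth$tissue[i] == tis) {
            if (truth$criterion[i] == 2L) cfg$intermediate_mean else cfg$hypo_mean
          } else cfg$hyper_mean
          lv[idx] <- clip01(stats::rnorm(length(idx), mu, cfg$level_sd))
        }
        sites[[ctg]] <- data.frame(chrom = ctg, pos = pos, level = lv,
                                   stringsAsFactors = FALSE)
      }
      track <- methylome_track(do.call(rbind, sites), sp, tis)
      f <- paste0(sp, "_", tis, ".bedGraph")
      files[[f]] <- pth(f)
      write_methylome(track, files[[f]])
    }
  }

  ## chains (one per contig per pair, plus decoys for rearranged blocks)
  chain_files <- list(c("rat", "mouse"), c("rat", "human"),
                      c("mouse", "human"))
  sp_len <- list(rat = stats::setNames(rep(clen, length(contigs)), contigs),
                 mouse = stats::setNames(vapply(mouse, `[[`, 0L, "len"), contigs),
                 human = stats::setNames(vapply(human, `[[`, 0L, "len"), contigs))
  sp_xs <- list(rat = lapply(stats::setNames(contigs, contigs),
                             function(ctg) segs[[ctg]]$start),
                mouse = lapply(mouse, `[[`, "x_start"),
                human = lapply(human, `[[`, "x_start"))
  for (pair in chain_files) {
    a <- pair[1]; b <- pair[2]
    chains <- list(); id <- 0L
    for (ctg in contigs) {
      keep <- !is.na(sp_xs[[a]][[ctg]]) & !is.na(sp_xs[[b]][[ctg]])
      drop_seg <- if (a == "mouse" && b == "human") rearr_seg[[ctg]] else NULL
      main_keep <- keep
      if (!is.null(drop_seg)) main_keep[drop_seg] <- FALSE
      lens <- segs[[ctg]]$end - segs[[ctg]]$start
      if (any(main_keep)) {
        id <- id + 1L
        chains[[length(chains) + 1L]] <- make_sim_chain(
          id, ctg, sp_len[[a]][[ctg]], ctg, sp_len[[b]][[ctg]],
          sp_xs[[a]][[ctg]][main_keep], sp_xs[[b]][[ctg]][main_keep],
          lens[main_keep])
        main_score <- chains[[length(chains)]]$score
      } else main_score <- 0
      for (s in drop_seg[keep[drop_seg]]) {
        # decoy: map the mouse block to a shifted human location
        id <- id + 1L
        L <- lens[s]
        hlen <- sp_len[[b]][[ctg]]
        qs <- (sp_xs[[b]][[ctg]][s] + hlen %/% 2L) %% (hlen - L)
        ch <- make_sim_chain(id, ctg, sp_len[[a]][[ctg]], ctg, hlen,
                             sp_xs[[a]][[ctg]][s], qs, L)
        ch$score <- main_score + 1
        chains[[length(chains) + 1L]] <- ch
      }
    }
    f <- paste0(a, ".", b, ".chain")
    files[[f]] <- pth(f)
    write_chain(as_chain_set(chains), files[[f]])
  }

  ## conserved elements on the reference: a 250-bp core inside DMR windows
  ## at the EC/ENC-dependent rate, plus background elements clear of DMRs
  truth$genetic_conserved <- stats::runif(n_dmr) <
    ifelse(isTRUE_v(truth$ec_mouse), cfg$element_overlap_rate_ec,
           cfg$element_overlap_rate_enc)
  elements <- data.frame(chrom = truth$chrom[truth$genetic_conserved],
                         start = truth$start[truth$genetic_conserved] + 100L,
                         end = truth$start[truth$genetic_conserved] + 350L)
  for (ctg in contigs) {
    bg <- rand_intervals(cfg$n_bg_elements_per_contig, clen, 150L, 300L, ctg)
    tw <- truth[truth$chrom == ctg, ]
    ok <- !vapply(seq_len(nrow(bg)), function(k)
      any(bg$start[k] < tw$end & bg$end[k] > tw$start), logical(1))
    elements <- rbind(elements, bg[ok, ])
  }
  files[["rat.elements.bed"]] <- pth("rat.elements.bed")
  write_bed(elements[order(elements$chrom, elements$start), ],
            files[["rat.elements.bed"]])

  ## conservation-score wigs on mouse/human: 50-bp runs, base noise plus
  ## the window's latent conservation score over every retained DMR image
  for (sp in c("mouse", "human")) {
    crd <- sp_coords[[sp]]
    latent <- truth[[paste0("score_latent_", sp)]]
    runs <- list()
    for (ctg in contigs) {
      L <- sp_len[[sp]][[ctg]]
      starts <- seq(0L, L - 50L, by = 50L)
      sc <- stats::rnorm(length(starts), 0, 0.3)
      sel <- which(truth$chrom == ctg & crd$keep)
      for (i in sel) {
        j <- which(starts < crd$start[i] + win & starts + 50L > crd$start[i])
        sc[j] <- sc[j] + latent[i]
      }
      runs[[ctg]] <- data.frame(chrom = ctg, start = starts,
                                end = starts + 50L, score = round(sc, 4))
    }
    f <- paste0(sp, ".phylop.wig")
    files[[f]] <- pth(f)
    write_wig(do.call(rbind, runs), files[[f]])
  }

  ## histone peaks on mouse/human: summit inside the DMR image at the
  ## EC/ENC-dependent rate; background peaks with summits clear of images
  for (sp in c("mouse", "human")) {
    crd <- sp_coords[[sp]]
    has_peak <- stats::runif(n_dmr) <
      ifelse(crd$ec, cfg$peak_rate_ec, cfg$peak_rate_enc)
    has_peak[!crd$keep] <- NA
    truth[[paste0("peak_", sp)]] <- has_peak
    pk <- list()
    sel <- which(crd$keep & !is.na(has_peak) & has_peak)
    if (length(sel))
      pk[[1]] <- data.frame(chrom = truth$chrom[sel],
                            start = pmax(0L, crd$start[sel] - 200L),
                            end = crd$start[sel] + win + 200L,
                            summit = crd$start[sel] + win %/% 2L)
    for (ctg in contigs) {
      L <- sp_len[[sp]][[ctg]]
      bg <- rand_intervals(cfg$n_bg_peaks_per_contig, L, 350L, 450L, ctg)
      bg$summit <- (bg$start + bg$end) %/% 2L
      img <- which(truth$chrom == ctg & crd$keep)
      bad <- vapply(bg$summit, function(s)
        any(s >= crd$start[img] & s < crd$start[img] + win), logical(1))
      pk[[length(pk) + 1L]] <- bg[!bad, ]
    }
    pk <- do.call(rbind, pk)
    pk <- pk[order(pk$chrom, pk$start), ]
    np <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                     name = paste0("peak", seq_len(nrow(pk))), score = 0L,
                     strand = ".", signal = 1, p = -1, q = -1,
                     offset = pk$summit - pk$start)
    f <- paste0(sp, ".peaks.narrowPeak")
    files[[f]] <- pth(f)
    write_bed(np, files[[f]])
  }

  ## gene models, CGIs and repeats per species
  for (sp in names(genomes)) {
    lens <- sp_len[[sp]]
    genes <- list(); cg <- list(); rp <- list()
    for (ctg in contigs) {
      L <- lens[[ctg]]
      n_g <- cfg$n_genes_per_contig
      st <- sort(sample.int(L - 45000L, n_g) - 1L)
      txlen <- sample(5000:40000, n_g, TRUE)
      en <- pmin(st + txlen, L)
      keep <- c(TRUE, st[-1] >= en[-n_g])   # drop overlapping placements
      st <- st[keep]; en <- en[keep]
      strand <- sample(c("+", "-"), length(st), TRUE)
      ex <- lapply(seq_along(st), function(g) {
        k <- sample(3:6, 1)
        es <- round(seq(st[g], en[g] - 200L, length.out = k))
        list(starts = as.integer(es), ends = as.integer(es + 200L))
      })
      genes[[ctg]] <- data.frame(
        name = paste0(sp, "_", ctg, "_g", seq_along(st)),
        chrom = ctg, strand = strand, txStart = st, txEnd = en,
        stringsAsFactors = FALSE)
      genes[[ctg]]$exon_starts <- lapply(ex, `[[`, "starts")
      genes[[ctg]]$exon_ends <- lapply(ex, `[[`, "ends")
      cg[[ctg]] <- rand_intervals(cfg$n_cgi_per_contig, L, 300L, 800L, ctg)
      rp[[ctg]] <- rand_intervals(cfg$n_repeats_per_contig, L, 150L, 500L, ctg)
    }
    gdf <- do.call(rbind, genes)
    files[[paste0(sp, ".genes.txt")]] <- pth(sp, ".genes.txt")
    write_genepred(gdf, files[[paste0(sp, ".genes.txt")]])
    cgd <- do.call(rbind, cg)
    files[[paste0(sp, ".cgi.bed")]] <- pth(sp, ".cgi.bed")
    write_bed(cgd[order(cgd$chrom, cgd$start), ],
              files[[paste0(sp, ".cgi.bed")]])
    rpd <- do.call(rbind, rp)
    files[[paste0(sp, ".repeats.bed")]] <- pth(sp, ".repeats.bed")
    write_bed(rpd[order(rpd$chrom, rpd$start), ],
              files[[paste0(sp, ".repeats.bed")]])
  }

  ## motif list and truth table
  files[["motifs.txt"]] <- pth("motifs.txt")
  writeLines(paste(names(cfg$motifs), unname(cfg$motifs), sep = "\t"),
             files[["motifs.txt"]])
  files[["truth.tsv"]] <- pth("truth.tsv")
  utils::write.table(truth, files[["truth.tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(structure(list(dir = out_dir, files = files, truth = truth,
                           genomes = genomes, config = cfg),
                      class = "trio_bundle"))
}

isTRUE_v <- function(x) !is.na(x) & x

# intercept a such that E_z[plogis(a + b z)] = p for z ~ N(0, 1)
logistic_intercept <- function(p, b) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (b == 0) return(stats::qlogis(p))
  z <- stats::qnorm(seq(0.0005, 0.9995, length.out = 2000))
  stats::uniroot(function(a) mean(stats::plogis(a + b * z)) - p,
                 c(-30, 30))$root
}

#' Generate one random chain (for oracle testing)
#'
#' Draws a random block structure (sizes and gaps), a random query strand,
#' and consistent header spans; useful as fixture input for per-base
#' liftover oracles. Uses the current RNG state.
#'
#' @param tName,qName contig names.
#' @param n_blocks number of aligned blocks (default 1-12, random).
#' @param max_block,max_gap maximum block and gap sizes in bp.
#' @param id chain id.
#' @param score chain score.
#' @return a `chain` object.
#' @export
random_chain <- function(tName = "chrT", qName = "chrQ",
                         n_blocks = sample(1:12, 1),
                         max_block = 300L, max_gap = 120L,
                         id = "1", score = 1000) {
  size <- sample.int(max_block, n_blocks, replace = TRUE)
  dt <- c(sample(0:max_gap, n_blocks - 1, replace = TRUE), 0L)
  dq <- c(sample(0:max_gap, n_blocks - 1, replace = TRUE), 0L)
  tStart <- sample(0:5000, 1)
  qStart <- sample(0:5000, 1)
  tEnd <- tStart + sum(size) + sum(dt)
  qEnd <- qStart + sum(size) + sum(dq)
  h <- list(score = score, tName = tName,
            tSize = tEnd + sample(0:1000, 1), tStrand = "+",
            tStart = tStart, tEnd = tEnd, qName = qName,
            qSize = qEnd + sample(0:1000, 1),
            qStrand = sample(c("+", "-"), 1),
            qStart = qStart, qEnd = qEnd, id = as.character(id))
  new_chain(h, data.frame(size = size, dt = dt, dq = dq))
}
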