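# End-to-end driver over a (synthetic or real) three-species bundle laid
# out with the simulator's file conventions, and the recovery report that
# scores pipeline output against the generator's truth table.

#' Run the full conservation pipeline on a trio bundle directory
#'
#' Reads the bundle files, tiles the reference genome into 500-bp windows,
#' computes window methylation scores, calls tsDMRs, maps them to both
#' comparison species, builds three-way orthologs, classifies EC/ENC
#' against each species, and calls genetic conservation against the
#' conserved-element track.
#'
#' @param dir bundle directory (as written by [simulate_trio()]).
#' @param tissues tissue names (default blood/brain/sperm).
#' @param q_threshold upstream q-value cutoff passed to [call_tsdmrs()].
#' @return list with `windows`, `scores`, `dmrs`, `lift_mouse`,
#'   `lift_human`, `threeway`, `cons_mouse`, `cons_human`, `genetic`,
#'   plus the parsed `chains` and per-species methylome `tracks`.
#' @export
run_trio_pipeline <- function(dir, tissues = c("blood", "brain", "sperm"),
                              q_threshold = 1e-5) {
  p <- function(...) file.path(dir, paste0(...))
  index <- read_genome_index(p("rat.fa"))
  windows <- tile_genome(index, 500L)
  tracks <- lapply(c(rat = "rat", mouse = "mouse", human = "human"),
                   function(sp) {
                     tl <- lapply(tissues, function(t)
                       read_methylome(p(sp, "_", t, ".bedGraph"), sp, t))
                     stats::setNames(tl, tissues)
                   })
  scores <- window_scores(tracks$rat, windows)
  dmrs <- call_tsdmrs(scores, tissues, q_threshold)
  chains <- list(rat_mouse = read_chain(p("rat.mouse.chain")),
                 rat_human = read_chain(p("rat.human.chain")),
                 mouse_human = read_chain(p("mouse.human.chain")))
  lift_mouse <- liftover_intervals(chains$rat_mouse, dmrs)
  lift_human <- liftover_intervals(chains$rat_human, dmrs)
  threeway <- build_threeway(lift_mouse, lift_human, chains$mouse_human)
  cons_mouse <- classify_conservation(dmrs, lift_mouse, tracks$mouse)
  cons_human <- classify_conservation(dmrs, lift_human, tracks$human)
  elements <- read_bed(p("rat.elements.bed"))
  genetic <- cbind(dmrs, genetic_conservation(dmrs, elements))
  list(windows = windows, scores = scores, dmrs = dmrs,
       lift_mouse = lift_mouse, lift_human = lift_human,
       threeway = threeway, cons_mouse = cons_mouse,
       cons_human = cons_human, genetic = genetic,
       chains = chains, tracks = tracks)
}

fate_to_call <- c(conserved = "CONSERVED_IN_PLACE", turnover = "TURNOVER",
                  loss = "LOSS", gain = "GAIN", none = "ABSENT_BOTH")

#' Score pipeline output against the generator's truth table
#'
#' Computes: precision/recall of tsDMR calls against the planted windows;
#' the estimated EC fraction per species pair (EC among classified
#' orthologs) and its error versus the planted probability; the three-way
#' recovery fraction; the EC-vs-ENC genetic-conservation contrast
#' (chi-square); the motif turnover confusion matrix with per-call
#' precision/recall for the TURNOVER class; and the score-bin EC-curve
#' trend (Spearman correlation of bin index and EC fraction).
#'
#' @param pipeline output of [run_trio_pipeline()].
#' @param bundle the `trio_bundle` from [simulate_trio()].
#' @param n_bins bins for the score curve (desk-scale default 20).
#' @return named list of metrics.
#' @export
recovery_report <- function(pipeline, bundle, n_bins = 20L) {
  truth <- bundle$truth
  cfg <- bundle$config
  if (nrow(pipeline$dmrs) == 0) stop("pipeline output has no tsDMR calls")
  ckey <- paste(pipeline$dmrs$chrom, pipeline$dmrs$start,
                pipeline$dmrs$target_tissue)
  tkey <- paste(truth$chrom, truth$start, truth$tissue)
  tp <- sum(ckey %in% tkey)
  out <- list(
    n_called = length(ckey), n_planted = length(tkey),
    tsdmr_precision = tp / length(ckey),
    tsdmr_recall = tp / length(tkey))

  for (sp in c("mouse", "human")) {
    st <- pipeline[[paste0("cons_", sp)]]$status
    cls <- st %in% c("EC", "ENC")
    est <- mean(st[cls] == "EC")
    out[[paste0("ec_fraction_", sp)]] <- est
    out[[paste0("ec_error_", sp)]] <-
      abs(est - cfg[[paste0("p_ec_", sp)]])
  }
  out$threeway_fraction <- nrow(pipeline$threeway) / nrow(pipeline$dmrs)

  ## genetic conservation contrast, scored on true EC labels
  m <- match(paste(pipeline$dmrs$chrom, pipeline$dmrs$start),
             paste(truth$chrom, truth$start))
  ecl <- truth$ec_mouse[m]
  gc_ <- pipeline$genetic$conserved
  ok <- !is.na(ecl)
  tab <- table(factor(ecl[ok], c(TRUE, FALSE)),
               factor(gc_[ok], c(TRUE, FALSE)))
  out$genetic_rate_ec <- tab[1, 1] / sum(tab[1, ])
  out$genetic_rate_enc <- tab[2, 1] / sum(tab[2, ])
  out$genetic_contrast_p <- chisq2x2(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2])$p

  ## motif turnover confusion per species pair
  motifs <- lapply(names(cfg$motifs), function(nm)
    motif_model(nm, consensus = cfg$motifs[[nm]]))
  names(motifs) <- names(cfg$motifs)
  conf <- NULL
  for (sp in c("mouse", "human")) {
    rows <- which(!is.na(truth$motif) & truth[[paste0("retained_", sp)]] &
                    !truth$rearranged)
    if (!length(rows)) next
    for (nm in unique(truth$motif[rows])) {
      r2 <- rows[truth$motif[rows] == nm]
      pairs <- data.frame(chrom = truth$chrom[r2], start = truth$start[r2],
                          end = truth$end[r2],
                          dst_chrom = truth$chrom[r2],
                          dst_start = truth[[paste0(sp, "_start")]][r2],
                          dst_end = truth[[paste0(sp, "_end")]][r2])
      calls <- motif_turnover(pairs, bundle$genomes$rat, bundle$genomes[[sp]],
                              motifs[[nm]],
                              pipeline$chains[[paste0("rat_", sp)]])
      expected <- fate_to_call[truth[[paste0("fate_", sp)]][r2]]
      conf <- rbind(conf, data.frame(expected = expected, called = calls))
    }
  }
  lv <- unname(fate_to_call)
  out$turnover_confusion <- table(factor(conf$expected, lv),
                                  factor(conf$called, lv))
  tv <- out$turnover_confusion["TURNOVER", "TURNOVER"]
  out$turnover_precision <- tv / sum(out$turnover_confusion[, "TURNOVER"])
  out$turnover_recall <- tv / sum(out$turnover_confusion["TURNOVER", ])

  ## score-bin EC curve trend (rat-mouse)
  score_track <- read_wig(file.path(bundle$dir, "mouse.phylop.wig"))
  curve <- phylop_ec_curve(pipeline$dmrs, pipeline$chains$rat_mouse,
                           score_track, pipeline$tracks$mouse,
                           n_bins = n_bins)
  out$curve <- curve
  out$curve_spearman <- stats::cor(curve$bin, curve$ec_fraction,
                                   method = "spearman")
  out
}
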