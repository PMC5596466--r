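# Epigenetic conservation (EC/ENC) of orthologous regions. A tsDMR's
# ortholog in another species is epigenetically conserved when it shows the
# same tissue-specific methylation pattern, expressed through categorical
# methylation states (0 unmethylated / 1 intermediate / 2 methylated):
#   EC iff (target state 0 and both other tissues in {1,2}) or
#          (target state 1 and both other tissues = 2); otherwise ENC.
# Orthologous regions without CpGs cannot be classified (NO_CPG); regions
# without an ortholog are NO_ORTHOLOG.

#' Classify epigenetic conservation from methylation states
#'
#' Vectorized over regions: each region contributes the state of its target
#' tissue and of the two other tissues in the comparison species.
#'
#' @param target_state integer states (0/1/2) in the tsDMR's own tissue.
#' @param other1,other2 states in the two other tissues.
#' @return character vector, `"EC"` or `"ENC"`.
#' @examples
#' classify_ec(0L, 1L, 2L)  # EC
#' classify_ec(1L, 1L, 2L)  # ENC: intermediate target needs both others at 2
#' @export
classify_ec <- function(target_state, other1, other2) {
  states <- c(target_state, other1, other2)
  if (anyNA(states)) stop("missing methylation state")
  if (!all(states %in% 0:2)) stop("methylation state must be 0, 1 or 2")
  ifelse((target_state == 0L & other1 >= 1L & other2 >= 1L) |
           (target_state == 1L & other1 == 2L & other2 == 2L),
         "EC", "ENC")
}

#' Classify conservation of tsDMR orthologs against another species
#'
#' Runs the full per-region pipeline: regions without a mapped ortholog are
#' `NO_ORTHOLOG`; orthologs lacking CpGs in any tissue track are `NO_CPG`
#' (only orthologous regions with CpG dinucleotides can be classified);
#' remaining regions get `EC`/`ENC` from [classify_ec()] on the categorized
#' region means.
#'
#' @param dmrs tsDMR call data.frame (needs `target_tissue`).
#' @param ortho matching liftover result rows from [liftover_intervals()]
#'   (same order as `dmrs`).
#' @param tracks named list of the comparison species' `methylome_track`s,
#'   one per tissue, covering all three tissues.
#' @return `dmrs` with added columns `status`
#'   (EC/ENC/NO_ORTHOLOG/NO_CPG) and `state_<tissue>` columns.
#' @export
classify_conservation <- function(dmrs, ortho, tracks) {
  stopifnot(nrow(dmrs) == nrow(ortho))
  tissues <- names(tracks)
  if (!all(unique(dmrs$target_tissue) %in% tissues))
    stop("tracks missing for some target tissue")
  n <- nrow(dmrs)
  out <- as.data.frame(dmrs)
  out$status <- rep(NA_character_, n)
  mapped <- which(ortho$mapped)
  out$status[setdiff(seq_len(n), mapped)] <- "NO_ORTHOLOG"
  if (length(mapped)) {
    tgt <- data.frame(chrom = ortho$target_chrom[mapped],
                      start = ortho$target_start[mapped],
                      end = ortho$target_end[mapped])
    states <- matrix(NA_integer_, length(mapped), length(tissues),
                     dimnames = list(NULL, tissues))
    ncpg_min <- rep(Inf, length(mapped))
    for (tis in tissues) {
      rm_ <- region_mean(tracks[[tis]], tgt)
      states[, tis] <- categorize_methylation(rm_$mean_level)
      ncpg_min <- pmin(ncpg_min, rm_$n_cpg)
    }
    nocpg <- ncpg_min == 0
    out$status[mapped[nocpg]] <- "NO_CPG"
    cls <- which(!nocpg)
    if (length(cls)) {
      ti <- dmrs$target_tissue[mapped[cls]]
      oth <- t(vapply(seq_along(cls), function(k) {
        o <- setdiff(tissues, ti[k])
        states[cls[k], o]
      }, integer(2)))
      out$status[mapped[cls]] <- classify_ec(
        states[cbind(cls, match(ti, tissues))], oth[, 1], oth[, 2])
    }
    for (tis in tissues) {
      col <- rep(NA_integer_, n)
      col[mapped] <- states[, tis]
      out[[paste0("state_", tis)]] <- col
    }
  }
  out
}

#' Integer percentage helper
#'
#' `round(100 * n / total)`, the rounding used in the conservation tables.
#'
#' @param n,total counts.
#' @return integer percentage(s).
#' @export
conservation_percent <- function(n, total) {
  if (any(total <= 0)) stop("total must be positive")
  as.integer(round(100 * n / total))
}

#' Tabulate EC/ENC counts per tissue
#'
#' Builds the per-tissue conservation summary: EC and ENC counts, the EC
#' percentage of all tsDMRs (regions lost to NO_ORTHOLOG/NO_CPG stay in the
#' denominator), and — when a background classification is supplied — the
#' upper-tail hypergeometric enrichment p-value with BH correction across
#' tissues.
#'
#' @param tissue character vector of tissue names.
#' @param n_ec,n_enc EC and ENC counts per tissue.
#' @param n_tsdmr total tsDMR count per tissue (>= n_ec + n_enc).
#' @param background_ec,background_n optional: EC count and size of a
#'   random-region background sample classified by the same pipeline.
#' @return data.frame with `tissue`, `n_tsdmr`, `n_ec`, `n_enc`,
#'   `percent_ec`, and `p_value`/`q_value` when a background is given.
#' @examples
#' tabulate_conservation("blood", 1477, 3583, 5506)  # percent_ec 27
#' @export
tabulate_conservation <- function(tissue, n_ec, n_enc, n_tsdmr,
                                  background_ec = NULL, background_n = NULL) {
  if (any(n_tsdmr <= 0)) stop("zero tsDMR total")
  if (any(n_ec + n_enc > n_tsdmr))
    stop("EC + ENC exceeds the tsDMR total")
  out <- data.frame(tissue = tissue, n_tsdmr = n_tsdmr, n_ec = n_ec,
                    n_enc = n_enc,
                    percent_ec = conservation_percent(n_ec, n_tsdmr),
                    stringsAsFactors = FALSE)
  if (!is.null(background_ec)) {
    out$p_value <- mapply(ec_enrichment_test, n_ec, n_tsdmr,
                          background_ec, background_n)
    out$q_value <- bh_fdr(out$p_value)
  }
  out
}

#' Hypergeometric test for epigenetic-conservation enrichment
#'
#' Upper-tail probability of observing at least `observed_ec` EC regions
#' among `n_tsdmr` draws, against a background sample of random regions
#' classified by the same pipeline. The urn pools background and observed
#' regions: population `N = background_n + n_tsdmr`, successes
#' `K = background_ec + observed_ec`, draws `n = n_tsdmr`; the p-value is
#' the survival function at `observed_ec - 1`, making the test exact under
#' the resampling scheme.
#'
#' @param observed_ec number of EC tsDMRs.
#' @param n_tsdmr number of tsDMRs.
#' @param background_ec number of EC regions in the background sample.
#' @param background_n background sample size.
#' @return upper-tail p-value.
#' @export
ec_enrichment_test <- function(observed_ec, n_tsdmr,
                               background_ec, background_n) {
  if (background_n <= 0) stop("empty background sample")
  stopifnot(observed_ec >= 0, observed_ec <= n_tsdmr,
            background_ec >= 0, background_ec <= background_n)
  N <- background_n + n_tsdmr
  K <- background_ec + observed_ec
  stats::phyper(observed_ec - 1, K, N - K, n_tsdmr, lower.tail = FALSE)
}

#' Assign three-way evolutionary groups
#'
#' For tsDMRs in three-way orthologous regions, combines the rat-mouse and
#' rat-human conservation calls into the four evolutionary groups:
#' `RMH_EC` (EC in both), `RM_EC` (mouse only), `RH_EC` (human only),
#' `RMH_ENC` (neither).
#'
#' @param mouse_status,human_status character vectors in `c("EC", "ENC")`.
#' @return character vector of group labels.
#' @export
assign_evolution_group <- function(mouse_status, human_status) {
  ok <- c("EC", "ENC")
  if (!all(mouse_status %in% ok) || !all(human_status %in% ok))
    stop("evolution groups are defined only for EC/ENC calls ",
         "(the three-way set excludes NO_ORTHOLOG/NO_CPG)")
  ifelse(mouse_status == "EC",
         ifelse(human_status == "EC", "RMH_EC", "RM_EC"),
         ifelse(human_status == "EC", "RH_EC", "RMH_ENC"))
}

#' Aggregate per-tissue evolutionary-group counts
#'
#' Sums a per-tissue group-count table into genome-wide group totals and the
#' grand total of classified three-way tsDMRs (the four groups partition the
#' classified set, so the totals sum to it).
#'
#' @param counts data.frame or matrix with columns `RMH_EC`, `RM_EC`,
#'   `RH_EC`, `RMH_ENC` and one row per tissue.
#' @return list with `group_totals` (named numeric) and `n_total`.
#' @export
tabulate_groups <- function(counts) {
  need <- c("RMH_EC", "RM_EC", "RH_EC", "RMH_ENC")
  counts <- as.data.frame(counts)
  if (!all(need %in% names(counts))) stop("missing group column")
  totals <- vapply(need, function(g) sum(counts[[g]]), numeric(1))
  list(group_totals = totals, n_total = sum(totals))
}
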