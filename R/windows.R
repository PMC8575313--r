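#' Tile sliding windows over a protein
#'
#' Candidate windows start on the shift grid (1, 1+S, 1+2S, ...), span
#' `W` amino acids and are clipped at the protein length `L`; windows whose
#' interval is contained in an earlier window are dropped. The retained
#' windows cover every position 1..L and consecutive windows overlap by
#' `W - S` except at the terminus. Defaults are the 500 aa / 200 aa grid
#' (1,500 bp windows shifted by 600 bp in transcript space).
#'
#' @param protein_length L, in amino acids.
#' @param window_aa window width W.
#' @param shift_aa shift S.
#' @return data frame: window_index, aa_start, aa_end.
#' @export
tile_windows <- function(protein_length, window_aa = 500, shift_aa = 200) {
  stopifnot(protein_length >= 1, window_aa >= 1, shift_aa >= 1)
  starts <- seq.int(1L, protein_length, by = shift_aa)
  ends <- pmin(starts + window_aa - 1L, protein_length)
  keep <- logical(length(starts))
  max_end <- 0L
  for (i in seq_along(starts)) {
    if (ends[i] > max_end) { keep[i] <- TRUE; max_end <- ends[i] }
  }
  data.frame(window_index = seq_len(sum(keep)),
             aa_start = starts[keep], aa_end = ends[keep])
}

#' Assign annotated variants to protein windows
#'
#' A variant belongs to every window containing its protein position;
#' range annotations (indels) are located by their start coordinate.
#' Variants without a protein position are excluded (returned in the
#' `unassigned` attribute).
#'
#' @param windows data frame from [tile_windows()].
#' @param annotations annotation rows for one transcript.
#' @param protein_length optional; when given, a protein position beyond it
#'   raises a validation error naming the transcript.
#' @return named list (window index -> character vector of site keys), with
#'   attribute `unassigned`.
#' @export
assign_variants_to_windows <- function(windows, annotations,
                                       protein_length = NULL) {
  pos <- annotations$protein_start
  if (!is.null(protein_length) && any(!is.na(pos) & pos > protein_length))
    stop(sprintf("protein position beyond protein length for transcript %s",
                 annotations$transcript[which(!is.na(pos) &
                                              pos > protein_length)[1]]))
  keys <- variant_key(annotations)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    keys[!is.na(pos) & pos >= windows$aa_start[i] & pos <= windows$aa_end[i]]
  })
  names(out) <- as.character(windows$window_index)
  attr(out, "unassigned") <- keys[is.na(pos)]
  out
}

#' Scan configuration
#'
#' @param window_aa,shift_aa tiling grid (default 500 / 200 aa).
#' @param alpha significance level for region calling.
#' @param scope `"gene_set"` adjusts across all non-empty windows of all
#'   genes; `"per_gene"` adjusts within each gene.
#' @param weights burden weight scheme (see [burden_score_test()]).
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_aa = 500, shift_aa = 200, alpha = 0.05,
                        scope = c("gene_set", "per_gene"), weights = "beta") {
  structure(list(window_aa = window_aa, shift_aa = shift_aa, alpha = alpha,
                 scope = match.arg(scope), weights = weights),
            class = "scan_config")
}

#' Sliding-window burden scan over a gene set
#'
#' Tiles each gene's canonical-transcript protein, assigns the supplied
#' (already frequency/consequence-filtered) variants to windows, runs the
#' burden score test and the exact carrier 2x2 machinery per non-empty
#' window, and adjusts p-values (BH and Holm) across the configured scope.
#' Empty windows appear in the output with missing statistics and do not
#' count towards the number of tests.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table.
#' @param annotations annotation rows restricted to the scan category
#'   (exonic nonsynonymous at the chosen MAF tier).
#' @param transcripts transcript table (gene, transcript, protein_length);
#'   every scanned gene must have a row.
#' @param config a [scan_config()].
#' @return data frame in the `window_scan` results schema (without region
#'   columns; see [call_regions()]).
#' @export
scan_gene_set <- function(genotypes, phenotypes, annotations, transcripts,
                          config = scan_config()) {
  genes <- sort(unique(annotations$gene))
  missing_tr <- setdiff(genes, transcripts$gene)
  if (length(missing_tr))
    stop("no transcript info for gene(s): ", paste(missing_tr, collapse = ", "))
  rows <- list()
  for (g in genes) {
    tr <- transcripts[transcripts$gene == g, ][1, ]
    ann <- annotations[annotations$gene == g, , drop = FALSE]
    wins <- tile_windows(tr$protein_length, config$window_aa, config$shift_aa)
    asg <- assign_variants_to_windows(wins, ann,
                                      protein_length = tr$protein_length)
    for (i in seq_len(nrow(wins))) {
      vs <- asg[[i]]
      if (length(vs)) {
        bt <- burden_score_test(genotypes, phenotypes, vs,
                                weights = config$weights)
        tb <- carrier_table(genotypes, phenotypes, vs)
        fe <- fisher_exact(tb, alpha = config$alpha)
        row <- data.frame(gene = g, transcript = tr$transcript,
                          window_index = wins$window_index[i],
                          aa_start = wins$aa_start[i], aa_end = wins$aa_end[i],
                          n_markers = length(vs),
                          n_case_carriers = tb[["a"]],
                          n_control_carriers = tb[["c"]],
                          Q = bt$Q, p = bt$p, or_cmle = fe$or,
                          ci_lo = fe$ci[1], ci_hi = fe$ci[2],
                          stringsAsFactors = FALSE)
      } else {
        row <- data.frame(gene = g, transcript = tr$transcript,
                          window_index = wins$window_index[i],
                          aa_start = wins$aa_start[i], aa_end = wins$aa_end[i],
                          n_markers = 0L, n_case_carriers = NA_integer_,
                          n_control_carriers = NA_integer_, Q = NA_real_,
                          p = NA_real_, or_cmle = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  if (config$scope == "gene_set") {
    res$p_bh <- adjust_pvalues(res$p, "BH")
    res$p_holm <- adjust_pvalues(res$p, "Holm")
  } else {
    res$p_bh <- NA_real_; res$p_holm <- NA_real_
    for (g in unique(res$gene)) {
      i <- res$gene == g
      res$p_bh[i] <- adjust_pvalues(res$p[i], "BH")
      res$p_holm[i] <- adjust_pvalues(res$p[i], "Holm")
    }
  }
  res
}

#' Call significant regions from a window scan
#'
#' A window is significant at tier `"adjusted"` when its BH-adjusted p is
#' below `alpha` *and* its odds ratio exceeds 1; at tier `"nominal"` the raw
#' p is used instead. Overlapping or abutting significant windows of the
#' same tier within a gene merge into one region spanning their union;
#' `best_p` is the smallest raw p among the merged windows and `or_cmle`
#' the odds ratio of that best window.
#'
#' @param results data frame from [scan_gene_set()].
#' @param alpha significance level.
#' @return data frame: gene, aa_start, aa_end, tier, n_windows, best_p,
#'   or_cmle.
#' @export
call_regions <- function(results, alpha = 0.05) {
  empty <- data.frame(gene = character(), aa_start = integer(),
                      aa_end = integer(), tier = character(),
                      n_windows = integer(), best_p = numeric(),
                      or_cmle = numeric())
  out <- list()
  for (tier in c("adjusted", "nominal")) {
    pcol <- if (tier == "adjusted") results$p_bh else results$p
    sig <- !is.na(pcol) & pcol < alpha &
      !is.na(results$or_cmle) & results$or_cmle > 1
    sel <- results[sig, , drop = FALSE]
    for (g in unique(sel$gene)) {
      w <- sel[sel$gene == g, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(w$aa_start, w$aa_end))
      for (r in seq_along(ir)) {
        lo <- IRanges::start(ir)[r]; hi <- IRanges::end(ir)[r]
        inside <- w$aa_start >= lo & w$aa_end <= hi
        best <- which.min(w$p[inside])
        out[[length(out) + 1L]] <- data.frame(
          gene = g, aa_start = lo, aa_end = hi, tier = tier,
          n_windows = sum(inside), best_p = min(w$p[inside]),
          or_cmle = w$or_cmle[inside][best], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out) %||% empty
  rownames(res) <- NULL
  res[order(res$gene, res$tier, res$aa_start), , drop = FALSE]
}
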