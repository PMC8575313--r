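#' Homozygous rare variants within runs of homozygosity
#'
#' Emits one hit per (individual, variant) where the genotype is hom-alt
#' (code 2) and the variant position lies inside an ROH of that individual
#' longer than `min_roh_bp` (strict `>`; the conventional screening cut-off
#' is 100 kb). Indels are located by their start position. Individuals with
#' genotypes but no ROH rows simply contribute no hits.
#'
#' @param genotypes a [genotype_matrix()].
#' @param annotations annotation table (already frequency- and
#'   consequence-filtered for the prioritisation use case); joined on
#'   variant key.
#' @param roh ROH table from [read_roh_bed()] (1-based inclusive).
#' @param min_roh_bp minimum ROH length in bp, strict.
#' @return data frame: individual, gene, chrom, pos, ref, alt, impact,
#'   consequence, in_roh_length.
#' @export
homozygous_in_roh <- function(genotypes, annotations, roh, min_roh_bp = 1e5) {
  key <- variant_key(annotations)
  idx <- match(key, colnames(genotypes$calls))
  ann <- annotations[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  qroh <- roh[roh$length > min_roh_bp, , drop = FALSE]
  hits <- list()
  for (i in seq_along(genotypes$individuals)) {
    ind <- genotypes$individuals[i]
    hom <- which(genotypes$calls[i, idx] == 2L)
    if (!length(hom)) next
    r <- qroh[qroh$individual == ind, , drop = FALSE]
    if (!nrow(r)) next
    for (j in hom) {
      a <- ann[j, ]
      inside <- r$chrom == a$chrom & r$start <= a$pos & a$pos <= r$end
      if (any(inside)) {
        hits[[length(hits) + 1L]] <- data.frame(
          individual = ind, gene = a$gene, chrom = a$chrom, pos = a$pos,
          ref = a$ref, alt = a$alt, impact = a$impact,
          consequence = a$consequence,
          in_roh_length = max(r$length[inside]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits) %||% data.frame(
    individual = character(), gene = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    impact = character(), consequence = character(), in_roh_length = integer())
  rownames(out) <- NULL
  out
}

#' Karyotype-wide ROH coverage in fixed bins
#'
#' For each chromosome bin (default 100 kb) counts the number of individuals
#' having at least one ROH longer than `min_len_bp` (strict `>`, default
#' 4 Mb) overlapping that bin -- the cumulative medium-to-large ROH coverage
#' view of a consanguineous cohort.
#'
#' @param roh ROH table (1-based inclusive, with `length`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_bp bin width.
#' @param min_len_bp qualifying ROH length, strict.
#' @return data frame: chrom, bin_start (1-based), bin_end, count; includes
#'   zero-count bins so the result is a dense matrix for heatmap plotting.
#' @export
roh_coverage_karyotype <- function(roh, chrom_lengths, bin_bp = 1e5,
                                   min_len_bp = 4e6) {
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_bp)
    data.frame(chrom = ch, bin = seq_len(nb), stringsAsFactors = FALSE)
  }))
  grid$bin_start <- (grid$bin - 1L) * bin_bp + 1
  grid$bin_end <- pmin(grid$bin * bin_bp, chrom_lengths[grid$chrom])
  grid$count <- 0L

  q <- roh[roh$length > min_len_bp, , drop = FALSE]
  q <- q[q$chrom %in% names(chrom_lengths), , drop = FALSE]
  clip <- q$end > chrom_lengths[q$chrom]
  if (any(clip)) {
    warning(sum(clip), " ROH interval(s) extend beyond the chromosome length; clipped")
    q$end[clip] <- chrom_lengths[q$chrom][clip]
  }
  if (nrow(q)) {
    # per (individual, chrom) the intervals are already non-overlapping, but
    # bins are deduplicated per individual anyway
    touched <- unique(do.call(rbind, lapply(seq_len(nrow(q)), function(i) {
      bins <- seq.int(floor((q$start[i] - 1) / bin_bp),
                      floor((q$end[i] - 1) / bin_bp)) + 1L
      data.frame(individual = q$individual[i], chrom = q$chrom[i], bin = bins,
                 stringsAsFactors = FALSE)
    })))
    tab <- table(paste(touched$chrom, touched$bin, sep = "\r"))
    gk <- paste(grid$chrom, grid$bin, sep = "\r")
    grid$count <- as.integer(ifelse(gk %in% names(tab), tab[gk], 0L))
  }
  grid[c("chrom", "bin_start", "bin_end", "count")]
}

#' Prioritise genes from homozygous-in-ROH hits
#'
#' A gene is selected when it contains a HIGH-impact variant, or when at
#' least two distinct affected individuals carry a qualifying variant in it.
#' With `rule = "results"` the narrower phrasing is used instead: one
#' carrier of a frameshift/stop-gain, or >= 2 carriers of a missense.
#'
#' @param hits data frame from [homozygous_in_roh()] (already filtered to
#'   the qualifying frequency and consequence categories).
#' @param rule `"methods"` (default) or `"results"`.
#' @return data frame: gene, n_carriers, has_high_impact, selected, reasons.
#' @export
prioritize_genes <- function(hits, rule = c("methods", "results")) {
  rule <- match.arg(rule)
  if (!nrow(hits))
    return(data.frame(gene = character(), n_carriers = integer(),
                      has_high_impact = logical(), selected = logical(),
                      reasons = character()))
  out <- do.call(rbind, lapply(split(hits, hits$gene), function(g) {
    n_car <- length(unique(g$individual))
    high <- any(g$impact == "HIGH")
    if (rule == "methods") {
      reasons <- c(if (high) "high_impact", if (n_car >= 2) "recurrent")
    } else {
      lof <- any(grepl("stop_gained|frameshift", g$consequence))
      mis <- grepl("missense", g$consequence)
      rec <- length(unique(g$individual[mis])) >= 2
      reasons <- c(if (lof) "high_impact", if (rec) "recurrent")
      high <- lof
    }
    data.frame(gene = g$gene[1], n_carriers = n_car, has_high_impact = high,
               selected = length(reasons) > 0,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Map human genes to fly orthologues by DIOPT score
#'
#' Keeps, per human gene, the candidate fly gene with the highest DIOPT
#' score; ties are broken towards the lexicographically smallest fly symbol
#' and flagged. Several human genes may share one fly orthologue, so the
#' distinct fly-gene set is reported alongside the mapping.
#'
#' @param genes human gene symbols to map.
#' @param ortho_rows orthologue table ([read_orthologues()] schema).
#' @param min_score optional minimum DIOPT score; candidates below it are
#'   ignored.
#' @param require_rnai drop candidates without an RNAi line.
#' @return list with `mapping` (human_gene, fly_gene, diopt_score, tie),
#'   `unmapped` (character) and `fly_genes` (distinct, sorted).
#' @export
map_orthologues <- function(genes, ortho_rows, min_score = NULL,
                            require_rnai = FALSE) {
  cand <- ortho_rows[ortho_rows$human_gene %in% genes, , drop = FALSE]
  if (!is.null(min_score))
    cand <- cand[cand$diopt_score >= min_score, , drop = FALSE]
  if (require_rnai) cand <- cand[cand$has_rnai_line, , drop = FALSE]
  mapping <- do.call(rbind, lapply(split(cand, cand$human_gene), function(g) {
    best <- g[g$diopt_score == max(g$diopt_score), , drop = FALSE]
    best <- best[order(best$fly_gene), , drop = FALSE]
    data.frame(human_gene = best$human_gene[1], fly_gene = best$fly_gene[1],
               diopt_score = best$diopt_score[1], tie = nrow(best) > 1,
               stringsAsFactors = FALSE)
  })) %||% data.frame(human_gene = character(), fly_gene = character(),
                      diopt_score = integer(), tie = logical())
  rownames(mapping) <- NULL
  list(mapping = mapping,
       unmapped = sort(setdiff(genes, mapping$human_gene)),
       fly_genes = sort(unique(mapping$fly_gene)))
}
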