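QC_METRICS <- c("DP", "MQ0", "QD", "MQ", "FS", "SOR", "MQRankSum",
                "ReadPosRankSum", "InbreedingCoeff")

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Read a VCF into a site table and genotype matrix
#'
#' Parses a VCF 4.x file (plain text or bgzip) with
#' [VariantAnnotation::readVcf()], harvests the site-level QC metrics used by
#' the hard-filter dialects (`QD`, `MQ`, `MQ0`, `FS`, `SOR`, `MQRankSum`,
#' `ReadPosRankSum`, `InbreedingCoeff`, `DP`, `FILTER`) and decomposes
#' multi-allelic records into one site per alternate allele. Genotypes are
#' coded per alt: `0` hom-ref, `1` het, `2` hom-alt, `-1` missing; a `1/2`
#' call codes 1 for each of the two alts.
#'
#' @param path VCF file.
#' @param dialect which QC dialect the sites are destined for (stored as an
#'   attribute and used as the default by [qc_filter()]): `"hc_hard"`
#'   (GATK-style hard thresholds), `"ug2013"` (depth / MQ0 exclusion rules)
#'   or `"gh"` (PASS + FS + per-call GQ).
#' @return list with elements `sites` (data frame: chrom, pos, ref, alt,
#'   variant_class, QC metric columns, FILTER, internal_af placeholder) and
#'   `genotypes` (a [genotype_matrix()] with per-call GQ/DP when present).
#' @export
read_vcf <- function(path, dialect = c("hc_hard", "ug2013", "gh")) {
  dialect <- match.arg(dialect)
  validate_vcf_lines(path)
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  nalt <- lengths(rr$ALT)
  row_idx <- rep(seq_along(rr), nalt)
  alt_idx <- unlist(lapply(nalt, seq_len), use.names = FALSE)

  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[row_idx],
    pos   = GenomicRanges::start(rr)[row_idx],
    ref   = as.character(rr$REF)[row_idx],
    alt   = unlist(lapply(rr$ALT, as.character), use.names = FALSE),
    stringsAsFactors = FALSE)
  sites$variant_class <- ifelse(is_snv(sites$ref, sites$alt), "SNV", "indel")

  inf <- VariantAnnotation::info(v)
  for (m in QC_METRICS) {
    col <- if (m %in% names(inf)) suppressWarnings(as.numeric(inf[[m]])) else
      rep(NA_real_, length(rr))
    sites[[m]] <- col[row_idx]
  }
  filt <- rr$FILTER
  sites$FILTER <- ifelse(filt %in% c(".", ""), NA_character_,
                         as.character(filt))[row_idx]
  sites$internal_af <- NA_real_

  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field")
  individuals <- colnames(gt)
  calls <- gt_to_codes(gt, row_idx, alt_idx)

  take <- function(name) {
    m <- VariantAnnotation::geno(v)[[name]]
    if (is.null(m)) return(NULL)
    out <- matrix(suppressWarnings(as.numeric(t(m[row_idx, , drop = FALSE]))),
                  nrow = length(individuals))
    out
  }
  gm <- genotype_matrix(calls, individuals, sites[c("chrom", "pos", "ref", "alt")],
                        gq = take("GQ"), dp = take("DP"))
  attr(sites, "dialect") <- dialect
  list(sites = sites, genotypes = gm)
}

# Light structural validation so malformed files fail with a line number
# (readVcf's own errors do not carry one).
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr))
    stop("malformed VCF: no #CHROM header line in ", path, call. = FALSE)
  hdr <- hdr[1]
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nf != nfield]
  if (length(bad))
    stop(sprintf("malformed VCF at line %d: expected %d columns, found %d",
                 bad[1], nfield, nf[match(bad[1], body)]), call. = FALSE)
  invisible(TRUE)
}

# GT strings ("0/1", "1|2", "./.") -> integer codes per (row, alt) pair.
gt_to_codes <- function(gt, row_idx, alt_idx) {
  n_ind <- ncol(gt)
  al <- strsplit(as.vector(gt), "[/|]")
  code_for <- function(alleles, k) {
    if (any(alleles == ".")) return(-1L)
    sum(alleles == as.character(k))
  }
  calls <- matrix(-1L, nrow = n_ind, ncol = length(row_idx))
  for (j in seq_along(row_idx)) {
    r <- row_idx[j]; k <- alt_idx[j]
    cells <- al[(seq_len(n_ind) - 1L) * nrow(gt) + r]
    calls[, j] <- vapply(cells, code_for, 1L, k = k)
  }
  calls
}

#' Read ROH intervals from a BED file
#'
#' Expects BED3+name (`chrom  start  end  individual`), 0-based half-open.
#' Intervals are converted once, at this boundary, to the package-internal
#' 1-based inclusive convention; per-(individual, chromosome) intervals are
#' sorted and merged when overlapping or abutting.
#'
#' @param path BED file. An empty file yields a zero-row table.
#' @return data frame with columns `individual`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `length` (bp).
#' @export
read_roh_bed <- function(path) {
  empty <- data.frame(individual = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("ROH BED needs 4 columns: chrom, start, end, name")
  names(df)[1:4] <- c("chrom", "start0", "end0", "individual")
  if (any(df$end0 <= df$start0))
    stop("ROH BED contains interval(s) with end <= start")
  df$start <- df$start0 + 1L
  df$end <- as.integer(df$end0)
  out <- do.call(rbind, lapply(
    split(df, list(df$individual, df$chrom), drop = TRUE),
    function(g) {
      m <- merge_intervals(g$start, g$end)
      data.frame(individual = g$individual[1], chrom = g$chrom[1],
                 start = m$start, end = m$end, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out <- out[order(out$individual, out$chrom, out$start), , drop = FALSE]
  out$length <- out$end - out$start + 1L
  out
}

#' Read a VEP-style annotation table
#'
#' One row per (variant, canonical transcript). `Protein_position`-style
#' strings are parsed: `"57"` gives (57, 57), `"57-59"` gives (57, 59),
#' `"-"`/blank gives missing. Blank allele-frequency cells become missing,
#' never 0 (the frequency filters treat missing as passing by default).
#'
#' @param path TSV with header. Required columns: chrom, pos, ref, alt, gene,
#'   transcript, consequence, impact, protein_position, sift, polyphen.
#' @param pop_afs names of the population allele-frequency columns; default:
#'   every column whose name starts with `af_`.
#' @return data frame with `protein_start`/`protein_end` integer columns and
#'   numeric AF columns; attribute `pop_afs` records the AF column names.
#' @export
read_annotations <- function(path, pop_afs = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  req <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
           "impact", "protein_position", "sift", "polyphen")
  assert_columns(df, req, "annotation table")
  if (is.null(pop_afs)) pop_afs <- grep("^af_", names(df), value = TRUE)
  bad <- setdiff(df$impact, IMPACT_LEVELS)
  if (length(bad))
    stop("unknown IMPACT label(s): ", paste(unique(bad), collapse = ", "))
  pp <- parse_protein_position(df$protein_position)
  out <- data.frame(chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref,
                    alt = df$alt, gene = df$gene, transcript = df$transcript,
                    consequence = df$consequence, impact = df$impact,
                    protein_start = pp$start, protein_end = pp$end,
                    sift = chr_or_na(df$sift), polyphen = chr_or_na(df$polyphen),
                    stringsAsFactors = FALSE)
  for (p in pop_afs) out[[p]] <- num_or_na(df[[p]])
  attr(out, "pop_afs") <- pop_afs
  out
}

parse_protein_position <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "-", ".", "NA") | is.na(x)] <- NA
  start <- rep(NA_integer_, length(x)); end <- start
  ok <- !is.na(x)
  parts <- strsplit(x[ok], "-", fixed = TRUE)
  start[ok] <- as.integer(vapply(parts, `[`, "", 1L))
  end[ok] <- as.integer(vapply(parts, function(p) p[length(p)], ""))
  if (any(ok & (is.na(start) | start < 1L)))
    stop("unparseable protein position value(s)")
  list(start = start, end = end)
}

#' Read phenotype, kinship, transcript and orthologue tables
#'
#' @param pheno_path TSV: individual, status (case/control/unknown), bmi.
#' @param kinship_path TSV: id1, id2, kinship.
#' @param transcript_path TSV: gene, transcript, protein_length.
#' @param ortho_path TSV: human_gene, fly_gene, diopt_score, has_rnai_line.
#' @return named list of the four data frames (an element is `NULL` when the
#'   corresponding path is).
#' @export
read_cohort_tables <- function(pheno_path = NULL, kinship_path = NULL,
                               transcript_path = NULL, ortho_path = NULL) {
  list(phenotypes = if (!is.null(pheno_path)) read_phenotypes(pheno_path),
       kinship = if (!is.null(kinship_path)) read_kinship(kinship_path),
       transcripts = if (!is.null(transcript_path)) read_transcripts(transcript_path),
       orthologues = if (!is.null(ortho_path)) read_orthologues(ortho_path))
}

#' @rdname read_cohort_tables
#' @param path a TSV file.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("individual", "status", "bmi"), "phenotype table")
  if (anyDuplicated(df$individual))
    stop("duplicate individual id(s) in phenotype table: ",
         paste(unique(df$individual[duplicated(df$individual)]), collapse = ", "))
  bad <- setdiff(df$status, c("case", "control", "unknown"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  df$bmi <- num_or_na(as.character(df$bmi))
  df[c("individual", "status", "bmi")]
}

#' @rdname read_cohort_tables
#' @export
read_kinship <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("id1", "id2", "kinship"), "kinship table")
  df$kinship <- as.numeric(df$kinship)
  if (any(df$kinship < 0)) stop("kinship coefficients must be >= 0")
  df[c("id1", "id2", "kinship")]
}

#' @rdname read_cohort_tables
#' @export
read_transcripts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("gene", "transcript", "protein_length"), "transcript table")
  df$protein_length <- as.integer(df$protein_length)
  if (any(df$protein_length < 1L)) stop("protein_length must be >= 1")
  df[c("gene", "transcript", "protein_length")]
}

#' @rdname read_cohort_tables
#' @export
read_orthologues <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("human_gene", "fly_gene", "diopt_score", "has_rnai_line"),
                 "orthologue table")
  df$diopt_score <- as.integer(df$diopt_score)
  if (any(df$diopt_score < 0L)) stop("diopt_score must be >= 0")
  df$has_rnai_line <- as.logical(df$has_rnai_line)
  df[c("human_gene", "fly_gene", "diopt_score", "has_rnai_line")]
}

RESULT_SCHEMAS <- list(
  gene_test = list(
    cols = c("unit_id", "n_markers", "n_case_carriers", "n_control_carriers",
             "Q", "p", "or_cmle", "ci_lo", "ci_hi", "p_bh", "p_holm"),
    sort = "unit_id"),
  window_scan = list(
    cols = c("gene", "transcript", "window_index", "aa_start", "aa_end",
             "n_markers", "n_case_carriers", "n_control_carriers", "Q", "p",
             "or_cmle", "ci_lo", "ci_hi", "p_bh", "p_holm", "region_id", "tier"),
    sort = c("gene", "window_index")),
  prioritization = list(
    cols = c("gene", "n_carriers", "has_high_impact", "selected", "reasons"),
    sort = "gene"))

#' Write a results table with a stable schema
#'
#' Columns in fixed order, rows sorted on the schema's documented keys,
#' floats at fixed precision (`%.6g`): two runs on the same input produce
#' byte-identical files.
#'
#' @param path output TSV.
#' @param records data frame conforming to the schema.
#' @param schema one of `"gene_test"`, `"window_scan"`, `"prioritization"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(path, records, schema) {
  if (!schema %in% names(RESULT_SCHEMAS))
    stop("unknown results schema: ", schema)
  sc <- RESULT_SCHEMAS[[schema]]
  if (nrow(records)) {
    assert_columns(records, sc$cols, sprintf("'%s' records", schema))
    records <- records[do.call(order, records[sc$sort]), sc$cols, drop = FALSE]
  } else {
    records <- as.data.frame(setNames(rep(list(character(0)), length(sc$cols)),
                                      sc$cols))
  }
  fmt <- records
  for (cl in names(fmt)) {
    v <- fmt[[cl]]
    fmt[[cl]] <- if (is.double(v)) ifelse(is.na(v), "NA", sprintf("%.6g", v))
      else as.character(v)
  }
  lines <- c(paste(sc$cols, collapse = "\t"),
             if (nrow(fmt)) do.call(paste, c(unname(fmt), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
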