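# SNP weight table: parsing, validation and per-biomarker selection.

.wt_columns <- c(
  "snp_id", "gene",
  paste0("risk_allele_", unname(.bm_suffix)),
  paste0("beta_", unname(.bm_suffix)),
  "genotyped"
)

#' Load and validate a SNP weight table
#'
#' Reads a tab-separated table of SNP effect estimates on the four iron
#' biomarkers (serum iron, ferritin, transferrin, transferrin saturation).
#' Each row gives, per biomarker, the risk allele (the allele associated with
#' lower iron status, or with higher transferrin, which marks iron
#' deficiency) and the GWAS effect estimate in SD units of the biomarker per
#' risk allele; a blank cell means the SNP is not used for that biomarker.
#'
#' Validation enforces: unique rsIDs, at least one effect per SNP, finite
#' nonzero effects, a risk allele (A/C/G/T) wherever an effect is present,
#' and a 0/1 genotyped flag.
#'
#' @param path Path to a TSV file with columns `snp_id`, `gene`,
#'   `risk_allele_iron`, `risk_allele_ferritin`, `risk_allele_transferrin`,
#'   `risk_allele_tsat`, `beta_iron`, `beta_ferritin`, `beta_transferrin`,
#'   `beta_tsat`, `genotyped`.
#' @return A data frame of class `snp_weight_table`.
#' @seealso [iron_weight_table()] for the packaged 12-SNP table,
#'   [select_snps_for_biomarker()], [build_risk_score()].
#' @export
load_weight_table <- function(path) {
  if (!file.exists(path)) {
    stop("weight table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path,
    colClasses = "character", check.names = FALSE,
    na.strings = NULL, stringsAsFactors = FALSE
  )

  missing_cols <- setdiff(.wt_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop(
      "weight table schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra_cols <- setdiff(names(raw), .wt_columns)
  if (length(extra_cols) > 0L) {
    stop(
      "weight table schema error: unknown column(s) ",
      paste(extra_cols, collapse = ", "),
      call. = FALSE
    )
  }

  tab <- raw[, .wt_columns]
  blank <- function(x) !nzchar(trimws(x))

  # numeric conversion with per-line diagnostics (line numbers include the
  # header, matching what an editor shows)
  for (col in paste0("beta_", unname(.bm_suffix))) {
    vals <- trimws(tab[[col]])
    num <- suppressWarnings(as.numeric(vals))
    bad <- !blank(vals) & is.na(num)
    if (any(bad)) {
      stop(
        "weight table parse error: non-numeric value '",
        vals[which(bad)[1L]], "' in column ", col,
        " at line ", which(bad)[1L] + 1L,
        call. = FALSE
      )
    }
    num[blank(vals)] <- NA_real_
    tab[[col]] <- num
  }

  for (col in paste0("risk_allele_", unname(.bm_suffix))) {
    vals <- trimws(tab[[col]])
    vals[blank(vals)] <- NA_character_
    bad <- !is.na(vals) & !vals %in% c("A", "C", "G", "T")
    if (any(bad)) {
      stop(
        "weight table parse error: invalid allele '", vals[which(bad)[1L]],
        "' in column ", col, " at line ", which(bad)[1L] + 1L,
        call. = FALSE
      )
    }
    tab[[col]] <- vals
  }

  gt <- trimws(tab$genotyped)
  if (!all(gt %in% c("0", "1"))) {
    stop(
      "weight table parse error: `genotyped` must be 0 or 1 (line ",
      which(!gt %in% c("0", "1"))[1L] + 1L, ")",
      call. = FALSE
    )
  }
  tab$genotyped <- gt == "1"
  tab$snp_id <- trimws(tab$snp_id)

  dup <- duplicated(tab$snp_id)
  if (any(dup)) {
    stop(
      "weight table schema error: duplicate rsID(s) ",
      paste(unique(tab$snp_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }

  beta_mat <- as.matrix(tab[, paste0("beta_", unname(.bm_suffix))])
  if (any(!is.finite(beta_mat) & !is.na(beta_mat))) {
    stop("weight table schema error: non-finite effect estimate", call. = FALSE)
  }
  if (any(beta_mat == 0, na.rm = TRUE)) {
    stop("weight table schema error: zero effect estimate", call. = FALSE)
  }
  all_absent <- rowSums(!is.na(beta_mat)) == 0L
  if (any(all_absent)) {
    stop(
      "weight table schema error: SNP(s) with no effect estimate for any ",
      "biomarker: ", paste(tab$snp_id[all_absent], collapse = ", "),
      call. = FALSE
    )
  }
  # a risk allele must accompany every effect (and vice versa)
  for (bm in iron_biomarkers()) {
    sfx <- .bm_suffix[[bm]]
    has_beta <- !is.na(tab[[paste0("beta_", sfx)]])
    has_allele <- !is.na(tab[[paste0("risk_allele_", sfx)]])
    if (any(has_beta != has_allele)) {
      stop(
        "weight table schema error: risk allele and effect must be given ",
        "together for biomarker '", bm, "' (SNP ",
        tab$snp_id[which(has_beta != has_allele)[1L]], ")",
        call. = FALSE
      )
    }
  }

  rownames(tab) <- NULL
  class(tab) <- c("snp_weight_table", "data.frame")
  tab
}

#' The packaged 12-SNP iron weight table
#'
#' Loads the weight table shipped with the package: 12 SNPs associated at
#' genome-wide significance with at least one of the four iron biomarkers in
#' a large GWA meta-analysis, with their per-biomarker risk alleles and
#' effect estimates. rs8177240 carries two distinct risk alleles: T for
#' serum iron, G for transferrin and transferrin saturation.
#'
#' @return A `snp_weight_table` with 12 rows.
#' @export
iron_weight_table <- function() {
  load_weight_table(
    system.file("extdata", "iron_snp_weights.tsv",
      package = "ironmr", mustWork = TRUE
    )
  )
}

#' SNPs contributing to a biomarker's risk score
#'
#' @param table A `snp_weight_table`.
#' @param biomarker One of `"iron"`, `"ferritin"`, `"transferrin"`,
#'   `"transferrin_saturation"` (alias `"tsat"`).
#' @return rsIDs with a non-absent effect for that biomarker, in table order.
#' @export
select_snps_for_biomarker <- function(table, biomarker) {
  stopifnot(inherits(table, "snp_weight_table"))
  bm <- match_biomarker(biomarker)
  beta <- table[[paste0("beta_", .bm_suffix[[bm]])]]
  table$snp_id[!is.na(beta)]
}

# effect estimates for the selected SNPs (named numeric vector)
biomarker_effects <- function(table, biomarker) {
  bm <- match_biomarker(biomarker)
  snps <- select_snps_for_biomarker(table, bm)
  beta <- table[[paste0("beta_", .bm_suffix[[bm]])]]
  stats::setNames(beta[match(snps, table$snp_id)], snps)
}

# per-biomarker risk alleles for the selected SNPs (named character vector)
biomarker_risk_alleles <- function(table, biomarker) {
  bm <- match_biomarker(biomarker)
  snps <- select_snps_for_biomarker(table, bm)
  al <- table[[paste0("risk_allele_", .bm_suffix[[bm]])]]
  stats::setNames(al[match(snps, table$snp_id)], snps)
}

#' Default counted allele per SNP
#'
#' The allele a dosage matrix is taken to count when no explicit allele
#' metadata is supplied: the SNP's risk allele for the first biomarker (in
#' the order iron, ferritin, transferrin, transferrin saturation) with a
#' non-absent effect. For rs8177240 this is the iron risk allele (T);
#' scoring transferrin or transferrin saturation flips its dosages to count
#' the G allele.
#'
#' @param table A `snp_weight_table`.
#' @return Named character vector, one allele per SNP in table order.
#' @export
default_counted_alleles <- function(table) {
  stopifnot(inherits(table, "snp_weight_table"))
  out <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    for (bm in iron_biomarkers()) {
      al <- table[[paste0("risk_allele_", .bm_suffix[[bm]])]][i]
      if (!is.na(al)) {
        out[i] <- al
        break
      }
    }
  }
  stats::setNames(out, table$snp_id)
}

#' @export
print.snp_weight_table <- function(x, ...) {
  counts <- vapply(
    iron_biomarkers(),
    function(bm) length(select_snps_for_biomarker(x, bm)),
    integer(1)
  )
  cat(
    "<snp_weight_table> ", nrow(x), " SNPs (",
    paste(paste0(names(counts), ": ", counts), collapse = ", "), ")\n",
    sep = ""
  )
  print.data.frame(x, ...)
  invisible(x)
}
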