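# Genotype container and file readers (VCF / TSV dosage matrix).

#' Construct a genotype matrix
#'
#' Holds risk-allele dosages (real values in \[0, 2\], `NA` allowed) for a set
#' of individuals at a set of SNPs, together with the counted allele per SNP
#' (the allele the dosage counts copies of).
#'
#' @param dosage Numeric matrix, individuals in rows (rownames = individual
#'   ids), SNPs in columns (colnames = rsIDs).
#' @param counted_alleles Named character vector giving, for each SNP, the
#'   counted allele; `NA` means unknown (dosages are then assumed already
#'   oriented to whatever risk allele a downstream scorer asks for).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, counted_alleles = NULL) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop("`dosage` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(dosage)) || is.null(rownames(dosage))) {
    stop("`dosage` must have individual ids as rownames and rsIDs as colnames",
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(dosage))) {
    stop("duplicate rsIDs in dosage matrix", call. = FALSE)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(counted_alleles)) {
    counted_alleles <- stats::setNames(
      rep(NA_character_, ncol(dosage)), colnames(dosage)
    )
  } else {
    if (is.null(names(counted_alleles)) ||
      !all(colnames(dosage) %in% names(counted_alleles))) {
      stop("`counted_alleles` must be named by rsID and cover every SNP",
        call. = FALSE
      )
    }
    counted_alleles <- counted_alleles[colnames(dosage)]
  }
  structure(
    list(dosage = dosage, counted_alleles = counted_alleles),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix> ", nrow(x$dosage), " individuals x ",
    ncol(x$dosage), " SNPs\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from VCF or a TSV dosage matrix
#'
#' For VCF input, dosages are taken from the `DS` FORMAT field when present
#' and otherwise from `GT` (count of ALT alleles; `.` calls become `NA`).
#' Multiallelic records are rejected.  Each SNP's dosages are re-oriented so
#' they count the SNP's default risk allele (see
#' [default_counted_alleles()]): if the ALT allele matches it the dosage is
#' kept, if the REF allele matches it the dosage is flipped to `2 - d` (with
#' a message), and any other allele pair is an error.
#'
#' TSV input is a tab-separated matrix with a leading `individual_id` column
#' and one column per rsID; values are assumed to already count the default
#' risk alleles.
#'
#' @param path Input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param weight_table A `snp_weight_table` used to resolve rsIDs and risk
#'   alleles.
#' @param require_all Error if any weight-table SNP is absent (default TRUE).
#' @return A `genotype_matrix` oriented to the default counted alleles.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           weight_table = iron_weight_table(),
                           require_all = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (!file.exists(path)) {
    stop("genotype file not found: ", path, call. = FALSE)
  }
  gm <- switch(format,
    vcf = read_genotypes_vcf(path, weight_table),
    tsv = read_genotypes_tsv(path, weight_table)
  )
  wanted <- weight_table$snp_id
  missing <- setdiff(wanted, colnames(gm$dosage))
  if (require_all && length(missing) > 0L) {
    stop(
      "required SNP(s) missing from genotype data: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  gm
}

read_genotypes_vcf <- function(path, weight_table) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  keep <- ids %in% weight_table$snp_id
  if (!any(keep)) {
    stop("no weight-table SNPs found in VCF ", path, call. = FALSE)
  }
  multi <- keep & grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop(
      "multiallelic record(s) not supported: ",
      paste(ids[multi], collapse = ", "),
      call. = FALSE
    )
  }

  fmt <- vcf@gt[, 1L]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt[keep]))
  if (has_ds) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    # count ALT alleles; any missing allele call yields NA
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) {
        return(NA_real_)
      }
      al <- strsplit(g, "[/|]")[[1L]]
      if (any(al == ".")) {
        return(NA_real_)
      }
      sum(al != "0")
    })
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- ids[keep]
  dosage <- t(d) # individuals x SNPs

  target <- default_counted_alleles(weight_table)[colnames(dosage)]
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  for (j in seq_along(target)) {
    snp <- colnames(dosage)[j]
    if (identical(alt[j], target[[j]])) {
      next
    }
    if (identical(ref[j], target[[j]])) {
      message(
        "flipping dosage orientation for ", snp,
        " (counted allele ", alt[j], " -> ", target[[j]], ")"
      )
      dosage[, j] <- 2 - dosage[, j]
    } else {
      stop(
        "allele mismatch for ", snp, ": VCF has REF=", ref[j],
        "/ALT=", alt[j], " but the weight table expects risk allele ",
        target[[j]],
        call. = FALSE
      )
    }
  }
  genotype_matrix(dosage, counted_alleles = target)
}

read_genotypes_tsv <- function(path, weight_table) {
  tab <- read_tsv(path)
  if (names(tab)[1L] != "individual_id") {
    stop("dosage TSV must start with an `individual_id` column", call. = FALSE)
  }
  ids <- as.character(tab$individual_id)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  counted <- default_counted_alleles(weight_table)
  counted <- counted[intersect(colnames(m), names(counted))]
  full <- stats::setNames(rep(NA_character_, ncol(m)), colnames(m))
  full[names(counted)] <- counted
  genotype_matrix(m, counted_alleles = full)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of the TSV branch of [read_genotypes()]: a tab-separated dosage
#' matrix with a leading `individual_id` column and `.` for missing.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  out <- data.frame(
    individual_id = rownames(genotypes$dosage),
    genotypes$dosage,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}
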