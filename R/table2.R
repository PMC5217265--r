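# md5 of the packaged fixture; guards against accidental edits
TABLE2_MD5 <- "ca19f678c81d32d97310bad23caa7800"

#' Load the packaged validated-loci fixture
#'
#' The package ships a transcription of the published table of loci validated
#' or replicated by individual TaqMan genotyping for the two cholangitides
#' (57 SNPs; GRCh37 positions; ORs are for minor alleles). The fixture is
#' data for bookkeeping checks, not ground truth for the statistics engine.
#' An md5 checksum guards against accidental edits.
#'
#' P-value columns accept both plain scientific notation (`1.53E-7`) and the
#' typeset form (`1.5 × 10−7`).
#'
#' @param path override the packaged file (checksum then skipped).
#' @return A `table2_fixture` data.frame: `locus`, `snp_id`, `position`,
#'   `location` (promoter/intron/intergenic/coding), `genes`, `pbc_p`,
#'   `pbc_or`, `psc_p`, `psc_or`, `minor_allele`, `maf`.
#' @export
load_table2 <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "table2.tsv", package = "pooledscan")
    if (!nzchar(path)) stop("packaged table2 fixture not found")
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, TABLE2_MD5))
      stop("table2 fixture checksum mismatch: file was modified (",
           sum, " != ", TABLE2_MD5, ")")
  }
  df <- utils::read.delim(path, na.strings = ".", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(pbc_p = "character",
                                         psc_p = "character"))
  for (col in c("pbc_p", "psc_p")) df[[col]] <- parse_pvalue(df[[col]])
  stopifnot(is.integer(df$position) || is.numeric(df$position),
            !any(is.na(df$position)))
  if (any(is.na(df$pbc_p) & is.na(df$psc_p)))
    stop("fixture row with neither disease column populated")
  class(df) <- c("table2_fixture", "data.frame")
  df
}

#' Parse p-values in plain or typeset scientific notation
#'
#' Accepts `"1.53E-7"`, `"7E-05"`, `"0.0023"`, and the typeset style
#' `"1.5 × 10−7"` (multiplication sign or `x`, Unicode or ASCII minus).
#'
#' @param x character vector.
#' @return Numeric vector.
#' @export
parse_pvalue <- function(x) {
  x <- gsub("−", "-", x)                       # Unicode minus
  x <- gsub("\\s*[×x]\\s*10\\^?", "e", x)      # "1.5 × 10-7" -> "1.5e-7"
  as.numeric(x)
}

#' Bookkeeping summary of the validated-loci fixture
#'
#' Recomputes the published bookkeeping counts from the fixture: total SNPs, distinct
#' locus labels, SNPs with only PBC columns, only PSC columns, or both, and
#' a per-locus breakdown (notably the MHC locus 6p21).
#'
#' @param fixture a `table2_fixture` from [load_table2()].
#' @return A list of class `table2_summary` with `total_snps`,
#'   `distinct_loci`, `pbc_only`, `psc_only`, `shared`,
#'   `shared_same_direction`, and `by_locus` (data.frame `locus`, `n`,
#'   `pbc_only`, `psc_only`, `both`).
#' @export
summarize_table2 <- function(fixture) {
  stopifnot(inherits(fixture, "table2_fixture"))
  has_pbc <- !is.na(fixture$pbc_p)
  has_psc <- !is.na(fixture$psc_p)
  both <- has_pbc & has_psc
  same_dir <- both & sign(log(fixture$pbc_or)) == sign(log(fixture$psc_or)) &
    fixture$pbc_or != 1 & fixture$psc_or != 1
  by_locus <- do.call(rbind, lapply(unique(fixture$locus), function(l) {
    sel <- fixture$locus == l
    data.frame(locus = l, n = sum(sel),
               pbc_only = sum(sel & has_pbc & !has_psc),
               psc_only = sum(sel & !has_pbc & has_psc),
               both = sum(sel & both), stringsAsFactors = FALSE)
  }))
  structure(list(total_snps = nrow(fixture),
                 distinct_loci = length(unique(fixture$locus)),
                 pbc_only = sum(has_pbc & !has_psc),
                 psc_only = sum(!has_pbc & has_psc),
                 shared = sum(both),
                 shared_same_direction = sum(same_dir),
                 by_locus = by_locus),
            class = "table2_summary")
}

#' @export
#' @method print table2_summary
print.table2_summary <- function(x, ...) {
  cat(sprintf(paste0("validated/replicated loci: %d SNPs, %d locus labels\n",
                     "  PBC only %d | PSC only %d | shared %d ",
                     "(same direction %d)\n"),
              x$total_snps, x$distinct_loci, x$pbc_only, x$psc_only,
              x$shared, x$shared_same_direction))
  invisible(x)
}
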