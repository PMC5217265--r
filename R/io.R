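# TSV dialect used throughout: UTF-8, tab-separated, '.' for missing,
# mandatory headers, no quoting.
write_tsv0 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv0 <- function(path, ...) {
  utils::read.delim(path, na.strings = ".", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write a genotype table as TSV
#'
#' Emits two files: the genotype matrix (`snp_id`, `chrom`, `pos`, `alleles`,
#' then one minor-allele dosage column per individual) and a sample sheet
#' (`id`, `group`) at `sample_path`, since the matrix alone does not carry
#' phenotype labels.
#'
#' @param gt a `genotype_table`.
#' @param path output TSV for the matrix.
#' @param sample_path output TSV for the sample sheet
#'   (default `<path>.samples.tsv`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path,
                            sample_path = paste0(path, ".samples.tsv")) {
  p <- gt$panel
  df <- data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos,
                   alleles = paste0(p$allele_a, "/", p$allele_b),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(t(gt$genotypes), check.names = FALSE))
  write_tsv0(df, path)
  write_tsv0(gt$individuals, sample_path)
  invisible(path)
}

#' Read a genotype table written by [write_genotypes()]
#'
#' @param path genotype matrix TSV.
#' @param sample_path sample sheet TSV (default `<path>.samples.tsv`).
#' @param maf optional per-SNP MAF to restore in the panel (the TSV does not
#'   carry simulation MAFs); defaults to the observed frequency.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path, sample_path = paste0(path, ".samples.tsv"),
                           maf = NULL) {
  df <- read_tsv0(path)
  samples <- read_tsv0(sample_path)
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  geno <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(colnames(df)[-(1:4)], df$snp_id)
  geno <- geno[samples$id, , drop = FALSE]
  obs <- colMeans(geno, na.rm = TRUE) / 2
  panel <- snp_panel(df$snp_id, df$chrom, df$pos,
                     allele_a = vapply(al, `[`, "", 1L),
                     allele_b = vapply(al, `[`, "", 2L),
                     maf = if (is.null(maf)) pmin(obs, 0.5) else maf)
  structure(list(individuals = samples, genotypes = geno, panel = panel),
            class = "genotype_table")
}

#' Write genotypes as a minimal VCF 4.2
#'
#' One record per SNP with `REF = allele_a`, `ALT = allele_b` (the
#' dosage-counted minor allele) and unphased `GT` fields (`./.` for missing).
#'
#' @param gt a `genotype_table`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  p <- gt$panel
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pooledscan",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$individuals$id),
                     collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  g <- gt$genotypes  # individuals x snps
  body <- vapply(seq_len(nrow(p)), function(j) {
    codes <- gtcode[g[, j] + 1L]
    codes[is.na(codes)] <- "./."
    paste(c(p$chrom[j], p$pos[j], p$snp_id[j], p$allele_a[j], p$allele_b[j],
            ".", "PASS", ".", "GT", codes), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses with `vcfR` and converts `GT` fields to minor-allele (ALT) dosages.
#'
#' @param path VCF file.
#' @param samples data.frame `id`, `group` assigning phenotype labels;
#'   defaults to all VCF samples with group `NA`.
#' @return A `genotype_table`.
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtf <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gtf), ncol(gtf), dimnames = dimnames(gtf))
  clean <- gsub("\\|", "/", gtf)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  if (is.null(samples))
    samples <- data.frame(id = colnames(gtf), group = NA_character_,
                          stringsAsFactors = FALSE)
  geno <- t(dos)[samples$id, , drop = FALSE]
  colnames(geno) <- fix[, "ID"]
  obs <- colMeans(geno, na.rm = TRUE) / 2
  panel <- snp_panel(fix[, "ID"], fix[, "CHROM"], as.integer(fix[, "POS"]),
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     maf = pmin(obs, 0.5))
  structure(list(individuals = samples, genotypes = geno, panel = panel),
            class = "genotype_table")
}

#' Write pooled two-channel intensities as TSV
#'
#' Columns: `pool_id`, `group`, `set_id`, then paired `<snp>.A`, `<snp>.B`
#' columns.
#'
#' @param intensities an `intensity_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(intensities, path) {
  a <- intensities$channel_a; b <- intensities$channel_b
  m <- ncol(a)
  ab <- matrix(NA_real_, nrow(a), 2L * m)
  ab[, seq(1L, 2L * m, by = 2L)] <- a
  ab[, seq(2L, 2L * m, by = 2L)] <- b
  colnames(ab) <- as.vector(rbind(paste0(colnames(a), ".A"),
                                  paste0(colnames(a), ".B")))
  write_tsv0(cbind(intensities$pools, as.data.frame(ab, check.names = FALSE)),
             path)
}

#' Read pooled intensities written by [write_intensities()]
#'
#' @param path TSV file.
#' @param panel optional `snp_panel` to attach (for positions downstream).
#' @return An `intensity_table`.
#' @export
read_intensities <- function(path, panel = NULL) {
  df <- read_tsv0(path)
  pools <- df[c("pool_id", "group", "set_id")]
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  nm <- colnames(vals)
  acol <- grepl("\\.A$", nm)
  snps <- sub("\\.A$", "", nm[acol])
  a <- vals[, acol, drop = FALSE]
  b <- vals[, !acol, drop = FALSE]
  dimnames(a) <- dimnames(b) <- list(pools$pool_id, snps)
  structure(list(pools = pools, channel_a = a, channel_b = b, panel = panel),
            class = "intensity_table")
}

#' Write / read a RAS matrix as TSV
#'
#' Layout: `pool_id`, `group`, `set_id`, then one RAS column per SNP.
#'
#' @param ras a `ras_matrix`.
#' @param path TSV path.
#' @return `path` ([write_ras()]) or a `ras_matrix` ([read_ras()]).
#' @export
write_ras <- function(ras, path) {
  write_tsv0(cbind(ras$pools,
                   as.data.frame(ras$values, check.names = FALSE)), path)
}

#' @rdname write_ras
#' @param panel optional `snp_panel` to attach as the SNP index.
#' @export
read_ras <- function(path, panel = NULL) {
  df <- read_tsv0(path)
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(vals) <- df$pool_id
  structure(list(pools = df[c("pool_id", "group", "set_id")],
                 values = vals, snp_index = panel),
            missing_by_snp = colSums(is.na(vals)),
            class = "ras_matrix")
}

#' Write / read a scan result table
#'
#' @param results a `scan_result`.
#' @param path TSV path.
#' @export
write_scan <- function(results, path) write_tsv0(results, path)

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- read_tsv0(path)
  df$skipped <- as.logical(df$skipped)
  class(df) <- c("scan_result", "data.frame")
  df
}

#' Write blocks as BED plus a member detail table
#'
#' BED intervals are 0-based half-open, converted from the 1-based member
#' positions (`start = start_pos - 1`, `end = end_pos`), so
#' `end - start = (end_pos - start_pos) + 1`.
#'
#' @param blocks a `block_list` (after [select_index_snps()] if index flags
#'   are wanted).
#' @param bed_path BED output path.
#' @param members_path detail TSV (`block`, `chrom`, `snp_id`, `pos`,
#'   `p_value`, `is_index`, `index_rank`).
#' @return `bed_path`, invisibly.
#' @export
write_blocks <- function(blocks, bed_path, members_path = NULL) {
  bed <- data.frame(
    chrom = vapply(blocks, `[[`, "", "chrom"),
    start = vapply(blocks, function(b) b$start_pos - 1L, 0),
    end = vapply(blocks, `[[`, 0, "end_pos"),
    name = sprintf("block_%03d", seq_along(blocks)))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(members_path)) {
    mem <- do.call(rbind, lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      df <- b$members
      idx <- if (is.null(b$index_snps)) character() else b$index_snps$snp_id
      rk <- if (is.null(b$index_snps)) integer() else b$index_snps$rank
      data.frame(block = sprintf("block_%03d", i), chrom = b$chrom,
                 snp_id = df$snp_id, pos = df$pos, p_value = df$p_value,
                 is_index = df$snp_id %in% idx,
                 index_rank = rk[match(df$snp_id, idx)],
                 stringsAsFactors = FALSE)
    }))
    write_tsv0(mem, members_path)
  }
  invisible(bed_path)
}

#' Write / read a candidate set with round provenance
#'
#' @param candidates a `candidate_set`.
#' @param path TSV path.
#' @export
write_candidates <- function(candidates, path) {
  df <- as.data.frame(candidates)
  df$disease <- rep_len(attr(candidates, "disease"), nrow(df))
  write_tsv0(df, path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- read_tsv0(path)
  disease <- unique(df$disease)
  df$disease <- NULL
  rounds <- sub("^best_p_", "", grep("^best_p_", names(df), value = TRUE))
  structure(df, disease = disease, rounds = rounds,
            class = c("candidate_set", "data.frame"))
}

#' Write a validation result table
#'
#' @param recs a `validation_result`.
#' @param path TSV path.
#' @export
write_validation <- function(recs, path) write_tsv0(recs, path)

#' Write / read a run configuration (YAML)
#'
#' A `run_config` is a plain named list of stage parameters (criteria,
#' thresholds, seeds, paths) that round-trips through its file form without
#' loss.
#'
#' @param config named list.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Build a simulation spec from a config list or YAML file
#'
#' Recognised fields: `n_cases`, `n_controls`, `seed`, `noise_sd`,
#' `ld_block_length`, `ld_r`, `case_label`, `control_label`; `panel` (either
#' `file:` a panel TSV with the [snp_panel()] columns, or `n_snps`,
#' `chrom`, `spacing_bp`, `maf_range`, `seed` for [random_panel()]);
#' `effect_loci` (list of `snp_id`, `odds_ratio`, `disease`); `pool_sets`
#' (list of `set_id`, `pool_size`, `pools_per_group`).
#'
#' @param config named list or path to a YAML file.
#' @return A [sim_spec()].
#' @export
sim_spec_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  pc <- config$panel
  panel <- if (!is.null(pc$file)) validate_snp_panel(read_tsv0(pc$file))
    else random_panel(pc$n_snps,
                      chrom = if (is.null(pc$chrom)) "1" else pc$chrom,
                      spacing_bp = if (is.null(pc$spacing_bp)) 5000L
                                   else pc$spacing_bp,
                      maf_range = if (is.null(pc$maf_range)) c(0.05, 0.5)
                                  else unlist(pc$maf_range),
                      seed = if (is.null(pc$seed)) config$seed else pc$seed)
  eff <- NULL
  if (length(config$effect_loci))
    eff <- effect_loci(
      snp_id = vapply(config$effect_loci, `[[`, "", "snp_id"),
      odds_ratio = vapply(config$effect_loci, `[[`, 0, "odds_ratio"),
      disease = vapply(config$effect_loci, function(e)
        if (is.null(e$disease)) {
          if (is.null(config$case_label)) "CASE" else config$case_label
        } else e$disease, ""))
  sets <- lapply(config$pool_sets, function(ps)
    pool_set(ps$set_id, unlist(ps$pool_size), unlist(ps$pools_per_group)))
  arg <- list(n_cases = config$n_cases, n_controls = config$n_controls,
              panel = panel,
              effects = eff, pool_sets = sets)
  for (f in c("ld_block_length", "ld_r", "noise_sd", "seed",
              "case_label", "control_label"))
    if (!is.null(config[[f]])) arg[[f]] <- config[[f]]
  do.call(sim_spec, arg)
}

#' Serialise a simulation spec to a config list
#'
#' Inverse of [sim_spec_from_config()] up to the panel, which is written to
#' `panel_file` and referenced. Every simulation run should write this next
#' to its outputs so the study is reproducible from files alone.
#'
#' @param spec a [sim_spec()].
#' @param panel_file where to write the panel TSV (referenced from the
#'   config); `NULL` to omit.
#' @return A named list suitable for [write_config()].
#' @export
sim_spec_to_config <- function(spec, panel_file = NULL) {
  if (!is.null(panel_file)) write_tsv0(as.data.frame(spec$panel), panel_file)
  list(n_cases = spec$n_cases, n_controls = spec$n_controls,
       case_label = spec$case_label, control_label = spec$control_label,
       ld_block_length = spec$ld_block_length, ld_r = spec$ld_r,
       noise_sd = spec$noise_sd, seed = spec$seed,
       panel = list(file = panel_file),
       effect_loci = if (is.null(spec$effects)) list() else
         lapply(seq_len(nrow(spec$effects)), function(i)
           list(snp_id = spec$effects$snp_id[i],
                odds_ratio = spec$effects$odds_ratio[i],
                disease = spec$effects$disease[i])),
       pool_sets = lapply(spec$pool_sets, function(ps)
         list(set_id = ps$set_id, pool_size = as.list(ps$pool_size),
              pools_per_group = as.list(ps$pools_per_group))))
}
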