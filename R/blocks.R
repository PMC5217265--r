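#' Block and index-SNP selection criteria
#'
#' Candidate loci are maximal runs of at least `min_snps` consecutive SNPs,
#' each associated at `p < p_block`, with strictly less than `max_gap_bp`
#' between adjacent members; "index SNPs" are block members below the
#' stricter `p_index`. Defaults are the published criteria (>= 10 SNPs,
#' < 30 kb, p < 0.005, index p < 1e-4), read as strict inequalities.
#'
#' @param min_snps minimum block size (>= 2).
#' @param max_gap_bp maximum adjacent-SNP gap in bp (strict).
#' @param p_block per-SNP association threshold (strict).
#' @param p_index index-SNP threshold (strict by default).
#' @param inclusive_index use `p <= p_index` instead of `<`.
#' @return A list of class `block_criteria`.
#' @export
block_criteria <- function(min_snps = 10L, max_gap_bp = 30000L,
                           p_block = 0.005, p_index = 1e-4,
                           inclusive_index = FALSE) {
  stopifnot(min_snps >= 2, max_gap_bp > 0,
            p_index > 0, p_index <= p_block, p_block < 1)
  structure(list(min_snps = as.integer(min_snps),
                 max_gap_bp = as.integer(max_gap_bp),
                 p_block = p_block, p_index = p_index,
                 inclusive_index = inclusive_index),
            class = "block_criteria")
}

#' Find maximal runs of associated, tightly spaced SNPs
#'
#' Scans a genome-ordered p-value track for the maximal runs of consecutive
#' qualifying SNPs (`p < p_block`) whose successive gaps are all below
#' `max_gap_bp` and whose length reaches `min_snps`. A non-qualifying SNP
#' terminates a run even if physically close (set `bridge = TRUE` to instead
#' skip non-qualifying SNPs and chain qualifying ones by distance alone, for
#' sensitivity analysis). Blocks never span chromosomes.
#'
#' The track must arrive sorted by chromosome and strictly increasing
#' position; unsorted input or duplicate positions raise an error rather than
#' being silently reordered.
#'
#' @param track data.frame with `chrom`, `pos`, `snp_id`, and `p_value`
#'   (or `p`).
#' @param criteria a [block_criteria()].
#' @param bridge logical, see above (default `FALSE`).
#' @return A `block_list`: list of blocks, each with `chrom`, `start_pos`,
#'   `end_pos`, `members` (data.frame `snp_id`, `pos`, `p_value`) and an
#'   `index_snps` slot filled by [select_index_snps()]. Sorted by
#'   `(chrom, start_pos)`.
#' @export
find_blocks <- function(track, criteria = block_criteria(), bridge = FALSE) {
  stopifnot(inherits(criteria, "block_criteria"))
  if (!"p_value" %in% names(track) && "p" %in% names(track))
    track$p_value <- track$p
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(track)))
  if (!"snp_id" %in% names(track))
    track$snp_id <- sprintf("snp%06d", seq_len(nrow(track)))
  if (any(track$p_value < 0 | track$p_value > 1, na.rm = TRUE))
    stop("p_values must lie in [0, 1]")
  ch <- as.character(track$chrom)
  chrom_runs <- rle(ch)$values
  if (anyDuplicated(chrom_runs))
    stop("track is not sorted: chromosome blocks are interleaved")
  blocks <- list()
  for (cc in chrom_runs) {
    sel <- which(ch == cc)
    pos <- track$pos[sel]
    if (any(diff(pos) == 0)) stop("duplicate positions on chromosome ", cc)
    if (any(diff(pos) < 0))
      stop("track is not sorted by position on chromosome ", cc,
           " (no silent sorting)")
    p <- track$p_value[sel]
    q <- which(!is.na(p) & p < criteria$p_block)
    if (!length(q)) next
    gap_break <- diff(pos[q]) >= criteria$max_gap_bp
    new_run <- if (bridge) c(TRUE, gap_break)
               else c(TRUE, diff(q) > 1L | gap_break)
    run_id <- cumsum(new_run)
    for (r in split(q, run_id)) {
      if (length(r) < criteria$min_snps) next
      idx <- sel[r]
      blocks[[length(blocks) + 1L]] <- structure(
        list(chrom = cc,
             start_pos = track$pos[idx[1L]],
             end_pos = track$pos[idx[length(idx)]],
             members = data.frame(snp_id = track$snp_id[idx],
                                  pos = track$pos[idx],
                                  p_value = track$p_value[idx],
                                  stringsAsFactors = FALSE),
             index_snps = NULL,
             flagged = NA),
        class = "snp_block")
    }
  }
  structure(blocks, class = "block_list")
}

#' @export
#' @method print block_list
print.block_list <- function(x, ...) {
  cat(sprintf("block_list: %d block(s)\n", length(x)))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
#' @method as.data.frame block_list
as.data.frame.block_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(block = integer(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), min_p = numeric(),
                      n_index = integer()))
  data.frame(block = seq_along(x),
             chrom = vapply(x, `[[`, "", "chrom"),
             start_pos = vapply(x, `[[`, 0, "start_pos"),
             end_pos = vapply(x, `[[`, 0, "end_pos"),
             n_snps = vapply(x, function(b) nrow(b$members), 0L),
             min_p = vapply(x, function(b) min(b$members$p_value), 0),
             n_index = vapply(x, function(b)
               if (is.null(b$index_snps)) NA_integer_ else
                 nrow(b$index_snps), 0L))
}

#' Choose index SNPs within blocks
#'
#' Marks every block member below `p_index` as an index SNP, ranked by
#' ascending p-value (rank 1 = smallest); a block may legitimately yield more
#' than one index SNP. Blocks with no member below the threshold are retained
#' with an empty index set and flagged.
#'
#' @param blocks a `block_list` from [find_blocks()].
#' @param criteria the [block_criteria()] (uses `p_index`,
#'   `inclusive_index`).
#' @param max_per_block optional cap on index SNPs per block
#'   (default unlimited).
#' @return The `block_list` with `index_snps` (data.frame `snp_id`, `pos`,
#'   `p_value`, `rank`) and `flagged` filled in.
#' @export
select_index_snps <- function(blocks, criteria = block_criteria(),
                              max_per_block = Inf) {
  stopifnot(inherits(blocks, "block_list"))
  for (i in seq_along(blocks)) {
    mem <- blocks[[i]]$members
    hit <- if (criteria$inclusive_index) mem$p_value <= criteria$p_index
           else mem$p_value < criteria$p_index
    sel <- mem[hit, , drop = FALSE]
    sel <- sel[order(sel$p_value, sel$pos), , drop = FALSE]
    if (nrow(sel) > max_per_block) sel <- sel[seq_len(max_per_block), ,
                                              drop = FALSE]
    sel$rank <- seq_len(nrow(sel))
    rownames(sel) <- NULL
    blocks[[i]]$index_snps <- sel
    blocks[[i]]$flagged <- nrow(sel) == 0L
  }
  blocks
}

#' Collect a round's index SNPs into a candidate set
#'
#' @param blocks a `block_list` after [select_index_snps()].
#' @param disease disease label the scan belongs to.
#' @param round round label (e.g. `"I"` or `"II"`).
#' @return A `candidate_set` data.frame: `snp_id`, `block_ref`
#'   (`chrom:start-end`), `rounds_found`, and one `best_p_<round>` column.
#' @export
candidates_from_blocks <- function(blocks, disease, round = "I") {
  rows <- list()
  for (b in blocks) {
    if (is.null(b$index_snps) || !nrow(b$index_snps)) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = b$index_snps$snp_id,
      block_ref = sprintf("%s:%d-%d", b$chrom, b$start_pos, b$end_pos),
      rounds_found = round,
      p = b$index_snps$p_value,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), block_ref = character(),
               rounds_found = character(), p = numeric(),
               stringsAsFactors = FALSE)
  names(df)[names(df) == "p"] <- paste0("best_p_", round)
  df <- df[!duplicated(df$snp_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, disease = disease, rounds = round,
            class = c("candidate_set", "data.frame"))
}

#' Merge the candidate sets of two GWAS rounds
#'
#' Union keyed by `snp_id`; `rounds_found` and the per-round best p-values
#' record provenance. The union size is `|r1| + |r2| - |r1 intersect r2|`.
#'
#' @param round1,round2 `candidate_set`s for the same disease.
#' @return The merged `candidate_set`.
#' @export
merge_rounds <- function(round1, round2) {
  d1 <- attr(round1, "disease"); d2 <- attr(round2, "disease")
  if (!identical(d1, d2))
    stop("cannot merge candidate sets for different diseases: ",
         d1, " vs ", d2)
  r1 <- attr(round1, "rounds"); r2 <- attr(round2, "rounds")
  p1 <- paste0("best_p_", r1); p2 <- paste0("best_p_", r2)
  a <- as.data.frame(round1); b <- as.data.frame(round2)
  if (!nrow(b)) mg <- a else if (!nrow(a)) mg <- b else {
    mg <- merge(a[c("snp_id", "block_ref", p1)],
                b[c("snp_id", "block_ref", p2)],
                by = "snp_id", all = TRUE, suffixes = c("", ".r2"))
    in1 <- !is.na(mg[[p1]]); in2 <- !is.na(mg[[p2]])
    mg$rounds_found <- ifelse(in1 & in2, paste(r1, r2, sep = ","),
                              ifelse(in1, r1, r2))
    mg$block_ref <- ifelse(is.na(mg$block_ref), mg$block_ref.r2,
                           mg$block_ref)
    mg$block_ref.r2 <- NULL
    mg <- mg[c("snp_id", "block_ref", "rounds_found", p1, p2)]
  }
  rownames(mg) <- NULL
  structure(mg, disease = d1, rounds = unique(c(r1, r2)),
            class = c("candidate_set", "data.frame"))
}

#' Best validation-facing p-value per candidate
#'
#' @param candidates a `candidate_set`.
#' @return Numeric vector: the minimum per-round best p of each candidate.
#' @export
candidate_best_p <- function(candidates) {
  pc <- grep("^best_p_", names(candidates), value = TRUE)
  apply(as.data.frame(candidates)[pc], 1L, min, na.rm = TRUE)
}
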