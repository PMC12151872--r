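# Chromatin-state segments and promoter-state assignment.
# Conventions (enforced, not merely assumed): BED is 0-based, half-open
# [start, end); TSS tables are 1-based.  A gene's promoter window is the
# symmetric interval TSS +/- `window` bp, so strand changes bookkeeping
# only, not the window.

#' Read BED4 chromatin-state segments
#'
#' Four tab-separated columns, no header: `chrom`, `start`, `end`,
#' `state` with 0-based half-open coordinates (`chr1 100 200 active`
#' covers positions 100..199 in 0-based terms).
#'
#' @param path File path.
#' @return A [GenomicRanges::GRanges] (1-based internally) with a
#'   `state` metadata column; empty file gives an empty GRanges.
#' @export
read_bed_states <- function(path) {
  if (!file.exists(path))
    stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(state = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L)
      stop_schema(sprintf("%s: line %d: expected 4 BED columns", path, i))
    s <- suppressWarnings(as.integer(p[2]))
    e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e))
      stop_schema(sprintf("%s: line %d: start/end must be integers", path, i))
    if (s < 0)
      stop_schema(sprintf("%s: line %d: start must be >= 0", path, i))
    if (s >= e)
      stop_schema(sprintf("%s: line %d: start (%d) must be < end (%d)",
                          path, i, s, e))
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- vapply(parts, function(p) as.integer(p[2]), 0L)
  end0 <- vapply(parts, function(p) as.integer(p[3]), 0L)
  state <- vapply(parts, `[[`, "", 4L)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    state = state)
}

#' Label gene promoters active/inactive from chromatin-state segments
#'
#' Each gene's promoter window is TSS +/- `window` bp (TSS is 1-based).
#' A gene is labelled `active` when any overlapping segment carries the
#' active state, `inactive` when it overlaps only non-active segments,
#' and `NA` when no segment overlaps its window.
#'
#' @param states GRanges from [read_bed_states()].
#' @param tss Data frame `gene_id`, `chrom`, `tss`, `strand` (see
#'   [read_tss_table()]).
#' @param window Half-width of the promoter window in bp (default 1000).
#' @param active_state The segment state meaning "active" (default
#'   `"active"`).
#' @return Data frame `gene_id`, `state` (`NA` for unannotated genes).
#' @export
promoter_states_from_bed <- function(states, tss, window = 1000,
                                     active_state = "active") {
  if (!methods::is(states, "GRanges"))
    stop_input("`states` must be a GRanges from read_bed_states()")
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!is.data.frame(tss) || !all(req %in% names(tss)))
    stop_input("`tss` needs columns gene_id, chrom, tss, strand")
  check_number(window, "window", lower = 0)
  win <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, tss$tss - window),
                              end = tss$tss + window),
    strand = tss$strand)
  hits <- GenomicRanges::findOverlaps(win, states, ignore.strand = TRUE)
  seg_state <- S4Vectors::mcols(states)$state
  state <- rep(NA_character_, nrow(tss))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    active <- seg_state[S4Vectors::subjectHits(hits)] == active_state
    has_active <- tapply(active, qh, any)
    idx <- as.integer(names(has_active))
    state[idx] <- ifelse(has_active, "active", "inactive")
  }
  data.frame(gene_id = tss$gene_id, state = state, stringsAsFactors = FALSE)
}
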