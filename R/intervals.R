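# Interval arithmetic helpers. All internal coordinates are 0-based
# half-open; IRanges (1-based closed) is used behind these wrappers.

to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Merge possibly-overlapping intervals within each chromosome.
# `x` is a tibble with chrom/start/end; extra columns are dropped.
merge_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe({
      red <- IRanges::reduce(to_iranges(.data$start, .data$end))
      tibble::tibble(
        start = IRanges::start(red) - 1L,
        end = IRanges::end(red)
      )
    }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# For point positions, return a logical: does (chrom, pos) fall inside any
# interval of `ivs` (tibble chrom/start/end)?
points_in_intervals <- function(chrom, pos, ivs) {
  hit <- rep(FALSE, length(pos))
  if (nrow(ivs) == 0 || length(pos) == 0) return(hit)
  for (cc in unique(ivs$chrom)) {
    sel <- chrom == cc
    if (!any(sel)) next
    sub <- ivs[ivs$chrom == cc, ]
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    s <- to_iranges(sub$start, sub$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Overlap join of point positions against intervals carrying an id column.
# Returns tibble(point_idx, interval_idx).
points_overlap_join <- function(chrom, pos, ivs) {
  out <- vector("list", 0)
  for (cc in unique(ivs$chrom)) {
    sel <- which(chrom == cc)
    if (length(sel) == 0) next
    sub_idx <- which(ivs$chrom == cc)
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    s <- to_iranges(ivs$start[sub_idx], ivs$end[sub_idx])
    ov <- IRanges::findOverlaps(q, s)
    out[[length(out) + 1L]] <- tibble::tibble(
      point_idx = sel[S4Vectors_from(ov)],
      interval_idx = sub_idx[S4Vectors_to(ov)]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(point_idx = integer(), interval_idx = integer()))
  }
  dplyr::bind_rows(out)
}

# Minimal accessors so S4Vectors need not be attached.
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

# Do intervals a (chrom/start/end) overlap any interval in b?
intervals_overlap_any <- function(a, b) {
  hit <- rep(FALSE, nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(hit)
  for (cc in unique(b$chrom)) {
    sel <- a$chrom == cc
    if (!any(sel)) next
    sub <- b[b$chrom == cc, ]
    q <- to_iranges(a$start[sel], a$end[sel])
    s <- to_iranges(sub$start, sub$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}
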