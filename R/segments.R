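## Internal segment helpers. A segment is a length-2 integer vector c(start, end),
## 1-based inclusive, start <= end. Multiblocks are named lists of segments.

seg <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("segment start/end must be single non-missing integers")
  if (start < 1L) stop("segment start must be >= 1")
  if (end < start) stop("segment end must be >= start")
  c(start, end)
}

seg_len <- function(s) s[2] - s[1] + 1L

## intervals share at least one position
seg_overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

seg_before <- function(a, b) a[2] < b[1]

seg_contains <- function(outer, inner) outer[1] <= inner[1] && inner[2] <= outer[2]

seg_union <- function(a, b) {
  ## union of two overlapping or abutting intervals; NULL if disjoint with a gap
  if (!(seg_overlaps(a, b) || a[2] + 1L == b[1] || b[2] + 1L == a[1])) return(NULL)
  c(min(a[1], b[1]), max(a[2], b[2]))
}

## exon chains are data.frames with integer columns start, end
exon_chain <- function(start, end) {
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  if (any(is.na(df))) stop("exon coordinates must be integers")
  if (any(df$end < df$start)) stop("exon end before start")
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    stop("successive exons must satisfy end_i < start_{i+1}")
  df
}

chain_length <- function(chain) sum(chain$end - chain$start + 1L)

## all positions covered by a chain (small inputs only; used for validation)
chain_positions <- function(chain) {
  if (nrow(chain) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(chain)), function(i) chain$start[i]:chain$end[i]))
}
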